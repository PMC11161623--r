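#' Astronomical day length
#'
#' Hours of daylight for a given latitude and day of year, from the standard
#' solar-declination formula with a geometric (sun-centre) horizon and no
#' atmospheric refraction. Declination is approximated by a cosine of the day
#' of year, which is accurate to a few minutes of day length at temperate
#' latitudes.
#'
#' @param latitude_deg latitude in degrees, in (-66, 66); polar latitudes,
#'   where the sun may not rise or set, are rejected.
#' @param doy day of year (1--366); vectorised.
#' @return numeric vector of day lengths in hours.
#' @examples
#' day_length_h(35.1, 172) # near the June solstice
#' @export
day_length_h <- function(latitude_deg, doy) {
  stopifnot(is.numeric(latitude_deg), length(latitude_deg) == 1L)
  if (latitude_deg <= -66 || latitude_deg >= 66)
    stop("polar latitudes (|lat| >= 66) are not supported: no sunrise/sunset on some days")
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365.25) * pi / 180
  lat <- latitude_deg * pi / 180
  x <- pmin(1, pmax(-1, -tan(lat) * tan(decl)))
  24 / pi * acos(x)
}

#' Simulate a daily environment series
#'
#' Generates one row per day with photoperiod from the solar-declination day
#' length at the given latitude, a sinusoidal daily mean temperature lagging
#' the photoperiod by \code{temp_lag_d} days (plus optional Gaussian noise),
#' and a nonnegative sinusoidal solar radiation.
#'
#' @param latitude_deg site latitude in degrees, in (-66, 66).
#' @param start_date,end_date \code{Date} (or coercible) range, inclusive.
#' @param temp_mean_C,temp_amplitude_C annual mean and amplitude of daily mean
#'   temperature (deg C).
#' @param temp_lag_d days by which the temperature peak lags the photoperiod
#'   peak (the June solstice in the northern hemisphere).
#' @param temp_noise_sd_C standard deviation of additive daily temperature
#'   noise; 0 gives a noiseless sinusoid.
#' @param rad_mean,rad_amplitude mean and amplitude of daily solar radiation
#'   (arbitrary consistent units); negative values are truncated at 0.
#' @param seed optional integer seed for the temperature noise.
#' @return data.frame with columns \code{date}, \code{photoperiod_h},
#'   \code{temperature_C}, \code{radiation}; one row per day, no gaps.
#' @examples
#' env <- sim_environment(35.1, "2019-01-01", "2019-12-31")
#' range(env$photoperiod_h)
#' @export
sim_environment <- function(latitude_deg = 35.1, start_date, end_date,
                            temp_mean_C = 14, temp_amplitude_C = 11,
                            temp_lag_d = 45, temp_noise_sd_C = 0,
                            rad_mean = 14, rad_amplitude = 8, seed = NULL) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (end_date <= start_date) stop("end_date must be after start_date")
  dates <- seq(start_date, end_date, by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  pp <- day_length_h(latitude_deg, doy)
  # photoperiod peaks near doy 172 (N hemisphere); temperature lags it
  temp <- temp_mean_C + temp_amplitude_C * cos(2 * pi * (doy - 172 - temp_lag_d) / 365.25)
  if (temp_noise_sd_C > 0) {
    if (!is.null(seed)) set.seed(seed)
    temp <- temp + stats::rnorm(length(temp), 0, temp_noise_sd_C)
  }
  rad <- pmax(0, rad_mean + rad_amplitude * cos(2 * pi * (doy - 172) / 365.25))
  data.frame(date = dates, photoperiod_h = pp, temperature_C = temp,
             radiation = rad)
}
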