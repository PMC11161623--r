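# Delimited-text interchange for census tables and result tables.
# All files are UTF-8 CSV with a header row, ISO-8601 dates, and a leading
# comment line recording the simulation seed for provenance.

write_seeded_csv <- function(df, file, seed) {
  con <- file(file, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Write a leaf census to CSV files
#'
#' Writes \code{leaves.csv}, \code{lengths.csv} and \code{environment.csv}
#' into a directory, each with a \code{# seed:} provenance header line.
#'
#' @param census a \code{leaf_census}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_leaf_census <- function(census, dir) {
  stopifnot(inherits(census, "leaf_census"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- census$config$seed
  write_seeded_csv(census$leaves, file.path(dir, "leaves.csv"), s)
  if (!is.null(census$lengths))
    write_seeded_csv(census$lengths, file.path(dir, "lengths.csv"), s)
  write_seeded_csv(census$env, file.path(dir, "environment.csv"), s)
  invisible(dir)
}

#' Read a leaf census from CSV files
#'
#' Reads the files written by [write_leaf_census()] (or any ingested data in
#' the same schema) back into a \code{leaf_census}. The configuration is not
#' stored in the files, so a matching [sim_config()] may be supplied; its
#' default is only used for census intervals and the classification window.
#'
#' @param dir directory holding \code{leaves.csv} and optionally
#'   \code{lengths.csv} and \code{environment.csv} (survival-only analyses
#'   need no environment; the full pipeline does).
#' @param config a [sim_config()] describing the protocol.
#' @return a \code{leaf_census}.
#' @export
read_leaf_census <- function(dir, config = sim_config()) {
  rd <- function(f) {
    if (!file.exists(f)) return(NULL)
    utils::read.csv(f, comment.char = "#", stringsAsFactors = FALSE)
  }
  leaves <- rd(file.path(dir, "leaves.csv"))
  if (is.null(leaves)) stop("leaves.csv not found in ", dir)
  env <- rd(file.path(dir, "environment.csv"))
  lengths <- rd(file.path(dir, "lengths.csv"))
  for (col in c("cohort_date", "end_date")) leaves[[col]] <- as.Date(leaves[[col]])
  if (!is.null(env)) env$date <- as.Date(env$date)
  if (!is.null(lengths)) lengths$date <- as.Date(lengths$date)
  structure(list(leaves = leaves, lengths = lengths, env = env,
                 config = config),
            class = "leaf_census")
}

#' Write the per-cohort summary of a fitted analysis
#'
#' One row per cohort: survival parameters, growth means, environmental
#' means and regime label, with a seed provenance header.
#'
#' @param x a \code{leaf_demography} object.
#' @param file output CSV path.
#' @return the path, invisibly.
#' @export
write_cohort_summary <- function(x, file) {
  stopifnot(inherits(x, "leaf_demography"))
  write_seeded_csv(x$cohorts, file, x$seed)
  invisible(file)
}
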