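# Cohort classification: k-means on (L50, growth rate) with
# silhouette-selected k, and recovery of the environmental decision
# threshold by a single-split entropy tree on post-emergence environmental
# means.

#' Environmental means over the post-emergence window
#'
#' Arithmetic means of photoperiod, temperature and radiation over the
#' \code{window_d} days starting at each emergence date (inclusive), i.e.
#' days \code{d .. d + window_d - 1}.
#'
#' @param env daily environment series from [sim_environment()] (or the same
#'   schema).
#' @param emergence_date one or more emergence dates; the window must lie
#'   entirely inside \code{env}.
#' @param window_d window length in days (default 33, the median time for
#'   leaves to reach 90\% of mature length).
#' @return data.frame: \code{cohort_date}, \code{mean_photoperiod_h},
#'   \code{mean_temperature_C}, \code{mean_radiation}.
#' @export
env_window_mean <- function(env, emergence_date, window_d = 33) {
  emergence_date <- as.Date(emergence_date)
  i0 <- match(emergence_date, env$date)
  if (any(is.na(i0)) || any(i0 + window_d - 1 > nrow(env)))
    stop("environmental window extends past env coverage")
  rows <- lapply(seq_along(emergence_date), function(j) {
    ix <- i0[j] + seq_len(window_d) - 1L
    data.frame(cohort_date = emergence_date[j],
               mean_photoperiod_h = mean(env$photoperiod_h[ix]),
               mean_temperature_C = mean(env$temperature_C[ix]),
               mean_radiation = mean(env$radiation[ix]))
  })
  do.call(rbind, rows)
}

#' k-means clustering of cohorts on longevity and growth rate
#'
#' Lloyd's algorithm with 20 restarts on z-score-standardised features. When
#' \code{k = 2} the clusters are named by their meaning: the cluster with the
#' smaller mean L50 (first feature column) is the growth-season (GS) class,
#' the other the overwintering (OW) class.
#'
#' @param features numeric data.frame/matrix, rows = cohorts; the first
#'   column must be the L50 (days). Typically \code{(L50_empirical_d,
#'   growth_rate_mm_per_d)}.
#' @param k number of clusters (>= 1).
#' @param seed integer seed for the restarts.
#' @param nstart number of random restarts; the best within-cluster sum of
#'   squares is kept.
#' @return list: \code{labels} (\code{"GS"}/\code{"OW"} when k = 2, else
#'   \code{"C1"}...), \code{cluster} (integer assignment), \code{centers}
#'   (original scale), \code{tot_withinss}, \code{k}, \code{seed}.
#' @export
kmeans_cohorts <- function(features, k = 2, seed = 1, nstart = 20) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("features must be finite; filter incomplete cohorts first")
  if (nrow(unique(x)) < k) stop("k exceeds the number of distinct points")
  z <- scale(x)
  z[, attr(z, "scaled:scale") == 0] <- 0   # constant feature: no information
  set.seed(as.integer(seed))
  if (k == 1L) {
    cl <- rep(1L, nrow(x))
    centers <- matrix(colMeans(x), 1, dimnames = list(NULL, colnames(x)))
    tw <- sum(scale(z, scale = FALSE)^2)
  } else {
    # Lloyd restarts occasionally empty a cluster on well-separated data;
    # such restarts are discarded by kmeans itself, so the warning is noise
    fit <- suppressWarnings(
      stats::kmeans(z, centers = k, nstart = nstart, iter.max = 200,
                    algorithm = "Lloyd"))
    cl <- fit$cluster
    centers <- do.call(rbind, lapply(seq_len(k), function(j)
      colMeans(x[cl == j, , drop = FALSE])))
    tw <- fit$tot.withinss
  }
  labels <- paste0("C", cl)
  if (k == 2L) {
    gs_cluster <- which.min(centers[, 1])   # smaller mean L50 = GS
    labels <- ifelse(cl == gs_cluster, "GS", "OW")
  }
  list(labels = labels, cluster = cl, centers = centers,
       tot_withinss = tw, k = k, seed = seed)
}

#' Silhouette selection of the number of cohort clusters
#'
#' Mean silhouette width (Euclidean distance on the standardised features)
#' for each candidate k, clustering with [kmeans_cohorts()]; the k with the
#' largest mean width is selected.
#'
#' @param features as in [kmeans_cohorts()].
#' @param k_range candidate k values, within \code{[2, n - 1]}.
#' @param seed integer seed.
#' @return list: \code{best_k}, \code{widths} (data.frame \code{k},
#'   \code{mean_silhouette}).
#' @export
silhouette_select_k <- function(features, k_range = 2:6, seed = 1) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range must contain values in [2, n - 1]")
  z <- scale(x)
  z[, attr(z, "scaled:scale") == 0] <- 0
  dz <- stats::dist(z)
  widths <- vapply(k_range, function(k) {
    cl <- kmeans_cohorts(features, k = k, seed = seed)$cluster
    mean(cluster::silhouette(cl, dz)[, "sil_width"])
  }, numeric(1))
  list(best_k = k_range[which.max(widths)],
       widths = data.frame(k = k_range, mean_silhouette = widths))
}

entropy_bits <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Single-split entropy decision rule on environmental features
#'
#' Depth-one decision tree: for every feature, every midpoint between
#' consecutive distinct sorted values is evaluated, and the (feature,
#' threshold) pair maximising information gain (parent entropy minus
#' weighted child entropies, base 2) is returned. Ties are broken by the
#' column order of \code{features} (put photoperiod first, then temperature,
#' then radiation). Each side of the split is labelled with its majority
#' class; the training error counts misclassified cohorts under the rule.
#'
#' @param features numeric data.frame, rows = cohorts, columns = candidate
#'   environmental features in tie-break priority order.
#' @param labels class labels (two or more classes, each present).
#' @return object of class \code{split_rule}: list with \code{feature},
#'   \code{threshold}, \code{class_below}, \code{class_above}, \code{gain}
#'   (bits), \code{training_error}, \code{n}.
#' @examples
#' f <- data.frame(photoperiod_h = c(10.8, 11.0, 11.2, 11.6, 12.1, 13.0))
#' entropy_split(f, c("OW", "OW", "OW", "GS", "GS", "GS"))
#' @export
entropy_split <- function(features, labels) {
  features <- as.data.frame(features)
  labels <- as.character(labels)
  if (nrow(features) < 2L) stop("need at least two cohorts to split")
  if (length(unique(labels)) < 2L) stop("pure single-class input: no split defined")
  h_parent <- entropy_bits(labels)
  n <- length(labels)
  best <- NULL
  for (fn in names(features)) {
    v <- features[[fn]]
    sv <- sort(unique(v))
    if (length(sv) < 2L) next
    mids <- (sv[-1] + sv[-length(sv)]) / 2
    for (thr in mids) {
      below <- v <= thr
      h <- (sum(below) * entropy_bits(labels[below]) +
            sum(!below) * entropy_bits(labels[!below])) / n
      gain <- h_parent - h
      if (is.null(best) || gain > best$gain + 1e-12) {
        maj <- function(l) names(which.max(table(l)))
        cb <- maj(labels[below]); ca <- maj(labels[!below])
        err <- sum(labels[below] != cb) + sum(labels[!below] != ca)
        best <- list(feature = fn, threshold = thr, class_below = cb,
                     class_above = ca, gain = gain, training_error = err,
                     n = n)
      }
    }
  }
  if (is.null(best)) stop("no candidate split: all features are constant")
  class(best) <- "split_rule"
  best
}

#' @export
print.split_rule <- function(x, ...) {
  cat(sprintf("Split rule: %s <= %.4g -> %s, > %.4g -> %s\n",
              x$feature, x$threshold, x$class_below, x$threshold, x$class_above))
  cat(sprintf("  information gain %.4g bits; training error %d / %d\n",
              x$gain, x$training_error, x$n))
  invisible(x)
}
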