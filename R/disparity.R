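#' Sum of variances across morphospace axes
#'
#' Within-group disparity as the sum over the selected score axes of the
#' sample variance (denominator n - 1) of the group members. Summed over all
#' PCA axes this equals the summed squared distances of the members from
#' their centroid in the original variable space divided by n - 1 (rotation
#' invariance), and the n - 1 denominator makes Foote partial disparities
#' add up to it exactly.
#'
#' @param scores n x m score matrix (rows named by specimen id).
#' @param members specimen ids or row indices of the group.
#' @param axes axis indices to sum over (default all).
#' @return The sum of variances, or `NA_real_` for groups of fewer than two.
#' @export
sumOfVariances <- function(scores, members, axes = NULL) {
  pts <- scores[members, , drop = FALSE]
  if (nrow(pts) < 2) return(NA_real_)
  if (is.null(axes)) axes <- seq_len(ncol(pts))
  pts <- pts[, axes, drop = FALSE]
  sum(apply(pts, 2, stats::var))
}

#' Mean pairwise distance within a group
#'
#' Mean of all `choose(n, 2)` pairwise Euclidean distances among the group
#' members — applied to aligned Procrustes coordinates this is the mean
#' pairwise Procrustes distance (MPD) of a time bin.
#'
#' @param x either a precomputed symmetric distance matrix (rows/cols named
#'   by specimen id), an `aligned_sample`, or an n x m coordinate/score
#'   matrix.
#' @param members specimen ids or row indices of the group.
#' @return Mean pairwise distance, or `NA_real_` for groups of fewer than
#'   two.
#' @export
meanPairwiseDistance <- function(x, members) {
  if (inherits(x, "aligned_sample")) x <- pairwiseProcrustes(x)
  x <- as.matrix(x)
  is_distmat <- nrow(x) == ncol(x) &&
    max(abs(x - t(x))) < 1e-12 && all(abs(diag(x)) < 1e-12)
  if (is_distmat) {
    dsub <- x[members, members, drop = FALSE]
  } else {
    dsub <- as.matrix(stats::dist(x[members, , drop = FALSE]))
  }
  n <- nrow(dsub)
  if (n < 2) return(NA_real_)
  mean(dsub[upper.tri(dsub)])
}

#' Normalize a disparity series by its maximum
#'
#' Divides every value by the series maximum so hull volumes computed from
#' different axis counts are comparable; missing values stay missing and are
#' excluded from the maximum. After normalization all values lie in (0, 1]
#' with the maximum bin at exactly 1.
#'
#' @param values numeric vector (may contain `NA`).
#' @return The normalized vector.
#' @export
normalizeSeries <- function(values) {
  if (all(is.na(values))) stop("all values missing; nothing to normalize")
  values / max(values, na.rm = TRUE)
}

#' Percentile bootstrap confidence interval for a disparity metric
#'
#' Resamples the group with replacement (same n) `B` times, evaluates
#' `metric_fn` on each resample, and returns the replicate mean with the
#' percentile interval. Replicates on which the metric is undefined (e.g. a
#' degenerate hull) are skipped and counted; if more than half are skipped
#' the interval is reported missing with a warning.
#'
#' @param metric_fn function taking a vector of members and returning a
#'   scalar (possibly `NA`).
#' @param members the group members to resample.
#' @param B number of bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed for reproducibility.
#' @return List with `mean`, `low`, `high`, `n_skipped`.
#' @export
bootstrapCI <- function(metric_fn, members, B = 1000, level = 0.95,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(members)
  reps <- vapply(seq_len(B), function(b)
    metric_fn(members[sample.int(n, n, replace = TRUE)]), numeric(1))
  skipped <- sum(is.na(reps))
  if (skipped > B / 2) {
    warning("metric undefined on ", skipped, " of ", B,
            " bootstrap replicates; interval reported missing")
    return(list(mean = NA_real_, low = NA_real_, high = NA_real_,
                n_skipped = skipped))
  }
  reps <- reps[!is.na(reps)]
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(mean = mean(reps), low = qs[1], high = qs[2], n_skipped = skipped)
}

#' Foote partial disparity of subgroups within a group
#'
#' Decomposes a group's total disparity into additive subgroup
#' contributions: with the centroid `c` of *all* group members over the
#' selected axes, a subgroup's partial disparity is the sum of its members'
#' squared distances from `c`, divided by `N - 1` (N the total group size).
#' The subgroup values sum exactly to the group's sum of variances over the
#' same axes.
#'
#' @param scores n x m score matrix (rows named by specimen id).
#' @param members specimen ids or row indices of the full group (e.g. a time
#'   bin).
#' @param group_labels subgroup label for each member (same length/order as
#'   `members`).
#' @param axes axis indices (default all).
#' @return Named list: `partial` (named numeric per subgroup), `total`,
#'   `share` (partial / total), `n`. `NA` throughout for singleton groups.
#' @export
partialDisparity <- function(scores, members, group_labels, axes = NULL) {
  if (length(group_labels) != length(members))
    stop("group_labels must label every member")
  pts <- scores[members, , drop = FALSE]
  N <- nrow(pts)
  if (N < 2)
    return(list(partial = NA_real_, total = NA_real_, share = NA_real_, n = N))
  if (is.null(axes)) axes <- seq_len(ncol(pts))
  pts <- pts[, axes, drop = FALSE]
  dev <- sweep(pts, 2, colMeans(pts))
  sq <- rowSums(dev^2)
  partial <- vapply(split(sq, group_labels), sum, numeric(1)) / (N - 1)
  total <- sum(partial)
  list(partial = partial, total = total, share = partial / total, n = N)
}

#' Per-bin disparity series with bootstrap confidence intervals
#'
#' Evaluates one disparity metric in every time bin of a binned dataset and
#' attaches percentile bootstrap CIs. Bins below `min_n` specimens are
#' reported missing: a variance from one or two specimens is not a
#' disparity estimate, and the smallest bins are exactly where a fossil
#' series is least trustworthy.
#'
#' @param binned a `binned_dataset` from [assignBins()].
#' @param scores score matrix (for `variance`, `hull`) or distance
#'   matrix/`aligned_sample` (for `mpd`); rows named by specimen id.
#' @param metric one of `"variance"`, `"mpd"`, `"hull"`.
#' @param axes axis indices for `variance` (default all).
#' @param n_axes hull dimensionality for `hull` (default 2).
#' @param B bootstrap replicates (default 1000); `B = 0` skips the CIs.
#' @param level confidence level (default 0.95).
#' @param min_n minimum bin size to report a value (default 3).
#' @param seed optional integer seed.
#' @param normalize divide the value column by the series maximum
#'   (customary for hull volumes; default `metric == "hull"`).
#' @return A `disparity_series`: data.frame-like list with `bin`, `metric`,
#'   `value`, `ci_low`, `ci_high`, `n`.
#' @export
disparitySeries <- function(binned, scores, metric = c("variance", "mpd", "hull"),
                            axes = NULL, n_axes = 2, B = 1000, level = 0.95,
                            min_n = 3, seed = NULL, normalize = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(binned, "binned_dataset"))
  if (is.null(normalize)) normalize <- metric == "hull"
  if (metric == "mpd" && inherits(scores, "aligned_sample"))
    scores <- pairwiseProcrustes(scores)
  fn <- switch(metric,
               variance = function(m) sumOfVariances(scores, m, axes = axes),
               mpd = function(m) meanPairwiseDistance(scores, m),
               hull = function(m) as.numeric(hullMeasure(scores, m, n_axes)))
  if (!is.null(seed)) set.seed(seed)
  bin_seeds <- sample.int(.Machine$integer.max, length(binned$bins))
  rows <- lapply(seq_along(binned$bins), function(i) {
    m <- binned$bins[[i]]
    if (length(m) < max(min_n, 2))
      return(data.frame(bin = names(binned$bins)[i], metric = metric,
                        value = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n = length(m)))
    val <- fn(m)
    ci <- if (B > 0 && !is.na(val))
      bootstrapCI(fn, m, B = B, level = level, seed = bin_seeds[i])
    else list(low = NA_real_, high = NA_real_)
    data.frame(bin = names(binned$bins)[i], metric = metric, value = val,
               ci_low = ci$low, ci_high = ci$high, n = length(m))
  })
  out <- do.call(rbind, rows)
  if (normalize && !all(is.na(out$value))) {
    mx <- max(out$value, na.rm = TRUE)
    out$value <- out$value / mx
    out$ci_low <- out$ci_low / mx
    out$ci_high <- out$ci_high / mx
  }
  out$axes_used <- if (metric == "hull") n_axes
  else if (is.null(axes)) NA_integer_ else length(axes)
  class(out) <- c("disparity_series", "data.frame")
  out
}

#' @export
print.disparity_series <- function(x, ...) {
  cat("Disparity series (", x$metric[1], "), ", nrow(x), " bins:\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
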