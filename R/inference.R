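#' @export
print.permutation_result <- function(x, ...) {
  cat(x$statistic_name, ": observed = ", format(x$observed, digits = 4),
      ", p = ", format(x$p_value, digits = 4),
      if (x$exhaustive) " (exhaustive, " else " (sampled, ",
      x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

.permResult <- function(statistic_name, observed, null_stats, exhaustive,
                        seed) {
  if (exhaustive) {
    p <- mean(null_stats >= observed - 1e-12)
  } else {
    p <- (sum(null_stats >= observed - 1e-12) + 1) / (length(null_stats) + 1)
  }
  structure(list(statistic_name = statistic_name, observed = observed,
                 n_permutations = length(null_stats),
                 exhaustive = exhaustive, p_value = p, seed = seed,
                 null_summary = c(mean = mean(null_stats),
                                  q95 = unname(stats::quantile(null_stats, 0.95)))),
            class = "permutation_result")
}

# all distinct assignments of nA out of (nA+nB) pooled rows to group A
.enumerateAssignments <- function(n_total, n_A) {
  utils::combn(n_total, n_A, simplify = FALSE)
}

#' Permutation test for a centroid shift between two groups
#'
#' NPMANOVA-style location test: the observed statistic is the Euclidean
#' distance between the two group centroids in the full score space; the
#' null distribution re-partitions the pooled members into groups of the
#' original sizes at random. When the number of distinct assignments
#' `choose(nA + nB, nA)` does not exceed `B`, all assignments are enumerated
#' and the p-value is exact (the observed assignment is one of them);
#' otherwise `B` random permutations are drawn and the +1-corrected
#' p-value `(count + 1) / (B + 1)` is reported, which can never be zero.
#'
#' @param scores n x m score matrix (rows named by specimen id).
#' @param members_A,members_B specimen ids or row indices of the two groups
#'   (at least 2 each).
#' @param B permutation budget (default 9999).
#' @param seed optional integer seed for the sampled mode.
#' @return A `permutation_result`.
#' @export
centroidShiftTest <- function(scores, members_A, members_B, B = 9999,
                              seed = NULL) {
  nA <- length(members_A); nB <- length(members_B)
  if (nA < 2 || nB < 2) stop("both groups need at least 2 members")
  pooled <- rbind(scores[members_A, , drop = FALSE],
                  scores[members_B, , drop = FALSE])
  stat <- function(idxA) {
    mA <- colMeans(pooled[idxA, , drop = FALSE])
    mB <- colMeans(pooled[-idxA, , drop = FALSE])
    sqrt(sum((mA - mB)^2))
  }
  observed <- stat(seq_len(nA))
  exhaustive <- choose(nA + nB, nA) <= B
  if (exhaustive) {
    null_stats <- vapply(.enumerateAssignments(nA + nB, nA), stat, numeric(1))
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_stats <- vapply(seq_len(B), function(b)
      stat(sample.int(nA + nB, nA)), numeric(1))
  }
  .permResult("centroid shift", observed, null_stats, exhaustive, seed)
}

#' Permutation test for a disparity difference between two groups
#'
#' Two-sided test of equal disparity: the observed statistic is the absolute
#' difference of the chosen metric between the groups; the null re-partitions
#' the pooled members as in [centroidShiftTest()]. Permutations on which the
#' metric is undefined for either side (e.g. a degenerate hull) are skipped
#' and counted.
#'
#' @param scores score matrix, or (for `metric = "mpd"`) a distance matrix
#'   or `aligned_sample`.
#' @param members_A,members_B the two groups.
#' @param metric one of `"variance"`, `"mpd"`, `"hull"`.
#' @param axes axis subset for `variance` (default all).
#' @param n_axes hull dimensionality (default 2).
#' @param B permutation budget (default 1000).
#' @param seed optional integer seed.
#' @return A `permutation_result` with an extra `n_skipped` field.
#' @export
disparityDifferenceTest <- function(scores, members_A, members_B,
                                    metric = c("variance", "mpd", "hull"),
                                    axes = NULL, n_axes = 2, B = 1000,
                                    seed = NULL) {
  metric <- match.arg(metric)
  if (metric == "mpd" && inherits(scores, "aligned_sample"))
    scores <- pairwiseProcrustes(scores)
  nA <- length(members_A); nB <- length(members_B)
  if (nA < 2 || nB < 2) stop("both groups need at least 2 members")
  pooled_ids <- c(members_A, members_B)
  one <- switch(metric,
                variance = function(m) sumOfVariances(scores, m, axes = axes),
                mpd = function(m) meanPairwiseDistance(scores, m),
                hull = function(m) as.numeric(hullMeasure(scores, m, n_axes)))
  stat <- function(idxA) {
    a <- one(pooled_ids[idxA]); b <- one(pooled_ids[-idxA])
    if (is.na(a) || is.na(b)) return(NA_real_)
    abs(a - b)
  }
  observed <- stat(seq_len(nA))
  if (is.na(observed))
    stop("disparity metric undefined on the observed groups")
  exhaustive <- choose(nA + nB, nA) <= B
  if (exhaustive) {
    null_stats <- vapply(.enumerateAssignments(nA + nB, nA), stat, numeric(1))
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_stats <- vapply(seq_len(B), function(b)
      stat(sample.int(nA + nB, nA)), numeric(1))
  }
  skipped <- sum(is.na(null_stats))
  null_stats <- null_stats[!is.na(null_stats)]
  out <- .permResult(paste0("disparity difference (", metric, ")"),
                     observed, null_stats, exhaustive, seed)
  out$n_skipped <- skipped
  out
}

#' Boundary bin pairs for extinction-crossing tests
#'
#' The named bin pairs flanking the Permo-Triassic boundary (late Permian
#' vs Early Triassic, ~252 Ma) and the Triassic-Jurassic boundary (Rhaetian
#' vs Hettangian, ~201 Ma) under the default Permian-Jurassic scheme. Any
#' other adjacent pair can be passed to the tests directly.
#'
#' @return Named list of `c(bin_A, bin_B)` pairs.
#' @export
boundaryPairs <- function() {
  list(PTB = c("late Permian", "Early Triassic"),
       TJB = c("Rhaetian", "Hettangian"))
}

#' Run boundary tests for a binned dataset
#'
#' For each boundary pair, runs the centroid-shift test and disparity
#' difference tests for the requested metrics, returning one tidy row per
#' test.
#'
#' @param binned a `binned_dataset`.
#' @param scores score matrix for the same specimens.
#' @param distances optional distance matrix (used for `mpd`).
#' @param pairs named list of bin pairs (default [boundaryPairs()]).
#' @param metrics disparity metrics to test (default variance and mpd,
#'   hull with 2 and 5 axes when requested).
#' @param n_axes_hull hull axis counts to test when `"hull"` is in
#'   `metrics` (default `c(2, 5)`).
#' @param B_centroid,B_disparity permutation budgets (defaults 9999, 1000).
#' @param seed optional integer seed.
#' @return data.frame: test, bin_A, bin_B, metric, observed, p, n_perm,
#'   exhaustive.
#' @export
boundaryTests <- function(binned, scores, distances = NULL,
                          pairs = boundaryPairs(),
                          metrics = c("variance", "mpd"),
                          n_axes_hull = c(2, 5),
                          B_centroid = 9999, B_disparity = 1000,
                          seed = NULL) {
  stopifnot(inherits(binned, "binned_dataset"))
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max,
                      length(pairs) * (1 + length(metrics) +
                                         ("hull" %in% metrics) * length(n_axes_hull)))
  si <- 0L
  nextseed <- function() { si <<- si + 1L; seeds[si] }
  rows <- list()
  for (pn in names(pairs)) {
    pr <- pairs[[pn]]
    mA <- binned$bins[[pr[1]]]; mB <- binned$bins[[pr[2]]]
    if (length(mA) < 2 || length(mB) < 2) {
      warning("skipping ", pn, ": a flanking bin has fewer than 2 specimens")
      next
    }
    r <- centroidShiftTest(scores, mA, mB, B = B_centroid, seed = nextseed())
    rows[[length(rows) + 1L]] <- data.frame(
      test = "centroid_shift", bin_A = pr[1], bin_B = pr[2], metric = "all_axes",
      observed = r$observed, p = r$p_value, n_perm = r$n_permutations,
      exhaustive = r$exhaustive)
    for (met in metrics) {
      if (met == "hull") {
        for (na in n_axes_hull) {
          r <- tryCatch(
            disparityDifferenceTest(scores, mA, mB, metric = "hull",
                                    n_axes = na, B = B_disparity,
                                    seed = nextseed()),
            error = function(e) {
              warning(pn, " hull_", na, "axes: ", conditionMessage(e))
              NULL
            })
          if (is.null(r)) next
          rows[[length(rows) + 1L]] <- data.frame(
            test = "disparity_difference", bin_A = pr[1], bin_B = pr[2],
            metric = paste0("hull_", na, "axes"), observed = r$observed,
            p = r$p_value, n_perm = r$n_permutations, exhaustive = r$exhaustive)
        }
      } else {
        x <- if (met == "mpd" && !is.null(distances)) distances else scores
        r <- disparityDifferenceTest(x, mA, mB, metric = met,
                                     B = B_disparity, seed = nextseed())
        rows[[length(rows) + 1L]] <- data.frame(
          test = "disparity_difference", bin_A = pr[1], bin_B = pr[2],
          metric = met, observed = r$observed, p = r$p_value,
          n_perm = r$n_permutations, exhaustive = r$exhaustive)
      }
    }
  }
  do.call(rbind, rows)
}
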