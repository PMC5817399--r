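#' Principal component analysis for morphospace construction
#'
#' Column-centred (and, under `mode = "correlation"`, column-standardized)
#' PCA of a specimen-by-variable matrix — Procrustes-aligned coordinates
#' flattened by [flattenAligned()], or functional characters. Axes are
#' ordered by decreasing variance; `min(n - 1, p)` axes are reported, with
#' trailing numerically-zero eigenvalues (below `1e-12` of the largest) set
#' to exact zeros. Loading signs follow a deterministic convention: the
#' largest-magnitude entry of each loading column is positive.
#'
#' @param data_matrix n x p numeric matrix, n >= 2, no missing values.
#' @param mode `"covariance"` (default) or `"correlation"`.
#' @return An object of class `ordination`: `scores` (n x m),
#'   `axis_variance` (eigenvalues), `proportion` (sums to one), `loadings`
#'   (p x m), `center`, `scale_used`, `mode`.
#' @export
shapePCA <- function(data_matrix, mode = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  data_matrix <- as.matrix(data_matrix)
  if (anyNA(data_matrix))
    stop("data matrix contains missing values; apply completeCaseFilter() first")
  n <- nrow(data_matrix); p <- ncol(data_matrix)
  if (n < 2) stop("need at least 2 rows")
  if (mode == "correlation") {
    sds <- apply(data_matrix, 2, stats::sd)
    if (any(sds < 1e-300))
      stop("zero-variance column under correlation mode: ",
           paste(which(sds < 1e-300), collapse = ", "))
  }
  fit <- stats::prcomp(data_matrix, center = TRUE,
                       scale. = (mode == "correlation"))
  m <- min(n - 1L, p)
  scores <- fit$x[, seq_len(m), drop = FALSE]
  loadings <- fit$rotation[, seq_len(m), drop = FALSE]
  ev <- fit$sdev[seq_len(m)]^2
  ev[ev < 1e-12 * max(ev)] <- 0
  # sign convention: largest-|entry| of each loading column positive
  for (j in seq_len(m)) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(data_matrix)
  structure(list(scores = scores, axis_variance = ev,
                 proportion = if (sum(ev) > 0) ev / sum(ev) else ev,
                 loadings = loadings, center = fit$center,
                 scale_used = if (mode == "correlation") fit$scale else NULL,
                 mode = mode),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  m <- length(x$axis_variance)
  cat("Ordination (", x$mode, " PCA): ", nrow(x$scores), " specimens, ",
      m, " axes\n", sep = "")
  show <- seq_len(min(5L, m))
  cat("  proportion of variance:",
      paste0("PC", show, "=", sprintf("%.3f", x$proportion[show]),
             collapse = " "), "\n")
  invisible(x)
}

#' Reconstruct a shape along a principal component axis
#'
#' For an ordination computed on flattened aligned coordinates, returns the
#' landmark configuration at a chosen score along one axis:
#' `consensus + score * loading`, with the loading vector reshaped back to
#' k x 2. At score 0 this is the consensus itself. Used to visualize the
#' extreme shapes of morphospace axes.
#'
#' @param ordination an `ordination` from [shapePCA()] on flattened
#'   coordinates (2k columns).
#' @param consensus the k x 2 consensus shape of the alignment.
#' @param axis axis number (1-based).
#' @param score position along the axis.
#' @return A k x 2 landmark configuration.
#' @export
shapeAlongAxis <- function(ordination, consensus, axis, score) {
  stopifnot(inherits(ordination, "ordination"))
  m <- ncol(ordination$scores)
  if (axis < 1 || axis > m) stop("axis must be in 1..", m)
  k <- nrow(consensus)
  if (nrow(ordination$loadings) != 2 * k)
    stop("ordination was not computed on flattened k x 2 coordinates")
  v <- unname(ordination$loadings[, axis])
  delta <- cbind(v[seq(1, 2 * k, by = 2)], v[seq(2, 2 * k, by = 2)])
  dimnames(delta) <- NULL
  consensus + score * delta
}

#' Export ordination scores to CSV
#'
#' Writes `specimen_id, PC1..PCm` rows; a second file with the per-axis
#' variance proportions can be written alongside.
#'
#' @param ordination an `ordination`.
#' @param path output CSV path for the scores.
#' @param proportion_path optional path for the axis-variance table.
#' @export
writeScores <- function(ordination, path, proportion_path = NULL) {
  stopifnot(inherits(ordination, "ordination"))
  df <- data.frame(specimen_id = rownames(ordination$scores),
                   ordination$scores, check.names = FALSE)
  colnames(df)[-1] <- paste0("PC", seq_len(ncol(ordination$scores)))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(proportion_path)) {
    utils::write.csv(data.frame(axis = seq_along(ordination$proportion),
                                variance = ordination$axis_variance,
                                proportion = ordination$proportion),
                     proportion_path, row.names = FALSE)
  }
  invisible(path)
}
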