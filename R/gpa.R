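#' Centre a configuration and scale it to unit centroid size
#'
#' Translates the landmark configuration so its centroid sits at the origin
#' and scales it so its centroid size (the root of the summed squared
#' deviations of all landmarks from the centroid) equals one.
#'
#' @param coords k x 2 coordinate matrix with at least 3 landmarks.
#' @return A list with `coords` (normalized k x 2 matrix) and
#'   `centroid_size` (the original size).
#' @export
centerAndScale <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need at least 3 landmarks")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  centred <- sweep(coords, 2, colMeans(coords))
  size <- sqrt(sum(centred^2))
  if (size < 1e-12) stop("degenerate shape: all landmarks coincident")
  list(coords = centred / size, centroid_size = size)
}

# Optimal proper rotation (det +1) of centred `shape` onto centred
# `reference`, in closed form for 2-D. Reflections are deliberately
# excluded: a mirrored specimen must be fixed upstream, not silently
# flipped into apparent similarity.
#' Rotate one configuration onto another (orthogonal Procrustes, 2-D)
#'
#' Returns `shape` rotated by the proper rotation (determinant +1) that
#' minimizes the summed squared distance to `reference`. Both inputs must be
#' centred. A mirror image is *not* reflected back: input images are assumed
#' to face the same way.
#'
#' @param shape,reference centred k x 2 matrices with equal k.
#' @return The rotated k x 2 matrix.
#' @export
optimalRotation <- function(shape, reference) {
  if (!all(dim(shape) == dim(reference)))
    stop("shape and reference must have identical dimensions")
  a <- sum(shape * reference)                              # tr(M)
  b <- sum(shape[, 2] * reference[, 1] -
             shape[, 1] * reference[, 2])                  # M21 - M12
  h <- sqrt(a * a + b * b)
  if (h < 1e-300) return(shape)                            # rotation undetermined
  cs <- a / h; sn <- b / h
  cbind(cs * shape[, 1] + sn * shape[, 2],
        -sn * shape[, 1] + cs * shape[, 2])
}

# internal: stack list of k x 2 configs into two k x n matrices
.stackXY <- function(configs) {
  k <- nrow(configs[[1]])
  list(x = vapply(configs, function(m) m[, 1], numeric(k)),
       y = vapply(configs, function(m) m[, 2], numeric(k)))
}

#' Generalized Procrustes analysis
#'
#' Jointly superimposes two or more landmark configurations by translation,
#' scaling and proper rotation. All configurations are centred and scaled to
#' unit centroid size, then iteratively rotated to the running consensus; the
#' consensus is the arithmetic mean of the aligned configurations, rescaled
#' to unit centroid size each iteration. Iteration stops when the root mean
#' squared movement of the consensus falls below `tol`.
#'
#' @param configurations a list of k x 2 matrices (all with the same k), a
#'   k x 2 x n array, or a list of configuration records as returned by
#'   [readTPS()].
#' @param tol convergence tolerance on consensus movement (RMS per
#'   coordinate), default 1e-8.
#' @param max_iter maximum number of iterations, default 100.
#' @return An object of class `aligned_sample`: list with `aligned`
#'   (k x 2 x n array, unit centroid size, common orientation), `consensus`
#'   (k x 2, unit size), `centroid_sizes`, `specimen_ids`, `n_iterations`,
#'   `converged`.
#' @export
gpa <- function(configurations, tol = 1e-8, max_iter = 100) {
  ids <- NULL
  if (is.array(configurations) && length(dim(configurations)) == 3) {
    ids <- dimnames(configurations)[[3]]
    configurations <- lapply(seq_len(dim(configurations)[3]),
                             function(i) configurations[, , i])
  } else if (is.list(configurations) && is.list(configurations[[1]]) &&
             !is.null(configurations[[1]]$coords)) {
    ids <- vapply(configurations, `[[`, character(1), "specimen_id")
    configurations <- lapply(configurations, `[[`, "coords")
  }
  n <- length(configurations)
  if (n < 2) stop("need at least 2 configurations")
  k <- nrow(configurations[[1]])
  if (!all(vapply(configurations, nrow, integer(1)) == k))
    stop("all configurations must have the same number of landmarks")
  if (is.null(ids)) ids <- paste0("spec_", seq_len(n))

  norm <- lapply(configurations, centerAndScale)
  sizes <- vapply(norm, `[[`, numeric(1), "centroid_size")
  s <- .stackXY(lapply(norm, `[[`, "coords"))          # x, y: k x n
  X <- s$x; Y <- s$y

  consensus <- cbind(X[, 1], Y[, 1])
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    # closed-form 2-D rotation of every column pair onto the consensus
    a <- colSums(X * consensus[, 1] + Y * consensus[, 2])
    b <- colSums(Y * consensus[, 1] - X * consensus[, 2])
    h <- sqrt(a * a + b * b)
    h[h < 1e-300] <- 1
    cs <- a / h; sn <- b / h
    Xr <- sweep(X, 2, cs, "*") + sweep(Y, 2, sn, "*")
    Yr <- sweep(Y, 2, cs, "*") - sweep(X, 2, sn, "*")
    X <- Xr; Y <- Yr
    new_consensus <- cbind(rowMeans(X), rowMeans(Y))
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  # canonical orientation: consensus major axis along x, sign fixed by the
  # largest-|x| landmark, so the result does not depend on input order or
  # the pose of any particular specimen
  R <- svd(consensus)$v
  if (det(R) < 0) R[, 2] <- -R[, 2]
  cons_rot <- consensus %*% R
  if (cons_rot[which.max(abs(cons_rot[, 1])), 1] < 0) R <- -R   # rotate by pi
  consensus <- consensus %*% R
  Xr <- X * R[1, 1] + Y * R[2, 1]
  Yr <- X * R[1, 2] + Y * R[2, 2]
  X <- Xr; Y <- Yr
  aligned <- array(0, dim = c(k, 2, n), dimnames = list(NULL, NULL, ids))
  aligned[, 1, ] <- X
  aligned[, 2, ] <- Y
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_sizes = sizes, specimen_ids = ids,
                 n_iterations = iter, converged = converged),
            class = "aligned_sample")
}

#' @export
print.aligned_sample <- function(x, ...) {
  d <- dim(x$aligned)
  cat("Aligned sample: ", d[3], " configurations of ", d[1],
      " landmarks\n", sep = "")
  cat("  GPA iterations: ", x$n_iterations,
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  if (!is.null(x$slide_cycles))
    cat("  semilandmark sliding: ", x$slide_cycles, " cycle(s)\n", sep = "")
  invisible(x)
}

#' Procrustes distance between two superimposed configurations
#'
#' Distance in the common aligned frame: the Euclidean norm of the
#' coordinate difference (partial Procrustes distance). With
#' `pair_align = TRUE` the second configuration is first re-rotated onto the
#' first, giving the per-pair optimal-rotation flavour.
#'
#' @param a either an `aligned_sample` (then `b` and `i` are specimen
#'   indices) or a k x 2 matrix.
#' @param b a k x 2 matrix, or a specimen index when `a` is an
#'   `aligned_sample`.
#' @param i second specimen index when `a` is an `aligned_sample`.
#' @param pair_align re-rotate the pair before measuring (default FALSE:
#'   distances are taken in the joint alignment frame).
#' @return Non-negative distance; zero iff the configurations coincide.
#' @export
procrustesDistance <- function(a, b, i = NULL, pair_align = FALSE) {
  if (inherits(a, "aligned_sample")) {
    stopifnot(!is.null(i))
    x <- a$aligned[, , b]; y <- a$aligned[, , i]
  } else {
    x <- as.matrix(a); y <- as.matrix(b)
  }
  if (!all(dim(x) == dim(y))) stop("configurations differ in dimension")
  if (pair_align) y <- optimalRotation(y, x)
  sqrt(sum((x - y)^2))
}

#' All pairwise Procrustes distances within an aligned sample
#'
#' @param aligned an `aligned_sample`.
#' @param pair_align per-pair re-rotation as in [procrustesDistance()].
#' @return A symmetric n x n distance matrix.
#' @export
pairwiseProcrustes <- function(aligned, pair_align = FALSE) {
  stopifnot(inherits(aligned, "aligned_sample"))
  n <- dim(aligned$aligned)[3]
  flat <- t(apply(aligned$aligned, 3, c))            # n x 2k
  if (!pair_align) {
    d <- as.matrix(stats::dist(flat))
  } else {
    d <- matrix(0, n, n)
    for (p in seq_len(n - 1)) for (q in (p + 1):n)
      d[p, q] <- d[q, p] <- procrustesDistance(aligned$aligned[, , p],
                                               aligned$aligned[, , q],
                                               pair_align = TRUE)
  }
  dimnames(d) <- list(aligned$specimen_ids, aligned$specimen_ids)
  d
}

#' Flatten an aligned sample to an n x 2k coordinate matrix
#'
#' Row order follows the sample; columns are `(x1, y1, x2, y2, ...)`.
#' This is the matrix handed to [shapePCA()].
#'
#' @param aligned an `aligned_sample`.
#' @return An n x 2k numeric matrix with specimen ids as row names.
#' @export
flattenAligned <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_sample"))
  k <- dim(aligned$aligned)[1]
  flat <- t(apply(aligned$aligned, 3, function(m) as.vector(t(m))))
  rownames(flat) <- aligned$specimen_ids
  colnames(flat) <- paste0(rep(c("x", "y"), k), rep(seq_len(k), each = 2))
  flat
}
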