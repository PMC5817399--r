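# d-dimensional convex hull volume by incremental (beneath-beyond)
# construction with simplicial facets. Written for the small point sets and
# low dimensions (2-5 axes) of per-bin morphospace volumes; exact up to
# floating point, no external geometry library required.

# hyperplane through d points, oriented away from interior point c0
.facetPlane <- function(pts, vidx, c0) {
  V <- pts[vidx, , drop = FALSE]
  d <- ncol(pts)
  A <- sweep(V[-1, , drop = FALSE], 2, V[1, ])
  sv <- svd(t(A), nu = d, nv = 0)
  w <- sv$u[, d]
  b <- sum(w * V[1, ])
  if (sum(w * c0) > b) { w <- -w; b <- -b }
  list(v = vidx, w = w, b = b)
}

#' Convex hull content of a point set
#'
#' Area (2-D), volume (3-D) or hypervolume (4-D and up) of the convex hull
#' of `points`, computed by incremental construction of the simplicial facet
#' complex followed by fan triangulation from an interior point. Returns
#' `NA` when the points are affinely dependent (fewer than `d + 1` points in
#' general position), since a flat point set occupies zero content in the
#' ambient space and is reported as missing rather than zero.
#'
#' @param points n x d numeric matrix, d >= 1.
#' @return Hull content, or `NA_real_` for degenerate input.
#' @export
convexHullVolume <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (anyNA(points)) stop("points contain missing values")
  points <- unique(points)
  n <- nrow(points); d <- ncol(points)
  if (d == 1) {
    if (n < 2) return(NA_real_)
    return(diff(range(points)))
  }
  if (n < d + 1) return(NA_real_)
  scale <- max(apply(points, 2, function(v) diff(range(v))))
  if (scale == 0) return(NA_real_)
  eps <- 1e-9 * scale

  # greedy affinely-independent seed simplex
  seed <- 1L
  for (i in 2:n) {
    seed_try <- c(seed, i)
    A <- sweep(points[seed_try[-1], , drop = FALSE], 2, points[seed[1], ])
    if (qr(t(A), tol = 1e-9)$rank == length(seed_try) - 1L) seed <- seed_try
    if (length(seed) == d + 1L) break
  }
  if (length(seed) < d + 1L) return(NA_real_)    # affinely dependent set

  c0 <- colMeans(points[seed, , drop = FALSE])
  facets <- lapply(seq_len(d + 1L), function(j)
    .facetPlane(points, seed[-j], c0))

  for (i in setdiff(seq_len(n), seed)) {
    p <- points[i, ]
    dists <- vapply(facets, function(f) sum(f$w * p) - f$b, numeric(1))
    vis <- which(dists > eps)
    if (!length(vis)) next
    # horizon ridges: (d-1)-faces of visible facets occurring exactly once
    ridges <- list(); counts <- integer(0)
    for (f in facets[vis]) {
      for (j in seq_len(d)) {
        r <- sort(f$v[-j])
        key <- paste(r, collapse = ",")
        if (is.na(counts[key])) { counts[key] <- 1L; ridges[[key]] <- r }
        else counts[key] <- counts[key] + 1L
      }
    }
    horizon <- ridges[names(counts)[counts == 1L]]
    new_facets <- lapply(horizon, function(r)
      .facetPlane(points, c(r, i), c0))
    facets <- c(facets[-vis], new_facets)
  }

  # fan triangulation from the interior point
  total <- 0
  for (f in facets) {
    V <- sweep(points[f$v, , drop = FALSE], 2, c0)
    total <- total + abs(det(V))
  }
  total / factorial(d)
}

#' Within-bin morphospace volume from ordination scores
#'
#' Convex hull content of a bin's specimens in the first `n_axes` score
#' dimensions: area for two axes up to a 5-D hypervolume. Missing (with the
#' reason retrievable via `attr(, "reason")`) when the bin holds fewer than
#' `n_axes + 1` specimens or the points are affinely dependent.
#'
#' @param scores n x m score matrix (rows named by specimen id).
#' @param members specimen ids or row indices of the bin.
#' @param n_axes number of leading axes to use (2-5 in standard use).
#' @return Hull content, or `NA_real_` for degenerate bins.
#' @export
hullMeasure <- function(scores, members, n_axes = 2) {
  if (n_axes < 2 || n_axes > ncol(scores))
    stop("n_axes must be in 2..", ncol(scores))
  pts <- scores[members, seq_len(n_axes), drop = FALSE]
  if (nrow(pts) < n_axes + 1) {
    out <- NA_real_
    attr(out, "reason") <- "fewer points than n_axes + 1"
    return(out)
  }
  v <- convexHullVolume(pts)
  if (is.na(v)) attr(v, "reason") <- "affinely dependent points"
  v
}
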