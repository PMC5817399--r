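#' Landmark scheme: fixed landmarks, semilandmarks and their sliding topology
#'
#' A landmark scheme declares, for a digitization protocol with `k` points per
#' specimen, which points are fixed anatomical landmarks and which are
#' semilandmarks that slide along outline curves during superimposition.
#' Each semilandmark carries a triple `(before, slider, after)` naming the two
#' neighbours that define its tangent direction; semilandmarks are grouped
#' into named curves.
#'
#' @param n_landmarks total number of landmarks per configuration.
#' @param fixed_indices integer indices (1-based) of the fixed landmarks.
#' @param slider_triples integer matrix with columns `before`, `slider`,
#'   `after` (one row per semilandmark), or `NULL` for an all-fixed scheme.
#' @param curves optional named list partitioning the slider indices into
#'   labelled curves.
#' @return An object of class `landmark_scheme`.
#' @examples
#' landmarkScheme(4, fixed_indices = c(1, 2, 4),
#'                slider_triples = rbind(c(2, 3, 4)))
#' @export
landmarkScheme <- function(n_landmarks, fixed_indices, slider_triples = NULL,
                           curves = NULL) {
  n_landmarks <- as.integer(n_landmarks)
  fixed_indices <- sort(unique(as.integer(fixed_indices)))
  if (is.null(slider_triples)) {
    slider_triples <- matrix(integer(0), ncol = 3L)
  }
  slider_triples <- matrix(as.integer(slider_triples), ncol = 3L,
                           dimnames = list(NULL, c("before", "slider", "after")))
  sliders <- slider_triples[, "slider"]
  if (anyDuplicated(sliders))
    stop("each semilandmark may appear in exactly one slider triple; duplicated: ",
         paste(unique(sliders[duplicated(sliders)]), collapse = ", "))
  if (any(slider_triples[, "before"] == sliders) ||
      any(slider_triples[, "after"] == sliders))
    stop("a slider triple's neighbours must be distinct from the slider itself")
  all_idx <- c(slider_triples)
  if (length(all_idx) && (min(all_idx) < 1L || max(all_idx) > n_landmarks))
    stop("slider triple index out of range 1..", n_landmarks)
  if (any(fixed_indices < 1L) || any(fixed_indices > n_landmarks))
    stop("fixed index out of range 1..", n_landmarks)
  if (length(intersect(fixed_indices, sliders)))
    stop("fixed and sliding index sets must be disjoint")
  covered <- sort(c(fixed_indices, sliders))
  if (!identical(covered, seq_len(n_landmarks)))
    stop("fixed and sliding indices together must cover 1..", n_landmarks)
  if (!is.null(curves)) {
    in_curves <- sort(unlist(curves, use.names = FALSE))
    if (!identical(as.integer(in_curves), sort(as.integer(sliders))))
      stop("curves must partition exactly the set of slider indices")
  }
  structure(list(n_landmarks = n_landmarks,
                 fixed_indices = fixed_indices,
                 slider_triples = slider_triples,
                 curves = curves),
            class = "landmark_scheme")
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme: ", x$n_landmarks, " landmarks (",
      length(x$fixed_indices), " fixed, ", nrow(x$slider_triples),
      " sliding", sep = "")
  if (!is.null(x$curves)) cat(" on ", length(x$curves), " curves", sep = "")
  cat(")\n")
  invisible(x)
}

#' Default 28-landmark fish body outline scheme
#'
#' The stock digitization protocol for lateral-view actinopterygian body
#' outlines: 14 fixed landmarks at discrete anatomical features (snout,
#' jaw, fin origins/insertions, caudal peduncle and tail margins) and 14
#' semilandmarks capturing body curvature on six curves between fixed
#' landmarks. Also the template used by the synthetic-data generator.
#'
#' @return A `landmark_scheme` with 28 landmarks.
#' @export
fishBodyScheme <- function() {
  triples <- rbind(
    # dorsal head -> dorsal-fin origin
    c(3L, 15L, 16L), c(15L, 16L, 17L), c(16L, 17L, 4L),
    # dorsal-fin end -> caudal peduncle top
    c(5L, 18L, 19L), c(18L, 19L, 20L), c(19L, 20L, 6L),
    # caudal peduncle bottom -> anal-fin end
    c(10L, 21L, 22L), c(21L, 22L, 11L),
    # anal-fin origin -> pelvic insertion
    c(12L, 23L, 24L), c(23L, 24L, 13L),
    # pelvic insertion -> lower jaw (belly)
    c(13L, 25L, 26L), c(25L, 26L, 14L),
    # snout -> anterior dorsal head
    c(1L, 27L, 28L), c(27L, 28L, 2L))
  landmarkScheme(
    28L, fixed_indices = 1:14, slider_triples = triples,
    curves = list(predorsal = 15:17, postdorsal = 18:20, postanal = 21:22,
                  anal_pelvic = 23:24, belly = 25:26, head = 27:28))
}

#' Template coordinates for the 28-landmark fish outline
#'
#' Idealized lateral-view fish outline matching [fishBodyScheme()], centred
#' and scaled to unit centroid size. Used as the base shape by the
#' synthetic-data generator and convenient as a GPA reference in examples.
#'
#' @return A 28 x 2 coordinate matrix.
#' @export
fishBodyTemplate <- function() {
  fixed <- rbind(
    c(-1.00,  0.00),   #  1 snout tip
    c(-0.80,  0.26),   #  2 anterior dorsal head
    c(-0.58,  0.31),   #  3 nape
    c(-0.10,  0.38),   #  4 dorsal-fin origin
    c( 0.25,  0.34),   #  5 dorsal-fin end
    c( 0.80,  0.13),   #  6 caudal peduncle, dorsal
    c( 1.12,  0.28),   #  7 caudal-fin tip, dorsal
    c( 1.02,  0.00),   #  8 caudal fork
    c( 1.12, -0.28),   #  9 caudal-fin tip, ventral
    c( 0.80, -0.13),   # 10 caudal peduncle, ventral
    c( 0.46, -0.23),   # 11 anal-fin end
    c( 0.24, -0.29),   # 12 anal-fin origin
    c(-0.16, -0.33),   # 13 pelvic-fin insertion
    c(-0.88, -0.13))   # 14 lower jaw tip
  interp <- function(a, b, ts, bulge) {
    # points between two fixed landmarks, bowed outward along the normal
    d <- b - a
    nrm <- c(-d[2], d[1]) / sqrt(sum(d^2))
    t(vapply(seq_along(ts),
             function(i) a + ts[i] * d + bulge * sin(pi * ts[i]) * nrm,
             numeric(2)))
  }
  semis <- rbind(
    interp(fixed[3, ],  fixed[4, ],  c(0.25, 0.50, 0.75),  0.020),  # 15-17
    interp(fixed[5, ],  fixed[6, ],  c(0.25, 0.50, 0.75), -0.015),  # 18-20
    interp(fixed[10, ], fixed[11, ], c(0.33, 0.67),        0.012),  # 21-22
    interp(fixed[12, ], fixed[13, ], c(0.33, 0.67),       -0.015),  # 23-24
    interp(fixed[13, ], fixed[14, ], c(0.33, 0.67),       -0.030),  # 25-26
    interp(fixed[1, ],  fixed[2, ],  c(0.33, 0.67),        0.035))  # 27-28
  coords <- rbind(fixed, semis)
  coords <- sweep(coords, 2, colMeans(coords))
  coords / sqrt(sum(coords^2))
}
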