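#' Thin-plate-spline bending energy matrix
#'
#' Builds the bending energy matrix of a 2-D reference configuration:
#' the upper-left k x k block of the inverse of the bordered thin-plate-spline
#' system with kernel `U(r) = r^2 log(r^2)` and affine block `[1 | x | y]`.
#' The matrix is symmetric positive semi-definite and annihilates affine
#' terms, so purely affine deformations of the reference have zero energy.
#'
#' @param reference k x 2 matrix without coincident landmarks.
#' @return An object of class `bending_energy` with fields `reference` and
#'   `matrix` (k x k).
#' @export
bendingEnergyMatrix <- function(reference) {
  reference <- as.matrix(reference)
  k <- nrow(reference)
  if (k < 4) stop("need at least 4 landmarks for a thin-plate spline")
  d <- as.matrix(stats::dist(reference))
  if (any(d[upper.tri(d)] < 1e-12))
    stop("coincident landmarks make the thin-plate-spline system singular")
  K <- d^2 * log(d^2 + (d == 0))          # U(0) = 0
  P <- cbind(1, reference)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Linv <- tryCatch(solve(L), error = function(e)
    stop("singular thin-plate-spline system: ", conditionMessage(e)))
  M <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  M <- (M + t(M)) / 2                      # enforce exact symmetry
  structure(list(reference = reference, matrix = M), class = "bending_energy")
}

#' Bending energy of a target configuration relative to a reference
#'
#' `t(x) M x + t(y) M y` over the target coordinate columns, where `M` is
#' the reference's bending energy matrix. Zero for the reference itself and
#' for any affine deformation of it.
#'
#' @param bem a `bending_energy` object from [bendingEnergyMatrix()].
#' @param target k x 2 matrix.
#' @return Non-negative scalar (up to numerical tolerance).
#' @export
bendingEnergy <- function(bem, target) {
  stopifnot(inherits(bem, "bending_energy"))
  target <- as.matrix(target)
  if (!all(dim(target) == dim(bem$reference)))
    stop("target must match the reference dimensions")
  drop(crossprod(target[, 1], bem$matrix %*% target[, 1]) +
         crossprod(target[, 2], bem$matrix %*% target[, 2]))
}

# One bending-energy slide of a single specimen against a reference.
# Semilandmarks move only along their tangent (unit chord between the
# specimen's own `before` and `after` neighbours); tangent offsets solve the
# restricted generalized least-squares system against M. Falls back to a
# plain tangent projection when that system is numerically singular.
.slideOne <- function(X, ref, M, triples) {
  s <- nrow(triples)
  sl <- triples[, "slider"]
  chord <- X[triples[, "after"], , drop = FALSE] -
    X[triples[, "before"], , drop = FALSE]
  len <- sqrt(rowSums(chord^2))
  len[len < 1e-12] <- 1
  u <- chord / len                                    # s x 2 unit tangents
  k <- nrow(X)
  Ux <- matrix(0, k, s); Uy <- matrix(0, k, s)
  Ux[cbind(sl, seq_len(s))] <- u[, 1]
  Uy[cbind(sl, seq_len(s))] <- u[, 2]
  d <- X - ref
  MUx <- M %*% Ux; MUy <- M %*% Uy
  A <- crossprod(Ux, MUx) + crossprod(Uy, MUy)
  rhs <- -(crossprod(MUx, d[, 1]) + crossprod(MUy, d[, 2]))
  t_off <- tryCatch({
    if (rcond(A) < 1e-12) stop("ill-conditioned")
    solve(A, rhs)
  }, error = function(e) NULL)
  fallback <- is.null(t_off)
  if (fallback)                                      # tangent projection
    t_off <- -(d[sl, 1] * u[, 1] + d[sl, 2] * u[, 2])
  X[sl, ] <- X[sl, ] + as.vector(t_off) * u
  list(X = X, fallback = fallback)
}

#' Slide semilandmarks by bending-energy minimization
#'
#' Iterative semilandmark sliding against the updated consensus: within each
#' cycle every specimen's semilandmarks are displaced along their tangent
#' directions so as to minimize the specimen's bending energy relative to
#' the current consensus, then the sample is re-superimposed by [gpa()] and
#' the consensus updated. Cycling stops when the consensus movement (RMS per
#' coordinate) drops below `tol`, after `max_cycles`, or as soon as a cycle
#' fails to lower the total bending energy — such a cycle is rejected and
#' the previous state kept, so the accepted energy trajectory is monotone
#' non-increasing by construction. Fixed landmarks move only through
#' superimposition.
#'
#' @param aligned an `aligned_sample` from [gpa()].
#' @param scheme a `landmark_scheme` whose slider triples are valid for the
#'   sample's k.
#' @param tol consensus-movement tolerance, default 1e-6.
#' @param max_cycles maximum sliding cycles, default 10.
#' @return The updated `aligned_sample`, with extra fields `slide_cycles`,
#'   `energy_history` (data.frame: cycle, energy_before, energy_after, both
#'   relative to that cycle's consensus) and `n_fallback` (specimens slid by
#'   tangent projection because the restricted system was singular).
#' @export
slideSemilandmarks <- function(aligned, scheme, tol = 1e-6, max_cycles = 10) {
  stopifnot(inherits(aligned, "aligned_sample"),
            inherits(scheme, "landmark_scheme"))
  k <- dim(aligned$aligned)[1]
  if (scheme$n_landmarks != k)
    stop("scheme is for ", scheme$n_landmarks, " landmarks, sample has ", k)
  triples <- scheme$slider_triples
  if (!nrow(triples)) return(aligned)
  n <- dim(aligned$aligned)[3]
  n_fallback <- 0L
  hist_rows <- list()
  prev_energy <- Inf
  accepted <- 0L
  for (cycle in seq_len(max_cycles)) {
    ref <- aligned$consensus
    bem <- bendingEnergyMatrix(ref)
    e_before <- sum(vapply(seq_len(n), function(i)
      bendingEnergy(bem, aligned$aligned[, , i]), numeric(1)))
    configs <- vector("list", n)
    for (i in seq_len(n)) {
      res <- .slideOne(aligned$aligned[, , i], ref, bem$matrix, triples)
      if (res$fallback) n_fallback <- n_fallback + 1L
      configs[[i]] <- res$X
    }
    e_after <- sum(vapply(configs, function(X)
      bendingEnergy(bem, X), numeric(1)))
    # monotone-descent safeguard: cycling against an updated consensus can
    # drift (semilandmarks migrating collectively along the outline); a
    # cycle that fails to lower total energy is rejected and iteration stops
    if (e_after > prev_energy * (1 + 1e-12)) break  # keep the entering state
    accepted <- accepted + 1L
    prev_energy <- e_after
    hist_rows[[accepted]] <- data.frame(cycle = accepted,
                                        energy_before = e_before,
                                        energy_after = e_after)
    realigned <- gpa(configs)
    realigned$specimen_ids <- aligned$specimen_ids
    dimnames(realigned$aligned)[[3]] <- aligned$specimen_ids
    realigned$centroid_sizes <- aligned$centroid_sizes
    # remove the arbitrary global spin of the fresh GPA so consensus
    # movement measures shape change only
    a <- sum(realigned$consensus * ref)
    b <- sum(realigned$consensus[, 2] * ref[, 1] -
               realigned$consensus[, 1] * ref[, 2])
    h <- sqrt(a * a + b * b)
    if (h > 1e-300) {
      cs <- a / h; sn <- b / h
      rot <- function(m) cbind(cs * m[, 1] + sn * m[, 2],
                               -sn * m[, 1] + cs * m[, 2])
      realigned$consensus <- rot(realigned$consensus)
      for (i in seq_len(n)) realigned$aligned[, , i] <- rot(realigned$aligned[, , i])
    }
    movement <- sqrt(mean((realigned$consensus - ref)^2))
    aligned <- realigned
    if (movement < tol) break
  }
  if (n_fallback > 0)
    message("sliding fell back to tangent projection for ", n_fallback,
            " specimen-cycle(s)")
  aligned$slide_cycles <- accepted
  aligned$energy_history <- do.call(rbind, hist_rows)
  aligned$n_fallback <- n_fallback
  aligned
}
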