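# Synthetic datasets with planted structure: fish-like landmark outlines
# whose per-bin shape variance follows a known ladder, and jaw-ratio trait
# tables drawn from ecotype clusters with preservational-style missingness.
# Every generator is a pure function of (design, seed).

# similarity-subspace basis (translation x/y, rotation, scaling) at a base
# shape, as columns of a 2k x 4 matrix in interleaved (x1, y1, ...) order
.similarityBasis <- function(base) {
  k <- nrow(base)
  tx <- rep(c(1, 0), k)
  ty <- rep(c(0, 1), k)
  rot <- as.vector(t(cbind(-base[, 2], base[, 1])))
  scl <- as.vector(t(base))
  B <- cbind(tx, ty, rot, scl)
  qr.Q(qr(B))
}

# deterministic deformation-mode basis: sinusoidal displacement fields over
# the outline, projected off the similarity subspace and orthonormalized,
# so planted variance survives the Procrustes projection (to first order)
.deformationModes <- function(base, n_modes) {
  k <- nrow(base)
  S <- .similarityBasis(base)
  raw <- vapply(seq_len(n_modes), function(m) {
    u <- cos(m * pi * base[, 1] * 3 + 0.31 * m)
    v <- sin(m * pi * base[, 2] * 5 + 0.73 * m)
    as.vector(t(cbind(u, v)))
  }, numeric(2 * k))
  raw <- raw - S %*% crossprod(S, raw)
  q <- qr(raw)
  if (q$rank < n_modes)
    stop("deformation-mode basis is rank deficient; reduce n_modes")
  qr.Q(q)[, seq_len(n_modes), drop = FALSE]
}

#' Design for the synthetic-data generators
#'
#' Collects the study conditions the generators emulate: the 28-landmark
#' body scheme with 14 semilandmarks on six curves, the Permian-Jurassic
#' 17-bin scheme, per-bin sample sizes, a ladder of planted per-bin shape
#' variances spread over orthonormal deformation modes, digitization noise,
#' ecotype trait clusters (a generalist, a deep-jawed/high-MA durophage
#' cluster, an elongate piscivore cluster) and per-character missingness
#' rates concentrated in characters two and five (17.2% of cells overall at
#' the defaults).
#'
#' @param scheme a `landmark_scheme` (default [fishBodyScheme()]).
#' @param base_shape k x 2 template (default [fishBodyTemplate()]).
#' @param bins a `time_bin_scheme` (default [permianJurassicBins()]).
#' @param n_per_bin specimens per bin (recycled to the number of bins).
#' @param bin_variances planted per-bin total shape variance; default a
#'   geometric ladder `4e-4 * 1.5^(0:(n_bins-1))`, increasing toward the
#'   youngest bin so the planted disparity ordering is strict.
#' @param n_modes number of deformation modes (default 12).
#' @param landmark_noise_sd isotropic per-coordinate digitization noise on
#'   the unit-centroid-size shape (default 0.0015).
#' @param trait_means 5-column matrix of per-ecotype character means.
#' @param trait_sds per-character within-ecotype standard deviations.
#' @param missing_rates per-character MCAR masking rates (default
#'   `c(0.06, 0.30, 0.05, 0.05, 0.40)`, mean 0.172).
#' @param subgroup_proportions mixing proportions of the ecotypes (summing
#'   to one), also used as infraclass proportions for metadata.
#' @return A `simulation_design` list.
#' @export
simulationDesign <- function(scheme = fishBodyScheme(),
                             base_shape = fishBodyTemplate(),
                             bins = permianJurassicBins(),
                             n_per_bin = 30,
                             bin_variances = NULL,
                             n_modes = 12,
                             landmark_noise_sd = 0.0015,
                             trait_means = NULL,
                             trait_sds = c(0.04, 0.07, 0.04, 0.03, 0.06),
                             missing_rates = c(0.06, 0.30, 0.05, 0.05, 0.40),
                             subgroup_proportions = c(Chondrostei = 0.40,
                                                      Holostei = 0.35,
                                                      Teleostei = 0.25)) {
  n_bins <- length(bins$bins)
  n_per_bin <- rep_len(n_per_bin, n_bins)
  if (is.null(bin_variances))
    bin_variances <- 4e-4 * 1.5^(seq_len(n_bins) - 1)
  if (length(bin_variances) != n_bins)
    stop("bin_variances must have one value per bin")
  if (any(bin_variances < 0) || landmark_noise_sd < 0)
    stop("variances and noise must be non-negative")
  if (any(missing_rates < 0 | missing_rates >= 1))
    stop("missing rates must lie in [0, 1)")
  if (abs(sum(subgroup_proportions) - 1) > 1e-9)
    stop("subgroup proportions must sum to 1")
  if (is.null(trait_means)) {
    trait_means <- rbind(
      Chondrostei = c(0.28, 0.55, 0.22, 0.16, 0.55),  # generalist
      Holostei    = c(0.45, 0.85, 0.42, 0.30, 0.35),  # deep-jawed durophage
      Teleostei   = c(0.18, 0.40, 0.15, 0.10, 0.70))  # elongate piscivore
    colnames(trait_means) <- paste0("char", 1:5)
  }
  structure(list(scheme = scheme, base_shape = base_shape, bins = bins,
                 n_per_bin = stats::setNames(n_per_bin, bins$bins),
                 bin_variances = stats::setNames(bin_variances, bins$bins),
                 n_modes = n_modes, landmark_noise_sd = landmark_noise_sd,
                 trait_means = trait_means, trait_sds = trait_sds,
                 missing_rates = missing_rates,
                 subgroup_proportions = subgroup_proportions),
            class = "simulation_design")
}

# shared metadata generator: one row per specimen with bin-consistent stage
.simulateRecords <- function(design, ids, bin_of) {
  n <- length(ids)
  infraclass <- sample(names(design$subgroup_proportions), n, replace = TRUE,
                       prob = design$subgroup_proportions)
  stage <- vapply(bin_of, function(b) {
    st <- design$bins$stages[[b]]
    st[sample.int(length(st), 1)]
  }, character(1))
  data.frame(specimen_id = ids,
             species = paste0("sp_", ids),
             genus = paste0("gen_", (seq_len(n) - 1) %/% 2 + 1),
             family = paste0("fam_", (seq_len(n) - 1) %/% 8 + 1),
             infraclass = infraclass,
             environment = sample(c("marine", "freshwater"), n,
                                  replace = TRUE, prob = c(0.7, 0.3)),
             stage = stage,
             lagerstatten_only = stats::runif(n) < 0.15,
             stringsAsFactors = FALSE)
}

#' Generate a landmark dataset with planted per-bin disparity
#'
#' Each specimen is the base outline plus a random combination of the
#' design's orthonormal deformation modes (per-mode amplitude
#' `sqrt(bin_variance / n_modes)` for its bin) plus isotropic digitization
#' noise, then hit with a random rotation, translation and scale for the
#' superimposition step to undo. The truth table records each bin's planted
#' population sum of variances in shape space,
#' `bin_variance + 2k * noise_sd^2` (up to Procrustes projection of the
#' noise, which loses the four similarity directions).
#'
#' @param design a `simulation_design`.
#' @param seed integer seed.
#' @param dir optional directory; when given, `landmarks.tps`,
#'   `sliders.csv` and `metadata.csv` are written there.
#' @return List with `configurations` (readTPS-style records), `records`
#'   (metadata data.frame), `truth` (data.frame: bin, n, bin_variance,
#'   planted_total).
#' @export
generateLandmarkDataset <- function(design, seed, dir = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (any(design$n_per_bin < 2)) stop("every bin needs n >= 2")
  set.seed(seed)
  base <- design$base_shape
  k <- nrow(base)
  modes <- .deformationModes(base, design$n_modes)    # 2k x M, orthonormal
  bin_of <- rep(design$bins$bins, design$n_per_bin)
  n <- length(bin_of)
  ids <- sprintf("sim%04d", seq_len(n))
  sigma_mode <- sqrt(design$bin_variances[bin_of] / design$n_modes)
  amps <- matrix(stats::rnorm(n * design$n_modes), n) * sigma_mode
  flat_base <- as.vector(t(base))
  configurations <- vector("list", n)
  for (i in seq_len(n)) {
    flat <- flat_base + modes %*% amps[i, ] +
      stats::rnorm(2 * k, sd = design$landmark_noise_sd)
    X <- matrix(flat, k, 2, byrow = TRUE)
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    s <- exp(stats::rnorm(1, log(100), 0.3))
    X <- s * X %*% R + matrix(stats::runif(2, -50, 50), k, 2, byrow = TRUE)
    configurations[[i]] <- list(specimen_id = ids[i], coords = X,
                                scale = NA_real_)
  }
  records <- .simulateRecords(design, ids, bin_of)
  truth <- data.frame(bin = design$bins$bins,
                      n = as.vector(design$n_per_bin),
                      bin_variance = as.vector(design$bin_variances),
                      planted_total = as.vector(design$bin_variances) +
                        2 * k * design$landmark_noise_sd^2)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeTPS(configurations, file.path(dir, "landmarks.tps"))
    writeSliders(design$scheme$slider_triples, file.path(dir, "sliders.csv"))
    utils::write.csv(records, file.path(dir, "metadata.csv"),
                     row.names = FALSE)
  }
  list(configurations = configurations, records = records, truth = truth)
}

#' Generate a functional trait dataset from ecotype clusters
#'
#' Rows are drawn per specimen from the multivariate normal of its ecotype
#' (independent characters at the design's per-character spreads, truncated
#' below at 0.01 to respect positivity), then cells are masked missing
#' completely at random at the per-character rates. The ecotype doubles as
#' the infraclass label in the accompanying metadata, so planted subgroup
#' structure is visible to partial disparity and the centroid-shift test.
#'
#' @param design a `simulation_design`.
#' @param seed integer seed.
#' @param n_specimens total rows (default: sum of the design's per-bin n).
#' @param dir optional directory; when given, `traits.csv` and
#'   `metadata.csv` are written there.
#' @return List with `traits` (trait data.frame with missing cells),
#'   `records` (metadata), `truth` (list: means, sds, missing_rates,
#'   proportions).
#' @export
generateTraitDataset <- function(design, seed, n_specimens = NULL,
                                 dir = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  if (is.null(n_specimens)) n_specimens <- sum(design$n_per_bin)
  bin_of <- sample(rep(design$bins$bins,
                       rep_len(ceiling(n_specimens / length(design$bins$bins)),
                               length(design$bins$bins))))[seq_len(n_specimens)]
  ids <- sprintf("jaw%04d", seq_len(n_specimens))
  records <- .simulateRecords(design, ids, bin_of)
  g <- records$infraclass
  mu <- design$trait_means[g, , drop = FALSE]
  vals <- mu + matrix(stats::rnorm(n_specimens * 5), n_specimens) %*%
    diag(design$trait_sds)
  vals <- pmax(vals, 0.01)
  mask <- matrix(stats::runif(n_specimens * 5), n_specimens) <
    matrix(design$missing_rates, n_specimens, 5, byrow = TRUE)
  vals[mask] <- NA_real_
  traits <- data.frame(specimen_id = ids, vals, stringsAsFactors = FALSE)
  names(traits)[-1] <- paste0("char", 1:5)
  truth <- list(means = design$trait_means, sds = design$trait_sds,
                missing_rates = design$missing_rates,
                proportions = design$subgroup_proportions)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeTraitTable(traits, file.path(dir, "traits.csv"))
    utils::write.csv(records, file.path(dir, "metadata.csv"),
                     row.names = FALSE)
  }
  list(traits = traits, records = records, truth = truth)
}

#' Generate a pair of exchangeable null groups
#'
#' Two groups drawn from one multivariate standard normal — the calibration
#' fixture for the permutation tests' type-I error.
#'
#' @param n_A,n_B group sizes (>= 2).
#' @param dim dimensionality.
#' @param seed integer seed.
#' @return List with `scores` ((n_A + n_B) x dim matrix), `members_A`,
#'   `members_B` (row indices).
#' @export
generateNullPair <- function(n_A, n_B, dim = 2, seed) {
  if (n_A < 2 || n_B < 2) stop("group sizes must be >= 2")
  set.seed(seed)
  n_A <- as.integer(n_A); n_B <- as.integer(n_B)
  scores <- matrix(stats::rnorm((n_A + n_B) * dim), n_A + n_B)
  rownames(scores) <- paste0("s", seq_len(n_A + n_B))
  list(scores = scores, members_A = seq_len(n_A),
       members_B = n_A + seq_len(n_B))
}
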