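#' Read a pipeline run configuration
#'
#' YAML (or JSON-compatible YAML) file with input paths and analysis
#' settings; unknown fields are kept so a resolved config can round-trip.
#'
#' @param path path to a YAML config.
#' @return Named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  num <- intersect(names(cfg),
                   c("B_bootstrap", "B_npmanova", "B_disparity", "alpha",
                     "min_bin_n", "seed"))
  for (f in num) cfg[[f]] <- as.numeric(cfg[[f]])
  if (!is.null(cfg$alpha) && (cfg$alpha <= 0 || cfg$alpha >= 1))
    stop("alpha must be in (0, 1)")
  for (f in c("B_bootstrap", "B_npmanova", "B_disparity"))
    if (!is.null(cfg[[f]]) && cfg[[f]] < 1) stop(f, " must be >= 1")
  cfg
}

# draw per-stage sub-seeds from the master seed so changing one stage's
# permutation budget does not shift any other stage's draws
.stageSeeds <- function(seed) {
  set.seed(seed)
  stats::setNames(as.list(sample.int(.Machine$integer.max %/% 2, 6)),
                  c("bootstrap", "tests", "hull", "partial", "extra1",
                    "extra2"))
}

.writeOutputs <- function(results, output_dir, config) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(results$series))
    utils::write.csv(results$series[[nm]],
                     file.path(output_dir, paste0("series_", nm, ".csv")),
                     row.names = FALSE, na = "")
  if (!is.null(results$tests))
    utils::write.csv(results$tests, file.path(output_dir, "tests.csv"),
                     row.names = FALSE)
  for (nm in names(results$partial))
    utils::write.csv(results$partial[[nm]],
                     file.path(output_dir, paste0("partial_", nm, ".csv")),
                     row.names = FALSE, na = "")
  writeScores(results$ordination, file.path(output_dir, "scores.csv"),
              file.path(output_dir, "axis_variance.csv"))
  yaml::write_yaml(config, file.path(output_dir, "resolved_config.yaml"))
  writeLines(results$log, file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}

# per-bin Foote partial disparity tables for one labelling of the specimens
.partialTable <- function(binned, scores, labels_of, min_n) {
  rows <- list()
  for (b in names(binned$bins)) {
    m <- binned$bins[[b]]
    if (length(m) < max(min_n, 2)) next
    pd <- partialDisparity(scores, m, labels_of[m])
    rows[[b]] <- data.frame(bin = b, subgroup = names(pd$partial),
                            partial = unname(pd$partial),
                            share = unname(pd$share), n = pd$n,
                            total = pd$total)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the body-shape disparity arm
#'
#' Full landmark pipeline: GPA, semilandmark sliding, PCA, per-bin variance
#' and mean-pairwise-Procrustes-distance series with bootstrap CIs,
#' normalized convex-hull volume series over 2..5 axes, boundary permutation
#' tests, and Foote partial disparity by infraclass and by environment.
#'
#' @param tps TPS path or list of configurations.
#' @param sliders sliders path or triples matrix (`NULL` for all-fixed).
#' @param metadata metadata path or data.frame.
#' @param bins a `time_bin_scheme` or scheme CSV path (default
#'   [permianJurassicBins()]).
#' @param seed master seed; every stage draws its own sub-seed from it.
#' @param pca_mode `"covariance"` (default) or `"correlation"`.
#' @param axis_counts axis counts for the variance sensitivity series
#'   (default `c(2, 5, 20)` plus all axes; counts above the available axes
#'   are dropped).
#' @param B_bootstrap,B_npmanova,B_disparity replication budgets (defaults
#'   1000, 9999, 1000).
#' @param min_bin_n smallest bin reported in disparity series (default 3).
#' @param pairs boundary bin pairs (default [boundaryPairs()]).
#' @param drop_lagerstatten remove specimens known only from Lagerstaetten
#'   before analysis (sensitivity run).
#' @param mpd_pair_align per-pair re-rotation for MPD distances (default
#'   FALSE: common-frame distances).
#' @param output_dir optional directory for CSV outputs, resolved config and
#'   run log.
#' @return List: `aligned`, `ordination`, `binned`, `series` (named list of
#'   disparity series), `tests`, `partial`, `diversity`, `log`, `config`.
#' @export
runBodyShape <- function(tps, sliders, metadata,
                         bins = permianJurassicBins(), seed = 1,
                         pca_mode = "covariance",
                         axis_counts = c(2, 5, 20),
                         B_bootstrap = 1000, B_npmanova = 9999,
                         B_disparity = 1000, min_bin_n = 3,
                         pairs = boundaryPairs(),
                         drop_lagerstatten = FALSE,
                         mpd_pair_align = FALSE,
                         output_dir = NULL) {
  t0 <- Sys.time()
  log <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  configs <- if (is.character(tps)) readTPS(tps) else tps
  triples <- if (is.character(sliders)) readSliders(sliders) else sliders
  records <- if (is.character(metadata)) readMetadata(metadata) else metadata
  if (is.character(bins)) bins <- timeBinScheme(bins)
  ids <- vapply(configs, `[[`, character(1), "specimen_id")
  checkIdsMatch(ids, records, "TPS")
  records <- records[match(ids, records$specimen_id), ]
  if (drop_lagerstatten) {
    keep <- !records$lagerstatten_only
    say("dropping ", sum(!keep), " Lagerstaetten-only specimen(s)")
    configs <- configs[keep]
    records <- records[keep, ]
    ids <- ids[keep]
  }
  k <- nrow(configs[[1]]$coords)
  scheme <- landmarkScheme(k,
                           fixed_indices = setdiff(seq_len(k),
                                                   triples[, "slider"]),
                           slider_triples = triples)
  seeds <- .stageSeeds(seed)
  say("stage gpa: ", length(configs), " configurations, k = ", k)
  aligned <- gpa(configs)
  if (nrow(scheme$slider_triples)) {
    aligned <- slideSemilandmarks(aligned, scheme)
    say("stage sliding: ", aligned$slide_cycles, " cycle(s), ",
        aligned$n_fallback, " fallback(s)")
  }
  ord <- shapePCA(flattenAligned(aligned), mode = pca_mode)
  say("stage pca: ", ncol(ord$scores), " axes; PC1-2 = ",
      sprintf("%.1f%%", 100 * sum(ord$proportion[1:min(2, ncol(ord$scores))])))
  binned <- assignBins(records, bins)
  dists <- pairwiseProcrustes(aligned, pair_align = mpd_pair_align)

  m_axes <- ncol(ord$scores)
  series <- list(
    variance = disparitySeries(binned, ord$scores, "variance",
                               B = B_bootstrap, min_n = min_bin_n,
                               seed = seeds$bootstrap),
    mpd = disparitySeries(binned, dists, "mpd", B = B_bootstrap,
                          min_n = min_bin_n, seed = seeds$bootstrap + 1L))
  for (na in 2:min(5, m_axes)) {
    series[[paste0("hull_", na, "axes")]] <-
      disparitySeries(binned, ord$scores, "hull", n_axes = na, B = 0,
                      min_n = min_bin_n, seed = seeds$hull)
  }
  axis_counts <- unique(pmin(axis_counts[axis_counts <= m_axes], m_axes))
  for (ac in axis_counts) {
    series[[paste0("variance_", ac, "axes")]] <-
      disparitySeries(binned, ord$scores, "variance", axes = seq_len(ac),
                      B = B_bootstrap, min_n = min_bin_n,
                      seed = seeds$bootstrap + ac)
  }
  say("stage disparity: ", length(series), " series over ",
      length(binned$bins), " bins")
  tests <- boundaryTests(binned, ord$scores, distances = dists, pairs = pairs,
                         metrics = c("variance", "mpd", "hull"),
                         B_centroid = B_npmanova, B_disparity = B_disparity,
                         seed = seeds$tests)
  say("stage tests: ", nrow(tests), " boundary tests")
  labels_ic <- stats::setNames(records$infraclass, records$specimen_id)
  labels_env <- stats::setNames(records$environment, records$specimen_id)
  partial <- list(infraclass = .partialTable(binned, ord$scores, labels_ic,
                                             min_bin_n),
                  environment = .partialTable(binned, ord$scores, labels_env,
                                              min_bin_n))
  say("done in ", sprintf("%.1f s", as.numeric(Sys.time() - t0, "secs")))
  config <- list(arm = "body_shape", seed = seed, pca_mode = pca_mode,
                 B_bootstrap = B_bootstrap, B_npmanova = B_npmanova,
                 B_disparity = B_disparity, min_bin_n = min_bin_n,
                 drop_lagerstatten = drop_lagerstatten,
                 mpd_pair_align = mpd_pair_align,
                 n_specimens = length(ids), n_landmarks = k)
  results <- list(aligned = aligned, ordination = ord, binned = binned,
                  series = series, tests = tests, partial = partial,
                  diversity = binSizes(binned), log = log, config = config)
  if (!is.null(output_dir)) .writeOutputs(results, output_dir, config)
  results
}

#' Run the jaw-functional disparity arm
#'
#' Functional pipeline: characters from raw measurements (or a ready trait
#' table), optional within-species averaging, missingness report,
#' complete-case filter, PCA of the five characters, per-bin variance series
#' with bootstrap CIs, normalized hull volumes over 2..5 axes, boundary
#' tests, and partial disparity by infraclass and environment.
#'
#' @param traits trait table (path or data.frame), or `NULL` when
#'   `measurements` is given.
#' @param metadata metadata path or data.frame.
#' @param measurements optional raw measurement table (path or data.frame);
#'   characters are computed from it.
#' @param species_average average characters within species before analysis
#'   (metadata then collapses to one record per species; default FALSE).
#' @param bins,seed,pca_mode,B_bootstrap,B_npmanova,B_disparity,min_bin_n,pairs,drop_lagerstatten,output_dir
#'   as in [runBodyShape()].
#' @return List like [runBodyShape()]'s, plus `missingness`, `n_complete`,
#'   `traits`.
#' @export
runFunctional <- function(traits = NULL, metadata, measurements = NULL,
                          species_average = FALSE,
                          bins = permianJurassicBins(), seed = 1,
                          pca_mode = "covariance",
                          B_bootstrap = 1000, B_npmanova = 9999,
                          B_disparity = 1000, min_bin_n = 3,
                          pairs = boundaryPairs(),
                          drop_lagerstatten = FALSE,
                          output_dir = NULL) {
  t0 <- Sys.time()
  log <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  records <- if (is.character(metadata)) readMetadata(metadata) else metadata
  if (is.character(bins)) bins <- timeBinScheme(bins)
  if (!is.null(measurements)) {
    meas <- if (is.character(measurements)) readMeasurements(measurements)
    else measurements
    traits <- computeCharacters(meas)
    say("stage characters: computed for ", nrow(traits), " specimens")
  } else if (is.character(traits)) {
    traits <- readTraitTable(traits)
  }
  checkIdsMatch(traits$specimen_id, records, "trait")
  records <- records[match(traits$specimen_id, records$specimen_id), ]
  if (drop_lagerstatten) {
    keep <- !records$lagerstatten_only
    say("dropping ", sum(!keep), " Lagerstaetten-only specimen(s)")
    traits <- traits[keep, , drop = FALSE]
    records <- records[keep, , drop = FALSE]
  }
  if (species_average) {
    traits <- averageBySpecies(traits, records[c("specimen_id", "species")])
    records <- records[!duplicated(records$species), ]
    records$specimen_id <- records$species
    records <- records[match(traits$specimen_id, records$specimen_id), ]
    say("stage averaging: ", nrow(traits), " species")
  }
  miss <- missingnessRate(traits)
  cc <- completeCaseFilter(traits)
  say("stage filter: missingness ", sprintf("%.1f%%", 100 * miss), "; ",
      cc$n_complete, " of ", nrow(traits), " complete cases")
  traits <- cc$traits
  records <- records[match(traits$specimen_id, records$specimen_id), ]
  X <- as.matrix(traits[paste0("char", 1:5)])
  rownames(X) <- traits$specimen_id
  seeds <- .stageSeeds(seed)
  ord <- shapePCA(X, mode = pca_mode)
  say("stage pca: PC1-2 = ",
      sprintf("%.1f%%", 100 * sum(ord$proportion[1:2])))
  binned <- assignBins(records, bins)
  series <- list(
    variance = disparitySeries(binned, ord$scores, "variance",
                               B = B_bootstrap, min_n = min_bin_n,
                               seed = seeds$bootstrap))
  for (na in 2:min(5, ncol(ord$scores))) {
    series[[paste0("hull_", na, "axes")]] <-
      disparitySeries(binned, ord$scores, "hull", n_axes = na, B = 0,
                      min_n = min_bin_n, seed = seeds$hull)
  }
  tests <- boundaryTests(binned, ord$scores, pairs = pairs,
                         metrics = c("variance", "hull"),
                         B_centroid = B_npmanova, B_disparity = B_disparity,
                         seed = seeds$tests)
  say("stage tests: ", nrow(tests), " boundary tests")
  labels_ic <- stats::setNames(records$infraclass, records$specimen_id)
  labels_env <- stats::setNames(records$environment, records$specimen_id)
  partial <- list(infraclass = .partialTable(binned, ord$scores, labels_ic,
                                             min_bin_n),
                  environment = .partialTable(binned, ord$scores, labels_env,
                                              min_bin_n))
  say("done in ", sprintf("%.1f s", as.numeric(Sys.time() - t0, "secs")))
  config <- list(arm = "functional", seed = seed, pca_mode = pca_mode,
                 species_average = species_average,
                 B_bootstrap = B_bootstrap, B_npmanova = B_npmanova,
                 B_disparity = B_disparity, min_bin_n = min_bin_n,
                 drop_lagerstatten = drop_lagerstatten,
                 n_specimens = nrow(traits))
  results <- list(ordination = ord, binned = binned, series = series,
                  tests = tests, partial = partial,
                  diversity = binSizes(binned), missingness = miss,
                  n_complete = cc$n_complete, traits = traits, log = log,
                  config = config)
  if (!is.null(output_dir)) .writeOutputs(results, output_dir, config)
  results
}
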