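test_that("generators are pure functions of design and seed", {
  des <- simulationDesign(n_per_bin = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generateLandmarkDataset(des, seed = 8, dir = d1)
  generateLandmarkDataset(des, seed = 8, dir = d2)
  expect_identical(readLines(file.path(d1, "landmarks.tps")),
                   readLines(file.path(d2, "landmarks.tps")))
  expect_identical(readLines(file.path(d1, "metadata.csv")),
                   readLines(file.path(d2, "metadata.csv")))
  t1 <- generateTraitDataset(des, seed = 9)
  t2 <- generateTraitDataset(des, seed = 9)
  expect_identical(t1$traits, t2$traits)
  # and the emitted files are readable by the package's own readers
  cfgs <- readTPS(file.path(d1, "landmarks.tps"))
  expect_length(cfgs, sum(des$n_per_bin))
  expect_equal(nrow(readSliders(file.path(d1, "sliders.csv"))), 14)
  expect_equal(nrow(readMetadata(file.path(d1, "metadata.csv"))),
               length(cfgs))
})

test_that("zero planted variance and noise yield zero disparity", {
  des <- simulationDesign(n_per_bin = 3, bin_variances = rep(0, 17),
                          landmark_noise_sd = 0)
  sim <- generateLandmarkDataset(des, seed = 10)
  al <- gpa(sim$configurations)
  expect_lt(max(pairwiseProcrustes(al)), 1e-8)
  ord <- shapePCA(flattenAligned(al))
  bd <- assignBins(sim$records, des$bins)
  v <- vapply(bd$bins, function(m) sumOfVariances(ord$scores, m), numeric(1))
  expect_lt(max(v), 1e-16)
})

test_that("doubling the planted sigma quadruples the estimated variance", {
  des <- simulationDesign(bins = twoBinScheme(), n_per_bin = 100,
                          bin_variances = c(0.0004, 0.0016),
                          landmark_noise_sd = 1e-5)
  sim <- generateLandmarkDataset(des, seed = 12)
  al <- slideSemilandmarks(gpa(sim$configurations), des$scheme)
  ord <- shapePCA(flattenAligned(al))
  bd <- assignBins(sim$records, des$bins)
  v <- vapply(bd$bins, function(m) sumOfVariances(ord$scores, m), numeric(1))
  expect_equal(unname(v[2] / v[1]), 4, tolerance = 0.2)
})

test_that("trait missingness matches the planted rates in expectation", {
  des <- simulationDesign(missing_rates = c(0, 0.3, 0, 0, 0.3))
  tr <- generateTraitDataset(des, seed = 13, n_specimens = 1000)
  expect_lt(abs(missingnessRate(tr$traits) - 0.12), 0.02)
  # missingness concentrated in the declared characters
  expect_equal(sum(is.na(tr$traits$char1)), 0)
  expect_gt(mean(is.na(tr$traits$char5)), 0.25)
  # default rates give the canonical overall fraction
  expect_equal(mean(simulationDesign()$missing_rates), 0.172, tolerance = 1e-12)
})

test_that("isotropic single-cluster traits spread variance over all axes", {
  des <- simulationDesign(trait_means = rbind(Chondrostei = rep(0.5, 5),
                                              Holostei = rep(0.5, 5),
                                              Teleostei = rep(0.5, 5)),
                          trait_sds = rep(0.05, 5))
  tr <- generateTraitDataset(des, seed = 14, n_specimens = 1000)
  X <- as.matrix(tr$traits[paste0("char", 1:5)])
  ord <- shapePCA(X[complete.cases(X), ])
  # sorted sample eigenvalues of an isotropic 5-D normal at n ~ 1000 spread
  # by a few percent around the common share
  expect_lt(max(abs(unname(ord$proportion) - 0.2)), 0.07)
})

test_that("well-separated ecotype clusters drive the centroid test", {
  des <- simulationDesign(missing_rates = rep(0, 5))
  tr <- generateTraitDataset(des, seed = 15, n_specimens = 200)
  X <- as.matrix(tr$traits[paste0("char", 1:5)])
  rownames(X) <- tr$traits$specimen_id
  holo <- tr$records$specimen_id[tr$records$infraclass == "Holostei"][1:30]
  tele <- tr$records$specimen_id[tr$records$infraclass == "Teleostei"][1:30]
  r <- centroidShiftTest(X, holo, tele, B = 9999, seed = 16)
  expect_lte(r$p_value, 0.001)
})

test_that("null pairs are exchangeable and reproducible", {
  p1 <- generateNullPair(20, 20, dim = 3, seed = 17)
  p2 <- generateNullPair(20, 20, dim = 3, seed = 17)
  expect_identical(p1$scores, p2$scores)
  expect_length(intersect(p1$members_A, p1$members_B), 0)
  expect_equal(nrow(p1$scores), 40)
  # relabelling halves leaves the pooled sample untouched
  expect_identical(sort(c(p1$members_A, p1$members_B)), 1:40)
})
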