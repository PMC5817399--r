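test_that("sum of variances matches hand computation and is axis-monotone", {
  sc <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  rownames(sc) <- paste0("s", 1:4)
  expect_equal(sumOfVariances(sc, 1:4), 4 / 3 + 4 / 3)
  expect_equal(sumOfVariances(matrix(1, 5, 3), 1:5), 0)
  expect_true(is.na(sumOfVariances(sc, 1)))       # singleton
  set.seed(41)
  sc5 <- matrix(rnorm(100), 20, 5)
  expect_lte(sumOfVariances(sc5, 1:20, axes = 1:2),
             sumOfVariances(sc5, 1:20))
  # rotation invariance: total variance equals centroid-deviation form
  dev <- sweep(sc5, 2, colMeans(sc5))
  expect_equal(sumOfVariances(sc5, 1:20), sum(dev^2) / 19, tolerance = 1e-12)
})

test_that("mean pairwise distance matches hand cases and scales linearly", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))
  expect_equal(meanPairwiseDistance(pts, 1:3), mean(c(3, 4, 5)))
  expect_equal(meanPairwiseDistance(rbind(c(0, 0), c(1, 1)), 1:2), sqrt(2))
  expect_equal(meanPairwiseDistance(2 * pts, 1:3),
               2 * meanPairwiseDistance(pts, 1:3))
  expect_true(is.na(meanPairwiseDistance(pts, 1)))
  # accepts a precomputed distance matrix
  expect_equal(meanPairwiseDistance(as.matrix(dist(pts)), 1:3), 4)
})

test_that("hull areas match the shoelace oracle and interior points", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(convexHullVolume(sq), 1)
  expect_equal(convexHullVolume(rbind(sq, c(0.5, 0.5))), 1)
  set.seed(42)
  for (trial in 1:20) {
    pts <- matrix(rnorm(2 * sample(4:12, 1)), ncol = 2)
    expect_equal(convexHullVolume(pts), shoelaceArea(pts), tolerance = 1e-10)
  }
  # degenerate: collinear points have no area, reported missing
  expect_true(is.na(convexHullVolume(cbind(1:5, 2 * (1:5)))))
})

test_that("hull content is monotone under added points and permutation-proof", {
  set.seed(43)
  pts <- matrix(rnorm(30), ncol = 3)
  v <- convexHullVolume(pts)
  expect_equal(convexHullVolume(pts[sample(10), ]), v, tolerance = 1e-10)
  v2 <- convexHullVolume(rbind(pts, rnorm(3)))
  expect_gte(v2, v - 1e-12)
  # known solids
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convexHullVolume(cube), 1, tolerance = 1e-12)
  simplex4 <- rbind(diag(4), 0)
  expect_equal(convexHullVolume(simplex4), 1 / factorial(4), tolerance = 1e-12)
})

test_that("hullMeasure flags undersized and degenerate bins as missing", {
  set.seed(44)
  sc <- matrix(rnorm(40), 8, 5)
  rownames(sc) <- paste0("s", 1:8)
  expect_false(is.na(hullMeasure(sc, 1:8, 2)))
  small <- hullMeasure(sc, 1:3, 3)               # 3 points cannot span 3-D
  expect_true(is.na(small))
  expect_match(attr(small, "reason"), "fewer points")
  expect_error(hullMeasure(sc, 1:8, 6), "n_axes")
})

test_that("series normalization maps the maximum to one and keeps NAs", {
  expect_equal(normalizeSeries(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(normalizeSeries(c(3, NA, 6)), c(0.5, NA, 1))
  expect_equal(normalizeSeries(c(5, 5, 5)), c(1, 1, 1))
  expect_error(normalizeSeries(c(NA_real_, NA_real_)), "all values missing")
})

test_that("bootstrap CIs are seeded, degenerate-safe and sensible", {
  sc <- matrix(1, 6, 2)
  rownames(sc) <- paste0("s", 1:6)
  ci <- bootstrapCI(function(m) sumOfVariances(sc, m), paste0("s", 1:6),
                    B = 200, seed = 5)
  expect_equal(c(ci$mean, ci$low, ci$high), c(0, 0, 0))
  set.seed(45)
  sc2 <- matrix(rnorm(80), 40, 2)
  rownames(sc2) <- paste0("s", 1:40)
  f <- function(m) sumOfVariances(sc2, m)
  ci1 <- bootstrapCI(f, rownames(sc2), B = 300, seed = 11)
  ci2 <- bootstrapCI(f, rownames(sc2), B = 300, seed = 11)
  expect_identical(ci1, ci2)
  expect_lt(ci1$low, ci1$mean)
  expect_gt(ci1$high, ci1$mean)
  # metric undefined on most resamples: missing interval with a warning
  collinear <- cbind(1:4, 2 * (1:4))
  rownames(collinear) <- paste0("s", 1:4)
  expect_warning(
    bad <- bootstrapCI(function(m) as.numeric(hullMeasure(collinear, m, 2)),
                       paste0("s", 1:4), B = 50, seed = 2),
    "reported missing")
  expect_true(is.na(bad$mean))
})

test_that("Foote partial disparity decomposes the bin total additively", {
  sc <- rbind(c(-1, 0), c(1, 0))
  rownames(sc) <- c("a", "b")
  pd <- partialDisparity(sc, c("a", "b"), c("A", "B"))
  expect_equal(unname(pd$partial), c(1, 1))
  expect_equal(pd$total, 2)
  set.seed(46)
  sc2 <- matrix(rnorm(140), 20, 7)
  rownames(sc2) <- paste0("s", 1:20)
  # one group containing everything equals the sum of variances
  pd_all <- partialDisparity(sc2, rownames(sc2), rep("all", 20))
  expect_equal(unname(pd_all$partial), sumOfVariances(sc2, rownames(sc2)),
               tolerance = 1e-12)
  # arbitrary partitions: exact additivity
  for (trial in 1:10) {
    labels <- sample(letters[1:sample(2:5, 1)], 20, replace = TRUE)
    pd <- partialDisparity(sc2, rownames(sc2), labels)
    expect_equal(pd$total, sumOfVariances(sc2, rownames(sc2)),
                 tolerance = 1e-12)
    expect_equal(sum(pd$share), 1, tolerance = 1e-12)
  }
  expect_true(is.na(partialDisparity(sc2, "s1", "A")$total))
})

test_that("disparity series report bins, CIs and minimum-n policy", {
  sch <- twoBinScheme()
  md <- makeMetadata(paste0("s", 1:12),
                     stage = c(rep("StageA", 10), rep("StageB", 2)))
  set.seed(47)
  sc <- matrix(rnorm(24), 12, 2)
  rownames(sc) <- md$specimen_id
  bd <- assignBins(md, sch)
  ds <- disparitySeries(bd, sc, "variance", B = 100, seed = 3)
  expect_equal(nrow(ds), 2)
  big <- ds[ds$bin == "older", ]
  expect_false(is.na(big$value))
  expect_lte(big$ci_low, big$ci_high)
  expect_equal(big$n, 10)
  # the two-specimen bin falls below the default minimum of 3
  expect_true(is.na(ds$value[ds$bin == "younger"]))
  ds2 <- disparitySeries(bd, sc, "variance", B = 0, min_n = 2)
  expect_false(any(is.na(ds2$value)))
  # hull series are normalized to a maximum of exactly 1
  dh <- disparitySeries(bd, sc, "hull", n_axes = 2, B = 0, min_n = 2)
  expect_equal(max(dh$value, na.rm = TRUE), 1)
})
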