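test_that("bending energy matrix has the thin-plate-spline properties", {
  set.seed(17)
  ref <- matrix(rnorm(20), 10, 2)
  bem <- bendingEnergyMatrix(ref)
  M <- bem$matrix
  expect_equal(M, t(M))
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-9)
  # affine annihilation: M 1 = M x = M y = 0
  expect_lt(max(abs(M %*% cbind(1, ref))), 1e-9)
  # matches an independent bordered-system inversion
  D <- as.matrix(dist(ref))
  K <- ifelse(D > 0, D^2 * log(D^2), 0)
  L <- rbind(cbind(K, 1, ref), cbind(t(cbind(1, ref)), matrix(0, 3, 3)))
  M2 <- solve(L)[1:10, 1:10]
  expect_equal(M, (M2 + t(M2)) / 2, tolerance = 1e-9)
})

test_that("bending energy is zero for affine maps, positive otherwise", {
  set.seed(18)
  ref <- fishBodyTemplate()
  bem <- bendingEnergyMatrix(ref)
  expect_equal(bendingEnergy(bem, ref), 0, tolerance = 1e-9)
  for (i in 1:5) {
    A <- matrix(rnorm(4, sd = 0.5), 2) + diag(2)
    b <- rnorm(2)
    target <- ref %*% A
    target[, 1] <- target[, 1] + b[1]; target[, 2] <- target[, 2] + b[2]
    expect_equal(bendingEnergy(bem, target), 0, tolerance = 1e-9)
  }
  bumped <- ref
  bumped[16, ] <- bumped[16, ] + c(0, 0.05)
  expect_gt(bendingEnergy(bem, bumped), 1e-6)
})

test_that("already-optimal semilandmarks do not move", {
  scheme <- fishBodyScheme()
  base <- fishBodyTemplate()
  al <- gpa(lapply(1:4, function(i) transformCopy(base)))
  sl <- slideSemilandmarks(al, scheme)
  # identical shapes: offsets to consensus are zero, so zero displacement
  expect_equal(sl$aligned, al$aligned, tolerance = 1e-7)
  expect_equal(sl$slide_cycles, 1)
})

test_that("semilandmarks on a straight chord stay on that chord", {
  # sliders 4 and 5 sit between fixed neighbours 3 and 6 on a line
  sch <- landmarkScheme(8, c(1, 2, 3, 6, 7, 8),
                        rbind(c(3, 4, 5), c(4, 5, 6)))
  base <- rbind(c(0, 0), c(1, 1.2), c(2, 1.5), c(3, 1.5), c(4, 1.5),
                c(5, 1.5), c(4, -1), c(1.5, -1.2))
  set.seed(19)
  cfgs <- lapply(1:6, function(i) {
    m <- base
    m[c(1, 2, 7, 8), ] <- m[c(1, 2, 7, 8), ] + matrix(rnorm(8, sd = 0.1), 4)
    m[4, 1] <- m[4, 1] + rnorm(1, sd = 0.2)   # slide noise along the chord
    m[5, 1] <- m[5, 1] + rnorm(1, sd = 0.2)
    transformCopy(m)
  })
  sl <- slideSemilandmarks(gpa(cfgs), sch)
  for (i in 1:6) {
    m <- sl$aligned[, , i]
    for (s in 4:5) {
      u <- m[6, ] - m[3, ]; u <- u / sqrt(sum(u^2))
      v <- m[s, ] - m[3, ]
      off <- v - sum(v * u) * u
      expect_lt(sqrt(sum(off^2)), 1e-6)
    }
  }
})

test_that("the GLS slide matches a grid-search oracle on a toy case", {
  # one slider on an 8-landmark shape: exhaustive search over its tangent
  # offset must agree with the closed-form solve
  set.seed(23)
  ref <- centerAndScale(matrix(rnorm(16), 8, 2))$coords
  bem <- bendingEnergyMatrix(ref)
  X <- ref + matrix(rnorm(16, sd = 0.05), 8, 2)
  triples <- rbind(c(2L, 5L, 7L))
  colnames(triples) <- c("before", "slider", "after")
  res <- morphodisp:::.slideOne(X, ref, bem$matrix, triples)
  u <- X[7, ] - X[2, ]; u <- u / sqrt(sum(u^2))
  grid <- seq(-0.6, 0.6, by = 1e-4)
  energies <- vapply(grid, function(t) {
    Y <- X; Y[5, ] <- Y[5, ] + t * u
    bendingEnergy(bem, Y)
  }, numeric(1))
  best <- grid[which.min(energies)]
  expect_lt(max(abs(res$X[5, ] - (X[5, ] + best * u))), 1e-4)
  # and the slide never lands above the grid minimum
  expect_lte(bendingEnergy(bem, res$X), min(energies) + 1e-10)
})

test_that("sliding lowers bending energy and reports a monotone history", {
  des <- simulationDesign(n_per_bin = 4, bin_variances = rep(0.01, 17))
  sim <- generateLandmarkDataset(des, seed = 29)
  sl <- slideSemilandmarks(gpa(sim$configurations), des$scheme)
  eh <- sl$energy_history
  expect_true(all(eh$energy_after <= eh$energy_before + 1e-9))
  expect_true(all(diff(eh$energy_after) <= 1e-9))
  expect_equal(sl$n_fallback, 0)
})
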