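test_that("jaw characters follow their ratio definitions", {
  m <- data.frame(specimen_id = "a", inlever = 2, outlever_anterior = 8,
                  outlever_posterior = 4, max_depth = 3, jaw_length = 12,
                  jaw_area = 24, tooth_row = 6)
  ch <- computeCharacters(m)
  expect_equal(ch$char1, 0.25)
  expect_equal(ch$char2, 0.5)
  expect_equal(ch$char3, 0.25)
  expect_equal(ch$char4, 24 / 144)
  expect_equal(ch$char5, 0.5)
  # missingness propagates per character
  m$outlever_posterior <- NA
  ch <- computeCharacters(m)
  expect_true(is.na(ch$char2))
  expect_equal(ch$char1, 0.25)
  m$inlever <- -1
  expect_error(computeCharacters(m), "non-positive.*inlever")
})

test_that("characters are invariant to measurement units", {
  set.seed(37)
  m <- data.frame(specimen_id = "a", inlever = runif(1, 1, 3),
                  outlever_anterior = runif(1, 5, 9),
                  outlever_posterior = runif(1, 3, 6),
                  max_depth = runif(1, 2, 4), jaw_length = runif(1, 8, 14),
                  jaw_area = runif(1, 15, 40), tooth_row = runif(1, 4, 8))
  for (c_scale in c(0.1, 2.54, 1000)) {
    m2 <- m
    lin <- c("inlever", "outlever_anterior", "outlever_posterior",
             "max_depth", "jaw_length", "tooth_row")
    m2[lin] <- m[lin] * c_scale
    m2$jaw_area <- m$jaw_area * c_scale^2
    expect_equal(as.numeric(computeCharacters(m2)[-1]),
                 as.numeric(computeCharacters(m)[-1]), tolerance = 1e-12)
  }
})

test_that("species averaging uses all available specimens per character", {
  tr <- data.frame(specimen_id = c("s1", "s2", "s3"),
                   char1 = c(0.2, 0.4, 0.3), char2 = c(0.5, NA, NA),
                   char3 = c(0.2, 0.3, 0.1), char4 = c(NA, NA, NA),
                   char5 = c(NA, NA, 0.6))
  sp <- c(s1 = "A", s2 = "A", s3 = "B")
  avg <- averageBySpecies(tr, sp)
  expect_equal(avg$char1[avg$specimen_id == "A"], 0.3)
  # char present in only one specimen: that value carries through
  expect_equal(avg$char2[avg$specimen_id == "A"], 0.5)
  expect_equal(avg$char5[avg$specimen_id == "B"], 0.6)
  # missing in all members stays missing
  expect_true(all(is.na(avg$char4)))
  # single-specimen species pass through unchanged
  expect_equal(as.numeric(avg[avg$specimen_id == "B", c("char1", "char3")]),
               c(0.3, 0.1))
})

test_that("missingness rate and complete-case filter agree with counts", {
  tr <- data.frame(specimen_id = c("a", "b"),
                   char1 = c(0.2, 0.3), char2 = c(NA, 0.5),
                   char3 = c(0.1, 0.2), char4 = c(0.4, NA),
                   char5 = c(0.6, 0.7))
  expect_equal(missingnessRate(tr), 0.2)
  cc <- completeCaseFilter(tr)
  expect_equal(cc$n_complete, 0)
  full <- tr; full$char2[1] <- 0.4; full$char4[2] <- 0.1
  expect_equal(missingnessRate(full), 0)
  cc <- completeCaseFilter(full)
  expect_equal(cc$n_complete, 2)
  expect_identical(cc$traits, full)
})

test_that("averaging and filtering commute under uniform missingness", {
  set.seed(38)
  # species whose specimens share the same missingness pattern
  pat <- rbind(c(TRUE, TRUE, TRUE, TRUE, TRUE),
               c(TRUE, FALSE, TRUE, TRUE, FALSE),
               c(TRUE, TRUE, TRUE, TRUE, TRUE))
  rows <- list(); sp <- character(0)
  for (s in 1:3) for (r in 1:2) {
    v <- runif(5, 0.1, 1)
    v[!pat[s, ]] <- NA
    rows[[length(rows) + 1]] <- v
    sp <- c(sp, LETTERS[s])
  }
  tr <- data.frame(specimen_id = paste0("x", 1:6),
                   do.call(rbind, rows))
  names(tr)[-1] <- paste0("char", 1:5)
  spmap <- setNames(sp, tr$specimen_id)
  a_then_f <- completeCaseFilter(averageBySpecies(tr, spmap))$traits
  f_then_a <- averageBySpecies(completeCaseFilter(tr)$traits,
                               spmap[completeCaseFilter(tr)$traits$specimen_id])
  expect_equal(a_then_f$specimen_id, f_then_a$specimen_id)
  expect_equal(as.matrix(a_then_f[-1]), as.matrix(f_then_a[-1]),
               tolerance = 1e-12, ignore_attr = TRUE)
})
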