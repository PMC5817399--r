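test_that("TPS records parse with ids, scale semantics and file order", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=a",
               "LM=3", "0 0", "1 0", "0 1", "SCALE=0.5",
               "IMAGE=C:\\scans\\fish_02.jpg"), f)
  recs <- readTPS(f)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$specimen_id, "a")
  expect_equal(recs[[1]]$coords, rbind(c(0, 0), c(1, 0), c(0, 1)))
  # SCALE multiplies coordinates; IMAGE basename is the id fallback
  expect_equal(recs[[2]]$coords, rbind(c(0, 0), c(0.5, 0), c(0, 0.5)))
  expect_equal(recs[[2]]$specimen_id, "fish_02")
})

test_that("malformed TPS records raise located parse errors", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "ID=a"), f)
  expect_error(readTPS(f), "record 1.*coordinate lines")
  writeLines(c("LM=2", "0 0", "1 zebra", "ID=a"), f)
  expect_error(readTPS(f), "coordinate line 2")
})

test_that("TPS write/read round trip preserves coordinates exactly", {
  set.seed(41)
  cfgs <- lapply(1:3, function(i)
    list(specimen_id = paste0("s", i),
         coords = matrix(rnorm(12) * 10^runif(1, -3, 3), 6, 2),
         scale = NA_real_))
  f <- withr::local_tempfile(fileext = ".tps")
  writeTPS(cfgs, f)
  back <- readTPS(f)
  for (i in 1:3) {
    expect_identical(back[[i]]$specimen_id, cfgs[[i]]$specimen_id)
    expect_identical(back[[i]]$coords, cfgs[[i]]$coords)
  }
})

test_that("sliders files parse, allow shared neighbours, reject reuse", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("3,4,5", f)
  expect_equal(unname(readSliders(f)[1, ]), c(3L, 4L, 5L))
  # empty file: all-fixed scheme
  writeLines(character(0), f)
  expect_equal(nrow(readSliders(f)), 0)
  # a landmark may neighbour one slider and slide itself
  writeLines(c("3,4,5", "4,6,7"), f)
  expect_equal(nrow(readSliders(f)), 2)
  # but a slider may only be defined once
  writeLines(c("2,4,6", "3,4,5"), f)
  expect_error(readSliders(f), "duplicate slider")
})

test_that("landmark scheme invariants are enforced at assembly", {
  expect_error(landmarkScheme(4, 1:4, rbind(c(1, 2, 3))), "disjoint")
  expect_error(landmarkScheme(5, 1:3, rbind(c(1, 4, 9))), "out of range")
  expect_error(landmarkScheme(5, 1:3, rbind(c(1, 4, 4))), "distinct")
  expect_error(landmarkScheme(6, 1:3, rbind(c(1, 4, 5))), "cover")
  sch <- landmarkScheme(5, c(1, 2, 3), rbind(c(2, 4, 5), c(4, 5, 1)))
  expect_s3_class(sch, "landmark_scheme")
})

test_that("metadata reader enforces the categorical enumerations", {
  f <- withr::local_tempfile(fileext = ".csv")
  md <- makeMetadata(c("a", "b"))
  write.csv(md, f, row.names = FALSE)
  expect_equal(readMetadata(f)$specimen_id, c("a", "b"))
  md$environment[2] <- "lacustrine"
  write.csv(md, f, row.names = FALSE)
  expect_error(readMetadata(f), "row 2.*lacustrine")
  write.csv(md[, -3], f, row.names = FALSE)
  expect_error(readMetadata(f), "missing required column.*genus")
})

test_that("disparity series CSV round-trips values exactly", {
  s <- data.frame(bin = c("b1", "b2", "b3"), metric = "variance",
                  value = c(0.123456789, 2.5, NA),
                  ci_low = c(0.1, 2.0, NA), ci_high = c(0.2, 3.0, NA),
                  n = c(10L, 20L, 1L))
  f <- withr::local_tempfile(fileext = ".csv")
  writeSeries(f, s)
  back <- readSeries(f)
  expect_equal(back$value, s$value)
  expect_equal(back$ci_high, s$ci_high)
  expect_equal(back$n, s$n)
})

test_that("trait table reader types characters and flags bad values", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,char1,char2,char3,char4,char5",
               "a,0.25,,0.3,0.16,0.5",
               "b,0.3,0.7,0.2,0.1,0.4"), f)
  tt <- readTraitTable(f)
  expect_true(is.na(tt$char2[1]))
  expect_equal(tt$char4[2], 0.1)
  writeLines(c("specimen_id,char1,char2,char3,char4,char5",
               "a,-0.25,0.5,0.3,0.16,0.5"), f)
  expect_error(readTraitTable(f), "non-positive")
})
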