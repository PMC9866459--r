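test_that("statistical features match hand arithmetic", {
  v <- extract_statistical(c(1, 2, 3, 4))
  expect_equal(unname(v["f08_0"]), 2.5)
  expect_equal(unname(v["f13_0"]), 1.25)        # population variance
  expect_equal(unname(v["f12_0"]), sqrt(7.5))   # RMS
  expect_equal(unname(v["f06_0"]), 1)
  expect_equal(unname(v["f07_0"]), 4)
  expect_equal(sum(v[grep("^f04_", names(v))]), 4)  # histogram counts sum to n
})

test_that("constant windows impute moment ratios to zero", {
  v <- extract_statistical(rep(5, 8))
  expect_equal(unname(v["f14_0"]), 0)
  expect_equal(unname(v["f16_0"]), 0)
  expect_equal(unname(v["f15_0"]), 0)
  tv <- extract_temporal(rep(5, 8), fs = 11)
  expect_equal(unname(tv["f30_0"]), 0)  # zero crossings
  expect_equal(unname(tv["f32_0"]), 0)  # traveled distance
  expect_equal(unname(tv["f33_0"]), 0)  # slope
})

test_that("negating a signal preserves variance and flips skewness", {
  set.seed(3)
  s <- rnorm(64)^3
  a <- extract_statistical(s)
  b <- extract_statistical(-s)
  expect_equal(unname(a["f13_0"]), unname(b["f13_0"]))
  expect_equal(unname(a["f16_0"]), -unname(b["f16_0"]))
})

test_that("temporal features match brute-force counts", {
  v <- extract_temporal(c(1, -1, 1, -1), fs = 11)
  expect_equal(unname(v["f30_0"]), 3)  # zero crossings
  expect_equal(unname(v["f31_0"]), 2)  # peak to peak
  expect_equal(unname(v["f27_0"]), 6)  # sum of absolute differences

  # strict local maxima / minima on an alternating signal
  v2 <- extract_temporal(c(0, 1, 0, 1, 0), fs = 11)
  expect_equal(unname(v2["f28_0"]), 2)
  expect_equal(unname(v2["f29_0"]), 1)
})

test_that("spectral features localize a pure tone", {
  fs <- 11; n <- 66
  t <- (0:(n - 1)) / fs
  s <- sin(2 * pi * 2 * t)  # 2 Hz, integer number of cycles -> no leakage
  v <- extract_spectral(s, fs)
  expect_equal(unname(v["f36_0"]), 2, tolerance = fs / n)  # fundamental
  expect_equal(unname(v["f45_0"]), 2, tolerance = fs / n)  # max frequency
  expect_lt(unname(v["f54_0"]), 0.1)                       # spread near 0
  expect_equal(unname(v["f37_0"]), 1, tolerance = 1e-6)    # in walking band
})

test_that("white noise has near-maximal spectral entropy", {
  set.seed(9)
  v <- extract_spectral(rnorm(256), fs = 11)
  expect_gt(unname(v["f42_0"]), 0.85)
  expect_lte(unname(v["f42_0"]), 1)
})

test_that("the all-zero window imputes every spectral feature to zero", {
  v <- extract_spectral(rep(0, 66), fs = 11)
  expect_true(all(v == 0))
})

test_that("positive scaling is covariant for scale features, invariant for counts", {
  set.seed(21)
  s <- rnorm(64)
  c0 <- 3.7
  a <- extract_all(s, 11)
  b <- extract_all(c0 * s, 11)
  for (nm in c("f08_0", "f12_0", "f14_0")) {
    expect_equal(unname(b[nm]), c0 * unname(a[nm]), tolerance = 1e-9)
  }
  for (nm in c("f28_0", "f29_0", "f30_0", "f34_0")) {
    expect_equal(unname(b[nm]), unname(a[nm]))
  }
})

test_that("the feature matrix has a deterministic schema and 60 groups", {
  rec <- accel_recording("s1", rnorm(132), rnorm(132), rnorm(132),
                         labels = rep(c("walking", "other"), c(70, 62)))
  segs <- segment_recording(rec, 6)
  fm <- build_feature_matrix(segs[1:2])
  expect_identical(nrow(fm$values), 2L)
  expect_length(fm$group_map, 60)
  expect_identical(as.integer(names(fm$group_map)), 1:60)
  # group map partitions the columns
  all_cols <- sort(unlist(fm$group_map, use.names = FALSE))
  expect_identical(all_cols, seq_len(ncol(fm$values)))
  # purity: same segment twice gives identical rows
  fm2 <- build_feature_matrix(list(segs[[1]], segs[[1]]))
  expect_identical(fm2$values[1, ], fm2$values[2, ])
  # no non-finite values survive
  expect_true(all(is.finite(fm$values)))
  expect_error(build_feature_matrix(list()), "no segments")
})

test_that("feature matrix round-trips to CSV with the documented header", {
  rec <- accel_recording("s1", rnorm(132), rnorm(132), rnorm(132))
  fm <- build_feature_matrix(segment_recording(rec, 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_identical(names(back)[1:2], c("subject_id", "label"))
  expect_identical(names(back)[-(1:2)], colnames(fm$values))
  expect_equal(as.matrix(back[, -(1:2)]), fm$values, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("standardization uses training statistics and tolerates constants", {
  X <- cbind(a = c(1, 2, 3, 4), b = rep(7, 4))
  sc <- standardize_fit(X)
  Z <- standardize_apply(X, sc)
  expect_equal(mean(Z[, "a"]), 0)
  expect_equal(sd(Z[, "a"]), 1)
  expect_true(all(Z[, "b"] == 0))  # constant column: unit scale, zero center
})
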