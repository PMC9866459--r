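test_that("imbalance bookkeeping matches the target-ratio arithmetic", {
  labs <- rep(c("walking", "other"), c(20, 80))
  ic <- imbalance_counts(labs, target_ratio = 1.0)
  expect_identical(ic$minority, "walking")
  expect_identical(ic$n_synthetic_needed, 60L)
  expect_identical(imbalance_counts(rep(c("walking", "other"), c(80, 80)))$n_synthetic_needed, 0L)
  expect_identical(imbalance_counts(labs, target_ratio = 0.5)$n_synthetic_needed, 20L)
  expect_error(imbalance_counts(rep("walking", 5)), "both classes")
})

test_that("allocation weights reflect boundary density and sum to one", {
  # one minority point inside the majority cloud, one far away
  X <- rbind(matrix(rnorm(40, sd = 0.1), 20, 2),
             c(0, 0),       # minority, surrounded by majority
             c(50, 50))     # minority, isolated
  labs <- c(rep("other", 20), "walking", "walking")
  aw <- allocation_weights(X, labs, k_neighbors = 5)
  expect_equal(sum(aw$weights), 1)
  expect_equal(aw$r[1], 1)   # all 5 neighbours are majority
  expect_equal(aw$r[2], 1)   # nearest non-self points are majority too
  # now give the isolated point minority company
  X2 <- rbind(X, matrix(50 + rnorm(20, sd = 0.1), 10, 2))
  labs2 <- c(labs, rep("walking", 10))
  aw2 <- allocation_weights(X2, labs2, k_neighbors = 5)
  r_far <- aw2$r[2]
  expect_equal(r_far, 0)     # its neighbourhood is now all-minority
  expect_equal(sum(aw2$weights), 1)
})

test_that("largest-remainder counts are integers summing exactly", {
  set.seed(8)
  for (i in 1:20) {
    w <- runif(sample(3:30, 1)); w <- w / sum(w)
    need <- sample(0:500, 1)
    cnt <- allocation_counts(w, need)
    expect_identical(sum(cnt), need)
    expect_true(all(cnt >= 0))
    expect_true(all(abs(cnt - w * need) < 1))
  }
})

test_that("synthetic points interpolate parent and neighbour exactly", {
  set.seed(12)
  Xm <- matrix(rnorm(30 * 4), 30, 4)
  gen <- generate_synthetic(Xm, counts = rep(3L, 30), k_neighbors = 5, seed = 2)
  expect_identical(nrow(gen$rows), 90L)
  pr <- gen$provenance
  expect_true(all(pr$lambda >= 0 & pr$lambda <= 1))
  recon <- Xm[pr$parent_row, ] +
    (Xm[pr$neighbor_row, ] - Xm[pr$parent_row, ]) * pr$lambda
  expect_equal(gen$rows, recon, tolerance = 1e-9, ignore_attr = TRUE)
  # collinear and between: |p - d| + |d - n| == |p - n|
  dpar <- sqrt(rowSums((gen$rows - Xm[pr$parent_row, ])^2))
  dnei <- sqrt(rowSums((gen$rows - Xm[pr$neighbor_row, ])^2))
  dtot <- sqrt(rowSums((Xm[pr$parent_row, ] - Xm[pr$neighbor_row, ])^2))
  expect_equal(dpar + dnei, dtot, tolerance = 1e-9)
})

test_that("oversampling balances the classes and is reproducible", {
  set.seed(4)
  X <- rbind(matrix(rnorm(160 * 3), 160, 3),
             matrix(rnorm(40 * 3, mean = 1.5), 40, 3))
  labs <- rep(c("other", "walking"), c(160, 40))
  ovs <- adasyn_oversample(X, labs, adasyn_config(seed = 6),
                           subject_id = rep(c("a", "b"), 100))
  tab <- table(ovs$labels)
  expect_identical(unname(tab["walking"]), unname(tab["other"]))
  expect_identical(sum(ovs$synthetic), 120L)
  expect_true(all(ovs$labels[ovs$synthetic] == "walking"))
  expect_true(all(ovs$provenance$parent_subject %in% c("a", "b")))
  ovs2 <- adasyn_oversample(X, labs, adasyn_config(seed = 6),
                            subject_id = rep(c("a", "b"), 100))
  expect_identical(ovs, ovs2)
  # already balanced: no-op
  bal <- adasyn_oversample(X[1:80, ], rep(c("walking", "other"), 40))
  expect_identical(sum(bal$synthetic), 0L)
})

test_that("a fractional target ratio under-fills deliberately", {
  set.seed(4)
  X <- matrix(rnorm(200 * 2), 200, 2)
  labs <- rep(c("other", "walking"), c(150, 50))
  ovs <- adasyn_oversample(X, labs, adasyn_config(target_ratio = 0.8, seed = 1))
  expect_identical(sum(ovs$labels == "walking"), 120L)  # round(0.8 * 150)
})
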