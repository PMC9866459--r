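test_that("velocity update follows the inertia/nostalgia/global rule", {
  cfg <- swarm_config()
  # stationary at the optimum: all attraction terms vanish
  x <- rep(0.5, 60)
  expect_equal(update_velocity(rep(0, 60), x, x, x, cfg, 0.3, 0.8), rep(0, 60))
  # pure inertia
  cfg1 <- swarm_config(omega = 1, c1 = 0, c2 = 0)
  v <- runif(60, -1, 1)
  expect_equal(update_velocity(v, rep(0, 60), rep(1, 60), rep(1, 60),
                               cfg1, 0.9, 0.9), v)
  # hand arithmetic: 0.9*1 + 2*0.5*(1-0) + 2*0.5*(2-0) = 3.9
  out <- update_velocity(rep(1, 60), rep(0, 60), rep(1, 60), rep(2, 60),
                         swarm_config(), 0.5, 0.5)
  expect_equal(out, rep(3.9, 60))
  # clamping
  out2 <- update_velocity(rep(4, 60), rep(0, 60), rep(4, 60), rep(4, 60),
                          swarm_config(), 1, 1)
  expect_true(all(out2 == 4))
  expect_error(update_velocity(rep(0, 59), rep(0, 60), rep(0, 60),
                               rep(0, 60), cfg, 0.5, 0.5), "equal length")
})

test_that("position update is additive", {
  expect_equal(update_position(rep(0, 60), rep(0, 60)), rep(0, 60))
  expect_equal(update_position(rep(1, 60), rep(-1, 60)), rep(0, 60))
  x <- runif(60); v1 <- runif(60); v2 <- runif(60)
  expect_equal(update_position(update_position(x, v1), v2), x + v1 + v2)
})

test_that("sigmoid binarization saturates, repairs and reproduces", {
  set.seed(1)
  expect_true(all(binarize_position(rep(20, 60))))
  m <- binarize_position(rep(-20, 60))
  expect_identical(sum(m), 1L)  # repair forces exactly one bit on
  set.seed(33); a <- binarize_position(rnorm(60))
  set.seed(33); b <- binarize_position(rnorm(60))
  expect_identical(a, b)
})

test_that("fitness combines wrapper error and subset-size penalty", {
  sep <- separable_xy(n = 60)
  X <- cbind(sep$X, matrix(rnorm(60 * 58), 60))
  colnames(X) <- paste0("c", 1:60)
  mask30 <- rep(c(TRUE, FALSE), 30)
  mask30[1:2] <- TRUE  # keep the informative columns in
  err_only <- pso_fitness(mask30, X, sep$y,
                          cfg = fitness_config(alpha = 1, beta = 0, seed = 4))
  full <- pso_fitness(mask30, X, sep$y,
                      cfg = fitness_config(alpha = 0.9, beta = 0.1, seed = 4))
  expect_equal(full, 0.9 * err_only + 0.1 * sum(mask30) / 60, tolerance = 1e-12)
  # perfectly separable with all features: error 0, fitness = beta * 1
  all_mask <- rep(TRUE, 2)
  expect_equal(pso_fitness(all_mask, sep$X, sep$y,
                           cfg = fitness_config(seed = 4)), 0.1,
               tolerance = 1e-12)
  expect_error(pso_fitness(rep(FALSE, 60), X, sep$y), "empty")
})

test_that("selection histories are monotone, bounded and reproducible", {
  pp <- planted_problem(n = 120, seed = 2)
  sw <- swarm_config(n_particles = 10, max_iter = 8, seed = 7)
  fc <- fitness_config(seed = 7)
  a <- select_features(pp$X, pp$y, swarm_cfg = sw, fit_cfg = fc)
  b <- select_features(pp$X, pp$y, swarm_cfg = sw, fit_cfg = fc)
  expect_identical(a, b)
  expect_true(all(diff(a$fitness_history) <= 0))
  expect_lte(a$n_iter, 8)
  expect_identical(a$selected, which(a$best_mask))

  one <- select_features(pp$X, pp$y,
                         swarm_cfg = swarm_config(n_particles = 5,
                                                  max_iter = 1, seed = 1),
                         fit_cfg = fc)
  expect_length(one$fitness_history, 1)
  expect_error(select_features(pp$X, rep("other", 120)), "both classes")
})

test_that("a seeded swarm recovers planted informative groups", {
  pp <- planted_problem(n = 160, informative = c(3, 17, 25, 44, 60), seed = 5)
  sel <- select_features(pp$X, pp$y,
                         swarm_cfg = swarm_config(n_particles = 20,
                                                  max_iter = 25, seed = 9),
                         fit_cfg = fitness_config(seed = 9))
  expect_gte(length(intersect(sel$selected, pp$informative)), 4)
})

test_that("selection results export to JSON", {
  pp <- planted_problem(n = 80, seed = 3)
  sel <- select_features(pp$X, pp$y,
                         swarm_cfg = swarm_config(n_particles = 5,
                                                  max_iter = 2, seed = 1),
                         fit_cfg = fitness_config(seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(as.integer(back$selected), sel$selected)
  expect_equal(back$best_fitness, sel$best_fitness)
})
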