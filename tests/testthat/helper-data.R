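# Shared fixtures, built in code.

# tiny simulated cohort for pipeline tests
tiny_cohort <- function(n_subjects = 3, seed = 11,
                        duration_range = c(280, 320)) {
  simulate_cohort(cohort_spec(n_subjects = n_subjects,
                              duration_range = duration_range, seed = seed))
}

# fast PSO settings for pipeline-level tests
fast_cv_config <- function(seed = 1, ...) {
  cv_config(seed = seed,
            swarm = swarm_config(n_particles = 8L, max_iter = 6L,
                                 stagnation = 3L),
            ...)
}

# planted feature-selection problem: `informative` of `n_groups` columns
# carry a class mean shift, the rest are noise
planted_problem <- function(n = 200, n_groups = 60, informative = 1:5,
                            shift = 2, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  y <- rep(c("walking", "other"), length.out = n)
  X <- matrix(rnorm(n * n_groups), n, n_groups,
              dimnames = list(NULL, paste0("g", seq_len(n_groups))))
  X[y == "walking", informative] <- X[y == "walking", informative] + shift
  list(X = X, y = y, informative = informative)
}

# well-separated two-class toy in 2-D
separable_xy <- function(n = 60, seed = 5) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  y <- rep(c("walking", "other"), each = n / 2)
  X <- matrix(rnorm(2 * n, sd = 0.4), n, 2, dimnames = list(NULL, c("a", "b")))
  X[y == "walking", ] <- X[y == "walking", ] + 3
  list(X = X, y = y)
}
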