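#' Swarm configuration for binary PSO feature selection
#'
#' Canonical constriction-free PSO with inertia weight 0.9 and acceleration
#' constants c1 = c2 = 2; per-step scalar random factors r1, r2 ~ U(0, 1).
#' Velocities are clamped to `[-v_max, v_max]` so the sigmoid transfer stays
#' responsive. The swarm stops at `max_iter` iterations or after `stagnation`
#' iterations without improvement of the global best.
#'
#' @param n_particles Swarm size (default 30).
#' @param max_iter Maximum iterations (default 50).
#' @param omega Inertia weight (default 0.9).
#' @param c1,c2 Nostalgia and global acceleration constants (default 2).
#' @param v_max Velocity clamp (default 4).
#' @param stagnation Early-stop patience in iterations (default 10).
#' @param seed Integer seed for the swarm's random stream.
#' @return A list of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 30L, max_iter = 50L, omega = 0.9,
                         c1 = 2, c2 = 2, v_max = 4, stagnation = 10L,
                         seed = 1L) {
  stopifnot(n_particles >= 2, max_iter >= 1, v_max > 0)
  structure(list(n_particles = as.integer(n_particles),
                 max_iter = as.integer(max_iter), omega = omega,
                 c1 = c1, c2 = c2, v_max = v_max,
                 stagnation = as.integer(stagnation),
                 seed = as.integer(seed)),
            class = "swarm_config")
}

#' Fitness configuration for wrapper feature selection
#'
#' The selection objective is `alpha * error + beta * n_selected / n_groups`,
#' trading classification error against subset size. The error term is the
#' misclassification rate of a k-nearest-neighbour wrapper under a stratified
#' inner k-fold on the training rows (the cheapest member of the pipeline's
#' own model family). For large training sets the inner evaluation uses a
#' stratified subsample of at most `max_rows` rows, drawn once per selection
#' run, so that wrapper cost does not scale with cohort size.
#'
#' @param alpha Weight of the error term (default 0.9).
#' @param beta Weight of the subset-size term (default 0.1).
#' @param wrapper_k Neighbours for the kNN wrapper (default 5).
#' @param inner_folds Inner stratified folds for the error estimate (default 3).
#' @param max_rows Cap on rows used by the wrapper (default 300).
#' @param seed Integer seed for the inner folds and subsample.
#' @return A list of class `fitness_config`.
#' @export
fitness_config <- function(alpha = 0.9, beta = 0.1, wrapper_k = 5L,
                           inner_folds = 3L, max_rows = 300L, seed = 1L) {
  stopifnot(alpha >= 0, beta >= 0, inner_folds >= 2)
  structure(list(alpha = alpha, beta = beta, wrapper_k = as.integer(wrapper_k),
                 inner_folds = as.integer(inner_folds),
                 max_rows = as.integer(max_rows), seed = as.integer(seed)),
            class = "fitness_config")
}

#' PSO velocity update
#'
#' `v' = omega * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)`, clamped
#' componentwise to `[-v_max, v_max]`.
#'
#' @param velocity,position,pbest,gbest Numeric vectors of equal length.
#' @param cfg A [swarm_config()].
#' @param r1,r2 Scalar random factors in `[0, 1]`.
#' @return The new velocity vector.
#' @export
update_velocity <- function(velocity, position, pbest, gbest, cfg, r1, r2) {
  d <- length(position)
  if (length(velocity) != d || length(pbest) != d || length(gbest) != d) {
    stop("velocity, position, pbest and gbest must have equal length",
         call. = FALSE)
  }
  v <- cfg$omega * velocity +
    cfg$c1 * r1 * (pbest - position) +
    cfg$c2 * r2 * (gbest - position)
  pmin(pmax(v, -cfg$v_max), cfg$v_max)
}

#' PSO position update
#'
#' @param position,velocity Numeric vectors of equal length.
#' @return `position + velocity`.
#' @export
update_position <- function(position, velocity) {
  stopifnot(length(position) == length(velocity))
  position + velocity
}

#' Stochastic sigmoid binarization of a particle position
#'
#' Standard binary-PSO transfer: bit j is on iff
#' `sigmoid(position_j) > u_j`, `u_j ~ U(0, 1)` drawn from the current RNG
#' stream. An all-zero mask is repaired by forcing on the single component
#' with the highest sigmoid value (selection must keep at least one group).
#'
#' @param position Numeric vector.
#' @return Logical mask of the same length.
#' @export
binarize_position <- function(position) {
  s <- 1 / (1 + exp(-position))
  mask <- s > stats::runif(length(position))
  if (!any(mask)) mask[which.max(s)] <- TRUE
  mask
}

#' Wrapper fitness of a feature-group mask
#'
#' `alpha * error + beta * n_selected / n_groups`, where `error` is the inner
#' cross-validated misclassification rate of the kNN wrapper restricted to
#' the columns of the selected groups.
#'
#' @param mask Logical vector over feature groups; at least one `TRUE`.
#' @param X Standardized numeric feature matrix (training rows).
#' @param y Character labels (`"walking"` / `"other"`).
#' @param group_map Named list mapping group to column indices, as in a
#'   [build_feature_matrix()] result. `NULL` means one column per group.
#' @param cfg A [fitness_config()].
#' @param folds Optional precomputed inner fold assignment (integer vector
#'   over rows of `X`); computed from `cfg$seed` when missing.
#' @return Scalar fitness (smaller is better).
#' @export
pso_fitness <- function(mask, X, y, group_map = NULL, cfg = fitness_config(),
                        folds = NULL) {
  if (!any(mask)) stop("empty feature mask", call. = FALSE)
  if (is.null(group_map)) group_map <- as.list(seq_len(ncol(X)))
  stopifnot(length(mask) == length(group_map))
  cols <- sort(unlist(group_map[mask], use.names = FALSE))
  if (is.null(folds)) folds <- .inner_folds(y, cfg$inner_folds, cfg$seed)
  err <- .wrapper_error(X[, cols, drop = FALSE], y, folds, cfg$wrapper_k)
  cfg$alpha * err + cfg$beta * sum(mask) / length(mask)
}

# stratified fold ids (values 0 = excluded by the row cap)
.inner_folds <- function(y, k, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# cap wrapper rows: keep a stratified subsample, mark the rest fold 0
.cap_folds <- function(y, folds, max_rows, seed) {
  n <- length(y)
  if (n <= max_rows) return(folds)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed + 1L)
  keep <- unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(2L, round(length(idx) * max_rows / n)))
  }))
  folds[setdiff(seq_len(n), keep)] <- 0L
  folds
}

# misclassification rate of kNN over the inner folds
.wrapper_error <- function(X, y, folds, k) {
  wrong <- 0L
  total <- 0L
  for (f in setdiff(unique(folds), 0L)) {
    te <- folds == f
    tr <- !te & folds != 0L
    kk <- min(k, sum(tr))
    pred <- class::knn(X[tr, , drop = FALSE], X[te, , drop = FALSE],
                       factor(y[tr]), k = kk)
    wrong <- wrong + sum(as.character(pred) != y[te])
    total <- total + sum(te)
  }
  wrong / total
}

#' Binary PSO feature-subset selection
#'
#' Runs a swarm over the feature-group space: velocities follow the inertia /
#' nostalgia / global-attraction update, positions accumulate velocities, and
#' masks are obtained by stochastic sigmoid thresholding. Each particle's
#' personal best and the swarm's global best track the smallest fitness seen,
#' so the returned fitness history is non-increasing by construction. Ties in
#' the global-best update are broken first-found.
#'
#' @param X Standardized numeric feature matrix (training rows only).
#' @param y Character labels; both classes must be present.
#' @param group_map Group-to-columns map (see [pso_fitness()]); `NULL` means
#'   one column per group.
#' @param swarm_cfg A [swarm_config()].
#' @param fit_cfg A [fitness_config()].
#' @return An object of class `selection_result`: list with `best_mask`
#'   (logical), `best_fitness`, `fitness_history` (global best after each
#'   iteration), `n_iter`, and `selected` (feature-group numbers).
#' @examples
#' \donttest{
#' X <- matrix(rnorm(200 * 8), 200)
#' y <- ifelse(X[, 1] + X[, 2] > 0, "walking", "other")
#' sel <- select_features(X, y, swarm_cfg = swarm_config(10, 15, seed = 2))
#' sel$selected
#' }
#' @export
select_features <- function(X, y, group_map = NULL,
                            swarm_cfg = swarm_config(),
                            fit_cfg = fitness_config()) {
  if (length(unique(y)) < 2) {
    stop("feature selection needs both classes present", call. = FALSE)
  }
  if (is.null(group_map)) group_map <- as.list(seq_len(ncol(X)))
  if (is.null(names(group_map))) names(group_map) <- seq_along(group_map)
  d <- length(group_map)
  folds <- .inner_folds(y, fit_cfg$inner_folds, fit_cfg$seed)
  folds <- .cap_folds(y, folds, fit_cfg$max_rows, fit_cfg$seed)
  fit_fun <- function(mask) pso_fitness(mask, X, y, group_map, fit_cfg, folds)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(swarm_cfg$seed)
  np <- swarm_cfg$n_particles
  pos <- matrix(stats::runif(np * d, -1, 1), np, d)
  vel <- matrix(stats::runif(np * d, -1, 1), np, d)
  masks <- t(apply(pos, 1, binarize_position))
  fitness <- apply(masks, 1, fit_fun)
  pbest_pos <- pos
  pbest_fit <- fitness
  g <- which.min(fitness)
  gbest_pos <- pos[g, ]
  gbest_mask <- masks[g, ]
  gbest_fit <- fitness[g]

  history <- numeric(0)
  stagnant <- 0L
  for (iter in seq_len(swarm_cfg$max_iter)) {
    improved <- FALSE
    for (i in seq_len(np)) {
      r1 <- stats::runif(1); r2 <- stats::runif(1)
      vel[i, ] <- update_velocity(vel[i, ], pos[i, ], pbest_pos[i, ],
                                  gbest_pos, swarm_cfg, r1, r2)
      pos[i, ] <- update_position(pos[i, ], vel[i, ])
      mask <- binarize_position(pos[i, ])
      fit <- fit_fun(mask)
      if (fit < pbest_fit[i]) {
        pbest_fit[i] <- fit
        pbest_pos[i, ] <- pos[i, ]
      }
      if (fit < gbest_fit) {
        gbest_fit <- fit
        gbest_pos <- pos[i, ]
        gbest_mask <- mask
        improved <- TRUE
      }
    }
    history <- c(history, gbest_fit)
    stagnant <- if (improved) 0L else stagnant + 1L
    if (stagnant >= swarm_cfg$stagnation) break
  }
  structure(
    list(best_mask = gbest_mask, best_fitness = gbest_fit,
         fitness_history = history, n_iter = length(history),
         selected = as.integer(names(group_map))[gbest_mask]),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d/%d groups, fitness %.4f after %d iterations\n",
              sum(x$best_mask), length(x$best_mask), x$best_fitness, x$n_iter))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.selection_result <- function(x, ...) {
  graphics::plot(seq_along(x$fitness_history), x$fitness_history, type = "s",
                 xlab = "iteration", ylab = "global best fitness", ...)
  invisible(x)
}

#' Export a selection result as JSON
#'
#' @param sel A `selection_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(
    list(selected = sel$selected, best_fitness = sel$best_fitness,
         fitness_history = sel$fitness_history),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# save/restore the global RNG state so seeded internals do not disturb the
# caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
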