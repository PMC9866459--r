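#' ADASYN oversampling configuration
#'
#' @param k_neighbors Number of nearest neighbours K (default 5, the method's
#'   canonical choice).
#' @param target_ratio Desired minority/majority count ratio after
#'   oversampling, in `(0, 1]` (default 1, full balance).
#' @param seed Integer seed for neighbour choice and interpolation draws.
#' @return A list of class `adasyn_config`.
#' @export
adasyn_config <- function(k_neighbors = 5L, target_ratio = 1.0, seed = 1L) {
  stopifnot(k_neighbors >= 1, target_ratio > 0, target_ratio <= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_ratio = target_ratio, seed = as.integer(seed)),
            class = "adasyn_config")
}

#' Class imbalance bookkeeping
#'
#' @param labels Character labels with both classes present.
#' @param target_ratio Desired minority/majority ratio.
#' @return List with `minority` (class name), `n_minority`, `n_majority`,
#'   and `n_synthetic_needed` =
#'   `max(0, round(target_ratio * n_majority) - n_minority)`.
#' @export
imbalance_counts <- function(labels, target_ratio = 1.0) {
  tab <- table(labels)
  if (length(tab) < 2) {
    stop("both classes must be present to measure imbalance", call. = FALSE)
  }
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab)
  n_maj <- max(tab)
  list(minority = minority,
       n_minority = as.integer(n_min),
       n_majority = as.integer(n_maj),
       n_synthetic_needed = max(0L, as.integer(round(target_ratio * n_maj) - n_min)))
}

#' Boundary-density allocation weights
#'
#' For each minority row, the fraction `r_i` of majority points among its K
#' nearest neighbours in the full training set measures how close the row sits
#' to the class boundary; ADASYN synthesizes more points where `r_i` is high.
#' Weights are the `r_i` normalized to sum 1, with a uniform fallback when all
#' `r_i` are zero (no minority row has majority neighbours).
#'
#' @param X Standardized numeric matrix of all training rows.
#' @param labels Character labels for the rows of `X`.
#' @param k_neighbors Neighbourhood size K.
#' @return List with `weights` (over minority rows, summing to 1), `r`
#'   (raw majority fractions) and `minority_rows` (row indices into `X`).
#' @export
allocation_weights <- function(X, labels, k_neighbors = 5L) {
  counts <- imbalance_counts(labels)
  min_rows <- which(labels == counts$minority)
  k <- min(k_neighbors, nrow(X) - 1L)
  # K+1 because the query point is its own nearest neighbour
  nn <- FNN::get.knnx(X, X[min_rows, , drop = FALSE], k = k + 1L)$nn.index
  r <- vapply(seq_along(min_rows), function(i) {
    nb <- setdiff(nn[i, ], min_rows[i])[seq_len(k)]
    mean(labels[nb] != counts$minority)
  }, 0)
  if (sum(r) == 0) {
    warning("no minority row has majority neighbours; using uniform weights",
            call. = FALSE)
    w <- rep(1 / length(min_rows), length(min_rows))
  } else {
    w <- r / sum(r)
  }
  list(weights = w, r = r, minority_rows = min_rows)
}

#' Integer synthesis counts by largest-remainder rounding
#'
#' Distributes `n_needed` synthetic points over minority rows proportionally
#' to `weights` such that the counts sum exactly to `n_needed`.
#'
#' @param weights Non-negative weights summing to 1.
#' @param n_needed Total synthetic points required.
#' @return Integer vector of per-row counts.
#' @export
allocation_counts <- function(weights, n_needed) {
  raw <- weights * n_needed
  base <- floor(raw)
  short <- n_needed - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate synthetic minority points by neighbour interpolation
#'
#' Each synthetic point is `d = x_i + (x_k - x_i) * lambda` with `x_k` drawn
#' uniformly from the K nearest *minority* neighbours of parent `x_i` and
#' `lambda ~ U(0, 1)`, so every synthetic point lies on the segment between
#' its parent and the chosen neighbour. A minority row with no minority
#' neighbour generates nothing (recorded in the `skipped` element).
#'
#' @param X_minority Numeric matrix of minority rows.
#' @param counts Integer synthesis count per minority row.
#' @param k_neighbors Neighbourhood size K among minority rows.
#' @param seed Integer seed.
#' @return List with `rows` (synthetic matrix), `provenance` (data frame
#'   `synthetic_id, parent_row, neighbor_row, lambda`, rows indexing
#'   `X_minority`), and `skipped` (parent rows that could not generate).
#' @export
generate_synthetic <- function(X_minority, counts, k_neighbors = 5L, seed = 1L) {
  n_min <- nrow(X_minority)
  stopifnot(length(counts) == n_min)
  if (n_min < 2) {
    return(list(rows = X_minority[0, , drop = FALSE],
                provenance = data.frame(synthetic_id = integer(),
                                        parent_row = integer(),
                                        neighbor_row = integer(),
                                        lambda = numeric()),
                skipped = which(counts > 0)))
  }
  k <- min(k_neighbors, n_min - 1L)
  nn <- FNN::get.knnx(X_minority, X_minority, k = k + 1L)$nn.index
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  parents <- rep(seq_len(n_min), counts)
  total <- length(parents)
  if (total == 0L) {
    return(list(rows = X_minority[0, , drop = FALSE],
                provenance = data.frame(synthetic_id = integer(),
                                        parent_row = integer(),
                                        neighbor_row = integer(),
                                        lambda = numeric()),
                skipped = integer()))
  }
  rows <- matrix(0, total, ncol(X_minority),
                 dimnames = list(NULL, colnames(X_minority)))
  neigh <- integer(total)
  lambda <- numeric(total)
  for (s in seq_len(total)) {
    i <- parents[s]
    pool <- setdiff(nn[i, ], i)[seq_len(k)]
    j <- pool[sample.int(length(pool), 1L)]
    l <- stats::runif(1)
    rows[s, ] <- X_minority[i, ] + (X_minority[j, ] - X_minority[i, ]) * l
    neigh[s] <- j
    lambda[s] <- l
  }
  list(rows = rows,
       provenance = data.frame(synthetic_id = seq_len(total),
                               parent_row = parents, neighbor_row = neigh,
                               lambda = lambda),
       skipped = integer())
}

#' Adaptive synthetic oversampling of the minority class
#'
#' The three ADASYN steps in one call: measure the imbalance, weight minority
#' rows by the majority fraction among their K nearest neighbours in the full
#' training set (Euclidean distance on standardized features), then
#' interpolate towards K nearest minority neighbours. Oversampling belongs on
#' training rows only; the per-fold pipeline enforces that and records the
#' provenance of every synthetic row.
#'
#' @param X Standardized numeric matrix of training rows.
#' @param labels Character labels for `X`.
#' @param cfg An [adasyn_config()].
#' @param subject_id Optional per-row subject identifiers, carried into the
#'   provenance table.
#' @return An object of class `oversampled_set`: list with `X` (original rows
#'   then synthetic rows), `labels`, `synthetic` (logical row tags), and
#'   `provenance` (per synthetic row: parent/neighbour indices into `X`,
#'   lambda, and parent subject when supplied).
#' @export
adasyn_oversample <- function(X, labels, cfg = adasyn_config(),
                              subject_id = NULL) {
  counts <- imbalance_counts(labels, cfg$target_ratio)
  if (counts$n_synthetic_needed == 0L) {
    return(structure(list(X = X, labels = labels,
                          synthetic = rep(FALSE, nrow(X)),
                          provenance = data.frame()),
                     class = "oversampled_set"))
  }
  alloc <- allocation_weights(X, labels, cfg$k_neighbors)
  per_row <- allocation_counts(alloc$weights, counts$n_synthetic_needed)
  gen <- generate_synthetic(X[alloc$minority_rows, , drop = FALSE], per_row,
                            cfg$k_neighbors, cfg$seed)
  prov <- gen$provenance
  prov$parent_row <- alloc$minority_rows[prov$parent_row]
  prov$neighbor_row <- alloc$minority_rows[prov$neighbor_row]
  if (!is.null(subject_id)) prov$parent_subject <- subject_id[prov$parent_row]
  structure(
    list(X = rbind(X, gen$rows),
         labels = c(labels, rep(counts$minority, nrow(gen$rows))),
         synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(gen$rows))),
         provenance = prov),
    class = "oversampled_set"
  )
}

#' @export
print.oversampled_set <- function(x, ...) {
  cat(sprintf("<oversampled_set> %d rows (%d synthetic); classes: %s\n",
              nrow(x$X), sum(x$synthetic),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}
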