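#' Classifier specification
#'
#' The pipeline compares four models: k-nearest neighbours, random forest,
#' gradient-boosted trees, and a stacking ensemble whose level-0 members are
#' the first three and whose level-1 meta-estimator is a logistic regression
#' on out-of-fold class probabilities. Hyperparameters default to the
#' libraries' canonical values and all stochastic fits are seeded.
#'
#' @param kind One of `"knn"`, `"rf"`, `"xgb"`, `"stack"`.
#' @param seed Integer seed.
#' @param ... Hyperparameter overrides: `knn_k` (kNN neighbours, 5),
#'   `ntree` (forest size, 100), `nrounds`/`max_depth`/`eta`
#'   (boosting: 100, 3, 0.1), `inner_folds` (stacking folds, 5).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(kind = c("knn", "rf", "xgb", "stack"), seed = 1L, ...) {
  kind <- match.arg(kind)
  hp <- utils::modifyList(
    list(knn_k = 5L, ntree = 100L, nrounds = 100L, max_depth = 3L, eta = 0.1,
         inner_folds = 5L),
    list(...)
  )
  structure(list(kind = kind, hyper = hp, seed = as.integer(seed)),
            class = "model_spec")
}

.check_xy <- function(X, y) {
  if (nrow(X) < 2) stop("need at least 2 training rows", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (length(y) != nrow(X)) stop("X and y sizes differ", call. = FALSE)
}

#' Train a classifier
#'
#' @param spec A [model_spec()].
#' @param X Numeric feature matrix with column names (the training schema).
#' @param y Character labels, `"walking"` (positive class) or `"other"`.
#' @return An object of class `walk_model` holding the fitted state and the
#'   training column schema; see [predict.walk_model()].
#' @examples
#' X <- matrix(rnorm(60), 30, dimnames = list(NULL, c("a", "b")))
#' y <- ifelse(X[, 1] > 0, "walking", "other")
#' m <- train_model(model_spec("rf", seed = 7), X, y)
#' table(predict(m, X), y)
#' @export
train_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  .check_xy(X, y)
  X <- as.matrix(X)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  fit <- switch(spec$kind,
    knn = list(X = X, y = y, k = min(spec$hyper$knn_k, nrow(X))),
    rf = randomForest::randomForest(
      x = X, y = factor(y, levels = c("other", "walking")),
      ntree = spec$hyper$ntree),
    xgb = xgboost::xgboost(
      X, factor(y, levels = c("other", "walking")),
      objective = "binary:logistic", nrounds = spec$hyper$nrounds,
      max_depth = spec$hyper$max_depth, learning_rate = spec$hyper$eta,
      nthreads = 1, seed = spec$seed, verbosity = 0),
    stack = .fit_stack(spec, X, y)
  )
  structure(list(spec = spec, fit = fit, schema = colnames(X)),
            class = "walk_model")
}

# stacking: stratified internal folds give out-of-fold level-0 probabilities,
# the logistic meta-estimator fits on those, level-0 models refit on all rows
.fit_stack <- function(spec, X, y) {
  folds <- .inner_folds(y, spec$hyper$inner_folds, spec$seed)
  level0_kinds <- c("knn", "rf", "xgb")
  meta_X <- matrix(NA_real_, nrow(X), 3,
                   dimnames = list(NULL, level0_kinds))
  for (f in seq_len(spec$hyper$inner_folds)) {
    tr <- folds != f
    te <- folds == f
    for (kind in level0_kinds) {
      m <- train_model(model_spec(kind, seed = spec$seed,
                                  knn_k = spec$hyper$knn_k, ntree = spec$hyper$ntree,
                                  nrounds = spec$hyper$nrounds,
                                  max_depth = spec$hyper$max_depth,
                                  eta = spec$hyper$eta),
                       X[tr, , drop = FALSE], y[tr])
      meta_X[te, kind] <- predict(m, X[te, , drop = FALSE], type = "score")
    }
  }
  meta_df <- data.frame(meta_X)
  meta_df$.y <- factor(y, levels = c("other", "walking"))
  meta <- suppressWarnings(
    stats::glm(.y ~ ., data = meta_df, family = stats::binomial())
  )
  level0 <- lapply(level0_kinds, function(kind) {
    train_model(model_spec(kind, seed = spec$seed,
                           knn_k = spec$hyper$knn_k, ntree = spec$hyper$ntree,
                           nrounds = spec$hyper$nrounds,
                           max_depth = spec$hyper$max_depth,
                           eta = spec$hyper$eta), X, y)
  })
  names(level0) <- level0_kinds
  list(level0 = level0, meta = meta, meta_features = meta_X, folds = folds)
}

#' Predict classes or walking scores
#'
#' @param object A fitted `walk_model`.
#' @param X Numeric matrix matching the training column schema.
#' @param type `"class"` for `"walking"`/`"other"` labels, `"score"` for
#'   walking-class scores in `[0, 1]` (class probabilities for the
#'   probabilistic models, vote fractions for kNN). Classes are scores
#'   thresholded at 0.5.
#' @param ... Unused.
#' @return Character vector of labels or numeric vector of scores.
#' @export
predict.walk_model <- function(object, X, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (ncol(X) != length(object$schema) ||
      !identical(colnames(X), object$schema)) {
    stop("prediction columns do not match the training schema", call. = FALSE)
  }
  if (nrow(X) == 0L) {
    return(if (type == "class") character(0) else numeric(0))
  }
  score <- switch(object$spec$kind,
    knn = {
      pred <- class::knn(object$fit$X, X,
                         factor(object$fit$y, levels = c("other", "walking")),
                         k = object$fit$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "walking", p, 1 - p)
    },
    rf = unname(stats::predict(object$fit, X, type = "prob")[, "walking"]),
    xgb = unname(stats::predict(object$fit, X)),
    stack = {
      meta_X <- vapply(object$fit$level0,
                       function(m) predict(m, X, type = "score"),
                       numeric(nrow(X)))
      if (nrow(X) == 1L) meta_X <- matrix(meta_X, 1,
                                          dimnames = list(NULL, names(object$fit$level0)))
      # rank-deficient meta fits are expected when level-0 models agree
      # perfectly; the prediction is still well-defined
      unname(suppressWarnings(stats::predict(object$fit$meta,
                                             data.frame(meta_X),
                                             type = "response")))
    }
  )
  if (type == "score") as.numeric(score)
  else ifelse(score > 0.5, "walking", "other")
}

#' @export
print.walk_model <- function(x, ...) {
  cat(sprintf("<walk_model> %s (seed %d), %d features\n",
              x$spec$kind, x$spec$seed, length(x$schema)))
  invisible(x)
}

#' Save / load a fitted model
#'
#' Stores the spec, schema and fitted state in a versioned RDS archive.
#'
#' @param model A `walk_model`.
#' @param path File path.
#' @return `path` invisibly; `read_model` returns the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "walk_model"))
  saveRDS(list(format = "backgait-model-1", model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "backgait-model-1")) {
    stop("not a backgait model archive: ", path, call. = FALSE)
  }
  obj$model
}
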