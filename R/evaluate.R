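#' Leave-one-group-out splits over subjects
#'
#' One split per subject: the held-out subject validates, all others train.
#' Subject-wise splitting prevents within-subject leakage between train and
#' validation segments.
#'
#' @param subject_ids Character vector (possibly with repeats) of subject ids.
#' @return List of splits, each a list with `train_ids` and `validation_id`.
#' @export
logo_splits <- function(subject_ids) {
  ids <- unique(subject_ids)
  if (length(ids) < 2) stop("need at least 2 subjects", call. = FALSE)
  lapply(ids, function(v) list(train_ids = setdiff(ids, v), validation_id = v))
}

#' Confusion matrix with walking as the positive class
#'
#' @param y_true,y_pred Equal-length character vectors over
#'   `{"walking", "other"}`.
#' @return Object of class `confusion_matrix`: list with `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ", call. = FALSE)
  }
  bad <- setdiff(unique(c(y_true, y_pred)), c("walking", "other"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(
    tp = sum(y_true == "walking" & y_pred == "walking"),
    tn = sum(y_true == "other" & y_pred == "other"),
    fp = sum(y_true == "other" & y_pred == "walking"),
    fn = sum(y_true == "walking" & y_pred == "other")
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, byrow = TRUE,
              dimnames = list(c("actual other", "actual walking"),
                              c("pred other", "pred walking")))
  print(m)
  invisible(x)
}

#' @export
as.matrix.confusion_matrix <- function(x, ...) {
  matrix(c(x$tn, x$fp, x$fn, x$tp), 2, byrow = TRUE,
         dimnames = list(c("actual other", "actual walking"),
                         c("pred other", "pred walking")))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, positive predictive
#' value (precision) `TP/(TP+FP)`, and the F-score
#' `(1+beta^2) * PPV * Se / (beta^2 * PPV + Se)`. A metric whose denominator
#' is zero is reported as 0 with a warning.
#'
#' @param cm A [confusion()] result.
#' @param beta F-score weight (default 1, the balanced F1).
#' @return Object of class `metrics_report`: list with `se`, `ppv`, `f1`,
#'   `acc` in `[0, 1]`.
#' @export
classification_metrics <- function(cm, beta = 1) {
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " has zero denominator; reporting 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  se <- safe(cm$tp, cm$tp + cm$fn, "sensitivity")
  ppv <- safe(cm$tp, cm$tp + cm$fp, "PPV")
  f1 <- if (ppv + se == 0) 0 else {
    (1 + beta^2) * ppv * se / (beta^2 * ppv + se)
  }
  structure(list(se = se, ppv = ppv, f1 = f1, acc = (cm$tp + cm$tn) / total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  vals <- unlist(x[c("se", "ppv", "f1", "acc")])
  cat(paste(sprintf("%s %.2f%%", toupper(names(vals)), 100 * vals),
            collapse = "  "), "\n")
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique scores as thresholds (predict walking when
#' `score >= threshold`) and integrates by trapezoid, which equals the
#' normalized Mann-Whitney U statistic (ties counted half).
#'
#' @param y_true Character labels; both classes must be present.
#' @param scores Numeric walking-class scores.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  P <- sum(y_true == "walking")
  N <- sum(y_true == "other")
  if (P == 0 || N == 0) {
    stop("ROC needs both classes in y_true", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- y_true[ord] == "walking"
  last <- cumsum(rep(1, length(s)))[!duplicated(s, fromLast = TRUE)]
  # cumulative counts at each distinct threshold (all ties included)
  uth <- s[!duplicated(s, fromLast = TRUE)]
  ctp <- cumsum(pos)[last]
  cfp <- cumsum(!pos)[last]
  points <- data.frame(threshold = c(Inf, uth),
                       fpr = c(0, cfp / N),
                       tpr = c(0, ctp / P))
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  list(points = points, auc = auc)
}

#' Cross-validation / pipeline configuration
#'
#' @param window_s Segment length in seconds (default 6; 3 and 9 are the
#'   other study lengths).
#' @param models Character subset of `c("knn", "rf", "xgb", "stack")`.
#' @param seed Master seed; per-fold seeds are derived from it and the
#'   held-out subject id, so a leave-one-out fold and a single-subject
#'   holdout with the same master seed coincide.
#' @param select Run PSO feature selection per fold (default `TRUE`);
#'   `FALSE` uses all 60 groups.
#' @param swarm A [swarm_config()] (its `seed` is re-derived per fold).
#' @param fitness A [fitness_config()] (idem).
#' @param adasyn An [adasyn_config()] (idem), or `NULL` to skip oversampling.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(window_s = 6, models = c("knn", "rf", "xgb", "stack"),
                      seed = 1L, select = TRUE,
                      swarm = swarm_config(), fitness = fitness_config(),
                      adasyn = adasyn_config()) {
  models <- match.arg(models, several.ok = TRUE)
  structure(list(window_s = window_s, models = models,
                 seed = as.integer(seed), select = select,
                 swarm = swarm, fitness = fitness, adasyn = adasyn),
            class = "cv_config")
}

# deterministic per-fold seed from the master seed and the held-out subject
.fold_seed <- function(seed, validation_id) {
  (abs(seed) + 31 * sum(utf8ToInt(validation_id))) %% 2147483647L
}

# one train/validate pass shared by LOGO-CV and the holdout evaluation
.run_fold <- function(fm, train_rows, val_rows, config, fold_tag) {
  fseed <- .fold_seed(config$seed, fold_tag)
  ytr <- fm$label[train_rows]
  scaler <- standardize_fit(fm$values[train_rows, , drop = FALSE])
  Xtr <- standardize_apply(fm$values[train_rows, , drop = FALSE], scaler)
  Xval <- standardize_apply(fm$values[val_rows, , drop = FALSE], scaler)

  if (config$select) {
    sw <- config$swarm; sw$seed <- fseed
    fc <- config$fitness; fc$seed <- fseed + 1L
    sel <- select_features(Xtr, ytr, fm$group_map, sw, fc)
  } else {
    mask <- rep(TRUE, length(fm$group_map))
    sel <- structure(list(best_mask = mask, best_fitness = NA_real_,
                          fitness_history = numeric(0), n_iter = 0L,
                          selected = as.integer(names(fm$group_map))),
                     class = "selection_result")
  }
  cols <- mask_columns(fm, sel$best_mask)
  Xtr_s <- Xtr[, cols, drop = FALSE]
  Xval_s <- Xval[, cols, drop = FALSE]

  if (!is.null(config$adasyn)) {
    ac <- config$adasyn; ac$seed <- fseed + 2L
    ovs <- adasyn_oversample(Xtr_s, ytr, ac,
                             subject_id = fm$subject_id[train_rows])
    Xfit <- ovs$X; yfit <- ovs$labels
    synth_parents <- unique(ovs$provenance$parent_subject)
  } else {
    Xfit <- Xtr_s; yfit <- ytr
    synth_parents <- character(0)
  }

  yval <- fm$label[val_rows]
  models <- lapply(config$models, function(kind) {
    m <- train_model(model_spec(kind, seed = fseed + 3L), Xfit, yfit)
    score <- predict(m, Xval_s, type = "score")
    pred <- ifelse(score > 0.5, "walking", "other")
    cm <- confusion(yval, pred)
    met <- classification_metrics(cm)
    roc <- if (length(unique(yval)) == 2) roc_auc(yval, score) else NULL
    list(kind = kind, confusion = cm, metrics = met,
         auc = if (is.null(roc)) NA_real_ else roc$auc,
         roc_points = if (is.null(roc)) NULL else roc$points)
  })
  names(models) <- config$models
  list(selected = sel$selected, fitness_history = sel$fitness_history,
       synthetic_parent_subjects = synth_parents, models = models,
       n_validation = length(val_rows))
}

#' Leave-one-subject-out cross-validated pipeline
#'
#' For each held-out subject: segment, extract features, standardize (fit on
#' training rows only), select feature groups by binary PSO, oversample the
#' training walking class by ADASYN, train the requested classifiers, and
#' evaluate on the held-out subject's segments. Aggregates are unweighted
#' means of the per-subject metrics.
#'
#' @param recordings List of [accel_recording()] objects (at least 2
#'   subjects).
#' @param config A [cv_config()].
#' @return Object of class `cv_report`: list with `folds` (per held-out
#'   subject: confusion matrices, metrics, AUC, selected feature groups,
#'   ADASYN provenance), `aggregate` (data frame of mean metrics per model),
#'   `config`.
#' @export
run_logo_cv <- function(recordings, config = cv_config()) {
  ids <- vapply(recordings, `[[`, "", "subject_id")
  if (length(unique(ids)) < 2) stop("need at least 2 subjects", call. = FALSE)
  segments <- unlist(lapply(recordings, segment_recording,
                            window_s = config$window_s), recursive = FALSE)
  fm <- build_feature_matrix(segments)
  splits <- logo_splits(fm$subject_id)
  folds <- lapply(splits, function(sp) {
    val_rows <- which(fm$subject_id == sp$validation_id)
    train_rows <- which(fm$subject_id != sp$validation_id)
    fold <- .run_fold(fm, train_rows, val_rows, config, sp$validation_id)
    fold$validation_id <- sp$validation_id
    fold$roc_points <- NULL
    fold
  })
  names(folds) <- vapply(splits, `[[`, "", "validation_id")
  structure(list(folds = folds, aggregate = .aggregate_folds(folds, config),
                 config = config),
            class = "cv_report")
}

.aggregate_folds <- function(folds, config) {
  do.call(rbind, lapply(config$models, function(kind) {
    vals <- t(vapply(folds, function(f) {
      m <- f$models[[kind]]
      c(se = m$metrics$se, ppv = m$metrics$ppv, f1 = m$metrics$f1,
        acc = m$metrics$acc, auc = m$auc)
    }, numeric(5)))
    data.frame(model = kind, t(colMeans(vals, na.rm = TRUE)))
  }))
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d leave-one-subject-out folds, window %g s\n",
              length(x$folds), x$config$window_s))
  agg <- x$aggregate
  agg[, -1] <- round(100 * agg[, -1], 2)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  per_fold <- do.call(rbind, lapply(names(object$folds), function(id) {
    f <- object$folds[[id]]
    do.call(rbind, lapply(f$models, function(m) {
      data.frame(subject = id, model = m$kind, se = m$metrics$se,
                 ppv = m$metrics$ppv, f1 = m$metrics$f1, acc = m$metrics$acc,
                 auc = m$auc, n_selected = length(f$selected))
    }))
  }))
  rownames(per_fold) <- NULL
  structure(list(per_fold = per_fold, aggregate = object$aggregate),
            class = "summary.cv_report")
}

#' @export
print.summary.cv_report <- function(x, ...) {
  cat("Per-subject metrics:\n")
  pf <- x$per_fold
  pf[, 3:7] <- round(100 * pf[, 3:7], 2)
  print(pf, row.names = FALSE)
  cat("\nUnweighted means over subjects:\n")
  agg <- x$aggregate
  agg[, -1] <- round(100 * agg[, -1], 2)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cv_report <- function(x, metric = "f1", ...) {
  s <- summary(x)$per_fold
  graphics::boxplot(s[[metric]] ~ s$model, xlab = "model", ylab = metric, ...)
  invisible(x)
}

#' Held-out-subjects evaluation
#'
#' Single-split variant of [run_logo_cv()]: train on `train_ids`, evaluate on
#' the pooled segments of `test_ids`. With a single test subject and the same
#' master seed this reproduces the corresponding LOGO fold.
#'
#' @param recordings List of [accel_recording()] objects.
#' @param train_ids,test_ids Disjoint character vectors of subject ids.
#' @param config A [cv_config()].
#' @return Object of class `holdout_report`: per-model confusion matrix,
#'   metrics, AUC and ROC points, plus the selected feature groups.
#' @export
run_holdout <- function(recordings, train_ids, test_ids,
                        config = cv_config()) {
  if (length(test_ids) == 0L) stop("test_ids is empty", call. = FALSE)
  if (length(intersect(train_ids, test_ids))) {
    stop("train and test subject sets overlap", call. = FALSE)
  }
  ids <- vapply(recordings, `[[`, "", "subject_id")
  missing <- setdiff(c(train_ids, test_ids), ids)
  if (length(missing)) {
    stop("unknown subject ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keep <- recordings[ids %in% c(train_ids, test_ids)]
  segments <- unlist(lapply(keep, segment_recording,
                            window_s = config$window_s), recursive = FALSE)
  fm <- build_feature_matrix(segments)
  train_rows <- which(fm$subject_id %in% train_ids)
  val_rows <- which(fm$subject_id %in% test_ids)
  tag <- if (length(test_ids) == 1L) test_ids else
    paste(sort(test_ids), collapse = "+")
  fold <- .run_fold(fm, train_rows, val_rows, config, tag)
  fold$test_ids <- test_ids
  structure(fold, class = "holdout_report")
}

#' @export
print.holdout_report <- function(x, ...) {
  cat(sprintf("<holdout_report> test subjects: %s (%d segments)\n",
              paste(x$test_ids, collapse = ", "), x$n_validation))
  for (m in x$models) {
    cat(sprintf("%-5s auc %.3f  ", m$kind, m$auc))
    print(m$metrics)
  }
  invisible(x)
}

#' @export
plot.holdout_report <- function(x, ...) {
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false positive rate", ylab = "true positive rate", ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  cols <- seq_along(x$models)
  for (i in cols) {
    p <- x$models[[i]]$roc_points
    if (!is.null(p)) graphics::lines(p$fpr, p$tpr, col = i)
  }
  graphics::legend("bottomright", legend = names(x$models), col = cols, lty = 1)
  invisible(x)
}

#' Export a CV report
#'
#' Writes per-fold metrics as CSV and the full report (metrics, selected
#' features, confusion counts) as JSON.
#'
#' @param report A `cv_report`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return The per-fold data frame, invisibly.
#' @export
write_cv_report <- function(report, csv_path = NULL, json_path = NULL) {
  pf <- summary(report)$per_fold
  if (!is.null(csv_path)) {
    out <- pf
    out[, 3:7] <- round(100 * out[, 3:7], 2)
    utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(aggregate = report$aggregate,
           folds = lapply(report$folds, function(f) {
             list(validation_id = f$validation_id, selected = f$selected,
                  models = lapply(f$models, function(m) {
                    list(confusion = unclass(m$confusion),
                         metrics = unclass(m$metrics), auc = m$auc)
                  }))
           })),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(pf)
}
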