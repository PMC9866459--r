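test_that("leave-one-group-out splits partition the subjects", {
  ids <- sprintf("s%02d", 1:20)
  splits <- logo_splits(ids)
  expect_length(splits, 20)
  for (sp in splits) {
    expect_length(sp$validation_id, 1)
    expect_setequal(c(sp$train_ids, sp$validation_id), ids)
    expect_false(sp$validation_id %in% sp$train_ids)
  }
  expect_setequal(vapply(splits, `[[`, "", "validation_id"), ids)
  two <- logo_splits(c("a", "b", "a"))
  expect_length(two, 2)
  expect_identical(two[[1]]$train_ids, "b")
  expect_error(logo_splits("a"), "at least 2")
})

test_that("confusion counts enumerate correctly and transpose on swap", {
  cm <- confusion(c("walking", "walking", "other", "other"),
                  c("walking", "other", "walking", "other"))
  expect_identical(unclass(cm)[c("tp", "fn", "fp", "tn")],
                   list(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  perfect <- confusion(rep(c("walking", "other"), 5),
                       rep(c("walking", "other"), 5))
  expect_identical(perfect$fp + perfect$fn, 0L)
  set.seed(5)
  yt <- sample(c("walking", "other"), 50, TRUE)
  yp <- sample(c("walking", "other"), 50, TRUE)
  a <- confusion(yt, yp); b <- confusion(yp, yt)
  expect_identical(a$fp, b$fn)
  expect_identical(a$fn, b$fp)
  expect_identical(a$tp + a$tn + a$fp + a$fn, 50L)
  expect_error(confusion(c("walking"), c("running")), "unknown")
  expect_error(confusion(yt, yp[-1]), "differ")
})

test_that("metrics match hand evaluation and degrade safely", {
  cm <- structure(list(tp = 80, tn = 90, fp = 10, fn = 20),
                  class = "confusion_matrix")
  m <- classification_metrics(cm)
  expect_equal(m$se, 0.80, tolerance = 1e-4)
  expect_equal(m$ppv, 8 / 9, tolerance = 1e-4)
  expect_equal(m$acc, 0.85, tolerance = 1e-4)
  expect_equal(m$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8), tolerance = 1e-4)

  perfect <- classification_metrics(confusion(rep("walking", 4), rep("walking", 4)) |>
    (\(x) { x$tn <- 4L; x })())
  expect_true(all(unlist(perfect[c("se", "ppv", "f1", "acc")]) == 1))

  zero <- structure(list(tp = 0, tn = 5, fp = 0, fn = 5),
                    class = "confusion_matrix")
  mz <- suppressWarnings(classification_metrics(zero))
  expect_identical(c(mz$se, mz$f1), c(0, 0))
  expect_error(classification_metrics(
    structure(list(tp = 0, tn = 0, fp = 0, fn = 0),
              class = "confusion_matrix")), "empty")
})

test_that("ROC/AUC equals the pairwise comparison oracle", {
  y <- rep(c("walking", "other"), c(4, 4))
  expect_equal(roc_auc(y, c(1, 1, 1, 1, 0, 0, 0, 0))$auc, 1)
  expect_equal(roc_auc(y, rep(0.3, 8))$auc, 0.5)
  expect_error(roc_auc(rep("walking", 4), runif(4)), "both classes")

  set.seed(14)
  for (i in 1:5) {
    yt <- sample(c("walking", "other"), 50, TRUE, prob = c(0.4, 0.6))
    if (length(unique(yt)) < 2) next
    sc <- round(runif(50), 2)  # rounding forces ties
    r <- roc_auc(yt, sc)
    pos <- sc[yt == "walking"]; neg <- sc[yt == "other"]
    wins <- 0
    for (p in pos) for (q in neg) {
      wins <- wins + (p > q) + 0.5 * (p == q)
    }
    expect_equal(r$auc, wins / (length(pos) * length(neg)), tolerance = 1e-9)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(r$points$fpr[c(1, nrow(r$points))], c(0, 1))
  }
})

test_that("the LOGO pipeline produces disjoint, complete folds", {
  cohort <- tiny_cohort(n_subjects = 4, seed = 3)
  rep1 <- suppressWarnings(run_logo_cv(cohort, fast_cv_config(seed = 2)))
  expect_s3_class(rep1, "cv_report")
  expect_length(rep1$folds, 4)
  ids <- vapply(cohort, `[[`, "", "subject_id")
  expect_setequal(names(rep1$folds), ids)
  # per-fold confusion totals equal the held-out subject's segment count
  for (id in ids) {
    f <- rep1$folds[[id]]
    n_seg <- length(segment_recording(cohort[[which(ids == id)]], 6))
    for (m in f$models) {
      cm <- m$confusion
      expect_identical(cm$tp + cm$tn + cm$fp + cm$fn, n_seg)
    }
    # no synthetic row derives from the held-out subject
    expect_false(id %in% f$synthetic_parent_subjects)
  }
  agg <- rep1$aggregate
  expect_setequal(agg$model, c("knn", "rf", "xgb", "stack"))
  # aggregate is the unweighted mean of per-fold metrics
  f1s <- vapply(rep1$folds, function(f) f$models[["stack"]]$metrics$f1, 0)
  expect_equal(agg$f1[agg$model == "stack"], mean(f1s))
})

test_that("identical seeds give byte-identical CV reports", {
  cohort <- tiny_cohort(n_subjects = 3, seed = 9)
  r1 <- suppressWarnings(run_logo_cv(cohort, fast_cv_config(seed = 7)))
  r2 <- suppressWarnings(run_logo_cv(cohort, fast_cv_config(seed = 7)))
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})

test_that("holdout evaluation matches the corresponding LOGO fold", {
  cohort <- tiny_cohort(n_subjects = 3, seed = 5)
  ids <- vapply(cohort, `[[`, "", "subject_id")
  cfg <- fast_cv_config(seed = 4)
  logo <- suppressWarnings(run_logo_cv(cohort, cfg))
  hold <- suppressWarnings(
    run_holdout(cohort, train_ids = ids[-2], test_ids = ids[2], cfg))
  fold <- logo$folds[[ids[2]]]
  for (kind in cfg$models) {
    expect_identical(unclass(hold$models[[kind]]$confusion),
                     unclass(fold$models[[kind]]$confusion))
    expect_equal(hold$models[[kind]]$auc, fold$models[[kind]]$auc)
  }
  expect_identical(hold$selected, fold$selected)

  expect_error(run_holdout(cohort, ids, ids[1]), "overlap")
  expect_error(run_holdout(cohort, ids[-1], character(0)), "empty")
  expect_error(run_holdout(cohort, ids[-1], "nope"), "unknown subject")
})

test_that("CV reports export to CSV and JSON", {
  cohort <- tiny_cohort(n_subjects = 3, seed = 13)
  rep1 <- suppressWarnings(
    run_logo_cv(cohort, fast_cv_config(seed = 1, select = FALSE)))
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  pf <- write_cv_report(rep1, csv, json)
  expect_identical(nrow(pf), 3L * 4L)
  back <- utils::read.csv(csv)
  expect_identical(nrow(back), 12L)
  j <- jsonlite::read_json(json)
  expect_length(j$folds, 3)
  expect_named(j$folds[[1]]$models, c("knn", "rf", "xgb", "stack"))
})
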