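test_that("class_metrics computes the one-vs-rest arithmetic", {
  truth <- c(rep("pte", 10), rep("no_pte", 10))
  pred <- c(rep("pte", 9), "no_pte", rep("no_pte", 8), "pte", "pte")
  m <- class_metrics(truth, pred, "pte")
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$classification_error, 0.15)

  perfect <- class_metrics(truth, truth, "pte")
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$classification_error, 0)

  expect_error(class_metrics(rep("pte", 5), rep("pte", 5), "pte"),
               "undefined")
})

test_that("Wilson interval matches the closed form and brackets the point", {
  ci <- wilson_ci(9, 10)
  expect_equal(unname(round(ci, 3)), c(0.596, 0.982))
  for (k in c(0, 3, 10)) {
    ci <- wilson_ci(k, 10)
    expect_lte(ci[["lower"]], k / 10 + 1e-12)
    expect_gte(ci[["upper"]], k / 10 - 1e-12)
  }
})

test_that("ROC handles separable, anti-correlated and degenerate responses", {
  truth <- rep(c("pte", "no_pte"), each = 20)
  resp <- as.numeric(truth == "pte")
  expect_equal(class_roc(truth, resp, "pte")$auc, 1)
  expect_equal(class_roc(truth, -resp, "pte")$auc, 0)

  set.seed(3)
  noise <- rnorm(40)
  a <- class_roc(truth, noise, "pte")$auc
  expect_equal(class_roc(truth, -noise, "pte")$auc, 1 - a, tolerance = 1e-10)

  deg <- class_roc(truth, rep(1, 40), "pte")
  expect_true(deg$degenerate)
  expect_equal(deg$auc, 0.5)
})

test_that("truth-independent responses give AUC near one half", {
  set.seed(4)
  n1 <- 200; n2 <- 300
  truth <- c(rep("pte", n1), rep("no_pte", n2))
  auc <- class_roc(truth, rnorm(n1 + n2), "pte")$auc
  sigma <- sqrt((n1 + n2 + 1) / (12 * n1 * n2))
  expect_lte(abs(auc - 0.5), 3 * sigma)
})

test_that("leave-one-dog-out builds one clean fold per dog", {
  st <- small_default_study(1)
  ft <- suppressMessages(feature_table(st))
  log_env <- new.env(); log_env$folds <- list()
  rep_ <- leave_one_dog_out(ft, recording_plsda_spec(log_env))
  expect_equal(rep_$n_folds, 35)
  # the last recorded fit is the calibration model on all dogs
  fold_logs <- head(log_env$folds, 35)
  all_dogs <- unique(ft$dog_id)
  held_out <- vapply(fold_logs,
                     function(f) setdiff(all_dogs, f$dogs), character(1))
  expect_setequal(held_out, all_dogs)
  for (i in seq_along(fold_logs)) {
    expect_length(fold_logs[[i]]$dogs, 34)
    expect_false(held_out[i] %in% fold_logs[[i]]$dogs)
  }
  # every held-out slice is predicted exactly once
  cv <- rep_$predictions[rep_$predictions$mode == "cv", ]
  expect_equal(nrow(cv), nrow(ft))
  per_dog <- dplyr::count(cv, dog_id)
  expect_true(all(per_dog$n == 2))
  # scaling is refit per fold on that fold's training rows only
  for (i in seq_along(fold_logs)) {
    train_rows <- ft[ft$dog_id != held_out[i], ]
    expect_equal(fold_logs[[i]]$scaler_mean,
                 colMeans(as.matrix(train_rows[names(fold_logs[[i]]$scaler_mean)])),
                 tolerance = 1e-12)
  }
})

test_that("folds that lose a class are skipped with a warning", {
  tab <- separable_table(n_per = 6, p = 3, delta = 4,
                         classes = c("healthy", "pte"))
  tab$dog_id <- c(rep("dogA", 6), rep(c("dogB", "dogC"), each = 3))
  # removing dogA removes the whole healthy class; its fold is skipped and
  # the healthy CV metrics become undefined (flagged NA, not silently 0)
  warnings <- capture_warnings(rep_ <- leave_one_dog_out(tab, plsda_spec(2)))
  expect_match(warnings, "lost a class", all = FALSE)
  expect_match(warnings, "undefined", all = FALSE)
  expect_equal(rep_$skipped_folds, "dogA")
  expect_equal(rep_$n_folds, 2)
  healthy_cv <- rep_$metrics[rep_$metrics$class == "healthy" &
                               rep_$metrics$mode == "cv", ]
  expect_true(is.na(healthy_cv$sensitivity))
  expect_error(leave_one_dog_out(tab[tab$dog_id != "dogC", ], plsda_spec(2)),
               "at least 3 dogs")
})

test_that("pooled metrics equal the summed per-fold confusion", {
  rep_ <- cached_report(1, "plsda")
  cv <- rep_$predictions[rep_$predictions$mode == "cv", ]
  for (cl in rep_$classes) {
    per_fold <- lapply(split(cv, cv$dog_id), function(sub) {
      pos <- sub$class_label == cl
      c(tp = sum(pos & sub$.pred_class == cl),
        fn = sum(pos & sub$.pred_class != cl),
        tn = sum(!pos & sub$.pred_class != cl),
        fp = sum(!pos & sub$.pred_class == cl))
    })
    tot <- Reduce(`+`, per_fold)
    m <- rep_$metrics[rep_$metrics$class == cl & rep_$metrics$mode == "cv", ]
    expect_equal(m$sensitivity, unname(tot["tp"] / (tot["tp"] + tot["fn"])))
    expect_equal(m$specificity, unname(tot["tn"] / (tot["tn"] + tot["fp"])))
  }
})

test_that("calibration is at least as optimistic as cross-validation", {
  for (learner in c("plsda", "svm")) {
    m <- cached_report(1, learner)$metrics
    ca <- m[m$mode == "calibration", ]
    cv <- m[m$mode == "cv", ]
    expect_lte(mean(ca$classification_error),
               mean(cv$classification_error) + 0.02)
  }
})

test_that("cv_roc returns a curve per class and mode", {
  curves <- cv_roc(cached_report(1, "plsda"))
  expect_equal(nrow(curves), 6)
  expect_setequal(curves$mode, c("calibration", "cv"))
  expect_true(all(curves$auc >= 0 & curves$auc <= 1))
  pts <- curves$curve[[1]]$points
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})
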