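# ---- learner specifications ------------------------------------------------

#' Learner specifications for cross-validation
#'
#' Thin descriptions of a classifier plus its hyperparameters, consumed by
#' [leave_one_dog_out()]; each fold fits a fresh model (scaling included)
#' from the specification object.
#'
#' @param n_lv Number of PLS latent variables.
#' @param gamma,cost Gaussian-kernel SVM hyperparameters (`gamma = NULL`
#'   uses 1/p on autoscaled features).
#' @return A `learner_spec` list with a `fit(train)` closure.
#' @export
plsda_spec <- function(n_lv = 3) {
  structure(list(name = "plsda", n_lv = n_lv,
                 fit = function(train) fit_plsda(train, n_lv = n_lv)),
            class = "learner_spec")
}

#' @rdname plsda_spec
#' @export
svm_spec <- function(gamma = NULL, cost = 1) {
  structure(list(name = "svm", gamma = gamma, cost = cost,
                 fit = function(train) fit_svm(train, gamma = gamma,
                                               cost = cost)),
            class = "learner_spec")
}

# ---- leave-one-dog-out CV --------------------------------------------------

#' Leave-one-dog-out cross-validation
#'
#' One fold per dog: all slices of the held-out dog are predicted by a model
#' trained on the remaining dogs only — scaling, latent variables and the
#' decision function are all refit per fold, so no statistic of the held-out
#' dog ever leaks into training. Pooled held-out predictions give the
#' cross-validated (CV) metrics; a single fit on all dogs gives the
#' calibration (resubstitution) metrics.
#'
#' @param table Feature table with `dog_id` and `class_label`.
#' @param learner A `learner_spec` ([plsda_spec()] or [svm_spec()]).
#' @return A `cv_report`: `predictions` (per slice, per mode, with
#'   continuous class responses), `metrics` (per class and mode, via
#'   [class_metrics()]), `n_folds`, `skipped_folds`, and the learner name.
#' @export
leave_one_dog_out <- function(table, learner) {
  stopifnot(inherits(learner, "learner_spec"))
  dogs <- unique(table$dog_id)
  if (length(dogs) < 3) abort("leave-one-dog-out CV needs at least 3 dogs.")
  classes <- sort(unique(table$class_label))
  if (length(classes) < 2) abort("need at least 2 classes.")

  meta_cols <- c("dog_id", "class_label", "slice_index")
  preds <- list()
  skipped <- character()
  for (dog in dogs) {
    train <- table[table$dog_id != dog, ]
    test <- table[table$dog_id == dog, ]
    stopifnot(length(intersect(unique(train$dog_id), dog)) == 0)
    if (length(unique(train$class_label)) < 2) {
      warn(sprintf("fold '%s': training set lost a class; fold skipped", dog))
      skipped <- c(skipped, dog)
      next
    }
    model <- learner$fit(train)
    preds[[dog]] <- dplyr::bind_cols(
      test[intersect(meta_cols, names(test))],
      predict(model, test))
  }
  cv_pred <- dplyr::bind_rows(preds)
  cv_pred$mode <- "cv"

  full_model <- learner$fit(table)
  ca_pred <- dplyr::bind_cols(
    table[intersect(meta_cols, names(table))],
    predict(full_model, table))
  ca_pred$mode <- "calibration"

  predictions <- dplyr::bind_rows(ca_pred, cv_pred)
  metrics <- dplyr::bind_rows(lapply(c("calibration", "cv"), function(m) {
    sub <- predictions[predictions$mode == m, ]
    dplyr::bind_rows(lapply(classes, function(cl) {
      row <- tryCatch(
        class_metrics(sub$class_label, sub$.pred_class, cl),
        error = function(e) {
          warn(sprintf("metrics undefined for class '%s' (%s mode)", cl, m))
          tibble::tibble(sensitivity = NA_real_, sens_lower = NA_real_,
                         sens_upper = NA_real_, specificity = NA_real_,
                         spec_lower = NA_real_, spec_upper = NA_real_,
                         classification_error = NA_real_,
                         n_pos = sum(sub$class_label == cl),
                         n_neg = sum(sub$class_label != cl))
        })
      dplyr::bind_cols(tibble::tibble(class = cl, mode = m), row)
    }))
  }))
  structure(list(predictions = predictions, metrics = metrics,
                 n_folds = length(dogs) - length(skipped),
                 skipped_folds = skipped,
                 classes = classes, learner = learner$name,
                 model = full_model),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Leave-one-dog-out CV report (%s), %d folds\n",
              x$learner, x$n_folds))
  print(x$metrics, n = Inf)
  invisible(x)
}

# ---- metrics ---------------------------------------------------------------

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Successes.
#' @param n Trials.
#' @param conf Confidence level (default 0.95).
#' @return Named vector `lower`, `upper`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' One-vs-rest classification metrics for one class
#'
#' Sensitivity (TP rate on the class), specificity (TN rate on the rest),
#' 95% Wilson score confidence intervals for both, and the classification
#' error defined as the mean of the false-negative and false-positive rates,
#' `1 - (sensitivity + specificity)/2`.
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels.
#' @param class The positive class.
#' @param conf CI confidence level.
#' @return One-row tibble of the metrics. Zero positives or zero negatives
#'   raise an error: the metric is undefined, never silently 0.
#' @export
class_metrics <- function(truth, predicted, class, conf = 0.95) {
  stopifnot(length(truth) == length(predicted))
  pos <- truth == class
  if (!any(pos) || all(pos)) {
    abort(sprintf("metrics for class '%s' undefined: need both positive and negative slices.",
                  class))
  }
  tp <- sum(pos & predicted == class)
  fn <- sum(pos & predicted != class)
  tn <- sum(!pos & predicted != class)
  fp <- sum(!pos & predicted == class)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ci_se <- wilson_ci(tp, tp + fn, conf)
  ci_sp <- wilson_ci(tn, tn + fp, conf)
  tibble::tibble(
    sensitivity = sens, sens_lower = ci_se[["lower"]],
    sens_upper = ci_se[["upper"]],
    specificity = spec, spec_lower = ci_sp[["lower"]],
    spec_upper = ci_sp[["upper"]],
    classification_error = 1 - (sens + spec) / 2,
    n_pos = tp + fn, n_neg = tn + fp)
}

# ---- ROC -------------------------------------------------------------------

#' One-vs-rest ROC curve for one class
#'
#' Sweeps every threshold of the continuous class response and reports the
#' (1 - specificity, sensitivity) operating points and the trapezoidal area
#' under the curve. Constant responses give the degenerate diagonal curve
#' with AUC 0.5, flagged in the result.
#'
#' @param truth True class labels.
#' @param response Continuous response toward `class` (higher = more like
#'   the class).
#' @param class The positive class.
#' @return A `roc_curve`: `points` tibble (`fpr`, `tpr`), `auc`, `class`,
#'   `degenerate` flag.
#' @export
class_roc <- function(truth, response, class) {
  stopifnot(length(truth) == length(response))
  pos <- truth == class
  if (!any(pos) || all(pos)) {
    abort(sprintf("ROC for class '%s' undefined: need both classes present.",
                  class))
  }
  if (length(unique(response)) == 1) {
    return(structure(list(
      points = tibble::tibble(fpr = c(0, 1), tpr = c(0, 1)),
      auc = 0.5, class = class, degenerate = TRUE),
      class = "roc_curve"))
  }
  r <- pROC::roc(response = pos, predictor = response, direction = "<",
                 quiet = TRUE, levels = c(FALSE, TRUE))
  pts <- tibble::tibble(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  structure(list(points = pts, auc = as.numeric(pROC::auc(r)),
                 class = class, degenerate = FALSE),
            class = "roc_curve")
}

#' All one-vs-rest ROC curves of a CV report
#'
#' One curve per class and per mode (calibration and cross-validation),
#' built from the continuous class responses stored in the report.
#'
#' @param report A `cv_report`.
#' @return Tibble with columns `class`, `mode`, `auc`, `degenerate` and a
#'   `curve` list-column of `roc_curve` objects.
#' @export
cv_roc <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  grid <- expand.grid(class = report$classes,
                      mode = c("calibration", "cv"),
                      stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cl <- grid$class[i]; m <- grid$mode[i]
    sub <- report$predictions[report$predictions$mode == m, ]
    rc <- class_roc(sub$class_label, sub[[paste0(".resp_", cl)]], cl)
    tibble::tibble(class = cl, mode = m, auc = rc$auc,
                   degenerate = rc$degenerate, curve = list(rc))
  })
}
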