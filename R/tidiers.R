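# broom-style accessors for the fitted objects

#' @export
#' @method tidy ct_pca
tidy.ct_pca <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") return(x$scores)
  tibble::as_tibble(x$loadings, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "component",
                        values_to = "loading")
}

#' @export
#' @method glance ct_pca
glance.ct_pca <- function(x, ...) {
  tibble::tibble(n_components = ncol(x$loadings),
                 explained_variance = sum(x$explained_variance))
}

#' @export
#' @method tidy plsda_model
tidy.plsda_model <- function(x, ...) {
  tibble::as_tibble(x$B, rownames = NULL) |>
    stats::setNames(x$classes) |>
    dplyr::mutate(feature = x$x_names, .before = 1) |>
    tidyr::pivot_longer(-"feature", names_to = "class",
                        values_to = "coefficient")
}

#' @export
#' @method glance plsda_model
glance.plsda_model <- function(x, ...) {
  tibble::tibble(n_lv = x$n_lv, n_classes = length(x$classes),
                 n_train = x$n_train, r2y = x$r2y)
}

#' @export
#' @method glance svm_model
glance.svm_model <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, cost = x$cost,
                 n_classes = length(x$classes), n_train = x$n_train,
                 n_support_vectors = nrow(x$fit$SV))
}

#' @export
#' @method tidy cv_report
tidy.cv_report <- function(x, ...) x$metrics

#' @export
#' @method glance cv_report
glance.cv_report <- function(x, ...) {
  cv <- x$metrics[x$metrics$mode == "cv", ]
  tibble::tibble(learner = x$learner, n_folds = x$n_folds,
                 n_classes = length(x$classes),
                 mean_cv_error = mean(cv$classification_error))
}

#' @export
#' @method tidy roc_curve
tidy.roc_curve <- function(x, ...) x$points

#' @export
#' @method glance roc_curve
glance.roc_curve <- function(x, ...) {
  tibble::tibble(class = x$class, auc = x$auc, degenerate = x$degenerate)
}
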