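#' Bootstrap test for a difference in group means
#'
#' Two-sided resampling test of H0: equal means, suited to small, unequal
#' group sizes where a t-test's normality assumption is doubtful. The test
#' statistic is the studentized mean difference
#' `T = (mean(a) - mean(b)) / sqrt(var(a)/n_a + var(b)/n_b)`; studentizing
#' keeps the test calibrated at small, unequal sizes, where the raw mean
#' difference is markedly anti-conservative. The null distribution is built
#' by translating both samples to the pooled mean and resampling with
#' replacement within each group at its original size; the p-value is
#' `(1 + #{|T*| >= |T|}) / (n_resamples + 1)` (the +1 smoothing keeps p > 0).
#' The reported `observed_diff` is the plain mean difference
#' `mean(a) - mean(b)`.
#'
#' @param a,b Numeric samples (each of length >= 2; sizes may differ).
#' @param n_resamples Bootstrap resamples (default 10000).
#' @param alpha Significance level for the flag (default 0.05).
#' @param seed Optional integer seed for reproducibility.
#' @param feature Optional feature name carried into the result.
#' @return A `bootstrap_result` one-row tibble: `feature`, `observed_diff`,
#'   `p_value`, `n_resamples`, `significant`.
#' @export
bootstrap_mean_test <- function(a, b, n_resamples = 10000, alpha = 0.05,
                                seed = NULL, feature = NA_character_) {
  stopifnot(length(a) >= 2, length(b) >= 2, n_resamples >= 1)
  if (!is.null(seed)) set.seed(seed)
  t_obs <- mean(a) - mean(b)
  pooled <- mean(c(a, b))
  if (all(c(a, b) == c(a, b)[1])) {
    out <- tibble::tibble(feature = feature, observed_diff = t_obs,
                          p_value = 1, n_resamples = as.integer(n_resamples),
                          significant = FALSE)
    class(out) <- c("bootstrap_result", class(out))
    return(out)
  }
  na <- length(a); nb <- length(b)
  stud <- function(ma, va, mb, vb) {
    se <- sqrt(va / na + vb / nb)
    ifelse(se == 0, 0, (ma - mb) / se)
  }
  t_stud <- stud(mean(a), var(a), mean(b), var(b))
  a0 <- a - mean(a) + pooled
  b0 <- b - mean(b) + pooled
  a_star <- matrix(sample(a0, na * n_resamples, replace = TRUE), nrow = na)
  b_star <- matrix(sample(b0, nb * n_resamples, replace = TRUE), nrow = nb)
  ma <- colMeans(a_star); mb <- colMeans(b_star)
  va <- (colSums(a_star^2) - na * ma^2) / (na - 1)
  vb <- (colSums(b_star^2) - nb * mb^2) / (nb - 1)
  t_star <- stud(ma, va, mb, vb)
  p <- (1 + sum(abs(t_star) >= abs(t_stud))) / (n_resamples + 1)
  out <- tibble::tibble(feature = feature, observed_diff = t_obs,
                        p_value = p, n_resamples = as.integer(n_resamples),
                        significant = p < alpha)
  class(out) <- c("bootstrap_result", class(out))
  out
}

#' Screen texture features for mean differences between the diseased groups
#'
#' Runs [bootstrap_mean_test()] per named feature, restricted to one
#' orientation's columns, comparing slices of diseased dogs with PTE against
#' diseased dogs without. The default list holds the six features reported
#' as most relevant for this contrast: entropy, energy, correlation,
#' homogeneity, sum variance and inverse difference normalized. No
#' multiple-testing correction is applied by default (per-feature
#' reporting); `bonferroni = TRUE` divides alpha by the number of features.
#'
#' @param table Feature table containing both diseased classes.
#' @param features Character vector of feature abbreviations (see
#'   [haralick_feature_names]).
#' @param orientation Orientation suffix of the columns to test
#'   (default `"0"`, horizontal).
#' @param n_resamples,alpha,seed Passed to [bootstrap_mean_test()].
#' @param bonferroni Apply a Bonferroni-adjusted alpha to the flags.
#' @return Tibble of `bootstrap_result` rows, one per feature.
#' @export
diseased_feature_screen <- function(table,
                                    features = c("entro", "energ", "corrm",
                                                 "homom", "svarh", "indnc"),
                                    orientation = "0",
                                    n_resamples = 10000, alpha = 0.05,
                                    seed = NULL, bonferroni = FALSE) {
  bad <- setdiff(features, haralick_feature_names)
  if (length(bad) > 0) {
    abort(sprintf("unknown feature(s): %s. Valid names: %s",
                  paste(bad, collapse = ", "),
                  paste(haralick_feature_names, collapse = ", ")))
  }
  cols <- paste0(features, "_", orientation)
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0) {
    abort(sprintf("feature table lacks columns: %s",
                  paste(missing, collapse = ", ")))
  }
  a_rows <- table$class_label == "pte"
  b_rows <- table$class_label == "no_pte"
  if (!any(a_rows) || !any(b_rows)) {
    abort("table must contain both diseased classes (pte, no_pte).")
  }
  eff_alpha <- if (bonferroni) alpha / length(features) else alpha
  if (!is.null(seed)) set.seed(seed)
  dplyr::bind_rows(lapply(seq_along(features), function(i) {
    bootstrap_mean_test(table[[cols[i]]][a_rows], table[[cols[i]]][b_rows],
                        n_resamples = n_resamples, alpha = eff_alpha,
                        feature = features[i])
  }))
}
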