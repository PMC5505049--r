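make_table <- function(X, class_label, dog_id = NULL) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  tibble::tibble(dog_id = dog_id %||% sprintf("d%03d", seq_len(nrow(X))),
                 class_label = class_label) |>
    dplyr::bind_cols(tibble::as_tibble(X))
}

test_that("PCA recovers a rank-1 structure and gives orthogonal scores", {
  set.seed(1)
  t_ <- rnorm(40)
  X <- outer(t_, runif(10, -1, 1)) + 1e-9 * matrix(rnorm(400), 40)
  tab <- make_table(X, sample(c("healthy", "pte"), 40, TRUE))
  fit <- fit_pca(tab, 3)
  expect_gte(fit$explained_variance[1], 1 - 1e-8)
  expect_lte(abs(cor(fit$scores$PC1, fit$scores$PC2)), 1e-6)
  expect_equal(crossprod(fit$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(fit_pca(tab[1, ], 1), "at least 2")
})

test_that("PCA explained-variance fractions account for the total variance", {
  set.seed(2)
  X <- matrix(rnorm(30 * 6), 30)
  tab <- make_table(X, rep(c("a", "b"), 15))
  fit <- fit_pca(tab, 6)
  expect_true(all(diff(fit$all_variance) <= 1e-12))
  expect_lte(sum(fit$all_variance), 1 + 1e-8)
  expect_equal(sum(fit$all_variance), 1, tolerance = 1e-8)
})

test_that("PCA separates healthy from diseased but not the diseased classes", {
  ft <- cached_features(1)
  fit <- fit_pca(ft, 2)
  xy <- as.matrix(fit$scores[, c("PC1", "PC2")])
  healthy_vs_rest <- silhouette_width(xy, ft$class_label == "healthy")
  expect_gte(healthy_vs_rest, 0.3)
  diseased <- ft$class_label != "healthy"
  pte_vs_nopte <- silhouette_width(xy[diseased, ],
                                   ft$class_label[diseased])
  expect_lt(pte_vs_nopte, 0.2)
})

test_that("PLS-DA separates well-separated clouds and validates n_lv", {
  tab <- separable_table(n_per = 15, p = 6, delta = 10)
  fit <- fit_plsda(tab, n_lv = 2)
  pred <- predict(fit, tab)
  expect_equal(pred$.pred_class, tab$class_label)
  expect_true(all(is.finite(as.matrix(pred[paste0(".resp_",
                                                  fit$classes)]))))
  expect_error(fit_plsda(tab, n_lv = 0), "positive")
  expect_error(fit_plsda(tab[tab$class_label == "pte", ], 2), "2 classes")
  expect_error(fit_plsda(tab, n_lv = 50), "rank")
})

test_that("full-rank PLS-DA reproduces least-squares regression", {
  set.seed(7)
  X <- matrix(rnorm(30 * 5), 30)
  y <- sample(c("a", "b", "c"), 30, TRUE)
  tab <- make_table(X, y)
  fit <- fit_plsda(tab, n_lv = 5)
  pred <- predict(fit, tab)
  Y <- outer(y, sort(unique(y)), "==") * 1
  Xs <- scale(X)
  ls_fit <- lm.fit(cbind(1, Xs), Y)
  ls_pred <- cbind(1, Xs) %*% ls_fit$coefficients
  got <- as.matrix(pred[paste0(".resp_", c("a", "b", "c"))])
  expect_equal(unname(got), unname(ls_pred), tolerance = 1e-6)
})

test_that("the first PLS weight vector is the leading singular vector of X'Y", {
  set.seed(12)
  X <- matrix(rnorm(40 * 8), 40)
  y <- sample(c("a", "b"), 40, TRUE)
  tab <- make_table(X, y)
  fit <- fit_plsda(tab, n_lv = 1)
  Xs <- scale(X)
  Yc <- scale(outer(y, c("a", "b"), "==") * 1, scale = FALSE)
  w_ref <- svd(crossprod(Xs, Yc))$u[, 1]
  w_got <- fit$weights[, 1]
  expect_equal(abs(sum(w_ref * w_got)), 1, tolerance = 1e-6)
})

test_that("PLS-DA prediction demands the training columns", {
  tab <- separable_table()
  fit <- fit_plsda(tab, 2)
  broken <- dplyr::rename(tab, zz = "f1")
  expect_error(predict(fit, broken), "f1")
})

test_that("SVM solves the XOR pattern with a Gaussian kernel", {
  xor <- tibble::tibble(
    dog_id = sprintf("d%d", 1:8),
    class_label = rep(c("a", "b", "b", "a"), 2),
    x = rep(c(0, 0, 1, 1), 2) + rep(c(0, 0.05), each = 4),
    y = rep(c(0, 1, 0, 1), 2) + rep(c(0, 0.05), each = 4))
  fit <- fit_svm(xor, gamma = 1, cost = 10)
  expect_equal(predict(fit, xor)$.pred_class, xor$class_label)
  expect_error(fit_svm(xor, gamma = -1), "positive")
  expect_error(fit_svm(xor[xor$class_label == "a", ]), "2 classes")
})

test_that("models are invariant to row order", {
  set.seed(30)
  tab <- separable_table(n_per = 12, p = 4, delta = 2)
  shuf <- tab[sample(nrow(tab)), ]
  expect_equal(sort(fit_pca(tab, 3)$explained_variance),
               sort(fit_pca(shuf, 3)$explained_variance), tolerance = 1e-8)
  expect_equal(fit_plsda(tab, 2)$B, fit_plsda(shuf, 2)$B, tolerance = 1e-8)
  p1 <- predict(fit_svm(tab), tab)
  p2 <- predict(fit_svm(shuf), tab)
  expect_equal(p1$.pred_class, p2$.pred_class)
})

test_that("prediction uses only training-set statistics (no leakage)", {
  set.seed(31)
  train <- separable_table(n_per = 15, p = 4, delta = 3, seed = 1)
  test <- separable_table(n_per = 5, p = 4, delta = 3, seed = 2)
  weird <- test
  weird[paste0("f", 1:4)] <- weird[paste0("f", 1:4)] * 100 + 50
  for (fit in list(fit_plsda(train, 2), fit_svm(train))) {
    alone <- predict(fit, test)
    padded <- predict(fit, dplyr::bind_rows(test, weird))
    expect_equal(alone$.pred_class, padded$.pred_class[seq_len(nrow(test))])
    resp_cols <- grep("^\\.resp_", names(alone), value = TRUE)
    expect_equal(as.matrix(alone[resp_cols]),
                 as.matrix(padded[seq_len(nrow(test)), resp_cols]),
                 tolerance = 1e-10)
  }
})

test_that("PLS-DA latent structure matches an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(50)
  X <- matrix(rnorm(40 * 10), 40)
  y <- rep(c("a", "b"), each = 20)
  tab <- make_table(X, y)
  fit <- fit_plsda(tab, n_lv = 3)
  Y <- outer(y, c("a", "b"), "==") * 1
  ref <- mixOmics::pls(scale(X), scale(Y, scale = FALSE), ncomp = 3,
                       scale = FALSE, mode = "regression")
  for (k in 1:3) {
    expect_gte(abs(cor(fit$scores[, k], ref$variates$X[, k])), 1 - 1e-6)
  }
})
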