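# ---- autoscaling -----------------------------------------------------------

# column-wise standardization learned on training rows only; constant
# columns get an SD floor so they scale to zero rather than Inf
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[sigma < 1e-12] <- 1e-12
  structure(list(mean = mu, sd = sigma), class = "pulmotex_scaler")
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(as.matrix(X), 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

invert_scaler <- function(scaler, Xs) {
  sweep(sweep(as.matrix(Xs), 2, scaler$sd, "*"), 2, scaler$mean, "+")
}

# extract the numeric feature matrix from a feature table, verifying that the
# model's training columns are all present and ordered identically
feature_matrix <- function(table, x_names = NULL) {
  cols <- feature_columns(table)
  if (!is.null(x_names)) {
    missing <- setdiff(x_names, cols)
    if (length(missing) > 0) {
      abort(sprintf("feature table is missing model columns: %s",
                    paste(missing, collapse = ", ")))
    }
    cols <- x_names
  }
  as.matrix(table[cols])
}

# ---- PCA -------------------------------------------------------------------

#' Principal component analysis of a feature table
#'
#' Exploratory projection of the autoscaled 88-column feature table onto
#' orthogonal axes of maximal variance. Used to check whether class structure
#' (healthy vs diseased) is visible before any supervised modelling.
#'
#' @param table Feature table from [feature_table()].
#' @param n_components Number of components to retain.
#' @return A `ct_pca`: scores tibble (with dog/class metadata), loadings
#'   matrix (columns orthonormal), explained variance fractions, and the
#'   training scaler.
#' @export
fit_pca <- function(table, n_components = 2) {
  X <- feature_matrix(table)
  if (nrow(X) < 2) abort("PCA needs at least 2 rows.")
  stopifnot(n_components >= 1, n_components < nrow(X))
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  dec <- svd(Xs)
  total_var <- sum(Xs^2) / (nrow(Xs) - 1)
  ev <- dec$d^2 / (nrow(Xs) - 1)
  k <- min(n_components, length(dec$d))
  scores <- dec$u[, seq_len(k), drop = FALSE] %*%
    diag(dec$d[seq_len(k)], k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  meta <- table[intersect(c("dog_id", "class_label", "slice_index"),
                          names(table))]
  loadings <- dec$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(
    scores = dplyr::bind_cols(meta, tibble::as_tibble(scores)),
    loadings = loadings,
    explained_variance = ev[seq_len(k)] / total_var,
    all_variance = ev / total_var,
    scaler = scaler, x_names = colnames(X)),
    class = "ct_pca")
}

# ---- PLS-DA ----------------------------------------------------------------

one_hot <- function(class_label, classes) {
  Y <- matrix(0, length(class_label), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(class_label), match(class_label, classes))] <- 1
  Y
}

# NIPALS PLS2: latent variables maximizing covariance between X scores and
# the one-vs-rest response block; returns regression coefficients B mapping
# scaled X to centred Y
nipals_pls2 <- function(Xs, Yc, n_lv, tol = 1e-12, max_iter = 500) {
  n <- nrow(Xs); p <- ncol(Xs); K <- ncol(Yc)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, K, n_lv); Tm <- matrix(0, n, n_lv)
  E <- Xs; F_ <- Yc
  for (a in seq_len(n_lv)) {
    u <- F_[, which.max(colSums(F_^2))]
    t_old <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u)
      w <- w / sqrt(sum(w^2))
      t_ <- E %*% w
      q <- crossprod(F_, t_) / sum(t_^2)
      u <- F_ %*% q / sum(q^2)
      if (sum((t_ - t_old)^2) < tol * sum(t_^2)) break
      t_old <- t_
    }
    p_ <- crossprod(E, t_) / sum(t_^2)
    E <- E - t_ %*% t(p_)
    F_ <- F_ - t_ %*% t(q)
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q; Tm[, a] <- t_
  }
  R <- W %*% solve(crossprod(P, W))
  list(B = R %*% t(Q), W = W, P = P, Q = Q, scores = Tm,
       x_residual = E, y_residual = F_)
}

#' Fit a one-vs-rest PLS-DA classifier
#'
#' Partial least squares regression of the autoscaled feature block against a
#' one-vs-rest indicator response per class (1 = member, 0 = rest), the
#' standard chemometric route to multiclass discriminant analysis. Latent
#' variables are extracted iteratively (NIPALS) to maximize covariance
#' between feature scores and the class indicators.
#'
#' @param train Feature table with at least two classes.
#' @param n_lv Number of latent variables (default 3).
#' @return A `plsda_model` holding the coefficients, intercepts, training
#'   scaler, class list and latent-variable decomposition.
#' @export
fit_plsda <- function(train, n_lv = 3) {
  if (!is.numeric(n_lv) || n_lv < 1) {
    abort("`n_lv` must be a positive integer.")
  }
  classes <- sort(unique(train$class_label))
  if (length(classes) < 2) abort("PLS-DA needs at least 2 classes.")
  X <- feature_matrix(train)
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  if (n_lv > min(dim(Xs))) {
    abort(sprintf("`n_lv` = %d exceeds the data rank bound %d.",
                  n_lv, min(dim(Xs))))
  }
  Y <- one_hot(train$class_label, classes)
  y_mean <- colMeans(Y)
  fit <- nipals_pls2(Xs, sweep(Y, 2, y_mean), n_lv)
  ss_y <- sum(sweep(Y, 2, y_mean)^2)
  structure(list(B = fit$B, y_mean = y_mean, classes = classes,
                 n_lv = n_lv, scaler = scaler, x_names = colnames(X),
                 weights = fit$W, loadings = fit$P, y_loadings = fit$Q,
                 scores = fit$scores,
                 r2y = 1 - sum(fit$y_residual^2) / ss_y,
                 n_train = nrow(X)),
            class = "plsda_model")
}

#' Predict class responses and labels from a PLS-DA model
#'
#' Returns the continuous one-vs-rest response per class (used for ROC
#' curves) and the hard label by argmax; ties are broken by class order and
#' reported via a message.
#'
#' @param object A `plsda_model`.
#' @param newdata Feature table with the model's feature columns.
#' @param ... Unused.
#' @return Tibble: one `.resp_<class>` column per class plus `.pred_class`.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  Xs <- apply_scaler(object$scaler, feature_matrix(newdata, object$x_names))
  resp <- Xs %*% object$B
  resp <- sweep(resp, 2, object$y_mean, "+")
  colnames(resp) <- paste0(".resp_", object$classes)
  if (any(!is.finite(resp))) abort("non-finite PLS-DA responses.")
  hard <- apply(resp, 1, which.max)
  ties <- apply(resp, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties)) {
    inform(sprintf("predict.plsda_model: %d tie(s) broken by class order",
                   sum(ties)))
  }
  out <- tibble::as_tibble(resp)
  out$.pred_class <- object$classes[hard]
  out
}

# ---- SVM -------------------------------------------------------------------

#' Fit a Gaussian-kernel support vector machine classifier
#'
#' Radial-basis-kernel SVM on the autoscaled feature block, with one-vs-one
#' voting for the multiclass decision (via e1071/libsvm). The default kernel
#' width `gamma = 1/p` is scale-free on autoscaled data (every column has
#' unit variance).
#'
#' @param train Feature table with at least two classes.
#' @param gamma Kernel width; `NULL` uses `1/ncol(features)`.
#' @param cost Soft-margin cost C (default 1).
#' @return An `svm_model` wrapping the fitted e1071 object and the training
#'   scaler.
#' @export
fit_svm <- function(train, gamma = NULL, cost = 1) {
  classes <- sort(unique(train$class_label))
  if (length(classes) < 2) abort("SVM needs at least 2 classes.")
  X <- feature_matrix(train)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  if (gamma <= 0 || cost <= 0) abort("`gamma` and `cost` must be positive.")
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  fit <- e1071::svm(Xs, factor(train$class_label, levels = classes),
                    kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
  structure(list(fit = fit, classes = classes, gamma = gamma, cost = cost,
                 scaler = scaler, x_names = colnames(X),
                 n_train = nrow(X)),
            class = "svm_model")
}

#' Predict class responses and labels from an SVM model
#'
#' The hard label comes from one-vs-one voting. The continuous per-class
#' response (for ROC analysis) aggregates the signed pairwise decision
#' values toward each class, which is deterministic (no probability
#' calibration involved).
#'
#' @param object An `svm_model`.
#' @param newdata Feature table with the model's feature columns.
#' @param ... Unused.
#' @return Tibble: one `.resp_<class>` column per class plus `.pred_class`.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  Xs <- apply_scaler(object$scaler, feature_matrix(newdata, object$x_names))
  pred <- predict(object$fit, Xs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  resp <- matrix(0, nrow(Xs), length(object$classes),
                 dimnames = list(NULL, object$classes))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    resp[, pair[1]] <- resp[, pair[1]] + dv[, cn]
    resp[, pair[2]] <- resp[, pair[2]] - dv[, cn]
  }
  colnames(resp) <- paste0(".resp_", object$classes)
  out <- tibble::as_tibble(resp)
  out$.pred_class <- as.character(pred)
  out
}
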