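# Shared fixtures and small utilities for the suite. Expensive objects
# (full default studies and their CV reports) are built lazily and cached so
# several test files can share them.

.cache <- new.env(parent = emptyenv())

cached_features <- function(seed) {
  key <- sprintf("ft_%d", seed)
  if (is.null(.cache[[key]])) {
    st <- generate_study(study_design(seed = seed))
    .cache[[key]] <- suppressMessages(feature_table(st))
  }
  .cache[[key]]
}

cached_report <- function(seed, learner = c("plsda", "svm")) {
  learner <- match.arg(learner)
  key <- sprintf("cv_%s_%d", learner, seed)
  if (is.null(.cache[[key]])) {
    spec <- if (learner == "plsda") plsda_spec(3) else svm_spec()
    .cache[[key]] <- suppressMessages(
      leave_one_dog_out(cached_features(seed), spec))
  }
  .cache[[key]]
}

# small study used by structural tests: default dog counts, few slices
small_default_study <- function(seed = 1) {
  key <- sprintf("small_%d", seed)
  if (is.null(.cache[[key]])) {
    d <- study_design(slices_per_dog = 2, image_size = 64, seed = seed)
    .cache[[key]] <- generate_study(d)
  }
  .cache[[key]]
}

# wrap an integer level matrix (NA = invalid) as a quantized image
make_quantized <- function(levels_matrix, G) {
  structure(list(levels = matrix(as.integer(levels_matrix),
                                 nrow(levels_matrix)),
                 n_levels = as.integer(G),
                 bin_edges = seq(0, 1, length.out = G + 1),
                 provenance = list(dog_id = "test", class_label = "unknown",
                                   slice_index = 1),
                 degenerate = FALSE),
            class = "quantized_image")
}

# wrap a probability matrix as a glcm object
make_glcm <- function(p, orientation = "0") {
  structure(list(p = p, orientation = orientation, n_pairs = NA_integer_,
                 n_levels = nrow(p),
                 provenance = list(dog_id = "test", slice_index = 1)),
            class = "glcm")
}

# random masked quantized image for oracle-equivalence checks
random_masked_image <- function(max_side = 16, max_G = 8,
                                p_invalid = 0.3) {
  nr <- sample(4:max_side, 1)
  nc <- sample(4:max_side, 1)
  G <- sample(2:max_G, 1)
  L <- matrix(sample.int(G, nr * nc, replace = TRUE), nr, nc)
  L[matrix(runif(nr * nc) < p_invalid, nr, nc)] <- NA
  list(q = make_quantized(L, G), L = L, G = G)
}

# two-group feature table with the groups separated by `delta` pooled SDs
separable_table <- function(n_per = 20, p = 5, delta = 10, seed = 42,
                            classes = c("healthy", "pte")) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = delta), n_per))
  colnames(X) <- paste0("f", seq_len(p))
  tibble::tibble(dog_id = rep(sprintf("d%02d", seq_len(2 * n_per %/% 2)),
                              length.out = 2 * n_per),
                 class_label = rep(classes, each = n_per)) |>
    dplyr::bind_cols(tibble::as_tibble(X))
}

# mean silhouette width of a 2-D embedding under a binary grouping
silhouette_width <- function(xy, groups) {
  d <- as.matrix(dist(xy))
  n <- nrow(xy)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- groups == groups[i]
    own[i] <- FALSE
    other <- groups != groups[i]
    a <- mean(d[i, own])
    b <- min(tapply(d[i, other], groups[other], mean))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# learner spec that records each fold's training dogs and scaler means,
# wrapping the real PLS-DA fit
recording_plsda_spec <- function(log_env, n_lv = 3) {
  structure(list(name = "recording_plsda", fit = function(train) {
    model <- fit_plsda(train, n_lv = n_lv)
    log_env$folds[[length(log_env$folds) + 1L]] <-
      list(dogs = unique(train$dog_id), scaler_mean = model$scaler$mean)
    model
  }), class = "learner_spec")
}
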