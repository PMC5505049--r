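test_that("a 2x2 image reproduces the hand-enumerated horizontal GLCM", {
  # [[1, 2], [2, 1]] by row
  L <- matrix(c(1, 2, 2, 1), 2, 2, byrow = TRUE)
  g <- cooccurrence(make_quantized(L, 2), "0")
  expect_equal(g$p[1, 2], 0.5)
  expect_equal(g$p[2, 1], 0.5)
  expect_equal(g$p[1, 1] + g$p[2, 2], 0)
  f <- haralick_features(g)
  expect_equal(unname(f["contr"]), 1)
  expect_equal(unname(f["energ"]), 0.5)
})

test_that("pairs touching invalid pixels are excluded", {
  L <- matrix(c(1, NA, 1, 1), 2, 2, byrow = TRUE)
  g <- cooccurrence(make_quantized(L, 2), "0")
  expect_equal(g$p[1, 1], 1)
  expect_equal(sum(g$p), 1)
})

test_that("a constant image gives a one-entry GLCM with the closed-form features", {
  g <- cooccurrence(make_quantized(matrix(3, 4, 4), 8), "45")
  expect_equal(g$p[3, 3], 1)
  f <- haralick_features(g)
  expect_equal(unname(f["energ"]), 1)
  expect_equal(unname(f["maxpr"]), 1)
  expect_equal(unname(f["entro"]), 0)
  expect_equal(unname(f["contr"]), 0)
  expect_equal(unname(f["dissi"]), 0)
  expect_equal(unname(f["homom"]), 1)
  expect_equal(unname(f["homop"]), 1)
  expect_equal(unname(f["corrm"]), 0)  # defined-limit for zero marginal SD
  expect_true(isTRUE(attr(f, "degenerate_sd")))
})

test_that("a fully masked image raises a degenerate-GLCM error", {
  L <- matrix(NA_integer_, 3, 3)
  expect_error(cooccurrence(make_quantized(L, 4), "0"),
               class = "pulmotex_degenerate_glcm")
  # a single valid pixel has no pair either
  L[2, 2] <- 1L
  expect_error(cooccurrence(make_quantized(L, 4), "0"),
               class = "pulmotex_degenerate_glcm")
})

test_that("the two-entry GLCM evaluates the closed forms", {
  p <- matrix(0, 2, 2)
  p[1, 2] <- 0.5
  p[2, 1] <- 0.5
  f <- haralick_features(make_glcm(p))
  expect_equal(unname(f["contr"]), 1)
  expect_equal(unname(f["autoc"]), 2)
  expect_equal(unname(f["savgh"]), 3)
  expect_equal(unname(f["energ"]), 0.5)
})

test_that("GLCMs are symmetric with unit mass in every orientation", {
  set.seed(17)
  for (rep in 1:20) {
    img <- random_masked_image()
    for (o in c("0", "45", "90", "135")) {
      g <- tryCatch(cooccurrence(img$q, o),
                    pulmotex_degenerate_glcm = function(e) NULL)
      if (is.null(g)) next
      expect_equal(g$p, t(g$p))
      expect_equal(sum(g$p), 1)
      expect_true(all(g$p >= 0))
    }
  }
})

test_that("corrm and corrp agree on random GLCMs", {
  set.seed(5)
  for (rep in 1:25) {
    G <- sample(2:8, 1)
    raw <- matrix(rexp(G * G), G, G)
    p <- (raw + t(raw))
    p <- p / sum(p)
    f <- haralick_features(make_glcm(p))
    expect_equal(unname(f["corrm"]), unname(f["corrp"]), tolerance = 1e-10)
  }
})

test_that("feature bounds hold on random GLCMs", {
  set.seed(6)
  for (rep in 1:20) {
    G <- sample(2:8, 1)
    raw <- matrix(rexp(G * G), G, G)
    p <- raw + t(raw)
    p <- p / sum(p)
    f <- haralick_features(make_glcm(p))
    expect_gt(unname(f["energ"]), 0); expect_lte(unname(f["energ"]), 1)
    expect_gt(unname(f["maxpr"]), 0); expect_lte(unname(f["maxpr"]), 1)
    expect_gte(unname(f["entro"]), 0)
    expect_gte(unname(f["corrm"]), -1); expect_lte(unname(f["corrm"]), 1)
    expect_gte(unname(f["inf2h"]), 0); expect_lte(unname(f["inf2h"]), 1)
  }
})

test_that("jointly permuting grey levels leaves the label-free features unchanged", {
  set.seed(8)
  img <- random_masked_image(max_side = 12, max_G = 6, p_invalid = 0.2)
  g0 <- cooccurrence(img$q, "0")
  f0 <- haralick_features(g0)
  perm <- sample(img$G)
  Lp <- matrix(perm[img$L], nrow(img$L))
  fp <- haralick_features(cooccurrence(make_quantized(Lp, img$G), "0"))
  for (feat in c("energ", "entro", "maxpr")) {
    expect_equal(unname(fp[feat]), unname(f0[feat]), tolerance = 1e-12)
  }
})

test_that("sum-variance centring is switchable", {
  set.seed(10)
  raw <- matrix(rexp(16), 4, 4)
  p <- raw + t(raw)
  p <- p / sum(p)
  g <- make_glcm(p)
  f_ent <- haralick_features(g, sum_variance_center = "sum_entropy")
  f_avg <- haralick_features(g, sum_variance_center = "sum_average")
  expect_false(isTRUE(all.equal(f_ent[["svarh"]], f_avg[["svarh"]])))
  expect_equal(f_ent[setdiff(names(f_ent), "svarh")],
               f_avg[setdiff(names(f_avg), "svarh")])
})

test_that("feature_table has the 22x4 layout and drops degenerate slices", {
  st <- generate_study(study_design(n_healthy = 1, n_pte = 1, n_nopte = 1,
                                    slices_per_dog = 1, image_size = 64,
                                    seed = 2))
  bad <- tibble::tibble(dog_id = "dogXX", class_label = "healthy",
                        slice_index = 99L,
                        pixels = list(matrix(500, 64, 64)))
  ft <- suppressMessages(feature_table(dplyr::bind_rows(st, bad)))
  expect_equal(nrow(ft), 3)
  cols <- setdiff(names(ft), c("dog_id", "class_label", "slice_index"))
  expect_length(cols, 88)
  for (feat in haralick_feature_names) {
    expect_length(grep(paste0("^", feat, "_"), cols), 4)
  }
  excl <- attr(ft, "excluded")
  expect_equal(excl$dog_id, "dogXX")
  expect_equal(excl$reason, "empty_mask")
  expect_error(suppressWarnings(suppressMessages(feature_table(bad))),
               "every slice")
})

test_that("contrast rises as the field's correlation length falls", {
  mean_contr <- vapply(c(1, 2.5, 4), function(cl) {
    params <- list(healthy = texture_params(-700, 90, cl),
                   pte = texture_params(-700, 90, cl),
                   no_pte = texture_params(-700, 90, cl))
    d <- study_design(n_healthy = 2, n_pte = 1, n_nopte = 1,
                      slices_per_dog = 8, image_size = 64, seed = 40,
                      class_params = params, dog_sigma = 0)
    ft <- feature_table(generate_study(d))
    mean(ft$contr_0)
  }, numeric(1))
  expect_true(all(diff(mean_contr) < 0))
})

test_that("the four orientations carry strongly correlated contrast", {
  ft <- cached_features(1)
  cors <- c(cor(ft$contr_0, ft$contr_45), cor(ft$contr_0, ft$contr_90),
            cor(ft$contr_0, ft$contr_135), cor(ft$contr_45, ft$contr_90),
            cor(ft$contr_45, ft$contr_135), cor(ft$contr_90, ft$contr_135))
  expect_gte(median(abs(cors)), 0.8)
})
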