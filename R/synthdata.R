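#' Texture parameters for one class of synthetic lung parenchyma
#'
#' The synthetic parenchymal field is a spatially correlated Gaussian random
#' field: white noise smoothed with a Gaussian kernel of scale
#' `correlation_length`, rescaled to `mean_hu` / `sd_hu`, plus a Poisson
#' number of focal hyperdense blobs emulating small consolidations.
#'
#' @param mean_hu Mean attenuation of the parenchymal field, in Hounsfield
#'   units (HU). Aerated lung is strongly negative (air is about -1000 HU).
#' @param sd_hu Standard deviation of the field, HU.
#' @param correlation_length Gaussian smoothing scale of the field, in pixels.
#'   Longer correlation gives smoother, more homogeneous texture.
#' @param blob_rate Expected number of focal hyperdense blobs per slice
#'   (Poisson rate).
#' @param blob_contrast Peak added attenuation of a blob, HU.
#' @return A `texture_params` list.
#' @export
texture_params <- function(mean_hu, sd_hu, correlation_length,
                           blob_rate = 0, blob_contrast = 0) {
  stopifnot(is.numeric(mean_hu), is.numeric(sd_hu), sd_hu > 0,
            is.numeric(correlation_length), correlation_length > 0,
            blob_rate >= 0)
  structure(list(mean_hu = mean_hu, sd_hu = sd_hu,
                 correlation_length = correlation_length,
                 blob_rate = blob_rate, blob_contrast = blob_contrast),
            class = "texture_params")
}

#' Default per-class texture parameters
#'
#' Healthy parenchyma is modelled as smooth (long correlation length), darker
#' and less variable than diseased parenchyma; the two diseased classes share
#' the same field statistics and differ only in the rate and contrast of focal
#' blobs. Classifiers on this design separate the healthy class near-perfectly
#' while the two diseased classes overlap strongly, the regime the analysis
#' pipeline is meant to handle.
#'
#' @return Named list with elements `healthy`, `pte`, `no_pte`, each a
#'   [texture_params()] object.
#' @export
default_class_params <- function() {
  list(
    healthy = texture_params(mean_hu = -780, sd_hu = 70,
                             correlation_length = 3.5,
                             blob_rate = 0, blob_contrast = 0),
    pte     = texture_params(mean_hu = -700, sd_hu = 95,
                             correlation_length = 1.2,
                             blob_rate = 3, blob_contrast = 120),
    no_pte  = texture_params(mean_hu = -690, sd_hu = 95,
                             correlation_length = 1.2,
                             blob_rate = 1.5, blob_contrast = 110)
  )
}

#' Design of a synthetic CT texture study
#'
#' Describes a cohort of dogs in three classes (healthy, diseased with
#' pulmonary thromboembolism, diseased without) with a fixed number of
#' transverse slices per dog. Defaults reproduce the cohort structure of a
#' 35-dog clinical study: 6 healthy, 7 with PTE, 22 without.
#'
#' @param n_healthy,n_pte,n_nopte Number of dogs per class.
#' @param slices_per_dog Number of slices generated per dog.
#' @param image_size Square image side, pixels. Must be at least 64 so a
#'   64-level co-occurrence matrix is populated.
#' @param seed Integer RNG seed; identical seeds give bit-identical studies.
#' @param class_params Per-class [texture_params()], as from
#'   [default_class_params()].
#' @param dog_sigma Between-dog variability, as a fraction of the
#'   between-class spread of each texture parameter.
#' @return A `study_design` list.
#' @export
study_design <- function(n_healthy = 6, n_pte = 7, n_nopte = 22,
                         slices_per_dog = 20, image_size = 128, seed = 1,
                         class_params = default_class_params(),
                         dog_sigma = 0.1) {
  if (n_healthy < 1 || n_pte < 1 || n_nopte < 1 || slices_per_dog < 1) {
    abort("all dog counts and slices_per_dog must be >= 1.")
  }
  if (image_size < 64) {
    abort("`image_size` must be >= 64 so that a 64-level GLCM is populated.")
  }
  stopifnot(setequal(names(class_params), the_classes), dog_sigma >= 0)
  for (cl in the_classes) {
    p <- class_params[[cl]]
    lo <- p$mean_hu - 3 * p$sd_hu
    hi <- p$mean_hu + 3 * p$sd_hu
    if (lo < HU_WINDOW[["low"]] || hi > HU_WINDOW[["high"]]) {
      abort(sprintf(
        "class '%s': mean_hu +/- 3*sd_hu = [%.0f, %.0f] HU leaves the parenchymal window [%d, %d]; the fixture would be mostly segmented away.",
        cl, lo, hi, HU_WINDOW[["low"]], HU_WINDOW[["high"]]))
    }
  }
  structure(list(n_healthy = n_healthy, n_pte = n_pte, n_nopte = n_nopte,
                 slices_per_dog = slices_per_dog, image_size = image_size,
                 seed = seed, class_params = class_params,
                 dog_sigma = dog_sigma),
            class = "study_design")
}

# elliptical left/right lung mask: TRUE inside either lung field
lung_mask <- function(n) {
  fx <- matrix(rep(seq_len(n), each = n), n, n) / n  # column fraction
  fy <- matrix(rep(seq_len(n), times = n), n, n) / n # row fraction
  left  <- ((fx - 0.30) / 0.17)^2 + ((fy - 0.52) / 0.33)^2 <= 1
  right <- ((fx - 0.70) / 0.17)^2 + ((fy - 0.52) / 0.33)^2 <= 1
  left | right
}

# circular separable Gaussian smoothing; keeps the field stationary so a
# single empirical standardization is valid everywhere in the image
smooth_field <- function(z, correlation_length) {
  half <- max(1L, ceiling(3 * correlation_length))
  k <- dnorm(seq(-half, half), sd = correlation_length)
  k <- k / sum(k)
  zc <- apply(z, 2, function(col) {
    as.numeric(stats::filter(col, k, method = "convolution",
                             sides = 2, circular = TRUE))
  })
  t(apply(zc, 1, function(row) {
    as.numeric(stats::filter(row, k, method = "convolution",
                             sides = 2, circular = TRUE))
  }))
}

# one slice: correlated field inside the lungs, soft tissue (+40 HU) outside,
# plus Poisson focal blobs
generate_slice <- function(n, mask, params) {
  z <- smooth_field(matrix(rnorm(n * n), n, n), params$correlation_length)
  z <- (z - mean(z)) / sd(z)
  img <- matrix(40, n, n)
  img[mask] <- params$mean_hu + params$sd_hu * z[mask]
  n_blobs <- rpois(1, params$blob_rate)
  if (n_blobs > 0) {
    inside <- which(mask)
    centres <- inside[sample.int(length(inside), n_blobs, replace = TRUE)]
    rows <- matrix(rep(seq_len(n), times = n), n, n)
    cols <- matrix(rep(seq_len(n), each = n), n, n)
    for (ctr in centres) {
      r0 <- ((ctr - 1) %% n) + 1
      c0 <- ((ctr - 1) %/% n) + 1
      radius <- runif(1, 2, 4)
      bump <- params$blob_contrast *
        exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * radius^2))
      img[mask] <- img[mask] + bump[mask]
    }
  }
  img <- round(img)
  img[img < HU_RANGE[1]] <- HU_RANGE[1]
  img[img > HU_RANGE[2]] <- HU_RANGE[2]
  img
}

# per-dog random effect: each numeric parameter is jittered by
# dog_sigma * (between-class SD of that parameter), floored to stay valid
perturb_params <- function(params, class_params, dog_sigma) {
  fields <- c("mean_hu", "sd_hu", "correlation_length",
              "blob_rate", "blob_contrast")
  out <- params
  for (f in fields) {
    spread <- sd(vapply(class_params, `[[`, numeric(1), f))
    out[[f]] <- params[[f]] + rnorm(1, 0, dog_sigma * spread)
  }
  out$sd_hu <- max(out$sd_hu, 5)
  out$correlation_length <- max(out$correlation_length, 0.3)
  out$blob_rate <- max(out$blob_rate, 0)
  out$blob_contrast <- max(out$blob_contrast, 0)
  out
}

#' Generate a synthetic CT texture study
#'
#' Draws the full cohort described by a [study_design()]: for every dog, a
#' per-dog perturbation of its class texture parameters, then
#' `slices_per_dog` transverse slices. Each slice is a square HU image with
#' two elliptical lung fields filled by a spatially correlated Gaussian
#' random field, embedded in soft-tissue background (+40 HU) that the
#' standard HU-window segmentation removes.
#'
#' @param design A [study_design()].
#' @return A tibble with one row per slice: `dog_id`, `class_label`,
#'   `slice_index`, and `pixels` (list-column of HU matrices).
#' @examples
#' tiny <- study_design(n_healthy = 1, n_pte = 1, n_nopte = 1,
#'                      slices_per_dog = 2, image_size = 64, seed = 7)
#' slices <- generate_study(tiny)
#' dplyr::count(slices, class_label)
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  n <- design$image_size
  mask <- lung_mask(n)
  counts <- c(healthy = design$n_healthy, pte = design$n_pte,
              no_pte = design$n_nopte)
  rows <- list()
  dog_no <- 0L
  for (cl in the_classes) {
    for (d in seq_len(counts[[cl]])) {
      dog_no <- dog_no + 1L
      dog_id <- sprintf("dog%02d_%s", dog_no, cl)
      params <- perturb_params(design$class_params[[cl]],
                               design$class_params, design$dog_sigma)
      for (s in seq_len(design$slices_per_dog)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          dog_id = dog_id,
          class_label = cl,
          slice_index = s,
          pixels = list(generate_slice(n, mask, params))
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a study to disk as 16-bit TIFF slices plus a CSV manifest
#'
#' Pixels are stored offset-encoded (`stored = HU + hu_offset`) in single
#' plane 16-bit unsigned TIFFs. The manifest records `dog_id`, `class` and
#' `slice_path` in generation order.
#'
#' @param study Slice tibble from [generate_study()].
#' @param dir Output directory (created if absent).
#' @param hu_offset Offset added to HU before storage; default 1024 maps the
#'   full CT range into unsigned 12 bits.
#' @return Invisibly, the manifest path.
#' @export
write_study <- function(study, dir, hu_offset = 1024) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(study))
  for (i in seq_len(nrow(study))) {
    fn <- sprintf("%s_slice%03d.tif", study$dog_id[i], study$slice_index[i])
    paths[i] <- file.path(dir, fn)
    write_tiff_slice(study$pixels[[i]], paths[i], hu_offset = hu_offset)
  }
  manifest <- data.frame(dog_id = study$dog_id, class = study$class_label,
                         slice_path = paths, stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}
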