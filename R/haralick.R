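#' The 22 texture feature abbreviations, in canonical order
#'
#' Autocorrelation (autoc), contrast (contr), two algebraically equivalent
#' correlation forms (corrm, corrp), cluster prominence (cprom),
#' dissimilarity (dissi), energy (energ), entropy (entro), inverse difference
#' homogeneity (homom), homogeneity (homop), maximum probability (maxpr), sum
#' of squares variance (sosvh), sum average (savgh), sum variance (svarh),
#' sum entropy (senth), difference variance (dvarh), difference entropy
#' (denth), the two information measures of correlation (inf1h, inf2h),
#' inverse difference normalized (indnc), inverse difference moment
#' normalized (indmc), cluster shade (cshad).
#'
#' @export
haralick_feature_names <- c(
  "autoc", "contr", "corrm", "corrp", "cprom", "dissi", "energ", "entro",
  "homom", "homop", "maxpr", "sosvh", "savgh", "svarh", "senth", "dvarh",
  "denth", "inf1h", "inf2h", "indnc", "indmc", "cshad")

# entropy helper with the 0*log(0) = 0 convention (natural log)
neg_plogp <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Haralick feature bank of one co-occurrence matrix
#'
#' Computes the 22 first- and second-order statistics from a normalized GLCM
#' `p(i, j)`: moments of the joint distribution, of the marginals, and of the
#' sum (`i + j`) and difference (`|i - j|`) distributions, plus entropy-based
#' information measures. Natural logarithms throughout, with `0 log 0 = 0`.
#' Sum variance is centred on sum entropy, per Haralick's printed definition;
#' set `sum_variance_center = "sum_average"` for the common alternative.
#'
#' For a constant image (a one-entry GLCM) both grey-level marginals have
#' zero variance; the correlation features are then returned as their
#' defined limit 0 and the result carries attribute `degenerate_sd = TRUE`.
#'
#' @param g A `glcm` from [cooccurrence()].
#' @param sum_variance_center Centre of the sum-variance moment:
#'   `"sum_entropy"` (default) or `"sum_average"`.
#' @return Named numeric vector of length 22 (see
#'   [haralick_feature_names]).
#' @export
haralick_features <- function(g,
                              sum_variance_center = c("sum_entropy",
                                                      "sum_average")) {
  stopifnot(inherits(g, "glcm"))
  sum_variance_center <- match.arg(sum_variance_center)
  p <- g$p
  G <- g$n_levels
  I <- row(p); J <- col(p)
  i <- seq_len(G)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(i * px); muy <- sum(i * py)
  sigx <- sqrt(sum((i - mux)^2 * px))
  sigy <- sqrt(sum((i - muy)^2 * py))

  # sum (k = 2..2G) and absolute-difference (k = 0..G-1) distributions
  k_sum <- 2:(2 * G)
  p_sum <- vapply(k_sum, function(k) sum(p[I + J == k]), numeric(1))
  k_dif <- 0:(G - 1)
  p_dif <- vapply(k_dif, function(k) sum(p[abs(I - J) == k]), numeric(1))

  autoc <- sum(I * J * p)
  contr <- sum((I - J)^2 * p)
  degenerate <- sigx == 0 || sigy == 0
  corrm <- if (degenerate) 0 else sum((I - mux) * (J - muy) * p) / (sigx * sigy)
  corrp <- if (degenerate) 0 else (autoc - mux * muy) / (sigx * sigy)
  cprom <- sum((I + J - mux - muy)^4 * p)
  cshad <- sum((I + J - mux - muy)^3 * p)
  dissi <- sum(abs(I - J) * p)
  energ <- sum(p^2)
  entro <- neg_plogp(p)
  homom <- sum(p / (1 + abs(I - J)))
  homop <- sum(p / (1 + (I - J)^2))
  maxpr <- max(p)
  sosvh <- sum((I - mux)^2 * p)
  savgh <- sum(k_sum * p_sum)
  senth <- neg_plogp(p_sum)
  sv_centre <- switch(sum_variance_center,
                      sum_entropy = senth, sum_average = savgh)
  svarh <- sum((k_sum - sv_centre)^2 * p_sum)
  dvarh <- sum(k_dif^2 * p_dif) - sum(k_dif * p_dif)^2
  denth <- neg_plogp(p_dif)

  hx <- neg_plogp(px); hy <- neg_plogp(py)
  pxpy <- outer(px, py)
  nz <- p > 0 & pxpy > 0
  hxy1 <- -sum(p[nz] * log(pxpy[nz]))
  nz2 <- pxpy > 0
  hxy2 <- -sum(pxpy[nz2] * log(pxpy[nz2]))
  inf1h <- if (max(hx, hy) == 0) 0 else (entro - hxy1) / max(hx, hy)
  inf2h <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entro))))

  indnc <- sum(p / (1 + abs(I - J) / G))
  indmc <- sum(p / (1 + ((I - J) / G)^2))

  out <- c(autoc = autoc, contr = contr, corrm = corrm, corrp = corrp,
           cprom = cprom, dissi = dissi, energ = energ, entro = entro,
           homom = homom, homop = homop, maxpr = maxpr, sosvh = sosvh,
           savgh = savgh, svarh = svarh, senth = senth, dvarh = dvarh,
           denth = denth, inf1h = inf1h, inf2h = inf2h, indnc = indnc,
           indmc = indmc, cshad = cshad)
  out <- out[haralick_feature_names]
  if (degenerate) attr(out, "degenerate_sd") <- TRUE
  out
}

#' Build the slices-by-features table for a study
#'
#' Runs the full per-slice texture chain — HU-window segmentation,
#' quantization to `levels` grey levels, one masked GLCM per orientation,
#' and the 22-feature bank — and assembles one row per slice with
#' `22 x length(orientations)` feature columns named
#' `<feature>_<orientation>`, plus `dog_id`, `class_label`, `slice_index`.
#' Slices with an empty parenchyma mask or a degenerate GLCM are dropped,
#' reported via a message, and listed in the `excluded` attribute, so every
#' input slice is accounted for.
#'
#' @param slices Slice tibble (`dog_id`, `class_label`, `slice_index`,
#'   `pixels`), e.g. from [generate_study()] or [read_manifest()].
#' @param low,high Segmentation window, HU.
#' @param levels Grey levels for quantization (default 64).
#' @param distance GLCM pair distance, pixels.
#' @param orientations Character vector of orientations to compute.
#' @param quantize_mode Passed to [quantize()].
#' @param sum_variance_center Passed to [haralick_features()].
#' @return Tibble of features; attribute `excluded` holds the dropped
#'   slices' identities (zero-row tibble when none).
#' @export
feature_table <- function(slices, low = -1024, high = -250, levels = 64,
                          distance = 1,
                          orientations = c("0", "45", "90", "135"),
                          quantize_mode = "fixed_window",
                          sum_variance_center = "sum_entropy") {
  stopifnot(is.data.frame(slices), nrow(slices) >= 1,
            all(c("dog_id", "class_label", "pixels") %in% names(slices)))
  if (!"slice_index" %in% names(slices)) {
    slices$slice_index <- seq_len(nrow(slices))
  }
  rows <- vector("list", nrow(slices))
  excluded <- list()
  for (s in seq_len(nrow(slices))) {
    masked <- withCallingHandlers(
      hu_window(slices[s, ], low = low, high = high),
      pulmotex_empty_mask = function(w) invokeRestart("muffleWarning"))
    if (isTRUE(attr(masked, "degenerate"))) {
      excluded[[length(excluded) + 1L]] <-
        tibble::tibble(dog_id = slices$dog_id[s],
                       slice_index = slices$slice_index[s],
                       reason = "empty_mask")
      next
    }
    q <- quantize(masked, levels = levels, mode = quantize_mode)
    feats <- tryCatch({
      unlist(lapply(orientations, function(o) {
        f <- haralick_features(cooccurrence(q, o, distance = distance),
                               sum_variance_center = sum_variance_center)
        setNames(as.numeric(f), paste0(names(f), "_", o))
      }))
    }, pulmotex_degenerate_glcm = function(e) NULL)
    if (is.null(feats)) {
      excluded[[length(excluded) + 1L]] <-
        tibble::tibble(dog_id = slices$dog_id[s],
                       slice_index = slices$slice_index[s],
                       reason = "degenerate_glcm")
      next
    }
    rows[[s]] <- tibble::tibble(dog_id = slices$dog_id[s],
                                class_label = slices$class_label[s],
                                slice_index = slices$slice_index[s],
                                !!!as.list(feats))
  }
  excluded <- if (length(excluded)) dplyr::bind_rows(excluded) else
    tibble::tibble(dog_id = character(), slice_index = integer(),
                   reason = character())
  if (nrow(excluded) > 0) {
    inform(sprintf("feature_table: excluded %d degenerate slice(s) of %d",
                   nrow(excluded), nrow(slices)))
  }
  out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) == 0) {
    abort("feature_table: every slice was degenerate; no features computed.")
  }
  attr(out, "excluded") <- excluded
  out
}

# names of the numeric feature columns of a feature table, in stable order
feature_columns <- function(table) {
  setdiff(names(table), c("dog_id", "class_label", "slice_index"))
}
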