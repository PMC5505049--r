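#' Segment pulmonary parenchyma by Hounsfield-unit windowing
#'
#' Keeps every pixel whose attenuation lies in `[low, high]` HU and flags the
#' rest invalid. The default window (-1024 to -250 HU) retains aerated lung
#' and excludes soft tissue, consolidation and bone. Invalid pixels carry
#' `NA` in the value matrix plus an explicit logical mask: they never enter
#' any downstream texture computation as numbers.
#'
#' @param slice A one-row slice tibble (see [ct_slice()]) or a bare HU
#'   matrix.
#' @param low,high Window bounds, HU (`low < high`).
#' @return A `masked_image`: list with `values` (HU, `NA` outside the mask),
#'   `valid` (logical matrix), `fraction_valid`, and `provenance`
#'   (dog/class/slice metadata). A slice with no in-window pixel is returned
#'   flagged degenerate, with a classed warning (`pulmotex_empty_mask`);
#'   downstream table builders drop and log such slices.
#' @export
hu_window <- function(slice, low = -1024, high = -250) {
  if (low >= high) abort("`low` must be strictly less than `high`.")
  if (is.data.frame(slice)) {
    stopifnot(nrow(slice) == 1)
    prov <- list(dog_id = slice$dog_id, class_label = slice$class_label,
                 slice_index = slice$slice_index)
    pixels <- slice$pixels[[1]]
  } else {
    prov <- list(dog_id = "unknown", class_label = "unknown", slice_index = NA)
    pixels <- slice
  }
  stopifnot(is.matrix(pixels))
  valid <- !is.na(pixels) & pixels >= low & pixels <= high
  values <- pixels
  values[!valid] <- NA_real_
  out <- structure(
    list(values = values, valid = valid,
         fraction_valid = mean(valid),
         window = c(low = low, high = high),
         provenance = prov),
    class = "masked_image")
  if (!any(valid)) {
    attr(out, "degenerate") <- TRUE
    warn(sprintf("slice %s/%s: no pixel in HU window [%g, %g]; flagged for exclusion",
                 prov$dog_id, prov$slice_index, low, high),
         class = "pulmotex_empty_mask")
  }
  out
}

#' Binary parenchyma mask of a segmented image
#'
#' Returns the logical mask (1 = parenchyma, 0 = background) as an explicit
#' artefact of the segmentation step.
#'
#' @param masked A `masked_image` from [hu_window()].
#' @return Logical matrix.
#' @export
binarize <- function(masked) {
  stopifnot(inherits(masked, "masked_image"))
  masked$valid
}

#' Quantize segmented parenchyma to G grey levels
#'
#' Valid pixels are binned into `levels` equal-width bins. With
#' `mode = "fixed_window"` (default) the bins span the segmentation window
#' itself, so grey levels are calibrated in HU and comparable across slices
#' and dogs; `mode = "per_image"` rescales each image to its own range,
#' which discards between-image brightness differences. Bins are left-closed
#' and right-open except the last, so every in-window value maps to exactly
#' one level; the window's upper bound maps to level `levels`.
#'
#' @param masked A `masked_image`.
#' @param levels Number of grey levels G (default 64).
#' @param mode Bin calibration, `"fixed_window"` or `"per_image"`.
#' @return A `quantized_image`: integer level matrix (`NA` where invalid),
#'   `n_levels`, `bin_edges` (length G+1), and the source provenance.
#' @export
quantize <- function(masked, levels = 64,
                     mode = c("fixed_window", "per_image")) {
  stopifnot(inherits(masked, "masked_image"), levels >= 2)
  mode <- match.arg(mode)
  rngv <- switch(mode,
    fixed_window = unname(masked$window),
    per_image = {
      if (!any(masked$valid)) unname(masked$window)
      else range(masked$values[masked$valid])
    })
  if (rngv[1] == rngv[2]) rngv[2] <- rngv[1] + 1e-6
  edges <- seq(rngv[1], rngv[2], length.out = levels + 1)
  width <- (rngv[2] - rngv[1]) / levels
  lev <- floor((masked$values - rngv[1]) / width) + 1
  lev[lev > levels] <- levels  # right-closed last bin
  lev[lev < 1] <- 1L
  lev[!masked$valid] <- NA_integer_
  structure(list(levels = matrix(as.integer(lev), nrow(masked$values)),
                 n_levels = as.integer(levels),
                 bin_edges = edges,
                 provenance = masked$provenance,
                 degenerate = isTRUE(attr(masked, "degenerate"))),
            class = "quantized_image")
}
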