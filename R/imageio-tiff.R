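#' Construct a CT slice record
#'
#' A slice is one row of the tidy study container: metadata plus the HU pixel
#' matrix in a list-column, so collections of slices are ordinary tibbles.
#'
#' @param pixels Numeric matrix of Hounsfield units.
#' @param dog_id Subject identifier (opaque string).
#' @param class_label One of `"healthy"`, `"pte"`, `"no_pte"`, `"unknown"`.
#' @param slice_index Ordinal position of the slice within its dog.
#' @return One-row tibble with columns `dog_id`, `class_label`,
#'   `slice_index`, `pixels`.
#' @export
ct_slice <- function(pixels, dog_id = "unknown", class_label = "unknown",
                     slice_index = 1L) {
  if (!is.matrix(pixels) || length(pixels) == 0) {
    abort("`pixels` must be a non-empty matrix.")
  }
  rng <- range(pixels)
  if (rng[1] < HU_RANGE[1] || rng[2] > HU_RANGE[2]) {
    abort(sprintf("HU values [%.0f, %.0f] fall outside the CT range [%d, %d].",
                  rng[1], rng[2], HU_RANGE[1], HU_RANGE[2]))
  }
  class_label <- match.arg(class_label,
                           c("healthy", "pte", "no_pte", "unknown"))
  tibble::tibble(dog_id = dog_id, class_label = class_label,
                 slice_index = as.integer(slice_index),
                 pixels = list(pixels))
}

#' Read one CT slice from a 16-bit grayscale TIFF
#'
#' The stored integers are offset-encoded Hounsfield units:
#' `HU = stored - hu_offset`.
#'
#' @param path TIFF file, single plane, grayscale.
#' @param hu_offset Offset used at write time (default 1024).
#' @param dog_id,class_label,slice_index Metadata attached to the slice.
#' @return One-row slice tibble, as [ct_slice()].
#' @export
read_tiff_slice <- function(path, hu_offset = 1024, dog_id = "unknown",
                            class_label = "unknown", slice_index = 1L) {
  if (!file.exists(path)) abort(sprintf("TIFF file not found: %s", path))
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1) {
      abort(sprintf("multi-sample (RGB) TIFF not supported: %s", path))
    }
    img <- img[, , 1]
  }
  ct_slice(img - hu_offset, dog_id = dog_id, class_label = class_label,
           slice_index = slice_index)
}

#' Write one HU matrix as a 16-bit grayscale TIFF
#'
#' @param pixels HU matrix.
#' @param path Output file.
#' @param hu_offset Offset added before storage so negative HU fit in
#'   unsigned 16 bits.
#' @return Invisibly, `path`.
#' @export
write_tiff_slice <- function(pixels, path, hu_offset = 1024) {
  stored <- round(pixels) + hu_offset
  if (any(stored < 0) || any(stored > 65535)) {
    abort("offset-encoded pixel values exceed unsigned 16-bit range.")
  }
  tiff::writeTIFF(stored / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a study manifest into a slice tibble
#'
#' The manifest (as written by [write_study()]) has columns `dog_id`,
#' `class`, `slice_path`; row order is preserved, and slices are numbered
#' consecutively within each dog in manifest order.
#'
#' @param manifest_path CSV manifest file.
#' @param hu_offset Offset used when the TIFFs were written.
#' @return Tibble of slices, one row per manifest row, in manifest order.
#' @export
read_manifest <- function(manifest_path, hu_offset = 1024) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: %s", manifest_path))
  }
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("dog_id", "class", "slice_path")
  if (!all(need %in% names(man))) {
    abort(sprintf("manifest must have columns %s",
                  paste(need, collapse = ", ")))
  }
  base <- dirname(manifest_path)
  idx <- stats::ave(seq_len(nrow(man)), man$dog_id, FUN = seq_along)
  purrr::map_dfr(seq_len(nrow(man)), function(i) {
    p <- man$slice_path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    read_tiff_slice(p, hu_offset = hu_offset, dog_id = man$dog_id[i],
                    class_label = man$class[i], slice_index = idx[i])
  })
}
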