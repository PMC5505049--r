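# pixel offsets (row, col) for the four neighbour orientations; 45 degrees
# points up-right so that the diagonal directions match radiological
# convention (image row 1 at the top)
GLCM_OFFSETS <- list(
  "0"   = c(0L, 1L),
  "45"  = c(-1L, 1L),
  "90"  = c(-1L, 0L),
  "135" = c(-1L, -1L)
)

#' Masked grey-level co-occurrence matrix
#'
#' Counts pairs of grey levels at a fixed pixel offset, restricted to pairs
#' where both pixels are valid parenchyma: pairs touching background or the
#' image border are excluded, so the matrix describes lung texture only.
#' Accumulation is symmetric (each pair contributes to `(a, b)` and
#' `(b, a)`), following Haralick's original definition, and the matrix is
#' normalized to unit total mass.
#'
#' @param q A `quantized_image` from [quantize()].
#' @param orientation One of `"0"`, `"45"`, `"90"`, `"135"` (degrees).
#' @param distance Pair distance in pixels along the orientation (default 1,
#'   i.e. immediate neighbours).
#' @return A `glcm`: list with `p` (G x G probability matrix), `orientation`,
#'   `n_pairs` (directed pair count after symmetrization), `n_levels`.
#'   A slice with no valid pair raises a classed error
#'   (`pulmotex_degenerate_glcm`).
#' @export
cooccurrence <- function(q, orientation = c("0", "45", "90", "135"),
                         distance = 1) {
  stopifnot(inherits(q, "quantized_image"), distance >= 1)
  orientation <- match.arg(as.character(orientation),
                           c("0", "45", "90", "135"))
  off <- GLCM_OFFSETS[[orientation]] * as.integer(distance)
  L <- q$levels
  nr <- nrow(L); nc <- ncol(L)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- L[r1, c1, drop = FALSE]
  b <- L[r1 + off[1], c1 + off[2], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) {
    abort(sprintf("degenerate GLCM: no valid pixel pair at orientation %s for slice %s/%s",
                  orientation, q$provenance$dog_id, q$provenance$slice_index),
          class = "pulmotex_degenerate_glcm")
  }
  G <- q$n_levels
  counts <- matrix(tabulate(a + G * (b - 1L), nbins = G * G), G, G)
  counts <- counts + t(counts)
  structure(list(p = counts / sum(counts), orientation = orientation,
                 n_pairs = sum(counts), n_levels = G,
                 provenance = q$provenance),
            class = "glcm")
}
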