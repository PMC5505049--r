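# Minimal single-frame CT DICOM IO (explicit VR, little endian).
#
# Only the tags the texture pipeline needs are interpreted: modality,
# rows/columns, bits allocated, pixel representation, rescale slope/intercept
# and pixel data. The writer emits small synthetic files for testing and
# interoperability checks; it is not a general-purpose DICOM serializer.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

# VRs whose explicit form carries a 2-byte reserved field + 4-byte length
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_uint <- function(raw, signed = FALSE) {
  n <- length(raw)
  val <- sum(as.numeric(raw) * 256^(seq_len(n) - 1))
  if (signed && val >= 256^n / 2) val <- val - 256^n
  val
}

#' Read one CT slice from a single-frame DICOM file
#'
#' Parses an explicit-VR little-endian DICOM file and converts stored pixel
#' values to Hounsfield units via the file's rescale slope and intercept
#' (`HU = slope * stored + intercept`). Files missing the rescale tags are
#' read with slope 1 and intercept 0, with a warning.
#'
#' @param path DICOM file.
#' @param dog_id,class_label,slice_index Metadata attached to the slice.
#' @return One-row slice tibble, as [ct_slice()].
#' @export
read_dicom_slice <- function(path, dog_id = "unknown",
                             class_label = "unknown", slice_index = 1L) {
  if (!file.exists(path)) abort(sprintf("DICOM file not found: %s", path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM") {
    abort(sprintf("not a DICOM file (missing DICM magic): %s", path))
  }
  pos <- 133L
  tags <- list()
  while (pos + 8 <= length(raw)) {
    group <- read_uint(raw[pos:(pos + 1)])
    element <- read_uint(raw[(pos + 2):(pos + 3)])
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- read_uint(raw[(pos + 8):(pos + 11)])
      body <- pos + 12L
    } else {
      len <- read_uint(raw[(pos + 6):(pos + 7)])
      body <- pos + 8L
    }
    if (len > 0 && body + len - 1 > length(raw)) {
      abort(sprintf("truncated DICOM element at offset %d: %s", pos, path))
    }
    value <- if (len > 0) raw[body:(body + len - 1)] else raw(0)
    tags[[dcm_tag(group, element)]] <- list(vr = vr, value = value)
    pos <- body + len
    if (group == 0x7FE0 && element == 0x0010) break
  }
  get_str <- function(tag) {
    el <- tags[[tag]]
    if (is.null(el)) return(NULL)
    trimws(rawToChar(el$value))
  }
  get_us <- function(tag) {
    el <- tags[[tag]]
    if (is.null(el)) return(NULL)
    read_uint(el$value[1:2])
  }
  modality <- get_str(dcm_tag(0x0008, 0x0060))
  if (!is.null(modality) && modality != "CT") {
    abort(sprintf("not a CT image (modality '%s'): %s", modality, path))
  }
  rows <- get_us(dcm_tag(0x0028, 0x0010))
  cols <- get_us(dcm_tag(0x0028, 0x0011))
  bits <- get_us(dcm_tag(0x0028, 0x0100)) %||% 16
  pixrep <- get_us(dcm_tag(0x0028, 0x0103)) %||% 0
  if (is.null(rows) || is.null(cols)) {
    abort(sprintf("no image dimensions (not an image DICOM?): %s", path))
  }
  slope_s <- get_str(dcm_tag(0x0028, 0x1053))
  inter_s <- get_str(dcm_tag(0x0028, 0x1052))
  if (is.null(slope_s) || is.null(inter_s)) {
    warn(sprintf("missing rescale slope/intercept in %s; assuming slope 1, intercept 0",
                 path))
    slope <- 1; intercept <- 0
  } else {
    slope <- as.numeric(slope_s); intercept <- as.numeric(inter_s)
  }
  px <- tags[[dcm_tag(0x7FE0, 0x0010)]]
  if (is.null(px)) abort(sprintf("no pixel data in %s", path))
  if (bits != 16) abort(sprintf("only 16-bit pixel data supported: %s", path))
  stored <- readBin(px$value, "integer", n = rows * cols, size = 2,
                    signed = FALSE, endian = "little")
  if (pixrep == 1) stored[stored > 32767] <- stored[stored > 32767] - 65536
  # DICOM pixel data is row-major (first full row first)
  hu <- matrix(slope * stored + intercept, nrow = rows, byrow = TRUE)
  ct_slice(hu, dog_id = dog_id, class_label = class_label,
           slice_index = slice_index)
}

dcm_uint_raw <- function(val, n) {
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(val %% 256)
    val <- val %/% 256
  }
  out
}

dcm_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) {
    pad <- if (vr %in% c("UI")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  head <- c(dcm_uint_raw(group, 2), dcm_uint_raw(element, 2), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, raw(2), dcm_uint_raw(length(value_raw), 4), value_raw)
  } else {
    c(head, dcm_uint_raw(length(value_raw), 2), value_raw)
  }
}

#' Write one HU matrix as a minimal single-frame CT DICOM file
#'
#' Stored values are `(HU - intercept) / slope`, unsigned 16-bit, explicit
#' VR little endian. Intended for producing small synthetic CT files.
#'
#' @param pixels HU matrix.
#' @param path Output file.
#' @param slope,intercept Rescale parameters written to the file. With the
#'   defaults (slope 1, intercept -1024) stored values are `HU + 1024`.
#' @param rescale Write the rescale tags at all; `FALSE` produces a file that
#'   exercises the reader's missing-tag fallback.
#' @return Invisibly, `path`.
#' @export
write_dicom_slice <- function(pixels, path, slope = 1, intercept = -1024,
                              rescale = TRUE) {
  stored <- round((pixels - intercept) / slope)
  if (any(stored < 0) || any(stored > 65535)) {
    abort("stored pixel values exceed unsigned 16-bit range; adjust intercept.")
  }
  rows <- nrow(pixels); cols <- ncol(pixels)
  pix_raw <- writeBin(as.integer(t(stored)), raw(), size = 2,
                      endian = "little")
  meta <- c(
    dcm_element(0x0002, 0x0010, "UI", charToRaw("1.2.840.10008.1.2.1"))
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint_raw(length(meta), 4)),
            meta)
  body <- c(
    dcm_element(0x0008, 0x0060, "CS", charToRaw("CT")),
    dcm_element(0x0028, 0x0010, "US", dcm_uint_raw(rows, 2)),
    dcm_element(0x0028, 0x0011, "US", dcm_uint_raw(cols, 2)),
    dcm_element(0x0028, 0x0100, "US", dcm_uint_raw(16, 2)),
    dcm_element(0x0028, 0x0101, "US", dcm_uint_raw(16, 2)),
    dcm_element(0x0028, 0x0102, "US", dcm_uint_raw(15, 2)),
    dcm_element(0x0028, 0x0103, "US", dcm_uint_raw(0, 2))
  )
  if (rescale) {
    body <- c(body,
              dcm_element(0x0028, 0x1052, "DS",
                          charToRaw(format(intercept))),
              dcm_element(0x0028, 0x1053, "DS", charToRaw(format(slope))))
  }
  body <- c(body, dcm_element(0x7FE0, 0x0010, "OW", pix_raw))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), path)
  invisible(path)
}
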