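# Minimal DICOM reader/writer: uncompressed single-frame grayscale,
# explicit or implicit VR little endian, enough for PixelSpacing plus the
# pixel grid. Written because no DICOM package ships with the target R
# stack; the scope is deliberately narrow (no sequences, no compressed
# transfer syntaxes, no multi-frame).

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

dcm_pad <- function(s, pad = as.raw(0x20)) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, pad)
  r
}

dcm_element <- function(group, elem, vr, value_raw) {
  head <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), dcm_u32(length(value_raw)), value_raw)
  } else {
    c(head, dcm_u16(length(value_raw)), value_raw)
  }
}

#' Write a minimal grayscale DICOM file
#'
#' Stores a single-frame grayscale image as explicit-VR little-endian
#' DICOM with Rows/Columns, BitsAllocated 16, and the PixelSpacing tag
#' (0028,0030) in mm as `(row spacing, column spacing)` per the standard.
#' Intended for fixtures and round-trip testing, not for clinical archives.
#'
#' @param pixels Integer matrix (values 0..65535).
#' @param path Output path.
#' @param spacing_mm Numeric (row, col) spacing in mm/px.
#' @return The path, invisibly.
#' @export
write_dicom <- function(pixels, path, spacing_mm) {
  if (!is.matrix(pixels)) abort("pixels must be a matrix")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  px <- round(pixels)
  storage.mode(px) <- "integer"
  if (any(px < 0L) || any(px > 65535L)) abort("pixel values must be in 0..65535")

  ts <- dcm_pad(TS_EXPLICIT_LE, as.raw(0L))
  meta <- dcm_element(0x0002L, 0x0010L, "UI", ts)
  meta_len <- dcm_element(0x0002L, 0x0000L, "UL", dcm_u32(length(meta)))

  spacing_str <- dcm_pad(sprintf("%.6g\\%.6g", spacing_mm[1L], spacing_mm[2L]))
  # pixel data in DICOM row-major order
  data16 <- writeBin(as.integer(t(px)), raw(), size = 2L, endian = "little")
  body <- c(
    dcm_element(0x0028L, 0x0002L, "US", dcm_u16(1L)),          # SamplesPerPixel
    dcm_element(0x0028L, 0x0004L, "CS", dcm_pad("MONOCHROME2")),
    dcm_element(0x0028L, 0x0010L, "US", dcm_u16(nrow(px))),    # Rows
    dcm_element(0x0028L, 0x0011L, "US", dcm_u16(ncol(px))),    # Columns
    dcm_element(0x0028L, 0x0030L, "DS", spacing_str),          # PixelSpacing
    dcm_element(0x0028L, 0x0100L, "US", dcm_u16(16L)),         # BitsAllocated
    dcm_element(0x0028L, 0x0101L, "US", dcm_u16(16L)),         # BitsStored
    dcm_element(0x0028L, 0x0102L, "US", dcm_u16(15L)),         # HighBit
    dcm_element(0x0028L, 0x0103L, "US", dcm_u16(0L)),          # PixelRepresentation
    dcm_element(0x7FE0L, 0x0010L, "OW", data16)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta_len, meta, body), con)
  invisible(path)
}

#' Read a minimal DICOM file
#'
#' Parses uncompressed explicit- or implicit-VR little-endian DICOM and
#' returns the pixel grid with the PixelSpacing tag. Unsupported transfer
#' syntaxes and missing pixel data raise errors naming the problem.
#'
#' @param path Path to a `.dcm` file.
#' @return A list: `pixels` (integer matrix), `pixel_spacing_mm` (numeric
#'   (row, col) or NULL if the tag is absent), `rows`, `cols`,
#'   `bits_allocated`.
#' @export
read_dicom <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 132L || rawToChar(raw_all[129:132]) != "DICM")
    abort("not a DICOM file (missing DICM marker)")
  pos <- 133L
  n <- length(raw_all)
  u16 <- function(at) sum(as.integer(raw_all[at + 0:1]) * c(1, 256))
  u32 <- function(at) sum(as.integer(raw_all[at + 0:3]) * 256^(0:3))

  ts <- TS_EXPLICIT_LE
  fields <- list(rows = NULL, cols = NULL, spacing = NULL, bits = 16L,
                 data = NULL)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  implicit <- FALSE

  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (implicit && group != 0x0002L) {
      len <- u32(pos + 4L)
      val_at <- pos + 8L
      vr <- NA_character_
    } else {
      vr <- rawToChar(raw_all[pos + 4:5])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L)
        val_at <- pos + 12L
      } else {
        len <- u16(pos + 6L)
        val_at <- pos + 8L
      }
    }
    if (len == 0xFFFFFFFF) abort("undefined-length elements are not supported")
    value <- raw_all[val_at + seq_len(len) - 1L]
    tag <- c(group, elem)

    if (group == 0x0002L && elem == 0x0010L) {
      ts <- sub("\\x00+$", "", rawToChar(value))
      if (!ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE))
        abort(paste0("unsupported transfer syntax: ", ts))
      implicit <- ts == TS_IMPLICIT_LE
    } else if (group == 0x0028L && elem == 0x0010L) {
      fields$rows <- u16(val_at)
    } else if (group == 0x0028L && elem == 0x0011L) {
      fields$cols <- u16(val_at)
    } else if (group == 0x0028L && elem == 0x0030L) {
      parts <- strsplit(trimws(rawToChar(value)), "\\\\")[[1L]]
      fields$spacing <- as.numeric(parts)
    } else if (group == 0x0028L && elem == 0x0100L) {
      fields$bits <- u16(val_at)
    } else if (group == 0x7FE0L && elem == 0x0010L) {
      fields$data <- value
      break
    }
    pos <- val_at + len
  }

  if (is.null(fields$data)) abort("DICOM has no PixelData (7FE0,0010)")
  if (is.null(fields$rows) || is.null(fields$cols))
    abort("DICOM is missing Rows/Columns")
  size <- if (fields$bits == 16L) 2L else 1L
  vals <- readBin(fields$data, "integer", n = length(fields$data) %/% size,
                  size = size, signed = FALSE, endian = "little")
  px <- matrix(vals[seq_len(fields$rows * fields$cols)],
               nrow = fields$rows, ncol = fields$cols, byrow = TRUE)
  list(pixels = px, pixel_spacing_mm = fields$spacing,
       rows = fields$rows, cols = fields$cols, bits_allocated = fields$bits)
}
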