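#' Read and write mask and image files
#'
#' Masks and grayscale images travel as PNG or TIFF. On reading, any
#' non-zero value is foreground for masks; multi-channel files are reduced
#' to grayscale by channel averaging for images and by the first channel for
#' masks.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @return `read_mask()` a 0/1 integer matrix; `read_image()` a numeric
#'   matrix in `[0, 1]`.
#' @export
read_mask <- function(path) {
  a <- read_raster(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  as_binary_mask(a)
}

#' @rdname read_mask
#' @export
read_image <- function(path) {
  a <- read_raster(path)
  if (length(dim(a)) == 3L) a <- apply(a, c(1L, 2L), mean)
  a
}

read_raster <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported raster format: .", ext))
  )
}

#' @rdname read_mask
#' @param mask,image Matrix to write.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  write_raster(mask, path)
}

#' @rdname read_mask
#' @export
write_image <- function(image, path) {
  write_raster(pmin(pmax(image, 0), 1), path)
}

write_raster <- function(m, path) {
  ext <- tolower(tools::file_ext(path))
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    abort(paste0("unsupported raster format: .", ext))
  )
  invisible(path)
}

#' Read pixel spacing from a JSON sidecar
#'
#' The sidecar holds spacing in millimeters per pixel, DICOM-style:
#' `{"row_spacing_mm": x, "col_spacing_mm": y}`; values are converted to
#' cm/px.
#'
#' @param path Path to the JSON file.
#' @return A [pixel_spacing()].
#' @export
read_spacing_sidecar <- function(path) {
  if (!file.exists(path)) abort(paste0("sidecar not found: ", path))
  j <- jsonlite::read_json(path)
  if (is.null(j$row_spacing_mm) || is.null(j$col_spacing_mm))
    abort("sidecar must contain row_spacing_mm and col_spacing_mm")
  spacing_from_mm(as.numeric(j$row_spacing_mm), as.numeric(j$col_spacing_mm))
}

#' Read an ultrasound study (DICOM, or image plus sidecar)
#'
#' Loads a grayscale image and its pixel spacing. For DICOM input, spacing
#' comes from the PixelSpacing tag (0028,0030), which the standard defines
#' as (row spacing, column spacing) in mm. `spacing_order = "paper"`
#' reproduces pipelines that read the first component as the column spacing
#' instead; the two agree whenever spacing is isotropic.
#'
#' @param path A `.dcm` file, or a PNG/TIFF image with a JSON sidecar.
#' @param sidecar Optional explicit sidecar path (default: image path with
#'   a `.json` extension appended).
#' @param spacing_order `"dicom"` (row first; default) or `"paper"`.
#' @return A list of class `"study_record"`: `image` (matrix in `[0, 1]`),
#'   `spacing` ([pixel_spacing()]), `source` path.
#' @export
read_study <- function(path, sidecar = NULL,
                       spacing_order = c("dicom", "paper")) {
  spacing_order <- match.arg(spacing_order)
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcm") {
    d <- read_dicom(path)
    if (is.null(d$pixel_spacing_mm))
      abort("DICOM is missing the PixelSpacing tag (0028,0030) and no sidecar applies")
    sp <- d$pixel_spacing_mm
    image <- d$pixels / max(1, max(d$pixels))
  } else {
    image <- read_image(path)
    sidecar <- sidecar %||% paste0(path, ".json")
    j <- read_spacing_sidecar(sidecar)
    sp <- 10 * c(j[["row_cm"]], j[["col_cm"]])
  }
  spacing <- if (spacing_order == "dicom") spacing_from_mm(sp[1L], sp[2L])
             else spacing_from_mm(sp[2L], sp[1L])
  structure(list(image = image, spacing = spacing, source = path),
            class = "study_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Center (or anchored) crop to the network input size
#'
#' Crops an image to `size` x `size`, by default centered, recording the
#' crop offset so measured rectangle corners can be mapped back to the
#' original frame (`original = cropped + offset - 1`). Images smaller than
#' the target are an error; there is no upscaling.
#'
#' @param image Matrix.
#' @param size Output side length (default 512).
#' @param anchor Optional (row, col) of the top-left corner of the crop
#'   window; default centers the window.
#' @return A list with `image` (size x size) and `offset` (row, col of the
#'   input pixel that became `image[1, 1]`).
#' @export
#' @examples
#' crop_to_input(matrix(0, 720, 960))$offset
crop_to_input <- function(image, size = 512L, anchor = NULL) {
  H <- nrow(image); W <- ncol(image)
  size <- as.integer(size)
  if (H < size || W < size)
    abort(sprintf("image %dx%d smaller than crop size %d (no upscaling)", H, W, size))
  if (is.null(anchor))
    anchor <- c((H - size) %/% 2L + 1L, (W - size) %/% 2L + 1L)
  anchor <- as.integer(anchor)
  if (anchor[1L] < 1L || anchor[2L] < 1L ||
      anchor[1L] + size - 1L > H || anchor[2L] + size - 1L > W)
    abort("crop window out of bounds")
  list(image = image[anchor[1L]:(anchor[1L] + size - 1L),
                     anchor[2L]:(anchor[2L] + size - 1L), drop = FALSE],
       offset = c(row = anchor[1L], col = anchor[2L]))
}
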