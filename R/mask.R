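#' Coerce to a binary mask
#'
#' A binary mask is an integer matrix of 0/1 values indexed as (row, col),
#' with foreground (the gestational sac) coded 1. Any non-zero value in the
#' input is treated as foreground, which matches how annotation tools export
#' binary PNG/TIFF masks.
#'
#' @param x A matrix (numeric, integer or logical).
#' @return An integer matrix of 0/1 with class `"binary_mask"` kept implicit
#'   (plain matrix), suitable for all mask-level operations in the package.
#' @export
#' @examples
#' m <- as_binary_mask(matrix(c(0, 2, 0, 255), 2, 2))
#' sum(m)
as_binary_mask <- function(x) {
  if (!is.matrix(x)) abort("`x` must be a matrix.")
  if (nrow(x) < 1L || ncol(x) < 1L) abort("mask must have positive dimensions")
  if (anyNA(x)) abort("mask contains NA values")
  m <- matrix(as.integer(x != 0), nrow(x), ncol(x))
  m
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) abort(sprintf("`%s` must be a matrix", arg))
  mask
}

#' Keep only the largest 8-connected foreground component
#'
#' The biometry chain assumes a single sac; stray speckle components from a
#' segmentation model are removed before boundary tracing. Connectivity is
#' 8-neighborhood (diagonals connect). Ties in component size are broken by
#' label order (first component found in column-major scan).
#'
#' @param mask Binary mask matrix (any non-zero value is foreground).
#' @return A 0/1 integer matrix of the same size retaining only the largest
#'   connected foreground component.
#' @export
#' @examples
#' m <- matrix(0, 10, 10); m[2:6, 2:6] <- 1; m[9, 9] <- 1
#' sum(extract_largest_component(m))
extract_largest_component <- function(mask) {
  mask <- as_binary_mask(assert_mask(mask))
  if (sum(mask) == 0L) abort("no foreground: mask has no non-zero pixels")
  lab <- label8_cpp(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  matrix(as.integer(lab == keep), nrow(mask), ncol(mask))
}

# pixels of `mask` with at least one background 4-neighbor (or image border);
# this is the set a Moore boundary walk visits on a simply connected shape
boundary_pixels_4 <- function(mask) {
  p <- pad_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  core <- p[2:(H + 1L), 2:(W + 1L), drop = FALSE]
  nb <- p[1:H, 2:(W + 1L), drop = FALSE] & p[3:(H + 2L), 2:(W + 1L), drop = FALSE] &
    p[2:(H + 1L), 1:W, drop = FALSE] & p[2:(H + 1L), 3:(W + 2L), drop = FALSE]
  which(core == 1L & !nb, arr.ind = TRUE)
}

# pixels with at least one background 8-neighbor (or border)
boundary_pixels_8 <- function(mask) {
  p <- pad_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  all_nb <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    all_nb <- all_nb & p[(2L + dr):(H + 1L + dr), (2L + dc):(W + 1L + dc), drop = FALSE]
  }
  core <- p[2:(H + 1L), 2:(W + 1L), drop = FALSE]
  which(core == 1L & !all_nb, arr.ind = TRUE)
}

pad_mask <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  p <- matrix(0L, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- mask
  p
}
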