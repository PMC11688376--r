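#' Pixel spacing in cm per pixel
#'
#' Physical distance between adjacent pixel centers along the row axis
#' (vertical step) and the column axis (horizontal step). The package works
#' in cm/px internally because sac diameters are reported in centimeters;
#' use [spacing_from_mm()] for DICOM-style mm values.
#'
#' @param row_cm,col_cm Spacing along the row / column axis, cm per pixel.
#' @return A named numeric vector of class `"pixel_spacing"`.
#' @export
#' @examples
#' pixel_spacing(0.01, 0.01)
pixel_spacing <- function(row_cm, col_cm = row_cm) {
  row_cm <- as.numeric(row_cm); col_cm <- as.numeric(col_cm)
  if (length(row_cm) != 1L || length(col_cm) != 1L)
    abort("spacing components must be scalars")
  if (!is.finite(row_cm) || !is.finite(col_cm) || row_cm <= 0 || col_cm <= 0)
    abort("pixel spacing must be strictly positive and finite")
  structure(c(row_cm = row_cm, col_cm = col_cm), class = "pixel_spacing")
}

#' @rdname pixel_spacing
#' @param row_mm,col_mm Spacing in mm per pixel (the DICOM PixelSpacing unit).
#' @export
spacing_from_mm <- function(row_mm, col_mm = row_mm) {
  pixel_spacing(row_mm / 10, col_mm / 10)
}

as_spacing <- function(spacing) {
  if (inherits(spacing, "pixel_spacing")) return(spacing)
  if (is.numeric(spacing) && length(spacing) %in% c(1L, 2L)) {
    if (length(spacing) == 1L) return(pixel_spacing(spacing))
    return(pixel_spacing(spacing[[1L]], spacing[[2L]]))
  }
  abort("`spacing` must be a pixel_spacing or a numeric of length 1 or 2 (cm/px)")
}

#' Measure the sac diameters of a fitted rectangle
#'
#' Converts the two labeled sides of a minimum-area rectangle into physical
#' lengths: each corner coordinate is scaled by its axis spacing before the
#' Euclidean distance is taken, so anisotropic pixels are handled per axis.
#' The maximum length `DM` spans corners `c1`--`c2` (the long side) and the
#' short diameter `Dm` spans `c1`--`c3`.
#'
#' @param rect A [min_area_rect()] result.
#' @param spacing A [pixel_spacing()] (cm/px).
#' @return Named numeric vector `c(DM_cm, Dm_cm)` with `DM_cm >= Dm_cm`
#'   whenever spacing is isotropic (guaranteed by corner labeling; with
#'   strongly anisotropic spacing the scaled lengths are still reported from
#'   the labeled sides).
#' @export
measure_diameters <- function(rect, spacing) {
  if (!inherits(rect, "min_area_rect")) abort("`rect` must be a min_area_rect")
  spacing <- as_spacing(spacing)
  ps_row <- spacing[["row_cm"]]; ps_col <- spacing[["col_cm"]]
  dist_cm <- function(a, b) {
    sqrt(((b[["col"]] - a[["col"]]) * ps_col)^2 +
         ((b[["row"]] - a[["row"]]) * ps_row)^2)
  }
  dm <- dist_cm(rect$c1, rect$c2)
  dm_small <- dist_cm(rect$c1, rect$c3)
  c(DM_cm = max(dm, dm_small), Dm_cm = min(dm, dm_small))
}

#' Gestational age from sac diameters (Hellman formula)
#'
#' Estimates gestational weeks from the mean sac diameter:
#' `GW = (0.5 * (DM + Dm) + 2.543) / 0.7`, where `DM` and `Dm` are the
#' maximum length and short diameter of the sac in centimeters. The estimate
#' depends on the diameters only through their sum and is strictly
#' increasing in each. At `DM = Dm = 2.5` cm (mean sac diameter 25 mm) the
#' formula gives 7.2 weeks, the classical empty-sac decision threshold.
#'
#' @param DM,Dm Sac diameters in cm (non-negative; vectorized).
#' @return Gestational age in weeks.
#' @export
#' @examples
#' estimate_gw(2.5, 2.5)
estimate_gw <- function(DM, Dm) {
  if (any(!is.finite(DM)) || any(!is.finite(Dm)) || any(DM < 0) || any(Dm < 0))
    abort("diameters must be finite and non-negative")
  (0.5 * (DM + Dm) + 2.543) / 0.7
}

# inverse of the Hellman formula: mean sac diameter (cm) for a given GW
msd_for_gw <- function(gw) 0.7 * gw - 2.543

#' Full sac biometry from a binary mask
#'
#' Runs the measurement chain on a segmented sac mask: keep the largest
#' 8-connected component, trace its outer boundary (Moore neighbor tracing),
#' fit the minimum-area enclosing rectangle to the boundary points (rotating
#' calipers), scale the rectangle sides by the pixel spacing to obtain the
#' maximum length `DM` and short diameter `Dm` in cm, and convert to
#' gestational weeks with the Hellman formula.
#'
#' A boundary pixel is a unit square, not a point: fitting the rectangle to
#' pixel centers would shave half a pixel off every side (a systematic
#' underestimate of about one pixel per diameter, which matters at coarse
#' spacing). With `pixel_extent = "square"` (the default) the rectangle is
#' fitted to the four corners of each boundary pixel, making the measured
#' extent an essentially unbiased estimate of the continuous object's;
#' `"center"` keeps the raw pixel-center convention.
#'
#' Degenerate masks (one or two boundary pixels) yield a degenerate
#' rectangle measured on pixel centers regardless of `pixel_extent`, so
#' `Dm = 0` (and `DM = 0` for a single pixel); the gestational age is
#' still computed and floors at `2.543 / 0.7` (about 3.63) weeks.
#'
#' @param mask Binary mask matrix, foreground = sac (at least one pixel).
#' @param spacing A [pixel_spacing()] or numeric (row, col) cm/px.
#' @param pixel_extent `"square"` (default) or `"center"`, see Details.
#' @return An object of class `"sac_biometry"`: list with `DM_cm`, `Dm_cm`,
#'   `GW_weeks`, the fitted `rect`, the `spacing` used and the traced
#'   `contour`. Use [tidy()] for a one-row tibble.
#' @export
#' @examples
#' sac <- generate_sac(sac_params(a = 80, b = 50, spacing = 0.01), seed = 1)
#' run_biometry(sac$mask, sac$params$spacing)
run_biometry <- function(mask, spacing, pixel_extent = c("square", "center")) {
  pixel_extent <- match.arg(pixel_extent)
  spacing <- as_spacing(spacing)
  mask <- tryCatch(extract_largest_component(mask),
                   error = function(e) abort(paste0("biometry failed: ", conditionMessage(e))))
  contour <- trace_boundary(mask)
  pts <- contour
  if (pixel_extent == "square" && nrow(unique_rows(contour)) >= 3L) {
    pts <- rbind(sweep(contour, 2, c(0.5, 0.5)), sweep(contour, 2, c(0.5, -0.5)),
                 sweep(contour, 2, c(-0.5, 0.5)), sweep(contour, 2, c(-0.5, -0.5)))
  }
  rect <- min_area_rect(pts)
  d <- measure_diameters(rect, spacing)
  gw <- estimate_gw(d[["DM_cm"]], d[["Dm_cm"]])
  structure(
    list(DM_cm = unname(d[["DM_cm"]]), Dm_cm = unname(d[["Dm_cm"]]),
         GW_weeks = unname(gw), rect = rect, spacing = spacing,
         contour = contour),
    class = "sac_biometry"
  )
}

#' @export
print.sac_biometry <- function(x, ...) {
  cat("Gestational sac biometry\n")
  cat(sprintf("  DM = %.3f cm, Dm = %.3f cm (MSD %.1f mm)\n",
              x$DM_cm, x$Dm_cm, 5 * (x$DM_cm + x$Dm_cm)))
  cat(sprintf("  GW = %.2f weeks (Hellman)\n", x$GW_weeks))
  cat(sprintf("  spacing: %.4f x %.4f cm/px, rect angle %.1f deg\n",
              x$spacing[["row_cm"]], x$spacing[["col_cm"]], x$rect$angle))
  invisible(x)
}

#' @export
tidy.sac_biometry <- function(x, ...) {
  tibble::tibble(DM_cm = x$DM_cm, Dm_cm = x$Dm_cm, GW_weeks = x$GW_weeks,
                 angle_deg = x$rect$angle, area_px = x$rect$area_px,
                 row_spacing_cm = x$spacing[["row_cm"]],
                 col_spacing_cm = x$spacing[["col_cm"]])
}

#' @export
glance.sac_biometry <- function(x, ...) tidy(x)

#' Plot a biometry result over its mask
#'
#' Shows the mask, the traced boundary and the fitted minimum-area rectangle.
#'
#' @param object A [run_biometry()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sac_biometry <- function(object, ...) {
  rect <- object$rect
  corners <- tidy(rect)[c(1, 2, 4, 3, 1), ]  # closed polygon in side order
  contour <- tibble::as_tibble(object$contour)
  ggplot2::ggplot() +
    ggplot2::geom_path(data = contour, ggplot2::aes(x = .data$col, y = .data$row),
                       color = "grey40", linewidth = 0.3) +
    ggplot2::geom_path(data = corners, ggplot2::aes(x = .data$col, y = .data$row),
                       color = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "col", y = "row",
      title = sprintf("DM %.2f cm, Dm %.2f cm, GW %.2f weeks",
                      object$DM_cm, object$Dm_cm, object$GW_weeks)
    ) +
    ggplot2::theme_minimal()
}
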