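#' Convex hull of a set of (row, col) points
#'
#' Thin wrapper around [grDevices::chull()] returning the hull vertices in
#' counterclockwise order (with respect to x = col, y = row axes), with
#' collinear interior points excluded. One or two points are returned as is.
#'
#' @param points A two-column matrix of (row, col) coordinates.
#' @return A two-column matrix of hull vertices (row, col), counterclockwise.
#' @export
convex_hull <- function(points) {
  points <- as_points(points)
  if (nrow(points) <= 2L) return(unique_rows(points))
  idx <- chull(points[, 2L], points[, 1L])  # clockwise in (x, y)
  out <- points[rev(idx), , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 1L)
    abort("`points` must be an n x 2 matrix of (row, col) coordinates")
  if (anyNA(points) || any(!is.finite(points))) abort("points must be finite")
  storage.mode(points) <- "double"
  colnames(points) <- c("row", "col")
  points
}

unique_rows <- function(m) m[!duplicated(m), , drop = FALSE]

#' Minimum-area enclosing rectangle (rotating calipers)
#'
#' Fits the smallest-area rectangle enclosing a point set. By the rotating
#' calipers theorem the optimal rectangle is flush with an edge of the convex
#' hull, so only hull-edge orientations are examined. Corners are labeled by
#' the side-adjacency convention: `c1` is the reference corner (smallest row,
#' ties broken by smallest column), `c2` is adjacent to `c1` along the longer
#' side, `c3` adjacent along the shorter side, and `c4` is the remaining
#' corner. This makes the `c1`--`c2` distance the maximum length and the
#' `c1`--`c3` distance the short diameter by construction.
#'
#' @param points A two-column matrix of (row, col) coordinates (e.g. a traced
#'   boundary). Degenerate inputs are allowed: collinear points give a
#'   zero-width rectangle, a single point a zero-size one.
#' @return An object of class `"min_area_rect"`: a list with real-valued
#'   corners `c1`..`c4` (named (row, col) vectors), `angle` (degrees of the
#'   long side against the column axis, in [0, 180)), `area_px` (squared
#'   pixels), and side lengths `long_px`, `short_px`.
#' @export
#' @examples
#' pts <- rbind(c(0, 0), c(1, 1), c(2, 0), c(1, -1))
#' min_area_rect(pts)$area_px
min_area_rect <- function(points) {
  points <- as_points(points)
  hull <- convex_hull(points)
  x <- hull[, 2L]; y <- hull[, 1L]
  n <- nrow(hull)

  if (n == 1L) {
    return(new_rect(cbind(rep(y, 4L), rep(x, 4L)), angle = 0, ex = 0, ey = 0))
  }

  # candidate orientations: hull edge directions (plus closing edge)
  nx <- c(x[-1L], x[1L]); ny <- c(y[-1L], y[1L])
  th <- atan2(ny - y, nx - x)
  th <- unique(th %% pi)

  best <- NULL
  for (t in th) {
    ct <- cos(t); st <- sin(t)
    u <- x * ct + y * st     # coordinate along the edge direction
    v <- -x * st + y * ct    # coordinate across
    ex <- max(u) - min(u); ey <- max(v) - min(v)
    a <- ex * ey
    if (is.null(best) || a < best$a - 1e-12) {
      best <- list(a = a, t = t, u0 = min(u), u1 = max(u),
                   v0 = min(v), v1 = max(v), ex = ex, ey = ey)
    }
  }

  ct <- cos(best$t); st <- sin(best$t)
  back <- function(u, v) c(row = u * st + v * ct, col = u * ct - v * st)
  corners <- rbind(back(best$u0, best$v0), back(best$u1, best$v0),
                   back(best$u1, best$v1), back(best$u0, best$v1))
  new_rect(corners, angle = best$t, ex = best$ex, ey = best$ey)
}

new_rect <- function(corners, angle, ex, ey) {
  colnames(corners) <- c("row", "col")
  # reference corner: smallest row, then smallest column
  ord <- order(round(corners[, 1L], 9), round(corners[, 2L], 9))
  c1 <- corners[ord[1L], ]
  others <- corners[-ord[1L], , drop = FALSE]
  d <- sqrt(rowSums((others - rep(c1, each = 3L))^2))
  c4 <- others[which.max(d), ]
  adj <- others[-which.max(d), , drop = FALSE]
  dd <- sqrt(rowSums((adj - rep(c1, each = 2L))^2))
  i2 <- which.max(dd)
  c2 <- adj[i2, ]       # adjacent along the longer side
  c3 <- adj[3L - i2, ]  # the other neighbor (distinct even on exact squares)
  long_px <- max(dd); short_px <- min(dd)
  ang <- atan2(c2["row"] - c1["row"], c2["col"] - c1["col"]) %% pi
  structure(
    list(c1 = c1, c2 = c2, c3 = c3, c4 = c4,
         angle = unname(ang * 180 / pi),
         area_px = ex * ey, long_px = long_px, short_px = short_px),
    class = "min_area_rect"
  )
}

#' @export
print.min_area_rect <- function(x, ...) {
  cat("Minimum-area rectangle\n")
  cat(sprintf("  sides: %.2f x %.2f px, area %.2f px^2, angle %.1f deg\n",
              x$long_px, x$short_px, x$area_px, x$angle))
  for (nm in c("c1", "c2", "c3", "c4"))
    cat(sprintf("  %s: (%.2f, %.2f)\n", nm, x[[nm]][1L], x[[nm]][2L]))
  invisible(x)
}

#' @export
tidy.min_area_rect <- function(x, ...) {
  tibble::tibble(
    corner = c("c1", "c2", "c3", "c4"),
    row = c(x$c1[1L], x$c2[1L], x$c3[1L], x$c4[1L]),
    col = c(x$c1[2L], x$c2[2L], x$c3[2L], x$c4[2L])
  )
}
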