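#' Trace the outer boundary of a binary object (Moore neighbor tracing)
#'
#' Walks the outer boundary of the (single) foreground component of a binary
#' mask through the Moore 8-neighborhood, visiting boundary pixels in order.
#' The walk starts at the first foreground pixel in row-major scan order
#' (top-to-bottom, left-to-right), scans neighbors clockwise from the
#' backtracked background pixel, and stops by Jacob's criterion: when the
#' start pixel is re-entered from the same background neighbor from which it
#' was first entered. The mask is implicitly padded with a one-pixel zero
#' frame so objects touching the image border have a well-defined boundary;
#' returned coordinates are in the original frame.
#'
#' @param mask Binary mask matrix with exactly one 8-connected foreground
#'   component (use [extract_largest_component()] first if unsure).
#' @return An integer matrix with columns `row`, `col`: the ordered boundary
#'   pixel sequence. Consecutive rows are 8-neighbors and the sequence is
#'   closed (the last point is an 8-neighbor of the first). Pixels may appear
#'   more than once on shapes with one-pixel-wide necks, as the walk must
#'   pass through them in both directions.
#' @export
#' @examples
#' m <- matrix(0, 10, 10); m[3:5, 3:5] <- 1
#' trace_boundary(m)
trace_boundary <- function(mask) {
  mask <- as_binary_mask(assert_mask(mask))
  if (sum(mask) == 0L) abort("no foreground: cannot trace an empty mask")
  p <- pad_mask(mask)
  H <- nrow(p); W <- ncol(p)

  # clockwise neighbor offsets in image coordinates (row grows downward)
  offs <- matrix(c(-1L, 0L,   # N
                   -1L, 1L,   # NE
                   0L, 1L,    # E
                   1L, 1L,    # SE
                   1L, 0L,    # S
                   1L, -1L,   # SW
                   0L, -1L,   # W
                   -1L, -1L), # NW
                 ncol = 2L, byrow = TRUE)
  dir_of <- matrix(NA_integer_, 3L, 3L)
  for (d in 1:8) dir_of[offs[d, 1L] + 2L, offs[d, 2L] + 2L] <- d

  # start pixel: first foreground in row-major scan of the padded grid
  fg <- which(t(p) == 1L)[1L]  # t() makes the scan row-major
  r0 <- (fg - 1L) %/% W + 1L
  c0 <- (fg - 1L) %% W + 1L
  p0 <- c(r0, c0)
  b0_dir <- 7L  # entered from the west neighbor, background by scan order

  contour <- matrix(0L, 4L * sum(mask) + 8L, 2L)
  contour[1L, ] <- p0
  n_pts <- 1L

  step <- function(cur, bdir) {
    for (s in 1:8) {
      d <- (bdir + s - 1L) %% 8L + 1L
      nb <- cur + offs[d, ]
      if (p[nb[1L], nb[2L]] == 1L) {
        prev_d <- (bdir + s - 2L) %% 8L + 1L  # neighbor checked just before
        back <- if (s == 1L) cur + offs[bdir, ] else cur + offs[prev_d, ]
        return(list(p = nb,
                    bdir = dir_of[back[1L] - nb[1L] + 2L, back[2L] - nb[2L] + 2L]))
      }
    }
    NULL  # isolated single pixel: no foreground neighbor
  }

  # Jacob's stopping criterion, phrased on transitions: the walk is a
  # deterministic orbit on (pixel, backtrack-direction) states, so the first
  # post-start state recurs exactly when the boundary cycle closes. The
  # start state itself is synthetic (its backtrack is fixed by scan order)
  # and may never recur on shapes entered "against" the scan direction.
  first <- step(p0, b0_dir)
  if (!is.null(first)) {
    cur <- first$p
    bdir <- first$bdir
    repeat {
      n_pts <- n_pts + 1L
      if (n_pts > nrow(contour)) abort("boundary walk failed to terminate")
      contour[n_pts, ] <- cur
      nxt <- step(cur, bdir)
      if (nxt$p[1L] == first$p[1L] && nxt$p[2L] == first$p[2L] &&
          nxt$bdir == first$bdir)
        break
      cur <- nxt$p
      bdir <- nxt$bdir
    }
    # drop a trailing revisit of the start pixel (the cycle is closed)
    if (n_pts > 1L && all(contour[n_pts, ] == p0)) n_pts <- n_pts - 1L
  }

  out <- contour[seq_len(n_pts), , drop = FALSE] - 1L  # unpad
  colnames(out) <- c("row", "col")
  out
}
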