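#' Parameters of a synthetic gestational sac phantom
#'
#' Describes a rotated, optionally irregular ellipse used to rasterize a
#' sac mask with analytically known ground truth. Semi-axes are in pixels,
#' the rotation angle in degrees of the major axis against the column axis,
#' and `irregularity` is the amplitude (fraction of the radius, at most 0.3)
#' of a smooth low-frequency radial perturbation that emulates the distorted
#' contours of abnormal sacs.
#'
#' @param a,b Semi-major and semi-minor axes in pixels (`a >= b > 0`).
#' @param angle Rotation of the major axis, degrees.
#' @param center Optional (row, col) center; default image center.
#' @param irregularity Radial perturbation amplitude in `[0, 0.3]`.
#' @param spacing [pixel_spacing()] or numeric cm/px (default 0.01, i.e.
#'   0.1 mm/px, the fine end of early-pregnancy ultrasound).
#' @param label `"normal"` or `"abnormal"`.
#' @param modality `"TAS"` or `"TVS"`.
#' @param size Image size (rows, cols); default 512 x 512.
#' @return A list of validated parameters of class `"sac_params"`.
#' @export
sac_params <- function(a, b, angle = 0, center = NULL, irregularity = 0,
                       spacing = 0.01, label = c("normal", "abnormal"),
                       modality = c("TAS", "TVS"), size = c(512L, 512L)) {
  label <- match.arg(label); modality <- match.arg(modality)
  if (!is.finite(a) || !is.finite(b) || b <= 0 || a < b)
    abort("need semi-axes a >= b > 0")
  if (irregularity < 0 || irregularity > 0.3)
    abort("irregularity must lie in [0, 0.3]")
  size <- as.integer(size)
  if (is.null(center)) center <- (size + 1) / 2
  structure(list(a = a, b = b, angle = angle, center = center,
                 irregularity = irregularity, spacing = as_spacing(spacing),
                 label = label, modality = modality, size = size),
            class = "sac_params")
}

# smooth 2*pi-periodic perturbation profile, normalized to max |f| = 1
perturb_profile <- function(seed) {
  coefs <- local_seed(seed, {
    k <- 2:4
    list(k = k, a = rnorm(length(k)), b = rnorm(length(k)))
  })
  psi <- seq(0, 2 * pi, length.out = 721L)
  f <- drop(cos(outer(psi, coefs$k)) %*% coefs$a +
            sin(outer(psi, coefs$k)) %*% coefs$b)
  coefs$scale <- 1 / max(abs(f))
  coefs
}

eval_profile <- function(coefs, psi) {
  drop(cos(outer(psi, coefs$k)) %*% coefs$a +
       sin(outer(psi, coefs$k)) %*% coefs$b) * coefs$scale
}

# run expr with a private RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic sac mask with known ground truth
#'
#' Rasterizes the (possibly perturbed) rotated ellipse: a pixel is foreground
#' iff its integer center lies inside the boundary; no anti-aliasing, so the
#' mask is strictly binary. Ground-truth diameters are reported for the
#' unperturbed ellipse, whose minimum-area rectangle has sides `2a` by `2b`
#' in pixels, scaled per axis by the pixel spacing; ground-truth gestational
#' age applies the Hellman formula to those diameters.
#'
#' @param params A [sac_params()] object.
#' @param seed Integer seed controlling the perturbation shape.
#' @return A list of class `"synthetic_sac"` with elements `mask`, `truth`
#'   (`DM_cm`, `Dm_cm`, `GW_weeks`), `params` and the perturbation `perturb`
#'   (so a pseudo-ultrasound rendering can be reproduced).
#' @export
#' @examples
#' sac <- generate_sac(sac_params(a = 125, b = 125, spacing = 0.01), seed = 1)
#' sac$truth$GW_weeks
generate_sac <- function(params, seed = 1L) {
  stopifnot(inherits(params, "sac_params"))
  H <- params$size[1L]; W <- params$size[2L]
  amp <- params$irregularity
  reach <- params$a * (1 + amp)
  ctr <- params$center
  if (ctr[1L] - reach < 1 || ctr[1L] + reach > H ||
      ctr[2L] - reach < 1 || ctr[2L] + reach > W)
    abort("ellipse (with perturbation) does not fit inside the image")

  coefs <- if (amp > 0) perturb_profile(seed) else NULL
  rho <- sac_rho(params, coefs)
  mask <- matrix(as.integer(rho <= 1), H, W)

  th <- params$angle * pi / 180
  ps <- params$spacing
  d_major <- 2 * params$a * sqrt((cos(th) * ps[["col_cm"]])^2 + (sin(th) * ps[["row_cm"]])^2)
  d_minor <- 2 * params$b * sqrt((sin(th) * ps[["col_cm"]])^2 + (cos(th) * ps[["row_cm"]])^2)
  DM <- max(d_major, d_minor); Dm <- min(d_major, d_minor)
  structure(
    list(mask = mask,
         truth = list(DM_cm = DM, Dm_cm = Dm, GW_weeks = estimate_gw(DM, Dm)),
         params = params, perturb = coefs),
    class = "synthetic_sac"
  )
}

# normalized radial coordinate of every pixel: <= 1 inside the sac
sac_rho <- function(params, coefs = NULL) {
  H <- params$size[1L]; W <- params$size[2L]
  th <- params$angle * pi / 180
  dr <- matrix(seq_len(H) - params$center[1L], H, W)
  dc <- matrix(seq_len(W) - params$center[2L], H, W, byrow = TRUE)
  u <- (dc * cos(th) + dr * sin(th)) / params$a
  v <- (-dc * sin(th) + dr * cos(th)) / params$b
  rho <- sqrt(u^2 + v^2)
  if (!is.null(coefs) && params$irregularity > 0) {
    psi <- atan2(v, u)
    rho <- rho / (1 + params$irregularity * eval_profile(coefs, as.numeric(psi)))
  }
  rho
}

#' Render a pseudo-ultrasound image of a synthetic sac
#'
#' Produces a grayscale rendering with the anechoic appearance of a sac on
#' ultrasound: dark fluid-filled lumen, bright rim (the trophoblastic ring),
#' mid-gray background, plus multiplicative speckle. This emulates contrast
#' and speckle statistics only, not beam physics.
#'
#' @param case A [generate_sac()] result.
#' @param noise_seed Integer seed for the speckle field.
#' @param noise_amp Speckle mixing amplitude in `[0, 1]`; 0 gives a clean
#'   three-level image.
#' @param rim_frac Rim thickness as a fraction of the sac radius.
#' @return A numeric matrix in `[0, 1]` of the same size as the mask.
#' @export
render_us_image <- function(case, noise_seed = 1L, noise_amp = 0.35,
                            rim_frac = 0.1) {
  stopifnot(inherits(case, "synthetic_sac"))
  rho <- sac_rho(case$params, case$perturb)
  img <- matrix(0.35, nrow(rho), ncol(rho))   # background
  img[rho <= 1 + rim_frac] <- 0.85            # echogenic rim
  img[rho <= 1] <- 0.12                       # anechoic lumen
  if (noise_amp > 0) {
    speckle <- local_seed(noise_seed, {
      sigma <- sqrt(2 / pi)  # Rayleigh scale with unit mean
      matrix(sigma * sqrt(-2 * log(runif(length(img)))), nrow(img), ncol(img))
    })
    img <- img * (1 - noise_amp + noise_amp * speckle)
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic study cohort
#'
#' Draws `n` sac phantoms whose Hellman-implied gestational ages are uniform
#' on `ga_range`: the mean sac diameter is obtained by inverting the formula
#' (`MSD = 0.7 * GW - 2.543` cm), split into major/minor diameters by a
#' random aspect ratio, oriented uniformly in 0--180 degrees, and placed at
#' a pixel spacing drawn from 0.1--0.5 mm/px (constrained so the sac fits in
#' the frame). Abnormal cases receive a non-zero contour irregularity.
#'
#' @param n Number of cases.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param ga_range Gestational-age range in weeks, default 4--10.
#' @param prop_abnormal Fraction of abnormal (irregular) cases.
#' @param prop_tvs Fraction of transvaginal-probe cases (bookkeeping only).
#' @param size Image size, default 512 x 512.
#' @return A list with `cases` (list of [generate_sac()] results) and
#'   `manifest`, a tibble with one row per case (identifier, geometry,
#'   spacing, ground-truth diameters and GW, label, modality).
#' @export
generate_dataset <- function(n, seed = 1L, ga_range = c(4, 10),
                             prop_abnormal = 226 / 500, prop_tvs = 195 / 500,
                             size = c(512L, 512L)) {
  if (n < 1L) abort("n must be at least 1")
  if (prop_abnormal < 0 || prop_abnormal > 1 || prop_tvs < 0 || prop_tvs > 1)
    abort("infeasible class or modality mix")
  if (diff(range(ga_range)) < 0 || ga_range[1L] < 3.7)
    abort("ga_range must be increasing and above the Hellman floor")

  n_abn <- round(n * prop_abnormal)
  n_tvs <- round(n * prop_tvs)
  draws <- local_seed(seed, {
    list(gw = runif(n, ga_range[1L], ga_range[2L]),
         q = runif(n, 0.65, 1),
         angle = runif(n, 0, 180),
         u_sp = runif(n),
         irr = runif(n, 0.05, 0.2),
         label = sample(rep(c("abnormal", "normal"), c(n_abn, n - n_abn))),
         modality = sample(rep(c("TVS", "TAS"), c(n_tvs, n - n_tvs))))
  })

  margin_px <- min(size) / 2 - 8
  cases <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    msd <- msd_for_gw(draws$gw[i])
    a_cm <- msd / (1 + draws$q[i])
    b_cm <- draws$q[i] * a_cm
    irr <- if (draws$label[i] == "abnormal") draws$irr[i] else 0
    s_lo <- max(0.01, a_cm * (1 + irr) / margin_px)
    s_hi <- 0.05
    s <- s_lo + draws$u_sp[i] * (s_hi - s_lo)
    p <- sac_params(a = a_cm / s, b = b_cm / s, angle = draws$angle[i],
                    irregularity = irr, spacing = s,
                    label = draws$label[i], modality = draws$modality[i],
                    size = size)
    cases[[i]] <- generate_sac(p, seed = seed + i)
    tr <- cases[[i]]$truth
    rows[[i]] <- tibble::tibble(
      case_id = sprintf("case_%04d", i),
      a_px = p$a, b_px = p$b, angle_deg = p$angle,
      row_spacing_cm = p$spacing[["row_cm"]], col_spacing_cm = p$spacing[["col_cm"]],
      DM_cm = tr$DM_cm, Dm_cm = tr$Dm_cm, GW_weeks = tr$GW_weeks,
      irregularity = irr, label = p$label, modality = p$modality
    )
  }
  list(cases = cases, manifest = dplyr::bind_rows(rows))
}
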