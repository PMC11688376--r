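test_that("diameters scale each axis by its own spacing", {
  r <- min_area_rect(rbind(c(0, 0), c(0, 100), c(50, 0), c(50, 100)))
  d <- measure_diameters(r, pixel_spacing(0.05, 0.05))
  expect_equal(unname(d), c(5, 2.5), tolerance = 1e-12)

  # axis-aligned 100x100 px square with anisotropic spacing
  r2 <- min_area_rect(rbind(c(0, 0), c(0, 100), c(100, 0), c(100, 100)))
  d2 <- measure_diameters(r2, pixel_spacing(row_cm = 0.01, col_cm = 0.02))
  expect_equal(unname(d2), c(2, 1), tolerance = 1e-12)

  expect_error(measure_diameters(r, c(-0.01, 0.01)), "positive")
})

test_that("a 45-degree rectangle reproduces the per-axis scaled distances", {
  # rectangle with sides along (1,1)/sqrt2 and (-1,1)/sqrt2
  c1 <- c(0, 0); c2 <- c(60, 60); c3 <- c(20, -20)
  r <- min_area_rect(rbind(c1, c2, c3, c2 + c3))
  ps <- pixel_spacing(0.013, 0.021)
  d <- measure_diameters(r, ps)
  hand <- function(a, b) sqrt(((b[2] - a[2]) * 0.021)^2 + ((b[1] - a[1]) * 0.013)^2)
  expect_equal(unname(d[["DM_cm"]]), hand(c1, c2), tolerance = 1e-9)
  expect_equal(unname(d[["Dm_cm"]]), hand(c1, c3), tolerance = 1e-9)
})

test_that("the Hellman formula hits its anchor values and depends only on the sum", {
  expect_equal(round(estimate_gw(2.5, 2.5), 1), 7.2)
  expect_equal(estimate_gw(2.5, 2.5), (2.5 + 2.543) / 0.7, tolerance = 1e-12)
  expect_equal(estimate_gw(0, 0), 2.543 / 0.7, tolerance = 1e-12)
  expect_equal(estimate_gw(3, 2), estimate_gw(2.5, 2.5), tolerance = 1e-12)
  # strictly increasing in each argument
  expect_gt(estimate_gw(2.6, 2.5), estimate_gw(2.5, 2.5))
  expect_gt(estimate_gw(2.5, 2.6), estimate_gw(2.5, 2.5))
  expect_error(estimate_gw(-1, 1), "non-negative")
})

test_that("full biometry recovers digitized ellipse geometry", {
  sac <- generate_sac(sac_params(a = 125, b = 75, spacing = 0.01), seed = 2)
  b <- run_biometry(sac$mask, sac$params$spacing)
  expect_equal(b$DM_cm, 2.5, tolerance = 0.02)
  expect_equal(b$Dm_cm, 1.5, tolerance = 0.02)
  expect_equal(b$GW_weeks, (2.0 + 2.543) / 0.7, tolerance = 0.05)

  rot <- generate_sac(sac_params(a = 125, b = 75, angle = 30, spacing = 0.01),
                      seed = 2)
  br <- run_biometry(rot$mask, rot$params$spacing)
  expect_equal(br$DM_cm, b$DM_cm, tolerance = 0.02 * b$DM_cm)
  expect_equal(br$Dm_cm, b$Dm_cm, tolerance = 0.02 * b$Dm_cm)
})

test_that("a 250 px circle at 0.01 cm/px lands on the 7.2-week threshold", {
  sac <- generate_sac(sac_params(a = 125, b = 125, spacing = 0.01), seed = 1)
  b <- run_biometry(sac$mask, sac$params$spacing)
  expect_equal(b$GW_weeks, 7.2043, tolerance = 0.05)
})

test_that("diameters are rotation-robust (CV below 2 percent)", {
  res <- sapply(c(0, 30, 45, 60, 90), function(ang) {
    sac <- generate_sac(sac_params(a = 80, b = 55, angle = ang, spacing = 0.01,
                                   size = c(256L, 256L)), seed = 3)
    b <- run_biometry(sac$mask, sac$params$spacing)
    c(b$DM_cm, b$Dm_cm)
  })
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(res[1, ]), 0.02)
  expect_lt(cv(res[2, ]), 0.02)
})

test_that("scaling the sac scales the diameters and GW floors at the constant", {
  small <- generate_sac(sac_params(a = 40, b = 25, spacing = 0.01,
                                   size = c(128L, 128L)), seed = 4)
  big <- generate_sac(sac_params(a = 80, b = 50, spacing = 0.01,
                                 size = c(256L, 256L)), seed = 4)
  bs <- run_biometry(small$mask, 0.01)
  bb <- run_biometry(big$mask, 0.01)
  expect_equal(bb$DM_cm / bs$DM_cm, 2, tolerance = 0.03)
  expect_equal(bb$Dm_cm / bs$Dm_cm, 2, tolerance = 0.03)

  # degenerate masks still yield a result with the GW floor
  m <- matrix(0, 8, 8); m[4, 4] <- 1
  b1 <- run_biometry(m, 0.01)
  expect_equal(b1$DM_cm, 0)
  expect_equal(b1$Dm_cm, 0)
  expect_equal(b1$GW_weeks, 2.543 / 0.7, tolerance = 1e-12)
  m[4, 5] <- 1
  b2 <- run_biometry(m, 0.01)
  expect_equal(b2$Dm_cm, 0)
  expect_gte(b2$GW_weeks, 2.543 / 0.7)
})

test_that("biometry errors cleanly on empty masks and tidies to one row", {
  expect_error(run_biometry(matrix(0, 5, 5), 0.01), "biometry failed")
  sac <- generate_sac(sac_params(a = 20, b = 15, spacing = 0.02,
                                 size = c(64L, 64L)), seed = 5)
  td <- tidy(run_biometry(sac$mask, sac$params$spacing))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("DM_cm", "Dm_cm", "GW_weeks") %in% names(td)))
})
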