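test_that("ground truth follows directly from the construction", {
  circ <- generate_sac(sac_params(a = 125, b = 125, spacing = 0.01), seed = 1)
  expect_equal(circ$truth$DM_cm, 2.5, tolerance = 1e-12)
  expect_equal(circ$truth$Dm_cm, 2.5, tolerance = 1e-12)
  expect_equal(circ$truth$GW_weeks, (2.5 + 2.543) / 0.7, tolerance = 1e-12)

  ell <- generate_sac(sac_params(a = 100, b = 60, angle = 30, spacing = 0.01),
                      seed = 1)
  expect_equal(ell$truth$DM_cm, 2.0, tolerance = 1e-12)
  expect_equal(ell$truth$Dm_cm, 1.2, tolerance = 1e-12)
  expect_equal(ell$truth$GW_weeks, (1.6 + 2.543) / 0.7, tolerance = 1e-12)
})

test_that("rasterized area approaches the analytic ellipse area", {
  circ <- generate_sac(sac_params(a = 100, b = 100, spacing = 0.01), seed = 1)
  expect_equal(sum(circ$mask), pi * 100^2, tolerance = 0.02 * pi * 100^2)
})

test_that("masks are binary, deterministic under seed, and in bounds", {
  p <- sac_params(a = 40, b = 25, angle = 70, irregularity = 0.2,
                  spacing = 0.02, size = c(128L, 128L), label = "abnormal")
  m1 <- generate_sac(p, seed = 7)$mask
  m2 <- generate_sac(p, seed = 7)$mask
  m3 <- generate_sac(p, seed = 8)$mask
  expect_identical(m1, m2)
  expect_false(identical(m1, m3))
  expect_setequal(unique(as.vector(m1)), c(0L, 1L))
  expect_error(generate_sac(sac_params(a = 300, b = 200, size = c(128L, 128L))),
               "fit")
})

test_that("pseudo-ultrasound rendering has sac contrast and speckle determinism", {
  sac <- generate_sac(sac_params(a = 30, b = 20, spacing = 0.02,
                                 size = c(96L, 96L)), seed = 2)
  img <- render_us_image(sac, noise_seed = 5)
  inside <- img[sac$mask == 1]
  outside <- img[sac$mask == 0]
  expect_lt(mean(inside), mean(outside))
  expect_identical(img, render_us_image(sac, noise_seed = 5))
  expect_false(identical(img, render_us_image(sac, noise_seed = 6)))
  clean <- render_us_image(sac, noise_amp = 0)
  expect_equal(sort(unique(as.vector(clean))), c(0.12, 0.35, 0.85))
  expect_true(all(img >= 0 & img <= 1))
})

test_that("cohorts respect the requested mix and GA range", {
  ds <- generate_dataset(20, seed = 3, prop_abnormal = 0.45, prop_tvs = 0.4,
                         size = c(160L, 160L))
  expect_equal(nrow(ds$manifest), 20)
  expect_equal(sum(ds$manifest$label == "abnormal"), 9)
  expect_equal(sum(ds$manifest$modality == "TVS"), 8)
  expect_true(all(ds$manifest$GW_weeks >= 4 & ds$manifest$GW_weeks <= 10))
  expect_true(all(ds$manifest$irregularity[ds$manifest$label == "normal"] == 0))
  expect_true(all(ds$manifest$irregularity[ds$manifest$label == "abnormal"] > 0))
  # manifests are reproducible under seed
  ds2 <- generate_dataset(20, seed = 3, prop_abnormal = 0.45, prop_tvs = 0.4,
                          size = c(160L, 160L))
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$cases[[5]]$mask, ds2$cases[[5]]$mask)
  expect_error(generate_dataset(0), "at least 1")
  expect_error(generate_dataset(5, prop_abnormal = 1.5), "infeasible")
})

test_that("biometry recovers the generator truth on regular sacs", {
  ds <- generate_dataset(12, seed = 5, prop_abnormal = 0, size = c(256L, 256L))
  err <- vapply(ds$cases, function(cs) {
    b <- run_biometry(cs$mask, cs$params$spacing)
    abs(b$GW_weeks - cs$truth$GW_weeks)
  }, 0)
  expect_lt(max(err), 0.1)
  expect_lt(mean(err), 0.05)
})

test_that("perturbation only grows the enclosing extent within its amplitude", {
  for (s in 1:5) {
    p0 <- sac_params(a = 60, b = 40, angle = 20, spacing = 0.01,
                     size = c(200L, 200L))
    p1 <- sac_params(a = 60, b = 40, angle = 20, irregularity = 0.15,
                     spacing = 0.01, size = c(200L, 200L), label = "abnormal")
    reg <- generate_sac(p0, seed = s)
    irr <- generate_sac(p1, seed = s)
    b <- run_biometry(irr$mask, 0.01)
    expect_gte(b$DM_cm, reg$truth$DM_cm * (1 - 0.15) - 0.05)
    expect_lte(b$DM_cm, reg$truth$DM_cm * (1 + 0.15) + 0.05)
  }
})
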