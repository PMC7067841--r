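flat_spectrum <- function(blue_total, red_total) {
  wl <- 400:550
  y <- numeric(length(wl))
  y[wl >= 420 & wl <= 460] <- blue_total / sum(wl >= 420 & wl <= 460)
  y[wl >= 470 & wl <= 510] <- red_total / sum(wl >= 470 & wl <= 510)
  emission_spectrum(wl, y)
}

test_that("spectral GP follows the band-sum ratio", {
  expect_equal(gp_from_spectrum(flat_spectrum(200, 200)), 0)
  expect_equal(gp_from_spectrum(flat_spectrum(500, 0)), 1)
  expect_equal(gp_from_spectrum(flat_spectrum(300, 100)), 0.5)
  expect_error(gp_from_spectrum(flat_spectrum(0, 0)), "zero")
  expect_error(
    gp_from_spectrum(emission_spectrum(430:480, rep(1, 51))), "cover")
})

test_that("synthetic spectra realize their target GP exactly when noiseless", {
  for (g in c(-0.3, 0, 0.25, 0.5, 0.8)) {
    sp <- simulate_emission_spectrum(gp_target = g, noise_sd = 0)
    expect_equal(gp_from_spectrum(sp), g, tolerance = 1e-9)
  }
})

test_that("binning sums photon counts and drops odd margins", {
  m <- matrix(1:16, 4, 4)
  b <- bin2(m)
  expect_equal(dim(b), c(2L, 2L))
  expect_equal(b[1, 1], sum(m[1:2, 1:2]))
  expect_equal(dim(bin2(matrix(1, 5, 7))), c(2L, 3L))
  expect_equal(bin2(matrix(1, 5, 7))[1, 1], 4)
})

test_that("preprocessing: subtraction, dual-channel 3-SD threshold", {
  # constant image over a flat background: all pixels valid, value 4(v-b)
  img <- matrix(50, 8, 8); bg <- matrix(FALSE, 8, 8); bg[1:2, 1:2] <- TRUE
  blue <- img; blue[bg] <- 10; red <- img; red[bg] <- 10
  pre <- preprocess_pair(spectral_image_pair(blue, red), bg)
  expect_true(all(pre$blue[!bin_mask(bg)] == 4 * (50 - 10)))
  expect_true(all(pre$valid[!bin_mask(bg)]))

  # pure background image: empty valid mask
  set.seed(1)
  noise <- matrix(rpois(64 * 64, 10), 64, 64)
  noise2 <- matrix(rpois(64 * 64, 10), 64, 64)
  roi <- matrix(TRUE, 64, 64)
  pre2 <- preprocess_pair(spectral_image_pair(noise, noise2), roi)
  expect_lt(mean(pre2$valid), 0.01)

  expect_error(preprocess_pair(
    spectral_image_pair(matrix(1, 8, 8), matrix(1, 8, 8)),
    matrix(FALSE, 8, 8)), "empty")
})

test_that("threshold mask matches the generator's cell body", {
  sim <- simulate_spectral_image(seed = 1)
  pre <- preprocess_pair(sim$pair, sim$masks$background_roi)
  truth <- bin_mask(sim$masks$pm | sim$masks$interior, min_count = 1)
  expect_lt(abs(sum(pre$valid) - sum(truth)) / sum(truth), 0.02)
})

test_that("GP map arithmetic, bounds and channel-swap antisymmetry", {
  pair <- spectral_image_pair(matrix(c(30, 10, 5, 0), 2, 2),
                              matrix(c(10, 10, 15, 0), 2, 2))
  g <- gp_map(pair)
  expect_equal(g$gp[1, 1], 0.5)
  expect_equal(g$gp[2, 1], 0)
  expect_equal(g$gp[1, 2], -0.5)
  expect_equal(g$n_zero_denominator, 1L)
  swapped <- gp_map(spectral_image_pair(matrix(c(10, 10, 15, 0), 2, 2),
                                        matrix(c(30, 10, 5, 0), 2, 2)))
  expect_equal(swapped$gp[g$valid], -g$gp[g$valid])
  expect_true(all(abs(g$gp[g$valid]) <= 1))
})

test_that("GP is invariant to intensity scale and to binning when noiseless", {
  sim <- simulate_spectral_image(poisson = FALSE, background_mean = 0)
  core <- bin_mask(sim$masks$interior, min_count = 4)
  g1 <- gp_map(preprocess_pair(sim$pair))
  scaled <- spectral_image_pair(sim$pair$blue * 7.3, sim$pair$red * 7.3)
  g2 <- gp_map(preprocess_pair(scaled))
  expect_equal(g2$gp[core], g1$gp[core], tolerance = 1e-12)
  # unbinned GP on the same constant-GP region equals the binned GP
  raw <- gp_map(sim$pair)
  expect_equal(unique(round(g1$gp[core], 12)),
               unique(round(raw$gp[sim$masks$interior], 12)))
})

test_that("constant-GP image with Poisson noise recovers its GP", {
  sim <- simulate_spectral_image(pm_gp = 0.25, interior_gp = 0.25, seed = 7)
  g <- gp_map(preprocess_pair(sim$pair, sim$masks$background_roi))
  cell <- bin_mask(sim$masks$cell, min_count = 4) & g$valid
  expect_equal(mean(g$gp[cell]), 0.25, tolerance = 0.01)
})

test_that("the three internal-membrane quantification methods agree", {
  sim <- simulate_spectral_image(seed = 3)
  g <- gp_map(preprocess_pair(sim$pair, sim$masks$background_roi))
  interior_roi <- bin_mask(sim$masks$interior, min_count = 4)
  q_mask <- quantify_regions(g, "mask_histogram", roi = interior_roi)
  q_line <- suppressWarnings(quantify_regions(g, "line_scan"))
  q_peri <- quantify_regions(g, "perinuclear_roi", roi = interior_roi)

  expect_lt(abs(q_line$pm_mean_gp - 0.45), 0.03)
  expect_lt(abs(q_line$internal_mean_gp - 0.10), 0.03)
  expect_lt(abs(q_mask$internal_mean_gp - 0.10), 0.03)
  vals <- c(q_mask$internal_mean_gp, q_line$internal_mean_gp,
            q_peri$internal_mean_gp)
  expect_lt(diff(range(vals)), 0.03)
  expect_equal(sum(q_mask$histogram$counts), q_mask$n_pixels)
})

test_that("uniform maps quantify to their uniform GP under any method", {
  u <- gp_map(spectral_image_pair(matrix(130, 20, 20), matrix(70, 20, 20)))
  roi <- matrix(TRUE, 20, 20)
  for (m in c("mask_histogram", "line_scan", "perinuclear_roi")) {
    q <- suppressWarnings(quantify_regions(u, m, roi = roi))
    expect_equal(q$internal_mean_gp, 0.3, tolerance = 1e-12)
  }
})

test_that("delta GP subtracts untreated from treated", {
  sim <- simulate_spectral_image(seed = 5)
  g <- gp_map(preprocess_pair(sim$pair, sim$masks$background_roi))
  q <- quantify_regions(g, "mask_histogram",
                        roi = bin_mask(sim$masks$interior, 4))
  expect_equal(delta_gp(list(q), list(q)), 0)
  expect_equal(delta_gp(c(0.10), c(0.25)), -0.15)

  quant_at <- function(shift, seeds) lapply(seeds, function(s) {
    sm <- simulate_spectral_image(interior_gp = 0.10 + shift, seed = s)
    quantify_regions(gp_map(preprocess_pair(sm$pair, sm$masks$background_roi)),
                     "mask_histogram", roi = bin_mask(sm$masks$interior, 4))
  })
  d <- delta_gp(quant_at(-0.08, 21:23), quant_at(0, 11:13))
  expect_lt(abs(d - (-0.08)), 0.02)

  q_line <- suppressWarnings(quantify_regions(g, "line_scan"))
  expect_error(delta_gp(list(q), list(q_line)), "mixed")
})
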