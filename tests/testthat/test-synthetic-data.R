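test_that("generators are seed-deterministic", {
  a <- simulate_lipidome("DHA", n_replicates = 2, seed = 9)
  b <- simulate_lipidome("DHA", n_replicates = 2, seed = 9)
  expect_identical(lapply(a$samples, `[[`, "abundance"),
                   lapply(b$samples, `[[`, "abundance"))
  expect_false(identical(
    a$samples[[1]]$abundance,
    simulate_lipidome("DHA", n_replicates = 2, seed = 10)$samples[[1]]$abundance))

  i1 <- simulate_spectral_image(seed = 4); i2 <- simulate_spectral_image(seed = 4)
  expect_identical(i1$pair$blue, i2$pair$blue)

  t1 <- simulate_time_course("washout", seed = 2)
  t2 <- simulate_time_course("washout", seed = 2)
  expect_identical(t1$values, t2$values)

  f1 <- simulate_fda_trace(seed = 8); f2 <- simulate_fda_trace(seed = 8)
  expect_identical(f1$fluorescence, f2$fluorescence)

  s1 <- simulate_emission_spectrum(0.3, noise_sd = 0.01, seed = 6)
  s2 <- simulate_emission_spectrum(0.3, noise_sd = 0.01, seed = 6)
  expect_identical(s1$intensities, s2$intensities)
})

test_that("neutral supplementation with zero noise reproduces the baseline", {
  base <- baseline_profile()
  sim <- simulate_lipidome("untreated", n_replicates = 1, cv = 0, seed = 1,
                           total_pmol = 100)
  m <- stats::setNames(sim$samples[[1]]$abundance, sim$samples[[1]]$species)
  expect_equal(m[base$species], stats::setNames(base$molpct, base$species),
               tolerance = 1e-12)
})

test_that("supplementation targets are realized exactly without noise", {
  sim <- simulate_lipidome("DHA", n_replicates = 1, cv = 0, seed = 1)
  gpl <- normalize_lipidome(sim$samples[[1]], "GPL")
  expect_equal(as.numeric(fraction_containing(gpl, omega3_chains())), 15,
               tolerance = 1e-9)

  base <- normalize_lipidome(
    simulate_lipidome("untreated", n_replicates = 1, cv = 0,
                      seed = 1)$samples[[1]], "GPL")
  sat_t <- suppressWarnings(saturation_profile(gpl))$fully_saturated_species_pct
  sat_b <- suppressWarnings(saturation_profile(base))$fully_saturated_species_pct
  expect_equal(sat_t / sat_b, 2, tolerance = 1e-9)

  aa <- normalize_lipidome(
    simulate_lipidome("AA", n_replicates = 1, cv = 0, seed = 1)$samples[[1]],
    "GPL")
  expect_equal(as.numeric(fraction_containing(aa, omega6_chains())), 18,
               tolerance = 1e-9)

  expect_error(simulate_lipidome("DHA", target_pufa_molpct = 99),
               "infeasible")
})

test_that("noisy replicates recover configured effects within 2 SEM", {
  sim <- simulate_lipidome("DHA", n_replicates = 4, cv = 0.1, seed = 42)
  fr <- vapply(sim$samples, function(s)
    as.numeric(fraction_containing(normalize_lipidome(s, "GPL"),
                                   omega3_chains())), numeric(1))
  sem <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 15), 2 * sem + 1e-9)
})

test_that("time-course generator follows first-order kinetics", {
  tc <- simulate_time_course("incorporation", half_time_h = 4, amplitude = 10,
                             noise_sd = 0, times = c(0, 2, 4, 8, 16))
  expect_equal(tc$values[tc$times == 4], 5)
  expect_equal(tc$values[tc$times == 0], 0)
  wo <- simulate_time_course("washout", half_time_h = 4, amplitude = 10,
                             noise_sd = 0, times = c(0, 2, 4, 8, 16))
  expect_equal(wo$values[wo$times == 4], 5)
  expect_equal(wo$values[wo$times == 0], 10)
  # rise and decay mirror around half the amplitude
  expect_equal(tc$values + wo$values, rep(10, 5), tolerance = 1e-12)
})

test_that("image generator encodes GP in its channel split", {
  # uniform zero GP, no noise: channels identical
  sim0 <- simulate_spectral_image(pm_gp = 0, interior_gp = 0, poisson = FALSE)
  expect_identical(sim0$pair$blue, sim0$pair$red)

  # noiseless ring GP is exact after the full map pipeline
  sim <- simulate_spectral_image(poisson = FALSE, background_mean = 0)
  g <- gp_map(preprocess_pair(sim$pair))
  ring <- bin_mask(sim$masks$pm, min_count = 4)
  expect_equal(unique(round(g$gp[ring], 12)), 0.45)

  # Poisson noise: ring mean within 0.01 of truth
  simp <- simulate_spectral_image(seed = 3)
  gp <- gp_map(preprocess_pair(simp$pair, simp$masks$background_roi))
  expect_equal(mean(gp$gp[bin_mask(simp$masks$pm, 4) & gp$valid]), 0.45,
               tolerance = 0.01)

  expect_error(simulate_spectral_image(radii = c(80, 80)), "bounds")
})

test_that("emission-spectrum generator is accurate under noise", {
  gps <- vapply(1:100, function(s)
    gp_from_spectrum(simulate_emission_spectrum(0.3, noise_sd = 0.01,
                                                seed = s)), numeric(1))
  expect_equal(mean(gps), 0.30, tolerance = 0.01)
})

test_that("trace generator: flux matches construction and scales with P", {
  tr <- simulate_fda_trace(p_cm_per_s = 2e-6, noise_frac = 0, seed = 1)
  truth <- attr(tr, "truth")
  expect_equal(truth$Q_mol_per_s,
               2e-6 * (250000 * 3000 * 1e-8) * (2.5 / 416.4 * 1e3 * 1e-9),
               tolerance = 1e-12)
  tr2 <- simulate_fda_trace(p_cm_per_s = 4e-6, noise_frac = 0, seed = 1)
  s1 <- diff(tr$fluorescence[1:2]); s2 <- diff(tr2$fluorescence[1:2])
  expect_equal(s2 / s1, 2, tolerance = 1e-9)
})
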