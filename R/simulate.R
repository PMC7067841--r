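# Seed-deterministic synthetic-data generators. Every generator retains its
# ground truth so downstream estimators can be scored without human input.
# Noise models follow each measurement's physics: multiplicative lognormal
# for lipid abundances (compositional data), additive Gaussian for traces and
# time courses, Poisson for photon-count images.

#' Simulate supplemented lipidome samples
#'
#' Applies a supplementation transform to the baseline profile and adds
#' replicate noise. The transform acts on the within-GPL composition:
#' \itemize{
#'   \item species containing the supplemented chains (omega-3 set for
#'     `"DHA"`, omega-6 set for `"AA"`) are scaled to `target_pufa_molpct`
#'     mol% of GPLs;
#'   \item fully saturated species (0 total double bonds) are scaled by
#'     `saturated_fold`;
#'   \item di-/tri-unsaturated species (2-3 total double bonds) are scaled by
#'     `di_tri_depletion`;
#'   \item the remaining species absorb the difference, keeping the GPL pool
#'     at 100 mol%.
#' }
#' Non-GPL classes keep their share. Configured targets are therefore realized
#' exactly in the noiseless case. When the baseline lacks supplemented-chain
#' species, canonical carriers (e.g. `PC-16:0;0-22:6;0`, `PE-18:0;0-22:6;0`)
#' are injected at the required mass.
#'
#' Replicate noise is i.i.d. multiplicative lognormal per species with the
#' given coefficient of variation, after which abundances are rescaled to
#' `total_pmol`.
#'
#' @param condition `"untreated"`, `"DHA"`, or `"AA"`.
#' @param target_pufa_molpct Target mol% of supplemented-chain-containing
#'   GPLs; default 15 for DHA and 18 for AA, ignored for `"untreated"`.
#' @param saturated_fold Fold applied to fully saturated GPL species
#'   (default 2; 1 for `"untreated"`).
#' @param di_tri_depletion Factor applied to 2-3 double-bond GPL species
#'   (default 0.6; 1 for `"untreated"`).
#' @param n_replicates Number of replicate samples.
#' @param cv Lognormal replicate noise CV (0.1 = 10%).
#' @param seed Random seed; recorded in the truth record.
#' @param total_pmol Total abundance each replicate is scaled to.
#' @param baseline Baseline profile data frame (`species`, `molpct`).
#' @return List with `samples` (list of [lipidome()] objects in pmol) and
#'   `truth` (configured targets, noiseless per-species mol%, seed).
#' @export
#' @examples
#' sim <- simulate_lipidome("DHA", n_replicates = 2, cv = 0, seed = 1)
#' gpl <- normalize_lipidome(sim$samples[[1]], "GPL")
#' fraction_containing(gpl, omega3_chains())
simulate_lipidome <- function(condition = c("untreated", "DHA", "AA"),
                              target_pufa_molpct = NULL,
                              saturated_fold = NULL,
                              di_tri_depletion = NULL,
                              n_replicates = 4, cv = 0.1, seed = 1,
                              total_pmol = 20000,
                              baseline = baseline_profile()) {
  condition <- match.arg(condition)
  if (condition == "untreated") {
    target_pufa_molpct <- target_pufa_molpct %||% NA_real_
    saturated_fold <- saturated_fold %||% 1
    di_tri_depletion <- di_tri_depletion %||% 1
  } else {
    target_pufa_molpct <- target_pufa_molpct %||%
      if (condition == "DHA") 15 else 18
    saturated_fold <- saturated_fold %||% 2
    di_tri_depletion <- di_tri_depletion %||% 0.6
  }
  stopifnot(n_replicates >= 1, cv >= 0, total_pmol > 0)
  if (!is.na(target_pufa_molpct) &&
      (target_pufa_molpct < 0 || target_pufa_molpct >= 100))
    stop("target_pufa_molpct must be in [0, 100)")
  if (saturated_fold <= 0 || di_tri_depletion <= 0)
    stop("fold factors must be > 0")
  if (abs(sum(baseline$molpct) - 100) > 1e-6)
    stop("baseline mol% must sum to 100")

  set <- switch(condition, DHA = omega3_chains(), AA = omega6_chains(),
                untreated = NULL)
  parsed <- lapply(baseline$species, parse_species)
  w <- baseline$molpct
  is_gpl <- vapply(parsed, function(p) p$lipid_class %in% gpl_classes(),
                   logical(1))

  if (condition != "untreated") {
    # inject canonical carriers if the baseline lacks supplemented chains
    carriers <- if (condition == "DHA")
      c("PC-16:0;0-22:6;0", "PE-18:0;0-22:6;0")
    else c("PC-16:0;0-20:4;0", "PE-18:0;0-20:4;0")
    have <- any(vapply(parsed[is_gpl], function(p)
      isTRUE(.contains_member(p, set$members)), logical(1)))
    if (!have) {
      for (sp in setdiff(carriers, baseline$species)) {
        parsed <- c(parsed, list(parse_species(sp)))
        w <- c(w, 0)
        is_gpl <- c(is_gpl, TRUE)
      }
    }
    gw <- w[is_gpl]
    G <- sum(gw)
    p <- gw / G * 100
    gpar <- parsed[is_gpl]
    in_set <- vapply(gpar, function(x)
      isTRUE(.contains_member(x, set$members)), logical(1))
    db <- vapply(gpar, `[[`, integer(1), "total_double_bonds")
    grp <- ifelse(in_set, "set",
                  ifelse(db == 0L, "sat",
                         ifelse(db %in% c(2L, 3L), "ditri", "rest")))
    gsum <- vapply(c("set", "sat", "ditri", "rest"),
                   function(g) sum(p[grp == g]), numeric(1))
    t_set <- target_pufa_molpct
    t_sat <- saturated_fold * unname(gsum["sat"])
    t_ditri <- di_tri_depletion * unname(gsum["ditri"])
    t_rest <- 100 - t_set - t_sat - t_ditri
    if (t_rest <= 0)
      stop("infeasible supplementation transform: remainder would be <= 0")
    if (gsum["rest"] <= 0)
      stop("baseline has no remainder species to absorb the transform")
    gsum <- unname(gsum)
    names(gsum) <- c("set", "sat", "ditri", "rest")
    scale_of <- c(
      set = if (gsum[["set"]] > 0) t_set / gsum[["set"]] else 0,
      sat = if (gsum[["sat"]] > 0) t_sat / gsum[["sat"]] else 1,
      ditri = if (gsum[["ditri"]] > 0) t_ditri / gsum[["ditri"]] else 1,
      rest = t_rest / gsum[["rest"]])
    if (gsum["set"] == 0 && t_set > 0) {
      # all target mass goes into the injected carriers, split evenly
      p[grp == "set"] <- t_set / sum(grp == "set")
      p[grp != "set"] <- p[grp != "set"] * scale_of[grp[grp != "set"]]
    } else {
      p <- p * scale_of[grp]
    }
    w[is_gpl] <- p * G / 100
  }
  w <- w / sum(w) * 100

  sigma <- sqrt(log(1 + cv^2))
  set.seed(seed)
  samples <- lapply(seq_len(n_replicates), function(r) {
    noisy <- if (cv > 0)
      w * stats::rlnorm(length(w), meanlog = -sigma^2 / 2, sdlog = sigma)
    else w
    lipidome(parsed, noisy / sum(noisy) * total_pmol,
             sample_id = sprintf("%s_rep%d", condition, r),
             condition = condition, replicate = r)
  })
  names(samples) <- vapply(samples, attr, character(1), "sample_id")
  truth_names <- vapply(parsed, render_species, character(1))
  list(samples = samples,
       truth = list(condition = condition,
                    target_pufa_molpct = target_pufa_molpct,
                    saturated_fold = saturated_fold,
                    di_tri_depletion = di_tri_depletion,
                    noiseless_molpct = stats::setNames(w, truth_names),
                    cv = cv, n_replicates = n_replicates, seed = seed))
}

#' Simulate a first-order incorporation or wash-out time course
#'
#' Incorporation: `y(t) = baseline + amplitude (1 - exp(-k t))`; wash-out:
#' `y(t) = baseline + amplitude exp(-k t)`, with `k = ln 2 / half_time_h`
#' and i.i.d. Gaussian noise.
#'
#' @param kind `"incorporation"` or `"washout"`.
#' @param half_time_h Half-time in hours (defaults: 4 h incorporation,
#'   25 h wash-out, the canonical DHA remodeling time scales).
#' @param amplitude Plateau amplitude (statistic units, default 15 mol%).
#' @param baseline Value at the unperturbed end.
#' @param noise_sd Gaussian noise SD.
#' @param times Sampling times (hours).
#' @param seed Random seed.
#' @return A [time_course()] with attribute `truth`.
#' @export
simulate_time_course <- function(kind = c("incorporation", "washout"),
                                 half_time_h = NULL, amplitude = 15,
                                 baseline = 0, noise_sd = 1.5,
                                 times = NULL, seed = 1) {
  kind <- match.arg(kind)
  half_time_h <- half_time_h %||% if (kind == "incorporation") 4 else 25
  stopifnot(half_time_h > 0, noise_sd >= 0)
  times <- times %||% if (kind == "incorporation")
    c(0, 1, 2, 4, 8, 24, 48) else c(0, 2, 4, 8, 24, 48, 72, 96)
  k <- log(2) / half_time_h
  y <- if (kind == "incorporation")
    baseline + amplitude * (1 - exp(-k * times))
  else baseline + amplitude * exp(-k * times)
  set.seed(seed)
  tc <- time_course(times, y + stats::rnorm(length(times), 0, noise_sd),
                    condition = kind)
  attr(tc, "truth") <- list(kind = kind, half_time_h = half_time_h, k = k,
                            amplitude = amplitude, baseline = baseline,
                            noise_sd = noise_sd, seed = seed)
  tc
}

#' Simulate a two-channel C-Laurdan spectral image of a cell
#'
#' Builds an elliptical cell with a tightly packed plasma-membrane ring
#' (high GP), looser internal membranes (low GP) and an intensity-dark
#' nucleus, over a dim background. Per pixel with total intensity `I` and GP
#' `g`, the channels are `blue = I (1+g)/2` and `red = I (1-g)/2`, optionally
#' followed by independent Poisson noise.
#'
#' @param width,height Image size (pixels, unbinned).
#' @param center Cell center `(row, col)`; default image center.
#' @param radii Cell ellipse semi-axes `(row, col)` in pixels.
#' @param ring_width PM ring thickness in pixels (keep >= 4 so the ring
#'   survives 2x2 binning).
#' @param pm_gp,interior_gp GP of the PM ring and internal membranes.
#' @param nucleus_radii Nucleus ellipse semi-axes; the nucleus is rendered at
#'   background intensity (dark).
#' @param cell_intensity Total per-pixel intensity (counts) in the cell.
#' @param background_mean Background intensity level.
#' @param poisson Apply Poisson noise.
#' @param seed Random seed.
#' @return List: `pair` ([spectral_image_pair()]), `masks` (logical matrices
#'   `cell`, `pm`, `interior`, `nucleus`, `background_roi` at unbinned
#'   resolution), `gp_field` (noiseless per-pixel GP), `truth` (parameters).
#' @export
simulate_spectral_image <- function(width = 128, height = 128, center = NULL,
                                    radii = c(40, 32), ring_width = 6,
                                    pm_gp = 0.45, interior_gp = 0.10,
                                    nucleus_radii = c(12, 10),
                                    cell_intensity = 500,
                                    background_mean = 10,
                                    poisson = TRUE, seed = 1) {
  stopifnot(width >= 16, height >= 16, ring_width >= 2,
            abs(pm_gp) < 1, abs(interior_gp) < 1,
            cell_intensity > 0, background_mean >= 0)
  center <- center %||% c(height / 2 + 0.5, width / 2 + 0.5)
  if (center[1] - radii[1] < 1 || center[1] + radii[1] > height ||
      center[2] - radii[2] < 1 || center[2] + radii[2] > width)
    stop("cell geometry exceeds image bounds")
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  edist <- function(ra, rb) ((rr - center[1]) / ra)^2 + ((cc - center[2]) / rb)^2
  cell <- edist(radii[1], radii[2]) <= 1
  inner <- edist(radii[1] - ring_width, radii[2] - ring_width) <= 1
  pm <- cell & !inner
  nucleus <- edist(nucleus_radii[1], nucleus_radii[2]) <= 1
  interior <- inner & !nucleus

  gp_field <- matrix(0, height, width)
  gp_field[pm] <- pm_gp
  gp_field[interior] <- interior_gp
  # dye signal rides on an unpolarized ambient background (split evenly
  # between channels), so background subtraction is unbiased; the nucleus
  # carries no dye signal and stays at background level (dark)
  signal <- matrix(0, height, width)
  signal[pm | interior] <- cell_intensity

  blue <- background_mean / 2 + signal * (1 + gp_field) / 2
  red <- background_mean / 2 + signal * (1 - gp_field) / 2
  if (poisson) {
    set.seed(seed)
    blue <- matrix(stats::rpois(length(blue), blue), height, width)
    red <- matrix(stats::rpois(length(red), red), height, width)
  }
  # background ROI: top-left corner strip well clear of the cell
  bg_roi <- matrix(FALSE, height, width)
  bg_roi[1:max(4, round(height / 12)), 1:max(4, round(width / 12))] <- TRUE
  if (any(bg_roi & cell)) bg_roi <- bg_roi & !cell

  list(pair = spectral_image_pair(blue, red),
       masks = list(cell = cell, pm = pm, interior = interior,
                    nucleus = nucleus, background_roi = bg_roi),
       gp_field = gp_field,
       truth = list(pm_gp = pm_gp, interior_gp = interior_gp,
                    cell_intensity = cell_intensity,
                    background_mean = background_mean,
                    poisson = poisson, seed = seed))
}

#' Simulate a C-Laurdan emission spectrum with a prescribed GP
#'
#' Two Gaussian emission bands (centers 440 and 490 nm, SD 15 nm) sampled at
#' 1-nm steps over 400-550 nm, with band weights solved so that the
#' spectroscopy band sums (420-460 vs 470-510 nm) realize `gp_target` exactly
#' in the noiseless case.
#'
#' @param gp_target Target GP in (-1, 1) (practically within about
#'   \[-0.8, 0.95\] given the band overlap).
#' @param total_intensity Total spectrum intensity.
#' @param noise_sd Gaussian noise SD as a fraction of the peak intensity.
#' @param seed Random seed.
#' @return An [emission_spectrum()] with attribute `truth`.
#' @export
simulate_emission_spectrum <- function(gp_target = 0.3, total_intensity = 1e4,
                                       noise_sd = 0, seed = 1) {
  stopifnot(gp_target > -1, gp_target < 1, total_intensity > 0, noise_sd >= 0)
  wl <- 400:550
  g1 <- stats::dnorm(wl, 440, 15)
  g2 <- stats::dnorm(wl, 490, 15)
  bands <- gp_bands("spectroscopy")
  bsum <- function(y, b) sum(y[wl >= b[1] & wl <= b[2]])
  a1 <- bsum(g1, bands$blue); b1 <- bsum(g1, bands$red)
  a2 <- bsum(g2, bands$blue); b2 <- bsum(g2, bands$red)
  g <- gp_target
  denom <- a1 * (1 - g) - b1 * (1 + g)
  w1 <- (g * (a2 + b2) - a2 + b2) / denom
  if (!is.finite(w1) || w1 < 0)
    stop("gp_target outside the range realizable by the two emission bands")
  y <- w1 * g1 + g2
  y <- y / sum(y) * total_intensity
  if (noise_sd > 0) {
    set.seed(seed)
    y <- pmax(y + stats::rnorm(length(y), 0, noise_sd * max(y)), 0)
  }
  sp <- emission_spectrum(wl, y)
  attr(sp, "truth") <- list(gp_target = gp_target, noise_sd = noise_sd,
                            seed = seed)
  sp
}

#' Simulate an FDA uptake fluorescence trace
#'
#' Linear accumulation generated from a prescribed permeability coefficient:
#' `F(t) = baseline_au + (P A C_out / cal_factor) t + noise`, matching the
#' constant-flux regime of the uptake assay.
#'
#' @param p_cm_per_s True permeability coefficient (cm/s).
#' @param n_cells,area_per_cell_um2 Transport-area parameters.
#' @param fda_ug_per_mL Bath FDA concentration.
#' @param volume_mL Cuvette volume.
#' @param cal_factor_mol_per_au Calibration factor (mol of fluorescein per
#'   fluorescence unit).
#' @param baseline_au Fluorescence at t = 0.
#' @param noise_frac Gaussian noise SD as a fraction of the full-trace signal
#'   rise.
#' @param duration_s,dt_s Trace length and sampling interval (seconds).
#' @param seed Random seed.
#' @return A [fluorescence_trace()] with attribute `truth` (includes the
#'   ground-truth flux `Q_mol_per_s`).
#' @export
simulate_fda_trace <- function(p_cm_per_s = 2.2e-6, n_cells = 250000,
                               area_per_cell_um2 = 3000, fda_ug_per_mL = 2.5,
                               volume_mL = 2, cal_factor_mol_per_au = 1e-16,
                               baseline_au = 100, noise_frac = 0.01,
                               duration_s = 300, dt_s = 1, seed = 1) {
  stopifnot(p_cm_per_s > 0, cal_factor_mol_per_au > 0, noise_frac >= 0)
  A_cm2 <- n_cells * area_per_cell_um2 * 1e-8
  c_out_uM <- fda_ug_per_mL / molar_masses()$fda * 1e3
  c_out <- c_out_uM * 1e-9
  Q <- p_cm_per_s * A_cm2 * c_out
  slope_au <- Q / cal_factor_mol_per_au
  times <- seq(0, duration_s, by = dt_s)
  f <- baseline_au + slope_au * times
  if (noise_frac > 0) {
    set.seed(seed)
    f <- f + stats::rnorm(length(f), 0, noise_frac * slope_au * duration_s)
  }
  tr <- fluorescence_trace(times, f, n_cells = n_cells, volume_mL = volume_mL,
                           fda_ug_per_mL = fda_ug_per_mL,
                           area_per_cell_um2 = area_per_cell_um2)
  attr(tr, "truth") <- list(p_cm_per_s = p_cm_per_s, Q_mol_per_s = Q,
                            slope_au_per_s = slope_au,
                            cal_factor_mol_per_au = cal_factor_mol_per_au,
                            noise_frac = noise_frac, seed = seed)
  tr
}
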