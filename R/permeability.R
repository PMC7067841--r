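# Fick's-law permeability estimation from fluorescein diacetate (FDA) uptake.
# FDA crosses the plasma membrane and is hydrolyzed to fluorescein inside the
# cell, so the fluorescence accumulation rate reads out the FDA flux Q, and
#   Q = P * A * (C_out - C_in),  C_in = 0 for FDA.

#' Molar masses used for concentration conversion (g/mol)
#' @return Named list: `fda` (fluorescein diacetate) and `fluorescein`
#'   (sodium salt calibrant).
#' @export
molar_masses <- function() list(fda = 416.4, fluorescein = 376.3)

#' Construct a fluorescence-vs-time trace
#'
#' @param times Seconds, ascending, spanning at least 60 s, >= 10 points.
#' @param fluorescence Arbitrary fluorescence units.
#' @param n_cells Cells in the cuvette.
#' @param volume_mL Bath volume (mL).
#' @param c_out_uM Bath FDA concentration (micromolar). Supply either this or
#'   `fda_ug_per_mL`.
#' @param fda_ug_per_mL Bath FDA mass concentration; converted with the FDA
#'   molar mass.
#' @param area_per_cell_um2 Membrane area per cell (square microns).
#' @param molar_mass_fda FDA molar mass (g/mol).
#' @return A `fluorescence_trace` object.
#' @export
fluorescence_trace <- function(times, fluorescence, n_cells = 250000,
                               volume_mL = 2, c_out_uM = NULL,
                               fda_ug_per_mL = NULL,
                               area_per_cell_um2 = 3000,
                               molar_mass_fda = molar_masses()$fda) {
  times <- as.numeric(times); fluorescence <- as.numeric(fluorescence)
  if (length(times) != length(fluorescence)) stop("length mismatch")
  if (length(times) < 10L) stop("trace needs at least 10 points")
  if (any(diff(times) <= 0)) stop("times must be ascending")
  if (max(times) - min(times) < 60) stop("trace must span at least 60 s")
  if (is.null(c_out_uM)) {
    if (is.null(fda_ug_per_mL)) stop("supply c_out_uM or fda_ug_per_mL")
    # ug/mL -> g/L; / (g/mol) -> mol/L; * 1e6 -> uM
    c_out_uM <- fda_ug_per_mL / molar_mass_fda * 1e3
  }
  stopifnot(n_cells > 0, volume_mL > 0, c_out_uM > 0, area_per_cell_um2 > 0)
  structure(list(times = times, fluorescence = fluorescence,
                 n_cells = n_cells, volume_mL = volume_mL,
                 c_out_uM = c_out_uM, area_per_cell_um2 = area_per_cell_um2),
            class = "fluorescence_trace")
}

#' Calibrate fluorescence to moles of fluorescein
#'
#' Ordinary least squares of fluorescence on standard concentration (through
#' the origin by default). The calibration factor converts fluorescence units
#' to moles of fluorescein in the cuvette.
#'
#' @param concentration_uM Standard concentrations (micromolar), >= 3 values
#'   spanning at least a 10-fold range.
#' @param fluorescence_au Readings at those concentrations.
#' @param volume_mL Cuvette volume used for the standards.
#' @param through_origin Fit without intercept (default `TRUE`).
#' @return A `calibration`: `factor_mol_per_au`, `slope_au_per_uM`,
#'   `r_squared`, `standards`.
#' @export
calibrate <- function(concentration_uM, fluorescence_au, volume_mL = 2,
                      through_origin = TRUE) {
  concentration_uM <- as.numeric(concentration_uM)
  fluorescence_au <- as.numeric(fluorescence_au)
  if (length(concentration_uM) < 3L) stop("need at least 3 standards")
  if (length(unique(concentration_uM)) < 2L)
    stop("standards are rank deficient (one distinct concentration)")
  if (max(concentration_uM) / min(concentration_uM[concentration_uM > 0]) < 10)
    stop("standards must span at least a 10-fold concentration range")
  fit <- if (through_origin)
    stats::lm(fluorescence_au ~ 0 + concentration_uM)
  else
    stats::lm(fluorescence_au ~ concentration_uM)
  slope <- unname(stats::coef(fit)[["concentration_uM"]])
  if (slope <= 0) stop("non-positive calibration slope")
  r2 <- suppressWarnings(summary(fit)$r.squared)
  # AU -> uM -> mol in cuvette: uM * 1e-6 mol/L * volume_L
  factor <- (1 / slope) * 1e-6 * (volume_mL / 1000)
  structure(list(factor_mol_per_au = factor, slope_au_per_uM = slope,
                 r_squared = r2,
                 standards = data.frame(concentration_uM = concentration_uM,
                                        fluorescence_au = fluorescence_au)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration: %.3e mol/AU (R^2 %.4f)>\n",
              x$factor_mol_per_au, x$r_squared))
  invisible(x)
}

#' FDA flux from a fluorescence trace
#'
#' The slope of fluorescence vs time (ordinary least squares) times the
#' calibration factor gives the molar flux Q. Reports the full-trace
#' R-squared and the largest prefix window with R-squared >= 0.99 as
#' linearity diagnostics; optionally restricts the slope to that window.
#'
#' @param trace A [fluorescence_trace()].
#' @param cal A [calibrate()] result.
#' @param use_linear_prefix Estimate the slope on the longest linear prefix
#'   instead of the full trace.
#' @return A `flux_result`: `Q_mol_per_s`, `slope_au_per_s`, `r_squared`,
#'   `linear_prefix_fraction`.
#' @export
flux <- function(trace, cal, use_linear_prefix = FALSE) {
  stopifnot(inherits(trace, "fluorescence_trace"), inherits(cal, "calibration"))
  t <- trace$times; f <- trace$fluorescence
  r2_of <- function(fit) {
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (!is.finite(r2)) 1 else r2   # zero-variance residuals: exact line
  }
  full <- stats::lm(f ~ t)
  r2_full <- r2_of(full)
  # longest prefix with R^2 >= 0.99 (at least 10 points)
  n <- length(t)
  prefix_n <- n
  for (m in seq(n, 10L)) {
    if (r2_of(stats::lm(f[1:m] ~ t[1:m])) >= 0.99) { prefix_n <- m; break }
    prefix_n <- 10L
  }
  fit <- if (use_linear_prefix)
    stats::lm(f[1:prefix_n] ~ t[1:prefix_n]) else full
  slope <- unname(stats::coef(fit)[2])
  if (slope < 0) stop("negative slope: no net influx")
  structure(list(Q_mol_per_s = slope * cal$factor_mol_per_au,
                 slope_au_per_s = slope, r_squared = r2_full,
                 linear_prefix_fraction = prefix_n / n),
            class = "flux_result")
}

#' Permeability coefficient from Fick's law
#'
#' `P = Q / (A * (C_out - C_in))` with the transport area estimated as
#' cells x area-per-cell. `C_in = 0` holds for FDA (instant intracellular
#' conversion) but a general `C_in` is accepted for reuse.
#'
#' @param Q Flux in mol/s (or a `flux_result`).
#' @param n_cells Cells contributing membrane area.
#' @param area_per_cell_um2 Area per cell in square microns.
#' @param c_out_uM Outside concentration (micromolar). Supply either this or
#'   `c_out_ug_per_mL` with `molar_mass`.
#' @param c_out_ug_per_mL Outside mass concentration.
#' @param molar_mass Molar mass (g/mol) for the mass-concentration input;
#'   defaults to FDA.
#' @param c_in_uM Inside concentration (default 0).
#' @return A `permeability_result`: `P_cm_per_s`, `Q_mol_per_s`, `A_cm2`,
#'   `C_out_mol_per_cm3`, `C_in_mol_per_cm3`, plus slope diagnostics when a
#'   `flux_result` was given.
#' @export
#' @examples
#' # the classic worked estimate: Q = 6.6e-5 nmol/s over 250,000 cells
#' permeability_coefficient(6.6e-14, 250000, 3000, c_out_ug_per_mL = 2.5)
permeability_coefficient <- function(Q, n_cells, area_per_cell_um2,
                                     c_out_uM = NULL, c_out_ug_per_mL = NULL,
                                     molar_mass = molar_masses()$fda,
                                     c_in_uM = 0) {
  diag <- list(r_squared = NA_real_, linear_prefix_fraction = NA_real_)
  if (inherits(Q, "flux_result")) {
    diag <- Q[c("r_squared", "linear_prefix_fraction")]
    Q <- Q$Q_mol_per_s
  }
  if (Q < 0) stop("flux must be >= 0")
  if (n_cells <= 0 || area_per_cell_um2 <= 0)
    stop("cell count and area must be > 0")
  if (is.null(c_out_uM)) {
    if (is.null(c_out_ug_per_mL)) stop("supply c_out_uM or c_out_ug_per_mL")
    c_out_uM <- c_out_ug_per_mL / molar_mass * 1e3
  }
  if (c_out_uM <= 0) stop("outside concentration must be > 0")
  A_cm2 <- n_cells * area_per_cell_um2 * 1e-8       # um^2 -> cm^2
  c_out <- c_out_uM * 1e-9                          # uM -> mol/cm^3
  c_in <- c_in_uM * 1e-9
  if (c_out - c_in <= 0) stop("C_out must exceed C_in")
  structure(list(P_cm_per_s = Q / (A_cm2 * (c_out - c_in)),
                 Q_mol_per_s = Q, A_cm2 = A_cm2,
                 C_out_mol_per_cm3 = c_out, C_in_mol_per_cm3 = c_in,
                 r_squared = diag$r_squared,
                 linear_prefix_fraction = diag$linear_prefix_fraction),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("Permeability P = %.3e cm/s (Q = %.3e mol/s, A = %.3g cm2, C_out = %.3e mol/cm3)\n",
              x$P_cm_per_s, x$Q_mol_per_s, x$A_cm2, x$C_out_mol_per_cm3))
  invisible(x)
}
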