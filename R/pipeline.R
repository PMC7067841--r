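# Study-level driver: one validated config -> simulate or load inputs, run
# the analysis chain, write a tidy per-sample statistics CSV plus a JSON
# report with condition summaries and provenance.

.study_kinds <- c("lipidome", "kinetics", "imaging", "permeability")

.config_defaults <- function() {
  list(
    study = NULL, seed = 0L, out_dir = ".", log_level = "info",
    lipidome = list(condition = "DHA", n_replicates = 4, cv = 0.1,
                    target_pufa_molpct = NULL, saturated_fold = NULL,
                    di_tri_depletion = NULL),
    kinetics = list(half_time_incorporation_h = 4, half_time_washout_h = 25,
                    amplitude = 15, noise_sd = 1.5),
    imaging = list(n_images = 3, interior_gp_shift = -0.08, pm_gp = 0.45,
                   interior_gp = 0.10),
    permeability = list(p_cm_per_s = 2.2e-6, noise_frac = 0.01,
                        n_cells = 250000, area_per_cell_um2 = 3000,
                        fda_ug_per_mL = 2.5))
}

#' Validate a study configuration
#'
#' Reads a YAML config, fills in documented defaults, and rejects unknown
#' keys (named in the error) and type mismatches. `seed` defaults to 0 and is
#' recorded in every report.
#'
#' @param path Path to a YAML config file, or a named list.
#' @return A validated `run_config` list.
#' @export
validate_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("config must be a mapping")
  defs <- .config_defaults()
  unknown <- setdiff(names(cfg), names(defs))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  if (is.null(cfg$study) || !cfg$study %in% .study_kinds)
    stop(sprintf("config 'study' must be one of: %s",
                 paste(.study_kinds, collapse = ", ")))
  for (blk in .study_kinds) {
    if (!is.null(cfg[[blk]])) {
      bad <- setdiff(names(cfg[[blk]]), names(defs[[blk]]))
      if (length(bad))
        stop(sprintf("unknown config key(s) under '%s': %s", blk,
                     paste(bad, collapse = ", ")))
      defs[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
    }
  }
  out <- defs
  out$study <- cfg$study
  out$seed <- as.integer(cfg$seed %||% 0L)
  if (is.na(out$seed)) stop("config 'seed' must be an integer")
  out$out_dir <- cfg$out_dir %||% "."
  out$log_level <- cfg$log_level %||% "info"
  structure(out, class = "run_config")
}

.provenance <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  list(config_md5 = .md5_text(txt),
       package_version = as.character(utils::packageVersion("memlipid")),
       seed = config$seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

.md5_text <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Run a study end to end
#'
#' Executes the configured study on simulated inputs, writes
#' `statistics.csv` (one row per sample and statistic) and `report.json`
#' (condition summaries, fit or estimate parameters, provenance) to the
#' output directory, and returns the report. Deterministic for a fixed
#' config and seed.
#'
#' @param config A `run_config` from [validate_run_config()], a path to a
#'   YAML config, or a named list.
#' @param out_dir Output directory override.
#' @return The report list, invisibly.
#' @export
run_study <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- NULL
  summary <- switch(config$study,
    lipidome = {
      p <- config$lipidome
      arms <- list(
        untreated = simulate_lipidome("untreated",
                                      n_replicates = p$n_replicates,
                                      cv = p$cv, seed = config$seed + 1L),
        treated = simulate_lipidome(p$condition,
                                    target_pufa_molpct = p$target_pufa_molpct,
                                    saturated_fold = p$saturated_fold,
                                    di_tri_depletion = p$di_tri_depletion,
                                    n_replicates = p$n_replicates,
                                    cv = p$cv, seed = config$seed + 2L))
      set <- if (p$condition == "AA") omega6_chains() else omega3_chains()
      rows <- do.call(rbind, lapply(unlist(lapply(arms, `[[`, "samples"),
                                           recursive = FALSE),
        function(s) {
          gpl <- normalize_lipidome(s, "GPL")
          rem <- exclude_set(gpl, set)
          data.frame(
            sample_id = attr(s, "sample_id"),
            condition = attr(s, "condition"),
            statistic = c("pufa_fraction_molpct", "unsaturation_index",
                          "remaining_unsaturation_index",
                          "fully_saturated_species_pct"),
            value = c(as.numeric(fraction_containing(gpl, set)),
                      unsaturation_index(gpl)$value,
                      unsaturation_index(rem)$value,
                      suppressWarnings(
                        saturation_profile(gpl)$fully_saturated_species_pct)),
            stringsAsFactors = FALSE)
        }))
      agg <- function(stat, cond) {
        v <- rows$value[rows$statistic == stat & rows$condition == cond]
        list(mean = mean(v), sd = stats::sd(v), n = length(v))
      }
      conds <- unique(rows$condition)
      stats_by_cond <- lapply(stats::setNames(conds, conds), function(cn)
        lapply(stats::setNames(unique(rows$statistic), unique(rows$statistic)),
               agg, cond = cn))
      treated <- setdiff(conds, "untreated")
      folds <- lapply(stats::setNames(treated, treated), function(cn) {
        list(
          pufa_fraction = condition_fold_change(
            rows$value[rows$statistic == "pufa_fraction_molpct" &
                         rows$condition == cn],
            rows$value[rows$statistic == "pufa_fraction_molpct" &
                         rows$condition == "untreated"]),
          fully_saturated = condition_fold_change(
            rows$value[rows$statistic == "fully_saturated_species_pct" &
                         rows$condition == cn],
            rows$value[rows$statistic == "fully_saturated_species_pct" &
                         rows$condition == "untreated"]))
      })
      list(conditions = stats_by_cond, fold_changes = folds)
    },
    kinetics = {
      p <- config$kinetics
      fits <- list(
        incorporation = fit_first_order(simulate_time_course(
          "incorporation", half_time_h = p$half_time_incorporation_h,
          amplitude = p$amplitude, noise_sd = p$noise_sd,
          seed = config$seed + 1L)),
        washout = fit_first_order(simulate_time_course(
          "washout", half_time_h = p$half_time_washout_h,
          amplitude = p$amplitude, noise_sd = p$noise_sd,
          seed = config$seed + 2L)))
      rows <- do.call(rbind, lapply(names(fits), function(nm)
        data.frame(sample_id = nm, condition = nm,
                   statistic = c("k_per_h", "half_time_h", "y0", "y_inf"),
                   value = c(fits[[nm]]$k, fits[[nm]]$half_time,
                             fits[[nm]]$y0, fits[[nm]]$y_inf),
                   stringsAsFactors = FALSE)))
      lapply(fits, unclass)
    },
    imaging = {
      p <- config$imaging
      quant <- function(shift, seed_off) {
        lapply(seq_len(p$n_images), function(i) {
          sim <- simulate_spectral_image(
            pm_gp = p$pm_gp, interior_gp = p$interior_gp + shift,
            seed = config$seed + seed_off + i)
          m <- gp_map(preprocess_pair(sim$pair, sim$masks$background_roi))
          quantify_regions(m, "mask_histogram",
                           roi = bin_mask(sim$masks$interior, min_count = 4))
        })
      }
      untreated <- quant(0, 100L)
      treated <- quant(p$interior_gp_shift, 200L)
      rows <- do.call(rbind, lapply(seq_len(p$n_images), function(i)
        data.frame(sample_id = sprintf("img%d", i),
                   condition = rep(c("untreated", "treated"), each = 1L),
                   statistic = "internal_mean_gp",
                   value = c(untreated[[i]]$internal_mean_gp,
                             treated[[i]]$internal_mean_gp),
                   stringsAsFactors = FALSE)))
      list(delta_gp_internal = delta_gp(treated, untreated),
           untreated_internal_gp = mean(vapply(untreated, `[[`, numeric(1),
                                               "internal_mean_gp")),
           treated_internal_gp = mean(vapply(treated, `[[`, numeric(1),
                                             "internal_mean_gp")))
    },
    permeability = {
      p <- config$permeability
      tr <- simulate_fda_trace(p_cm_per_s = p$p_cm_per_s,
                               n_cells = p$n_cells,
                               area_per_cell_um2 = p$area_per_cell_um2,
                               fda_ug_per_mL = p$fda_ug_per_mL,
                               noise_frac = p$noise_frac,
                               seed = config$seed + 1L)
      truth <- attr(tr, "truth")
      # noiseless standards at the simulated calibration factor
      conc <- c(0.05, 0.1, 0.5, 1, 5)
      au <- conc * 1e-6 * (tr$volume_mL / 1000) / truth$cal_factor_mol_per_au
      cal <- calibrate(conc, au, volume_mL = tr$volume_mL)
      q <- flux(tr, cal)
      res <- permeability_coefficient(q, n_cells = tr$n_cells,
                                      area_per_cell_um2 = tr$area_per_cell_um2,
                                      c_out_uM = tr$c_out_uM)
      rows <- data.frame(sample_id = "trace1", condition = "untreated",
                         statistic = c("Q_mol_per_s", "P_cm_per_s",
                                       "r_squared"),
                         value = c(res$Q_mol_per_s, res$P_cm_per_s,
                                   res$r_squared),
                         stringsAsFactors = FALSE)
      unclass(res)
    })

  utils::write.csv(rows, file.path(out_dir, "statistics.csv"),
                   row.names = FALSE)
  report <- list(study = config$study, summary = summary,
                 provenance = .provenance(config))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
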