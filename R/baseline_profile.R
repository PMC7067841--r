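# Hand-constructed synthetic baseline lipidome (~55 species). This is a
# fixture built in code, not measured data: class proportions loosely follow
# published mammalian whole-cell membrane ranges (PC/PE dominated GPL pool,
# ~25 mol% cholesterol, minor sphingolipid and storage pools). GPL species
# are chain-resolved so chain-level statistics are defined; CL is left
# sum-only deliberately to exercise the unresolved-chain path.

#' Baseline synthetic lipidome profile
#'
#' A mammalian-whole-cell-like species table used as the default substrate of
#' [simulate_lipidome()]. Mol% sum to 100 exactly. The omega-3-containing GPL
#' fraction is < 1 mol% of GPLs and the omega-6 fraction about 5 mol%,
#' matching the untreated state the supplementation transform starts from.
#'
#' @return A data frame with columns `species` and `molpct`.
#' @export
baseline_profile <- function() {
  non_gpl <- c(
    "Chol" = 25, "SM-34:1;2" = 4, "SM-42:2;2" = 1.5,
    "Cer-34:1;2" = 0.8, "HexCer-34:1;2" = 0.4, "DiHexCer-34:1;2" = 0.2,
    "DAG-16:0;0-18:1;0" = 1.0, "TAG-52:2;0" = 3.0, "TAG-54:3;0" = 1.0,
    "SE-18:1;0" = 0.5)
  gpl <- c(
    # omega-3 containing (DHA / EPA / 24:6 chains), < 1% of GPL
    "PC-16:0;0-22:6;0" = 0.40, "PE-18:0;0-22:6;0" = 0.25,
    "PS-18:0;0-22:6;0" = 0.10, "PE-16:0;0-20:5;0" = 0.05,
    # omega-6 containing (AA and elongation products)
    "PC-16:0;0-20:4;0" = 2.0, "PE-18:0;0-20:4;0" = 1.4,
    "PI-18:0;0-20:4;0" = 1.0, "PC-18:0;0-22:4;0" = 0.3,
    "PS-18:0;0-20:4;0" = 0.3,
    # fully saturated species
    "PC-16:0;0-16:0;0" = 2.2, "PC-16:0;0-18:0;0" = 1.0,
    "PE-16:0;0-18:0;0" = 0.8, "PC O-16:0;0-16:0;0" = 0.6,
    "PS-18:0;0-18:0;0" = 0.4,
    # di- and tri-unsaturated species (2-3 total double bonds)
    "PC-16:0;0-18:2;0" = 6.0, "PC-18:1;0-18:1;0" = 5.0,
    "PE-18:1;0-18:1;0" = 3.5, "PC-18:1;0-18:2;0" = 3.0,
    "PE-16:0;0-18:2;0" = 2.5, "PE-18:0;0-18:2;0" = 2.2,
    "PI-18:1;0-18:1;0" = 1.5, "PS-18:0;0-18:2;0" = 1.5,
    "PG-18:1;0-18:1;0" = 1.0, "PC O-16:0;0-18:2;0" = 1.0,
    "PE O-18:1;0-18:1;0" = 1.0, "PA-18:1;0-18:1;0" = 0.8,
    "PC-16:1;0-18:1;0" = 1.0,
    # monounsaturated bulk, 4-db non-omega-6, lyso and cardiolipin
    "PC-16:0;0-18:1;0" = 17.0, "PC-14:0;0-18:1;0" = 1.2,
    "PE-16:0;0-18:1;0" = 8.0, "PE-18:0;0-18:1;0" = 5.0,
    "PE O-16:0;0-18:1;0" = 2.0, "PC O-16:0;0-18:1;0" = 2.5,
    "PS-18:0;0-18:1;0" = 5.0, "PI-16:0;0-18:1;0" = 3.0,
    "PI-18:0;0-18:1;0" = 2.5, "PG-16:0;0-18:1;0" = 1.2,
    "PA-16:0;0-18:1;0" = 1.0, "LPC-16:1;0" = 0.8,
    "LPC-18:1;0" = 1.0, "LPE-18:1;0" = 0.5,
    "CL-72:4;0" = 1.5, "PC-18:2;0-18:2;0" = 1.5,
    "PE-18:2;0-18:2;0" = 0.8, "PE-18:1;0-20:3;0" = 1.0)
  gpl <- gpl / sum(gpl) * (100 - sum(non_gpl))
  w <- c(non_gpl, gpl)
  data.frame(species = names(w), molpct = as.numeric(w),
             stringsAsFactors = FALSE, row.names = NULL)
}
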