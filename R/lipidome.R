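# Lipidome container: one sample's species -> abundance map with metadata.
# Internally a data.frame with a list-column of parsed species, so every
# statistic can reach class and chain structure without re-parsing.

#' Construct a lipidome sample
#'
#' @param species Character vector of species names (parsed with
#'   [parse_species()]) or a list of `lipid_species` objects.
#' @param abundance Non-negative abundances, same length (pmol for raw data).
#' @param sample_id,condition,replicate,time_h Sample metadata.
#' @param unit `"pmol"` for raw abundances or `"molpct"`.
#' @param scope Composition scope, one of `"all"`, `"membrane"`, `"GPL"`.
#' @return A `lipidome` object (data.frame subclass) with columns `species`,
#'   `class`, `total_c`, `total_db`, `total_oh`, `parsed`, `abundance`.
#' @export
#' @examples
#' lip <- lipidome(c("PC-34:1;0", "TAG-52:2;0", "Chol"), c(60, 25, 15))
#' normalize_lipidome(lip, "membrane")
lipidome <- function(species, abundance, sample_id = NA_character_,
                     condition = NA_character_, replicate = NA_integer_,
                     time_h = NA_real_, unit = "pmol", scope = "all") {
  if (is.character(species)) {
    parsed <- lapply(species, parse_species)
  } else {
    parsed <- species
    stopifnot(all(vapply(parsed, inherits, logical(1), "lipid_species")))
  }
  abundance <- as.numeric(abundance)
  if (length(parsed) != length(abundance))
    stop("species and abundance lengths differ")
  if (length(parsed) == 0L) stop("lipidome is empty")
  if (any(!is.finite(abundance)) || any(abundance < 0))
    stop("abundances must be finite and non-negative")
  if (all(abundance == 0)) stop("at least one species must be > 0")
  nm <- vapply(parsed, render_species, character(1))
  if (anyDuplicated(nm))
    stop(sprintf("duplicated species: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  x <- data.frame(species = nm,
                  class = vapply(parsed, `[[`, character(1), "lipid_class"),
                  total_c = vapply(parsed, `[[`, integer(1), "total_carbons"),
                  total_db = vapply(parsed, `[[`, integer(1), "total_double_bonds"),
                  total_oh = vapply(parsed, `[[`, integer(1), "total_hydroxyls"),
                  abundance = abundance,
                  stringsAsFactors = FALSE)
  x$parsed <- parsed
  structure(x, class = c("lipidome", "data.frame"),
            sample_id = sample_id, condition = condition,
            replicate = replicate, time_h = time_h,
            unit = unit, scope = scope)
}

.lipidome_meta <- function(x) {
  attributes(x)[c("sample_id", "condition", "replicate", "time_h",
                  "unit", "scope")]
}

.rebuild_lipidome <- function(x, keep, new_abundance, unit = NULL,
                              scope = NULL) {
  meta <- .lipidome_meta(x)
  lipidome(x$parsed[keep], new_abundance,
           sample_id = meta$sample_id, condition = meta$condition,
           replicate = meta$replicate, time_h = meta$time_h,
           unit = unit %||% meta$unit, scope = scope %||% meta$scope)
}

#' @export
print.lipidome <- function(x, ...) {
  cat(sprintf("<lipidome: %d species, unit %s, scope %s>\n",
              nrow(x), attr(x, "unit"), attr(x, "scope")))
  print.data.frame(utils::head(as.data.frame(x)[,
    c("species", "class", "total_db", "abundance")], 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more species\n", nrow(x) - 10L))
  invisible(x)
}

#' Glycerophospholipid class set
#'
#' Class names counted as glycerophospholipids (GPLs): PA, PC, PE, PG, PI, PS,
#' their lyso and ether variants, and CL.
#' @return Character vector of class names.
#' @export
gpl_classes <- function() {
  cls <- lipid_classes()
  cls$name[cls$is_glycerophospholipid]
}

#' Normalize a lipidome to mol%
#'
#' Transforms abundances into mol% of the scoped total. Scope `"membrane"`
#' drops the storage lipids (TAG, SE) before renormalizing; scope `"GPL"`
#' further restricts to glycerophospholipid classes.
#'
#' @param x A `lipidome`.
#' @param scope One of `"all"`, `"membrane"`, `"GPL"`.
#' @return A `lipidome` in mol% (sums to 100) restricted to the scope.
#' @export
normalize_lipidome <- function(x, scope = c("all", "membrane", "GPL")) {
  stopifnot(inherits(x, "lipidome"))
  scope <- match.arg(scope)
  cls <- lipid_classes()
  keep <- switch(scope,
    all = rep(TRUE, nrow(x)),
    membrane = !x$class %in% cls$name[cls$is_storage],
    GPL = x$class %in% gpl_classes())
  if (!any(keep)) stop(sprintf("no species in scope '%s'", scope))
  ab <- x$abundance[keep]
  tot <- sum(ab)
  if (tot <= 0) stop(sprintf("zero total abundance in scope '%s'", scope))
  .rebuild_lipidome(x, keep, ab / tot * 100, unit = "molpct", scope = scope)
}

#' Define a fatty-acid chain set
#'
#' @param label Set label (e.g. `"omega-3"`).
#' @param members Character vector of `"carbons:double_bonds"` signatures.
#' @return A `fatty_acid_set` object.
#' @export
fatty_acid_set <- function(label, members) {
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("fatty-acid set must be non-empty")
  if (!all(grepl("^[0-9]+:[0-9]+$", members)))
    stop("members must look like 'C:D', e.g. '22:6'")
  structure(list(label = label, members = members), class = "fatty_acid_set")
}

#' @export
print.fatty_acid_set <- function(x, ...) {
  cat(sprintf("<fatty-acid set '%s': %s>\n", x$label,
              paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Omega-3 chain set (DHA and its retroconversion products)
#'
#' DHA (22:6) together with its retroconversion derivatives EPA (20:5) and
#' 24:6; lipids carrying any of these chains count as omega-3-containing.
#' @return A `fatty_acid_set`.
#' @export
omega3_chains <- function() fatty_acid_set("omega-3", c("22:6", "20:5", "24:6"))

#' Omega-6 chain set (AA and its elongation products)
#'
#' AA (20:4) together with its conversion products 22:4 and 24:4.
#' @return A `fatty_acid_set`.
#' @export
omega6_chains <- function() fatty_acid_set("omega-6", c("20:4", "22:4", "24:4"))

# Chain containment: TRUE / FALSE / NA (undetermined: multi-chain species
# without chain resolution). A species "contains" a member chain when any
# resolved chain matches a 'C:D' signature (hydroxyls ignored); lyso species
# have their single chain implied by the totals.
.contains_member <- function(parsed, members) {
  ch <- chains_of(parsed)
  if (is.null(ch)) return(NA)
  if (length(ch) == 0L) return(FALSE)
  sigs <- vapply(ch, function(c) sprintf("%d:%d", c$carbons, c$double_bonds),
                 character(1))
  any(sigs %in% members)
}

.containment_vector <- function(x, set) {
  vapply(x$parsed, .contains_member, logical(1), members = set$members)
}

#' Mol% of species containing a chain from a set
#'
#' Sums the mol% of species that carry at least one member chain. Species
#' without chain resolution whose class has more than one chain cannot be
#' judged; they count as not containing, and their total mol% is attached as
#' attribute `unresolved_molpct` so the user can bound the error.
#'
#' @param x A mol% `lipidome` (see [normalize_lipidome()]).
#' @param set A [fatty_acid_set()].
#' @return Mol% in \[0, 100\] with attribute `unresolved_molpct`.
#' @export
fraction_containing <- function(x, set) {
  stopifnot(inherits(x, "lipidome"), inherits(set, "fatty_acid_set"))
  .check_molpct(x)
  hit <- .containment_vector(x, set)
  val <- sum(x$abundance[which(hit)])
  structure(val, unresolved_molpct = sum(x$abundance[is.na(hit)]))
}

.check_molpct <- function(x) {
  if (!identical(attr(x, "unit"), "molpct"))
    stop("expected a mol% lipidome; call normalize_lipidome() first")
  if (abs(sum(x$abundance) - 100) > 1e-9)
    stop("mol% lipidome does not sum to 100")
  invisible(TRUE)
}

#' Remove species containing chains from a set and renormalize
#'
#' Implements the "remaining lipids" analysis: species containing any member
#' chain (the supplemented fatty acid and its derivatives) are removed and the
#' remainder renormalized to 100 mol%, so compensatory remodeling is not
#' masked by the supplemented species themselves.
#'
#' @param x A mol% `lipidome`.
#' @param set A [fatty_acid_set()] to exclude.
#' @return A mol% `lipidome` with attribute `excluded_set` = `set$label`.
#' @export
exclude_set <- function(x, set) {
  stopifnot(inherits(x, "lipidome"), inherits(set, "fatty_acid_set"))
  .check_molpct(x)
  hit <- .containment_vector(x, set)
  keep <- !hit | is.na(hit)   # undetermined species are retained
  if (!any(keep)) stop("exclusion removed every species")
  ab <- x$abundance[keep]
  out <- .rebuild_lipidome(x, keep, ab / sum(ab) * 100)
  attr(out, "excluded_set") <- set$label
  out
}

#' Concentration-weighted unsaturation index
#'
#' Mean number of double bonds per lipid, weighted by mol%. Cholesterol (no
#' acyl composition) is excluded automatically with a message.
#'
#' @param x A mol% `lipidome`.
#' @return An `unsaturation_index` object: `value` (double bonds per lipid),
#'   `scope`, `n_species`, `excluded_set` label or `NA`.
#' @export
unsaturation_index <- function(x) {
  stopifnot(inherits(x, "lipidome"))
  .check_molpct(x)
  has_db <- !is.na(x$total_db)
  if (any(!has_db))
    message(sprintf("%d species without acyl composition (e.g. Chol) excluded",
                    sum(!has_db)))
  w <- x$abundance[has_db]
  if (sum(w) <= 0) stop("all included species have zero weight")
  db <- x$total_db[has_db]
  structure(list(value = sum(w * db) / sum(w),
                 scope = attr(x, "scope"),
                 n_species = sum(has_db),
                 excluded_set = attr(x, "excluded_set") %||% NA_character_),
            class = "unsaturation_index")
}

#' @export
print.unsaturation_index <- function(x, ...) {
  cat(sprintf("Unsaturation index: %.4f double bonds/lipid (%d species, scope %s%s)\n",
              x$value, x$n_species, x$scope,
              if (is.na(x$excluded_set)) ""
              else paste0(", excluding ", x$excluded_set)))
  invisible(x)
}

#' Saturation profile of a lipidome
#'
#' Species-level mol% distribution by total double-bond count (0..6, 7+), the
#' mol% of fully saturated species, and chain-level statistics over
#' chain-resolved species: the abundance-weighted percentage of saturated
#' (0 double bond) acyl chains and of very highly unsaturated (5 or 6 double
#' bond) chains. The mol% of abundance lacking chain resolution is reported so
#' chain-level numbers can be qualified.
#'
#' @param x A mol% `lipidome` (GPL scope recommended; a warning is issued
#'   otherwise since chain statistics are conventionally quoted for GPLs).
#' @return A `saturation_profile` list.
#' @export
saturation_profile <- function(x) {
  stopifnot(inherits(x, "lipidome"))
  .check_molpct(x)
  if (!identical(attr(x, "scope"), "GPL"))
    warning("saturation profile is conventionally computed on GPL scope")
  has_db <- !is.na(x$total_db)
  w <- x$abundance[has_db]
  db <- x$total_db[has_db]
  bins <- c(as.character(0:6), "7+")
  key <- ifelse(db >= 7, "7+", as.character(db))
  dist <- vapply(bins, function(b) sum(w[key == b]), numeric(1))
  dist <- dist / sum(w) * 100

  chains <- lapply(x$parsed, chains_of)
  resolved <- !vapply(chains, is.null, logical(1))
  n_chain <- vapply(chains, function(ch) length(ch %||% list()), integer(1))
  resolved <- resolved & n_chain > 0L
  unresolved_pct <- sum(x$abundance[!resolved])
  if (!any(resolved))
    stop("no chain-resolved species: chain-level statistics unavailable")
  wt_chains <- x$abundance[resolved] * n_chain[resolved]
  frac_sat <- vapply(chains[resolved], function(ch)
    mean(vapply(ch, function(c) c$double_bonds == 0L, logical(1))), numeric(1))
  frac_high <- vapply(chains[resolved], function(ch)
    mean(vapply(ch, function(c) c$double_bonds %in% c(5L, 6L), logical(1))),
    numeric(1))
  structure(list(
    distribution = dist,
    fully_saturated_species_pct = unname(dist["0"]),
    saturated_chain_pct = sum(wt_chains * frac_sat) / sum(wt_chains) * 100,
    high_unsat_chain_pct = sum(wt_chains * frac_high) / sum(wt_chains) * 100,
    unresolved_molpct = unresolved_pct,
    scope = attr(x, "scope")),
    class = "saturation_profile")
}

#' @export
print.saturation_profile <- function(x, ...) {
  cat("Saturation profile (mol% by total double bonds):\n")
  print(round(x$distribution, 3))
  cat(sprintf("fully saturated species: %.3f mol%%\n",
              x$fully_saturated_species_pct))
  cat(sprintf("saturated chains: %.3f%%; 5-6 db chains: %.3f%% (unresolved %.2f mol%%)\n",
              x$saturated_chain_pct, x$high_unsat_chain_pct,
              x$unresolved_molpct))
  invisible(x)
}

#' Class composition of a lipidome
#'
#' @param x A mol% `lipidome`.
#' @return Named numeric vector of class mol% (sums to 100). The `Chol` entry
#'   is the cholesterol statistic used for sterol-level comparisons.
#' @export
class_composition <- function(x) {
  stopifnot(inherits(x, "lipidome"))
  .check_molpct(x)
  out <- tapply(x$abundance, x$class, sum)
  out <- out[order(-out)]
  structure(as.numeric(out), names = names(out))
}

#' Fold change between two groups of statistic values
#'
#' Ratio of group means with a delta-method standard deviation.
#'
#' @param group_a,group_b Numeric vectors of per-replicate statistic values;
#'   the fold is `mean(group_a) / mean(group_b)`.
#' @return List with `fold`, `sd` (propagated, `NA` for singleton groups),
#'   `n_a`, `n_b`.
#' @export
condition_fold_change <- function(group_a, group_b) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  ma <- mean(group_a); mb <- mean(group_b)
  if (mb <= 0) stop("denominator group mean must be > 0")
  fold <- ma / mb
  va <- if (length(group_a) > 1L) stats::var(group_a) / length(group_a) else NA_real_
  vb <- if (length(group_b) > 1L) stats::var(group_b) / length(group_b) else NA_real_
  sd <- if (is.na(va) || is.na(vb)) NA_real_ else
    sqrt(va / mb^2 + ma^2 * vb / mb^4)
  list(fold = fold, sd = sd, n_a = length(group_a), n_b = length(group_b))
}

#' Read a species-by-sample abundance table
#'
#' Expects a CSV/TSV with a first column `species` and one column per sample
#' (abundances in pmol). An optional metadata table (CSV with columns
#' `sample_id`, `condition`, `replicate`, `time_h`; or a YAML list keyed by
#' sample id) attaches conditions to samples.
#'
#' @param path Abundance table path (delimiter inferred from extension).
#' @param metadata Optional path to metadata CSV/YAML.
#' @return Named list of `lipidome` objects, one per sample column.
#' @export
read_lipidome_table <- function(path, metadata = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"species" %in% names(tab))
    stop("abundance table needs a 'species' column")
  meta <- NULL
  if (!is.null(metadata)) {
    meta <- if (grepl("\\.ya?ml$", metadata, ignore.case = TRUE)) {
      m <- yaml::read_yaml(metadata)
      do.call(rbind, lapply(names(m), function(id)
        data.frame(sample_id = id,
                   condition = m[[id]]$condition %||% NA_character_,
                   replicate = m[[id]]$replicate %||% NA_integer_,
                   time_h = m[[id]]$time_h %||% NA_real_,
                   stringsAsFactors = FALSE)))
    } else {
      utils::read.csv(metadata, stringsAsFactors = FALSE)
    }
  }
  samples <- setdiff(names(tab), "species")
  parsed <- lapply(tab$species, parse_species)
  out <- lapply(samples, function(s) {
    mrow <- if (!is.null(meta)) meta[match(s, meta$sample_id), ] else NULL
    lipidome(parsed, tab[[s]], sample_id = s,
             condition = if (!is.null(mrow)) mrow$condition else NA_character_,
             replicate = if (!is.null(mrow)) mrow$replicate else NA_integer_,
             time_h = if (!is.null(mrow)) mrow$time_h else NA_real_)
  })
  names(out) <- samples
  out
}
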