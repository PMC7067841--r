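make_molpct <- function(species, ab, scope = "all") {
  normalize_lipidome(lipidome(species, ab), scope)
}

test_that("mol% normalization honors scope exclusions", {
  m <- make_molpct(c("PC-34:1;0", "PE-36:2;0"), c(30, 70))
  expect_equal(m$abundance, c(30, 70))

  m2 <- make_molpct(c("PC-34:1;0", "TAG-52:2;0"), c(50, 50), "membrane")
  expect_equal(m2$species, "PC-34:1;0")
  expect_equal(m2$abundance, 100)

  # five-species toy table, storage lipids removed then renormalized
  m3 <- make_molpct(c("PC-34:1;0", "PE-36:2;0", "TAG-58:2;0", "Chol",
                      "SM-34:1;1"), c(40, 20, 20, 15, 5), "membrane")
  expect_equal(stats::setNames(m3$abundance, m3$species),
               c("PC-34:1;0" = 50, "PE-36:2;0" = 25, "Chol" = 18.75,
                 "SM-34:1;1" = 6.25))

  g <- make_molpct(c("PC-34:1;0", "Chol", "SM-34:1;1"), c(50, 30, 20), "GPL")
  expect_equal(g$species, "PC-34:1;0")
  expect_error(make_molpct(c("Chol", "SM-34:1;1"), c(50, 50), "GPL"),
               "no species in scope")
})

test_that("unsaturation index is the mol%-weighted mean double-bond count", {
  expect_equal(unsaturation_index(make_molpct("PC-36:2;0", 10))$value, 2)
  expect_equal(unsaturation_index(
    make_molpct(c("PC-32:0;0", "PC-36:6;0"), c(50, 50)))$value, 3)
  expect_equal(unsaturation_index(
    make_molpct(c("PC-34:1;0", "PC-36:4;0", "PC-32:0;0"),
                c(50, 25, 25)))$value, 1.5)
  # cholesterol is excluded from the weighting, with a note
  expect_message(
    ui <- unsaturation_index(make_molpct(c("PC-34:1;0", "Chol"), c(50, 50))),
    "excluded")
  expect_equal(ui$value, 1)
})

test_that("exclusion-set analysis removes carriers and renormalizes", {
  m <- make_molpct(c("PC-16:0;0-22:6;0", "PC-34:1;0"), c(15, 85))
  r <- exclude_set(m, omega3_chains())
  expect_equal(stats::setNames(r$abundance, r$species), c("PC-34:1;0" = 100))
  expect_equal(attr(r, "excluded_set"), "omega-3")

  # empty overlap is the identity
  m2 <- make_molpct(c("PC-16:0;0-18:1;0", "PE-16:0;0-18:2;0"), c(40, 60))
  r2 <- exclude_set(m2, omega3_chains())
  expect_equal(r2$abundance, m2$abundance)

  # six-species table with two 22:6 carriers at 10 mol% each -> 1/0.8 rescale
  sp <- c("PC-16:0;0-22:6;0", "PE-18:0;0-22:6;0", "PC-16:0;0-18:1;0",
          "PE-16:0;0-18:1;0", "PS-18:0;0-18:1;0", "PI-18:0;0-20:4;0")
  m3 <- make_molpct(sp, c(10, 10, 40, 20, 10, 10))
  r3 <- exclude_set(m3, omega3_chains())
  expect_equal(r3$abundance, c(40, 20, 10, 10) / 0.8)
  expect_equal(sum(r3$abundance), 100, tolerance = 1e-12)

  expect_equal(as.numeric(fraction_containing(r3, omega3_chains())), 0)
  mall <- make_molpct(c("PC-16:0;0-22:6;0", "PC-16:0;0-18:1;0"), c(30, 70))
  expect_error(exclude_set(mall, fatty_acid_set("x", c("22:6", "18:1"))),
               "every species")
})

test_that("fraction_containing sums carrier mol% and flags unresolved mass", {
  m <- make_molpct(c("PC-16:0;0-18:1;0", "PE-16:0;0-18:2;0"), c(40, 60))
  expect_equal(as.numeric(fraction_containing(m, omega3_chains())), 0)
  m2 <- make_molpct(c("PC-16:0;0-22:6;0", "PE-18:0;0-20:5;0"), c(30, 70))
  expect_equal(as.numeric(fraction_containing(m2, omega3_chains())), 100)
  m3 <- make_molpct(c("PC-16:0;0-22:6;0", "PE-18:0;0-22:6;0",
                      "PC-16:0;0-18:1;0"), c(12, 3, 85))
  expect_equal(as.numeric(fraction_containing(m3, omega3_chains())), 15)
  # sum-only multi-chain species are undetermined, reported not guessed
  m4 <- make_molpct(c("PC-38:6;0", "PC-16:0;0-18:1;0"), c(30, 70))
  f4 <- fraction_containing(m4, omega3_chains())
  expect_equal(as.numeric(f4), 0)
  expect_equal(attr(f4, "unresolved_molpct"), 30)
  # lyso species contain the chain their totals imply
  m5 <- make_molpct(c("LPC-22:6;0", "PC-16:0;0-18:1;0"), c(25, 75))
  expect_equal(as.numeric(fraction_containing(m5, omega3_chains())), 25)
})

test_that("saturation profile: species distribution and chain percentages", {
  p1 <- saturation_profile(make_molpct("PC-16:0;0-16:0;0", 5, "GPL"))
  expect_equal(p1$fully_saturated_species_pct, 100)
  expect_equal(p1$saturated_chain_pct, 100)
  # chain-level statistics need at least one chain-resolved species
  expect_error(saturation_profile(make_molpct("PC-32:0;0", 5, "GPL")),
               "chain-resolved")

  p2 <- saturation_profile(make_molpct(
    c("PC-16:0;0-22:6;0", "PC-16:0;0-16:0;0"), c(50, 50), "GPL"))
  expect_equal(p2$saturated_chain_pct, 75)
  expect_equal(p2$high_unsat_chain_pct, 25)
  expect_equal(p2$fully_saturated_species_pct, 50)

  p3 <- saturation_profile(make_molpct(
    c("PC-16:0;0-16:0;0", "PC-16:0;0-18:2;0", "PC-18:1;0-18:2;0"),
    c(1, 1, 1), "GPL"))
  expect_equal(unname(p3$distribution[c("0", "2", "3")]),
               rep(100 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(p3$distribution), 100, tolerance = 1e-9)

  # unresolved abundance (sum-only CL) is reported against chain stats
  p4 <- saturation_profile(make_molpct(
    c("PC-16:0;0-16:0;0", "CL-72:4;0"), c(80, 20), "GPL"))
  expect_equal(p4$unresolved_molpct, 20)
  expect_warning(saturation_profile(make_molpct("PC-16:0;0-16:0;0", 5)), "GPL")
})

test_that("class composition aggregates species to 100 mol%", {
  cc <- class_composition(make_molpct(
    c("PC-34:1;0", "PC-36:2;0", "PC-32:0;0", "PE-34:1;0", "Chol"),
    c(10, 20, 10, 25, 35)))
  expect_equal(cc[["PC"]], 40)
  expect_equal(cc[["Chol"]], 35)
  expect_equal(sum(cc), 100, tolerance = 1e-9)
})

test_that("fold change is the ratio of group means with delta-method SD", {
  expect_equal(condition_fold_change(15, 1)$fold, 15)
  expect_equal(condition_fold_change(c(2, 3, 4), c(2, 3, 4))$fold, 1)
  fc <- condition_fold_change(c(14, 16, 18), c(0.9, 1.0, 1.1))
  expect_equal(fc$fold, 16)
  expect_true(fc$sd > 0)
  expect_error(condition_fold_change(c(1, 2), c(0, 0)), "denominator")
})

test_that("statistics agree with brute-force oracles on random tables", {
  for (seed in 1:5) {
    tab <- random_species_table(20, seed = seed)
    m <- make_molpct(tab$species, tab$abundance)
    w <- m$abundance
    expect_equal(unsaturation_index(m)$value,
                 oracle_unsaturation_index(m$species, w),
                 tolerance = 1e-10)
    for (set in list(omega3_chains(), omega6_chains()))
      expect_equal(as.numeric(fraction_containing(m, set)),
                   oracle_fraction_containing(m$species, w, set$members),
                   tolerance = 1e-10)
    cc <- class_composition(m)
    occ <- oracle_class_composition(m$species, w)
    expect_equal(cc[sort(names(cc))], occ[sort(names(occ))],
                 tolerance = 1e-10)
  }
})

test_that("mol% statistics are invariant to uniform abundance rescaling", {
  tab <- random_species_table(20, seed = 11)
  m1 <- make_molpct(tab$species, tab$abundance)
  m2 <- make_molpct(tab$species, tab$abundance * 1234.5)
  expect_equal(m1$abundance, m2$abundance, tolerance = 1e-12)
  expect_equal(unsaturation_index(m1)$value, unsaturation_index(m2)$value,
               tolerance = 1e-12)
})

test_that("adding saturated abundance never raises the unsaturation index", {
  tab <- random_species_table(15, seed = 3)
  species <- c(tab$species, "PC-32:0;0")
  prev <- Inf
  for (extra in c(0, 5, 20, 100, 500)) {
    ui <- unsaturation_index(make_molpct(species,
                                         c(tab$abundance, extra)))$value
    expect_lte(ui, prev + 1e-12)
    prev <- ui
  }
})

test_that("species tables round-trip through CSV with metadata sidecar", {
  dir <- withr::local_tempdir()
  tab <- data.frame(species = c("PC-34:1;0", "PE-36:2;0", "Chol"),
                    s1 = c(40, 40, 20), s2 = c(10, 60, 30))
  utils::write.csv(tab, file.path(dir, "abund.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample_id = c("s1", "s2"),
                              condition = c("untreated", "DHA"),
                              replicate = c(1L, 1L), time_h = c(0, 24)),
                   file.path(dir, "meta.csv"), row.names = FALSE)
  lips <- read_lipidome_table(file.path(dir, "abund.csv"),
                              file.path(dir, "meta.csv"))
  expect_named(lips, c("s1", "s2"))
  expect_equal(attr(lips$s2, "condition"), "DHA")
  expect_equal(attr(lips$s2, "time_h"), 24)
  expect_equal(normalize_lipidome(lips$s1)$abundance, c(40, 40, 20))
})
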