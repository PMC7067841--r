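# Independent brute-force oracles for composition statistics. These parse
# species names with their own minimal regex logic and loop explicitly, so
# they share no code path with the package implementation.

oracle_parse_chains <- function(name) {
  # returns list(db_total, chains = list of c(C, D)) or NULL chains
  if (name == "Chol") return(list(db = NA_integer_, chains = list()))
  body <- sub("^[A-Za-z]+ ?O?-", "", name)
  toks <- strsplit(body, "-", fixed = TRUE)[[1]]
  parts <- lapply(toks, function(tk) {
    cd <- strsplit(sub(";.*$", "", tk), ":", fixed = TRUE)[[1]]
    as.integer(cd)
  })
  db <- sum(vapply(parts, `[`, integer(1), 2))
  lyso <- grepl("^(LPA|LPC|LPE|LPI|LPS|SE)", name)
  chains <- if (length(parts) > 1L || lyso) parts else NULL
  list(db = db, chains = chains)
}

oracle_unsaturation_index <- function(names, molpct) {
  num <- 0; den <- 0
  for (i in seq_along(names)) {
    info <- oracle_parse_chains(names[i])
    if (is.na(info$db)) next
    num <- num + molpct[i] * info$db
    den <- den + molpct[i]
  }
  num / den
}

oracle_fraction_containing <- function(names, molpct, members) {
  tot <- 0
  for (i in seq_along(names)) {
    info <- oracle_parse_chains(names[i])
    if (is.null(info$chains)) next
    sigs <- vapply(info$chains, function(cd) paste0(cd[1], ":", cd[2]),
                   character(1))
    if (any(sigs %in% members)) tot <- tot + molpct[i]
  }
  tot
}

oracle_class_composition <- function(names, molpct) {
  cls <- vapply(names, function(n) {
    if (n == "Chol" || grepl("^Chol", n)) return("Chol")
    m <- regmatches(n, regexec("^([A-Za-z]+( O-)?)", n))[[1]][2]
    trimws(sub("-$", "", m))
  }, character(1))
  out <- c()
  for (k in unique(cls)) out[k] <- sum(molpct[cls == k])
  out
}

# random valid GPL-heavy species table for property tests
random_species_table <- function(n = 20, seed = 1) {
  set.seed(seed)
  classes <- c("PC", "PE", "PS", "PI", "PG", "PA")
  fas <- c("14:0", "16:0", "16:1", "18:0", "18:1", "18:2", "18:3",
           "20:4", "20:5", "22:6")
  nm <- character(0)
  while (length(nm) < n) {
    cl <- sample(classes, 1)
    ch <- sample(fas, 2, replace = TRUE)
    cand <- sprintf("%s-%s;0-%s;0", cl, ch[1], ch[2])
    if (!cand %in% nm) nm <- c(nm, cand)
  }
  list(species = nm, abundance = stats::runif(n, 1, 100))
}
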