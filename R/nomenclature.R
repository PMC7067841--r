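# Lipid species nomenclature: "[class]-[carbons]:[double bonds];[hydroxyls]",
# optionally chain-resolved ("PC-16:0;0-18:1;0"). Shotgun-lipidomics vendors
# emit both hyphen- and space-separated dialects; both are accepted on input,
# the hyphen form is canonical on output.

#' Lipid class registry
#'
#' The controlled vocabulary of lipid classes with their category flags and
#' expected acyl-chain counts. The vocabulary is closed by default but can be
#' extended via [register_lipid_class()].
#'
#' @return A data frame with one row per class: `name`, `is_storage`,
#'   `is_glycerophospholipid`, `is_lyso`, `is_ether`, `expected_chain_count`.
#' @export
#' @examples
#' lipid_classes()
lipid_classes <- function() {
  get("classes", envir = .memlipid_registry)
}

# class table; GPL flag covers glycerol-backbone phospholipids incl. lyso,
# ether and cardiolipin variants.
.default_lipid_classes <- function() {
  def <- function(name, storage = FALSE, gpl = FALSE, lyso = FALSE,
                  ether = FALSE, chains = 2L) {
    data.frame(name = name, is_storage = storage,
               is_glycerophospholipid = gpl, is_lyso = lyso,
               is_ether = ether, expected_chain_count = chains,
               stringsAsFactors = FALSE)
  }
  rbind(
    def("CL",      gpl = TRUE, chains = 4L),
    def("Cer"),
    def("DAG"),
    def("DiHexCer"),
    def("HexCer"),
    def("SE",      storage = TRUE, chains = 1L),
    def("TAG",     storage = TRUE, chains = 3L),
    def("PA",      gpl = TRUE),
    def("PC",      gpl = TRUE),
    def("PE",      gpl = TRUE),
    def("PG",      gpl = TRUE),
    def("PI",      gpl = TRUE),
    def("PS",      gpl = TRUE),
    def("LPA",     gpl = TRUE, lyso = TRUE, chains = 1L),
    def("LPC",     gpl = TRUE, lyso = TRUE, chains = 1L),
    def("LPE",     gpl = TRUE, lyso = TRUE, chains = 1L),
    def("LPI",     gpl = TRUE, lyso = TRUE, chains = 1L),
    def("LPS",     gpl = TRUE, lyso = TRUE, chains = 1L),
    def("PC O-",   gpl = TRUE, ether = TRUE),
    def("PE O-",   gpl = TRUE, ether = TRUE),
    def("LPC O-",  gpl = TRUE, lyso = TRUE, ether = TRUE, chains = 1L),
    def("LPE O-",  gpl = TRUE, lyso = TRUE, ether = TRUE, chains = 1L),
    def("SM"),
    def("Chol",    chains = 0L)
  )
}

.memlipid_registry <- new.env(parent = emptyenv())
assign("classes", .default_lipid_classes(), envir = .memlipid_registry)

#' Extend the lipid class vocabulary
#'
#' @param name Class token as it appears in species names.
#' @param is_storage,is_glycerophospholipid,is_lyso,is_ether Category flags.
#' @param expected_chain_count Number of acyl chains carried by the class.
#' @return Invisibly, the updated class table.
#' @export
register_lipid_class <- function(name, is_storage = FALSE,
                                 is_glycerophospholipid = FALSE,
                                 is_lyso = FALSE, is_ether = FALSE,
                                 expected_chain_count = 2L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  cls <- get("classes", envir = .memlipid_registry)
  cls <- cls[cls$name != name, , drop = FALSE]
  cls <- rbind(cls, data.frame(
    name = name, is_storage = is_storage,
    is_glycerophospholipid = is_glycerophospholipid,
    is_lyso = is_lyso, is_ether = is_ether,
    expected_chain_count = as.integer(expected_chain_count),
    stringsAsFactors = FALSE))
  assign("classes", cls, envir = .memlipid_registry)
  invisible(cls)
}

#' Reset the lipid class vocabulary to the built-in default
#' @return Invisibly, the default class table.
#' @export
reset_lipid_classes <- function() {
  assign("classes", .default_lipid_classes(), envir = .memlipid_registry)
  invisible(lipid_classes())
}

.class_info <- function(name) {
  cls <- lipid_classes()
  i <- match(name, cls$name)
  if (is.na(i)) NULL else cls[i, , drop = FALSE]
}

#' Construct an acyl chain
#'
#' @param carbons Carbon count (>= 1).
#' @param double_bonds Number of C=C double bonds (>= 0, <= carbons).
#' @param hydroxyls Number of hydroxyl groups (>= 0).
#' @return An `acyl_chain` object (named list).
#' @export
acyl_chain <- function(carbons, double_bonds, hydroxyls = 0L) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  hydroxyls <- as.integer(hydroxyls)
  if (is.na(carbons) || carbons < 1L)
    stop("acyl chain carbons must be a positive integer")
  if (is.na(double_bonds) || double_bonds < 0L || double_bonds > carbons)
    stop("double_bonds must be in [0, carbons]")
  if (is.na(hydroxyls) || hydroxyls < 0L)
    stop("hydroxyls must be >= 0")
  structure(list(carbons = carbons, double_bonds = double_bonds,
                 hydroxyls = hydroxyls),
            class = "acyl_chain")
}

#' @export
format.acyl_chain <- function(x, ...) {
  sprintf("%d:%d;%d", x$carbons, x$double_bonds, x$hydroxyls)
}

#' @export
print.acyl_chain <- function(x, ...) {
  cat("<acyl chain ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Construct a lipid species
#'
#' Chain-resolved species must have chain sums matching the totals and the
#' chain count expected for the class; these invariants are asserted here.
#'
#' @param lipid_class Class token from [lipid_classes()].
#' @param total_carbons,total_double_bonds,total_hydroxyls Sum composition
#'   across all chains (all `NA` for "Chol").
#' @param chains Optional list of [acyl_chain()] objects.
#' @param raw_name Optional original string the species was parsed from.
#' @return A `lipid_species` object.
#' @export
lipid_species <- function(lipid_class, total_carbons = NA_integer_,
                          total_double_bonds = NA_integer_,
                          total_hydroxyls = NA_integer_,
                          chains = NULL, raw_name = NULL) {
  info <- .class_info(lipid_class)
  if (is.null(info))
    stop(sprintf("unknown lipid class '%s'", lipid_class))
  if (info$expected_chain_count == 0L) {
    if (!is.na(total_carbons) || !is.na(total_double_bonds))
      stop(sprintf("class '%s' carries no composition numbers", lipid_class))
    chains <- list()
  } else {
    total_carbons <- as.integer(total_carbons)
    total_double_bonds <- as.integer(total_double_bonds)
    total_hydroxyls <- as.integer(total_hydroxyls)
    if (is.na(total_carbons) || is.na(total_double_bonds))
      stop("sum composition (carbons, double bonds) is required")
    if (is.na(total_hydroxyls)) total_hydroxyls <- 0L
    if (total_carbons < 1L || total_double_bonds < 0L || total_hydroxyls < 0L)
      stop("invalid sum composition")
    if (!is.null(chains)) {
      if (length(chains) != info$expected_chain_count)
        stop(sprintf("class '%s' expects %d chains, got %d",
                     lipid_class, info$expected_chain_count, length(chains)))
      sc <- sum(vapply(chains, `[[`, integer(1), "carbons"))
      sd <- sum(vapply(chains, `[[`, integer(1), "double_bonds"))
      sh <- sum(vapply(chains, `[[`, integer(1), "hydroxyls"))
      if (sc != total_carbons || sd != total_double_bonds ||
          sh != total_hydroxyls)
        stop("chain sums do not match the stated totals")
    }
  }
  structure(list(lipid_class = lipid_class,
                 total_carbons = total_carbons,
                 total_double_bonds = total_double_bonds,
                 total_hydroxyls = total_hydroxyls,
                 chains = chains,
                 raw_name = raw_name %||% NA_character_),
            class = "lipid_species")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_chain_token <- function(token, name) {
  m <- regmatches(token, regexec("^([0-9]+):([0-9]+)(?:;([0-9]+))?$", token))[[1]]
  if (length(m) == 0L)
    stop(sprintf("malformed composition '%s' in '%s' (expected C:D or C:D;H)",
                 token, name))
  acyl_chain(as.integer(m[2]), as.integer(m[3]),
             if (is.na(m[4]) || m[4] == "") 0L else as.integer(m[4]))
}

#' Parse a lipid species name
#'
#' Accepts the sum-composition form (`"SM-32:2;1"`), the chain-resolved form
#' (`"PC-18:1;0-24:2;0"`), and `"Chol"`. The separator between class and
#' composition may be a hyphen or a space; the hydroxyl field defaults to 0
#' when omitted. Ether classes keep the `"O-"` marker as part of the class
#' token. Isotope-labelled cholesterol standards (e.g. `"Chol-D6"`) are
#' stripped to `"Chol"` with a warning.
#'
#' @param name Species name.
#' @return A `lipid_species` object.
#' @export
#' @examples
#' parse_species("SM-32:2;1")
#' parse_species("PC-18:1;0-24:2;0")
parse_species <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  name <- trimws(name)
  if (!nzchar(name)) stop("species name is empty")

  if (name == "Chol") return(lipid_species("Chol", raw_name = name))
  if (grepl("^Chol[- ]?D[0-9]+$", name)) {
    warning(sprintf("isotope label stripped from '%s'; treated as Chol", name))
    return(lipid_species("Chol", raw_name = name))
  }

  cls <- lipid_classes()
  # longest tokens first so "PC O-" wins over "PC", "LPC O-" over "LPC"
  tokens <- cls$name[order(-nchar(cls$name))]
  matched <- NULL
  rest <- NULL
  for (tok in tokens) {
    if (grepl("O-$", tok)) {
      # ether marker doubles as the separator: "PC O-34:1;0"
      alt <- c(tok, sub(" O-$", "-O-", tok), sub(" O-$", " O ", tok))
      for (a in alt) {
        if (startsWith(name, a) && nchar(name) > nchar(a)) {
          matched <- tok
          rest <- substring(name, nchar(a) + 1L)
          break
        }
      }
    } else {
      for (sep in c("-", " ")) {
        pre <- paste0(tok, sep)
        if (startsWith(name, pre) && nchar(name) > nchar(pre)) {
          matched <- tok
          rest <- substring(name, nchar(pre) + 1L)
          break
        }
      }
    }
    if (!is.null(matched)) break
  }
  if (is.null(matched)) {
    guess <- sub("[- ].*$", "", name)
    stop(sprintf("unknown lipid class '%s' in '%s'", guess, name))
  }

  # split composition on "-" between chain tokens
  parts <- strsplit(rest, "-", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L)
    stop(sprintf("missing composition after class token in '%s'", name))
  chains <- lapply(parts, .parse_chain_token, name = name)
  info <- .class_info(matched)
  if (length(parts) == 1L && info$expected_chain_count > 1L) {
    # sum composition only
    ch <- chains[[1]]
    lipid_species(matched, ch$carbons, ch$double_bonds, ch$hydroxyls,
                  chains = NULL, raw_name = name)
  } else if (length(parts) == 1L) {
    # single-chain class: the one token is both sum and chain
    ch <- chains[[1]]
    lipid_species(matched, ch$carbons, ch$double_bonds, ch$hydroxyls,
                  chains = chains, raw_name = name)
  } else {
    if (length(parts) != info$expected_chain_count)
      stop(sprintf("class '%s' expects %d chains, found %d in '%s'",
                   matched, info$expected_chain_count, length(parts), name))
    lipid_species(matched,
                  sum(vapply(chains, `[[`, integer(1), "carbons")),
                  sum(vapply(chains, `[[`, integer(1), "double_bonds")),
                  sum(vapply(chains, `[[`, integer(1), "hydroxyls")),
                  chains = chains, raw_name = name)
  }
}

#' Render a lipid species to its canonical name
#'
#' The inverse of [parse_species()]: `render_species(parse_species(x))` is the
#' canonical (hyphen-separated) form of `x`, and parsing a rendered name
#' reproduces the species.
#'
#' @param species A `lipid_species` object.
#' @return Canonical species name.
#' @export
render_species <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  info <- .class_info(species$lipid_class)
  if (info$expected_chain_count == 0L) return(species$lipid_class)
  sep <- if (grepl("O-$", species$lipid_class)) "" else "-"
  comp <- if (!is.null(species$chains) && length(species$chains) > 1L) {
    paste(vapply(species$chains, format, character(1)), collapse = "-")
  } else {
    sprintf("%d:%d;%d", species$total_carbons, species$total_double_bonds,
            species$total_hydroxyls)
  }
  paste0(species$lipid_class, sep, comp)
}

#' @export
format.lipid_species <- function(x, ...) render_species(x)

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid species ", render_species(x), ">\n", sep = "")
  invisible(x)
}

#' Acyl chains of a species
#'
#' Returns the resolved chains when present. For sum-only species of a
#' single-chain class (lyso species) the one chain implied by the totals is
#' returned; for sum-only multi-chain species the split is underdetermined and
#' `NULL` is returned. `"Chol"` yields an empty list.
#'
#' @param species A `lipid_species` object.
#' @return List of `acyl_chain` objects, empty list, or `NULL`.
#' @export
chains_of <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  info <- .class_info(species$lipid_class)
  if (info$expected_chain_count == 0L) return(list())
  if (!is.null(species$chains) && length(species$chains) > 0L)
    return(species$chains)
  if (info$expected_chain_count == 1L)
    return(list(acyl_chain(species$total_carbons, species$total_double_bonds,
                           species$total_hydroxyls)))
  NULL
}
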