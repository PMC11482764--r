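# Chemical formula parsing and monoisotopic mass arithmetic.
#
# Monoisotopic atomic masses (most abundant isotope), >= 6 decimals. The
# table is deliberately small -- druglike elements plus common adduct
# cations -- and extensible via options(msDrugLib.extraElements = c(X = m)).
.ATOMIC_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  Na = 22.9897692809,
  K  = 38.96370668
)

.PROTON_MASS <- 1.007276466

.elementMasses <- function() {
  extra <- getOption("msDrugLib.extraElements", NULL)
  if (is.null(extra)) .ATOMIC_MASS else c(.ATOMIC_MASS, extra)
}

#' Parse a molecular formula
#'
#' Parses a Hill-notation-like formula string ("C17H19ClN2") into named
#' element counts. Counts of 1 are implicit; multi-letter element symbols
#' (Cl, Br, Na...) are recognised greedily. A leading "-" marks a net loss
#' (e.g. "-H2O" for dehydration) and is returned in the \code{sign}
#' attribute; the counts themselves stay nonnegative.
#'
#' @param text formula string.
#' @return named integer vector of element counts with attribute
#'   \code{sign} (+1 or -1).
#' @examples
#' parseFormula("CH2")          # methylation gain
#' parseFormula("C17H19ClN2")   # a chlorinated piperazine analog
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop("formula must be a single non-empty string")
  text <- trimws(text)
  sign <- 1L
  if (startsWith(text, "-")) {
    sign <- -1L
    text <- substring(text, 2L)
  } else if (startsWith(text, "+")) {
    text <- substring(text, 2L)
  }
  masses <- .elementMasses()
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text) || !length(tokens))
    stop(sprintf("cannot parse formula '%s'", text))
  counts <- integer()
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(masses))
      stop(sprintf("unknown element '%s' in formula '%s'", sym, text))
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts <- counts[counts > 0L]
  if (!length(counts)) stop("formula has no atoms")
  attr(counts, "sign") <- sign
  counts
}

.asFormula <- function(formula) {
  if (is.character(formula)) parseFormula(formula) else {
    stopifnot(is.numeric(formula), !is.null(names(formula)))
    formula
  }
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the monoisotopic atomic mass (mass of
#' the most abundant isotope). A "-"-signed formula returns a negative mass,
#' so curated loss offsets (e.g. "-H2O") validate directly against their
#' stated delta masses.
#'
#' @param formula formula string or named count vector from [parseFormula()].
#' @return mass in Da.
#' @examples
#' monoisotopicMass("CH2")     # 14.0157, the (de)methylation offset
#' monoisotopicMass("O")       # 15.9949, oxidation
#' monoisotopicMass("C6H8O6")  # 176.0321, glucuronidation
#' @export
monoisotopicMass <- function(formula) {
  f <- .asFormula(formula)
  masses <- .elementMasses()
  unknown <- setdiff(names(f), names(masses))
  if (length(unknown))
    stop(sprintf("unknown element(s): %s", paste(unknown, collapse = ", ")))
  s <- attr(f, "sign")
  if (is.null(s)) s <- 1L
  s * sum(masses[names(f)] * as.numeric(f))
}

#' m/z of a protonated (or multiply protonated) species
#'
#' \code{(M + z * m_proton) / z} with the proton mass 1.007276 Da; charge 1
#' gives the [M+H]+ ion.
#'
#' @param formula formula string or named count vector.
#' @param charge positive integer charge state.
#' @return m/z in Th.
#' @examples
#' protonatedMz("C17H19N3O3S")  # omeprazole [M+H]+, 346.122
#' @export
protonatedMz <- function(formula, charge = 1L) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1)
    stop("charge must be a positive integer")
  charge <- as.integer(charge)
  (monoisotopicMass(formula) + charge * .PROTON_MASS) / charge
}

# ---------------------------------------------------------------------------
# Curated delta-mass list
# ---------------------------------------------------------------------------

.DELTA_CATEGORIES <- c("metabolism", "adduct", "isotope")

#' Read a curated delta-mass list
#'
#' The list enumerates the precursor mass offsets accepted between a
#' propagated analog and its connected drug: drug-metabolism
#' transformations (methylation +14.02, glucuronidation +176.03, ...),
#' mass-spectrometry adducts (ammonium +17.03, ...) and isotope spacings.
#' Gains and losses are distinct, signed entries.
#'
#' @param path TSV with columns \code{delta_mass} (signed Da),
#'   \code{interpretation}, \code{category} (metabolism | adduct | isotope)
#'   and optional \code{formula_change} ("-"-prefixed for losses).
#' @return data.frame with those columns.
#' @export
readDeltaMassList <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("delta_mass", "interpretation", "category")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("delta-mass list %s lacks column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (!"formula_change" %in% names(df)) df$formula_change <- NA_character_
  df$formula_change[!nzchar(trimws(ifelse(is.na(df$formula_change), "",
                                          df$formula_change)))] <- NA_character_
  bad <- setdiff(unique(df$category), .DELTA_CATEGORIES)
  if (length(bad))
    stop(sprintf("unknown delta-mass category: %s", paste(bad, collapse = ", ")))
  if (any(!is.finite(df$delta_mass)))
    stop("delta_mass must be finite")
  df
}

#' The curated delta-mass list shipped with the package
#'
#' A documented subset of the drug-metabolism / adduct / isotope offsets
#' used for analog curation, with formula changes where a single-sign
#' formula exists. Users extend it by supplying their own TSV to
#' [readDeltaMassList()].
#'
#' @return data.frame as in [readDeltaMassList()].
#' @export
defaultDeltaMassList <- function() {
  readDeltaMassList(system.file("extdata", "delta_mass_list.tsv",
                                package = "msDrugLib", mustWork = TRUE))
}

#' Match an observed mass offset against the curated list
#'
#' Sign-sensitive: a gain and a loss of the same magnitude are distinct
#' entries. Returns all entries within tolerance, ordered by absolute
#' deviation (ties by delta_mass), so callers can take the closest
#' interpretation deterministically.
#'
#' @param observed observed signed precursor difference (Da).
#' @param entries data.frame from [readDeltaMassList()].
#' @param tolerance absolute matching tolerance in Da (default 0.01, enough
#'   to separate CH2 at 14.0157 from nearby offsets at the two-decimal
#'   precision the curated list is reported at).
#' @return the matching rows of \code{entries}, possibly zero rows.
#' @export
matchDeltaMass <- function(observed, entries, tolerance = 0.01) {
  stopifnot(is.numeric(observed), length(observed) == 1L, tolerance > 0)
  if (!nrow(entries)) return(entries)
  dev <- abs(observed - entries$delta_mass)
  hit <- entries[dev <= tolerance, , drop = FALSE]
  dev <- dev[dev <= tolerance]
  hit[order(dev, hit$delta_mass), , drop = FALSE]
}
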