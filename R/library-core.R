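# Drug-library assembly: merging reference collections, clinical-phase
# selection, partial-name metabolite capture, metadata enrichment, export.

.nameKey <- function(x) tolower(trimws(x))

.inchikeyBlock <- function(ik) substr(ik, 1L, 14L)

# lowercase synonym -> index of synonym set
.synonymLookup <- function(synonymIndex) {
  if (is.null(synonymIndex)) return(NULL)
  idx <- rep(seq_along(synonymIndex),
             vapply(synonymIndex, length, integer(1)))
  setNames(idx, .nameKey(unlist(synonymIndex, use.names = FALSE)))
}

#' Merge reference spectral collections into a DrugLibrary
#'
#' Spectra from multiple open reference collections are grouped into
#' records: by the first (2D-structure) InChIKey block when a structure is
#' known -- so salts and stereoisomers of one drug collapse -- and by
#' case-folded compound name otherwise. Spectra of duplicates concatenate
#' under one record; duplicate spectrum ids are kept once, which makes the
#' merge idempotent. The primary name follows the first-synonym convention
#' when a synonym index is supplied.
#'
#' @param collections list of spectrum collections (each a list of
#'   [Spectrum-class] carrying compound names).
#' @param structureIndex optional data.frame with columns \code{name},
#'   \code{inchikey} and optionally \code{smiles}, joining names to
#'   structures (case-insensitive on name).
#' @param synonymIndex optional list of character vectors; each vector is
#'   one compound's synonym set, first element the primary name.
#' @return a [DrugLibrary-class]. Attribute \code{skipped} counts spectra
#'   dropped for lacking both name and structure.
#' @export
mergeReferenceLibraries <- function(collections, structureIndex = NULL,
                                    synonymIndex = NULL) {
  lookup <- .synonymLookup(synonymIndex)
  structKey <- NULL
  if (!is.null(structureIndex)) {
    stopifnot(all(c("name", "inchikey") %in% names(structureIndex)))
    structKey <- setNames(as.character(structureIndex$inchikey),
                          .nameKey(structureIndex$name))
  }
  skipped <- 0L
  groups <- list()  # key -> list(names, inchikey, smiles, spectra)
  for (coll in collections) {
    for (s in coll) {
      nm <- s@compoundName
      ik <- NA_character_
      if (!is.na(nm) && !is.null(structKey)) {
        hit <- structKey[.nameKey(nm)]
        if (!is.na(hit)) ik <- unname(hit)
      }
      if (is.na(nm) && is.na(ik)) {
        skipped <- skipped + 1L
        next
      }
      key <- if (!is.na(ik)) .inchikeyBlock(ik) else .nameKey(nm)
      g <- groups[[key]]
      if (is.null(g))
        g <- list(names = character(), inchikey = ik, spectra = list())
      if (!is.na(nm) && !.nameKey(nm) %in% .nameKey(g$names))
        g$names <- c(g$names, nm)
      if (is.na(g$inchikey) && !is.na(ik)) g$inchikey <- ik
      sid <- s@spectrumId
      have <- vapply(g$spectra, spectrumId, character(1))
      if (!sid %in% have) g$spectra <- c(g$spectra, s)
      groups[[key]] <- g
    }
  }
  if (skipped > 0L)
    warning(sprintf("%d spectra skipped (no name and no structure)", skipped))
  smilesOf <- NULL
  if (!is.null(structureIndex) && "smiles" %in% names(structureIndex))
    smilesOf <- setNames(as.character(structureIndex$smiles),
                         .inchikeyBlock(structureIndex$inchikey))
  records <- lapply(names(groups), function(key) {
    g <- groups[[key]]
    primary <- if (length(g$names)) g$names[[1L]] else key
    syns <- g$names
    if (!is.null(lookup) && length(g$names)) {
      hit <- lookup[.nameKey(g$names)]
      hit <- hit[!is.na(hit)]
      if (length(hit)) {
        set <- synonymIndex[[hit[[1L]]]]
        primary <- set[[1L]]
        syns <- unique(c(set, g$names))
      }
    }
    smi <- NA_character_
    if (!is.null(smilesOf) && !is.na(g$inchikey)) {
      hit <- smilesOf[.inchikeyBlock(g$inchikey)]
      if (!is.na(hit)) smi <- unname(hit)
    }
    DrugRecord(drugId = key, primaryName = primary,
               synonyms = setdiff(syns, primary),
               smiles = smi, inchikey = g$inchikey,
               spectra = g$spectra)
  })
  names(records) <- names(groups)
  out <- DrugLibrary(records = records)
  attr(out, "skipped") <- skipped
  out
}

#' Subset a library by clinical phase
#'
#' @param library a [DrugLibrary-class].
#' @param keep character vector of phases to keep (subset of approved,
#'   clinical_trial, withdrawn, unknown).
#' @return the restricted [DrugLibrary-class]; metabolite records are kept
#'   only if their parent survives.
#' @export
filterClinicalPhase <- function(library, keep) {
  stopifnot(all(keep %in% .CLINICAL_PHASES))
  recs <- library@records
  ok <- vapply(recs, function(r) r@clinicalPhase %in% keep, logical(1))
  kept <- recs[ok]
  # drop metabolites whose parent was removed
  repeat {
    orphan <- vapply(kept, function(r)
      r@recordType == "metabolite" && !r@parentDrugId %in% names(kept),
      logical(1))
    if (!any(orphan)) break
    kept <- kept[!orphan]
  }
  DrugLibrary(records = kept,
              pharmMeta = library@pharmMeta[
                intersect(names(library@pharmMeta), names(kept))])
}

# Positions where `name` occurs in `candidate` ending at a word boundary
# (string edge, whitespace, hyphen or comma). The left side may be fused:
# metabolite nomenclature prefixes modifiers directly onto the drug name
# (N-desmethylvenlafaxine), while suffix modifiers are separated
# (venlafaxine N-oxide).
.nameOccurs <- function(name, candidate) {
  pat <- paste0("(?i)", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", name),
                "(?=$|[[:space:],-])")
  m <- gregexpr(pat, candidate, perl = TRUE)[[1]]
  m[1L] != -1L
}

#' Capture drug metabolites by partial name match
#'
#' Named candidate spectra are linked to a library drug when the drug's
#' primary name or a synonym occurs inside the candidate name ending at a
#' word boundary, case-insensitively, and the candidate name is not itself
#' an exact library compound name. When several drugs match, the longest
#' drug name wins; equal-length ties to distinct drugs are emitted to the
#' review list rather than auto-linked.
#'
#' @param library a [DrugLibrary-class].
#' @param candidates list of named [Spectrum-class] (compoundName set).
#' @return list with \code{metabolites} (list of metabolite
#'   [DrugRecord-class] with parent links) and \code{review} (data.frame of
#'   ambiguous candidates: candidate_name, matched_drugs).
#' @export
partialNameMetaboliteMatch <- function(library, candidates) {
  drugs <- Filter(function(r) r@recordType == "drug", library@records)
  allNames <- unlist(lapply(library@records, function(r)
    c(r@primaryName, r@synonyms)), use.names = FALSE)
  exactKeys <- .nameKey(allNames)
  nameToDrug <- do.call(rbind, lapply(drugs, function(r) {
    nms <- c(r@primaryName, r@synonyms)
    data.frame(name = nms, drug_id = r@drugId, stringsAsFactors = FALSE)
  }))
  mets <- list()
  review <- data.frame(candidate_name = character(),
                       matched_drugs = character(),
                       stringsAsFactors = FALSE)
  counter <- new.env()
  for (s in candidates) {
    cn <- s@compoundName
    if (is.na(cn)) next
    if (.nameKey(cn) %in% exactKeys) next  # exact library compound, not a metabolite
    if (is.null(nameToDrug)) next
    hit <- nameToDrug[vapply(nameToDrug$name, .nameOccurs, logical(1),
                             candidate = cn), , drop = FALSE]
    if (!nrow(hit)) next
    len <- nchar(hit$name)
    best <- hit[len == max(len), , drop = FALSE]
    if (length(unique(best$drug_id)) > 1L) {
      review <- rbind(review, data.frame(
        candidate_name = cn,
        matched_drugs = paste(sort(unique(best$drug_id)), collapse = ";"),
        stringsAsFactors = FALSE))
      next
    }
    parent <- best$drug_id[[1L]]
    n <- (if (is.null(counter[[parent]])) 0L else counter[[parent]]) + 1L
    counter[[parent]] <- n
    mets[[length(mets) + 1L]] <- DrugRecord(
      drugId = sprintf("%s_met%d", parent, n), primaryName = cn,
      spectra = list(s), recordType = "metabolite", parentDrugId = parent)
  }
  list(metabolites = mets, review = review)
}

#' Add records to a DrugLibrary
#'
#' @param library a [DrugLibrary-class].
#' @param records list of [DrugRecord-class] to add; ids must be new.
#' @return the extended [DrugLibrary-class].
#' @export
addRecords <- function(library, records) {
  if (!length(records)) return(library)
  ids <- vapply(records, function(r) r@drugId, character(1))
  if (any(ids %in% names(library@records)))
    stop("record ids already present in library")
  recs <- c(library@records, setNames(records, ids))
  DrugLibrary(records = recs, pharmMeta = library@pharmMeta)
}

.META_FIELDS <- c(exposure_source = "exposureSource",
                  pharmacologic_class = "pharmacologicClass",
                  therapeutic_area = "therapeuticArea",
                  therapeutic_indication = "therapeuticIndication",
                  mechanism_of_action = "mechanismOfAction")

.splitMulti <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) character()
  else trimws(strsplit(as.character(x), ";", fixed = TRUE)[[1]])
}

#' Enrich a library with controlled-vocabulary metadata tables
#'
#' Tables are joined in the listed priority order, with all structure
#' (InChIKey) joins taking precedence over name joins; later tables only
#' fill fields still missing -- existing nonempty fields are never
#' overwritten, and no record is ever removed. Recognised columns:
#' \code{clinical_phase} (fills the record's phase while it is "unknown"),
#' \code{exposure_source}, \code{pharmacologic_class},
#' \code{therapeutic_area}, \code{therapeutic_indication},
#' \code{mechanism_of_action} (semicolon-separated multi-values).
#'
#' @param library a [DrugLibrary-class].
#' @param tables list of \code{list(data = data.frame, key = "inchikey" |
#'   "name")}; the data must contain the declared key column.
#' @return the enriched [DrugLibrary-class]; records first matched through
#'   a name join carry metadata provenance \code{"name-join"}.
#' @export
enrichMetadata <- function(library, tables) {
  for (ti in seq_along(tables)) {
    tab <- tables[[ti]]
    if (!tab$key %in% c("inchikey", "name"))
      stop(sprintf("table %d: key must be 'inchikey' or 'name'", ti))
    if (!tab$key %in% names(tab$data))
      stop(sprintf("table %d lacks its join key column '%s'", ti, tab$key))
  }
  recs <- library@records
  meta <- library@pharmMeta
  applyTable <- function(tab, provenance) {
    df <- tab$data
    for (id in names(recs)) {
      r <- recs[[id]]
      row <- NULL
      if (tab$key == "inchikey") {
        if (is.na(r@inchikey)) next
        hit <- which(.inchikeyBlock(df$inchikey) == .inchikeyBlock(r@inchikey))
      } else {
        keys <- .nameKey(c(r@primaryName, r@synonyms))
        hit <- which(.nameKey(df$name) %in% keys)
      }
      if (!length(hit)) next
      row <- df[hit[[1L]], , drop = FALSE]
      m <- meta[[id]]
      if (is.null(m)) m <- DrugMetadata(id, provenance = provenance)
      for (col in intersect(names(.META_FIELDS), names(row))) {
        slotName <- .META_FIELDS[[col]]
        if (length(slot(m, slotName)) == 0L) {
          vals <- .splitMulti(row[[col]])
          if (length(vals)) slot(m, slotName) <- vals
        }
      }
      meta[[id]] <<- m
      if ("clinical_phase" %in% names(row)) {
        ph <- trimws(as.character(row$clinical_phase))
        if (!is.na(ph) && nzchar(ph) && ph %in% .CLINICAL_PHASES &&
            r@clinicalPhase == "unknown") {
          r@clinicalPhase <- ph
          recs[[id]] <<- r
        }
      }
    }
  }
  for (tab in tables) if (tab$key == "inchikey")
    applyTable(tab, "structure-join")
  for (tab in tables) if (tab$key == "name")
    applyTable(tab, "name-join")
  DrugLibrary(records = recs, pharmMeta = meta)
}

#' Export a DrugLibrary as MGF plus metadata TSV
#'
#' Mirrors the distributed library shape: one MGF with every reference
#' spectrum and one TSV of records with their controlled-vocabulary
#' metadata (multi-values semicolon-joined).
#'
#' @param library a [DrugLibrary-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the two paths written.
#' @export
exportDrugLibrary <- function(library, dir, prefix = "drug_library") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- librarySpectra(library)
  mgf <- file.path(dir, paste0(prefix, ".mgf"))
  tsv <- file.path(dir, paste0(prefix, "_metadata.tsv"))
  writeMGF(sp, mgf)
  join <- function(x) paste(x, collapse = ";")
  rows <- lapply(library@records, function(r) {
    m <- library@pharmMeta[[r@drugId]]
    data.frame(
      drug_id = r@drugId, primary_name = r@primaryName,
      inchikey = r@inchikey, clinical_phase = r@clinicalPhase,
      record_type = r@recordType, parent_drug_id = r@parentDrugId,
      exposure_source = if (is.null(m)) "" else join(m@exposureSource),
      pharmacologic_class = if (is.null(m)) "" else join(m@pharmacologicClass),
      therapeutic_area = if (is.null(m)) "" else join(m@therapeuticArea),
      therapeutic_indication = if (is.null(m)) "" else
        join(m@therapeuticIndication),
      mechanism_of_action = if (is.null(m)) "" else join(m@mechanismOfAction),
      stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), tsv, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(mgf = mgf, tsv = tsv))
}
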