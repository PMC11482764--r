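#' @import methods
#' @importFrom stats median setNames
#' @importFrom utils read.delim write.table head
NULL

# ---------------------------------------------------------------------------
# Spectrum
# ---------------------------------------------------------------------------

#' Spectrum: one MS/MS scan
#'
#' Container for a single tandem mass spectrum: the precursor ion selected
#' for fragmentation and its fragment peak list. Peaks are stored as a
#' two-column matrix (\code{mz}, \code{intensity}), deduplicated (equal m/z
#' merged by intensity sum) and sorted strictly ascending by m/z on
#' construction.
#'
#' @slot spectrumId opaque identifier, unique within a collection.
#' @slot precursorMz precursor mass-to-charge ratio (Th), positive.
#' @slot charge signed integer charge; spectra read without a charge default
#'   to +1 (positive ionisation assumed).
#' @slot peaks numeric matrix with columns \code{mz} (> 0) and
#'   \code{intensity} (>= 0), strictly ascending m/z.
#' @slot retentionTime retention time in minutes, \code{NA} when unknown.
#' @slot sourceFile provenance file name (may be empty).
#' @slot compoundName compound annotation, \code{NA} when unannotated.
#' @slot adduct adduct/ion-form string, \code{NA} when unknown.
#'
#' @examples
#' s <- Spectrum("s1", precursorMz = 300.1,
#'               peaks = cbind(mz = c(100, 150), intensity = c(10, 20)))
#' peakMatrix(s)
#' @export
setClass("Spectrum",
  slots = c(
    spectrumId = "character",
    precursorMz = "numeric",
    charge = "integer",
    peaks = "matrix",
    retentionTime = "numeric",
    sourceFile = "character",
    compoundName = "character",
    adduct = "character"
  )
)

setValidity("Spectrum", function(object) {
  p <- object@peaks
  msg <- character()
  if (!is.numeric(p) || ncol(p) != 2L)
    msg <- c(msg, "peaks must be a numeric matrix with columns mz, intensity")
  else {
    if (nrow(p) > 0L) {
      if (any(p[, 1L] <= 0)) msg <- c(msg, "peak m/z must be > 0")
      if (any(p[, 2L] < 0)) msg <- c(msg, "peak intensity must be >= 0")
      if (is.unsorted(p[, 1L], strictly = TRUE))
        msg <- c(msg, "peaks must be strictly ascending by m/z")
    }
  }
  if (length(object@precursorMz) != 1L || is.na(object@precursorMz) ||
      object@precursorMz <= 0)
    msg <- c(msg, "precursorMz must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' Duplicate m/z values are merged by summing their intensities before the
#' ascending sort, so every constructor path satisfies the peak-ordering
#' invariant.
#'
#' @param spectrumId character scalar identifier.
#' @param precursorMz precursor m/z (Th).
#' @param peaks two-column numeric matrix (mz, intensity) in any order.
#' @param charge integer charge, default +1.
#' @param retentionTime retention time in minutes (NA if unknown).
#' @param sourceFile,compoundName,adduct optional provenance strings.
#' @return a [Spectrum-class] object.
#' @export
Spectrum <- function(spectrumId, precursorMz, peaks, charge = 1L,
                     retentionTime = NA_real_, sourceFile = "",
                     compoundName = NA_character_, adduct = NA_character_) {
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L)
    stop("peaks must have two columns (mz, intensity)")
  storage.mode(peaks) <- "double"
  colnames(peaks) <- c("mz", "intensity")
  if (nrow(peaks) > 0L) {
    if (anyDuplicated(peaks[, 1L])) {
      inten <- tapply(peaks[, 2L], peaks[, 1L], sum)
      peaks <- cbind(mz = as.numeric(names(inten)), intensity = as.numeric(inten))
    }
    peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
  }
  new("Spectrum",
      spectrumId = as.character(spectrumId),
      precursorMz = as.numeric(precursorMz),
      charge = as.integer(charge),
      peaks = peaks,
      retentionTime = as.numeric(retentionTime),
      sourceFile = as.character(sourceFile),
      compoundName = as.character(compoundName),
      adduct = as.character(adduct))
}

#' @describeIn Spectrum display a short summary
#' @param object a Spectrum
#' @export
setMethod("show", "Spectrum", function(object) {
  cat("Spectrum", object@spectrumId,
      sprintf("| precursor m/z %.4f (%+d)", object@precursorMz, object@charge),
      sprintf("| %d peaks", nrow(object@peaks)))
  if (!is.na(object@retentionTime))
    cat(sprintf(" | RT %.2f min", object@retentionTime))
  if (!is.na(object@compoundName))
    cat(" |", object@compoundName)
  cat("\n")
})

# ---------------------------------------------------------------------------
# DrugRecord / DrugMetadata / DrugLibrary
# ---------------------------------------------------------------------------

.CLINICAL_PHASES <- c("approved", "clinical_trial", "withdrawn", "unknown")
.EXPOSURE_SOURCES <- c("medical", "endogenous", "food", "personal_care",
                       "industrial")
.VOCAB_LEVELS <- c("exposure_source", "pharmacologic_class",
                   "therapeutic_area", "therapeutic_indication",
                   "mechanism_of_action")

#' DrugRecord: one library compound
#'
#' A compound in the drug library: structure identifiers, naming (the primary
#' name follows the first-synonym convention), clinical phase, its reference
#' spectra, and -- for metabolite records -- the link to the parent drug.
#'
#' @slot drugId opaque identifier.
#' @slot primaryName display name (first synonym when a synonym index is
#'   available).
#' @slot synonyms character vector of alternative names.
#' @slot smiles,inchikey structure identifiers (\code{NA} when absent).
#' @slot clinicalPhase one of approved, clinical_trial, withdrawn, unknown.
#' @slot spectra list of [Spectrum-class] reference spectra.
#' @slot recordType \code{"drug"} or \code{"metabolite"}.
#' @slot parentDrugId for metabolite records, the drugId of the parent drug.
#' @export
setClass("DrugRecord",
  slots = c(
    drugId = "character",
    primaryName = "character",
    synonyms = "character",
    smiles = "character",
    inchikey = "character",
    clinicalPhase = "character",
    spectra = "list",
    recordType = "character",
    parentDrugId = "character"
  )
)

setValidity("DrugRecord", function(object) {
  msg <- character()
  if (!object@clinicalPhase %in% .CLINICAL_PHASES)
    msg <- c(msg, sprintf("clinicalPhase must be one of %s",
                          paste(.CLINICAL_PHASES, collapse = ", ")))
  if (!object@recordType %in% c("drug", "metabolite"))
    msg <- c(msg, "recordType must be 'drug' or 'metabolite'")
  if (object@recordType == "metabolite" && is.na(object@parentDrugId))
    msg <- c(msg, "metabolite records require parentDrugId")
  if (is.na(object@primaryName) && is.na(object@smiles) &&
      is.na(object@inchikey))
    msg <- c(msg, "record needs at least a name or a structure identifier")
  if (!all(vapply(object@spectra, is, logical(1), "Spectrum")))
    msg <- c(msg, "spectra must be a list of Spectrum objects")
  if (length(msg)) msg else TRUE
})

#' Construct a DrugRecord
#' @param drugId identifier.
#' @param primaryName display name.
#' @param synonyms character vector of alternative names.
#' @param smiles,inchikey optional structure identifiers.
#' @param clinicalPhase one of approved, clinical_trial, withdrawn, unknown.
#' @param spectra list of Spectrum objects.
#' @param recordType "drug" or "metabolite".
#' @param parentDrugId parent drug id (metabolite records only).
#' @return a [DrugRecord-class].
#' @export
DrugRecord <- function(drugId, primaryName, synonyms = character(),
                       smiles = NA_character_, inchikey = NA_character_,
                       clinicalPhase = "unknown", spectra = list(),
                       recordType = "drug", parentDrugId = NA_character_) {
  new("DrugRecord", drugId = as.character(drugId),
      primaryName = as.character(primaryName),
      synonyms = as.character(synonyms),
      smiles = as.character(smiles), inchikey = as.character(inchikey),
      clinicalPhase = clinicalPhase, spectra = spectra,
      recordType = recordType, parentDrugId = as.character(parentDrugId))
}

#' DrugMetadata: controlled-vocabulary pharmacologic annotations
#'
#' The exposure-source field uses the closed five-class vocabulary
#' (medical, endogenous, food, personal_care, industrial) and is
#' multi-valued: a compound may, e.g., be both a food component and a
#' medication. The remaining vocabularies may be empty for withdrawn or
#' unapproved compounds.
#'
#' @slot drugId identifier of the annotated record.
#' @slot exposureSource subset of the five-class vocabulary.
#' @slot pharmacologicClass,therapeuticArea,therapeuticIndication,mechanismOfAction
#'   character vectors of controlled-vocabulary terms (possibly empty).
#' @slot provenance how the metadata was joined ("structure-join",
#'   "name-join" or "" when unset).
#' @export
setClass("DrugMetadata",
  slots = c(
    drugId = "character",
    exposureSource = "character",
    pharmacologicClass = "character",
    therapeuticArea = "character",
    therapeuticIndication = "character",
    mechanismOfAction = "character",
    provenance = "character"
  )
)

setValidity("DrugMetadata", function(object) {
  bad <- setdiff(object@exposureSource, .EXPOSURE_SOURCES)
  if (length(bad))
    sprintf("unknown exposure source(s): %s", paste(bad, collapse = ", "))
  else TRUE
})

#' Construct DrugMetadata
#' @param drugId identifier.
#' @param exposureSource character subset of medical, endogenous, food,
#'   personal_care, industrial.
#' @param pharmacologicClass,therapeuticArea,therapeuticIndication,mechanismOfAction
#'   controlled-vocabulary term vectors.
#' @param provenance join provenance flag.
#' @return a [DrugMetadata-class].
#' @export
DrugMetadata <- function(drugId, exposureSource = character(),
                         pharmacologicClass = character(),
                         therapeuticArea = character(),
                         therapeuticIndication = character(),
                         mechanismOfAction = character(),
                         provenance = "") {
  new("DrugMetadata", drugId = as.character(drugId),
      exposureSource = as.character(exposureSource),
      pharmacologicClass = as.character(pharmacologicClass),
      therapeuticArea = as.character(therapeuticArea),
      therapeuticIndication = as.character(therapeuticIndication),
      mechanismOfAction = as.character(mechanismOfAction),
      provenance = provenance)
}

#' DrugLibrary: records plus pharmacologic metadata
#'
#' The assembled spectral library: a named list of [DrugRecord-class]
#' objects (drugs and metabolites) and a parallel named list of
#' [DrugMetadata-class]. Invariants enforced: every metadata key names an
#' existing record, every metabolite's parent exists, and spectrum ids are
#' globally unique across the library.
#'
#' @slot records named list of DrugRecord (names = drugIds).
#' @slot pharmMeta named list of DrugMetadata (keys subset of record ids).
#' @export
setClass("DrugLibrary",
  slots = c(records = "list", pharmMeta = "list"))

setValidity("DrugLibrary", function(object) {
  msg <- character()
  ids <- names(object@records)
  if (length(object@records) && (is.null(ids) || anyDuplicated(ids)))
    msg <- c(msg, "records must be uniquely named by drugId")
  extra <- setdiff(names(object@pharmMeta), ids)
  if (length(extra))
    msg <- c(msg, sprintf("metadata for unknown drugId(s): %s",
                          paste(extra, collapse = ", ")))
  parents <- vapply(object@records, function(r)
    if (r@recordType == "metabolite") r@parentDrugId else NA_character_,
    character(1))
  orphan <- parents[!is.na(parents) & !parents %in% ids]
  if (length(orphan))
    msg <- c(msg, sprintf("metabolite parent(s) missing from library: %s",
                          paste(unique(orphan), collapse = ", ")))
  sids <- unlist(lapply(object@records, function(r)
    vapply(r@spectra, spectrumId, character(1))), use.names = FALSE)
  if (anyDuplicated(sids))
    msg <- c(msg, "spectrum ids must be globally unique within the library")
  if (length(msg)) msg else TRUE
})

#' Construct a DrugLibrary
#' @param records list of DrugRecord objects (named by drugId, or names are
#'   taken from the records).
#' @param pharmMeta list of DrugMetadata objects keyed by drugId.
#' @return a [DrugLibrary-class].
#' @export
DrugLibrary <- function(records = list(), pharmMeta = list()) {
  if (length(records) && is.null(names(records)))
    names(records) <- vapply(records, function(r) r@drugId, character(1))
  if (length(pharmMeta) && is.null(names(pharmMeta)))
    names(pharmMeta) <- vapply(pharmMeta, function(m) m@drugId, character(1))
  new("DrugLibrary", records = records, pharmMeta = pharmMeta)
}

#' @describeIn DrugLibrary display a summary of counts by record type
#' @param object a DrugLibrary
#' @export
setMethod("show", "DrugLibrary", function(object) {
  types <- vapply(object@records, function(r) r@recordType, character(1))
  nsp <- sum(vapply(object@records, function(r) length(r@spectra), integer(1)))
  cat(sprintf(
    "DrugLibrary: %d records (%d drugs, %d metabolites), %d spectra, %d with metadata\n",
    length(object@records), sum(types == "drug"),
    sum(types == "metabolite"), nsp, length(object@pharmMeta)))
})

# ---------------------------------------------------------------------------
# CohortFeatureTable / ExposureTable (SummarizedExperiment-backed)
# ---------------------------------------------------------------------------

#' CohortFeatureTable: samples-by-features peak areas
#'
#' A \linkS4class{SummarizedExperiment} with features as rows and samples as
#' columns, carrying a nonnegative \code{peakArea} assay, per-feature
#' precursor m/z and retention time in \code{rowData}, and (optionally) the
#' feature MS/MS spectra in \code{metadata(x)$featureSpectra}. Constructors
#' accept the samples-by-features orientation common in exported feature
#' tables and transpose internally.
#'
#' @export
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
setClass("CohortFeatureTable", contains = "SummarizedExperiment")

setValidity("CohortFeatureTable", function(object) {
  msg <- character()
  if (!"peakArea" %in% assayNames(object))
    msg <- c(msg, "assay 'peakArea' is required")
  else if (any(assay(object, "peakArea") < 0, na.rm = TRUE))
    msg <- c(msg, "peak areas must be >= 0")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate feature ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortFeatureTable
#'
#' @param peakAreas numeric matrix, samples x features (rownames = sample
#'   ids, colnames = feature ids); blank/NA cells are treated as 0.
#' @param featureMz numeric vector of feature precursor m/z (Th), parallel to
#'   features (optional).
#' @param featureRt numeric vector of feature retention times (minutes,
#'   optional).
#' @param featureSpectra named list of [Spectrum-class], keyed by feature id
#'   (optional).
#' @return a [CohortFeatureTable-class].
#' @export
CohortFeatureTable <- function(peakAreas, featureMz = NULL, featureRt = NULL,
                               featureSpectra = NULL) {
  peakAreas <- as.matrix(peakAreas)
  peakAreas[is.na(peakAreas)] <- 0
  if (is.null(rownames(peakAreas)))
    rownames(peakAreas) <- paste0("sample_", seq_len(nrow(peakAreas)))
  if (is.null(colnames(peakAreas)))
    colnames(peakAreas) <- paste0("feature_", seq_len(ncol(peakAreas)))
  if (any(peakAreas < 0)) stop("peak areas must be >= 0")
  nfeat <- ncol(peakAreas)
  rd <- DataFrame(
    mz = if (is.null(featureMz)) rep(NA_real_, nfeat) else as.numeric(featureMz),
    rt = if (is.null(featureRt)) rep(NA_real_, nfeat) else as.numeric(featureRt),
    row.names = colnames(peakAreas))
  se <- SummarizedExperiment(assays = list(peakArea = t(peakAreas)),
                             rowData = rd)
  obj <- new("CohortFeatureTable", se)
  if (!is.null(featureSpectra)) {
    stopifnot(!is.null(names(featureSpectra)))
    metadata(obj)$featureSpectra <- featureSpectra
  }
  obj
}

#' @describeIn CohortFeatureTable sample identifiers
#' @param x a CohortFeatureTable
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn CohortFeatureTable feature identifiers
#' @export
featureIds <- function(x) rownames(x)

#' @describeIn CohortFeatureTable samples-by-features peak-area matrix
#' @export
peakAreas <- function(x) t(assay(x, "peakArea"))

#' @describeIn CohortFeatureTable per-feature precursor m/z
#' @export
featureMz <- function(x) setNames(rowData(x)$mz, rownames(x))

#' @describeIn CohortFeatureTable per-feature retention time (minutes)
#' @export
featureRt <- function(x) setNames(rowData(x)$rt, rownames(x))

#' @describeIn CohortFeatureTable named list of feature MS/MS spectra (or
#'   NULL when the table carries none)
#' @export
featureSpectra <- function(x) metadata(x)$featureSpectra

#' ExposureTable: samples-by-drugs exposure readout
#'
#' A \linkS4class{SummarizedExperiment} with parent drugs as rows and samples
#' as columns. Assays: \code{raw} (summed peak areas over all annotations of
#' the drug -- parent ion forms, metabolites, analogs), \code{abundance}
#' (\code{log10(raw + 1)}) and \code{detected} (raw > 0). \code{rowData}
#' records which annotation types (drug/metabolite/analog) contributed.
#'
#' @export
setClass("ExposureTable", contains = "SummarizedExperiment")

setValidity("ExposureTable", function(object) {
  msg <- character()
  need <- c("raw", "abundance", "detected")
  if (!all(need %in% assayNames(object)))
    msg <- c(msg, "assays raw, abundance, detected are required")
  else {
    if (!all((assay(object, "raw") > 0) == (assay(object, "detected") == 1)))
      msg <- c(msg, "detected must equal raw > 0")
    if (any(!is.finite(assay(object, "abundance"))))
      msg <- c(msg, "abundance must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ExposureTable log10(raw + 1) abundance, samples x drugs
#' @param x an ExposureTable
#' @export
exposureAbundance <- function(x) t(assay(x, "abundance"))

#' @describeIn ExposureTable logical detection matrix, samples x drugs
#' @export
exposureDetected <- function(x) {
  m <- t(assay(x, "detected"))
  storage.mode(m) <- "logical"
  m
}

#' @describeIn ExposureTable raw summed peak areas, samples x drugs
#' @export
exposureRaw <- function(x) t(assay(x, "raw"))

#' @describeIn ExposureTable drug identifiers (rows)
#' @export
exposureDrugs <- function(x) rownames(x)

#' @describeIn ExposureTable annotation types seen per drug (named list)
#' @export
annotationProvenance <- function(x) {
  setNames(strsplit(rowData(x)$provenance, ";", fixed = TRUE), rownames(x))
}

# ---------------------------------------------------------------------------
# StratificationResult
# ---------------------------------------------------------------------------

#' StratificationResult: sample groups from exposure co-occurrence
#'
#' Output of [stratifyByExposure()]: hierarchical-clustering group labels for
#' every sample, with the linkage/distance used, the cut level k, and mean
#' silhouette widths over a range of k to assist (never replace) the user's
#' choice of k.
#'
#' @slot labels named integer vector, one group label per sample; groups are
#'   numbered 1..k by decreasing size (ties by first sample id).
#' @slot k number of groups.
#' @slot linkageMethod,distanceMetric clustering parameters.
#' @slot silhouette data.frame with columns k, mean_width.
#' @export
setClass("StratificationResult",
  slots = c(labels = "integer", k = "integer", linkageMethod = "character",
            distanceMetric = "character", silhouette = "data.frame"))

setValidity("StratificationResult", function(object) {
  msg <- character()
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by sample id")
  if (object@k < 1L || object@k > length(object@labels))
    msg <- c(msg, "k must be between 1 and the number of samples")
  if (length(msg)) msg else TRUE
})

#' @describeIn StratificationResult group labels named by sample
#' @param x a StratificationResult
#' @export
groupLabels <- function(x) x@labels

#' @describeIn StratificationResult display group sizes
#' @param object a StratificationResult
#' @export
setMethod("show", "StratificationResult", function(object) {
  tab <- table(object@labels)
  cat(sprintf("StratificationResult: %d samples in %d groups (%s, %s)\n",
              length(object@labels), object@k, object@linkageMethod,
              object@distanceMetric))
  cat("  sizes:", paste(sprintf("g%s=%d", names(tab), tab), collapse = " "),
      "\n")
})
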