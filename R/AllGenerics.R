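# Accessor generics for the S4 containers.

#' @rdname Spectrum-class
#' @param x a Spectrum
#' @export
setGeneric("spectrumId", function(x) standardGeneric("spectrumId"))
#' @rdname Spectrum-class
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))
#' @rdname Spectrum-class
#' @export
setGeneric("peakMatrix", function(x) standardGeneric("peakMatrix"))
#' @rdname Spectrum-class
#' @export
setGeneric("retentionTime", function(x) standardGeneric("retentionTime"))
#' @rdname Spectrum-class
#' @export
setGeneric("compoundName", function(x) standardGeneric("compoundName"))
#' @rdname Spectrum-class
#' @export
setGeneric("spectrumCharge", function(x) standardGeneric("spectrumCharge"))

#' @rdname Spectrum-class
#' @export
setMethod("spectrumId", "Spectrum", function(x) x@spectrumId)
#' @rdname Spectrum-class
#' @export
setMethod("precursorMz", "Spectrum", function(x) x@precursorMz)
#' @rdname Spectrum-class
#' @export
setMethod("peakMatrix", "Spectrum", function(x) x@peaks)
#' @rdname Spectrum-class
#' @export
setMethod("retentionTime", "Spectrum", function(x) x@retentionTime)
#' @rdname Spectrum-class
#' @export
setMethod("compoundName", "Spectrum", function(x) x@compoundName)
#' @rdname Spectrum-class
#' @export
setMethod("spectrumCharge", "Spectrum", function(x) x@charge)

#' @rdname DrugLibrary-class
#' @param x a DrugLibrary
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))
#' @rdname DrugLibrary-class
#' @export
setMethod("drugIds", "DrugLibrary", function(x) names(x@records))

#' @rdname DrugLibrary-class
#' @export
setGeneric("drugRecords", function(x) standardGeneric("drugRecords"))
#' @rdname DrugLibrary-class
#' @export
setMethod("drugRecords", "DrugLibrary", function(x) x@records)

#' @rdname DrugLibrary-class
#' @export
setGeneric("drugMeta", function(x) standardGeneric("drugMeta"))
#' @rdname DrugLibrary-class
#' @export
setMethod("drugMeta", "DrugLibrary", function(x) x@pharmMeta)

#' All reference spectra of a DrugLibrary
#'
#' @param x a DrugLibrary
#' @param recordType optional filter: "drug", "metabolite" or NULL for all.
#' @return named list of [Spectrum-class]; names are spectrum ids. The
#'   attribute \code{drugId} maps each spectrum to its record.
#' @export
librarySpectra <- function(x, recordType = NULL) {
  recs <- x@records
  if (!is.null(recordType))
    recs <- Filter(function(r) r@recordType %in% recordType, recs)
  sp <- unlist(lapply(recs, function(r) r@spectra), use.names = FALSE)
  if (is.null(sp)) sp <- list()
  ids <- vapply(sp, spectrumId, character(1))
  owner <- unlist(lapply(recs, function(r)
    rep(r@drugId, length(r@spectra))), use.names = FALSE)
  names(sp) <- ids
  attr(sp, "drugId") <- setNames(owner, ids)
  sp
}

#' Resolve a record to its parent drug id
#'
#' Metabolite records resolve to their parent drug; drug records resolve to
#' themselves.
#' @param library a DrugLibrary
#' @param drugId record identifier(s)
#' @return character vector of parent drug ids
#' @export
parentDrugId <- function(library, drugId) {
  vapply(drugId, function(id) {
    r <- library@records[[id]]
    if (is.null(r)) return(NA_character_)
    if (r@recordType == "metabolite" && !is.na(r@parentDrugId))
      r@parentDrugId else r@drugId
  }, character(1))
}

#' Exposure sources of a record, resolved through the metadata map
#'
#' Records without metadata are treated as medical-only (conservative: they
#' stay eligible for analog propagation and exposure readout) and flagged by
#' the caller where the distinction matters.
#' @param library a DrugLibrary
#' @param drugId record identifier
#' @return character vector of exposure sources
#' @export
exposureSources <- function(library, drugId) {
  m <- library@pharmMeta[[drugId]]
  if (is.null(m) || length(m@exposureSource) == 0L) "medical"
  else m@exposureSource
}
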