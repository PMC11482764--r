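# Cosine / modified-cosine MS/MS similarity, analog search, greedy
# spectral clustering.

# Candidate fragment-peak pairs between two peak lists: unshifted pairs
# within tolerance, plus (for modified cosine) pairs within tolerance after
# adding the precursor difference to the first spectrum. A pair eligible
# both ways counts as unshifted.
.pairCandidates <- function(mza, mzb, shift, tol) {
  du <- abs(outer(mza, mzb, "-"))
  un <- which(du <= tol, arr.ind = TRUE)
  i <- un[, 1L]; j <- un[, 2L]; shifted <- rep(FALSE, nrow(un))
  if (abs(shift) > 1e-9) {
    ds <- abs(outer(mza + shift, mzb, "-"))
    sh <- which(ds <= tol, arr.ind = TRUE)
    if (nrow(sh)) {
      new <- !(paste(sh[, 1L], sh[, 2L]) %in% paste(i, j))
      i <- c(i, sh[new, 1L]); j <- c(j, sh[new, 2L])
      shifted <- c(shifted, rep(TRUE, sum(new)))
    }
  }
  list(i = i, j = j, shifted = shifted)
}

# Greedy one-to-one assignment of candidate pairs by descending scaled
# intensity product (ties by query then target index, for determinism).
.greedyAssign <- function(cand, wa, wb) {
  if (!length(cand$i))
    return(list(i = integer(), j = integer(), shifted = logical()))
  p <- wa[cand$i] * wb[cand$j]
  ord <- order(-p, cand$i, cand$j)
  usedA <- logical(length(wa)); usedB <- logical(length(wb))
  keep <- integer()
  for (k in ord) {
    ii <- cand$i[k]; jj <- cand$j[k]
    if (!usedA[ii] && !usedB[jj]) {
      usedA[ii] <- TRUE; usedB[jj] <- TRUE
      keep <- c(keep, k)
    }
  }
  list(i = cand$i[keep], j = cand$j[keep], shifted = cand$shifted[keep])
}

.scaleIntensity <- function(x, scaling) {
  if (scaling == "sqrt") sqrt(x) else x
}

.matchCore <- function(a, b, shift, fragmentTolerance, scaling) {
  pa <- a@peaks; pb <- b@peaks
  if (!nrow(pa) || !nrow(pb)) stop("spectra must have at least one peak")
  wa <- .scaleIntensity(pa[, 2L], scaling)
  wb <- .scaleIntensity(pb[, 2L], scaling)
  cand <- .pairCandidates(pa[, 1L], pb[, 1L], shift, fragmentTolerance)
  asg <- .greedyAssign(cand, wa, wb)
  num <- sum(wa[asg$i] * wb[asg$j])
  denom <- sqrt(sum(wa^2)) * sqrt(sum(wb^2))
  score <- if (denom > 0) num / denom else 0
  score <- min(max(score, 0), 1)
  data.frame(query_id = a@spectrumId, target_id = b@spectrumId,
             score = score, matched_peaks = length(asg$i),
             shifted_matches = sum(asg$shifted),
             precursor_delta = b@precursorMz - a@precursorMz,
             stringsAsFactors = FALSE)
}

#' Cosine spectral similarity
#'
#' Fragment peaks are paired one-to-one within the tolerance, greedily by
#' descending intensity product, and the score is the normalised dot
#' product of the paired (by default square-root-scaled) intensities.
#' Square-root scaling dampens base-peak dominance, the common practice in
#' molecular-networking workflows; \code{scaling = "none"} gives the plain
#' dot product.
#'
#' @param a,b [Spectrum-class] objects, non-empty.
#' @param fragmentTolerance fragment m/z tolerance in Da (default 0.01).
#' @param scaling "sqrt" (default) or "none".
#' @return one-row data.frame: query_id, target_id, score, matched_peaks,
#'   shifted_matches (always 0 here), precursor_delta (target - query).
#' @export
cosineSimilarity <- function(a, b, fragmentTolerance = 0.01,
                             scaling = c("sqrt", "none")) {
  scaling <- match.arg(scaling)
  .matchCore(a, b, shift = 0, fragmentTolerance, scaling)
}

#' Modified-cosine spectral similarity
#'
#' Like [cosineSimilarity()], but fragment pairs may also match after
#' shifting the query fragment by the precursor difference
#' Delta = precursor(b) - precursor(a). This lets a compound align with its
#' structural analog: fragments retaining the unmodified substructure match
#' unshifted, fragments carrying the modification match shifted. With
#' Delta = 0 the result reduces exactly to the cosine similarity.
#'
#' @inheritParams cosineSimilarity
#' @return one-row data.frame as in [cosineSimilarity()];
#'   \code{shifted_matches} counts peak pairs matched under the shift.
#' @export
modifiedCosine <- function(a, b, fragmentTolerance = 0.01,
                           scaling = c("sqrt", "none")) {
  scaling <- match.arg(scaling)
  if (is.na(a@precursorMz) || is.na(b@precursorMz))
    stop("modified cosine requires precursor m/z on both spectra")
  .matchCore(a, b, shift = b@precursorMz - a@precursorMz,
             fragmentTolerance, scaling)
}

#' Analog search of library spectra against a corpus
#'
#' Scores every (query, corpus) pair with the modified cosine and keeps
#' pairs that clear the score and matched-peak thresholds and differ in
#' precursor mass by at least \code{minPrecursorDelta} (same-mass hits are
#' library matches, not analogs). Results are sorted by descending score,
#' ties broken by (query_id, target_id), so the output is invariant to
#' corpus input order.
#'
#' @param queries a [DrugLibrary-class] (all its spectra are queried and a
#'   \code{drug_id} column is added) or a list of [Spectrum-class].
#' @param corpus list of [Spectrum-class] to search.
#' @param minPrecursorDelta minimum |precursor difference| in Da (default
#'   0.5).
#' @param scoreThreshold minimum modified-cosine score (default 0.7).
#' @param minMatchedPeaks minimum matched fragment pairs (default 6).
#' @param fragmentTolerance fragment m/z tolerance in Da (default 0.01).
#' @return data.frame of match results (possibly zero rows).
#' @export
analogSearch <- function(queries, corpus, minPrecursorDelta = 0.5,
                         scoreThreshold = 0.7, minMatchedPeaks = 6L,
                         fragmentTolerance = 0.01) {
  stopifnot(minPrecursorDelta > 0, scoreThreshold > 0, minMatchedPeaks > 0)
  drugOf <- NULL
  if (is(queries, "DrugLibrary")) {
    qsp <- librarySpectra(queries)
    drugOf <- attr(qsp, "drugId")
  } else qsp <- queries
  rows <- vector("list", 0L)
  for (q in qsp) {
    for (s in corpus) {
      if (abs(s@precursorMz - q@precursorMz) < minPrecursorDelta) next
      r <- modifiedCosine(q, s, fragmentTolerance)
      if (r$score >= scoreThreshold && r$matched_peaks >= minMatchedPeaks)
        rows[[length(rows) + 1L]] <- r
    }
  }
  if (!length(rows)) {
    out <- data.frame(query_id = character(), target_id = character(),
                      score = numeric(), matched_peaks = integer(),
                      shifted_matches = integer(),
                      precursor_delta = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(-out$score, out$query_id, out$target_id), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(drugOf)) out$drug_id <- unname(drugOf[out$query_id])
  out
}

#' Greedy centroid clustering of spectra
#'
#' Spectra are visited by descending total intensity (ties by spectrum id).
#' Each spectrum joins the first existing cluster whose representative is
#' within \code{precursorTolerance} of its precursor and scores at least
#' \code{scoreThreshold} by cosine; otherwise it founds a new cluster. The
#' representative is the member with the highest summed intensity (the
#' founder, by the visiting order), making the procedure deterministic.
#'
#' @param spectra list of [Spectrum-class].
#' @param scoreThreshold cosine threshold to join a cluster (default 0.7).
#' @param fragmentTolerance fragment m/z tolerance in Da (default 0.01).
#' @param precursorTolerance maximum precursor difference within a cluster
#'   in Da (default 0.01).
#' @return data.frame with columns cluster_id, member_id,
#'   is_representative; attribute \code{representatives} maps cluster_id to
#'   the representative spectrum id.
#' @export
clusterSpectra <- function(spectra, scoreThreshold = 0.7,
                           fragmentTolerance = 0.01,
                           precursorTolerance = 0.01) {
  if (!length(spectra))
    return(structure(data.frame(cluster_id = character(),
                                member_id = character(),
                                is_representative = logical()),
                     representatives = character()))
  tot <- vapply(spectra, function(s) sum(s@peaks[, 2L]), numeric(1))
  ids <- vapply(spectra, spectrumId, character(1))
  ord <- order(-tot, ids)
  reps <- list()          # representative Spectrum per cluster
  members <- list()       # member spectrum ids per cluster
  for (k in ord) {
    s <- spectra[[k]]
    placed <- FALSE
    for (ci in seq_along(reps)) {
      r <- reps[[ci]]
      if (abs(r@precursorMz - s@precursorMz) > precursorTolerance) next
      sc <- cosineSimilarity(r, s, fragmentTolerance)$score
      if (sc >= scoreThreshold) {
        members[[ci]] <- c(members[[ci]], s@spectrumId)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- s
      members[[length(members) + 1L]] <- s@spectrumId
    }
  }
  cid <- sprintf("cluster_%03d", seq_along(members))
  df <- do.call(rbind, lapply(seq_along(members), function(ci) {
    data.frame(cluster_id = cid[ci], member_id = members[[ci]],
               is_representative = members[[ci]] ==
                 reps[[ci]]@spectrumId,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  attr(df, "representatives") <- setNames(
    vapply(reps, spectrumId, character(1)), cid)
  df
}
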