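# Five-filter curation cascade for propagated drug analogs:
# exposure source -> curated delta-mass list -> known-library match ->
# structural similarity of shared parents -> background-cohort prevalence;
# plus retention-time-based in-source-fragment flagging.

#' Configuration for analog propagation and curation
#'
#' All thresholds of the propagation/curation workflow in one place.
#' Defaults follow conventional molecular-networking practice: modified
#' cosine >= 0.7 with >= 6 matched fragment peaks at 0.01 Da fragment
#' tolerance; candidate analogs must differ from their parent by at least
#' 0.5 Da of precursor mass; mass offsets match the curated list within
#' 0.01 Da and must recur at least \code{minOffsetOccurrence} times across
#' the run (10 at repository scale; scale down for small corpora); shared
#' analogs require pairwise parent Tanimoto >= 0.5; in-source-fragment
#' flagging uses a 0.1 min retention-time tolerance (a typical UHPLC peak
#' width).
#'
#' @param scoreThreshold minimum modified-cosine score.
#' @param minMatchedPeaks minimum matched fragment pairs.
#' @param fragmentTolerance fragment m/z tolerance (Da).
#' @param precursorTolerance precursor m/z tolerance for clustering and
#'   library matching (Da).
#' @param minPrecursorDelta minimum |precursor difference| for an analog
#'   (Da).
#' @param deltaTolerance tolerance for matching offsets to the curated list
#'   (Da).
#' @param minOffsetOccurrence minimum run-wide occurrences of a matched
#'   offset.
#' @param tanimotoThreshold minimum pairwise parent fingerprint similarity
#'   for shared analogs.
#' @param rtTolerance retention-time tolerance for in-source-fragment
#'   flagging (minutes).
#' @return named list of thresholds.
#' @export
analogConfig <- function(scoreThreshold = 0.7, minMatchedPeaks = 6L,
                         fragmentTolerance = 0.01, precursorTolerance = 0.01,
                         minPrecursorDelta = 0.5, deltaTolerance = 0.01,
                         minOffsetOccurrence = 10L, tanimotoThreshold = 0.5,
                         rtTolerance = 0.1) {
  list(scoreThreshold = scoreThreshold, minMatchedPeaks = minMatchedPeaks,
       fragmentTolerance = fragmentTolerance,
       precursorTolerance = precursorTolerance,
       minPrecursorDelta = minPrecursorDelta,
       deltaTolerance = deltaTolerance,
       minOffsetOccurrence = as.integer(minOffsetOccurrence),
       tanimotoThreshold = tanimotoThreshold, rtTolerance = rtTolerance)
}

#' Tanimoto similarity of two bit-vector fingerprints
#'
#' Intersection over union of the set bits. Accepts logical or 0/1 numeric
#' vectors of equal length (e.g. circular fingerprints folded to a fixed
#' width).
#'
#' @param a,b fingerprint vectors.
#' @return similarity in [0, 1]; two all-zero fingerprints score 0.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

.newCandidate <- function(spectrum, clusterId, memberIds, parents) {
  list(analog_spectrum_id = spectrum@spectrumId, spectrum = spectrum,
       cluster_id = clusterId, member_ids = memberIds, parents = parents,
       filter_status = data.frame(filter = character(), status = character(),
                                  reason = character(),
                                  stringsAsFactors = FALSE),
       in_source_fragment = FALSE)
}

.markStatus <- function(cand, filter, status, reason = "") {
  cand$filter_status <- rbind(cand$filter_status,
                              data.frame(filter = filter, status = status,
                                         reason = reason,
                                         stringsAsFactors = FALSE))
  cand
}

.splitCandidates <- function(cands, keep, failed) {
  out <- cands[keep]
  attr(out, "failures") <- cands[failed]
  out
}

#' Form analog candidates from raw analog-search matches
#'
#' Clusters the matched corpus spectra ([clusterSpectra()]) and forms one
#' candidate per cluster, listing every connected parent drug (metabolite
#' query records resolve to their parent drug) with the best-scoring match
#' and its precursor delta.
#'
#' @param rawMatches data.frame from [analogSearch()] run with a
#'   [DrugLibrary-class] (carries \code{drug_id}).
#' @param library the query [DrugLibrary-class].
#' @param corpus the searched list of [Spectrum-class].
#' @param config an [analogConfig()] list.
#' @return list of analog candidates (opaque; consumed by the filters).
#' @export
formAnalogCandidates <- function(rawMatches, library, corpus,
                                 config = analogConfig()) {
  if (!nrow(rawMatches)) return(list())
  corpusIds <- vapply(corpus, spectrumId, character(1))
  names(corpus) <- corpusIds
  targets <- unique(rawMatches$target_id)
  clu <- clusterSpectra(corpus[targets],
                        scoreThreshold = config$scoreThreshold,
                        fragmentTolerance = config$fragmentTolerance,
                        precursorTolerance = config$precursorTolerance)
  reps <- attr(clu, "representatives")
  rawMatches$parent <- unname(parentDrugId(library, rawMatches$drug_id))
  memberCluster <- setNames(clu$cluster_id, clu$member_id)
  cands <- lapply(names(reps), function(cid) {
    memb <- clu$member_id[clu$cluster_id == cid]
    rows <- rawMatches[rawMatches$target_id %in% memb, , drop = FALSE]
    parents <- list()
    for (p in sort(unique(rows$parent))) {
      pr <- rows[rows$parent == p, , drop = FALSE]
      best <- pr[which.max(pr$score), , drop = FALSE]
      parents[[p]] <- list(delta = best$precursor_delta,
                           score = best$score,
                           matched_peaks = best$matched_peaks,
                           n_matches = nrow(pr),
                           interpretation = NA_character_,
                           matched_delta = NA_real_)
    }
    .newCandidate(corpus[[reps[[cid]]]], cid, memb, parents)
  })
  cands
}

#' Exposure-source filter
#'
#' Analogs are only propagated from compounds whose exposure is
#' unambiguously medical: parents with endogenous or dietary (food)
#' exposure sources are removed from the candidate's parent list, and
#' candidates left without parents fail. Parents lacking metadata are
#' treated as medical-only and logged.
#'
#' @param candidates list of candidates from [formAnalogCandidates()].
#' @param library a [DrugLibrary-class] with metadata.
#' @return surviving candidates; failures in \code{attr(, "failures")},
#'   parents without metadata in \code{attr(, "no_metadata")}.
#' @export
filterBySource <- function(candidates, library) {
  noMeta <- character()
  keep <- logical(length(candidates))
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    drop <- character()
    for (p in names(cand$parents)) {
      if (is.null(library@pharmMeta[[p]])) noMeta <- c(noMeta, p)
      src <- exposureSources(library, p)
      if (length(intersect(src, c("endogenous", "food"))))
        drop <- c(drop, p)
    }
    cand$parents[drop] <- NULL
    if (length(cand$parents)) {
      cand <- .markStatus(cand, "source", "pass",
                          if (length(drop))
                            paste("removed parents:",
                                  paste(drop, collapse = ";")) else "")
      keep[k] <- TRUE
    } else {
      cand <- .markStatus(cand, "source", "fail",
                          "all parents endogenous/food-sourced")
    }
    candidates[[k]] <- cand
  }
  out <- .splitCandidates(candidates, keep, !keep)
  attr(out, "no_metadata") <- unique(noMeta)
  out
}

#' Curated delta-mass filter
#'
#' Each candidate-parent precursor offset must match the curated
#' delta-mass list (sign-sensitive, within \code{tolerance}), and the
#' matched list entry must recur at least \code{minOffsetOccurrence} times
#' across all surviving candidate-parent pairs of the run. Failing pairs
#' are removed; candidates left without parents fail. Surviving pairs gain
#' the matched offset's interpretation.
#'
#' @param candidates candidate list.
#' @param deltaList data.frame from [readDeltaMassList()].
#' @param tolerance matching tolerance (Da).
#' @param minOffsetOccurrence minimum run-wide occurrence count.
#' @return surviving candidates; failures in \code{attr(, "failures")}.
#' @export
filterByDeltaMass <- function(candidates, deltaList, tolerance = 0.01,
                              minOffsetOccurrence = 10L) {
  stopifnot(minOffsetOccurrence >= 1L)
  # pass 1: list membership
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    for (p in names(cand$parents)) {
      hit <- matchDeltaMass(cand$parents[[p]]$delta, deltaList, tolerance)
      if (nrow(hit)) {
        cand$parents[[p]]$matched_delta <- hit$delta_mass[[1L]]
        cand$parents[[p]]$interpretation <- hit$interpretation[[1L]]
      } else cand$parents[p] <- list(NULL)
    }
    cand$parents <- Filter(Negate(is.null), cand$parents)
    candidates[[k]] <- cand
  }
  # pass 2: run-wide occurrence of the matched offsets
  offs <- unlist(lapply(candidates, function(cand)
    vapply(cand$parents, function(pp) pp$matched_delta, numeric(1))),
    use.names = FALSE)
  occ <- table(sprintf("%.6f", offs))
  keep <- logical(length(candidates))
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    for (p in names(cand$parents)) {
      key <- sprintf("%.6f", cand$parents[[p]]$matched_delta)
      if (occ[[key]] < minOffsetOccurrence) cand$parents[p] <- list(NULL)
    }
    cand$parents <- Filter(Negate(is.null), cand$parents)
    if (length(cand$parents)) {
      cand <- .markStatus(cand, "delta_mass", "pass")
      keep[k] <- TRUE
    } else {
      cand <- .markStatus(cand, "delta_mass", "fail",
                          "offset not in curated list or below occurrence threshold")
    }
    candidates[[k]] <- cand
  }
  .splitCandidates(candidates, keep, !keep)
}

#' Known-library match filter
#'
#' A candidate whose representative spectrum matches a known library
#' spectrum at the same precursor mass is a known compound, not a new
#' analog (drugs of one pharmacologic family are often analogs of each
#' other), and would otherwise overwrite a proper library annotation. Such
#' candidates fail, with the matched compound recorded.
#'
#' @param candidates candidate list.
#' @param library a [DrugLibrary-class]; all its spectra are the known set.
#' @param scoreThreshold,minMatchedPeaks,fragmentTolerance,precursorTolerance
#'   matching thresholds as in [analogConfig()].
#' @return surviving candidates; failures in \code{attr(, "failures")}.
#' @export
filterByLibraryMatch <- function(candidates, library, scoreThreshold = 0.7,
                                 minMatchedPeaks = 6L,
                                 fragmentTolerance = 0.01,
                                 precursorTolerance = 0.01) {
  known <- librarySpectra(library)
  knownPrec <- vapply(known, precursorMz, numeric(1))
  keep <- logical(length(candidates))
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    s <- cand$spectrum
    near <- which(abs(knownPrec - s@precursorMz) <= precursorTolerance)
    hitName <- NULL
    for (j in near) {
      r <- cosineSimilarity(s, known[[j]], fragmentTolerance)
      if (r$score >= scoreThreshold && r$matched_peaks >= minMatchedPeaks) {
        rec <- library@records[[attr(known, "drugId")[[spectrumId(known[[j]])]]]]
        hitName <- rec@primaryName
        break
      }
    }
    if (is.null(hitName)) {
      candidates[[k]] <- .markStatus(cand, "library_match", "pass")
      keep[k] <- TRUE
    } else {
      candidates[[k]] <- .markStatus(cand, "library_match", "fail",
                                     paste("library match:", hitName))
    }
  }
  .splitCandidates(candidates, keep, !keep)
}

#' Shared-analog structural-similarity filter
#'
#' An analog spectrum connected to several drugs is only credible when the
#' drugs share a core structure (e.g. one analog bridging a piperazine
#' drug and its chlorinated/demethylated relative); a candidate with two or
#' more parents passes only if every parent pair has Tanimoto similarity at
#' least the threshold, and fails otherwise (conservative: no parent
#' re-assignment). Single-parent candidates pass unchanged. Multi-parent
#' candidates with a missing fingerprint go to the review list, not
#' auto-passed.
#'
#' @param candidates candidate list.
#' @param fingerprints named list of bit-vector fingerprints keyed by drug
#'   id.
#' @param tanimotoThreshold minimum pairwise similarity (default 0.5).
#' @return surviving candidates; failures in \code{attr(, "failures")},
#'   unresolved candidates in \code{attr(, "review")}.
#' @export
filterSharedAnalogs <- function(candidates, fingerprints,
                                tanimotoThreshold = 0.5) {
  keep <- logical(length(candidates))
  review <- logical(length(candidates))
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    ps <- names(cand$parents)
    if (length(ps) < 2L) {
      candidates[[k]] <- .markStatus(cand, "shared_analog", "pass",
                                     "single parent")
      keep[k] <- TRUE
      next
    }
    if (!all(ps %in% names(fingerprints))) {
      candidates[[k]] <- .markStatus(cand, "shared_analog", "flag",
                                     "missing fingerprint; sent to review")
      review[k] <- TRUE
      next
    }
    pairs <- utils::combn(ps, 2L)
    sims <- apply(pairs, 2L, function(pq)
      tanimoto(fingerprints[[pq[1L]]], fingerprints[[pq[2L]]]))
    if (all(sims >= tanimotoThreshold)) {
      candidates[[k]] <- .markStatus(cand, "shared_analog", "pass")
      keep[k] <- TRUE
    } else {
      candidates[[k]] <- .markStatus(
        cand, "shared_analog", "fail",
        sprintf("min pairwise Tanimoto %.3f < %.3f", min(sims),
                tanimotoThreshold))
    }
  }
  out <- .splitCandidates(candidates, keep, !keep & !review)
  attr(out, "review") <- candidates[review]
  out
}

.detectionFrequency <- function(spectrum, cohort, scoreThreshold,
                                minMatchedPeaks, fragmentTolerance,
                                precursorTolerance) {
  fs <- featureSpectra(cohort)
  if (is.null(fs)) return(NA_real_)
  prec <- vapply(fs, precursorMz, numeric(1))
  near <- names(fs)[abs(prec - spectrum@precursorMz) <= precursorTolerance]
  hits <- character()
  for (fid in near) {
    r <- cosineSimilarity(spectrum, fs[[fid]], fragmentTolerance)
    if (r$score >= scoreThreshold && r$matched_peaks >= minMatchedPeaks)
      hits <- c(hits, fid)
  }
  if (!length(hits)) return(0)
  areas <- peakAreas(cohort)[, intersect(hits, featureIds(cohort)),
                             drop = FALSE]
  mean(rowSums(areas) > 0)
}

#' Background-prevalence filter
#'
#' An analog detected in most samples of a general background cohort
#' (e.g. population-scale feces or milk) cannot plausibly indicate
#' drug exposure -- such signals are ubiquitous contaminants or
#' endogenous-like chemistry. A candidate fails when its detection
#' frequency in any background cohort exceeds that cohort's own threshold
#' (detection = spectral match of the analog to a nonzero feature at the
#' annotation thresholds). Cohorts without feature spectra are skipped with
#' a warning.
#'
#' @param candidates candidate list.
#' @param backgroundCohorts list of \code{list(table = CohortFeatureTable,
#'   threshold = fraction)} pairs (e.g. 0.5 for general-population feces,
#'   0.7 for milk).
#' @param scoreThreshold,minMatchedPeaks,fragmentTolerance,precursorTolerance
#'   annotation thresholds.
#' @return surviving candidates; failures in \code{attr(, "failures")}.
#' @export
filterByBackgroundPrevalence <- function(candidates, backgroundCohorts,
                                         scoreThreshold = 0.7,
                                         minMatchedPeaks = 6L,
                                         fragmentTolerance = 0.01,
                                         precursorTolerance = 0.01) {
  usable <- vapply(backgroundCohorts, function(bg)
    !is.null(featureSpectra(bg$table)), logical(1))
  for (bi in which(!usable))
    warning(sprintf("background cohort %d has no feature spectra; skipped",
                    bi))
  keep <- rep(TRUE, length(candidates))
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    reason <- ""
    for (bi in which(usable)) {
      bg <- backgroundCohorts[[bi]]
      freq <- .detectionFrequency(cand$spectrum, bg$table, scoreThreshold,
                                  minMatchedPeaks, fragmentTolerance,
                                  precursorTolerance)
      if (is.na(freq)) next
      if (freq > bg$threshold) {
        keep[k] <- FALSE
        reason <- sprintf("detected in %.0f%% of background cohort %d (threshold %.0f%%)",
                          100 * freq, bi, 100 * bg$threshold)
        break
      }
    }
    candidates[[k]] <- .markStatus(cand, "background_prevalence",
                                   if (keep[k]) "pass" else "fail", reason)
  }
  .splitCandidates(candidates, keep, !keep)
}

#' Flag in-source fragments by retention-time overlap
#'
#' An analog that always co-elutes with its parent drug and has a lower
#' precursor mass is most likely an in-source fragment of the parent, not a
#' metabolite. Entries are flagged (retained, never deleted -- their
#' indication of drug exposure is unchanged) when, across samples where
#' both are detected, the median |RT(analog) - RT(parent)| is within the
#' tolerance and the analog's mass offset is negative.
#'
#' @param entries data.frame of analog-library entries from
#'   [buildAnalogLibrary()].
#' @param parentDetections named list, drug id -> data.frame(sample, rt)
#'   (rt in minutes).
#' @param analogDetections named list, analog id -> data.frame(sample, rt).
#' @param rtTolerance co-elution tolerance in minutes (default 0.1).
#' @return \code{entries} with \code{in_source_fragment} updated; entries
#'   with no co-detections stay unflagged and are listed in
#'   \code{attr(, "indeterminate")}.
#' @export
flagInSourceFragments <- function(entries, parentDetections,
                                  analogDetections, rtTolerance = 0.1) {
  indeterminate <- character()
  for (k in seq_len(nrow(entries))) {
    aid <- entries$analog_id[[k]]
    pid <- entries$parent_drug_id[[k]]
    ad <- analogDetections[[aid]]
    pd <- parentDetections[[pid]]
    if (is.null(ad) || is.null(pd)) {
      indeterminate <- c(indeterminate, aid)
      next
    }
    co <- merge(ad, pd, by = "sample", suffixes = c("_analog", "_parent"))
    if (!nrow(co)) {
      indeterminate <- c(indeterminate, aid)
      next
    }
    medDiff <- median(abs(co$rt_analog - co$rt_parent))
    entries$in_source_fragment[[k]] <-
      medDiff <= rtTolerance && entries$delta_mass[[k]] < 0
  }
  attr(entries, "indeterminate") <- indeterminate
  entries
}

.emptyAttrition <- function() {
  data.frame(stage = c("input", "fail_source", "fail_delta_mass",
                       "fail_library_match", "fail_shared_analog",
                       "review_shared_analog", "fail_background_prevalence",
                       "output"),
             count = 0L, stringsAsFactors = FALSE)
}

#' Build the curated analog library
#'
#' Runs the full propagation cascade: clusters the raw analog matches,
#' forms candidates, applies the five filters in their fixed order
#' (source, delta mass, library match, shared analog, background
#' prevalence -- each candidate is attributed to its first failing
#' filter), attaches the curated delta interpretations, and emits one
#' library entry per surviving candidate-parent pair plus a per-filter
#' attrition report.
#'
#' @param rawMatches data.frame from [analogSearch()] with \code{drug_id}.
#' @param library the query [DrugLibrary-class].
#' @param deltaList curated delta-mass data.frame.
#' @param corpus the searched spectra.
#' @param config an [analogConfig()] list.
#' @param fingerprints named list of parent fingerprints (for the
#'   shared-analog filter).
#' @param backgroundCohorts background cohort/threshold pairs (may be
#'   empty).
#' @return list with \code{entries} (data.frame: analog_id,
#'   parent_drug_id, delta_mass, delta_interpretation,
#'   in_source_fragment, cluster_size, n_matches, score),
#'   \code{spectra} (named list of representative spectra),
#'   \code{attrition} (data.frame stage/count), \code{candidates}
#'   (surviving candidate objects) and \code{review}.
#' @export
buildAnalogLibrary <- function(rawMatches, library, deltaList, corpus,
                               config = analogConfig(),
                               fingerprints = list(),
                               backgroundCohorts = list()) {
  att <- .emptyAttrition()
  emptyEntries <- data.frame(
    analog_id = character(), parent_drug_id = character(),
    delta_mass = numeric(), delta_interpretation = character(),
    in_source_fragment = logical(), cluster_size = integer(),
    n_matches = integer(), score = numeric(), stringsAsFactors = FALSE)
  if (!nrow(rawMatches))
    return(list(entries = emptyEntries, spectra = list(), attrition = att,
                candidates = list(), review = list()))
  cands <- formAnalogCandidates(rawMatches, library, corpus, config)
  att$count[att$stage == "input"] <- length(cands)

  s1 <- filterBySource(cands, library)
  att$count[att$stage == "fail_source"] <- length(attr(s1, "failures"))
  s2 <- filterByDeltaMass(s1, deltaList, tolerance = config$deltaTolerance,
                          minOffsetOccurrence = config$minOffsetOccurrence)
  att$count[att$stage == "fail_delta_mass"] <- length(attr(s2, "failures"))
  s3 <- filterByLibraryMatch(s2, library,
                             scoreThreshold = config$scoreThreshold,
                             minMatchedPeaks = config$minMatchedPeaks,
                             fragmentTolerance = config$fragmentTolerance,
                             precursorTolerance = config$precursorTolerance)
  att$count[att$stage == "fail_library_match"] <- length(attr(s3, "failures"))
  s4 <- filterSharedAnalogs(s3, fingerprints,
                            tanimotoThreshold = config$tanimotoThreshold)
  att$count[att$stage == "fail_shared_analog"] <- length(attr(s4, "failures"))
  att$count[att$stage == "review_shared_analog"] <- length(attr(s4, "review"))
  s5 <- filterByBackgroundPrevalence(
    s4, backgroundCohorts, scoreThreshold = config$scoreThreshold,
    minMatchedPeaks = config$minMatchedPeaks,
    fragmentTolerance = config$fragmentTolerance,
    precursorTolerance = config$precursorTolerance)
  att$count[att$stage == "fail_background_prevalence"] <-
    length(attr(s5, "failures"))
  att$count[att$stage == "output"] <- length(s5)

  survivors <- s5
  attributes(survivors) <- NULL
  rows <- list()
  spectra <- list()
  for (cand in survivors) {
    spectra[[cand$analog_spectrum_id]] <- cand$spectrum
    for (p in names(cand$parents)) {
      pp <- cand$parents[[p]]
      rows[[length(rows) + 1L]] <- data.frame(
        analog_id = cand$analog_spectrum_id, parent_drug_id = p,
        delta_mass = pp$matched_delta,
        delta_interpretation = pp$interpretation,
        in_source_fragment = FALSE,
        cluster_size = length(cand$member_ids),
        n_matches = pp$n_matches, score = pp$score,
        stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else emptyEntries
  rownames(entries) <- NULL
  list(entries = entries, spectra = spectra, attrition = att,
       candidates = survivors, review = attr(s4, "review"))
}

#' Export the curated analog library
#'
#' Representative spectra as MGF plus the entry table and attrition report
#' as TSV.
#'
#' @param analogLibrary result of [buildAnalogLibrary()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
exportAnalogLibrary <- function(analogLibrary, dir,
                                prefix = "analog_library") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(entries = file.path(dir, paste0(prefix, ".tsv")),
             attrition = file.path(dir, paste0(prefix, "_attrition.tsv")))
  write.table(analogLibrary$entries, paths[["entries"]], sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(analogLibrary$attrition, paths[["attrition"]], sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (length(analogLibrary$spectra)) {
    paths[["mgf"]] <- file.path(dir, paste0(prefix, ".mgf"))
    writeMGF(analogLibrary$spectra, paths[["mgf"]])
  }
  invisible(paths)
}
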