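# Synthetic drug libraries, analog corpora and cohorts with planted ground
# truth, so every pipeline stage is testable without repository downloads.
# Deterministic under a fixed seed; every planted fact is returned in an
# answer key.

#' Specification for the synthetic fixture suite
#'
#' Defines the study conditions the generators emulate. The defaults are
#' the standard planted-truth design: 8 true analogs carrying curated
#' offsets (methylation +14.0157, oxidation +15.9949), 4 analogs of
#' endogenous/food-sourced compounds, 3 off-list offsets, 2 known-drug
#' decoys (a drug pair whose members are each other's methylation analog,
#' mimicking same-family ACE-inhibitor pairs), 1 analog shared by two
#' structurally dissimilar isobaric drugs, 1 background-ubiquitous analog,
#' and 100 noise spectra; plus a 60-sample cohort drawn from 3 disjoint
#' treatment-regimen templates. Planted effects sit far from the default
#' decision thresholds (full-spectrum matches score near 1 against a 0.7
#' cutoff; offsets are exact list values against a 0.01 Da tolerance), so
#' tests are not threshold-knife-edge. \code{minOffsetOccurrence = 2}
#' scales the repository-scale recurrence rule (10) down to the fixture's
#' ~20 candidate-parent pairs.
#'
#' @param seed integer RNG seed; fixed seed implies byte-identical outputs.
#' @param nDrugs number of synthetic drugs (>= 22 for the full role set).
#' @param nMetabolitesPerDrug metabolite records generated per drug.
#' @param nEndogenous number of drugs given endogenous/food sources.
#' @param peakRange range of fragment-peak counts per spectrum.
#' @param peakJitterSd Gaussian m/z jitter (Da) applied to corpus/feature
#'   spectra.
#' @param nTrueAnalogs,nOfflistAnalogs,nKnownDecoys,nSharedDissimilar,nBackgroundUbiquitous
#'   planted corpus composition (see Details above).
#' @param trueOffsets curated offsets used for the true analogs (must be
#'   in the shipped delta-mass list).
#' @param offlistOffsets offsets guaranteed absent from the curated list.
#' @param nNoiseSpectra number of random unrelated corpus spectra.
#' @param shiftFraction range of the fraction of peaks shifted in a
#'   planted analog.
#' @param minOffsetOccurrence fixture-scale occurrence threshold.
#' @param cohort list: nSamples, nTemplates, drugsPerTemplate, dropout,
#'   abundanceMeanlog, abundanceSdlog, nNoiseFeatures, nEndogenousVars,
#'   effectSize (in pooled SDs, applied to group 1 of the first
#'   endogenous variable).
#' @param background list: nSamples, prevalence (planted detection
#'   fraction of the ubiquitous analog), threshold (the filter's cutoff
#'   for this cohort), nNoiseFeatures.
#' @return a fixture specification list.
#' @export
fixtureSpec <- function(seed = 1L,
                        nDrugs = 24L,
                        nMetabolitesPerDrug = 1L,
                        nEndogenous = 4L,
                        peakRange = c(8L, 20L),
                        peakJitterSd = 0.002,
                        nTrueAnalogs = 8L,
                        trueOffsets = c(14.015650, 15.994915),
                        nOfflistAnalogs = 3L,
                        offlistOffsets = c(13.37, 23.456, 57.001),
                        nKnownDecoys = 2L,
                        nSharedDissimilar = 1L,
                        nBackgroundUbiquitous = 1L,
                        nNoiseSpectra = 100L,
                        shiftFraction = c(0.3, 0.7),
                        minOffsetOccurrence = 2L,
                        cohort = list(),
                        background = list()) {
  co <- utils::modifyList(list(
    nSamples = 60L, nTemplates = 3L, drugsPerTemplate = 3L, dropout = 0.1,
    abundanceMeanlog = 11, abundanceSdlog = 0.5, nNoiseFeatures = 30L,
    nEndogenousVars = 3L, effectSize = 2), cohort)
  bg <- utils::modifyList(list(
    nSamples = 40L, prevalence = 0.6, threshold = 0.5,
    nNoiseFeatures = 10L), background)
  dl <- defaultDeltaMassList()
  if (!all(trueOffsets %in% dl$delta_mass))
    stop("trueOffsets must be entries of the curated delta-mass list")
  if (any(vapply(offlistOffsets, function(o)
    nrow(matchDeltaMass(o, dl)) > 0, logical(1))))
    stop("offlistOffsets must not match the curated delta-mass list")
  list(seed = as.integer(seed), nDrugs = as.integer(nDrugs),
       nMetabolitesPerDrug = as.integer(nMetabolitesPerDrug),
       nEndogenous = as.integer(nEndogenous), peakRange = peakRange,
       peakJitterSd = peakJitterSd,
       nTrueAnalogs = as.integer(nTrueAnalogs), trueOffsets = trueOffsets,
       nOfflistAnalogs = as.integer(nOfflistAnalogs),
       offlistOffsets = offlistOffsets,
       nKnownDecoys = as.integer(nKnownDecoys),
       nSharedDissimilar = as.integer(nSharedDissimilar),
       nBackgroundUbiquitous = as.integer(nBackgroundUbiquitous),
       nNoiseSpectra = as.integer(nNoiseSpectra),
       shiftFraction = shiftFraction,
       minOffsetOccurrence = as.integer(minOffsetOccurrence),
       cohort = co, background = bg)
}

.randFormula <- function() {
  c(C = sample(12:24, 1), H = sample(seq(14L, 30L, 2L), 1),
    N = sample(0:3, 1), O = sample(0:4, 1))
}

.randSpectrum <- function(id, precursor, npeaks, name = NA_character_) {
  mz <- sort(runif(npeaks, 50, precursor - 20))
  intensity <- exp(rnorm(npeaks, 3, 1))
  Spectrum(id, precursorMz = precursor,
           peaks = cbind(mz = mz, intensity = intensity),
           compoundName = name)
}

.jitterSpectrum <- function(s, id, sd) {
  p <- s@peaks
  p[, 1L] <- p[, 1L] + rnorm(nrow(p), 0, sd)
  Spectrum(id, precursorMz = s@precursorMz, peaks = p,
           retentionTime = s@retentionTime, compoundName = s@compoundName)
}

# shift a random subset of peaks (fraction in `frac` range) and the
# precursor by `offset`, with Gaussian m/z jitter
.makeAnalog <- function(parentSpec, id, offset, frac, jitterSd) {
  p <- parentSpec@peaks
  n <- nrow(p)
  nshift <- max(1L, round(runif(1, frac[1L], frac[2L]) * n))
  idx <- sample(n, nshift)
  p[idx, 1L] <- p[idx, 1L] + offset
  p[, 1L] <- p[, 1L] + rnorm(n, 0, jitterSd)
  Spectrum(id, precursorMz = parentSpec@precursorMz + offset, peaks = p)
}

.randFingerprint <- function(nbits = 256L, density = 0.3) {
  runif(nbits) < density
}

#' Generate a synthetic drug library with answer key
#'
#' Synthetic drugs with random druglike formulas, [M+H]+ precursors,
#' random fragment spectra, per-drug metabolite records (full-spectrum
#' methylation loss of the parent), controlled-vocabulary metadata over
#' the five exposure-source classes and a small class/area vocabulary, and
#' pseudo-structure fingerprints generated directly as bit vectors with
#' controlled pairwise similarity. Role assignments for the planted corpus
#' (which drugs are endogenous, which form the known-decoy pair, the
#' dissimilar isobaric pair, the background drug) are part of the answer
#' key.
#'
#' @param spec a [fixtureSpec()] list.
#' @return list: \code{library} ([DrugLibrary-class]),
#'   \code{fingerprints} (named list of bit vectors), \code{key}
#'   (data.frame drug_id, name, role, formula mass and sources).
#' @export
generateDrugLibrary <- function(spec) {
  set.seed(spec$seed)
  n <- spec$nDrugs
  need <- spec$nTrueAnalogs + spec$nOfflistAnalogs +
    2L * spec$nKnownDecoys + 2L * spec$nSharedDissimilar +
    spec$nBackgroundUbiquitous + spec$nEndogenous
  if (n < need)
    stop(sprintf("nDrugs = %d too small for the planted role set (%d)", n,
                 need))
  ids <- sprintf("drug%02d", seq_len(n))
  names <- sprintf("syndrug%02d", seq_len(n))
  roles <- rep("plain", n)
  k <- 0L
  take <- function(m) { r <- k + seq_len(m); k <<- k + m; r }
  iTrue <- take(spec$nTrueAnalogs); roles[iTrue] <- "true_parent"
  iOff <- take(spec$nOfflistAnalogs); roles[iOff] <- "offlist_parent"
  iKnownA <- take(spec$nKnownDecoys); roles[iKnownA] <- "decoy_parent"
  iKnownB <- take(spec$nKnownDecoys); roles[iKnownB] <- "decoy_twin"
  iShared <- take(2L * spec$nSharedDissimilar); roles[iShared] <- "isobaric_pair"
  iBg <- take(spec$nBackgroundUbiquitous); roles[iBg] <- "background_parent"
  iEndo <- take(spec$nEndogenous); roles[iEndo] <- "endogenous"

  classes <- c("statin", "ACE inhibitor", "SSRI", "NSAID", "beta blocker",
               "antihistamine", "antiretroviral", "PPI")
  areas <- c("cardiology", "psychiatry", "analgesics", "allergy",
             "infectious disease", "gastroenterology")

  formulas <- replicate(n, .randFormula(), simplify = FALSE)
  masses <- vapply(formulas, monoisotopicMass, numeric(1))
  precursors <- masses + 1.007276466
  # decoy twins: exact methylation analogs of their parents
  for (j in seq_len(spec$nKnownDecoys)) {
    formulas[[iKnownB[j]]] <- formulas[[iKnownA[j]]] + c(C = 1, H = 2, N = 0, O = 0)
    precursors[iKnownB[j]] <- precursors[iKnownA[j]] + 14.015650
  }
  # isobaric pairs share formula and precursor
  for (j in seq_len(spec$nSharedDissimilar)) {
    a <- iShared[2L * j - 1L]; b <- iShared[2L * j]
    formulas[[b]] <- formulas[[a]]
    precursors[b] <- precursors[a]
  }

  records <- list()
  fingerprints <- list()
  for (i in seq_len(n)) {
    np <- sample(spec$peakRange[1L]:spec$peakRange[2L], 1L)
    sp <- .randSpectrum(sprintf("ref_%s", ids[i]), precursors[i], np,
                        name = names[i])
    if (roles[i] == "decoy_twin") {
      j <- match(i, iKnownB)
      parentSp <- records[[ids[iKnownA[j]]]]@spectra[[1L]]
      p <- parentSp@peaks
      p[, 1L] <- p[, 1L] + 14.015650
      sp <- Spectrum(sprintf("ref_%s", ids[i]), precursorMz = precursors[i],
                     peaks = p, compoundName = names[i])
    }
    if (roles[i] == "isobaric_pair" && match(i, iShared) %% 2L == 0L) {
      twin <- ids[iShared[match(i, iShared) - 1L]]
      tw <- records[[twin]]@spectra[[1L]]
      sp <- Spectrum(sprintf("ref_%s", ids[i]), precursorMz = precursors[i],
                     peaks = tw@peaks, compoundName = names[i])
    }
    records[[ids[i]]] <- DrugRecord(
      drugId = ids[i], primaryName = names[i],
      clinicalPhase = "approved", spectra = list(sp), recordType = "drug")
    fingerprints[[ids[i]]] <- .randFingerprint()
  }
  # the isobaric pair must be structurally dissimilar: near-disjoint bits
  for (j in seq_len(spec$nSharedDissimilar)) {
    a <- ids[iShared[2L * j - 1L]]; b <- ids[iShared[2L * j]]
    fp <- logical(256L); fp[1:64] <- runif(64) < 0.6
    fq <- logical(256L); fq[193:256] <- runif(64) < 0.6
    fingerprints[[a]] <- fp; fingerprints[[b]] <- fq
  }

  # metabolite records: full-spectrum demethylation of the parent
  for (i in seq_len(n)) {
    for (m in seq_len(spec$nMetabolitesPerDrug)) {
      parent <- records[[ids[i]]]
      ps <- parent@spectra[[1L]]
      p <- ps@peaks
      p[, 1L] <- pmax(p[, 1L] - 14.015650, 20)
      mid <- sprintf("%s_met%d", ids[i], m)
      records[[mid]] <- DrugRecord(
        drugId = mid, primaryName = sprintf("desmethyl%s", names[i]),
        clinicalPhase = "approved",
        spectra = list(Spectrum(sprintf("ref_%s", mid),
                                precursorMz = ps@precursorMz - 14.015650,
                                peaks = p)),
        recordType = "metabolite", parentDrugId = ids[i])
    }
  }

  meta <- list()
  for (i in seq_len(n)) {
    src <- if (roles[i] == "endogenous")
      c("medical", sample(c("endogenous", "food"), 1L)) else "medical"
    meta[[ids[i]]] <- DrugMetadata(
      ids[i], exposureSource = src,
      pharmacologicClass = sample(classes, 1L),
      therapeuticArea = sample(areas, 1L),
      therapeuticIndication = sprintf("indication_%d", sample(6L, 1L)),
      mechanismOfAction = sprintf("mechanism_%d", sample(6L, 1L)))
  }
  key <- data.frame(drug_id = ids, name = names, role = roles,
                    precursor_mz = precursors,
                    sources = vapply(ids, function(d)
                      paste(meta[[d]]@exposureSource, collapse = ";"),
                      character(1)),
                    stringsAsFactors = FALSE)
  list(library = DrugLibrary(records = records, pharmMeta = meta),
       fingerprints = fingerprints, key = key)
}

#' Generate a synthetic analog corpus with answer key
#'
#' Builds the planted corpus against the library from
#' [generateDrugLibrary()]: true analogs (a random 30-70\% of the parent's
#' peaks plus the precursor shifted by a curated offset, with Gaussian
#' jitter), analogs of endogenous/food drugs, decoys carrying off-list
#' offsets, verbatim known-drug reference spectra (the decoy twins),
#' analogs connecting both members of the dissimilar isobaric pair, a
#' background-ubiquitous analog, and random noise spectra.
#'
#' @param libraryFixture result of [generateDrugLibrary()].
#' @param spec the same [fixtureSpec()] list.
#' @return list: \code{corpus} (list of [Spectrum-class]) and \code{key}
#'   (data.frame spectrum_id, label, parent_drug_id, offset). Labels:
#'   true_analog, endogenous_analog, decoy_offlist, decoy_known,
#'   shared_dissimilar, background_ubiquitous, noise.
#' @export
generateAnalogCorpus <- function(libraryFixture, spec) {
  set.seed(spec$seed + 1L)
  lib <- libraryFixture$library
  key <- libraryFixture$key
  refOf <- function(d) lib@records[[d]]@spectra[[1L]]
  corpus <- list()
  rows <- list()
  addRow <- function(id, label, parent = NA_character_, offset = NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(
      spectrum_id = id, label = label, parent_drug_id = parent,
      offset = offset, stringsAsFactors = FALSE)

  trueParents <- key$drug_id[key$role == "true_parent"]
  offs <- rep_len(spec$trueOffsets, length(trueParents))
  for (j in seq_along(trueParents)) {
    id <- sprintf("corpus_true%02d", j)
    corpus[[id]] <- .makeAnalog(refOf(trueParents[j]), id, offs[j],
                                spec$shiftFraction, spec$peakJitterSd)
    addRow(id, "true_analog", trueParents[j], offs[j])
  }
  endoParents <- key$drug_id[key$role == "endogenous"]
  endoOffs <- rep_len(spec$trueOffsets, length(endoParents))
  for (j in seq_along(endoParents)) {
    id <- sprintf("corpus_endo%02d", j)
    corpus[[id]] <- .makeAnalog(refOf(endoParents[j]), id, endoOffs[j],
                                spec$shiftFraction, spec$peakJitterSd)
    addRow(id, "endogenous_analog", endoParents[j], endoOffs[j])
  }
  offParents <- key$drug_id[key$role == "offlist_parent"]
  for (j in seq_along(offParents)) {
    id <- sprintf("corpus_offlist%02d", j)
    off <- spec$offlistOffsets[((j - 1L) %% length(spec$offlistOffsets)) + 1L]
    corpus[[id]] <- .makeAnalog(refOf(offParents[j]), id, off,
                                spec$shiftFraction, spec$peakJitterSd)
    addRow(id, "decoy_offlist", offParents[j], off)
  }
  twins <- key$drug_id[key$role == "decoy_twin"]
  decoyParents <- key$drug_id[key$role == "decoy_parent"]
  for (j in seq_along(twins)) {
    id <- sprintf("corpus_known%02d", j)
    tw <- refOf(twins[j])
    corpus[[id]] <- Spectrum(id, precursorMz = tw@precursorMz,
                             peaks = tw@peaks)
    addRow(id, "decoy_known", decoyParents[j], 14.015650)
  }
  isobaric <- key$drug_id[key$role == "isobaric_pair"]
  for (j in seq_len(spec$nSharedDissimilar)) {
    id <- sprintf("corpus_shared%02d", j)
    a <- isobaric[2L * j - 1L]
    corpus[[id]] <- .makeAnalog(refOf(a), id, 15.994915,
                                spec$shiftFraction, spec$peakJitterSd)
    addRow(id, "shared_dissimilar", a, 15.994915)
  }
  bgParents <- key$drug_id[key$role == "background_parent"]
  for (j in seq_along(bgParents)) {
    id <- sprintf("corpus_bg%02d", j)
    corpus[[id]] <- .makeAnalog(refOf(bgParents[j]), id, 15.994915,
                                spec$shiftFraction, spec$peakJitterSd)
    addRow(id, "background_ubiquitous", bgParents[j], 15.994915)
  }
  for (j in seq_len(spec$nNoiseSpectra)) {
    id <- sprintf("corpus_noise%03d", j)
    corpus[[id]] <- .randSpectrum(id, runif(1, 220, 620),
                                  sample(spec$peakRange[1L]:spec$peakRange[2L], 1L))
    addRow(id, "noise")
  }
  list(corpus = unname(corpus),
       key = do.call(rbind, rows))
}

#' Generate a background cohort for the prevalence filter
#'
#' A feature table emulating a general-population background dataset: the
#' background-ubiquitous analog appears (slightly jittered) as a feature
#' detected in \code{spec$background$prevalence} of samples; noise
#' features fill the rest. True analogs are absent.
#'
#' @param corpusFixture result of [generateAnalogCorpus()].
#' @param spec the [fixtureSpec()] list.
#' @return list of \code{list(table = CohortFeatureTable, threshold)} as
#'   consumed by [filterByBackgroundPrevalence()].
#' @export
generateBackgroundCohorts <- function(corpusFixture, spec) {
  set.seed(spec$seed + 2L)
  bg <- spec$background
  ns <- bg$nSamples
  samples <- sprintf("bg_sample%03d", seq_len(ns))
  ubi <- corpusFixture$key$spectrum_id[
    corpusFixture$key$label == "background_ubiquitous"]
  corpusIds <- vapply(corpusFixture$corpus, spectrumId, character(1))
  feats <- list(); areas <- list()
  for (j in seq_along(ubi)) {
    s <- corpusFixture$corpus[[match(ubi[j], corpusIds)]]
    fid <- sprintf("bgfeat_ubi%02d", j)
    feats[[fid]] <- .jitterSpectrum(s, fid, spec$peakJitterSd / 2)
    present <- seq_len(ns) %in% sample(ns, round(bg$prevalence * ns))
    areas[[fid]] <- ifelse(present, exp(rnorm(ns, 10, 0.5)), 0)
  }
  for (j in seq_len(bg$nNoiseFeatures)) {
    fid <- sprintf("bgfeat_noise%02d", j)
    feats[[fid]] <- .randSpectrum(fid, runif(1, 220, 620), 10L)
    present <- runif(ns) < 0.3
    areas[[fid]] <- ifelse(present, exp(rnorm(ns, 10, 0.5)), 0)
  }
  m <- do.call(cbind, areas)
  rownames(m) <- samples
  tab <- CohortFeatureTable(m,
                            featureMz = vapply(feats, precursorMz, numeric(1)),
                            featureSpectra = feats)
  list(list(table = tab, threshold = bg$threshold))
}

#' Generate a regimen-structured cohort with answer key
#'
#' Emulates co-occurrence structure of combination-therapy exposure: each
#' sample draws one of \code{nTemplates} disjoint regimen templates (drug
#' sets taken from the true-analog parents); template drugs receive
#' lognormal peak areas with dropout at the stated rate (at least one
#' regimen drug always remains detected -- an exposed sample is assumed to
#' show some trace of its regimen); each detected drug contributes its
#' parent-ion feature and a lower-abundance metabolite feature. Noise
#' features and endogenous-metabolite variables (the first carrying a
#' planted location shift of \code{effectSize} pooled SDs in group 1) are
#' added for the statistics modules.
#'
#' @param libraryFixture result of [generateDrugLibrary()].
#' @param spec the [fixtureSpec()] list.
#' @return list: \code{table} ([CohortFeatureTable-class]),
#'   \code{sampleMeta} (data.frame sample_id, group, age, sex),
#'   \code{endogenous} (samples x variables matrix), \code{key} (list:
#'   groups, templates, effect_variable, effect_size).
#' @export
generateCohort <- function(libraryFixture, spec) {
  set.seed(spec$seed + 3L)
  co <- spec$cohort
  lib <- libraryFixture$library
  key <- libraryFixture$key
  pool <- key$drug_id[key$role == "true_parent"]
  need <- co$nTemplates * co$drugsPerTemplate
  if (length(pool) < need)
    pool <- c(pool, key$drug_id[key$role == "plain"])
  if (length(pool) < need)
    stop("not enough drugs for the requested regimen templates")
  templates <- split(pool[seq_len(need)],
                     rep(seq_len(co$nTemplates), each = co$drugsPerTemplate))
  ns <- co$nSamples
  samples <- sprintf("sample%03d", seq_len(ns))
  groups <- setNames(rep_len(seq_len(co$nTemplates), ns), samples)

  feats <- list(); areas <- list()
  addFeature <- function(fid, spectrum, vec) {
    feats[[fid]] <<- spectrum
    areas[[fid]] <<- vec
  }
  templDrugs <- unlist(templates, use.names = FALSE)
  detected <- matrix(FALSE, ns, length(templDrugs),
                     dimnames = list(samples, templDrugs))
  for (si in seq_len(ns)) {
    tdr <- templates[[groups[[si]]]]
    on <- runif(length(tdr)) >= co$dropout
    if (!any(on)) on[sample(length(tdr), 1L)] <- TRUE
    detected[si, tdr] <- on
  }
  for (d in templDrugs) {
    ref <- lib@records[[d]]@spectra[[1L]]
    fid <- sprintf("feat_%s", d)
    vec <- ifelse(detected[, d],
                  exp(rnorm(ns, co$abundanceMeanlog, co$abundanceSdlog)), 0)
    addFeature(fid, .jitterSpectrum(ref, fid, spec$peakJitterSd), vec)
    metId <- sprintf("%s_met1", d)
    if (!is.null(lib@records[[metId]])) {
      mref <- lib@records[[metId]]@spectra[[1L]]
      mfid <- sprintf("feat_%s", metId)
      mvec <- ifelse(detected[, d],
                     exp(rnorm(ns, co$abundanceMeanlog - 2,
                               co$abundanceSdlog)), 0)
      addFeature(mfid, .jitterSpectrum(mref, mfid, spec$peakJitterSd), mvec)
    }
  }
  for (j in seq_len(co$nNoiseFeatures)) {
    fid <- sprintf("feat_noise%03d", j)
    vec <- ifelse(runif(ns) < 0.3, exp(rnorm(ns, 9, 1)), 0)
    addFeature(fid, .randSpectrum(fid, runif(1, 220, 620), 10L), vec)
  }
  m <- do.call(cbind, areas)
  rownames(m) <- samples
  tab <- CohortFeatureTable(m,
                            featureMz = vapply(feats, precursorMz, numeric(1)),
                            featureSpectra = feats)
  endo <- matrix(rnorm(ns * co$nEndogenousVars), ns, co$nEndogenousVars,
                 dimnames = list(samples,
                                 sprintf("endo_var%d", seq_len(co$nEndogenousVars))))
  if (co$nEndogenousVars > 0L && co$effectSize != 0)
    endo[groups == 1L, 1L] <- endo[groups == 1L, 1L] + co$effectSize
  sampleMeta <- data.frame(
    sample_id = samples, group = unname(groups),
    age = round(runif(ns, 20, 80)),
    sex = sample(c("female", "male"), ns, replace = TRUE),
    stringsAsFactors = FALSE)
  list(table = tab, sampleMeta = sampleMeta, endogenous = endo,
       key = list(groups = groups, templates = templates,
                  effect_variable = if (co$nEndogenousVars > 0L)
                    colnames(endo)[1L] else NA_character_,
                  effect_size = co$effectSize))
}
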