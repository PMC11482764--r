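# Empirical drug-exposure readout: cohort annotation, exposure tables,
# ontology summaries, co-occurrence stratification, group statistics.

#' Annotate a cohort feature table against drug and analog libraries
#'
#' Each feature MS/MS spectrum is matched (cosine, same precursor within
#' the precursor tolerance) against the drug/metabolite reference spectra
#' and against the curated analog spectra; the best match above the
#' thresholds per partition is kept, and the drug/metabolite partition wins
#' over the analog partition -- analog annotations never overwrite library
#' matches of known drugs and metabolites. Drug ids are parent-resolved
#' (metabolite records and analog entries report their parent drug).
#'
#' @param cohort a [CohortFeatureTable-class] carrying feature spectra.
#' @param drugLibrary a [DrugLibrary-class].
#' @param analogLibrary result of [buildAnalogLibrary()] (or NULL to skip
#'   analog annotation).
#' @param scoreThreshold,minMatchedPeaks,fragmentTolerance,precursorTolerance
#'   matching thresholds.
#' @return data.frame with columns feature_id, matched_spectrum_id,
#'   drug_id, annotation_type (drug | metabolite | analog), score,
#'   matched_peaks.
#' @export
annotateCohort <- function(cohort, drugLibrary, analogLibrary = NULL,
                           scoreThreshold = 0.7, minMatchedPeaks = 6L,
                           fragmentTolerance = 0.01,
                           precursorTolerance = 0.01) {
  fs <- featureSpectra(cohort)
  if (is.null(fs)) stop("cohort table carries no feature spectra")
  known <- librarySpectra(drugLibrary)
  knownOwner <- attr(known, "drugId")
  knownPrec <- vapply(known, precursorMz, numeric(1))
  knownType <- vapply(names(known), function(sid)
    drugLibrary@records[[knownOwner[[sid]]]]@recordType, character(1))
  ana <- if (is.null(analogLibrary)) list() else analogLibrary$spectra
  anaPrec <- vapply(ana, precursorMz, numeric(1))
  anaParent <- if (length(ana))
    setNames(analogLibrary$entries$parent_drug_id[
      match(names(ana), analogLibrary$entries$analog_id)], names(ana))
  else character()

  bestMatch <- function(fspec, pool, prec) {
    near <- which(abs(prec - fspec@precursorMz) <= precursorTolerance)
    best <- NULL
    for (j in near) {
      r <- cosineSimilarity(fspec, pool[[j]], fragmentTolerance)
      if (r$score >= scoreThreshold && r$matched_peaks >= minMatchedPeaks &&
          (is.null(best) || r$score > best$score))
        best <- list(sid = names(pool)[[j]], score = r$score,
                     peaks = r$matched_peaks)
    }
    best
  }

  rows <- list()
  for (fid in names(fs)) {
    fspec <- fs[[fid]]
    hit <- bestMatch(fspec, known, knownPrec)
    if (!is.null(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = fid, matched_spectrum_id = hit$sid,
        drug_id = unname(parentDrugId(drugLibrary, knownOwner[[hit$sid]])),
        annotation_type = unname(knownType[[hit$sid]]),
        score = hit$score, matched_peaks = hit$peaks,
        stringsAsFactors = FALSE)
      next
    }
    if (length(ana)) {
      hit <- bestMatch(fspec, ana, anaPrec)
      if (!is.null(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = fid, matched_spectrum_id = hit$sid,
          drug_id = unname(anaParent[[hit$sid]]),
          annotation_type = "analog", score = hit$score,
          matched_peaks = hit$peaks, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(feature_id = character(),
                      matched_spectrum_id = character(),
                      drug_id = character(), annotation_type = character(),
                      score = numeric(), matched_peaks = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the samples-by-drugs exposure table
#'
#' Per sample and parent drug, the raw abundance sums the peak areas of
#' every feature annotated to that drug -- all ion/adduct forms of the
#' parent, its metabolites, and its analogs are grouped into one drug
#' column. Abundance is log10(raw + 1); detection is raw > 0.
#'
#' @param matches annotation data.frame from [annotateCohort()].
#' @param cohort the annotated [CohortFeatureTable-class].
#' @param library a [DrugLibrary-class] (row universe is the matched
#'   drugs).
#' @return an [ExposureTable-class].
#' @export
buildExposureTable <- function(matches, cohort, library) {
  areas <- peakAreas(cohort)
  drugs <- sort(unique(matches$drug_id))
  raw <- matrix(0, nrow = length(drugs), ncol = nrow(areas),
                dimnames = list(drugs, rownames(areas)))
  prov <- setNames(vector("list", length(drugs)), drugs)
  for (k in seq_len(nrow(matches))) {
    d <- matches$drug_id[[k]]
    f <- matches$feature_id[[k]]
    if (!f %in% colnames(areas)) next
    raw[d, ] <- raw[d, ] + areas[, f]
    prov[[d]] <- union(prov[[d]], matches$annotation_type[[k]])
  }
  rd <- DataFrame(provenance = vapply(prov, paste, character(1),
                                      collapse = ";"),
                  row.names = drugs)
  se <- SummarizedExperiment(
    assays = list(raw = raw, abundance = log10(raw + 1),
                  detected = (raw > 0) * 1),
    rowData = rd)
  new("ExposureTable", se)
}

#' Drop drugs with endogenous or food exposure sources
#'
#' Detections of compounds that can also arise endogenously or from diet
#' cannot be read as medication exposure, so their columns are removed
#' from the exposure table. Applying the operation twice equals applying
#' it once.
#'
#' @param table an [ExposureTable-class].
#' @param library a [DrugLibrary-class] with metadata.
#' @return the restricted [ExposureTable-class].
#' @export
excludeEndogenousFood <- function(table, library) {
  keep <- vapply(rownames(table), function(d)
    !length(intersect(exposureSources(library, d),
                      c("endogenous", "food"))), logical(1))
  table[keep, ]
}

#' Summarise detections by controlled-vocabulary level
#'
#' Aggregates the exposure table over one metadata vocabulary
#' (exposure_source, pharmacologic_class, therapeutic_area,
#' therapeutic_indication or mechanism_of_action). Multi-valued terms
#' credit every term. Rows are sorted by descending sample fraction, ties
#' by term.
#'
#' @param table an [ExposureTable-class].
#' @param library a [DrugLibrary-class] with metadata.
#' @param level one vocabulary level name.
#' @return data.frame: term, n_drugs (detected drugs carrying the term),
#'   n_samples (samples with >= 1 detection of such a drug), fraction
#'   (n_samples / total samples).
#' @export
summarizeByVocab <- function(table, library,
                             level = c("pharmacologic_class",
                                       "exposure_source",
                                       "therapeutic_area",
                                       "therapeutic_indication",
                                       "mechanism_of_action")) {
  level <- match.arg(level)
  slotName <- c(exposure_source = "exposureSource", .META_FIELDS)[[level]]
  det <- exposureDetected(table)
  empty <- data.frame(term = character(), n_drugs = integer(),
                      n_samples = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (!ncol(det) || !nrow(det)) return(empty)
  termDrugs <- list()
  for (d in colnames(det)) {
    if (!any(det[, d])) next
    m <- library@pharmMeta[[d]]
    terms <- if (is.null(m)) character() else slot(m, slotName)
    for (tm in terms) termDrugs[[tm]] <- union(termDrugs[[tm]], d)
  }
  if (!length(termDrugs)) return(empty)
  rows <- lapply(names(termDrugs), function(tm) {
    ds <- termDrugs[[tm]]
    hit <- rowSums(det[, ds, drop = FALSE]) > 0
    data.frame(term = tm, n_drugs = length(ds), n_samples = sum(hit),
               fraction = mean(hit), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$fraction, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratify samples by drug co-occurrence
#'
#' Agglomerative hierarchical clustering (Ward linkage, Euclidean
#' distance) of the samples on their log-abundance exposure profiles,
#' cut at k groups. Drugs detected in fewer than
#' \code{minDetectionFraction} of samples are removed before clustering.
#' Group labels are renumbered by decreasing group size (ties by first
#' sample id), so the labelling is invariant to sample input order. Mean
#' silhouette widths for k in 2..8 are reported to assist choosing k;
#' k is never auto-selected.
#'
#' @param table an [ExposureTable-class].
#' @param drugSubset optional character vector restricting the drugs used.
#' @param k number of groups (>= 1).
#' @param minDetectionFraction minimum detection fraction per drug
#'   (default 0.1).
#' @return a [StratificationResult-class].
#' @importFrom stats dist hclust cutree
#' @importFrom cluster silhouette
#' @export
stratifyByExposure <- function(table, drugSubset = NULL, k,
                               minDetectionFraction = 0.1) {
  stopifnot(k >= 1L)
  ab <- exposureAbundance(table)
  det <- exposureDetected(table)
  if (!is.null(drugSubset)) {
    ab <- ab[, intersect(colnames(ab), drugSubset), drop = FALSE]
    det <- det[, colnames(ab), drop = FALSE]
  }
  frac <- colMeans(det)
  ab <- ab[, frac >= minDetectionFraction, drop = FALSE]
  if (!ncol(ab)) stop("no drugs left after the detection-fraction filter")
  ord <- order(rownames(ab))
  ab <- ab[ord, , drop = FALSE]
  d <- dist(ab, method = "euclidean")
  hc <- hclust(d, method = "ward.D2")
  rawLabels <- if (k == 1L) setNames(rep(1L, nrow(ab)), rownames(ab))
  else cutree(hc, k = k)
  # renumber groups by decreasing size, ties by first sample id
  sizes <- table(rawLabels)
  firstSample <- vapply(names(sizes), function(g)
    min(rownames(ab)[rawLabels == as.integer(g)]), character(1))
  newOrder <- names(sizes)[order(-as.integer(sizes), firstSample)]
  relabel <- setNames(seq_along(newOrder), newOrder)
  labels <- setNames(as.integer(relabel[as.character(rawLabels)]),
                     rownames(ab))
  sil <- data.frame(k = integer(), mean_width = numeric())
  if (nrow(ab) > 3L) {
    dm <- as.matrix(d)
    for (kk in 2:min(8L, nrow(ab) - 1L)) {
      lab <- cutree(hc, k = kk)
      if (length(unique(lab)) < 2L) next
      sw <- cluster::silhouette(lab, dmatrix = dm)
      sil <- rbind(sil, data.frame(k = kk, mean_width = mean(sw[, 3L])))
    }
  }
  new("StratificationResult", labels = labels, k = as.integer(k),
      linkageMethod = "ward.D2", distanceMetric = "euclidean",
      silhouette = sil)
}

#' Compare per-sample measurements across stratification groups
#'
#' For each variable: a Kruskal-Wallis test across the groups, followed by
#' pairwise two-sided Wilcoxon rank-sum tests with Benjamini-Hochberg
#' adjustment over the pairwise family within that variable. Tests run on
#' the raw values -- max-standardisation (each variable scaled to its
#' maximum across samples) is a display transform that does not change
#' ranks. Variables constant across all samples get p = 1 by convention.
#'
#' @param values numeric matrix (samples x variables) or named vector (one
#'   variable), sample ids as rownames/names.
#' @param groups a [StratificationResult-class] (or named group vector).
#' @return object of class \code{groupComparison}: list with \code{kw}
#'   (data.frame variable, p), \code{pairwise} (data.frame variable,
#'   group_a, group_b, p_raw, p_adj) and \code{adjustment}
#'   ("Benjamini-Hochberg").
#' @importFrom stats kruskal.test wilcox.test p.adjust
#' @export
compareGroups <- function(values, groups) {
  g <- if (is(groups, "StratificationResult")) groups@labels else groups
  if (is.null(dim(values))) {
    values <- matrix(values, ncol = 1,
                     dimnames = list(names(values), "variable"))
  }
  common <- intersect(rownames(values), names(g))
  if (length(common) < length(g))
    g <- g[common]
  values <- values[names(g), , drop = FALSE]
  tab <- table(g)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 groups with >= 2 samples each")
  gf <- factor(g)
  pairs <- utils::combn(levels(gf), 2L)
  kwRows <- list(); pwRows <- list()
  for (v in colnames(values)) {
    x <- values[, v]
    if (length(unique(x)) == 1L) {
      kwRows[[v]] <- data.frame(variable = v, p = 1,
                                stringsAsFactors = FALSE)
      pw <- data.frame(variable = v, group_a = pairs[1L, ],
                       group_b = pairs[2L, ], p_raw = 1, p_adj = 1,
                       stringsAsFactors = FALSE)
      pwRows[[v]] <- pw
      next
    }
    kwRows[[v]] <- data.frame(variable = v,
                              p = kruskal.test(x, gf)$p.value,
                              stringsAsFactors = FALSE)
    praw <- apply(pairs, 2L, function(pq) {
      xa <- x[gf == pq[1L]]; xb <- x[gf == pq[2L]]
      if (length(unique(c(xa, xb))) == 1L) return(1)
      suppressWarnings(wilcox.test(xa, xb, exact = FALSE)$p.value)
    })
    pwRows[[v]] <- data.frame(variable = v, group_a = pairs[1L, ],
                              group_b = pairs[2L, ], p_raw = praw,
                              p_adj = p.adjust(praw, method = "BH"),
                              stringsAsFactors = FALSE)
  }
  out <- list(kw = do.call(rbind, c(kwRows, list(make.row.names = FALSE))),
              pairwise = do.call(rbind, c(pwRows,
                                          list(make.row.names = FALSE))),
              adjustment = "Benjamini-Hochberg")
  class(out) <- "groupComparison"
  out
}

#' @export
print.groupComparison <- function(x, ...) {
  cat(sprintf("groupComparison: %d variable(s), %s-adjusted pairwise tests\n",
              nrow(x$kw), x$adjustment))
  print(head(x$kw, 10))
  invisible(x)
}

#' Chi-square test of detection frequency against a categorical variable
#'
#' Pearson chi-square (no continuity correction) on the detection-by-
#' category contingency table, df = (r-1)(c-1). Expected cells below 5 are
#' recorded as a warning flag, not auto-corrected.
#'
#' @param detected logical (or 2-level) vector per sample.
#' @param category categorical vector per sample (>= 2 levels).
#' @return list: statistic, df, p.value, expected (matrix),
#'   low_expected_cells (count of expected cells < 5).
#' @importFrom stats chisq.test
#' @export
testDetectionAssociation <- function(detected, category) {
  tab <- table(detected, category)
  if (ncol(tab) < 2L) stop("need >= 2 categories")
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  low <- sum(res$expected < 5)
  if (low > 0L)
    warning(sprintf("%d expected cell(s) below 5; chi-square approximation may be poor",
                    low))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value, expected = res$expected,
       low_expected_cells = low)
}

#' Max-standardise an abundance matrix for display
#'
#' Scales each variable (column) to its maximum observed value across
#' samples -- a display/export transform; statistics are computed on raw
#' values.
#'
#' @param m numeric samples-by-variables matrix.
#' @return matrix with column maxima 1 (all-zero columns unchanged).
#' @export
maxStandardize <- function(m) {
  mx <- apply(m, 2L, max)
  mx[mx == 0] <- 1
  sweep(m, 2L, mx, "/")
}

#' Export an ExposureTable as TSV files
#'
#' Log-abundance matrix, detection matrix and per-drug annotation
#' provenance, samples as rows.
#'
#' @param table an [ExposureTable-class].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
exportExposureTable <- function(table, dir, prefix = "exposure") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(abundance = file.path(dir, paste0(prefix, "_abundance.tsv")),
             detected = file.path(dir, paste0(prefix, "_detected.tsv")),
             provenance = file.path(dir, paste0(prefix, "_provenance.tsv")))
  wr <- function(m, p) {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wr(exposureAbundance(table), paths[["abundance"]])
  wr(exposureDetected(table) * 1, paths[["detected"]])
  write.table(data.frame(drug_id = rownames(table),
                         provenance = rowData(table)$provenance),
              paths[["provenance"]], sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(paths)
}
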