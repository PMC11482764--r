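test_that("cohort annotation resolves types and parents, analog never overrides library", {
  lib <- tinyLibrary()
  refA <- drugRecords(lib)$drugA@spectra[[1]]
  met <- DrugRecord("drugA_met1", "desmethylalphadrug",
                    spectra = list(mkspec("ref_metA", 286, c(90, 140, 190),
                                          c(10, 20, 30))),
                    recordType = "metabolite", parentDrugId = "drugA")
  lib <- addRecords(lib, list(met))
  feats <- list(
    f1 = Spectrum("f1", precursorMz = 300, peaks = peakMatrix(refA)),
    f2 = mkspec("f2", 286, c(90, 140, 190), c(10, 20, 30)),
    f3 = mkspec("f3", 500, c(77, 88), c(1, 1)))
  areas <- matrix(10, 2, 3, dimnames = list(c("s1", "s2"), names(feats)))
  tab <- CohortFeatureTable(areas, featureSpectra = feats)
  ann <- annotateCohort(tab, lib, minMatchedPeaks = 3L)
  expect_equal(nrow(ann), 2)
  a1 <- ann[ann$feature_id == "f1", ]
  expect_equal(a1$annotation_type, "drug")
  expect_equal(a1$score, 1.0, tolerance = 1e-12)
  a2 <- ann[ann$feature_id == "f2", ]
  expect_equal(a2$annotation_type, "metabolite")
  expect_equal(a2$drug_id, "drugA")  # parent-resolved

  # a feature matching both a drug record and an analog keeps the drug
  fakeAnalog <- list(entries = data.frame(
    analog_id = "an1", parent_drug_id = "drugB", delta_mass = 14.02,
    delta_interpretation = "methylation", in_source_fragment = FALSE,
    cluster_size = 1L, n_matches = 1L, score = 0.9,
    stringsAsFactors = FALSE),
    spectra = list(an1 = Spectrum("an1", precursorMz = 300,
                                  peaks = peakMatrix(refA))))
  ann2 <- annotateCohort(tab, lib, fakeAnalog, minMatchedPeaks = 3L)
  expect_equal(ann2[ann2$feature_id == "f1", "annotation_type"], "drug")
  expect_error(annotateCohort(CohortFeatureTable(areas), lib),
               "feature spectra")
})

test_that("planted cohort features are annotated exactly, noise rejected", {
  spec <- fixtureSpec(seed = 8)
  lf <- generateDrugLibrary(spec)
  lib <- lf$library
  set.seed(81)
  key <- lf$key
  drugIdsUse <- key$drug_id[key$role %in% c("true_parent", "offlist_parent",
                                            "plain")][1:12]
  metIds <- paste0(key$drug_id[key$role == "true_parent"], "_met1")[1:5]
  feats <- list(); truth <- character()
  for (d in drugIdsUse) {
    fid <- paste0("f_", d)
    feats[[fid]] <- msDrugLib:::.jitterSpectrum(
      drugRecords(lib)[[d]]@spectra[[1]], fid, 0.002)
    truth[fid] <- "drug"
  }
  for (m in metIds) {
    fid <- paste0("f_", m)
    feats[[fid]] <- msDrugLib:::.jitterSpectrum(
      drugRecords(lib)[[m]]@spectra[[1]], fid, 0.002)
    truth[fid] <- "metabolite"
  }
  cf <- generateAnalogCorpus(lf, spec)
  trueIds <- cf$key$spectrum_id[cf$key$label == "true_analog"][1:3]
  corpusIds <- vapply(cf$corpus, spectrumId, character(1))
  analogSpectra <- list()
  for (aid in trueIds) {
    fid <- paste0("f_", aid)
    s <- cf$corpus[[match(aid, corpusIds)]]
    feats[[fid]] <- msDrugLib:::.jitterSpectrum(s, fid, 0.001)
    analogSpectra[[aid]] <- s
    truth[fid] <- "analog"
  }
  for (i in 1:200) {
    fid <- sprintf("f_noise%03d", i)
    feats[[fid]] <- randSpec(fid, npeaks = 10)
  }
  areas <- matrix(runif(2 * length(feats), 1, 100), nrow = 2,
                  dimnames = list(c("s1", "s2"), names(feats)))
  tab <- CohortFeatureTable(areas, featureSpectra = feats)
  analogLib <- list(
    entries = data.frame(
      analog_id = trueIds,
      parent_drug_id = cf$key$parent_drug_id[match(trueIds,
                                                   cf$key$spectrum_id)],
      delta_mass = 14.02, delta_interpretation = "methylation",
      in_source_fragment = FALSE, cluster_size = 1L, n_matches = 1L,
      score = 0.95, stringsAsFactors = FALSE),
    spectra = analogSpectra)
  ann <- annotateCohort(tab, lib, analogLib)
  expect_equal(nrow(ann), 20)
  got <- setNames(ann$annotation_type, ann$feature_id)
  expect_mapequal(got, truth)
})

test_that("exposure table sums evidence per parent drug and log-transforms", {
  matches <- data.frame(
    feature_id = c("fp", "fm", "fadduct"),
    matched_spectrum_id = c("r1", "r2", "r3"),
    drug_id = "drugA",
    annotation_type = c("drug", "metabolite", "drug"),
    score = 0.9, matched_peaks = 8L, stringsAsFactors = FALSE)
  areas <- matrix(c(100, 0, 10, 0, 5, 0), nrow = 2,
                  dimnames = list(c("s1", "s2"), c("fp", "fm", "fadduct")))
  tab <- CohortFeatureTable(areas)
  lib <- tinyLibrary()
  et <- buildExposureTable(matches, tab, lib)
  # two ion forms + metabolite collapse into a single drug column
  expect_equal(exposureDrugs(et), "drugA")
  expect_equal(unname(exposureRaw(et)["s1", "drugA"]), 115)
  expect_equal(unname(exposureAbundance(et)["s1", "drugA"]), log10(116))
  expect_false(exposureDetected(et)["s2", "drugA"])
  expect_equal(unname(exposureAbundance(et)["s2", "drugA"]), 0)
  expect_setequal(annotationProvenance(et)$drugA, c("drug", "metabolite"))
  # evidence conservation: summed drug abundance <= summed feature areas
  expect_lte(sum(exposureRaw(et)), sum(areas))
})

test_that("endogenous/food drugs are excluded idempotently", {
  matches <- data.frame(
    feature_id = c("fa", "fb"), matched_spectrum_id = c("ra", "rb"),
    drug_id = c("drugA", "drugB"), annotation_type = "drug",
    score = 0.9, matched_peaks = 8L, stringsAsFactors = FALSE)
  areas <- matrix(5, 2, 2, dimnames = list(c("s1", "s2"), c("fa", "fb")))
  et <- buildExposureTable(matches, CohortFeatureTable(areas), tinyLibrary())
  out <- excludeEndogenousFood(et, tinyLibrary())
  expect_equal(exposureDrugs(out), "drugA")  # drugB is medical+endogenous
  expect_equal(exposureDrugs(excludeEndogenousFood(out, tinyLibrary())),
               "drugA")
})

test_that("vocabulary summaries credit multi-valued terms with exact fractions", {
  lib <- DrugLibrary(
    records = list(
      d1 = DrugRecord("d1", "statindrug",
                      spectra = list(mkspec("r1", 200, 100, 1))),
      d2 = DrugRecord("d2", "twoclassdrug",
                      spectra = list(mkspec("r2", 210, 100, 1)))),
    pharmMeta = list(
      d1 = DrugMetadata("d1", exposureSource = "medical",
                        pharmacologicClass = "statin"),
      d2 = DrugMetadata("d2", exposureSource = "medical",
                        pharmacologicClass = c("NSAID", "analgesic"))))
  raw <- matrix(0, 10, 2, dimnames = list(sprintf("s%02d", 1:10),
                                          c("fd1", "fd2")))
  raw[1:3, "fd1"] <- 10
  raw[4, "fd2"] <- 10
  matches <- data.frame(
    feature_id = c("fd1", "fd2"), matched_spectrum_id = c("r1", "r2"),
    drug_id = c("d1", "d2"), annotation_type = "drug", score = 1,
    matched_peaks = 8L, stringsAsFactors = FALSE)
  et <- buildExposureTable(matches, CohortFeatureTable(raw), lib)
  s <- summarizeByVocab(et, lib, "pharmacologic_class")
  expect_equal(s$fraction[s$term == "statin"], 0.3)
  expect_true(all(c("NSAID", "analgesic") %in% s$term))
  expect_equal(s$term[1], "statin")  # sorted by descending fraction
  emptyEt <- et[, 0]
  expect_equal(nrow(summarizeByVocab(emptyEt, lib, "pharmacologic_class")), 0)
})

test_that("stratification recovers planted regimens and labels deterministically", {
  spec <- fixtureSpec(seed = 6)
  lf <- generateDrugLibrary(spec)
  cof <- generateCohort(lf, spec)
  ann <- annotateCohort(cof$table, lf$library)
  et <- buildExposureTable(ann, cof$table, lf$library)
  strat <- stratifyByExposure(et, k = 3)
  labs <- groupLabels(strat)
  truth <- cof$key$groups
  expect_equal(adjustedRand(labs[names(truth)], truth), 1.0)
  # k = 1: everything in one group
  s1 <- stratifyByExposure(et, k = 1)
  expect_true(all(groupLabels(s1) == 1L))
  # sample order invariance
  strat2 <- stratifyByExposure(et[, rev(seq_len(ncol(et)))], k = 3)
  expect_identical(groupLabels(strat2)[names(labs)], labs)
  # duplicate profiles get identical labels
  ab <- exposureAbundance(et)
  dup <- which(duplicated(ab) | duplicated(ab, fromLast = TRUE))
  if (length(dup) >= 2) {
    k <- apply(ab[dup, , drop = FALSE], 1, paste, collapse = ",")
    for (g in split(names(k), k))
      expect_length(unique(labs[g]), 1)
  }
  expect_true(all(strat@silhouette$k %in% 2:8))
})

test_that("group comparison: KW + pairwise Wilcoxon + BH behaves as specified", {
  set.seed(99)
  g <- setNames(rep(1:2, each = 50), sprintf("s%03d", 1:100))
  x <- setNames(c(rnorm(50), rnorm(50, 1)), names(g))
  gc <- compareGroups(x, g)
  # two groups: KW p equals the z-test rank-sum p asymptotically
  ref <- suppressWarnings(stats::wilcox.test(x[g == 1], x[g == 2],
                                             exact = FALSE,
                                             correct = FALSE)$p.value)
  expect_equal(gc$kw$p, ref, tolerance = 1e-6)
  expect_equal(nrow(gc$pairwise), 1)

  # constant variable: p = 1 by convention
  g3 <- setNames(rep(1:3, each = 5), sprintf("t%02d", 1:15))
  vals <- cbind(flat = rep(2, 15), varying = rnorm(15))
  rownames(vals) <- names(g3)
  gc3 <- compareGroups(vals, g3)
  expect_equal(gc3$kw$p[gc3$kw$variable == "flat"], 1)
  expect_equal(nrow(gc3$pairwise), 2 * choose(3, 2))

  # BH monotonicity within the family
  pw <- gc3$pairwise[gc3$pairwise$variable == "varying", ]
  expect_true(all(pw$p_adj >= pw$p_raw))
  expect_identical(order(pw$p_adj), order(pw$p_raw))
  expect_error(compareGroups(x, setNames(rep(1, 100), names(x))), "groups")
})

test_that("detection association is the Pearson chi-square without correction", {
  det <- rep(c(TRUE, FALSE), each = 20)
  cat2 <- rep(c("a", "b"), 20)
  flat <- testDetectionAssociation(det, cat2)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)

  det2 <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 30))
  cat22 <- rep(c("f", "m"), each = 40)
  r <- testDetectionAssociation(det2, cat22)
  expect_equal(r$statistic, 20.0, tolerance = 1e-12)
  expect_equal(r$df, 1)

  det5 <- rep(c(TRUE, FALSE), 50)
  cat5 <- rep(letters[1:5], each = 20)
  expect_equal(testDetectionAssociation(det5, cat5)$df, 4)
  expect_warning(
    testDetectionAssociation(c(TRUE, FALSE, TRUE, FALSE),
                             c("a", "a", "b", "b")), "expected")
})

test_that("max-standardisation scales columns to unit maxima", {
  m <- matrix(c(1, 2, 4, 0, 0, 0), ncol = 2)
  out <- maxStandardize(m)
  expect_equal(max(out[, 1]), 1)
  expect_equal(out[, 2], c(0, 0, 0))
  # ranks unchanged
  expect_identical(order(out[, 1]), order(m[, 1]))
})
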