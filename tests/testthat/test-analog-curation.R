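test_that("source filter removes endogenous/food parents and drops emptied candidates", {
  lib <- tinyLibrary()  # drugA medical-only, drugB medical+endogenous
  s <- mkspec("cand", 320, c(100, 150), c(1, 1))
  onlyEndo <- mkCandidate(s, list(drugB = mkParent(14.0157)))
  onlyMed <- mkCandidate(s, list(drugA = mkParent(14.0157)))
  mixed <- mkCandidate(s, list(drugA = mkParent(14.0157),
                               drugB = mkParent(14.0157)))
  out <- filterBySource(list(onlyEndo, onlyMed, mixed), lib)
  expect_length(out, 2)
  expect_length(attr(out, "failures"), 1)
  survivors <- lapply(out, function(x) names(x$parents))
  expect_true(all(vapply(survivors, identical, logical(1), "drugA")))
  # parent set-subtraction oracle: mixed keeps exactly the medical parent
  expect_identical(setdiff(c("drugA", "drugB"), "drugB"), survivors[[2]])
})

test_that("delta-mass filter enforces list membership and run-wide occurrence", {
  dl <- defaultDeltaMassList()
  s <- function(i) mkspec(paste0("c", i), 300 + i, c(100, 150), c(1, 1))
  inList <- lapply(1:12, function(i)
    mkCandidate(s(i), list(drugA = mkParent(14.016))))
  offList <- mkCandidate(s(90), list(drugA = mkParent(13.37)))
  rare <- lapply(1:9, function(i)
    mkCandidate(s(40 + i), list(drugA = mkParent(176.032))))

  out <- filterByDeltaMass(c(inList, list(offList), rare), dl,
                           tolerance = 0.01, minOffsetOccurrence = 10L)
  # 12 methylation pairs pass; the off-list offset and the 9 rare
  # glucuronidation pairs all fail
  expect_length(out, 12)
  expect_length(attr(out, "failures"), 10)
  expect_true(all(vapply(out, function(x)
    x$parents$drugA$interpretation, character(1)) == "methylation"))

  # with the threshold at 1 the rare offset passes, membership still rules
  out2 <- filterByDeltaMass(c(inList, list(offList), rare), dl,
                            tolerance = 0.01, minOffsetOccurrence = 1L)
  expect_length(out2, 21)
})

test_that("library-match filter removes exactly the planted known-drug spectra", {
  set.seed(55)
  refs <- lapply(1:4, function(i)
    mkspec(sprintf("known_ref%d", i), 280 + 10 * i,
           sort(runif(10, 50, 260)), runif(10, 5, 80)))
  recs <- lapply(1:4, function(i)
    DrugRecord(sprintf("kd%d", i), sprintf("knowndrug%d", i),
               spectra = refs[i]))
  lib <- DrugLibrary(records = recs)
  cands <- list()
  for (i in 1:16)
    cands[[i]] <- mkCandidate(randSpec(sprintf("new%02d", i), npeaks = 10),
                              list(kd1 = mkParent(15.9949)))
  for (i in 1:4) {
    decoy <- Spectrum(sprintf("decoy%d", i),
                      precursorMz = precursorMz(refs[[i]]),
                      peaks = peakMatrix(refs[[i]]))
    cands[[16 + i]] <- mkCandidate(decoy, list(kd1 = mkParent(15.9949)))
  }
  out <- filterByLibraryMatch(cands, lib)
  failed <- vapply(attr(out, "failures"), function(x)
    x$analog_spectrum_id, character(1))
  expect_setequal(failed, sprintf("decoy%d", 1:4))
  expect_length(out, 16)
  reasons <- vapply(attr(out, "failures"), function(x)
    x$filter_status$reason[x$filter_status$filter == "library_match"],
    character(1))
  expect_true(all(grepl("library match: knowndrug", reasons)))
})

test_that("shared-analog filter arbitrates by pairwise Tanimoto", {
  fpSim <- list(d1 = c(rep(TRUE, 80), rep(FALSE, 176)),
                d2 = c(rep(TRUE, 70), rep(FALSE, 186)),
                d3 = c(rep(FALSE, 200), rep(TRUE, 56)))
  expect_gte(tanimoto(fpSim$d1, fpSim$d2), 0.5)
  expect_lte(tanimoto(fpSim$d1, fpSim$d3), 0.1)
  s <- mkspec("sh", 300, c(100, 150), c(1, 1))
  similar <- mkCandidate(s, list(d1 = mkParent(88.05), d2 = mkParent(14.02)))
  dissimilar <- mkCandidate(s, list(d1 = mkParent(15.99),
                                    d3 = mkParent(15.99)))
  single <- mkCandidate(s, list(d1 = mkParent(14.02)))
  unknown <- mkCandidate(s, list(d1 = mkParent(14.02),
                                 dX = mkParent(14.02)))
  out <- filterSharedAnalogs(list(similar, dissimilar, single, unknown),
                             fpSim, tanimotoThreshold = 0.5)
  expect_length(out, 2)            # similar + single
  expect_length(attr(out, "failures"), 1)
  expect_length(attr(out, "review"), 1)
  expect_equal(attr(out, "failures")[[1]]$analog_spectrum_id, "sh")
})

test_that("background-prevalence filter uses each cohort's own threshold", {
  set.seed(66)
  ubi <- mkspec("ubi", 333.3, sort(runif(10, 50, 300)), runif(10, 5, 50))
  clean <- mkspec("clean", 444.4, sort(runif(10, 50, 400)), runif(10, 5, 50))
  ns <- 20
  feats <- list(f_ubi = ubi)
  areas <- matrix(0, ns, 1, dimnames = list(sprintf("s%02d", 1:ns), "f_ubi"))
  areas[1:12, 1] <- 100  # 60% prevalence
  bgTab <- CohortFeatureTable(areas, featureSpectra = feats)
  bg <- list(list(table = bgTab, threshold = 0.5))
  cands <- list(mkCandidate(ubi, list(d = mkParent(14.02))),
                mkCandidate(clean, list(d = mkParent(14.02))))
  out <- filterByBackgroundPrevalence(cands, bg)
  expect_length(out, 1)
  expect_equal(out[[1]]$analog_spectrum_id, "clean")
  # a milk-like cohort with a laxer threshold lets the same candidate pass
  out2 <- filterByBackgroundPrevalence(cands,
                                       list(list(table = bgTab,
                                                 threshold = 0.7)))
  expect_length(out2, 2)
  # cohort without spectra is skipped with a warning
  noSpec <- CohortFeatureTable(areas)
  expect_warning(out3 <- filterByBackgroundPrevalence(
    cands, list(list(table = noSpec, threshold = 0.5))), "skipped")
  expect_length(out3, 2)
})

test_that("in-source fragments are flagged by RT overlap and lower precursor only", {
  entries <- data.frame(
    analog_id = c("a1", "a2", "a3", "a4"),
    parent_drug_id = "dar",
    delta_mass = c(-100.1, -100.1, 14.02, -50.0),
    delta_interpretation = "x", in_source_fragment = FALSE,
    cluster_size = 1L, n_matches = 1L, score = 0.9,
    stringsAsFactors = FALSE)
  pd <- list(dar = data.frame(sample = c("s1", "s2", "s3"),
                              rt = c(5.00, 5.10, 5.05)))
  ad <- list(
    a1 = data.frame(sample = c("s1", "s2", "s3"), rt = c(5.02, 5.11, 5.04)),
    a2 = data.frame(sample = c("s1", "s2"), rt = c(6.5, 6.6)),
    a3 = data.frame(sample = c("s1", "s2"), rt = c(5.01, 5.09)))
  out <- flagInSourceFragments(entries, pd, ad, rtTolerance = 0.1)
  expect_true(out$in_source_fragment[1])    # co-eluting, lower precursor
  expect_false(out$in_source_fragment[2])   # RT off by 1.5 min
  expect_false(out$in_source_fragment[3])   # higher precursor: never flagged
  expect_false(out$in_source_fragment[4])   # no detections: indeterminate
  expect_equal(attr(out, "indeterminate"), "a4")
})

test_that("the full cascade recovers the planted truth with exact attrition", {
  spec <- fixtureSpec(seed = 3)
  lf <- generateDrugLibrary(spec)
  cf <- generateAnalogCorpus(lf, spec)
  bg <- generateBackgroundCohorts(cf, spec)
  raw <- analogSearch(lf$library, cf$corpus)
  cfg <- analogConfig(minOffsetOccurrence = spec$minOffsetOccurrence)
  res <- buildAnalogLibrary(raw, lf$library, defaultDeltaMassList(),
                            cf$corpus, config = cfg,
                            fingerprints = lf$fingerprints,
                            backgroundCohorts = bg)
  truth <- cf$key[cf$key$label == "true_analog", ]
  got <- res$entries
  expect_setequal(got$analog_id, truth$spectrum_id)
  expect_equal(nrow(got), nrow(truth))
  m <- match(got$analog_id, truth$spectrum_id)
  expect_identical(got$parent_drug_id, truth$parent_drug_id[m])
  expect_equal(got$delta_mass, truth$offset[m], tolerance = 1e-6)
  att <- setNames(res$attrition$count, res$attrition$stage)
  expect_equal(unname(att["fail_source"]), spec$nEndogenous)
  expect_equal(unname(att["fail_delta_mass"]), spec$nOfflistAnalogs)
  expect_equal(unname(att["fail_library_match"]), spec$nKnownDecoys)
  expect_equal(unname(att["fail_shared_analog"]), spec$nSharedDissimilar)
  expect_equal(unname(att["fail_background_prevalence"]),
               spec$nBackgroundUbiquitous)
  expect_equal(unname(att["output"]), spec$nTrueAnalogs)
  # every surviving entry carries a curated interpretation
  expect_true(all(!is.na(got$delta_interpretation)))
  # attrition sums: input = output + all exclusive failures
  expect_equal(unname(att["input"]),
               unname(att["output"] + att["fail_source"] +
                        att["fail_delta_mass"] + att["fail_library_match"] +
                        att["fail_shared_analog"] +
                        att["review_shared_analog"] +
                        att["fail_background_prevalence"]))
})

test_that("cascade handles empty input and is idempotent on its survivors", {
  lib <- tinyLibrary()
  empty <- analogSearch(lib, list())
  res <- buildAnalogLibrary(empty, lib, defaultDeltaMassList(), list())
  expect_equal(nrow(res$entries), 0)
  expect_true(all(res$attrition$count == 0))

  spec <- fixtureSpec(seed = 4, nNoiseSpectra = 20L)
  lf <- generateDrugLibrary(spec)
  cf <- generateAnalogCorpus(lf, spec)
  raw <- analogSearch(lf$library, cf$corpus)
  cfg <- analogConfig(minOffsetOccurrence = spec$minOffsetOccurrence)
  dl <- defaultDeltaMassList()
  s1 <- filterBySource(formAnalogCandidates(raw, lf$library, cf$corpus, cfg),
                       lf$library)
  s2 <- filterByDeltaMass(s1, dl, cfg$deltaTolerance,
                          cfg$minOffsetOccurrence)
  s3 <- filterByLibraryMatch(s2, lf$library)
  s4 <- filterSharedAnalogs(s3, lf$fingerprints)
  # re-running every filter on its own output changes nothing
  again <- filterSharedAnalogs(
    filterByLibraryMatch(
      filterByDeltaMass(
        filterBySource(s4, lf$library), dl, cfg$deltaTolerance,
        cfg$minOffsetOccurrence),
      lf$library),
    lf$fingerprints)
  expect_equal(length(again), length(s4))
  expect_identical(vapply(again, function(x) x$analog_spectrum_id, ""),
                   vapply(s4, function(x) x$analog_spectrum_id, ""))
  expect_identical(lapply(again, function(x) names(x$parents)),
                   lapply(s4, function(x) names(x$parents)))
})
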