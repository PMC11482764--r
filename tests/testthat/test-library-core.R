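test_that("merging collections deduplicates by structure block and by name", {
  sA1 <- mkspec("c1_s1", 300, c(100, 150), c(1, 2), name = "penicillin G")
  sA2 <- mkspec("c2_s1", 300, c(100, 150), c(1, 2), name = "benzylpenicillin")
  sB <- mkspec("c2_s2", 250, c(90, 120), c(1, 1), name = "otherdrug")
  sIdx <- data.frame(
    name = c("penicillin G", "benzylpenicillin"),
    inchikey = c("JGSARLDLIJGVTE-MBNYWOFBSA-N", "JGSARLDLIJGVTE-MBNYWOFBSA-N"),
    stringsAsFactors = FALSE)
  lib <- mergeReferenceLibraries(list(list(sA1), list(sA2, sB)),
                                 structureIndex = sIdx)
  expect_length(drugIds(lib), 2)
  pen <- drugRecords(lib)[["JGSARLDLIJGVTE"]]
  expect_length(pen@spectra, 2)

  # first-synonym convention
  lib2 <- mergeReferenceLibraries(
    list(list(sA1)), structureIndex = sIdx,
    synonymIndex = list(c("benzylpenicillin", "penicillin G")))
  expect_equal(drugRecords(lib2)[[1]]@primaryName, "benzylpenicillin")
})

test_that("merge counts are exact and the merge is idempotent", {
  set.seed(9)
  colls <- lapply(1:10, function(i)
    lapply(1:3, function(j)
      mkspec(sprintf("cmp%02d_s%d", i, j), 200 + i, c(100, 110 + j),
             c(1, 2), name = sprintf("compound%02d", i))))
  lib <- mergeReferenceLibraries(colls)
  expect_length(drugIds(lib), 10)
  expect_length(librarySpectra(lib), 30)
  # merging the same spectra again adds nothing
  lib2 <- mergeReferenceLibraries(c(colls, colls))
  expect_length(drugIds(lib2), 10)
  expect_length(librarySpectra(lib2), 30)
  expect_equal(sort(drugIds(lib2)), sort(drugIds(lib)))

  anon <- Spectrum("anon", 100, cbind(mz = 50, intensity = 1))
  expect_warning(lib3 <- mergeReferenceLibraries(list(list(anon))),
                 "skipped")
  expect_equal(attr(lib3, "skipped"), 1L)
})

test_that("clinical-phase filtering keeps exactly the requested phases", {
  set.seed(10)
  phases <- c(rep("approved", 7), rep("clinical_trial", 5), rep("unknown", 8))
  recs <- lapply(seq_along(phases), function(i)
    DrugRecord(sprintf("d%02d", i), sprintf("name%02d", i),
               clinicalPhase = phases[i],
               spectra = list(mkspec(sprintf("sp%02d", i), 200 + i, 100, 1))))
  lib <- DrugLibrary(records = recs)
  kept <- filterClinicalPhase(lib, c("approved", "clinical_trial"))
  expect_length(drugIds(kept), 12)
  expect_identical(drugIds(filterClinicalPhase(lib, msDrugLib:::.CLINICAL_PHASES)),
                   drugIds(lib))
  # a compound of unknown phase is removed when unknown is not kept
  expect_false("d20" %in% drugIds(kept))
})

test_that("partial-name matching captures fused and suffixed metabolite names", {
  ven <- DrugRecord("ven", "venlafaxine",
                    spectra = list(mkspec("ven_s", 278.2, c(58, 121), c(5, 9))))
  lib <- DrugLibrary(records = list(ven = ven))
  candNames <- c("N-desmethylvenlafaxine", "O-desmethylvenlafaxine",
                 "N,O-didesmethylvenlafaxine", "N,N-didesmethylvenlafaxine",
                 "venlafaxine N-oxide")
  cands <- lapply(seq_along(candNames), function(i)
    mkspec(sprintf("cand%d", i), 260 + i, c(58, 100), c(1, 1),
           name = candNames[i]))
  res <- partialNameMetaboliteMatch(lib, cands)
  expect_length(res$metabolites, 5)
  expect_true(all(vapply(res$metabolites, function(r) r@parentDrugId,
                         character(1)) == "ven"))
  expect_true(all(vapply(res$metabolites, function(r) r@recordType,
                         character(1)) == "metabolite"))

  # exact library names are not metabolites
  exact <- mkspec("ex", 278.2, c(58, 121), c(5, 9), name = "venlafaxine")
  expect_length(partialNameMetaboliteMatch(lib, list(exact))$metabolites, 0)
})

test_that("partial-name matching requires a right word boundary and reviews ties", {
  carb <- DrugRecord("carb", "carbamazepine",
                     spectra = list(mkspec("carb_s", 237.1, c(100), c(1))))
  lib <- DrugLibrary(records = list(carb = carb))
  oxc <- mkspec("oxc", 253.1, c(100), c(1), name = "oxcarbazepine")
  expect_length(partialNameMetaboliteMatch(lib, list(oxc))$metabolites, 0)

  # short names embedded mid-word do not match
  val <- DrugRecord("val", "val",
                    spectra = list(mkspec("val_s", 100, c(50), c(1))))
  lib2 <- DrugLibrary(records = list(val = val))
  vs <- mkspec("vs", 436.2, c(50), c(1), name = "valsartan acid")
  expect_length(partialNameMetaboliteMatch(lib2, list(vs))$metabolites, 0)

  # equal-length ties to distinct drugs go to the review list
  d1 <- DrugRecord("d1", "alphafen", spectra = list(mkspec("d1s", 200, 50, 1)))
  d2 <- DrugRecord("d2", "betaafen", spectra = list(mkspec("d2s", 210, 50, 1)))
  lib3 <- DrugLibrary(records = list(d1 = d1, d2 = d2))
  amb <- mkspec("amb", 220, c(50), c(1), name = "alphafen betaafen salt")
  res <- partialNameMetaboliteMatch(lib3, list(amb))
  expect_length(res$metabolites, 0)
  expect_equal(nrow(res$review), 1)
})

test_that("metadata enrichment fills without overwriting and tracks provenance", {
  mk <- function(i, ik) DrugRecord(
    sprintf("r%02d", i), sprintf("cmpd%02d", i), inchikey = ik,
    spectra = list(mkspec(sprintf("rs%02d", i), 200 + i, 100, 1)))
  recs <- lapply(1:15, function(i)
    mk(i, if (i <= 9) sprintf("%014dABCDEFGHIJ-N", i) else NA_character_))
  lib <- DrugLibrary(records = recs)
  tab1 <- list(key = "inchikey", data = data.frame(
    inchikey = sprintf("%014dABCDEFGHIJ-N", 1:9),
    pharmacologic_class = "statin", stringsAsFactors = FALSE))
  tab2 <- list(key = "inchikey", data = data.frame(
    inchikey = sprintf("%014dABCDEFGHIJ-N", 1:9),
    pharmacologic_class = "lipid agent", stringsAsFactors = FALSE))
  tab3 <- list(key = "name", data = data.frame(
    name = sprintf("cmpd%02d", 10:12),
    pharmacologic_class = "NSAID", stringsAsFactors = FALSE))
  out <- enrichMetadata(lib, list(tab1, tab2, tab3))
  expect_identical(drugIds(out), drugIds(lib))  # never removes records
  withMeta <- Filter(function(m) length(m@pharmacologicClass) > 0,
                     drugMeta(out))
  expect_length(withMeta, 12)
  expect_equal(drugMeta(out)[["r01"]]@pharmacologicClass, "statin")
  expect_equal(drugMeta(out)[["r10"]]@provenance, "name-join")
  expect_error(enrichMetadata(lib, list(list(key = "inchikey",
                                             data = data.frame(x = 1)))),
               "join key")
})

test_that("library export writes the spectra and the metadata columns", {
  lib <- tinyLibrary()
  dir <- withr::local_tempdir()
  paths <- exportDrugLibrary(lib, dir)
  expect_length(readMGF(paths[["mgf"]]), 2)
  meta <- read.delim(paths[["tsv"]])
  expect_setequal(meta$drug_id, c("drugA", "drugB"))
  expect_true(all(c("exposure_source", "pharmacologic_class",
                    "therapeutic_indication") %in% names(meta)))
})
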