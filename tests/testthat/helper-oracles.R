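# Independent oracles and small builders used across the suite.

# terse spectrum builder
mkspec <- function(id, prec, mz, int, rt = NA_real_, name = NA_character_,
                   charge = 1L) {
  Spectrum(id, precursorMz = prec, peaks = cbind(mz = mz, intensity = int),
           retentionTime = rt, compoundName = name, charge = charge)
}

randSpec <- function(id, npeaks = NULL, prec = NULL) {
  if (is.null(npeaks)) npeaks <- sample(1:6, 1)
  if (is.null(prec)) prec <- runif(1, 200, 600)
  mkspec(id, prec, mz = sort(runif(npeaks, 50, 500)),
         int = runif(npeaks, 1, 100))
}

# Exhaustive optimal-assignment modified-cosine score: enumerates every
# one-to-one selection of candidate fragment pairs (unshifted within tol,
# or shifted by the precursor difference) and maximises the summed
# sqrt-intensity products. Independent of the greedy implementation.
exactModifiedCosine <- function(a, b, tol = 0.01) {
  pa <- peakMatrix(a); pb <- peakMatrix(b)
  wa <- sqrt(pa[, 2]); wb <- sqrt(pb[, 2])
  shift <- precursorMz(b) - precursorMz(a)
  ii <- integer(); jj <- integer()
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb))) {
    if (abs(pa[i, 1] - pb[j, 1]) <= tol ||
        abs(pa[i, 1] + shift - pb[j, 1]) <= tol) {
      ii <- c(ii, i); jj <- c(jj, j)
    }
  }
  best <- 0
  n <- length(ii)
  rec <- function(k, usedA, usedB, acc) {
    if (k > n) { best <<- max(best, acc); return(invisible()) }
    rec(k + 1L, usedA, usedB, acc)
    i <- ii[k]; j <- jj[k]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <- TRUE; usedB[j] <- TRUE
      rec(k + 1L, usedA, usedB, acc + wa[i] * wb[j])
    }
  }
  rec(1L, logical(nrow(pa)), logical(nrow(pb)), 0)
  denom <- sqrt(sum(wa^2)) * sqrt(sum(wb^2))
  if (denom > 0) best / denom else 0
}

# candidate builder for filter unit tests (bypasses clustering)
mkCandidate <- function(spectrum, parents) {
  msDrugLib:::.newCandidate(spectrum, paste0("cl_", spectrumId(spectrum)),
                            spectrumId(spectrum), parents)
}

mkParent <- function(delta, score = 0.9, matched_peaks = 8L) {
  list(delta = delta, score = score, matched_peaks = matched_peaks,
       n_matches = 1L, interpretation = NA_character_,
       matched_delta = NA_real_)
}

# tiny two-drug library with metadata, for filter tests
tinyLibrary <- function() {
  s1 <- mkspec("ref_a", 300, c(100, 150, 200), c(10, 20, 30))
  s2 <- mkspec("ref_b", 350, c(110, 160, 210), c(10, 20, 30))
  DrugLibrary(
    records = list(
      drugA = DrugRecord("drugA", "alphadrug", spectra = list(s1)),
      drugB = DrugRecord("drugB", "betadrug", spectra = list(s2))),
    pharmMeta = list(
      drugA = DrugMetadata("drugA", exposureSource = "medical"),
      drugB = DrugMetadata("drugB",
                           exposureSource = c("medical", "endogenous"))))
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

digest_peaks <- function(s)
  paste(sprintf("%.6f", peakMatrix(s)), collapse = "|")
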