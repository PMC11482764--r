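# MGF / MSP spectrum I/O and delimited feature-table I/O.

.parseChargeToken <- function(tok) {
  # MGF writes charges as "2+", "1-", sometimes bare integers
  tok <- trimws(tok)
  sgn <- if (grepl("-", tok, fixed = TRUE)) -1L else 1L
  n <- suppressWarnings(as.integer(gsub("[^0-9]", "", tok)))
  if (is.na(n)) NA_integer_ else sgn * n
}

#' Read an MGF file
#'
#' Parses Mascot generic format: BEGIN IONS / END IONS blocks with PEPMASS,
#' optional CHARGE, TITLE, NAME, and retention time as either RTINSECONDS or
#' RTINMINUTES (the internal unit is minutes). Spectra without a charge
#' default to +1 (positive mode assumed). Peak lists are deduplicated and
#' sorted ascending on construction.
#'
#' @param path path to an MGF file.
#' @return list of [Spectrum-class]. An empty file returns an empty list
#'   with a warning.
#' @export
readMGF <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    warning(sprintf("empty MGF file: %s", path))
    return(list())
  }
  spectra <- list()
  i <- 1L
  nblock <- 0L
  src <- basename(path)
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (!identical(toupper(ln), "BEGIN IONS"))
      stop(sprintf("%s:%d: expected BEGIN IONS, got '%s'", path, i, ln))
    nblock <- nblock + 1L
    fields <- list()
    mzs <- numeric(); ints <- numeric()
    i <- i + 1L
    closed <- FALSE
    while (i <= n) {
      ln <- trimws(lines[[i]])
      if (identical(toupper(ln), "END IONS")) { closed <- TRUE; i <- i + 1L; break }
      if (nzchar(ln)) {
        if (grepl("=", ln, fixed = TRUE)) {
          key <- toupper(sub("=.*$", "", ln))
          fields[[key]] <- sub("^[^=]*=", "", ln)
        } else {
          parts <- strsplit(ln, "[[:space:]]+")[[1]]
          vals <- suppressWarnings(as.numeric(parts[1:2]))
          if (length(parts) < 2L || anyNA(vals))
            stop(sprintf("%s:%d: malformed peak line '%s'", path, i, ln))
          mzs <- c(mzs, vals[1L]); ints <- c(ints, vals[2L])
        }
      }
      i <- i + 1L
    }
    if (!closed)
      stop(sprintf("%s: unterminated BEGIN IONS block starting near line %d",
                   path, i))
    pm <- fields[["PEPMASS"]]
    if (is.null(pm))
      stop(sprintf("%s: block %d lacks PEPMASS", path, nblock))
    pm <- suppressWarnings(as.numeric(strsplit(trimws(pm),
                                               "[[:space:]]+")[[1]][1L]))
    if (is.na(pm)) stop(sprintf("%s: block %d has non-numeric PEPMASS", path,
                                nblock))
    charge <- if (!is.null(fields[["CHARGE"]]))
      .parseChargeToken(fields[["CHARGE"]]) else 1L
    if (is.na(charge)) charge <- 1L
    rt <- NA_real_
    if (!is.null(fields[["RTINSECONDS"]]))
      rt <- suppressWarnings(as.numeric(fields[["RTINSECONDS"]])) / 60
    else if (!is.null(fields[["RTINMINUTES"]]))
      rt <- suppressWarnings(as.numeric(fields[["RTINMINUTES"]]))
    id <- fields[["TITLE"]]
    if (is.null(id) || !nzchar(id)) id <- sprintf("%s_scan%d", src, nblock)
    nm <- fields[["NAME"]]
    adduct <- fields[["ADDUCT"]]
    spectra[[length(spectra) + 1L]] <- Spectrum(
      spectrumId = id, precursorMz = pm,
      peaks = cbind(mz = mzs, intensity = ints), charge = charge,
      retentionTime = rt, sourceFile = src,
      compoundName = if (is.null(nm)) NA_character_ else nm,
      adduct = if (is.null(adduct)) NA_character_ else adduct)
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' m/z values are written with five decimals (>= 4 required for round-trip
#' fidelity at the 1e-4 Th level); retention time is emitted as RTINSECONDS.
#'
#' @param spectra non-empty list of [Spectrum-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMGF <- function(spectra, path) {
  if (!length(spectra)) stop("spectra must be non-empty")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    lines <- c("BEGIN IONS",
               paste0("TITLE=", s@spectrumId),
               sprintf("PEPMASS=%.5f", s@precursorMz),
               sprintf("CHARGE=%d%s", abs(s@charge),
                       if (s@charge < 0) "-" else "+"))
    if (!is.na(s@retentionTime))
      lines <- c(lines, sprintf("RTINSECONDS=%.4f", s@retentionTime * 60))
    if (!is.na(s@compoundName))
      lines <- c(lines, paste0("NAME=", s@compoundName))
    if (!is.na(s@adduct))
      lines <- c(lines, paste0("ADDUCT=", s@adduct))
    p <- s@peaks
    if (nrow(p))
      lines <- c(lines, sprintf("%.5f %.8g", p[, 1L], p[, 2L]))
    lines <- c(lines, "END IONS", "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an MSP library file (read-only)
#'
#' Minimal NIST MSP dialect for reference libraries: records begin with
#' \code{Name:}, carry \code{PrecursorMZ:} (or \code{MW:}) and
#' \code{Num Peaks:}, followed by whitespace- or semicolon-separated peak
#' pairs.
#'
#' @param path path to an MSP file.
#' @return list of [Spectrum-class].
#' @export
readMSP <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  rec <- NULL
  src <- basename(path)
  flush <- function(rec, k) {
    if (is.null(rec)) return(NULL)
    if (is.null(rec$pm))
      stop(sprintf("%s: record '%s' lacks PrecursorMZ", path, rec$name))
    Spectrum(spectrumId = sprintf("%s_msp%d", src, k),
             precursorMz = rec$pm,
             peaks = cbind(mz = rec$mz, intensity = rec$int),
             charge = 1L, sourceFile = src, compoundName = rec$name)
  }
  k <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (grepl("^Name:", ln, ignore.case = TRUE)) {
      if (!is.null(rec)) {
        k <- k + 1L
        spectra[[k]] <- flush(rec, k)
      }
      rec <- list(name = trimws(sub("^Name:", "", ln, ignore.case = TRUE)),
                  pm = NULL, mz = numeric(), int = numeric())
    } else if (is.null(rec)) {
      stop(sprintf("%s:%d: content before first Name:", path, i))
    } else if (grepl("^(PrecursorMZ|PRECURSORMZ|MW):", ln, ignore.case = TRUE)) {
      rec$pm <- suppressWarnings(as.numeric(sub("^[^:]*:", "", ln)))
    } else if (grepl("^[A-Za-z][A-Za-z ._]*:", ln)) {
      # other header fields ignored
    } else {
      parts <- strsplit(gsub(";", " ", ln), "[[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (anyNA(vals) || length(vals) %% 2L != 0L)
        stop(sprintf("%s:%d: malformed peak line '%s'", path, i, ln))
      idx <- seq(1L, length(vals), by = 2L)
      rec$mz <- c(rec$mz, vals[idx]); rec$int <- c(rec$int, vals[idx + 1L])
    }
  }
  if (!is.null(rec)) {
    k <- k + 1L
    spectra[[k]] <- flush(rec, k)
  }
  spectra
}

# ---------------------------------------------------------------------------
# Feature tables
# ---------------------------------------------------------------------------

.readDelim <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a cohort feature table
#'
#' Delimited text (TSV or CSV, autodetected by extension) with an id header
#' row and an id first column. Blank cells read as 0; duplicate ids and
#' negative values are errors. Optional columns/rows named \code{mz} and
#' \code{rt} (on the feature axis) populate per-feature precursor m/z and
#' retention time.
#'
#' @param path input path.
#' @param orientation "rows-are-samples" (default) or "rows-are-features".
#' @return a [CohortFeatureTable-class].
#' @export
readFeatureTable <- function(path,
                             orientation = c("rows-are-samples",
                                             "rows-are-features")) {
  orientation <- match.arg(orientation)
  df <- .readDelim(path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate row ids in %s", path))
  if (anyDuplicated(colnames(df)[-1L]))
    stop(sprintf("duplicate column ids in %s", path))
  df <- df[, -1L, drop = FALSE]
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  m[is.na(m)] <- 0
  rownames(m) <- ids
  if (orientation == "rows-are-features") m <- t(m)
  # samples x features now
  featMz <- featRt <- NULL
  special <- tolower(rownames(m)) %in% c("mz", "rt")
  if (any(special)) {
    aux <- m[special, , drop = FALSE]
    m <- m[!special, , drop = FALSE]
    if ("mz" %in% tolower(rownames(aux)))
      featMz <- aux[match("mz", tolower(rownames(aux))), ]
    if ("rt" %in% tolower(rownames(aux)))
      featRt <- aux[match("rt", tolower(rownames(aux))), ]
  }
  if (any(m < 0))
    stop(sprintf("negative peak areas in %s", path))
  CohortFeatureTable(m, featureMz = featMz, featureRt = featRt)
}

#' Write a cohort feature table
#'
#' @param x a [CohortFeatureTable-class].
#' @param path output path (.csv or .tsv).
#' @param orientation as in [readFeatureTable()].
#' @return invisibly, the path.
#' @export
writeFeatureTable <- function(x, path,
                              orientation = c("rows-are-samples",
                                              "rows-are-features")) {
  orientation <- match.arg(orientation)
  m <- peakAreas(x)
  if (orientation == "rows-are-features") m <- t(m)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
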