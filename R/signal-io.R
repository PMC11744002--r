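## MIT-BIH annotation codes <-> symbols (subset of the standard code table
## covering every beat and non-beat symbol this package emits or consumes).
MIT_CODE_TO_SYMBOL <- c(
  `1` = "N", `2` = "L", `3` = "R", `4` = "a", `5` = "V", `6` = "F",
  `7` = "J", `8` = "A", `9` = "S", `10` = "E", `11` = "j", `12` = "/",
  `13` = "Q", `14` = "~", `16` = "|", `18` = "s", `19` = "T", `20` = "*",
  `21` = "D", `22` = "\"", `23` = "=", `24` = "p", `25` = "B", `26` = "^",
  `27` = "t", `28` = "+", `29` = "u", `30` = "?", `31` = "!", `32` = "[",
  `33` = "]", `34` = "e", `35` = "n", `37` = "x", `38` = "f", `39` = "(",
  `40` = ")", `41` = "r"
)
MIT_SYMBOL_TO_CODE <- stats::setNames(
  as.integer(names(MIT_CODE_TO_SYMBOL)), MIT_CODE_TO_SYMBOL
)

## AAMI EC57 grouping of MIT-BIH beat symbols into the five classes.
AAMI_TABLE <- c(
  N = "N", L = "N", R = "N", e = "N", j = "N", B = "N",
  A = "S", a = "S", J = "S", S = "S", n = "S",
  V = "V", E = "V", r = "V",
  F = "F",
  `/` = "Q", f = "Q", Q = "Q", `?` = "Q"
)

## annotation symbols that are not beats (rhythm changes, waveform
## boundaries, noise markers, ...): callers must skip these
NON_BEAT_SYMBOLS <- c(
  "+", "~", "|", "s", "T", "*", "D", "\"", "=", "p", "t", "u",
  "!", "[", "]", "(", ")", "^", "x"
)

#' Map an MIT-BIH beat symbol to its AAMI class
#'
#' Implements the AAMI EC57 grouping: N = {N, L, R, e, j, B},
#' S = {A, a, J, S, n}, V = {V, E, r}, F = {F}, Q = {/, f, Q, ?}.
#' Beat symbols absent from the table map to Q (the unknown-beat
#' catch-all); non-beat annotation symbols (rhythm markers, noise flags,
#' wave boundaries) raise an error so callers can skip them.
#'
#' @param symbol single-character annotation symbol.
#' @return one of `"N"`, `"S"`, `"V"`, `"F"`, `"Q"`.
#' @examples
#' mapSymbolToAami("A") # atrial premature -> S
#' mapSymbolToAami("L") # left bundle branch block -> N
#' @export
mapSymbolToAami <- function(symbol) {
  if (length(symbol) != 1L || nchar(symbol) != 1L) {
    stop("symbol must be a single character")
  }
  if (symbol %in% NON_BEAT_SYMBOLS) {
    stop("'", symbol, "' is not a beat annotation")
  }
  cls <- AAMI_TABLE[symbol]
  if (is.na(cls)) "Q" else unname(cls)
}

#' Read an ECG record
#'
#' Two dialects are supported:
#' * `"csv"` — `<base>.csv` with header `sample,<ch1>,<ch2>,...`, values in
#'   millivolts, plus a JSON sidecar `<base>.meta.json` carrying `fs`,
#'   `recordId` and `channelNames`.
#' * `"wfdb"` — `<base>.hea` header plus `<base>.dat` signal file
#'   (format 16: interleaved little-endian 16-bit integers); values are
#'   converted to millivolts using the per-signal gain and baseline.
#'
#' @param path record base path (with or without extension).
#' @param dialect `"csv"` or `"wfdb"`.
#' @return an [ECGRecord-class].
#' @seealso [writeRecord()], [readAnnotations()]
#' @export
readRecord <- function(path, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  base <- sub("\\.(csv|hea|dat)$", "", path)
  if (dialect == "csv") {
    csv <- paste0(base, ".csv")
    meta <- paste0(base, ".meta.json")
    if (!file.exists(csv)) stop("no such file: ", csv)
    if (!file.exists(meta)) stop("missing sidecar: ", meta)
    md <- jsonlite::read_json(meta, simplifyVector = TRUE)
    if (is.null(md$fs) || !is.numeric(md$fs) || md$fs <= 0) {
      stop("format error in ", meta, ": field 'fs' must be a positive number")
    }
    df <- utils::read.csv(csv, check.names = FALSE)
    if (colnames(df)[1L] != "sample") {
      stop("format error in ", csv, ": first column must be 'sample'")
    }
    sig <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(sig)) {
      stop("format error in ", csv, ": non-numeric sample values")
    }
    ECGRecord(t(sig),
      fs = md$fs, channelNames = colnames(df)[-1L],
      recordId = if (!is.null(md$recordId)) md$recordId else basename(base)
    )
  } else {
    read_wfdb_record(base)
  }
}

#' Write an ECG record (and optional annotations)
#'
#' Inverse of [readRecord()]; see there for the dialect definitions.
#' Annotations are written to `<base>.ann.csv` (csv dialect) or `<base>.atr`
#' (wfdb dialect, MIT annotation byte format).
#'
#' @param record an [ECGRecord-class].
#' @param path record base path.
#' @param annotations optional [beatAnnotations()] table.
#' @param dialect `"csv"` or `"wfdb"`.
#' @return invisibly, the base path written.
#' @export
writeRecord <- function(record, path, annotations = NULL,
                        dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  stopifnot(is(record, "ECGRecord"))
  validObject(record)
  if (!is.null(annotations) && nrow(annotations) &&
    is.unsorted(annotations$sampleIndex)) {
    stop("annotations must be sorted by sampleIndex")
  }
  base <- sub("\\.(csv|hea|dat)$", "", path)
  if (dialect == "csv") {
    df <- data.frame(sample = seq_len(nSamples(record)) - 1L)
    sig <- t(record@samples)
    colnames(sig) <- channelNames(record)
    utils::write.csv(cbind(df, as.data.frame(sig)),
      paste0(base, ".csv"),
      row.names = FALSE
    )
    jsonlite::write_json(
      list(
        fs = record@fs, recordId = record@recordId,
        channelNames = channelNames(record)
      ),
      paste0(base, ".meta.json"),
      auto_unbox = TRUE, digits = NA
    )
    if (!is.null(annotations)) {
      utils::write.csv(as.data.frame(annotations),
        paste0(base, ".ann.csv"),
        row.names = FALSE
      )
    }
  } else {
    write_wfdb_record(record, base)
    if (!is.null(annotations)) {
      write_mit_annotations(annotations, paste0(base, ".atr"))
    }
  }
  invisible(base)
}

#' Read beat annotations
#'
#' Reads `<base>.ann.csv` (csv dialect) or `<base>.atr` (wfdb dialect).
#' Non-beat annotations (rhythm changes, noise markers) are skipped; the
#' number skipped is attached as attribute `skippedNonBeat`.
#'
#' @param path record base path.
#' @param dialect `"csv"` or `"wfdb"`.
#' @return a [beatAnnotations()] `DataFrame`.
#' @export
readAnnotations <- function(path, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  base <- sub("\\.(csv|hea|dat|atr|ann)$", "", path)
  if (dialect == "csv") {
    f <- paste0(base, ".ann.csv")
    if (!file.exists(f)) stop("no such file: ", f)
    df <- utils::read.csv(f, colClasses = c("integer", "character", "character"))
    if (!nrow(df)) {
      out <- beatAnnotations(integer(0), character(0))
      attr(out, "skippedNonBeat") <- 0L
      return(out)
    }
    isBeat <- !(df$symbol %in% NON_BEAT_SYMBOLS)
    out <- beatAnnotations(df$sampleIndex[isBeat], df$symbol[isBeat])
    attr(out, "skippedNonBeat") <- sum(!isBeat)
    out
  } else {
    read_mit_annotations(paste0(base, ".atr"))
  }
}

## ---- WFDB codec (format 16) -------------------------------------------

WFDB_GAIN <- 1000 # ADC units per millivolt used when writing

write_wfdb_record <- function(record, base) {
  nSig <- nChannels(record)
  n <- nSamples(record)
  datName <- paste0(basename(base), ".dat")
  adc <- round(record@samples * WFDB_GAIN)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  storage.mode(adc) <- "integer"
  ## samples are ch x n and R arrays are column-major, so as.vector gives
  ## the channel-interleaved sample order WFDB expects
  interleaved <- as.vector(adc)
  con <- file(paste0(base, ".dat"), "wb")
  writeBin(interleaved, con, size = 2L, endian = "little")
  close(con)
  checksum <- vapply(seq_len(nSig), function(i) {
    s <- sum(as.numeric(adc[i, ])) %% 65536
    as.integer(if (s >= 32768) s - 65536 else s)
  }, integer(1))
  hdr <- c(
    sprintf("%s %d %g %d", basename(base), nSig, record@fs, n),
    sprintf(
      "%s 16 %d(0)/mV 16 0 %d %d 0 %s",
      datName, as.integer(WFDB_GAIN), adc[, 1L], checksum,
      channelNames(record)
    )
  )
  writeLines(hdr, paste0(base, ".hea"))
}

read_wfdb_record <- function(base) {
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop("no such file: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nSig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(top[3L]) else 250
  n <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  if (!is.finite(fs) || fs <= 0) stop("format error in ", hea, ": fs must be positive")
  sigLines <- lines[1L + seq_len(nSig)]
  gains <- numeric(nSig)
  baselines <- numeric(nSig)
  names <- character(nSig)
  fmt <- character(nSig)
  for (i in seq_len(nSig)) {
    f <- strsplit(trimws(sigLines[i]), "\\s+")[[1L]]
    fmt[i] <- f[2L]
    gainField <- f[3L]
    m <- regmatches(gainField, regexec("^([-0-9.eE+]+)(\\(([-0-9]+)\\))?(/(.*))?$", gainField))[[1L]]
    gains[i] <- as.numeric(m[2L])
    baselines[i] <- if (nzchar(m[4L])) as.numeric(m[4L]) else 0
    names[i] <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else paste0("ch", i)
    if (gains[i] == 0) gains[i] <- 200 # WFDB convention for unspecified gain
  }
  if (any(fmt != "16")) stop("only WFDB format 16 is supported, got: ", paste(unique(fmt), collapse = ","))
  dat <- paste0(base, ".dat")
  if (!file.exists(dat)) stop("no such file: ", dat)
  raw <- readBin(dat, "integer",
    n = file.info(dat)$size / 2L, size = 2L,
    signed = TRUE, endian = "little"
  )
  if (is.na(n)) n <- length(raw) %/% nSig
  mat <- matrix(raw[seq_len(nSig * n)], nrow = nSig)
  mv <- (mat - baselines) / gains
  ECGRecord(mv, fs = fs, channelNames = names, recordId = basename(base))
}

## ---- MIT annotation codec ----------------------------------------------

write_mit_annotations <- function(annotations, path) {
  words <- integer(0)
  for (i in seq_len(nrow(annotations))) {
    code <- MIT_SYMBOL_TO_CODE[annotations$symbol[i]]
    if (is.na(code)) code <- MIT_SYMBOL_TO_CODE["Q"]
    # intervals are differential, from the previous annotation (or sample 0)
    delta <- annotations$sampleIndex[i] -
      (if (i == 1L) 0L else annotations$sampleIndex[i - 1L])
    if (delta > 1023L) {
      ## SKIP word, then the 32-bit interval (high word first), then the
      ## annotation word with a zero interval
      words <- c(
        words, bitwShiftL(59L, 10L),
        bitwAnd(bitwShiftR(delta, 16L), 65535L),
        bitwAnd(delta, 65535L),
        bitwOr(bitwShiftL(as.integer(code), 10L), 0L)
      )
    } else {
      words <- c(words, bitwOr(bitwShiftL(as.integer(code), 10L), delta))
    }
  }
  words <- c(words, 0L) # end of file
  con <- file(path, "wb")
  ## writeBin with size=2 expects values representable as signed shorts
  signed <- ifelse(words >= 32768L, words - 65536L, words)
  writeBin(as.integer(signed), con, size = 2L, endian = "little")
  close(con)
}

read_mit_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBin(path, "integer",
    n = file.info(path)$size / 2L, size = 2L,
    signed = FALSE, endian = "little"
  )
  idx <- integer(0)
  sym <- character(0)
  skipped <- 0L
  t <- 0L
  i <- 1L
  while (i <= length(raw)) {
    word <- raw[i]
    code <- bitwShiftR(word, 10L)
    interval <- bitwAnd(word, 1023L)
    if (word == 0L) break
    if (code == 59L) { # SKIP: 4-byte interval follows
      delta <- bitwShiftL(raw[i + 1L], 16L) + raw[i + 2L]
      t <- t + delta
      i <- i + 3L
      next
    } else if (code == 63L) { # AUX: skip payload
      i <- i + 1L + (interval + interval %% 2L) %/% 2L
      next
    } else if (code %in% c(60L, 61L, 62L)) { # NUM / SUB / CHN
      i <- i + 1L
      next
    }
    t <- t + interval
    s <- MIT_CODE_TO_SYMBOL[as.character(code)]
    if (!is.na(s) && !(s %in% NON_BEAT_SYMBOLS)) {
      idx <- c(idx, t)
      sym <- c(sym, s)
    } else {
      skipped <- skipped + 1L
    }
    i <- i + 1L
  }
  out <- beatAnnotations(idx, sym)
  attr(out, "skippedNonBeat") <- skipped
  out
}

#' List records in a directory
#'
#' @param dir directory to scan.
#' @param dialect `"csv"` or `"wfdb"`.
#' @return character vector of record base paths.
#' @export
listRecords <- function(dir, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  ext <- if (dialect == "csv") "\\.csv$" else "\\.hea$"
  files <- list.files(dir, pattern = ext, full.names = TRUE)
  files <- files[!grepl("\\.(ann|meta)\\.", files)]
  sub(ext, "", files)
}
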