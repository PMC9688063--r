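# Recording I/O: plain CSV (channels x samples, JSON sidecar with the
# sampling rate) and a minimal EDF reader/writer (16-bit continuous
# recordings, one signal per channel, 1-second data records).

padTo <- function(s, n) {
  s <- substr(s, 1, n)
  paste0(s, strrep(" ", n - nchar(s)))
}

#' Write a recording to disk
#'
#' @param rec an [EEGRecording-class].
#' @param path output path.
#' @param format `"csv"` (channels x samples matrix with a `channel`
#'   column, plus a `<path>.json` sidecar carrying fs, subject and group)
#'   or `"edf"` (16-bit European Data Format, 1-second records; the
#'   trailing sub-second remainder is dropped).
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(channel = rownames(rec@data), rec@data,
                     check.names = FALSE)
    colnames(df) <- c("channel", sprintf("s%d", seq_len(ncol(rec@data))))
    utils::write.csv(df, path, row.names = FALSE)
    jsonlite::write_json(list(fs = rec@fs, subject_id = rec@subjectId,
                              group = rec@group,
                              channels = rec@montage@channels),
                         paste0(path, ".json"), auto_unbox = TRUE)
    return(invisible(path))
  }
  fs <- round(rec@fs)
  if (abs(fs - rec@fs) > 1e-9)
    stop("EDF writer supports integer sampling rates only")
  ns <- nrow(rec@data)
  nrec <- ncol(rec@data) %/% fs
  if (nrec < 1L) stop("recording shorter than one EDF record (1 s)")
  X <- rec@data[, seq_len(nrec * fs), drop = FALSE]
  # the header stores physical bounds with 2 decimals; use the rounded
  # bounds for scaling so writer and reader agree exactly
  pmin_ <- floor(apply(X, 1, min) * 100) / 100
  pmax_ <- ceiling(apply(X, 1, max) * 100) / 100
  pmax_[pmax_ <= pmin_] <- pmin_[pmax_ <= pmin_] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(padTo("0", 8), padTo(rec@subjectId, 80),
                padTo(rec@group, 80), "01.01.00", "00.00.00",
                padTo(as.character(256 * (1 + ns)), 8), strrep(" ", 44),
                padTo(as.character(nrec), 8), padTo("1", 8),
                padTo(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, padTo, character(1), n = width),
                     collapse = ""), con, eos = NULL)
  field(rownames(X), 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(sprintf("%.2f", pmin_), 8)
  field(sprintf("%.2f", pmax_), 8)
  field(rep(as.character(dmin), ns), 8)
  field(rep(as.character(dmax), ns), 8)
  field(rep("", ns), 80)
  field(rep(as.character(fs), ns), 8)
  field(rep("", ns), 32)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    sl <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((X[ch, sl] - pmin_[ch]) / scale[ch] + dmin)
      writeBin(as.integer(pmin(dmax, pmax(dmin, dig))), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

readEDFHeader <- function(con) {
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  rd(8); rd(8)                     # date, time
  as.numeric(rd(8))                # header bytes
  rd(44)
  nrec <- as.integer(rd(8)); durRec <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  vapply(seq_len(ns), function(i) rd(80), character(1))
  vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(80), character(1))
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(32), character(1))
  list(patient = trimws(patient), recording = trimws(recording),
       nrec = nrec, durRec = durRec, ns = ns, labels = labels,
       pmin = pmin_, pmax = pmax_, dmin = dmin, dmax = dmax,
       nsamp = nsamp)
}

resolveMontage <- function(channels) {
  std <- standardMontage1020()
  idx <- match(channels, std@channels)
  if (anyNA(idx)) {
    warning("unknown channel name(s): ",
            paste(channels[is.na(idx)], collapse = ", "),
            "; falling back to positional 10/20 coordinates")
    if (length(channels) > length(std@channels))
      stop("cannot positionally resolve more channels than the 10/20 montage")
    return(montage(channels,
                   std@positions[seq_along(channels), , drop = FALSE]))
  }
  montage(channels, std@positions[idx, , drop = FALSE])
}

#' Read a recording from disk
#'
#' @param path a `.csv` (channels x samples, as written by
#'   [writeRecording()]; the sampling rate comes from the JSON sidecar or
#'   the `fs` argument) or `.edf` file.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param fs sampling rate override for CSV without a sidecar.
#' @param subjectId,group optional overrides of the stored metadata.
#' @return An [EEGRecording-class]; the montage is resolved from the
#'   channel names (unknown names fall back to positional 10/20
#'   coordinates with a warning).
#' @export
readRecording <- function(path, format = c("auto", "csv", "edf"),
                          fs = NULL, subjectId = NULL, group = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") {
    side <- paste0(path, ".json")
    meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                       simplifyVector = TRUE)
            else list()
    if (is.null(fs)) fs <- meta$fs
    if (is.null(fs))
      stop("CSV recordings need a sampling rate (sidecar JSON or fs=)")
    df <- utils::read.csv(path, check.names = FALSE)
    ch <- as.character(df[[1]])
    X <- as.matrix(df[, -1, drop = FALSE])
    rownames(X) <- ch
    dimnames(X)[2] <- list(NULL)
    return(new("EEGRecording", data = X, fs = as.numeric(fs),
               montage = resolveMontage(ch),
               subjectId = subjectId %||% (meta$subject_id %||% "S"),
               group = group %||% (meta$group %||% "NA")))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readEDFHeader(con)
  if (length(unique(h$nsamp)) != 1L)
    stop("EDF reader supports a common sampling rate across signals")
  fs_ <- h$nsamp[1] / h$durRec
  X <- matrix(0, h$ns, h$nrec * h$nsamp[1])
  for (r in seq_len(h$nrec)) for (ch in seq_len(h$ns)) {
    dig <- readBin(con, "integer", n = h$nsamp[ch], size = 2,
                   endian = "little")
    sl <- ((r - 1L) * h$nsamp[ch] + 1L):(r * h$nsamp[ch])
    X[ch, sl] <- h$pmin[ch] + (dig - h$dmin[ch]) *
      (h$pmax[ch] - h$pmin[ch]) / (h$dmax[ch] - h$dmin[ch])
  }
  rownames(X) <- h$labels
  new("EEGRecording", data = X, fs = fs_,
      montage = resolveMontage(h$labels),
      subjectId = subjectId %||% h$patient,
      group = group %||% h$recording)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a template set as CSV + JSON metadata
#'
#' @param templates a [TemplateSet-class].
#' @param path CSV path (channels x K matrix with a `channel` column);
#'   metadata (labels, GEV, restarts, seed) goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeTemplates <- function(templates, path) {
  df <- data.frame(channel = rownames(templates@maps), templates@maps,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(labels = templates@labels, gev = templates@gev,
                            nRestarts = templates@nRestarts,
                            seed = templates@seed),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a template set written by [writeTemplates()]
#'
#' @param path CSV path.
#' @return A [TemplateSet-class].
#' @export
readTemplates <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  maps <- as.matrix(df[, -1, drop = FALSE])
  rownames(maps) <- df[[1]]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  gv <- if (is.null(meta$gev)) NA_real_ else as.numeric(meta$gev)
  new("TemplateSet", maps = maps, labels = as.character(meta$labels),
      gev = gv, nRestarts = as.integer(meta$nRestarts),
      seed = as.integer(meta$seed))
}

#' Write a feature table as CSV (+ JSON flag sidecar)
#'
#' The CSV header is exactly `subject_id`, `group`, then the 20 feature
#' columns; the absent-state flags travel in `<path>.json`.
#'
#' @param table a feature table from [extractFeatureTable()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  cols <- c("subject_id", "group",
            intersect(microstateFeatureNames(), names(table)))
  utils::write.csv(table[, cols, drop = FALSE], path, row.names = FALSE)
  fl <- attr(table, "flags")
  jsonlite::write_json(
    list(flags = if (is.null(fl)) list() else fl),
    paste0(path, ".json"))
  invisible(path)
}
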