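#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' (`signal::filtfilt`), per channel: zero phase distortion, ~unit gain in
#' the passband.
#'
#' @param rec an [EEGRecording-class].
#' @param low,high band edges in Hz (defaults 2 and 20).
#' @return The filtered [EEGRecording-class].
#' @export
bandpassFilter <- function(rec, low = 2, high = 20) {
  fs <- rec@fs
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= fs / 2) stop("high edge must be below the Nyquist frequency")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(rec@data, 1, function(ch) signal::filtfilt(bf, ch)))
  dimnames(out) <- dimnames(rec@data)
  initialize(rec, data = out)
}

#' Common-average reference
#'
#' Subtracts, at every sample, the mean over channels, so that each
#' column of the data matrix has zero mean. Idempotent.
#'
#' @param rec an [EEGRecording-class] with at least 2 channels.
#' @return The re-referenced [EEGRecording-class].
#' @export
averageReference <- function(rec) {
  if (nrow(rec@data) < 2L) stop("average reference needs >= 2 channels")
  initialize(rec, data = sweep(rec@data, 2, colMeans(rec@data)))
}

#' Cut a recording into nonoverlapping epochs
#'
#' `floor(duration / lengthS)` epochs are cut in temporal order; a
#' trailing remainder shorter than one epoch is dropped.
#'
#' @param rec an [EEGRecording-class].
#' @param lengthS epoch length in seconds (default 5).
#' @return An [EpochSet-class] with all epochs retained.
#' @export
epochSignal <- function(rec, lengthS = 5) {
  spe <- round(rec@fs * lengthS)
  nep <- ncol(rec@data) %/% spe
  if (nep < 1L) stop("recording is shorter than one epoch")
  ep <- array(0, dim = c(nep, nrow(rec@data), spe))
  for (i in seq_len(nep))
    ep[i, , ] <- rec@data[, ((i - 1L) * spe + 1L):(i * spe)]
  new("EpochSet", epochs = ep, fs = rec@fs, epochLength = lengthS,
      retained = rep(TRUE, nep), montage = rec@montage,
      subjectId = rec@subjectId, group = rec@group)
}

#' Variance-based outlier epoch rejection
#'
#' One scalar variance per epoch is computed over all channels and
#' samples; epochs whose variance exceeds mean + 3 SD of the per-epoch
#' variance distribution (within the subject, single pass) are marked
#' rejected in the retained mask.
#'
#' @param es an [EpochSet-class] with at least 3 epochs.
#' @param nSd rejection threshold in SD units (default 3).
#' @return The [EpochSet-class] with an updated retained mask.
#' @export
rejectOutlierEpochs <- function(es, nSd = 3) {
  nep <- dim(es@epochs)[1]
  if (nep < 3L) stop("need at least 3 epochs to estimate the variance spread")
  v <- vapply(seq_len(nep),
              function(i) stats::var(as.vector(es@epochs[i, , ])),
              numeric(1))
  thr <- mean(v) + nSd * stats::sd(v)
  initialize(es, retained = es@retained & (v <= thr))
}
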