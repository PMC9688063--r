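#' Microstate occurrence rate
#'
#' Number of maximal contiguous runs of the state divided by the epoch
#' length: the average number of appearances per second (Hz).
#'
#' @param seg a [MicrostateSegmentation-class].
#' @param state state label.
#' @param epochLenS epoch length in seconds (default inferred from the
#'   segmentation length and sampling rate).
#' @return Occurrence in Hz (0 for an absent state).
#' @export
occurrence <- function(seg, state,
                       epochLenS = length(seg@labels) / seg@fs) {
  r <- rle(seg@labels)
  sum(r$values == state) / epochLenS
}

#' Mean microstate duration
#'
#' Mean length of the maximal contiguous runs of the state, in
#' milliseconds. An absent state yields 0 (flagged upstream in
#' [extractFeatureTable()]).
#'
#' @param seg a [MicrostateSegmentation-class].
#' @param state state label.
#' @param fs sampling rate (default the segmentation's).
#' @return Mean dwell time in ms.
#' @export
duration <- function(seg, state, fs = seg@fs) {
  r <- rle(seg@labels)
  len <- r$lengths[r$values == state]
  if (!length(len)) return(0)
  mean(len) * 1000 / fs
}

#' Microstate coverage
#'
#' Percentage of samples labeled with the state.
#'
#' @param seg a [MicrostateSegmentation-class].
#' @param state state label.
#' @return Coverage in percent.
#' @export
coverage <- function(seg, state)
  100 * sum(seg@labels == state) / length(seg@labels)

#' Mean GFP during state dominance
#'
#' Mean of the GFP series over the samples labeled with the state.
#'
#' @param seg a [MicrostateSegmentation-class].
#' @param gfp numeric GFP series aligned with the segmentation labels.
#' @param state state label.
#' @return Mean GFP (microvolts); 0 for an absent state.
#' @export
meanGFP <- function(seg, gfp, state) {
  if (length(gfp) != length(seg@labels))
    stop("gfp series must be aligned with the segmentation")
  sel <- seg@labels == state
  if (!any(sel)) return(0)
  mean(gfp[sel])
}

#' Microstate map correlation (MsMC)
#'
#' The mean absolute spatial correlation between the GFP-peak maps
#' labeled with a state and that state's template: a measure of how
#' consistently the state's topography is reproduced at its peaks.
#'
#' @param seg a [MicrostateSegmentation-class] (per-peak correlations are
#'   stored at backfitting time).
#' @param state state label.
#' @return MsMC in `[0, 1]`; 0 if the state is absent among the peaks.
#' @export
msmc <- function(seg, state) {
  sel <- seg@peakLabels == state
  if (!any(sel)) return(0)
  mean(seg@peakCorrelations[sel])
}

#' Microstate feature-column names
#'
#' @param states state labels (default A-D).
#' @return The 20 feature names, family-major:
#'   `Occurrence_A .. MsMC_D`.
#' @export
microstateFeatureNames <- function(states = c("A", "B", "C", "D"))
  as.vector(vapply(c("Occurrence", "Duration", "Coverage", "MeanGFP", "MsMC"),
                   function(f) paste(f, states, sep = "_"),
                   character(length(states))))

#' Extract the per-epoch microstate feature table
#'
#' Backfits the shared template set to every retained epoch of every
#' subject and computes the 20 features (occurrence, duration, coverage,
#' mean GFP and MsMC for each state). States absent from an epoch
#' contribute 0 and are recorded in the `flags` attribute (never silent
#' NA).
#'
#' @param epochSets list of [EpochSet-class] (one per subject).
#' @param templates the shared [TemplateSet-class].
#' @return A data.frame with columns `subject_id`, `group`, `epoch`, the
#'   20 features, and attributes `flags` (data.frame of absent-state
#'   events) and `gev` (per-epoch backfitting GEV).
#' @export
extractFeatureTable <- function(epochSets, templates) {
  if (is(epochSets, "EpochSet")) epochSets <- list(epochSets)
  states <- templates@labels
  rows <- list(); flags <- list(); gevs <- numeric(0)
  meta <- list()
  for (es in epochSets) {
    for (i in which(es@retained)) {
      ep <- epochData(es, i)
      seg <- backfitLabels(ep, templates, es@fs)
      g <- computeGFP(ep)
      feat <- c(
        vapply(states, function(s) occurrence(seg, s), numeric(1)),
        vapply(states, function(s) duration(seg, s), numeric(1)),
        vapply(states, function(s) coverage(seg, s), numeric(1)),
        vapply(states, function(s) meanGFP(seg, g, s), numeric(1)),
        vapply(states, function(s) msmc(seg, s), numeric(1)))
      rows[[length(rows) + 1L]] <- feat
      meta[[length(meta) + 1L]] <- c(es@subjectId, es@group, i)
      gevs <- c(gevs, seg@gev)
      absent <- states[!(states %in% seg@labels)]
      absentPk <- states[!(states %in% seg@peakLabels)]
      if (length(absent) || length(absentPk))
        flags[[length(flags) + 1L]] <- data.frame(
          subject_id = es@subjectId, epoch = i,
          state = union(absent, absentPk),
          where = ifelse(union(absent, absentPk) %in% absent,
                         "labels", "peaks"))
    }
  }
  X <- do.call(rbind, rows)
  colnames(X) <- microstateFeatureNames(states)
  M <- do.call(rbind, meta)
  out <- data.frame(subject_id = M[, 1], group = M[, 2],
                    epoch = as.integer(M[, 3]), X,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "flags") <- if (length(flags)) do.call(rbind, flags) else
    data.frame(subject_id = character(0), epoch = integer(0),
               state = character(0), where = character(0))
  attr(out, "gev") <- gevs
  out
}

#' Subject-level feature aggregation
#'
#' Mean of each feature over a subject's epochs, for cohort-style
#' reporting of group statistics.
#'
#' @param table a feature table from [extractFeatureTable()].
#' @return One row per subject with the averaged features.
#' @export
aggregateBySubject <- function(table) {
  featCols <- setdiff(names(table), c("subject_id", "group", "epoch"))
  agg <- stats::aggregate(table[featCols],
                          by = table[c("subject_id", "group")], FUN = mean)
  agg[order(agg$subject_id), , drop = FALSE]
}
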