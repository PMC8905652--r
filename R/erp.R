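# ERP preprocessing and measurement: re-reference, zero-phase filtering,
# epoching, baseline correction, threshold artifact rejection, inclusion
# rule, condition averaging and ROI/window amplitude extraction.

#' Canonical regions of interest
#'
#' The three electrode sets the analysis averages over.
#'
#' @return Named list of electrode vectors: `fronto_central`, `frontal`,
#'   `central`.
#' @export
canonical_rois <- function() {
  list(
    fronto_central = c("F1", "Fz", "F2", "FC1", "FCz", "FC2", "C1", "Cz", "C2"),
    frontal = c("AF3", "AFz", "AF4", "F1", "Fz", "F2", "FC1", "FCz", "FC2"),
    central = c("FC1", "FCz", "FC2", "C1", "Cz", "C2", "CP1", "CPz", "CP2")
  )
}

#' Component measurement defaults per group
#'
#' Analysis windows and ROIs for the two deflections: N100 at 80-120 ms for
#' both groups (fronto-central ROI in children, central in adults); N400 at
#' 350-450 ms (adults, central ROI) or 400-500 ms (children, central ROI).
#'
#' @param group `"adults"` or `"children"`.
#' @return Data frame with `component`, `roi`, `win_lo`, `win_hi` (ms).
#' @export
default_components <- function(group = c("adults", "children")) {
  group <- match.arg(group)
  if (group == "adults") {
    data.frame(component = c("N100", "N400"), roi = c("central", "central"),
               win_lo = c(80, 350), win_hi = c(120, 450), stringsAsFactors = FALSE)
  } else {
    data.frame(component = c("N100", "N400"), roi = c("fronto_central", "central"),
               win_lo = c(80, 400), win_hi = c(120, 500), stringsAsFactors = FALSE)
  }
}

#' Re-reference to the algebraic mastoid average
#'
#' Subtracts `(M1 + M2) / 2` sample-wise from every channel.
#'
#' @param eeg An `sl_eeg`.
#' @return The re-referenced `sl_eeg`.
#' @export
rereference_mastoids <- function(eeg) {
  miss <- setdiff(c("M1", "M2"), eeg$channels)
  if (length(miss) > 0)
    stopf("mastoid channel(s) missing: %s", paste(miss, collapse = ", "))
  ref <- (eeg$data["M1", ] + eeg$data["M2", ]) / 2
  eeg$data <- sweep(eeg$data, 2, ref, "-")
  eeg
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero phase shift) filtering, applied as separate
#' high-pass and low-pass Butterworth passes of the given order each; the
#' widely separated corners (0.1 and 30 Hz by default) make the split
#' design numerically robust at EEG sampling rates.
#'
#' @param eeg An `sl_eeg`.
#' @param low,high Band edges in Hz (defaults 0.1 and 30).
#' @param order Filter order per pass (default 4).
#' @return The filtered `sl_eeg`.
#' @export
bandpass_filter <- function(eeg, low = 0.1, high = 30, order = 4) {
  nyq <- eeg$rate / 2
  if (high >= nyq || low <= 0 || low >= high)
    stopf("band (%g, %g) Hz invalid for sampling rate %g", low, high, eeg$rate)
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  eeg$data <- t(apply(eeg$data, 1, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x))))
  dimnames(eeg$data) <- list(eeg$channels, NULL)
  eeg
}

#' Cut word-locked epochs from continuous EEG
#'
#' Epochs span `window_ms` relative to each word onset (the onset sample is
#' t = 0) and are baseline-corrected by subtracting the per-channel mean of
#' `baseline_ms` (inclusive bounds at sample resolution); pass
#' `baseline_ms = NULL` to skip. Events without full pre/post context are
#' dropped with a warning.
#'
#' @param eeg An `sl_eeg`.
#' @param events Word-onset table with `onset` (ms) and condition labels.
#' @param window_ms Length-2 epoch window in ms (default `c(-300, 1200)`).
#' @param baseline_ms Length-2 baseline window in ms (default `c(-300, 0)`).
#' @return An `sl_epochs`: `data` (epochs x channels x samples array),
#'   `times` (ms), `channels`, `labels`, `retained`, `rate`.
#' @export
epoch_eeg <- function(eeg, events, window_ms = c(-300, 1200),
                      baseline_ms = c(-300, 0)) {
  rate <- eeg$rate
  rel <- seq(round(window_ms[1] * rate / 1000),
             length.out = round(diff(window_ms) * rate / 1000))
  times <- rel / rate * 1000
  onset_samp <- round(events$onset / 1000 * rate)
  lo <- onset_samp + rel[1]
  hi <- onset_samp + rel[length(rel)]
  ok <- lo >= 1 & hi <= ncol(eeg$data)
  if (any(!ok))
    warning(sprintf("dropping %d event(s) too close to the record edge", sum(!ok)))
  events <- events[ok, , drop = FALSE]
  onset_samp <- onset_samp[ok]
  n_ep <- length(onset_samp)
  data <- array(NA_real_, dim = c(n_ep, nrow(eeg$data), length(rel)))
  for (e in seq_len(n_ep)) {
    data[e, , ] <- eeg$data[, onset_samp[e] + rel, drop = FALSE]
  }
  ep <- structure(
    list(data = data, times = times, channels = eeg$channels,
         labels = as.data.frame(events, stringsAsFactors = FALSE),
         retained = rep(TRUE, n_ep), rate = rate),
    class = "sl_epochs")
  if (!is.null(baseline_ms)) ep <- apply_baseline(ep, baseline_ms)
  ep
}

#' Baseline-correct epochs
#'
#' @param epochs An `sl_epochs`.
#' @param baseline_ms Length-2 baseline window in ms, inclusive.
#' @return The corrected `sl_epochs`.
#' @export
apply_baseline <- function(epochs, baseline_ms = c(-300, 0)) {
  sel <- epochs$times >= baseline_ms[1] & epochs$times <= baseline_ms[2]
  if (!any(sel)) stopf("baseline window contains no samples")
  bl <- rowMeans(epochs$data[, , sel, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - array(bl, dim = dim(epochs$data))
  epochs
}

#' Threshold artifact rejection
#'
#' Marks an epoch rejected iff any channel at any sample strictly exceeds
#' `threshold` in absolute value, on the baseline-corrected signal.
#'
#' @param epochs An `sl_epochs`.
#' @param threshold Rejection threshold in uV (default 100).
#' @return The `sl_epochs` with its `retained` mask updated.
#' @export
reject_artifacts <- function(epochs, threshold = 100) {
  mx <- apply(abs(epochs$data), 1, max)
  epochs$retained <- epochs$retained & (mx <= threshold)
  epochs
}

#' Two-thirds inclusion rule
#'
#' A participant is included iff every condition cell (task x word type x
#' exposure half) retains at least `ceiling(min_fraction * cell size)`
#' epochs after rejection.
#'
#' @param epochs An `sl_epochs`.
#' @param min_fraction Minimum retained fraction per cell (default 2/3).
#' @param cells Label columns defining the condition cells.
#' @return Logical; attributes `cell_counts` (data frame) and, when
#'   excluded, `reason`.
#' @export
include_participant <- function(epochs, min_fraction = 2 / 3,
                                cells = c("task", "tp_class", "half")) {
  lb <- epochs$labels
  key <- interaction(lb[cells], drop = FALSE, sep = ":")
  tot <- table(key)
  ret <- table(key[epochs$retained])
  counts <- data.frame(cell = names(tot), total = as.integer(tot),
                       retained = as.integer(ret[names(tot)]),
                       stringsAsFactors = FALSE)
  counts$retained[is.na(counts$retained)] <- 0L
  if (any(counts$total == 0L)) {
    out <- FALSE
    attr(out, "reason") <- "empty condition cell"
    attr(out, "cell_counts") <- counts
    return(out)
  }
  need <- ceiling(min_fraction * counts$total)
  out <- all(counts$retained >= need)
  if (!out)
    attr(out, "reason") <- sprintf(
      "cell(s) below the %.0f%% retention minimum: %s", 100 * min_fraction,
      paste(counts$cell[counts$retained < need], collapse = ", "))
  attr(out, "cell_counts") <- counts
  out
}

#' Per-condition average waveforms
#'
#' Sample-wise mean over retained epochs in each condition cell; empty
#' cells propagate as missing.
#'
#' @param epochs An `sl_epochs`.
#' @param by Label columns defining the cells.
#' @return List of class `sl_erps`: `erps` (named list of channel x sample
#'   matrices, `NULL` for empty cells), `n` (epoch counts), `times`,
#'   `channels`, `cells` (data frame of cell labels).
#' @export
condition_erps <- function(epochs, by = c("task", "tp_class", "half")) {
  lb <- epochs$labels
  key <- interaction(lb[by], drop = FALSE, sep = ":")
  cells <- unique(lb[by])
  cells <- cells[do.call(order, cells), , drop = FALSE]
  rownames(cells) <- NULL
  keys <- do.call(paste, c(cells, sep = ":"))
  erps <- list(); n <- integer()
  for (i in seq_along(keys)) {
    sel <- which(key == keys[i] & epochs$retained)
    n[keys[i]] <- length(sel)
    erps[[keys[i]]] <- if (length(sel) == 0) NULL else
      colMeans(epochs$data[sel, , , drop = FALSE])
  }
  structure(list(erps = erps, n = n, times = epochs$times,
                 channels = epochs$channels, cells = cells),
            class = "sl_erps")
}

#' Mean amplitude over an ROI and time window
#'
#' Mean over the ROI electrodes and over all samples with
#' `win_lo <= t <= win_hi` (inclusive bounds at sample resolution).
#'
#' @param erp Channel x sample waveform matrix.
#' @param times Sample times in ms.
#' @param channels Channel names matching the rows of `erp`.
#' @param electrodes ROI electrode names.
#' @param window_ms Length-2 analysis window in ms.
#' @return Mean amplitude in uV.
#' @export
roi_window_mean <- function(erp, times, channels, electrodes, window_ms) {
  miss <- setdiff(electrodes, channels)
  if (length(miss) > 0)
    stopf("ROI electrode(s) missing from the montage: %s",
          paste(miss, collapse = ", "))
  sel_t <- times >= window_ms[1] & times <= window_ms[2]
  if (!any(sel_t)) stopf("analysis window contains no samples")
  mean(erp[match(electrodes, channels), sel_t])
}

#' Extract the per-condition ROI/window amplitude table for one subject
#'
#' Applies [condition_erps()] then [roi_window_mean()] for each configured
#' component.
#'
#' @param epochs An `sl_epochs` (rejected epochs already masked).
#' @param components Component table as from [default_components()].
#' @param rois Named list of ROI electrode sets.
#' @param by Condition cell columns.
#' @return Data frame: one row per cell x component with `amplitude` (uV)
#'   and the retained epoch count.
#' @export
erp_measures <- function(epochs, components = default_components("adults"),
                         rois = canonical_rois(),
                         by = c("task", "tp_class", "half")) {
  avg <- condition_erps(epochs, by = by)
  keys <- do.call(paste, c(avg$cells, sep = ":"))
  rows <- list()
  for (ci in seq_len(nrow(components))) {
    comp <- components[ci, ]
    for (k in seq_along(keys)) {
      erp <- avg$erps[[keys[k]]]
      amp <- if (is.null(erp)) NA_real_ else
        roi_window_mean(erp, avg$times, avg$channels,
                        rois[[comp$roi]], c(comp$win_lo, comp$win_hi))
      rows[[length(rows) + 1]] <- cbind(
        avg$cells[k, , drop = FALSE],
        data.frame(component = comp$component, roi = comp$roi,
                   amplitude = amp, n_epochs = unname(avg$n[keys[k]]),
                   stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full single-subject ERP pipeline
#'
#' Mastoid re-reference, 0.1-30 Hz zero-phase band-pass, word-locked
#' epoching with baseline correction, +/-100 uV rejection, two-thirds
#' inclusion check, and ROI/window amplitude extraction.
#'
#' @param eeg An `sl_eeg`.
#' @param events Word-onset events for this recording.
#' @param group `"adults"` or `"children"` (selects component windows/ROIs).
#' @param reject_uV Rejection threshold (default 100); `NULL` disables.
#' @param min_fraction Inclusion minimum retained fraction (default 2/3).
#' @param filter Apply the band-pass (default `TRUE`).
#' @return List: `measures` (amplitude table), `included` (logical with
#'   cell counts), `epochs` (the masked `sl_epochs`).
#' @export
process_subject <- function(eeg, events, group = "adults", reject_uV = 100,
                            min_fraction = 2 / 3, filter = TRUE) {
  eeg <- rereference_mastoids(eeg)
  if (filter) eeg <- bandpass_filter(eeg)
  ep <- epoch_eeg(eeg, events)
  if (!is.null(reject_uV)) ep <- reject_artifacts(ep, reject_uV)
  inc <- include_participant(ep, min_fraction = min_fraction)
  list(measures = erp_measures(ep, components = default_components(group)),
       included = inc, epochs = ep)
}
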