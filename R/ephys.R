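# Single-cell electrophysiology quantification: threshold spike detection,
# response areas, sub/suprathreshold classification, arithmetic-sum versus
# crossmodal comparison, and MSIn under pharmacology.

#' Electrophysiology trace container
#'
#' @param samples Amplitude time series.
#' @param sample_hz Sampling rate (> 0).
#' @param stimulus_onsets Data frame with columns `time` (s) and `modality`
#'   (`V`, `H`; a VH trial carries both onsets, 50 ms apart).
#' @param recording_mode `"whole_cell"` or `"loose_patch"`.
#' @param pharmacology E.g. `"control"`, `"APV"`, `"PTX"`, `"MK801"`.
#' @return Object of class `"ephys_trace"`.
#' @export
ephys_trace <- function(samples, sample_hz, stimulus_onsets,
                        recording_mode = c("whole_cell", "loose_patch"),
                        pharmacology = "control") {
  recording_mode <- match.arg(recording_mode)
  if (sample_hz <= 0) stop("ephys_trace: sample_hz must be > 0")
  dur <- length(samples) / sample_hz
  if (any(stimulus_onsets$time < 0 | stimulus_onsets$time > dur))
    stop("ephys_trace: stimulus onsets outside the trace")
  structure(list(samples = as.numeric(samples), sample_hz = sample_hz,
                 stimulus_onsets = stimulus_onsets,
                 recording_mode = recording_mode,
                 pharmacology = pharmacology),
            class = "ephys_trace")
}

#' Amplitude-threshold spike detection
#'
#' An event is emitted at every upward crossing of `threshold`, suppressing
#' further crossings within the refractory window. Events within
#' `count_window_s` (default 1.2 s) of the first stimulus onset form the
#' response spike count.
#'
#' @param trace An [ephys_trace()].
#' @param threshold Detection amplitude (above baseline noise).
#' @param refractory_ms Refractory window (ms, default 2).
#' @param count_window_s Response window after the first stimulus onset (s).
#' @return List with `times` (all event times, s), `relative_times` (to the
#'   first stimulus onset), and `n_response` (events within the window).
#' @export
detect_spikes <- function(trace, threshold, refractory_ms = 2,
                          count_window_s = 1.2) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (refractory_ms < 0) stop("detect_spikes: refractory must be >= 0")
  x <- trace$samples
  t <- (seq_along(x) - 1L) / trace$sample_hz
  up <- which(x[-1L] >= threshold & x[-length(x)] < threshold) + 1L
  keep <- numeric(0); last <- -Inf
  for (i in up) {
    if (t[i] - last >= refractory_ms / 1000) {
      keep <- c(keep, t[i]); last <- t[i]
    }
  }
  onset <- min(trace$stimulus_onsets$time)
  rel <- keep - onset
  list(times = keep, relative_times = rel,
       n_response = sum(rel >= 0 & rel <= count_window_s))
}

#' Response area under a trace
#'
#' Trapezoidal integral of (sample - baseline) over `window_s` seconds
#' following the first stimulus onset, with the baseline estimated as the
#' mean of the `baseline_s` pre-stimulus seconds. Units: trace amplitude x
#' seconds.
#'
#' @param trace An [ephys_trace()].
#' @param window_s Integration window (s, default 1.5).
#' @param baseline_s Pre-stimulus span used for the baseline (s).
#' @return Area (numeric scalar).
#' @export
response_area <- function(trace, window_s = 1.5, baseline_s = 0.1) {
  stopifnot(inherits(trace, "ephys_trace"))
  sr <- trace$sample_hz
  onset <- min(trace$stimulus_onsets$time)
  i_on <- floor(onset * sr) + 1L
  i_end <- i_on + round(window_s * sr)
  if (i_end > length(trace$samples))
    stop("response_area: window exceeds the trace")
  i_b0 <- max(1L, i_on - round(baseline_s * sr))
  base <- mean(trace$samples[i_b0:(i_on - 1L)])
  y <- trace$samples[i_on:i_end] - base
  sum((y[-1L] + y[-length(y)]) / 2) / sr
}

#' Sub/suprathreshold classification of a trial pair
#'
#' Subthreshold when both unisensory areas are below `bound`; suprathreshold
#' when either reaches it. An area exactly at the bound classifies as
#' suprathreshold (documented tie rule; the bound itself, 12 area units by
#' default, is on whatever amplitude scale the traces carry).
#'
#' @param area_v,area_h Unisensory response areas.
#' @param bound Threshold area (default 12).
#' @return `"subthreshold"` or `"suprathreshold"`.
#' @export
classify_cell_threshold <- function(area_v, area_h, bound = 12) {
  if (bound < 0) stop("classify_cell_threshold: bound must be >= 0")
  ifelse(area_v < bound & area_h < bound, "subthreshold", "suprathreshold")
}

#' Linear sum versus measured crossmodal response
#'
#' `linear_sum = v + h`; `ratio = vh / linear_sum`. Ratios above/below 1
#' indicate supralinear/sublinear multisensory summation (points above and
#' below the identity diagonal in a V+H vs VH plot).
#'
#' @param v,h,vh Response measures (areas or spike counts) from the same
#'   cell.
#' @return Data frame: linear_sum, measured, ratio, class
#'   (supralinear/linear/sublinear; NA and flagged when the sum is <= 0).
#' @export
linearity_analysis <- function(v, h, vh) {
  ls <- v + h
  ratio <- ifelse(ls > 0, vh / ls, NA_real_)
  cls <- ifelse(is.na(ratio), NA_character_,
                ifelse(ratio > 1, "supralinear",
                       ifelse(ratio < 1, "sublinear", "linear")))
  data.frame(linear_sum = ls, measured = vh, ratio = ratio, class = cls,
             flagged = ls <= 0)
}

#' Electrophysiological multisensory index
#'
#' `msin = (vh - uni) / uni` with the unisensory term chosen by
#' `denominator` (default: the larger of the two unisensory measures,
#' consistent with the imaging index). Undefined (NA) when the denominator
#' is not positive.
#'
#' @param v,h,vh Response measures from the same cell.
#' @param denominator `"max"`, `"min"`, or `"sum"`.
#' @return MSIn value(s).
#' @export
ephys_msin <- function(v, h, vh, denominator = c("max", "min", "sum")) {
  denominator <- match.arg(denominator)
  den <- switch(denominator, max = pmax(v, h), min = pmin(v, h), sum = v + h)
  ifelse(den > 0, (vh - den) / den, NA_real_)
}

#' Per-group inverse-effectiveness fits
#'
#' Fits `msin = a * exp(b * x)` per group of cells (e.g. control vs
#' picrotoxin), where `x` is the cell's maximum unisensory response; groups
#' with fewer than 3 cells are skipped with a warning.
#'
#' @param x Maximum unisensory response per cell.
#' @param msin Per-cell MSIn.
#' @param group Group labels.
#' @return Named list of `tmsi_expfit` objects plus a `summary` data.frame
#'   (group, n, a, b, decay_retained = b < 0).
#' @export
ie_by_group <- function(x, msin, group) {
  group <- factor(group)
  fits <- list()
  rows <- list()
  for (g in levels(group)) {
    sel <- group == g & is.finite(x) & is.finite(msin)
    if (sum(sel) < 3L) {
      warning("ie_by_group: group '", g, "' has fewer than 3 cells; skipped")
      next
    }
    f <- fit_exp_decay(x[sel], msin[sel])
    fits[[g]] <- f
    rows[[g]] <- data.frame(group = g, n = sum(sel), a = f$a, b = f$b,
                            decay_retained = f$b < 0)
  }
  c(fits, list(summary = do.call(rbind, c(rows, make.row.names = FALSE))))
}

#' Quantify a simulated or recorded trial set
#'
#' Computes the per-modality response measure (area for whole-cell traces,
#' 1.2 s spike count for loose-patch), classifies the cell from the mean
#' unisensory areas, and derives the linearity ratio and MSIn from the
#' per-modality means.
#'
#' @param traces List of [ephys_trace()] objects.
#' @param meta Data frame with a `modality` column (V, H, VH) aligned with
#'   `traces`.
#' @param spike_threshold Detection threshold for loose-patch traces.
#' @param bound Sub/suprathreshold area bound.
#' @return List with `measures` (per-trial data.frame), `means`
#'   (per-modality), `threshold_class`, `linearity` (one-row data.frame),
#'   and `msin`.
#' @export
analyze_ephys_trials <- function(traces, meta, spike_threshold = 50,
                                 bound = 12) {
  stopifnot(length(traces) == nrow(meta))
  measure <- vapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    if (tr$recording_mode == "loose_patch")
      detect_spikes(tr, spike_threshold)$n_response
    else
      response_area(tr)
  }, 0)
  measures <- data.frame(trial = seq_along(traces),
                         modality = meta$modality, measure = measure)
  mm <- tapply(measures$measure, measures$modality, mean)
  v <- unname(mm["V"]); h <- unname(mm["H"]); vh <- unname(mm["VH"])
  cls <- classify_cell_threshold(v, h, bound = bound)
  list(measures = measures,
       means = data.frame(modality = names(mm), mean = as.numeric(mm)),
       threshold_class = cls,
       linearity = linearity_analysis(v, h, vh),
       msin = ephys_msin(v, h, vh))
}
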