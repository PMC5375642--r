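# Synthetic single-cell electrophysiology traces: evoked synaptic responses
# to visual (V), mechanosensory/hindbrain (H), and paired (VH) stimulation
# with an NMDA-like supralinear component confined to small inputs, plus a
# loose-patch spiking variant.

#' Configuration for the synaptic-trace generator
#'
#' The crossmodal (VH) waveform is the 50 ms offset sum of the unisensory
#' waveforms; when both unisensory response areas lie below the
#' sub/suprathreshold bound, an extra kernel-shaped component with amplitude
#' `g_nmda * min(v_amp, h_amp)` is added at the second stimulus onset —
#' the trace-level analog of [crossmodal_rule()]. `blocked = TRUE` (NMDAR
#' antagonist applied) forces the effective gain to 0 so summation is
#' linear. Amplitudes are in the same arbitrary trace units the area bound
#' (default 12 area units, as used by the sub/suprathreshold rule) refers
#' to.
#'
#' @param seed Integer RNG seed.
#' @param sample_hz Sampling rate (Hz).
#' @param trace_s Trace duration (s).
#' @param onset_s First (visual) stimulus onset (s).
#' @param offset_ms Crossmodal stimulus offset (ms, default 50).
#' @param kernel_rise,kernel_decay Synaptic kernel time constants (s).
#' @param v_amp,h_amp Unisensory peak amplitudes.
#' @param g_nmda Supralinearity coefficient (>= 0).
#' @param blocked Logical: NMDAR blockade (effective gain 0).
#' @param area_bound Sub/suprathreshold area bound used to gate the bonus.
#' @param noise_sd Additive Gaussian trace noise SD.
#' @param spike_threshold Amplitude at which the spiking variant emits
#'   spike-shaped events.
#' @return A list of class `"sim_ephys_config"`.
#' @export
sim_ephys_config <- function(seed = 1L, sample_hz = 5000, trace_s = 3,
                             onset_s = 1, offset_ms = 50,
                             kernel_rise = 0.005, kernel_decay = 0.08,
                             v_amp = 40, h_amp = 30, g_nmda = 1,
                             blocked = FALSE, area_bound = 12,
                             noise_sd = 0.5, spike_threshold = 60) {
  if (offset_ms < 0) stop("sim_ephys_config: offset_ms must be >= 0")
  if (g_nmda < 0) stop("sim_ephys_config: g_nmda must be >= 0")
  structure(list(seed = as.integer(seed), sample_hz = sample_hz,
                 trace_s = trace_s, onset_s = onset_s, offset_ms = offset_ms,
                 kernel_rise = kernel_rise, kernel_decay = kernel_decay,
                 v_amp = v_amp, h_amp = h_amp, g_nmda = g_nmda,
                 blocked = isTRUE(blocked), area_bound = area_bound,
                 noise_sd = noise_sd, spike_threshold = spike_threshold),
            class = "sim_ephys_config")
}

# Area (amplitude x s) of one unit-peak kernel transient, by quadrature.
kernel_unit_area <- function(rise, decay, sample_hz, dur = 1.5) {
  t <- seq(0, dur, by = 1 / sample_hz)
  k <- transient_kernel(t, rise, decay)
  sum((k[-1] + k[-length(k)]) / 2) / sample_hz
}

#' Simulate evoked synaptic traces
#'
#' Generates `n_trials` traces per modality (V, H, VH). The VH waveform is
#' the offset sum of the unisensory waveforms plus the gated supralinear
#' component (see [sim_ephys_config()]); amplitudes receive small
#' multiplicative trial-to-trial variability and traces carry additive
#' Gaussian noise. With `spiking = TRUE`, loose-patch-style traces are
#' returned instead: brief large spike deflections wherever the underlying
#' subthreshold waveform crosses `spike_threshold` (one spike per crossing,
#' 10 ms refractory).
#'
#' @param config A [sim_ephys_config()].
#' @param n_trials Trials per modality.
#' @param spiking Emit loose-patch spiking traces instead of graded ones.
#' @return List with `traces` (list of [ephys_trace()] objects), `meta`
#'   (data.frame: trial, modality, pharmacology), and `truth` (per-modality
#'   noiseless amplitudes and areas, bonus applied or not, config).
#' @export
simulate_ephys <- function(config, n_trials = 10L, spiking = FALSE) {
  stopifnot(inherits(config, "sim_ephys_config"))
  set.seed(config$seed)
  sr <- config$sample_hz
  n <- round(config$trace_s * sr)
  t <- (seq_len(n) - 1L) / sr
  offset_s <- config$offset_ms / 1000
  unit_area <- kernel_unit_area(config$kernel_rise, config$kernel_decay, sr)

  area_v <- config$v_amp * unit_area
  area_h <- config$h_amp * unit_area
  g_eff <- if (config$blocked) 0 else config$g_nmda
  bonus_on <- area_v < config$area_bound && area_h < config$area_bound
  bonus_amp <- if (bonus_on) g_eff * min(config$v_amp, config$h_amp) else 0

  kern_at <- function(onset, amp)
    amp * transient_kernel(t - onset, config$kernel_rise, config$kernel_decay)

  waveform <- function(modality, va, ha, ba) {
    switch(modality,
           V = kern_at(config$onset_s, va),
           H = kern_at(config$onset_s, ha),
           VH = kern_at(config$onset_s, va) +
             kern_at(config$onset_s + offset_s, ha) +
             kern_at(config$onset_s + offset_s, ba))
  }

  spikify <- function(w) {
    # one fast biphasic event per upward threshold crossing, 10 ms refractory
    up <- which(w[-1] >= config$spike_threshold &
                  w[-length(w)] < config$spike_threshold) + 1L
    keep <- integer(0); last <- -Inf
    for (i in up) if (t[i] - last >= 0.010) { keep <- c(keep, i); last <- t[i] }
    out <- numeric(n)
    sp_len <- max(3L, round(0.002 * sr))
    shape <- sin(seq(0, pi, length.out = sp_len)) * 5 * config$spike_threshold
    for (i in keep) {
      idx <- i:min(n, i + sp_len - 1L)
      out[idx] <- out[idx] + shape[seq_along(idx)]
    }
    list(trace = out, n_spikes = length(keep))
  }

  mods <- rep(c("V", "H", "VH"), each = n_trials)
  pharm <- if (config$blocked) "APV" else "control"
  traces <- vector("list", length(mods))
  n_spk_true <- integer(length(mods))
  for (i in seq_along(mods)) {
    jit <- exp(stats::rnorm(3, 0, 0.05))     # trial-to-trial amplitude scatter
    w <- waveform(mods[i], config$v_amp * jit[1], config$h_amp * jit[2],
                  bonus_amp * jit[3])
    if (spiking) {
      sp <- spikify(w)
      w <- sp$trace
      n_spk_true[i] <- sp$n_spikes
    }
    samples <- w + stats::rnorm(n, 0, config$noise_sd)
    onsets <- if (mods[i] == "VH")
      data.frame(time = c(config$onset_s, config$onset_s + offset_s),
                 modality = c("V", "H"))
    else data.frame(time = config$onset_s, modality = mods[i])
    traces[[i]] <- ephys_trace(samples, sr, onsets,
                               recording_mode = if (spiking) "loose_patch"
                               else "whole_cell",
                               pharmacology = pharm)
  }

  list(traces = traces,
       meta = data.frame(trial = seq_along(mods), modality = mods,
                         pharmacology = pharm,
                         n_spikes_true = n_spk_true),
       truth = list(area_v = area_v, area_h = area_h,
                    bonus_applied = bonus_on && g_eff > 0,
                    bonus_amp = bonus_amp, unit_area = unit_area,
                    config = config))
}
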