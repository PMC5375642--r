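# Synthetic behavioral data: free-swimming speed trials across visual
# contrasts (with or without an acoustic prestimulus) and cyclic
# startle-scoring sessions for the NMDAR-blockade protocol.

#' Configuration for the swim-speed behavior generator
#'
#' Defaults reproduce the multisensory swimming protocol: 37 tadpoles, 40
#' block-randomized presentations each (half visual, half multisensory)
#' across contrasts 0/25/50/100% with a 20 s interstimulus interval, 1 s
#' pre-trial window and 2 s stimulus window. Baseline speeds per contrast
#' are the group means of the unisensory condition (3.22, 3.29, 3.7,
#' 4.76 cm/s) and the additive multisensory enhancement is confined to the
#' low contrasts (1.9 and 0.2 cm/s at 25% and 50%), so inverse effectiveness
#' is built in. A configurable fraction of tadpoles is inactive throughout,
#' to exercise the exclusion rule.
#'
#' @param seed Integer RNG seed.
#' @param n_tadpoles Number of animals.
#' @param contrasts Visual contrasts (%).
#' @param base_speed_cms Mean swim speed per contrast, visual-only (cm/s).
#' @param enhancement Additive multisensory speed boost per contrast (cm/s).
#' @param trial_noise_sd Between-trial SD of the trial mean speed (cm/s).
#' @param tadpole_sd SD of the per-animal random speed offset (cm/s).
#' @param inactive_fraction Fraction of animals that never move.
#' @param n_presentations Presentations per animal (half per condition).
#' @param isi_s Interstimulus interval (s).
#' @param trial_dur_s,pre_dur_s Stimulus and pre-trial window lengths (s).
#' @param sample_hz Speed sampling rate (Hz).
#' @return A list of class `"sim_behavior_config"`.
#' @export
sim_behavior_config <- function(seed = 1L, n_tadpoles = 37L,
                                contrasts = c(0, 25, 50, 100),
                                base_speed_cms = c(3.22, 3.29, 3.7, 4.76),
                                enhancement = c(0, 1.9, 0.2, 0),
                                trial_noise_sd = 1.2, tadpole_sd = 0.6,
                                inactive_fraction = 0,
                                n_presentations = 40L, isi_s = 20,
                                trial_dur_s = 2, pre_dur_s = 1,
                                sample_hz = 10) {
  if (length(enhancement) != length(contrasts))
    stop("sim_behavior_config: enhancement must match contrasts in length")
  if (length(base_speed_cms) != length(contrasts))
    stop("sim_behavior_config: base_speed_cms must match contrasts in length")
  if (any(base_speed_cms < 0))
    stop("sim_behavior_config: speeds must be >= 0")
  structure(list(seed = as.integer(seed), n_tadpoles = as.integer(n_tadpoles),
                 contrasts = contrasts, base_speed_cms = base_speed_cms,
                 enhancement = enhancement, trial_noise_sd = trial_noise_sd,
                 tadpole_sd = tadpole_sd,
                 inactive_fraction = inactive_fraction,
                 n_presentations = as.integer(n_presentations), isi_s = isi_s,
                 trial_dur_s = trial_dur_s, pre_dur_s = pre_dur_s,
                 sample_hz = sample_hz),
            class = "sim_behavior_config")
}

#' Simulate swim-speed behavior trials
#'
#' Emits one row per trial with the pre-trial and during-trial speed sample
#' series (wide columns `pre_1..`, `trial_1..`), block-randomized over
#' condition x contrast, with wall-clock timestamps at the configured
#' interstimulus interval. Inactive animals swim at (truncated) zero speed
#' throughout. Identical seed and config give identical output.
#'
#' @param config A [sim_behavior_config()].
#' @return List with `trials` (data.frame: tadpole, timestamp_s, condition,
#'   contrast, pre/trial speed sample columns) and `truth` (per-animal
#'   offsets and inactive flags, plus the config).
#' @export
simulate_swim_trials <- function(config) {
  stopifnot(inherits(config, "sim_behavior_config"))
  set.seed(config$seed)
  K <- length(config$contrasts)
  n_pre <- round(config$pre_dur_s * config$sample_hz)
  n_tr <- round(config$trial_dur_s * config$sample_hz)
  conds <- c("visual", "multisensory")
  per_block <- 2L * K
  n_blocks <- config$n_presentations %/% per_block

  offs <- stats::rnorm(config$n_tadpoles, 0, config$tadpole_sd)
  inactive <- stats::runif(config$n_tadpoles) < config$inactive_fraction

  rows <- vector("list", config$n_tadpoles * n_blocks * per_block)
  k <- 0L
  for (td in seq_len(config$n_tadpoles)) {
    sched <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      g <- expand.grid(condition = conds, contrast = config$contrasts,
                       stringsAsFactors = FALSE)
      g[sample.int(nrow(g)), ]
    }))
    for (i in seq_len(nrow(sched))) {
      ci <- match(sched$contrast[i], config$contrasts)
      is_ms <- sched$condition[i] == "multisensory"
      if (inactive[td]) {
        mu_pre <- 0; mu_tr <- 0
      } else {
        mu_pre <- max(0, config$base_speed_cms[1L] + offs[td] +
                        stats::rnorm(1, 0, config$trial_noise_sd / 2))
        enh <- if (is_ms) config$enhancement[ci] else 0
        mu_tr <- max(0, config$base_speed_cms[ci] + enh + offs[td] +
                       stats::rnorm(1, 0, config$trial_noise_sd))
      }
      pre <- pmax(0, stats::rnorm(n_pre, mu_pre, 0.2))
      trs <- pmax(0, stats::rnorm(n_tr, mu_tr, 0.2))
      k <- k + 1L
      rows[[k]] <- c(list(tadpole = td,
                          timestamp_s = (i - 1L) * config$isi_s,
                          condition = sched$condition[i],
                          contrast = sched$contrast[i]),
                     stats::setNames(as.list(pre), paste0("pre_", seq_len(n_pre))),
                     stats::setNames(as.list(trs), paste0("trial_", seq_len(n_tr))))
    }
  }
  trials <- do.call(rbind, lapply(rows[seq_len(k)], function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  list(trials = trials,
       truth = list(offsets = offs, inactive = inactive, config = config))
}

#' Configuration for the cyclic startle-protocol generator
#'
#' Emulates the NMDAR-blockade behavioral design: three experimental groups
#' (`control_low` n = 15 and `mk801_low` n = 15, each receiving 3 stimulus
#' types x 10 cyclic presentations; `control_high` n = 23, receiving 5 types
#' x 5), binary startle outcomes, and a per-animal latent acoustic
#' responsiveness that shifts all response probabilities on the logit scale —
#' the covariate the ANCOVA adjusts for. The multisensory boost applies to
#' low-contrast pairings only and is removed in the MK-801 group
#' (`blocked`), mirroring NMDAR blockade.
#'
#' @param seed Integer RNG seed.
#' @param n_control_low,n_control_high,n_mk801_low Group sizes.
#' @param p_acoustic,p_visual_low,p_visual_high Baseline response
#'   probabilities per stimulus type.
#' @param boost_low,boost_high Logit-scale multisensory shift for low/high
#'   contrast pairings (control animals).
#' @param beta_acoustic Logit slope of the latent responsiveness.
#' @return A list of class `"sim_startle_config"`.
#' @export
sim_startle_config <- function(seed = 1L, n_control_low = 15L,
                               n_control_high = 23L, n_mk801_low = 15L,
                               p_acoustic = 0.2, p_visual_low = 0.3,
                               p_visual_high = 0.6, boost_low = 1.0,
                               boost_high = -0.2, beta_acoustic = 0.8) {
  structure(list(seed = as.integer(seed),
                 n_control_low = as.integer(n_control_low),
                 n_control_high = as.integer(n_control_high),
                 n_mk801_low = as.integer(n_mk801_low),
                 p_acoustic = p_acoustic, p_visual_low = p_visual_low,
                 p_visual_high = p_visual_high, boost_low = boost_low,
                 boost_high = boost_high, beta_acoustic = beta_acoustic),
            class = "sim_startle_config")
}

#' Simulate cyclic startle-protocol sessions
#'
#' Binary startle outcomes per stimulus type and animal, with response
#' probabilities `plogis(qlogis(p_type) + boost + beta * a_i)` where `a_i`
#' is the animal's latent acoustic responsiveness and the boost applies only
#' to multisensory pairings of unblocked animals. Low-contrast-only groups
#' receive 10 presentations of each of {acoustic, visual_low, multi_low}
#' (30 total); the high-contrast group receives 5 of each of all five types
#' (25 total), matching the cyclic protocol.
#'
#' @param config A [sim_startle_config()].
#' @return List with `sessions` (long data.frame: tadpole, group, stimulus,
#'   n_presented, n_responded) and `truth` (latent responsiveness, true
#'   probabilities, config).
#' @export
simulate_startle_sessions <- function(config) {
  stopifnot(inherits(config, "sim_startle_config"))
  set.seed(config$seed)
  groups <- c(rep("control_low", config$n_control_low),
              rep("control_high", config$n_control_high),
              rep("mk801_low", config$n_mk801_low))
  n <- length(groups)
  a <- stats::rnorm(n)

  p_of <- function(stim, group, ai) {
    base <- switch(stim,
                   acoustic = config$p_acoustic,
                   visual_low = config$p_visual_low,
                   multi_low = config$p_visual_low,
                   visual_high = config$p_visual_high,
                   multi_high = config$p_visual_high)
    boost <- 0
    if (stim == "multi_low" && group != "mk801_low") boost <- config$boost_low
    if (stim == "multi_high") boost <- config$boost_high
    stats::plogis(stats::qlogis(base) + boost + config$beta_acoustic * ai)
  }

  out <- list(); truth_p <- list()
  for (i in seq_len(n)) {
    stims <- if (groups[i] == "control_high")
      c(acoustic = 5L, visual_low = 5L, multi_low = 5L,
        visual_high = 5L, multi_high = 5L)
    else
      c(acoustic = 10L, visual_low = 10L, multi_low = 10L)
    for (s in names(stims)) {
      p <- p_of(s, groups[i], a[i])
      out[[length(out) + 1L]] <- data.frame(
        tadpole = i, group = groups[i], stimulus = s,
        n_presented = stims[[s]],
        n_responded = stats::rbinom(1L, stims[[s]], p))
      truth_p[[length(truth_p) + 1L]] <- data.frame(
        tadpole = i, stimulus = s, p = p)
    }
  }
  list(sessions = do.call(rbind, out),
       truth = list(latent = a, probs = do.call(rbind, truth_p),
                    config = config))
}
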