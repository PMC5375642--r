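# Behavioral quantification: swim-speed multisensory enhancement across
# visual contrasts, startle-rate MSI under NMDAR blockade, and their
# statistical batteries.

speed_cols <- function(trials, prefix) {
  cols <- grep(paste0("^", prefix, "_\\d+$"), names(trials), value = TRUE)
  if (length(cols) == 0L)
    stop("no '", prefix, "_*' speed sample columns found")
  cols[order(as.integer(sub(paste0(prefix, "_"), "", cols)))]
}

#' Per-trial behavioral response
#'
#' `"speed"` mode returns the mean speed during the stimulus window (cm/s,
#' the scale the swim-speed comparisons are reported on); `"percent_change"`
#' returns `|mean(trial) - mean(pre)| / mean(pre) * 100`.
#'
#' @param pre,trial Numeric speed sample vectors for the 1 s pre-trial and
#'   the stimulus window.
#' @param mode `"speed"` (default) or `"percent_change"`.
#' @return Response value, with the mode in attribute `"mode"`;
#'   `percent_change` with a zero pre-trial mean returns `NA` (flagged via
#'   attribute `"flagged"`).
#' @export
response_change <- function(pre, trial, mode = c("speed", "percent_change")) {
  mode <- match.arg(mode)
  if (length(pre) == 0L || length(trial) == 0L)
    stop("response_change: both sample windows must be non-empty")
  val <- if (mode == "speed") {
    mean(trial)
  } else {
    mp <- mean(pre)
    if (mp <= 0) NA_real_ else abs(mean(trial) - mp) / mp * 100
  }
  structure(val, mode = mode, flagged = is.na(val))
}

#' Add a response column to a wide trial table
#'
#' @param trials Trial table with `pre_*` and `trial_*` speed columns.
#' @param mode Passed to [response_change()].
#' @return `trials` with added columns `response` and `trial_mean_speed`.
#' @export
score_trials <- function(trials, mode = c("speed", "percent_change")) {
  mode <- match.arg(mode)
  pc <- speed_cols(trials, "pre"); tc <- speed_cols(trials, "trial")
  pre_m <- rowMeans(trials[, pc, drop = FALSE])
  tr_m <- rowMeans(trials[, tc, drop = FALSE])
  trials$trial_mean_speed <- tr_m
  trials$response <- if (mode == "speed") tr_m else
    ifelse(pre_m > 0, abs(tr_m - pre_m) / pre_m * 100, NA_real_)
  attr(trials, "mode") <- mode
  trials
}

#' Exclude inactive tadpoles
#'
#' Removes animals for which some contiguous span of at least
#' `min_span_s` seconds (default 3 minutes) covers stimuli without any
#' trial showing movement (trial mean speed above `floor_cms`). Retained
#' records are returned unaltered.
#'
#' @param trials Scored trial table with columns `tadpole`, `timestamp_s`
#'   and `trial_mean_speed` (see [score_trials()]).
#' @param floor_cms Movement floor (cm/s, default 0.1).
#' @param min_span_s Minimum still span triggering exclusion (s).
#' @param trial_dur_s Trial duration added to the span end (s).
#' @return List with `trials` (filtered), `excluded` (data.frame: tadpole,
#'   span_start_s, span_end_s).
#' @export
exclude_inactive <- function(trials, floor_cms = 0.1, min_span_s = 180,
                             trial_dur_s = 2) {
  if (is.null(trials$timestamp_s) || any(!is.finite(trials$timestamp_s)))
    stop("exclude_inactive: trials must carry timestamps")
  if (is.null(trials$trial_mean_speed))
    stop("exclude_inactive: score the trials first (see score_trials)")
  log <- list()
  for (td in unique(trials$tadpole)) {
    d <- trials[trials$tadpole == td, ]
    d <- d[order(d$timestamp_s), ]
    still <- d$trial_mean_speed <= floor_cms
    r <- rle(still)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      t0 <- d$timestamp_s[starts[j]]
      t1 <- d$timestamp_s[ends[j]] + trial_dur_s
      if (t1 - t0 >= min_span_s) {
        log[[length(log) + 1L]] <- data.frame(tadpole = td,
                                              span_start_s = t0,
                                              span_end_s = t1)
        break
      }
    }
  }
  excluded <- if (length(log)) do.call(rbind, log) else
    data.frame(tadpole = integer(0), span_start_s = numeric(0),
               span_end_s = numeric(0))
  list(trials = trials[!trials$tadpole %in% excluded$tadpole, ],
       excluded = excluded)
}

#' Per-tadpole, per-contrast MSIn from scored trials
#'
#' Averages all trials of each condition at each contrast and computes
#' `MSIn = (multisensory mean - visual mean) / visual mean` per animal.
#'
#' @param trials Scored trial table (columns `tadpole`, `condition`,
#'   `contrast`, `response`).
#' @return Data frame: tadpole, contrast, visual_mean, multi_mean, msin
#'   (NA when the visual mean is not positive).
#' @export
session_msin <- function(trials) {
  need <- c("tadpole", "condition", "contrast", "response")
  if (!all(need %in% names(trials)))
    stop("session_msin: trials must carry ", paste(need, collapse = ", "))
  ag <- stats::aggregate(response ~ tadpole + contrast + condition,
                         data = trials, FUN = mean, na.rm = TRUE)
  v <- ag[ag$condition == "visual", c("tadpole", "contrast", "response")]
  m <- ag[ag$condition == "multisensory", c("tadpole", "contrast", "response")]
  out <- merge(v, m, by = c("tadpole", "contrast"),
               suffixes = c("_visual", "_multi"))
  names(out)[3:4] <- c("visual_mean", "multi_mean")
  out$msin <- ifelse(out$visual_mean > 0,
                     (out$multi_mean - out$visual_mean) / out$visual_mean,
                     NA_real_)
  out[order(out$tadpole, out$contrast), ]
}

#' Group MSIn summary across tadpoles
#'
#' @param msin_tab Output of [session_msin()].
#' @return Data frame: contrast, n, mean, sd, sem.
#' @export
aggregate_msin <- function(msin_tab) {
  do.call(rbind, lapply(split(msin_tab, msin_tab$contrast), function(d) {
    x <- d$msin[is.finite(d$msin)]
    data.frame(contrast = d$contrast[1L], n = length(x), mean = mean(x),
               sd = stats::sd(x), sem = stats::sd(x) / sqrt(length(x)))
  }))
}

#' Statistical battery for the swim-speed experiment
#'
#' Runs (i) the two-way comparison of visual vs multisensory responses at
#' every contrast with Sidak adjustment (paired formulation by default; see
#' [anova_twoway_sidak()]) and (ii) the one-way ANOVA of MSIn across
#' contrasts with Dunnett comparisons against the 0% reference.
#'
#' @param trials Scored trial table.
#' @param method Error formulation for the two-way battery.
#' @param ref Reference contrast for Dunnett (default `"0"`).
#' @return List with `twoway` (condition x contrast battery), `oneway`
#'   (MSIn ANOVA + Dunnett), `msin` (per-animal table), `msin_summary`.
#' @export
anova_battery <- function(trials, method = c("paired", "pooled"), ref = "0") {
  method <- match.arg(method)
  trials$condition <- factor(trials$condition,
                             levels = c("visual", "multisensory"))
  two <- anova_twoway_sidak(trials, y = "response", f1 = "condition",
                            f2 = "contrast", subject = "tadpole",
                            method = method)
  ms <- session_msin(trials)
  ok <- is.finite(ms$msin)
  one <- anova_oneway_dunnett(ms$msin[ok], factor(ms$contrast[ok]), ref = ref)
  list(twoway = two, oneway = one, msin = ms,
       msin_summary = aggregate_msin(ms))
}

#' Startle-rate multisensory index per session
#'
#' Response rate = `n_responded / n_presented` per stimulus type;
#' `msi = (multisensory rate - visual rate) / visual rate` at each contrast
#' present in the session. Animals that responded to none of their stimuli
#' are excluded; a zero visual rate with multisensory responses yields an
#' undefined (NA) index, flagged rather than imputed.
#'
#' @param sessions Long startle table: columns `tadpole`, `group`,
#'   `stimulus` (acoustic, visual_low, multi_low, visual_high, multi_high),
#'   `n_presented`, `n_responded`.
#' @return List with `msi` (data.frame: tadpole, group, contrast,
#'   visual_rate, multi_rate, acoustic_rate, msi, flagged) and
#'   `excluded` (non-responder tadpole ids).
#' @export
startle_msi <- function(sessions) {
  need <- c("tadpole", "group", "stimulus", "n_presented", "n_responded")
  if (!all(need %in% names(sessions)))
    stop("startle_msi: sessions must carry ", paste(need, collapse = ", "))
  if (any(sessions$n_responded > sessions$n_presented) ||
      any(sessions$n_presented <= 0))
    stop("startle_msi: need 0 <= n_responded <= n_presented, n_presented > 0")
  tot <- stats::aggregate(n_responded ~ tadpole, data = sessions, FUN = sum)
  excluded <- tot$tadpole[tot$n_responded == 0L]
  keep <- sessions[!sessions$tadpole %in% excluded, ]

  rate_of <- function(d, stim) {
    r <- d[d$stimulus == stim, ]
    if (nrow(r) == 0L) return(NA_real_)
    sum(r$n_responded) / sum(r$n_presented)
  }
  rows <- lapply(split(keep, keep$tadpole), function(d) {
    ac <- rate_of(d, "acoustic")
    out <- list()
    for (lvl in c("low", "high")) {
      vr <- rate_of(d, paste0("visual_", lvl))
      mr <- rate_of(d, paste0("multi_", lvl))
      if (is.na(vr) && is.na(mr)) next
      msi <- if (!is.na(vr) && vr > 0) (mr - vr) / vr else NA_real_
      out[[lvl]] <- data.frame(tadpole = d$tadpole[1L], group = d$group[1L],
                               contrast = lvl, visual_rate = vr,
                               multi_rate = mr, acoustic_rate = ac,
                               msi = msi,
                               flagged = is.na(msi))
    }
    do.call(rbind, out)
  })
  list(msi = do.call(rbind, c(rows, make.row.names = FALSE)),
       excluded = excluded)
}

#' ANCOVA battery for the NMDAR-blockade startle experiment
#'
#' Builds the per-animal MSI table (one value per session: low-contrast MSI
#' for the low-contrast groups, high-contrast MSI for the high-contrast
#' group), then runs the one-way ANCOVA of MSI on group with the acoustic
#' response rate as covariate, Tukey HSD on the covariate-adjusted means,
#' and one-sample t-tests of each group against zero.
#'
#' @param sessions Long startle table (see [startle_msi()]).
#' @return List with `msi` (analysis table), `ancova` (see
#'   [ancova_tukey()]), and `excluded`.
#' @export
ancova_msi <- function(sessions) {
  sm <- startle_msi(sessions)
  d <- sm$msi
  d <- d[(grepl("low$", d$group) & d$contrast == "low") |
           (grepl("high$", d$group) & d$contrast == "high"), ]
  d <- d[is.finite(d$msi) & is.finite(d$acoustic_rate), ]
  res <- ancova_tukey(d$msi, d$acoustic_rate, d$group)
  list(msi = d, ancova = res, excluded = sm$excluded)
}
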