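# Calcium-imaging analysis chain: motion registration, ROI trace
# extraction, bleach flattening and neuropil subtraction, dF/F0, 3-point
# peak estimation, per-cell summaries (primary modality, inclusion, MSIn),
# and the inverse-effectiveness curve fit.

#' Calcium movie container
#'
#' @param frames Numeric array `T x H x W` of fluorescence frames.
#' @param frame_rate Frames per second (> 0).
#' @param trial_markers Data frame with columns `start` (1-based first frame
#'   of each trial) and `condition` (one of visual, mechanosensory,
#'   multisensory, none).
#' @param frame_times Optional wall-clock time (s) of each frame; defaults
#'   to `(0:(T-1)) / frame_rate`. Used by the bleach model, which runs in
#'   real time even when only trial epochs are recorded.
#' @param prestim_s Prestimulus period within each trial (s).
#' @return Object of class `"tmsi_movie"`.
#' @export
tmsi_movie <- function(frames, frame_rate, trial_markers,
                       frame_times = NULL, prestim_s = 5) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[1L] >= 1L)
  if (frame_rate <= 0) stop("tmsi_movie: frame_rate must be > 0")
  if (!all(c("start", "condition") %in% names(trial_markers)))
    stop("tmsi_movie: trial_markers needs columns start, condition")
  if (!all(trial_markers$condition %in% CONDITIONS))
    stop("tmsi_movie: conditions must be one of ",
         paste(CONDITIONS, collapse = ", "))
  if (any(trial_markers$start < 1L | trial_markers$start > dim(frames)[1L]))
    stop("tmsi_movie: trial starts must lie within the movie")
  if (is.null(frame_times))
    frame_times <- (seq_len(dim(frames)[1L]) - 1L) / frame_rate
  structure(list(frames = frames, frame_rate = frame_rate,
                 trial_markers = trial_markers, frame_times = frame_times,
                 prestim_s = prestim_s),
            class = "tmsi_movie")
}

#' @export
print.tmsi_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("tmsi_movie: %d frames of %dx%d px at %.1f fps, %d trials\n",
              d[1L], d[2L], d[3L], x$frame_rate, nrow(x$trial_markers)))
  invisible(x)
}

#' ROI set container
#'
#' @param labels Integer matrix `H x W`; pixel value i > 0 assigns the pixel
#'   to ROI i.
#' @param neuropil Integer matrix of the same shape assigning neuropil
#'   pixels to ROIs; must be disjoint from every ROI pixel.
#' @return Object of class `"tmsi_rois"`.
#' @export
tmsi_rois <- function(labels, neuropil) {
  stopifnot(is.matrix(labels), is.matrix(neuropil),
            all(dim(labels) == dim(neuropil)))
  n_roi <- max(labels)
  if (n_roi < 1L) stop("tmsi_rois: no ROIs in label image")
  for (i in seq_len(n_roi)) {
    if (!any(labels == i)) stop("tmsi_rois: ROI ", i, " has an empty mask")
    if (any(labels == i & neuropil == i))
      stop("tmsi_rois: ROI ", i, " overlaps its own neuropil mask")
  }
  if (any(labels > 0L & neuropil > 0L))
    stop("tmsi_rois: neuropil masks must exclude all ROI pixels")
  structure(list(labels = labels, neuropil = neuropil, n_roi = n_roi),
            class = "tmsi_rois")
}

#' Rigid XY registration against a template average
#'
#' Translates every frame by the integer shift that maximizes its circular
#' cross-correlation with the average of the template frames, searching
#' shifts up to `max_shift` pixels in each direction. Frames whose best
#' normalized correlation falls below `min_corr` (e.g. pure noise) keep
#' their zero shift and are flagged.
#'
#' @param movie A [tmsi_movie()].
#' @param template_frames Frame indices averaged into the template
#'   (typically 100-300 frames).
#' @param max_shift Maximum shift magnitude searched (px).
#' @param min_corr Normalized-correlation floor below which a frame is
#'   flagged and left unshifted.
#' @return List with `movie` (registered) and `shifts` (data.frame: frame,
#'   dy, dx, corr, flagged).
#' @export
register <- function(movie, template_frames, max_shift = 5, min_corr = 0.2) {
  stopifnot(inherits(movie, "tmsi_movie"))
  Tn <- dim(movie$frames)[1L]
  if (length(template_frames) == 0L) stop("register: empty template range")
  if (any(template_frames < 1L | template_frames > Tn))
    stop("register: template range outside the movie")
  H <- dim(movie$frames)[2L]; W <- dim(movie$frames)[3L]
  tmpl <- apply(movie$frames[template_frames, , , drop = FALSE], c(2, 3), mean)
  tmpl_c <- tmpl - mean(tmpl)
  ft_tmpl <- stats::fft(tmpl_c)
  denom_t <- sqrt(sum(tmpl_c^2))

  # admissible circular lags
  dys <- c(0:max_shift, (H - max_shift):(H - 1L)) %% H
  dxs <- c(0:max_shift, (W - max_shift):(W - 1L)) %% W

  out <- data.frame(frame = seq_len(Tn), dy = 0L, dx = 0L,
                    corr = NA_real_, flagged = FALSE)
  reg <- movie$frames
  for (f in seq_len(Tn)) {
    fr <- movie$frames[f, , ]
    fr_c <- fr - mean(fr)
    # circular cross-correlation: cc at lag (u, v) sums tmpl[i+u, j+v] *
    # frame[i, j], so its argmax is the correction shift that re-aligns the
    # frame with the template
    cc <- Re(stats::fft(ft_tmpl * Conj(stats::fft(fr_c)), inverse = TRUE)) /
      length(fr_c)
    cc <- cc / (denom_t * sqrt(sum(fr_c^2)) + .Machine$double.eps)
    sub <- cc[dys + 1L, dxs + 1L, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    dy <- dys[best[1L]]; dx <- dxs[best[2L]]
    if (dy > H / 2) dy <- dy - H
    if (dx > W / 2) dx <- dx - W
    cmax <- max(sub)
    out$corr[f] <- cmax
    if (cmax < min_corr) {
      out$flagged[f] <- TRUE           # unreliable: leave frame in place
    } else {
      out$dy[f] <- dy; out$dx[f] <- dx
      if (dy != 0L || dx != 0L) reg[f, , ] <- shift_matrix(fr, dy, dx)
    }
  }
  movie$frames <- reg
  list(movie = movie, shifts = out)
}

#' Extract ROI and neuropil mean-fluorescence traces
#'
#' Arithmetic mean over the mask pixels of every frame, for each ROI and its
#' neuropil region.
#'
#' @param movie A [tmsi_movie()].
#' @param rois A [tmsi_rois()] matching the frame size.
#' @return Object of class `"tmsi_traces"`: list with `raw` and `neuropil`
#'   (`T x n_roi` matrices) plus the movie's timing metadata.
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "tmsi_movie"), inherits(rois, "tmsi_rois"))
  d <- dim(movie$frames)
  if (!all(dim(rois$labels) == d[2:3]))
    stop("extract_traces: ROI masks do not match the frame size")
  flat <- matrix(movie$frames, nrow = d[1L])   # T x (H*W), column-major
  raw <- matrix(NA_real_, d[1L], rois$n_roi)
  np <- matrix(NA_real_, d[1L], rois$n_roi)
  for (i in seq_len(rois$n_roi)) {
    ri <- which(rois$labels == i)
    ni <- which(rois$neuropil == i)
    if (length(ri) == 0L) stop("extract_traces: ROI ", i, " mask is empty")
    raw[, i] <- rowMeans(flat[, ri, drop = FALSE])
    np[, i] <- if (length(ni) == 0L) 0 else
      rowMeans(flat[, ni, drop = FALSE])
  }
  structure(list(raw = raw, neuropil = np, frame_rate = movie$frame_rate,
                 frame_times = movie$frame_times,
                 trial_markers = movie$trial_markers,
                 prestim_s = movie$prestim_s),
            class = "tmsi_traces")
}

# Slowly varying baseline of a fluorescence trace. Stage 1: a rolling
# lower-quantile envelope plus a single-exponential-with-offset fit to it.
# Stage 2: refit the exponential directly to the samples the stage-1
# baseline identifies as non-transient, which removes the envelope's
# quantile and window-edge bias. Runs in real time when frame times are
# supplied; falls back to the envelope when the fits fail.
estimate_baseline <- function(x, t = NULL, window = 101L, prob = 0.2) {
  n <- length(x)
  if (is.null(t)) t <- seq_len(n) - 1
  window <- min(window, n)
  half <- window %/% 2L
  env <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::quantile(x[lo:hi], prob, names = FALSE)
  }, 0)
  # Levenberg-Marquardt on the residuals directly (robust to the
  # zero-residual case that trips the nls object construction)
  exp_fit <- function(ti, xi, start) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start,
        lower = c(A = 0, tau = 1e-6, C = -Inf),
        fn = function(p) xi - (p[["A"]] * exp(-ti / p[["tau"]]) + p[["C"]]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info < 1 || fit$info > 4) return(NULL)
    fit$par
  }
  eval_exp <- function(p, ti) p[["A"]] * exp(-ti / p[["tau"]]) + p[["C"]]
  s0 <- list(A = max(env) - min(env) + 1e-6, tau = max(diff(range(t)), 1),
             C = min(env))
  p1 <- exp_fit(t, env, s0)
  if (is.null(p1))
    return(list(baseline = env, method = "rolling_percentile"))
  b1 <- eval_exp(p1, t)
  # non-transient samples: trace not far above the provisional baseline
  q <- x / pmax(b1, .Machine$double.eps)
  spread <- stats::mad(q, center = stats::median(q))
  keep <- q <= stats::median(q) + 3 * max(spread, 1e-12)
  if (sum(keep) >= 10L) {
    p2 <- exp_fit(t[keep], x[keep], p1)
    if (!is.null(p2))
      return(list(baseline = eval_exp(p2, t), method = "exponential"))
  }
  list(baseline = b1, method = "exponential")
}

#' Bleach flattening and neuropil subtraction
#'
#' Divides a slowly varying baseline (single-exponential fit anchored on a
#' rolling lower-quantile envelope, or the envelope itself when the fit
#' fails) out of both traces to flatten photobleaching — rescaled to the
#' initial baseline level so an unbleached trace passes through unchanged
#' and a bleached one is restored to its unbleached scale — then subtracts the
#' scaled neuropil trace and restores its mean, keeping the corrected trace
#' positive in expectation:
#' `corrected = raw_flat - r * np_flat + mean(r * np_flat)`.
#'
#' @param raw,neuropil Fluorescence traces of equal length.
#' @param r Neuropil mixing coefficient in `[0, 1]` (default 0.7).
#' @param t Optional frame times (s) for the bleach fit.
#' @param bleach `"exp"` (default: envelope + exponential fit with
#'   percentile fallback), `"percentile"`, or `"none"`.
#' @return List with `corrected`, `baseline`, `baseline_method`.
#' @export
correct_trace <- function(raw, neuropil, r = 0.7, t = NULL,
                          bleach = c("exp", "percentile", "none")) {
  bleach <- match.arg(bleach)
  if (length(raw) != length(neuropil))
    stop("correct_trace: series lengths differ")
  if (r < 0 || r > 1) stop("correct_trace: r must lie in [0, 1]")

  flatten <- function(x) {
    if (bleach == "none") return(list(x = x, b = rep(mean(x), length(x)),
                                      method = "none"))
    est <- estimate_baseline(x, t = t)
    if (bleach == "percentile") {
      env <- estimate_baseline(x, t = t, prob = 0.2)
      est <- list(baseline = env$baseline, method = "rolling_percentile")
    }
    if (any(est$baseline <= 0))
      stop("correct_trace: non-positive baseline estimate (min = ",
           signif(min(est$baseline), 4), "); check the input trace")
    # rescale to the initial baseline level, i.e. the unbleached scale
    list(x = x / est$baseline * est$baseline[1L], b = est$baseline,
         method = est$method)
  }

  rf <- flatten(raw)
  if (all(neuropil == 0)) {
    return(list(corrected = rf$x, baseline = rf$b,
                baseline_method = rf$method))
  }
  nf <- flatten(neuropil)
  corrected <- rf$x - r * nf$x + mean(r * nf$x)
  list(corrected = corrected, baseline = rf$b, baseline_method = rf$method)
}

#' Fractional fluorescence change for one trial
#'
#' `F0` is the mean over the prestimulus window; `dF/F0(t) = (F(t) - F0) /
#' F0` over the trial. Invariant to rescaling the trace by any positive
#' factor.
#'
#' @param trace Corrected fluorescence trace (whole recording).
#' @param trial_start First frame of the trial (1-based).
#' @param n_frames Trial length in frames.
#' @param prestim_frames Number of leading trial frames forming the
#'   prestimulus window.
#' @return List of class `"dff_trial"` with `samples` (dF/F0), `f0`, and
#'   `prestim_frames`.
#' @export
compute_dff <- function(trace, trial_start, n_frames, prestim_frames) {
  if (prestim_frames < 1L || prestim_frames >= n_frames)
    stop("compute_dff: prestimulus window must precede the stimulus within the trial")
  idx <- trial_start + seq_len(n_frames) - 1L
  if (any(idx < 1L) || any(idx > length(trace)))
    stop("compute_dff: trial window outside the trace")
  f <- trace[idx]
  f0 <- mean(f[seq_len(prestim_frames)])
  if (!is.finite(f0) || f0 <= 0)
    stop("compute_dff: prestimulus baseline F0 must be > 0 (got ",
         signif(f0, 4), ")")
  structure(list(samples = (f - f0) / f0, f0 = f0,
                 prestim_frames = prestim_frames),
            class = "dff_trial")
}

#' Three-point peak of a dF/F trial
#'
#' Locates the absolute maximum within the post-stimulus portion of the
#' trial and returns the mean of that sample and its two neighbors (at the
#' window edges, the mean of the two available samples).
#'
#' @param dff A `dff_trial` from [compute_dff()], or a numeric dF/F vector.
#' @param post_start First sample of the post-stimulus window; defaults to
#'   the sample after the prestimulus window for `dff_trial` input, 1
#'   otherwise.
#' @return Peak dF/F value.
#' @export
peak_response <- function(dff, post_start = NULL) {
  x <- if (inherits(dff, "dff_trial")) dff$samples else as.numeric(dff)
  if (is.null(post_start))
    post_start <- if (inherits(dff, "dff_trial")) dff$prestim_frames + 1L else 1L
  n <- length(x)
  if (post_start > n) stop("peak_response: empty post-stimulus window")
  post <- post_start:n
  pk <- post[which.max(x[post])]
  nb <- intersect((pk - 1L):(pk + 1L), seq_len(n))
  mean(x[nb])
}

#' Per-cell summary: mean peaks, inclusion, primary modality, MSIn
#'
#' Averages the trial peaks of each stimulus condition; a cell is included
#' when any of the three stimulus conditions (visual, mechanosensory,
#' multisensory) has a mean peak of at least `threshold` (default 0.1 dF/F).
#' The primary modality is the condition with the largest mean peak (ties
#' broken toward the larger unisensory response, then visual). MSIn is
#' `(multisensory - unisensory) / unisensory` with the unisensory term
#' chosen by `denominator`: the larger of the two unisensory mean peaks
#' (default), the smaller, or their sum.
#'
#' @param peaks Named list of numeric trial-peak vectors; names among
#'   visual, mechanosensory, multisensory (none is ignored).
#' @param roi ROI id carried into the output.
#' @param threshold Inclusion threshold on mean peak dF/F.
#' @param denominator `"max"`, `"min"`, or `"sum"`.
#' @return One-row data.frame: roi, mean peaks per condition, included,
#'   primary_modality, msin (NA when excluded or undefined).
#' @export
summarize_cell <- function(peaks, roi = NA_integer_, threshold = 0.1,
                           denominator = c("max", "min", "sum")) {
  denominator <- match.arg(denominator)
  stim <- c("visual", "mechanosensory", "multisensory")
  if (!any(stim %in% names(peaks)))
    stop("summarize_cell: no stimulus-condition peaks supplied")
  mp <- vapply(stim, function(cn)
    if (cn %in% names(peaks) && length(peaks[[cn]]) > 0)
      mean(peaks[[cn]]) else NA_real_, 0)
  included <- isTRUE(any(mp >= threshold, na.rm = TRUE))

  primary <- "none"
  ms_val <- NA_real_
  if (included) {
    # argmax; exact ties resolve toward the larger unisensory, then visual,
    # which the fixed priority visual < mechanosensory < multisensory yields
    uni <- mp[c("visual", "mechanosensory")]
    cand <- names(mp)[!is.na(mp) & mp == max(mp, na.rm = TRUE)]
    primary <- stim[stim %in% cand][1L]
    den <- switch(denominator,
                  max = max(uni, na.rm = TRUE),
                  min = min(uni, na.rm = TRUE),
                  sum = sum(uni, na.rm = TRUE))
    if (is.finite(den) && den > 0 && is.finite(mp["multisensory"]))
      ms_val <- (mp[["multisensory"]] - den) / den
  }
  data.frame(roi = roi, visual = mp[["visual"]],
             mechanosensory = mp[["mechanosensory"]],
             multisensory = mp[["multisensory"]],
             included = included, primary_modality = primary,
             msin = ms_val, row.names = NULL)
}

#' Inverse-effectiveness curve fit
#'
#' Fits `msin = a * exp(b * x)` to (largest unisensory mean peak, MSIn)
#' pairs by nonlinear least squares; a negative `b` is the signature of
#' inverse effectiveness (enhancement decaying with unisensory response
#' size).
#'
#' @param x Largest unisensory mean peak per cell (>= 0).
#' @param msin Per-cell multisensory index.
#' @return A `tmsi_expfit` (see [fit_exp_decay()]) with a `form` note.
#' @export
fit_ie_curve <- function(x, msin) {
  keep <- is.finite(x) & is.finite(msin)
  if (sum(keep) < 3L) stop("fit_ie_curve: need at least 3 finite points")
  if (any(x[keep] < 0)) stop("fit_ie_curve: responses must be >= 0")
  fit <- fit_exp_decay(x[keep], msin[keep])
  fit$form <- "a*exp(b*x)"
  fit
}

#' Full imaging pipeline: movie + ROIs to per-cell summaries
#'
#' Optionally registers the movie, extracts ROI and neuropil traces,
#' flattens bleaching and subtracts neuropil, computes per-trial dF/F0 and
#' 3-point peaks, and summarizes every cell (inclusion, primary modality,
#' MSIn).
#'
#' @param movie A [tmsi_movie()].
#' @param rois A [tmsi_rois()].
#' @param r Neuropil coefficient (see [correct_trace()]).
#' @param register_movie Run [register()] first (template: first 100-300
#'   frames).
#' @param threshold Inclusion threshold (see [summarize_cell()]).
#' @param denominator MSIn denominator choice (see [summarize_cell()]).
#' @param bleach Bleach model passed to [correct_trace()].
#' @return List with `cells` (CellSummary data.frame), `trial_peaks` (long
#'   data.frame: roi, condition, trial, peak), and `shifts` (when
#'   registered).
#' @export
analyze_movie <- function(movie, rois, r = 0.7, register_movie = FALSE,
                          threshold = 0.1,
                          denominator = c("max", "min", "sum"),
                          bleach = c("exp", "percentile", "none")) {
  denominator <- match.arg(denominator)
  bleach <- match.arg(bleach)
  shifts <- NULL
  if (register_movie) {
    n_tmpl <- min(300L, dim(movie$frames)[1L])
    regd <- register(movie, seq_len(n_tmpl))
    movie <- regd$movie
    shifts <- regd$shifts
  }
  tr <- extract_traces(movie, rois)
  # trial length: marker spacing for contiguous trial epochs, else to the end
  nf_trial <- if (nrow(movie$trial_markers) > 1L)
    min(diff(movie$trial_markers$start)) else
      dim(movie$frames)[1L] - movie$trial_markers$start[1L] + 1L
  prestim_frames <- max(1L, floor(movie$prestim_s * movie$frame_rate))

  peaks_long <- list()
  cells <- list()
  for (i in seq_len(rois$n_roi)) {
    cor <- correct_trace(tr$raw[, i], tr$neuropil[, i], r = r,
                         t = tr$frame_times, bleach = bleach)
    by_cond <- list()
    for (k in seq_len(nrow(movie$trial_markers))) {
      cond <- movie$trial_markers$condition[k]
      if (cond == "none") next
      d <- compute_dff(cor$corrected, movie$trial_markers$start[k],
                       nf_trial, prestim_frames)
      pk <- peak_response(d)
      by_cond[[cond]] <- c(by_cond[[cond]], pk)
      peaks_long[[length(peaks_long) + 1L]] <-
        data.frame(roi = i, condition = cond, trial = k, peak = pk)
    }
    cells[[i]] <- summarize_cell(by_cond, roi = i, threshold = threshold,
                                 denominator = denominator)
  }
  list(cells = do.call(rbind, cells),
       trial_peaks = do.call(rbind, peaks_long),
       shifts = shifts)
}
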