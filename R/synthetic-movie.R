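# Synthetic calcium-imaging movies with known per-cell ground truth.
# The generator emulates the acquisition design of the tectal imaging
# experiments: 7 s trials at 22.8 frames/s with a 5 s prestimulus period,
# blocks of 3 repetitions x 4 stimulus conditions (visual, mechanosensory,
# multisensory, none), 30 s start-to-start spacing (only trial epochs are
# recorded; the wall-clock gap drives photobleaching).

CONDITIONS <- c("visual", "mechanosensory", "multisensory", "none")

#' Crossmodal summation rule
#'
#' The generative stand-in for NMDA-receptor-dependent supralinear summation
#' of coincident subthreshold inputs: the multisensory amplitude is
#' `v + h + g * bonus`, where the bonus is `min(v, h)` when both unisensory
#' amplitudes lie below the threshold `theta` and 0 otherwise. With `g = 0`
#' summation is exactly linear; because the bonus is confined to small
#' inputs, populations built with `g > 0` exhibit inverse effectiveness by
#' construction.
#'
#' @param v,h Unisensory amplitudes (>= 0).
#' @param g Supralinearity coefficient (>= 0).
#' @param theta Amplitude threshold below which the bonus applies.
#' @return Multisensory amplitude (vectorized over `v` and `h`).
#' @export
#' @examples
#' crossmodal_rule(2, 3, 0, 10)   # 5: linear
#' crossmodal_rule(2, 3, 1, 10)   # 7: 2 + 3 + min(2, 3)
#' crossmodal_rule(12, 3, 1, 10)  # 15: bonus disabled above threshold
crossmodal_rule <- function(v, h, g, theta) {
  if (any(c(v, h, g, theta) < 0) || any(!is.finite(c(v, h, g, theta))))
    stop("crossmodal_rule: all arguments must be finite and >= 0")
  bonus <- ifelse(v < theta & h < theta, pmin(v, h), 0)
  v + h + g * bonus
}

# Difference-of-exponentials transient, normalized to unit peak; 0 for t < 0.
transient_kernel <- function(t, rise = 0.1, decay = 1.5) {
  stopifnot(rise > 0, decay > rise)
  k <- ifelse(t >= 0, exp(-t / decay) - exp(-t / rise), 0)
  t_pk <- rise * decay / (decay - rise) * log(decay / rise)
  k / (exp(-t_pk / decay) - exp(-t_pk / rise))
}

#' Simulation configuration for calcium movies
#'
#' Defaults reproduce the imaging protocol: 22.8 frames/s, 7 s trials with a
#' 5 s prestimulus period, 30 s start-to-start interval, 5 blocks of 3
#' repetitions x 4 conditions. `noise_sd` is additive Gaussian pixel noise in
#' fluorescence units (baseline is 100), `bleach_tau` the photobleaching time
#' constant in wall-clock seconds, `neuropil_mix` the fraction of the shared
#' neuropil dF/F that contaminates cell pixels, `jitter_px` the maximum
#' integer per-frame XY shift, and `supralinear_threshold` the amplitude
#' below which the crossmodal bonus applies.
#'
#' @param seed Integer RNG seed.
#' @param frame_rate,trial_s,prestim_s,start_to_start_s Acquisition timing.
#' @param n_blocks Number of blocks (each 3 reps x 4 conditions).
#' @param noise_sd,bleach_tau,neuropil_mix,jitter_px,supralinear_threshold
#'   See description.
#' @param gain Population supralinearity coefficient used when cells carry
#'   none of their own.
#' @param width,height Frame size in pixels.
#' @param baseline,neuropil_baseline Cell and background fluorescence levels.
#' @param texture_amp Relative SD of the static spatial baseline texture
#'   (bulk-loaded tissue is spatially heterogeneous; this is also what
#'   registration correlates on).
#' @param neuropil_response Peak dF/F of the shared neuropil transient on
#'   stimulus trials.
#' @param kernel_rise,kernel_decay Transient kernel time constants (s).
#' @param noise_model `"gaussian"` (default) or `"poisson"`.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, frame_rate = 22.8, trial_s = 7,
                       prestim_s = 5, start_to_start_s = 30, n_blocks = 5L,
                       noise_sd = 2, bleach_tau = 600, neuropil_mix = 0.7,
                       jitter_px = 0L, supralinear_threshold = 0.3,
                       gain = 1.5, width = 128L, height = 128L,
                       baseline = 100, neuropil_baseline = 100,
                       texture_amp = 0.15, neuropil_response = 0.05,
                       kernel_rise = 0.1, kernel_decay = 1.5,
                       noise_model = c("gaussian", "poisson")) {
  noise_model <- match.arg(noise_model)
  if (prestim_s >= trial_s) stop("sim_config: prestim_s must be < trial_s")
  if (frame_rate <= 0) stop("sim_config: frame_rate must be > 0")
  if (neuropil_mix < 0 || neuropil_mix > 1)
    stop("sim_config: neuropil_mix must lie in [0, 1]")
  structure(list(seed = as.integer(seed), frame_rate = frame_rate,
                 trial_s = trial_s, prestim_s = prestim_s,
                 start_to_start_s = start_to_start_s,
                 n_blocks = as.integer(n_blocks), noise_sd = noise_sd,
                 bleach_tau = bleach_tau, neuropil_mix = neuropil_mix,
                 jitter_px = as.integer(jitter_px),
                 supralinear_threshold = supralinear_threshold, gain = gain,
                 width = as.integer(width), height = as.integer(height),
                 baseline = baseline, neuropil_baseline = neuropil_baseline,
                 texture_amp = texture_amp,
                 neuropil_response = neuropil_response,
                 kernel_rise = kernel_rise, kernel_decay = kernel_decay,
                 noise_model = noise_model,
                 bonus_form = "min(v,h) gated by hard threshold"),
            class = "sim_config")
}

#' Random tectal cell population with ground-truth amplitudes
#'
#' Places approximately circular cells in the frame (rejection sampling with
#' a minimum center separation; overlaps that survive are flagged by
#' `simulate_movie`) and draws unisensory peak dF/F amplitudes log-uniformly
#' over `amp_range` with a random visual/mechanosensory balance, so the
#' population spans weak to strong responders.
#'
#' @param n Number of cells.
#' @param config A [sim_config()] (frame size and seed are taken from it).
#' @param radius Cell radius in pixels.
#' @param amp_range Range of the larger unisensory amplitude (peak dF/F).
#' @param ratio_range Range of the smaller/larger amplitude ratio.
#' @return Data frame with columns x, y, radius, visual_amp, mech_amp, gain.
#' @export
sim_cell_population <- function(n, config, radius = 4,
                                amp_range = c(0.06, 1.0),
                                ratio_range = c(0.3, 1.0)) {
  stopifnot(n >= 1, radius > 0)
  set.seed(config$seed + 104729L)
  margin <- radius + 2
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n && tries < 50000L) {
    cx <- stats::runif(1, margin, config$width - margin)
    cy <- stats::runif(1, margin, config$height - margin)
    if (all(sqrt((xs - cx)^2 + (ys - cy)^2) > 2 * radius + 2)) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
    tries <- tries + 1L
  }
  if (length(xs) < n)
    stop("sim_cell_population: could not place ", n, " cells in a ",
         config$width, "x", config$height, " frame")
  big <- exp(stats::runif(n, log(amp_range[1]), log(amp_range[2])))
  ratio <- stats::runif(n, ratio_range[1], ratio_range[2])
  small <- big * ratio
  vis_is_big <- stats::runif(n) < 0.5
  data.frame(x = round(xs), y = round(ys), radius = radius,
             visual_amp = ifelse(vis_is_big, big, small),
             mech_amp = ifelse(vis_is_big, small, big),
             gain = config$gain)
}

# Pixel index helpers -------------------------------------------------------

disk_pixels <- function(cx, cy, radius, width, height) {
  x0 <- max(1L, floor(cx - radius)); x1 <- min(width, ceiling(cx + radius))
  y0 <- max(1L, floor(cy - radius)); y1 <- min(height, ceiling(cy + radius))
  gx <- rep(x0:x1, each = y1 - y0 + 1L)
  gy <- rep(y0:y1, times = x1 - x0 + 1L)
  keep <- (gx - cx)^2 + (gy - cy)^2 <= radius^2
  cbind(row = gy[keep], col = gx[keep])   # row = y, col = x
}

#' ROI and neuropil masks from a cell table
#'
#' Builds the label image of cell disks plus, for each cell, an annular
#' neuropil region (`annulus[1]` to `annulus[2]` pixels beyond the cell
#' radius) from which every cell pixel has been excluded.
#'
#' @param cells Cell table as from [sim_cell_population()].
#' @param width,height Frame size.
#' @param annulus Inner and outer margin of the neuropil ring, in pixels.
#' @return Object of class `"tmsi_rois"`: list with integer label matrices
#'   `labels` and `neuropil` (0 = background) and `n_roi`.
#' @export
make_roi_masks <- function(cells, width, height, annulus = c(2, 6)) {
  labels <- matrix(0L, height, width)
  for (i in seq_len(nrow(cells))) {
    px <- disk_pixels(cells$x[i], cells$y[i], cells$radius[i], width, height)
    labels[px] <- i
  }
  neuropil <- matrix(0L, height, width)
  for (i in seq_len(nrow(cells))) {
    r <- cells$radius[i]
    outer <- disk_pixels(cells$x[i], cells$y[i], r + annulus[2], width, height)
    inner <- disk_pixels(cells$x[i], cells$y[i], r + annulus[1], width, height)
    ring <- outer[!paste(outer[, 1], outer[, 2]) %in%
                    paste(inner[, 1], inner[, 2]), , drop = FALSE]
    ok <- labels[ring] == 0L & neuropil[ring] == 0L
    neuropil[ring[ok, , drop = FALSE]] <- i
  }
  tmsi_rois(labels, neuropil)
}

#' Simulate a calcium-imaging movie
#'
#' Generates the recorded trial epochs of an imaging session. Each trial is
#' `round(trial_s * frame_rate)` frames; per trial and cell the fluorescence
#' follows `baseline * (1 + amp * k(t - prestim_s) + neuropil_mix * s(t))`
#' where `k` is the transient kernel, `amp` is the condition amplitude
#' (visual_amp, mech_amp, [crossmodal_rule()] of the two, or 0 for blank
#' trials) and `s(t)` the shared neuropil dF/F; background pixels carry
#' `neuropil_baseline * (1 + s(t))`. A multiplicative exponential bleach in
#' wall-clock time (trials start every `start_to_start_s`) and additive
#' noise are applied; optional integer XY jitter is applied as a circular
#' shift and recorded in the truth. Identical seed and config give identical
#' output.
#'
#' @param config A [sim_config()].
#' @param cells Cell table (columns x, y, radius, visual_amp, mech_amp, and
#'   optionally gain); may have zero rows for a pure-background movie.
#' @return List with `movie` (a [tmsi_movie()]), `rois` (a `tmsi_rois`),
#'   and `truth` (cell table with the multisensory amplitude, overlap flags,
#'   per-frame jitter shifts, and the generator configuration).
#' @export
simulate_movie <- function(config, cells) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(cells)) cells <- data.frame()
  n_cells <- nrow(cells)
  if (n_cells > 0) {
    if (any(cells$radius <= 0) || any(cells$visual_amp < 0) ||
        any(cells$mech_amp < 0))
      stop("simulate_movie: invalid cell table (radius > 0, amplitudes >= 0)")
    if (any(cells$x - cells$radius < 1 | cells$x + cells$radius > config$width |
            cells$y - cells$radius < 1 | cells$y + cells$radius > config$height))
      stop("simulate_movie: cells must fit within the frame")
    gain <- if ("gain" %in% names(cells)) cells$gain else rep(config$gain, n_cells)
    ms_amp <- crossmodal_rule(cells$visual_amp, cells$mech_amp, gain,
                              config$supralinear_threshold)
  }

  set.seed(config$seed)
  H <- config$height; W <- config$width
  nf_trial <- round(config$trial_s * config$frame_rate)
  n_trials <- config$n_blocks * 12L
  # fixed cycle of the 4 conditions, 3 repetitions per block
  cond_seq <- rep(rep(CONDITIONS, times = 3L), times = config$n_blocks)
  total_frames <- n_trials * nf_trial

  # static spatial texture of the bulk-loaded tissue (drawn once)
  texture <- 1 + matrix(stats::rnorm(H * W, 0, config$texture_amp), H, W)
  texture <- pmax(texture, 0.1)

  # baseline and response-amplitude images
  base_img <- matrix(config$neuropil_baseline, H, W)
  mix_img <- matrix(1, H, W)          # weight of the shared neuropil dF/F
  cell_px <- vector("list", n_cells)
  overlap <- logical(n_cells)
  if (n_cells > 0) {
    owner <- matrix(0L, H, W)
    for (i in seq_len(n_cells)) {
      px <- disk_pixels(cells$x[i], cells$y[i], cells$radius[i], W, H)
      cell_px[[i]] <- px
      prev <- owner[px]
      if (any(prev > 0L)) { overlap[i] <- TRUE; overlap[prev[prev > 0L]] <- TRUE }
      owner[px] <- i
      base_img[px] <- config$baseline
      mix_img[px] <- config$neuropil_mix
    }
  }
  base_img <- base_img * texture

  amp_of <- function(i, cond) {
    switch(cond,
           visual = cells$visual_amp[i],
           mechanosensory = cells$mech_amp[i],
           multisensory = ms_amp[i],
           none = 0)
  }

  t_rel <- (seq_len(nf_trial) - 1L) / config$frame_rate
  kern <- transient_kernel(t_rel - config$prestim_s,
                           config$kernel_rise, config$kernel_decay)

  frames <- array(0, dim = c(total_frames, H, W))
  frame_times <- numeric(total_frames)
  shifts <- matrix(0L, total_frames, 2L,
                   dimnames = list(NULL, c("dy", "dx")))
  trial_markers <- data.frame(start = integer(n_trials),
                              condition = cond_seq,
                              stringsAsFactors = FALSE)

  for (tr in seq_len(n_trials)) {
    i0 <- (tr - 1L) * nf_trial
    trial_markers$start[tr] <- i0 + 1L
    wall <- (tr - 1L) * config$start_to_start_s + t_rel
    frame_times[i0 + seq_len(nf_trial)] <- wall
    cond <- cond_seq[tr]
    s_t <- if (cond == "none") numeric(nf_trial) else
      config$neuropil_response * kern
    # amplitude image for this condition
    amp_img <- matrix(0, H, W)
    if (n_cells > 0)
      for (i in seq_len(n_cells)) amp_img[cell_px[[i]]] <- amp_of(i, cond)
    bleach <- exp(-wall / config$bleach_tau)
    for (f in seq_len(nf_trial)) {
      img <- base_img * (1 + amp_img * kern[f] + mix_img * s_t[f]) * bleach[f]
      if (config$noise_model == "gaussian") {
        if (config$noise_sd > 0)
          img <- img + matrix(stats::rnorm(H * W, 0, config$noise_sd), H, W)
      } else {
        img <- matrix(stats::rpois(H * W, pmax(img, 0)), H, W)
      }
      if (config$jitter_px > 0L) {
        dy <- sample(-config$jitter_px:config$jitter_px, 1L)
        dx <- sample(-config$jitter_px:config$jitter_px, 1L)
        shifts[i0 + f, ] <- c(dy, dx)
        img <- shift_matrix(img, dy, dx)
      }
      frames[i0 + f, , ] <- img
    }
  }

  movie <- tmsi_movie(frames, config$frame_rate, trial_markers,
                      frame_times = frame_times,
                      prestim_s = config$prestim_s)
  truth <- if (n_cells > 0) {
    cbind(cells, roi = seq_len(n_cells), multi_amp = ms_amp,
          overlap = overlap)
  } else {
    data.frame()
  }
  rois <- if (n_cells > 0) make_roi_masks(cells, W, H) else NULL
  list(movie = movie, rois = rois,
       truth = list(cells = truth, shifts = shifts, config = config))
}

# Circular integer shift: content moves down by dy rows and right by dx cols.
shift_matrix <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  ri <- ((seq_len(H) - 1L - dy) %% H) + 1L
  ci <- ((seq_len(W) - 1L - dx) %% W) + 1L
  m[ri, ci]
}
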