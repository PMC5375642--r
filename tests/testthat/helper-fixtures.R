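# Shared fixture builders; everything is generated in code at test time.

# A tiny textured movie with given per-frame shifts applied on top of an
# unjittered simulation, plus the clean template frames.
tiny_jittered_movie <- function(seed = 11, shifts) {
  cfg <- sim_config(seed = seed, width = 48, height = 48, n_blocks = 1,
                    noise_sd = 1)
  cells <- sim_cell_population(3, cfg)
  sim <- simulate_movie(cfg, cells)
  n <- nrow(shifts)
  stopifnot(dim(sim$movie$frames)[1] >= n + 50)
  frames <- sim$movie$frames[seq_len(n + 50), , , drop = FALSE]
  for (i in seq_len(n))
    frames[50 + i, , ] <- tectomsi:::shift_matrix(frames[50 + i, , ],
                                                  shifts[i, 1], shifts[i, 2])
  movie <- tmsi_movie(frames, cfg$frame_rate,
                      data.frame(start = 1L, condition = "none"))
  list(movie = movie, template = 1:50, shifted_idx = 50 + seq_len(n))
}

# Brute-force 3-point-peak oracle: maximum of the 3-sample (edge: 2-sample)
# centered means, evaluated at the post-window argmax.
peak_oracle <- function(x, post_start = 1L) {
  post <- post_start:length(x)
  pk <- post[which.max(x[post])]
  nb <- intersect((pk - 1L):(pk + 1L), seq_along(x))
  mean(x[nb])
}

# Independent response-area oracle: mean of the left and right rectangle
# sums of the baseline-subtracted post-stimulus samples.
area_oracle <- function(trace, window_s = 1.5, baseline_s = 0.1) {
  sr <- trace$sample_hz
  onset <- min(trace$stimulus_onsets$time)
  i_on <- floor(onset * sr) + 1L
  i_end <- i_on + round(window_s * sr)
  base <- mean(trace$samples[max(1L, i_on - round(baseline_s * sr)):(i_on - 1L)])
  y <- trace$samples[i_on:i_end] - base
  left <- sum(y[-length(y)]) / sr
  right <- sum(y[-1L]) / sr
  (left + right) / 2
}

# Pair-count Mann-Whitney U oracle.
u_oracle <- function(x, y) {
  u_lt <- 0
  for (xi in x) u_lt <- u_lt + sum(xi < y) + 0.5 * sum(xi == y)
  min(u_lt, length(x) * length(y) - u_lt)
}

# Exact two-sided Mann-Whitney p by complete enumeration of rank subsets.
mwu_p_enum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_obs <- u_oracle(x, y)
  subsets <- utils::combn(n1 + n2, n1)
  r <- rank(pooled)
  us <- apply(subsets, 2, function(ix) {
    u_gt <- sum(sort(ix)) - n1 * (n1 + 1) / 2   # ranks are 1..n, no ties
    min(u_gt, n1 * n2 - u_gt)
  })
  # P(min-U <= u_obs) = 2 * P(U <= u_obs) by symmetry of the unfolded null
  min(1, mean(us <= u_obs))
}
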