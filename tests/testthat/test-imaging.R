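test_that("registration: identity, known constant shift, noise flagging", {
  set.seed(2)
  base <- matrix(rnorm(48 * 48, 100, 15), 48)
  frames <- array(0, dim = c(4, 48, 48))
  frames[1, , ] <- base
  frames[2, , ] <- base                                      # unshifted
  frames[3, , ] <- tectomsi:::shift_matrix(base, 3, -2)      # known shift
  frames[4, , ] <- matrix(rnorm(48 * 48), 48)                # pure noise
  mov <- tmsi_movie(frames, 22.8, data.frame(start = 1L, condition = "none"))
  reg <- register(mov, 1L, max_shift = 5)
  expect_equal(unlist(reg$shifts[2, c("dy", "dx")]), c(dy = 0, dx = 0))
  expect_equal(unlist(reg$shifts[3, c("dy", "dx")]), c(dy = -3, dx = 2))
  expect_equal(reg$movie$frames[3, , ], base)                # residual zero
  expect_true(reg$shifts$flagged[4])
  expect_equal(unlist(reg$shifts[4, c("dy", "dx")]), c(dy = 0, dx = 0))
  expect_error(register(mov, integer(0)), "empty template")
  expect_error(register(mov, 1:10), "outside the movie")
})

test_that("registration recovers every generated jitter shift exactly", {
  cfg <- sim_config(seed = 5, width = 64, height = 64, n_blocks = 1,
                    noise_sd = 1, jitter_px = 3)
  cells <- sim_cell_population(6, cfg)
  sim <- simulate_movie(cfg, cells)
  truth <- sim$truth$shifts
  tmpl <- which(truth[, 1] == 0L & truth[, 2] == 0L)
  reg <- register(sim$movie, tmpl, max_shift = 5)
  expect_equal(cbind(reg$shifts$dy, reg$shifts$dx), -unname(truth),
               ignore_attr = TRUE)
})

test_that("trace extraction is the mask mean, including hand-computed cases", {
  frames <- array(0, dim = c(3, 4, 4))
  frames[1, , ] <- 7; frames[2, , ] <- 7; frames[3, , ] <- 7
  labels <- matrix(0L, 4, 4); labels[1:2, 1:2] <- 1L
  np <- matrix(0L, 4, 4); np[4, 4] <- 1L
  mov <- tmsi_movie(frames, 10, data.frame(start = 1L, condition = "none"))
  tr <- extract_traces(mov, tmsi_rois(labels, np))
  expect_equal(tr$raw[, 1], c(7, 7, 7))    # uniform frame -> constant trace

  # checkerboard values on a 4-pixel mask: mean by hand
  f2 <- array(0, dim = c(1, 4, 4))
  f2[1, , ] <- matrix(c(1, 2, 3, 4), 4, 4)  # column-constant rows 1..4
  mov2 <- tmsi_movie(f2, 10, data.frame(start = 1L, condition = "none"))
  np_d <- matrix(0L, 4, 4); np_d[1, 4] <- 1L
  lb <- matrix(0L, 4, 4); lb[cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))] <- 1L
  tr2 <- extract_traces(mov2, tmsi_rois(lb, np_d))
  expect_equal(tr2$raw[, 1], mean(c(1, 2, 3, 4)))

  # single-pixel mask equals that pixel's series
  f3 <- array(rnorm(3 * 16), dim = c(3, 4, 4))
  lb3 <- matrix(0L, 4, 4); lb3[2, 3] <- 1L
  mov3 <- tmsi_movie(f3, 10, data.frame(start = 1L, condition = "none"))
  tr3 <- extract_traces(mov3, tmsi_rois(lb3, np))
  expect_equal(tr3$raw[, 1], f3[, 2, 3])

  expect_error(tmsi_rois(matrix(0L, 4, 4), np), "no ROIs")
})

test_that("trace correction: identity, bleach recovery, full subtraction", {
  set.seed(3)
  t <- seq(0, 200, by = 0.5)
  signal <- 100 + 20 * (sin(t / 5) > 0.95)
  # neuropil zero, no bleach: corrected equals raw
  c0 <- correct_trace(signal, rep(0, length(t)), r = 0.7, t = t)
  expect_equal(c0$corrected, signal, tolerance = 0.01)

  # known exponential bleach divided out: RMS error < 1%
  bl <- exp(-t / 120)
  c1 <- correct_trace(signal * bl, rep(0, length(t)), r = 0.7, t = t)
  rms <- sqrt(mean((c1$corrected - signal)^2)) / mean(signal)
  expect_lt(rms, 0.01)

  # r = 1 and neuropil = raw: constant at the restored mean
  c2 <- correct_trace(signal, signal, r = 1, t = t)
  expect_equal(c2$corrected, rep(mean(c2$corrected), length(t)),
               tolerance = 1e-8)

  expect_error(correct_trace(signal, signal, r = 1.5), "\\[0, 1\\]")
  expect_error(correct_trace(signal, signal[-1], r = 0.5), "lengths differ")
})

test_that("dF/F: hand case, scale invariance, F0 guard", {
  f <- c(100, 100, 100, 100, 110, 120, 100)
  d <- compute_dff(f, 1L, 7L, 4L)
  expect_equal(d$f0, 100)
  expect_equal(d$samples, c(0, 0, 0, 0, 0.1, 0.2, 0))
  dk <- compute_dff(3.7 * f, 1L, 7L, 4L)
  expect_equal(dk$samples, d$samples)
  expect_equal(compute_dff(rep(5, 10), 1L, 10L, 4L)$samples, rep(0, 10))
  expect_error(compute_dff(c(-1, -1, -1, 1, 1), 1L, 5L, 3L), "F0 must be > 0")
  expect_error(compute_dff(f, 1L, 7L, 7L), "precede")
})

test_that("3-point peak: hand cases, edge rule, constant trace", {
  expect_equal(peak_response(c(0, 0.1, 0.3, 0.1, 0)), (0.1 + 0.3 + 0.1) / 3)
  expect_equal(peak_response(c(0, 0.1, 0.4)), (0.1 + 0.4) / 2)  # edge: 2 samples
  expect_equal(peak_response(rep(0, 8)), 0)
  expect_error(peak_response(c(1, 2), post_start = 5L), "empty post-stimulus")
})

test_that("3-point peak equals the moving-average oracle on random traces", {
  set.seed(14)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    ps <- sample(seq_len(n - 1L), 1)
    expect_equal(peak_response(x, post_start = ps), peak_oracle(x, ps))
  }
})

test_that("cell summary: inclusion rule, ties, MSIn arithmetic", {
  # all three stimulus means below 0.1: excluded
  s1 <- summarize_cell(list(visual = 0.05, mechanosensory = 0.08,
                            multisensory = 0.09))
  expect_false(s1$included)
  expect_equal(s1$primary_modality, "none")
  expect_true(is.na(s1$msin))

  # multisensory ties the best unisensory: primary visual, msin 0
  s2 <- summarize_cell(list(visual = 0.3, mechanosensory = 0.2,
                            multisensory = 0.3))
  expect_true(s2$included)
  expect_equal(s2$primary_modality, "visual")
  expect_equal(s2$msin, 0)

  # msin against the larger unisensory
  s3 <- summarize_cell(list(visual = 0.1, mechanosensory = 0.2,
                            multisensory = 0.5))
  expect_equal(s3$msin, 1.5)
  expect_equal(s3$primary_modality, "multisensory")

  # denominator switches
  expect_equal(summarize_cell(list(visual = 0.1, mechanosensory = 0.2,
                                   multisensory = 0.5),
                              denominator = "sum")$msin, (0.5 - 0.3) / 0.3)
  expect_error(summarize_cell(list()), "no stimulus-condition")
})

test_that("exclusion rule partitions any synthetic population", {
  cfg <- sim_config(seed = 9, width = 64, height = 64, n_blocks = 1,
                    noise_sd = 2)
  cells <- sim_cell_population(10, cfg, amp_range = c(0.02, 0.8))
  sim <- simulate_movie(cfg, cells)
  res <- analyze_movie(sim$movie, sim$rois, r = cfg$neuropil_mix)
  expect_equal(sum(res$cells$included) + sum(!res$cells$included),
               nrow(cells))
  exc <- res$cells[!res$cells$included, ]
  expect_true(all(pmax(exc$visual, exc$mechanosensory, exc$multisensory) < 0.1))
})

test_that("IE curve fit: exact on noiseless data, flags its model form", {
  x <- seq(0, 1, length.out = 15)
  f <- fit_ie_curve(x, 4 * exp(-3 * x))
  expect_equal(f$a, 4, tolerance = 1e-6)
  expect_equal(f$b, -3, tolerance = 1e-6)
  expect_equal(f$form, "a*exp(b*x)")
  expect_error(fit_ie_curve(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_ie_curve(c(-1, 1, 2), c(1, 1, 1)), ">= 0")
})
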