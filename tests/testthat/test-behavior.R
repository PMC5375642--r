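test_that("response change: percent-change and speed modes", {
  r <- response_change(c(2, 2), c(3, 3), mode = "percent_change")
  expect_equal(as.numeric(r), 50)
  expect_equal(as.numeric(response_change(c(2, 2), c(2, 2), "percent_change")), 0)
  expect_equal(as.numeric(response_change(c(1, 1), c(4, 4), "speed")), 4)
  z <- response_change(c(0, 0), c(3, 3), "percent_change")
  expect_true(is.na(z) && attr(z, "flagged"))
  expect_error(response_change(numeric(0), 1:3), "non-empty")
})

test_that("inactivity exclusion honors the 3-minute rule", {
  mk <- function(td, ts, speeds)
    data.frame(tadpole = td, timestamp_s = ts, condition = "visual",
               contrast = 0, trial_mean_speed = speeds)
  ts <- seq(0, by = 20, length.out = 12)
  tr <- rbind(mk(1, ts, rep(0, 12)),                   # still throughout
              mk(2, ts, rep(3, 12)),                   # moves on every trial
              mk(3, ts, c(rep(0, 6), rep(3, 6))))      # still 100+2 s < 180 s
  exc <- exclude_inactive(tr)
  expect_equal(exc$excluded$tadpole, 1)
  expect_setequal(unique(exc$trials$tadpole), c(2, 3))
  # retained records are unaltered (pure filtering)
  expect_identical(exc$trials, tr[tr$tadpole != 1, ])
  tr_na <- tr; tr_na$timestamp_s <- NA
  expect_error(exclude_inactive(tr_na), "timestamps")

  # still for 9 trials spanning 162 s, i.e. just short via span: retained;
  # one extra still trial pushes past 180 s: excluded
  tr4 <- mk(4, ts, c(rep(0, 9), 3, 3, 3))
  expect_equal(nrow(exclude_inactive(tr4)$excluded), 0)
  tr5 <- mk(5, ts, c(rep(0, 10), 3, 3))
  expect_equal(exclude_inactive(tr5)$excluded$tadpole, 5)
})

test_that("session MSIn: hand cases and zero-visual flag", {
  tr <- data.frame(tadpole = 1,
                   condition = rep(c("visual", "multisensory"), each = 2),
                   contrast = 25,
                   response = c(2, 2, 4, 4))
  ms <- session_msin(tr)
  expect_equal(ms$msin, 1)
  tr0 <- tr; tr0$response <- c(3, 3, 3, 3)
  expect_equal(session_msin(tr0)$msin, 0)
  trz <- tr; trz$response <- c(0, 0, 2, 2)
  expect_true(is.na(session_msin(trz)$msin))
})

test_that("session and startle MSIn agree with the shared index primitive", {
  tr <- data.frame(tadpole = 1,
                   condition = rep(c("visual", "multisensory"), each = 3),
                   contrast = 50,
                   response = c(2, 3, 4, 5, 6, 7))
  expect_equal(session_msin(tr)$msin, msin(mean(c(5, 6, 7)), mean(c(2, 3, 4))))

  st <- data.frame(tadpole = 1, group = "control_low",
                   stimulus = c("acoustic", "visual_low", "multi_low"),
                   n_presented = 10, n_responded = c(2, 3, 6))
  sm <- startle_msi(st)
  expect_equal(sm$msi$msi, msin(0.6, 0.3))
  expect_equal(sm$msi$msi, 1)
})

test_that("startle MSI: equal rates, exclusions, zero-visual flagging", {
  st <- data.frame(tadpole = c(1, 1, 1, 2, 2, 2, 3, 3, 3),
                   group = "control_low",
                   stimulus = rep(c("acoustic", "visual_low", "multi_low"), 3),
                   n_presented = 10,
                   n_responded = c(2, 4, 4,   0, 0, 0,   1, 0, 5))
  sm <- startle_msi(st)
  expect_equal(sm$msi$msi[sm$msi$tadpole == 1], 0)     # equal rates
  expect_equal(sm$excluded, 2)                          # all-zero responder
  t3 <- sm$msi[sm$msi$tadpole == 3, ]
  expect_true(is.na(t3$msi) && t3$flagged)              # visual rate 0
  bad <- st; bad$n_responded[1] <- 11
  expect_error(startle_msi(bad), "n_responded")
})

test_that("swim battery recovers enhancement confined to 25% contrast", {
  cfg <- sim_behavior_config(seed = 31, n_tadpoles = 20,
                             enhancement = c(0, 2, 0, 0))
  tr <- score_trials(simulate_swim_trials(cfg)$trials, "speed")
  bat <- anova_battery(exclude_inactive(tr)$trials)
  cmp <- bat$twoway$comparisons
  expect_equal(cmp$f2[which.min(cmp$p_adj)], "25")
  expect_lt(cmp$p_adj[cmp$f2 == "25"], 0.01)
  expect_equal(cmp$df[1], 20 * 4 - 4)      # paired formulation df
  dn <- bat$oneway$comparisons
  expect_equal(dn$contrast[which.min(dn$p_adj)], "25 - 0")
})

test_that("ANCOVA battery separates enhanced from blocked-and-high groups", {
  cfg <- sim_startle_config(seed = 17)
  anc <- ancova_msi(simulate_startle_sessions(cfg)$sessions)
  am <- anc$ancova$adjusted_means
  expect_gt(am$adj_mean[am$group == "control_low"],
            am$adj_mean[am$group == "control_high"])
  expect_equal(anc$ancova$anova$df2[1],
               nrow(anc$msi) - 3 - 1)      # N - k groups - covariate
})
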