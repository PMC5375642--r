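test_that("msin computes the index, is scale invariant, rejects bad input", {
  expect_equal(msin(4, 2), 1)
  expect_equal(msin(2, 2), 0)
  expect_equal(msin(1, 2), -0.5)
  k <- 7.3
  expect_equal(msin(4 * k, 2 * k), msin(4, 2))
  expect_error(msin(1, 0), "> 0")
  expect_error(msin(1, -2), "> 0")
})

test_that("Mann-Whitney U matches hand cases and reports the method", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 0.1)
  expect_equal(r$method, "exact")

  # identical samples: U = n1*n2/2 (all pairs tied)
  r2 <- suppressWarnings(mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(unname(r2$statistic), 8)
  expect_equal(r2$method, "normal_approx")   # ties force the approximation

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("U statistic equals the pair-count oracle on random samples", {
  set.seed(42)
  for (i in 1:300) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    x <- round(rnorm(n1), 2); y <- round(rnorm(n2, 0.3), 2)
    r <- suppressWarnings(mann_whitney_u(x, y))
    expect_equal(unname(r$statistic), u_oracle(x, y))
  }
})

test_that("exact Mann-Whitney p matches complete enumeration (no ties)", {
  set.seed(7)
  for (i in 1:40) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    xy <- sample(seq_len(50), n1 + n2)   # distinct values: tie-free
    x <- xy[seq_len(n1)]; y <- xy[-seq_len(n1)]
    expect_equal(mann_whitney_u(x, y)$p.value, mwu_p_enum(x, y))
  }
})

test_that("exact Mann-Whitney p agrees with the reference rank test", {
  set.seed(9)
  for (i in 1:25) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)
    xy <- sample(seq_len(100), n1 + n2)
    x <- xy[seq_len(n1)]; y <- xy[-seq_len(n1)]
    expect_equal(mann_whitney_u(x, y)$p.value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("interleaved symmetric samples give large p at large n", {
  set.seed(3)
  x <- rnorm(80); y <- rnorm(90)
  r <- mann_whitney_u(x, y)
  expect_equal(r$method, "normal_approx")
  expect_gt(r$p.value, 0.2)
})

test_that("fit_exp_decay recovers noiseless parameters exactly", {
  x <- seq(0, 1, length.out = 20)
  f <- fit_exp_decay(x, 10 * exp(-2 * x))
  expect_equal(f$a, 10, tolerance = 1e-6)
  expect_equal(f$b, -2, tolerance = 1e-6)
  expect_equal(f$adj_r2, 1, tolerance = 1e-9)
  # constant response degenerates to b = 0, a = mean
  fc <- fit_exp_decay(x, rep(3, 20))
  expect_equal(fc$a, 3, tolerance = 1e-6)
  expect_equal(fc$b, 0, tolerance = 1e-6)
  expect_error(fit_exp_decay(1:2, 1:2), "at least 3")
})

test_that("exp-fit confidence intervals bracket the estimates", {
  set.seed(21)
  x <- runif(50, 0, 2)
  y <- 5 * exp(-1.5 * x) + rnorm(50, 0, 0.05)
  f <- fit_exp_decay(x, y)
  expect_lt(f$ci["a", 1], f$a); expect_gt(f$ci["a", 2], f$a)
  expect_lt(f$ci["b", 1], f$b); expect_gt(f$ci["b", 2], f$b)
})

test_that("Sidak adjustment matches its closed form and dominates raw p", {
  p <- c(0.01, 0.2, 0.6)
  expect_equal(sidak_adjust(p, 4), 1 - (1 - p)^4)
  expect_true(all(sidak_adjust(p, 4) >= p))
})

test_that("one-way Dunnett: identical groups give p near 1, adjusted >= raw", {
  set.seed(5)
  y <- rep(rnorm(20), 3); g <- rep(c("ref", "a", "b"), each = 20)
  r <- anova_oneway_dunnett(y, g, ref = "ref")
  expect_true(all(r$comparisons$p_adj > 0.99))
  raw <- 2 * pt(-abs(r$comparisons$t), r$anova$df2)
  expect_true(all(r$comparisons$p_adj >= raw - 1e-10))
})

test_that("two-group one-way ANOVA F equals the squared pooled t", {
  set.seed(6)
  y <- c(rnorm(15), rnorm(15, 1)); g <- rep(c("a", "b"), each = 15)
  r <- anova_oneway_dunnett(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(r$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("one-sample t is zero at the hypothesized mean", {
  x <- c(1, 2, 3, 4)
  r <- one_sample_t(x, mu = 2.5)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
})

test_that("two-way Sidak battery flags only the enhanced contrast", {
  set.seed(8)
  n <- 20
  d <- expand.grid(tadpole = seq_len(n), condition = c("visual", "multisensory"),
                   contrast = c(0, 25, 50, 100))
  d$response <- rnorm(nrow(d), 3) +
    ifelse(d$condition == "multisensory" & d$contrast == 25, 2, 0)
  r <- anova_twoway_sidak(d, "response", "condition", "contrast",
                          subject = "tadpole")
  expect_equal(r$comparisons$f2[which.min(r$comparisons$p_adj)], "25")
  expect_lt(r$comparisons$p_adj[r$comparisons$f2 == "25"], 0.001)
  # identical groups: large adjusted p everywhere
  d0 <- d; d0$response <- rep(rnorm(n * 4), times = 2)
  r0 <- anova_twoway_sidak(d0, "response", "condition", "contrast",
                           subject = "tadpole")
  expect_true(all(r0$comparisons$p_adj > 0.9))
  expect_error(anova_twoway_sidak(d[d$contrast != 0 | d$condition != "visual", ],
                                  "response", "condition", "contrast",
                                  subject = "tadpole"),
               "empty design cell")
})

test_that("ANCOVA: null groups give small F; covariate slope drives covariate F", {
  set.seed(10)
  n <- 60
  g <- rep(c("a", "b", "c"), each = n / 3)
  cov <- rnorm(n)
  y0 <- rnorm(n)
  r0 <- ancova_tukey(y0, cov, g)
  expect_gt(r0$anova$p[r0$anova$term == "group"], 0.05)
  # add a pure covariate effect, orthogonal to group
  y1 <- y0 + 2 * cov
  r1 <- ancova_tukey(y1, cov, g)
  expect_gt(r1$anova$F[r1$anova$term == "covariate"],
            r0$anova$F[r0$anova$term == "covariate"])
  expect_equal(r1$anova$F[r1$anova$term == "group"],
               r0$anova$F[r0$anova$term == "group"], tolerance = 1e-8)
  expect_error(ancova_tukey(rnorm(5), rnorm(5), c("a", "a", "a", "b", "b")),
               "at least 3")
})
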