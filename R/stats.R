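# Shared statistical primitives: the multisensory index, exact Mann-Whitney U,
# exponential-decay least squares, and the ANOVA / ANCOVA batteries used by the
# behavior and ephys front ends.

#' Multisensory index
#'
#' MSIn = (multisensory - unisensory) / unisensory. Positive values indicate
#' multisensory enhancement; the index is invariant to rescaling both
#' responses by a common positive factor.
#'
#' @param multi Multisensory response (numeric, any length).
#' @param uni Unisensory response; must be strictly positive.
#' @return Numeric vector of indices.
#' @export
#' @examples
#' msin(4, 2)   # 1
#' msin(2, 2)   # 0
msin <- function(multi, uni) {
  if (!is.numeric(multi) || !is.numeric(uni))
    stop("msin: inputs must be numeric")
  if (any(!is.finite(uni)) || any(uni <= 0))
    stop("msin: unisensory response must be finite and > 0")
  (multi - uni) / uni
}

#' Sidak multiplicity adjustment
#'
#' @param p Raw p-values.
#' @param m Number of comparisons in the family (default `length(p)`).
#' @return Adjusted p-values, `1 - (1 - p)^m`.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

# Null distribution of the Mann-Whitney U statistic (number of (x, y) pairs
# with x > y) for sample sizes n1, n2 without ties, by dynamic programming
# over rank placements. Returns counts for U = 0 .. n1*n2; sums to C(n1+n2, n1).
mwu_null_counts <- function(n1, n2) {
  n <- n1 + n2
  # dp[j + 1, u + 1]: number of ways to place j x's among the first k ranks
  # accumulating u pairs (x above a previously placed y).
  dp <- matrix(0, n1 + 1L, n1 * n2 + 1L)
  dp[1L, 1L] <- 1
  for (k in seq_len(n)) {
    for (j in rev(seq_len(min(k, n1)))) {
      # placing an x at rank k beats the (k - 1) - (j - 1) y's already placed
      add <- (k - 1L) - (j - 1L)
      u_to <- seq(add, n1 * n2)
      dp[j + 1L, u_to + 1L] <- dp[j + 1L, u_to + 1L] + dp[j, u_to - add + 1L]
    }
  }
  dp[n1 + 1L, ]
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent samples.
#' The statistic counts pairs `(x_i, y_j)` with `x_i < y_j` (plus 1/2 per
#' tie) and is reported as `min(U, n1*n2 - U)`, the convention under which a
#' complete separation of the samples gives U = 0. For tie-free samples with
#' `min(n1, n2) <= 20` the two-sided p-value is exact (twice the smaller tail
#' of the full permutation distribution of U, capped at 1); otherwise a
#' normal approximation with tie correction and continuity correction is
#' used. The method actually applied is reported.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` chooses exact when there are no ties and
#'   `min(n1, n2) <= 20`.
#' @return A list of class `"tmsi_test"` with elements `statistic` (named
#'   `U`), `p.value`, `method` (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("mann_whitney_u: both samples must be non-empty")
  if (any(!is.finite(c(x, y))))
    stop("mann_whitney_u: samples must be finite")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  has_ties <- any(duplicated(pooled))
  # pairs with x > y (+ 1/2 per tie), from the rank sum of x
  u_gt <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_lt <- n1 * n2 - u_gt                    # pairs with x < y (+ 1/2 per tie)
  u_min <- min(u_lt, u_gt)

  if (is.null(exact)) exact <- !has_ties && min(n1, n2) <= 20L
  if (exact && has_ties) {
    warning("mann_whitney_u: ties present; falling back to normal approximation")
    exact <- FALSE
  }

  if (exact) {
    counts <- mwu_null_counts(n1, n2)
    total <- sum(counts)
    lower <- sum(counts[seq_len(u_min + 1L)]) / total      # P(U <= u_min)
    p <- min(1, 2 * lower)                                  # symmetric null
    method <- "exact"
  } else {
    n <- n1 + n2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1                                               # all values tied
    } else {
      z <- (abs(u_lt - n1 * n2 / 2) - 0.5) / sqrt(sigma2)  # continuity corr.
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal_approx"
  }

  structure(
    list(statistic = c(U = u_min), p.value = p, method = method,
         n1 = n1, n2 = n2, ties = has_ties),
    class = "tmsi_test")
}

#' @export
print.tmsi_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              x$statistic, x$n1, x$n2, x$p.value, x$method))
  invisible(x)
}

#' Exponential-decay least-squares fit
#'
#' Fits `y = a * exp(b * x)` by nonlinear least squares, initialized from a
#' log-linear regression on the positive-y subset, with bounded restarts on
#' non-convergence. Confidence intervals come from the parameter covariance
#' with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, at least 3 points.
#' @param level Confidence level for the intervals (default 0.95).
#' @return A list of class `"tmsi_expfit"` with `a`, `b`, `cov`, `r2`,
#'   `adj_r2`, `ci` (2x2 matrix, rows `a` and `b`), `n`, and `fitted`.
#' @export
fit_exp_decay <- function(x, y, level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("fit_exp_decay: x and y lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("fit_exp_decay: need at least 3 points")

  starts <- list()
  pos <- y > 0
  if (sum(pos) >= 2L && stats::sd(x[pos]) > 0) {
    lf <- stats::lm(log(y[pos]) ~ x[pos])
    starts[[1L]] <- list(a = exp(unname(coef(lf)[1L])), b = unname(coef(lf)[2L]))
  }
  xr <- max(x) - min(x)
  b_scale <- if (xr > 0) 1 / xr else 1
  starts <- c(starts,
              list(list(a = mean(y), b = 0),
                   list(a = max(abs(y)), b = -b_scale),
                   list(a = max(abs(y)), b = -5 * b_scale)))

  fit <- NULL; tried <- list()
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x),
                        start = s,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    tried <- c(tried, list(s))
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("fit_exp_decay: did not converge; initializations tried: ",
         paste(vapply(tried, function(s)
           sprintf("(a=%.3g, b=%.3g)", s$a, s$b), ""), collapse = ", "))

  cf <- coef(fit)
  res <- y - fitted(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res <= 1e-12) 1 else 0
  adj_r2 <- if (n > 3L) 1 - (1 - r2) * (n - 1) / (n - 3) else r2

  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  tq <- stats::qt(1 - (1 - level) / 2, df = max(n - 2L, 1L))
  ci <- cbind(lower = cf - tq * se, upper = cf + tq * se)
  rownames(ci) <- c("a", "b")

  structure(
    list(a = unname(cf["a"]), b = unname(cf["b"]), cov = vc,
         r2 = r2, adj_r2 = adj_r2, ci = ci, n = n,
         fitted = fitted(fit), model = "y = a * exp(b * x)"),
    class = "tmsi_expfit")
}

#' @export
print.tmsi_expfit <- function(x, ...) {
  cat(sprintf("%s\n  a = %.4g (%.4g, %.4g)\n  b = %.4g (%.4g, %.4g)\n  adjusted R^2 = %.3f, n = %d\n",
              x$model, x$a, x$ci["a", 1], x$ci["a", 2],
              x$b, x$ci["b", 1], x$ci["b", 2], x$adj_r2, x$n))
  invisible(x)
}

#' One-way ANOVA with Dunnett comparisons against a reference level
#'
#' Standard between-groups one-way ANOVA followed by Dunnett's many-to-one
#' comparisons against `ref`.
#'
#' @param y Response vector.
#' @param g Grouping factor (or coercible).
#' @param ref Reference level name (default: first level).
#' @return List with `anova` (data.frame: F, df1, df2, p) and `comparisons`
#'   (data.frame: contrast, estimate, t, p_adj).
#' @export
anova_oneway_dunnett <- function(y, g, ref = NULL) {
  g <- factor(g)
  if (nlevels(g) < 2L) stop("anova_oneway_dunnett: need >= 2 groups")
  if (!is.null(ref)) {
    if (!ref %in% levels(g)) stop("anova_oneway_dunnett: unknown reference level ", ref)
    g <- stats::relevel(g, ref)
  }
  dat <- data.frame(y = y, g = g)
  fit <- stats::aov(y ~ g, data = dat)
  tab <- summary(fit)[[1L]]
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl)
  structure(list(
    anova = data.frame(F = tab[1L, "F value"], df1 = tab[1L, "Df"],
                       df2 = tab[2L, "Df"], p = tab[1L, "Pr(>F)"]),
    comparisons = data.frame(
      contrast = names(sm$test$coefficients),
      estimate = unname(sm$test$coefficients),
      t = unname(sm$test$tstat),
      p_adj = unname(sm$test$pvalues))),
    class = "tmsi_anova")
}

#' Two-way comparison battery with Sidak adjustment
#'
#' Compares the two levels of `f1` (e.g. visual vs multisensory condition) at
#' every level of `f2` (e.g. stimulus contrast), with Sidak adjustment over
#' the `f2` family, alongside the omnibus two-way ANOVA table.
#'
#' Two error formulations are available. `"paired"` (default) uses the
#' within-subject difference between the `f1` levels for every subject x
#' `f2` cell and pools the difference variance across `f2` levels, giving
#' `n_subjects * K - K` error df for K levels of `f2` — the formulation that
#' respects the repeated-measures design in which every subject sees both
#' `f1` levels. `"pooled"` uses the residual mean square of the between-cells
#' two-way ANOVA.
#'
#' @param data Data frame.
#' @param y,f1,f2,subject Column names (strings) of the response, the
#'   two-level factor, the crossing factor, and the subject id.
#' @param method `"paired"` or `"pooled"`.
#' @return List with `anova` (omnibus two-way table as a data.frame) and
#'   `comparisons` (per-`f2` difference, t, df, raw and Sidak-adjusted p).
#' @export
anova_twoway_sidak <- function(data, y, f1, f2, subject = NULL,
                               method = c("paired", "pooled")) {
  method <- match.arg(method)
  d <- data.frame(y = data[[y]], f1 = factor(data[[f1]]),
                  f2 = factor(data[[f2]]))
  if (nlevels(d$f1) != 2L)
    stop("anova_twoway_sidak: f1 must have exactly 2 levels")
  if (any(table(d$f1, d$f2) == 0L)) {
    bad <- which(table(d$f1, d$f2) == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("anova_twoway_sidak: empty design cell (%s, %s)",
                 levels(d$f1)[bad[1L]], levels(d$f2)[bad[2L]]))
  }
  om <- summary(stats::aov(y ~ f1 * f2, data = d))[[1L]]
  om_df <- data.frame(term = trimws(rownames(om)), df = om$Df,
                      F = om$`F value`, p = om$`Pr(>F)`)

  lv <- levels(d$f1)
  K <- nlevels(d$f2)
  if (method == "paired") {
    if (is.null(subject)) stop("anova_twoway_sidak: paired method needs a subject column")
    d$subject <- factor(data[[subject]])
    # per subject x f2 cell means for each f1 level, then their difference
    m <- stats::aggregate(y ~ subject + f2 + f1, data = d, FUN = mean)
    w1 <- m[m$f1 == lv[1L], c("subject", "f2", "y")]
    w2 <- m[m$f1 == lv[2L], c("subject", "f2", "y")]
    mg <- merge(w1, w2, by = c("subject", "f2"), suffixes = c("_1", "_2"))
    mg$diff <- mg$y_2 - mg$y_1
    fitd <- stats::lm(diff ~ 0 + f2, data = mg)
    mse <- sum(resid(fitd)^2) / stats::df.residual(fitd)
    df_err <- stats::df.residual(fitd)
    cmp <- do.call(rbind, lapply(levels(mg$f2), function(lev) {
      dd <- mg$diff[mg$f2 == lev]
      se <- sqrt(mse / length(dd))
      tt <- mean(dd) / se
      data.frame(f2 = lev, estimate = mean(dd), t = tt, df = df_err,
                 p_raw = 2 * stats::pt(-abs(tt), df_err))
    }))
  } else {
    fit <- stats::lm(y ~ f1 * f2, data = d)
    mse <- sum(resid(fit)^2) / stats::df.residual(fit)
    df_err <- stats::df.residual(fit)
    cmp <- do.call(rbind, lapply(levels(d$f2), function(lev) {
      a <- d$y[d$f1 == lv[1L] & d$f2 == lev]
      b <- d$y[d$f1 == lv[2L] & d$f2 == lev]
      est <- mean(b) - mean(a)
      se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
      tt <- est / se
      data.frame(f2 = lev, estimate = est, t = tt, df = df_err,
                 p_raw = 2 * stats::pt(-abs(tt), df_err))
    }))
  }
  cmp$p_adj <- sidak_adjust(cmp$p_raw, K)
  rownames(cmp) <- NULL
  structure(list(anova = om_df, comparisons = cmp,
                 method = method, levels = lv),
            class = "tmsi_anova")
}

#' One-way ANCOVA with Tukey HSD on adjusted means
#'
#' Fits `y ~ covariate + group`, reports the covariate-adjusted group F and
#' the covariate F (partial, Type II sums of squares), covariate-adjusted
#' group means at the mean covariate value, all pairwise Tukey HSD contrasts
#' on those adjusted means, and a one-sample t-test of each group's raw mean
#' against zero.
#'
#' @param y Response vector.
#' @param covariate Numeric covariate.
#' @param group Grouping factor.
#' @return List with `anova`, `adjusted_means`, `tukey`, `t_vs_zero`.
#' @export
ancova_tukey <- function(y, covariate, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("ancova_tukey: need >= 2 groups")
  if (any(table(group) < 3L))
    stop("ancova_tukey: every group needs at least 3 observations")
  dat <- data.frame(y = y, covariate = covariate, group = group)
  fit <- stats::lm(y ~ covariate + group, data = dat)
  a2 <- car::Anova(fit, type = 2)
  df2 <- a2["Residuals", "Df"]
  anova_tab <- data.frame(
    term = c("group", "covariate"),
    F = c(a2["group", "F value"], a2["covariate", "F value"]),
    df1 = c(a2["group", "Df"], a2["covariate", "Df"]),
    df2 = df2,
    p = c(a2["group", "Pr(>F)"], a2["covariate", "Pr(>F)"]))

  emm <- emmeans::emmeans(fit, "group")
  emm_df <- as.data.frame(emm)
  tk <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))

  tz <- do.call(rbind, lapply(levels(group), function(g) {
    tt <- one_sample_t(dat$y[dat$group == g], mu = 0)
    data.frame(group = g, mean = tt$mean, t = tt$statistic, df = tt$df,
               p = tt$p.value)
  }))

  structure(list(anova = anova_tab,
                 adjusted_means = data.frame(group = emm_df$group,
                                             adj_mean = emm_df$emmean,
                                             se = emm_df$SE),
                 tukey = data.frame(contrast = tk$contrast,
                                    estimate = tk$estimate,
                                    t = tk$t.ratio, p_adj = tk$p.value),
                 t_vs_zero = tz, fit = fit),
            class = "tmsi_anova")
}

#' One-sample t-test against a hypothesized mean
#'
#' @param x Numeric sample (n >= 2).
#' @param mu Hypothesized mean (default 0).
#' @return List with `mean`, `statistic`, `df`, `p.value`.
#' @export
one_sample_t <- function(x, mu = 0) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("one_sample_t: need at least 2 finite values")
  tt <- stats::t.test(x, mu = mu)
  list(mean = unname(tt$estimate), statistic = unname(tt$statistic),
       df = unname(tt$parameter), p.value = tt$p.value, mu = mu)
}
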