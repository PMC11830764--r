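# Paired test battery (Shapiro-Wilk gated t / Wilcoxon) and JZS Bayes
# factors for a one-sample t design with a Cauchy prior on effect size.

#' Paired comparison with normality-gated test choice
#'
#' Two-tailed paired t-test, unless Shapiro-Wilk on the differences
#' rejects normality at alpha = 0.05, in which case a Wilcoxon
#' signed-rank test is used. Reports Cohen's d (mean difference / SD of
#' differences) or the rank-biserial correlation, each with a 95% CI
#' (normal approximation).
#'
#' @param cond_a,cond_b Paired per-participant values.
#' @return List: `test` ("t" or "wilcoxon"), `statistic`, `p_two_tailed`,
#'   `effect`, `effect_name`, `ci95`, `shapiro_p`, `n`.
#' @export
paired_contrast_test <- function(cond_a, cond_b) {
  if (length(cond_a) != length(cond_b)) stop("conditions differ in length")
  n <- length(cond_a)
  if (n < 5L) stop("need at least 5 pairs")
  d <- cond_a - cond_b
  if (all(d == d[1L])) {
    stop("degenerate input: all paired differences are identical")
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= 0.05) {
    tt <- stats::t.test(d)
    eff <- mean(d) / stats::sd(d)
    se <- sqrt(1 / n + eff^2 / (2 * n))
    list(test = "t", statistic = unname(tt$statistic),
         p_two_tailed = tt$p.value, effect = eff, effect_name = "cohen_d",
         ci95 = eff + c(-1, 1) * stats::qnorm(0.975) * se,
         shapiro_p = sw$p.value, n = n)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(cond_a, cond_b, paired = TRUE))
    m <- sum(d != 0)
    s_total <- m * (m + 1) / 2
    v_stat <- unname(wt$statistic)
    rb <- (2 * v_stat - s_total) / s_total
    se <- sqrt(2 * (2 * m + 1) / (3 * m * (m + 1)))
    list(test = "wilcoxon", statistic = v_stat,
         p_two_tailed = wt$p.value, effect = rb,
         effect_name = "rank_biserial",
         ci95 = pmin(1, pmax(-1, rb + c(-1, 1) * stats::qnorm(0.975) * se)),
         shapiro_p = sw$p.value, n = n)
  }
}

#' JZS Bayes factor for a one-sample t design
#'
#' BF-01 (evidence for the null of zero effect) under a Cauchy prior on
#' the standardized effect size, computed by numerical integration of
#' the noncentral-t marginal likelihood over the prior:
#' `m1 = integral dt(t; nu, ncp = sqrt(n) * delta) * Cauchy(delta; 0, r)`,
#' with the prior truncated to delta > 0 (and doubled) for
#' `tail = "greater"`; `BF01 = dt(t; nu) / m1`.
#'
#' @param x Per-participant scores (one-sample design); alternatively
#'   supply `t` and `n` directly.
#' @param t,n t statistic and sample size (used when `x` is NULL).
#' @param tail `"two_sided"` or `"greater"` (positive effects only).
#' @param cauchy_scale Prior scale r (default 0.707, i.e. sqrt(2)/2).
#' @return List with `bf01`, `bf10`, `t`, `n`, `tail`.
#' @export
jzs_bf01 <- function(x = NULL, t = NULL, n = NULL,
                     tail = c("two_sided", "greater"),
                     cauchy_scale = 0.707) {
  tail <- match.arg(tail)
  if (!is.null(x)) {
    n <- length(x)
    if (n < 3L) stop("need at least 3 observations")
    if (stats::sd(x) == 0) stop("zero-variance input")
    t <- mean(x) / (stats::sd(x) / sqrt(n))
  }
  if (is.null(t) || is.null(n)) stop("supply x, or both t and n")
  if (n < 3L) stop("need at least 3 observations")
  nu <- n - 1L
  integrand <- function(delta) {
    suppressWarnings(stats::dt(t, df = nu, ncp = sqrt(n) * delta)) *
      stats::dcauchy(delta, 0, cauchy_scale)
  }
  m1 <- if (tail == "greater") {
    res <- stats::integrate(function(d) 2 * integrand(d), 0, Inf,
                            rel.tol = 1e-9, stop.on.error = FALSE)
    res
  } else {
    stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-9,
                     stop.on.error = FALSE)
  }
  if (m1$message != "OK" || !is.finite(m1$value) || m1$value <= 0) {
    stop("JZS integration did not converge: ", m1$message)
  }
  m0 <- stats::dt(t, df = nu)
  list(bf01 = m0 / m1$value, bf10 = m1$value / m0, t = t, n = n, tail = tail)
}
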