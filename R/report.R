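#' Questionnaire of Spatial Strategies scores
#'
#' Scores the everyday-navigation questionnaire: Navigation Confidence
#' is the sum of items 3, 4, 5s, 10, 11 and 13; Route knowledge is
#' q5r + q6r; Survey knowledge is q5s + q6s + q9_sp - q9_verb; and dRS
#' is Route minus Survey, positive values flagging a preference for
#' egocentric route strategies.
#'
#' @param items Data frame (one row per subject) with columns `q3`,
#'   `q4`, `q5s`, `q10`, `q11`, `q13`, `q5r`, `q6r`, `q9_sp`,
#'   `q9_verb`, `q6s`.
#' @return Data frame with `nav_confidence`, `route`, `survey`, `dRS`.
#' @export
qos_scores <- function(items) {
  need <- c("q3", "q4", "q5s", "q10", "q11", "q13", "q5r", "q6r",
            "q6s", "q9_sp", "q9_verb")
  miss <- setdiff(need, names(items))
  if (length(miss)) {
    stop("missing questionnaire item(s): ", paste(miss, collapse = ", "))
  }
  route <- items$q5r + items$q6r
  survey <- items$q5s + items$q6s + items$q9_sp - items$q9_verb
  data.frame(
    nav_confidence = items$q3 + items$q4 + items$q5s + items$q10 +
      items$q11 + items$q13,
    route = route, survey = survey, dRS = route - survey)
}

# Wilcoxon signed-rank with Pratt handling of zeros (zeros keep their
# ranks and are then discarded), average ranks for ties, normal
# approximation with tie correction.  Returns the z statistic of W+.
signed_rank_z <- function(x, mu0 = 0) {
  d <- x - mu0
  n_all <- length(d)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  n0 <- sum(d == 0)
  ew <- (n_all * (n_all + 1) - n0 * (n0 + 1)) / 4
  tie_tab <- table(r[d != 0])
  vw <- n_all * (n_all + 1) * (2 * n_all + 1) / 24 -
    n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (vw <= 0) stop("degenerate sample for the signed-rank test")
  list(W = w_pos, z = (w_pos - ew) / sqrt(vw), n = n_all)
}

tail_p <- function(z, tails) {
  switch(tails,
         two = 2 * stats::pnorm(-abs(z)),
         greater = stats::pnorm(z, lower.tail = FALSE),
         less = stats::pnorm(z))
}

#' One-sample test with a normality gate
#'
#' A Shapiro--Wilk test at alpha = 0.05 decides between the one-sample
#' t test (normal) and the Wilcoxon signed-rank test (non-normal; Pratt
#' zeros, average ranks for ties, normal approximation).  Effect size
#' is Cohen's d for the t test and r = |z| / sqrt(n) for the signed
#' rank.
#'
#' @param x Numeric sample (n >= 3, non-constant).
#' @param mu0 Null value.
#' @param tails `"two"`, `"greater"` or `"less"`.
#' @param alpha Significance threshold recorded in the result (pass a
#'   Bonferroni-corrected level where applicable).
#' @return A `test_result` list: `test_name`, `statistic`, `p`,
#'   `effect_size`, `ci`, `alpha_used`, `tails`, `normality_p`,
#'   `significant`.
#' @export
normality_gated_test <- function(x, mu0 = 0,
                                 tails = c("two", "greater", "less"),
                                 alpha = 0.05) {
  tails <- match.arg(tails)
  if (length(x) < 3) stop("need at least three observations")
  if (stats::sd(x) == 0) stop("constant sample: test is degenerate")
  sw <- stats::shapiro.test(x)$p.value
  alt <- c(two = "two.sided", greater = "greater", less = "less")[tails]
  if (sw >= 0.05) {
    tt <- stats::t.test(x, mu = mu0, alternative = alt)
    res <- list(test_name = "one-sample t",
                statistic = unname(tt$statistic),
                p = tt$p.value,
                effect_size = mean(x - mu0) / stats::sd(x),
                ci = unname(tt$conf.int))
  } else {
    sr <- signed_rank_z(x, mu0)
    res <- list(test_name = "wilcoxon signed-rank",
                statistic = sr$z,
                p = tail_p(sr$z, tails),
                effect_size = abs(sr$z) / sqrt(sr$n),
                ci = c(NA_real_, NA_real_))
  }
  res$alpha_used <- alpha
  res$tails <- tails
  res$normality_p <- sw
  res$significant <- res$p < alpha
  class(res) <- "test_result"
  res
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: stat = %.3f, p = %.4g (%s, alpha = %g)%s\n",
              x$test_name, x$statistic, x$p, x$tails, x$alpha_used,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Bonferroni-corrected alpha level
#'
#' @param base_alpha Familywise level (default 0.05).
#' @param n_tests Number of tests in the family (>= 1).
#' @return `base_alpha / n_tests` (e.g. 0.05 / 3 ~ 0.016 across
#'   hemispheres, 0.05 / 5 = 0.01 across tested periodicities).
#' @export
bonferroni_alpha <- function(base_alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  base_alpha / n_tests
}

#' Two-group comparison with normality gate and variance check
#'
#' Two-sample t test (pooled variance) when both samples pass the
#' Shapiro--Wilk gate, Wilcoxon rank-sum otherwise; Levene's test for
#' homogeneity of variance is reported alongside.
#'
#' @param a,b Numeric samples (each n >= 3).
#' @param tails `"two"`, `"greater"` or `"less"` (`a` relative to `b`).
#' @param alpha Recorded significance threshold.
#' @return A `test_result` with additional fields `levene_p` and
#'   `test_name` describing the chosen test.
#' @export
group_compare <- function(a, b, tails = c("two", "greater", "less"),
                          alpha = 0.05) {
  tails <- match.arg(tails)
  if (length(a) < 3 || length(b) < 3) stop("need n >= 3 per group")
  alt <- c(two = "two.sided", greater = "greater", less = "less")[tails]
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  lev <- car::leveneTest(c(a, b) ~ g)
  lev_p <- lev[["Pr(>F)"]][1]
  normal <- stats::sd(a) > 0 && stats::sd(b) > 0 &&
    stats::shapiro.test(a)$p.value >= 0.05 &&
    stats::shapiro.test(b)$p.value >= 0.05
  if (normal) {
    tt <- stats::t.test(a, b, var.equal = TRUE, alternative = alt)
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    res <- list(test_name = "two-sample t",
                statistic = unname(tt$statistic), p = tt$p.value,
                effect_size = (mean(a) - mean(b)) / sp,
                ci = unname(tt$conf.int))
  } else {
    wt <- stats::wilcox.test(a, b, alternative = alt, exact = FALSE,
                             correct = FALSE)
    n <- length(a) + length(b)
    z <- stats::qnorm(
      stats::wilcox.test(a, b, alternative = "less", exact = FALSE,
                         correct = FALSE)$p.value)
    res <- list(test_name = "wilcoxon rank-sum",
                statistic = unname(wt$statistic), p = wt$p.value,
                effect_size = abs(z) / sqrt(n),
                ci = c(NA_real_, NA_real_))
  }
  res$levene_p <- lev_p
  res$alpha_used <- alpha
  res$tails <- tails
  res$significant <- res$p < alpha
  class(res) <- "test_result"
  res
}

#' Pearson (or partial) correlation test
#'
#' Plain Pearson product-moment correlation, or, when a covariate is
#' supplied, the partial correlation obtained by residualising both
#' variables on the covariate (p from the t distribution with n - 3
#' degrees of freedom).
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @param covariate Optional numeric covariate.
#' @param alpha Recorded significance threshold.
#' @return A `test_result` with fields `r` and `r_squared`.
#' @export
correlate <- function(x, y, covariate = NULL, alpha = 0.05) {
  n <- length(x)
  if (length(y) != n || n < 4) stop("x and y must share length >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  if (is.null(covariate)) {
    ct <- stats::cor.test(x, y)
    res <- list(test_name = "pearson correlation",
                statistic = unname(ct$statistic), p = ct$p.value,
                r = unname(ct$estimate),
                r_squared = unname(ct$estimate)^2,
                effect_size = unname(ct$estimate),
                ci = unname(ct$conf.int))
  } else {
    rx <- stats::resid(stats::lm(x ~ covariate))
    ry <- stats::resid(stats::lm(y ~ covariate))
    r <- stats::cor(rx, ry)
    df <- n - 3
    tstat <- r * sqrt(df / (1 - r^2))
    res <- list(test_name = "partial pearson correlation",
                statistic = tstat,
                p = 2 * stats::pt(-abs(tstat), df),
                r = r, r_squared = r^2, effect_size = r,
                ci = c(NA_real_, NA_real_))
  }
  res$alpha_used <- alpha
  res$tails <- "two"
  res$significant <- res$p < alpha
  class(res) <- "test_result"
  res
}

#' Group-by-covariate interaction model
#'
#' Least-squares fit `y ~ covariate * group`; reports the t statistic
#' and two-tailed p of the interaction coefficient plus the model R^2.
#'
#' @param y Response vector.
#' @param covariate Numeric covariate.
#' @param group Factor (or coercible) with exactly two levels present.
#' @param alpha Recorded significance threshold.
#' @return A `test_result` with fields `coefficient` and `r_squared`.
#' @export
interaction_model <- function(y, covariate, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2) {
    stop("both groups must be represented")
  }
  fit <- stats::lm(y ~ covariate * group)
  sm <- summary(fit)
  co <- sm$coefficients
  term <- grep(":", rownames(co), value = TRUE)
  res <- list(test_name = "interaction (covariate x group)",
              statistic = co[term, "t value"],
              p = co[term, "Pr(>|t|)"],
              coefficient = co[term, "Estimate"],
              r_squared = sm$r.squared,
              effect_size = co[term, "t value"],
              ci = unname(stats::confint(fit)[term, ]),
              alpha_used = alpha, tails = "two")
  res$significant <- res$p < alpha
  class(res) <- "test_result"
  res
}
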