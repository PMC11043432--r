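qos_fixture <- function(n = 1, route = 4.5, survey = 2.5) {
  data.frame(q3 = rep(4, n), q4 = 4, q5s = survey, q10 = 4, q11 = 4,
             q13 = 4, q5r = route, q6r = route + 0.5, q6s = survey,
             q9_sp = 3, q9_verb = 1)
}

test_that("questionnaire scoring follows the stated formulas", {
  it <- data.frame(q3 = 3, q4 = 2, q5s = 2, q10 = 4, q11 = 5, q13 = 1,
                   q5r = 4, q6r = 5, q6s = 2, q9_sp = 3, q9_verb = 1)
  sc <- qos_scores(it)
  expect_equal(sc$route, 9)
  expect_equal(sc$survey, 6)
  expect_equal(sc$dRS, 3)
  expect_equal(sc$nav_confidence, 3 + 2 + 2 + 4 + 5 + 1)
  expect_error(qos_scores(it[, setdiff(names(it), "q6r")]), "q6r")
  # linearity: scaling every item scales dRS
  expect_equal(qos_scores(it * 3)$dRS, 3 * sc$dRS)
})

test_that("signed-rank (Pratt) matches the reference implementation", {
  # reference p-values from an independent statistical library
  # (Pratt zeros, tie-corrected normal approximation, no continuity
  # correction)
  x1 <- c(1.1, -0.5, 2.3, 0.0, 1.7, -0.2, 0.8, 1.2, 0.4, -1.0, 0.6, 2.0)
  x2 <- c(1, 1, -1, 2, 2, -2, 3, 0, 0, 4)
  s1 <- gridclock:::signed_rank_z(x1, 0)
  s2 <- gridclock:::signed_rank_z(x2, 0)
  expect_equal(2 * pnorm(-abs(s1$z)), 0.04529278621703289,
               tolerance = 1e-10)
  expect_equal(pnorm(s1$z, lower.tail = FALSE), 0.022646393108516447,
               tolerance = 1e-10)
  expect_equal(2 * pnorm(-abs(s2$z)), 0.12183145048736106,
               tolerance = 1e-10)
  expect_equal(pnorm(s2$z, lower.tail = FALSE), 0.06091572524368053,
               tolerance = 1e-10)
})

test_that("the normality gate picks the right test", {
  set.seed(31)
  gauss <- rnorm(25)
  tg <- normality_gated_test(gauss, tails = "two")
  expect_equal(tg$test_name, "one-sample t")
  # matches a hand-rolled t oracle on random fixtures
  for (i in 1:20) {
    x <- rnorm(10 + i)
    r <- normality_gated_test(x, mu0 = 0.2, tails = "two")
    if (r$test_name == "one-sample t") {
      t_o <- mean(x - 0.2) / (sd(x) / sqrt(length(x)))
      p_o <- 2 * pt(-abs(t_o), length(x) - 1)
      expect_equal(r$statistic, t_o, tolerance = 1e-10)
      expect_equal(r$p, p_o, tolerance = 1e-10)
    }
  }

  skewed <- exp(rnorm(40, sd = 1.2)) - 1
  expect_equal(normality_gated_test(skewed)$test_name,
               "wilcoxon signed-rank")
  expect_error(normality_gated_test(rep(1, 10)), "constant")
  expect_error(normality_gated_test(c(1, 2)), "three")
})

test_that("Bonferroni levels reproduce the corrected thresholds", {
  expect_equal(bonferroni_alpha(0.05, 3), 0.05 / 3)
  expect_equal(round(bonferroni_alpha(0.05, 3), 3), 0.017)
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
})

test_that("group comparison gates on normality and reports Levene", {
  set.seed(41)
  a <- rnorm(19)
  tr <- group_compare(a, a)
  expect_gt(tr$p, 0.99)
  expect_equal(tr$effect_size, 0, tolerance = 1e-12)
  expect_true(is.finite(tr$levene_p))

  # power: groups two pooled SDs apart are detected at alpha = 0.01
  hits <- vapply(1:200, function(i) {
    set.seed(i)
    x <- rnorm(19)
    y <- rnorm(19) + 2
    group_compare(x, y)$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # scale difference flagged by Levene
  set.seed(77)
  x <- rnorm(30)
  y <- rnorm(30, 1, 3.5)
  expect_lt(group_compare(x, y)$levene_p, 0.05)

  # non-normal branch
  set.seed(42)
  sk <- exp(rnorm(30, sd = 1.5))
  expect_equal(group_compare(sk, sk + 0.1)$test_name,
               "wilcoxon rank-sum")
  expect_error(group_compare(1:2, 1:5), "n >= 3")
})

test_that("correlation tests are calibrated and partial out covariates", {
  expect_equal(correlate(1:10, 1:10)$r, 1)
  expect_error(correlate(rep(1, 10), 1:10), "variance")

  set.seed(55)
  rej <- vapply(1:10000, function(i) {
    correlate(rnorm(19), rnorm(19))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.01)

  # partial correlation equals the explicit residualisation oracle
  set.seed(56)
  z <- rnorm(40)
  x <- rnorm(40)
  y <- x + z
  pc <- correlate(x, y, covariate = z)
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-12)
  expect_gt(pc$r, cor(x, y) - 1)   # defined
})

test_that("interaction model isolates slope differences", {
  set.seed(60)
  g <- rep(c("a", "b"), each = 19)
  x <- rnorm(38)
  # identical slopes, noiseless: interaction exactly zero
  y0 <- 2 + 0.8 * x
  r0 <- suppressWarnings(interaction_model(y0, x, g))
  expect_equal(r0$coefficient, 0, tolerance = 1e-10)

  expect_error(interaction_model(y0[1:19], x[1:19], g[1:19]), "group")

  hits <- vapply(1:60, function(i) {
    set.seed(100 + i)
    xx <- rnorm(38)
    yy <- ifelse(g == "b", 0.5 * xx, 0) + rnorm(38, 0, 0.5)
    interaction_model(yy, xx, g)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("reports on hand-built records flag the planted pattern", {
  set.seed(70)
  n <- 19
  mk <- function(group, b4, b6, act) {
    cbind(data.frame(subject = seq_len(n), group = group,
                     beta_fold4 = b4, beta_fold5 = rnorm(n, 0, 0.5),
                     beta_fold6 = b6, beta_fold7 = rnorm(n, 0, 0.5),
                     beta_fold8 = rnorm(n, 0, 0.5),
                     phi_fold4 = if (group == "blind") {
                       (30 + rnorm(n, 0, 5)) %% 90
                     } else runif(n, 0, 90),
                     phi_fold6 = runif(n, 0, 60),
                     roi_activity_beta = act,
                     accuracy = pmin(1, rnorm(n, 0.92, 0.03)),
                     pi_performance = rnorm(
                       n, if (group == "blind") 0.6 else 1.0, 0.15)),
          qos_scores(qos_fixture(n,
                                 route = if (group == "blind") 5.5 else 4,
                                 survey = if (group == "blind") 2.5 else 4)))
  }
  b4_blind <- rnorm(n, 2.5, 0.8)
  recs <- rbind(
    mk("sighted", rnorm(n, 0, 0.5), rnorm(n, 2.5, 0.8), rnorm(n, 1, 1)),
    mk("blind", b4_blind, rnorm(n, 0, 0.5),
       1 + 0.8 * scale(b4_blind)[, 1] + rnorm(n, 0, 0.4)))
  rep1 <- build_report(recs)
  expect_true(rep1$flags[["fold6_sig_group1"]])
  expect_false(rep1$flags[["fold6_sig_group2"]])
  expect_false(rep1$flags[["fold4_sig_group1"]])
  expect_true(rep1$flags[["fold4_sig_group2"]])
  expect_true(rep1$flags[["fold4_group2_gt_group1"]])
  expect_false(rep1$flags[["rayleigh_sig_group1_fold6"]])
  expect_true(rep1$flags[["rayleigh_sig_group2_fold4"]])
  expect_true(rep1$correlations$significant[
    rep1$correlations$group == "blind"])

  # byte-identical output for identical input
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(rep1, d1)
  write_report(build_report(recs), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }

  expect_error(build_report(recs[recs$group == "blind", ]), "two groups")
})
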