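# minimal synthetic event table: n well-separated trials with given
# angles, run long enough for the responses to decay
toy_events <- function(angles, duration = 5, gap = 20) {
  n <- length(angles)
  onset <- 10 + (seq_len(n) - 1) * (duration + gap)
  rbind(
    data.frame(onset = onset, duration = duration,
               trial_type = "imagination", trial = seq_len(n),
               angle_deg = angles, target_number = NA,
               correct_side = NA),
    data.frame(onset = onset + duration, duration = 0.5,
               trial_type = "target", trial = seq_len(n),
               angle_deg = NA, target_number = 1, correct_side = "left"),
    data.frame(onset = onset + duration + 0.5, duration = 2,
               trial_type = "response", trial = seq_len(n),
               angle_deg = NA, target_number = NA, correct_side = NA))
}

test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf(tr_s = 1, microtime = 16)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  t_peak <- (which.max(h) - 1) / 16
  expect_gt(t_peak, 4)
  expect_lt(t_peak, 6)
  expect_lt(min(h), 0)   # undershoot
})

test_that("DCT high-pass basis has floor(2 T f) columns", {
  expect_equal(ncol(dct_basis(600, 1, 1 / 128)), 9)
  expect_equal(ncol(dct_basis(256, 1, 1 / 128)), 4)
  expect_error(dct_basis(100, 1, 0.6), "Nyquist")
})

test_that("design matrix modulators behave at degenerate angles", {
  ev <- toy_events(rep(0, 8))
  des <- build_design(ev, fold_n = 6, tr_s = 1, duration_s = 220)
  # all angles equal: sin modulator is identically zero, cos modulator
  # is constant and vanishes after centering
  expect_true(all(abs(des$X[, "mod_sin"]) < 1e-12))
  expect_true(all(abs(des$X[, "mod_cos"]) < 1e-12))

  ev2 <- toy_events(seq(15, 360, by = 45))
  des2 <- build_design(ev2, fold_n = 6, tr_s = 1, duration_s = 220,
                       reference_phase_deg = NULL)
  expect_true(all(c("mod_cos", "mod_sin") %in% colnames(des2$X)))
  # test model aligned with every trial: modulator constant 1 before
  # centering, hence zero after
  des3 <- build_design(toy_events(rep(30, 8)), fold_n = 6, tr_s = 1,
                       duration_s = 220, reference_phase_deg = 30)
  expect_true(all(abs(des3$X[, "mod_aligned"]) < 1e-12))

  expect_error(build_design(toy_events(0, duration = 500), fold_n = 6,
                            tr_s = 1, duration_s = 100),
               "outside")
})

test_that("OLS recovers exact coefficients and flags rank deficiency", {
  ev <- toy_events(seq(0, 315, by = 45))
  des <- build_design(ev, fold_n = 6, tr_s = 1, duration_s = 300)
  y <- des$X[, "imagination"]
  fit <- fit_ols(des, y)
  expect_equal(unname(fit$betas[1, "imagination"]), 1, tolerance = 1e-10)
  other <- setdiff(colnames(fit$betas), c("imagination"))
  expect_true(all(abs(fit$betas[1, other]) < 1e-8))
  expect_lt(fit$residual_variance[1], 1e-12)
  expect_equal(fit$dof, des$n_scans - fit$rank)

  # planted combination recovered exactly
  b_true <- c(2, 0.7, -0.4)
  y2 <- des$X[, "imagination"] * b_true[1] +
    des$X[, "mod_cos"] * b_true[2] + des$X[, "mod_sin"] * b_true[3]
  fit2 <- fit_ols(des, y2)
  expect_equal(unname(fit2$betas[1, c("imagination", "mod_cos",
                                      "mod_sin")]),
               b_true, tolerance = 1e-8)

  # duplicated column triggers the pseudo-inverse warning
  Xdup <- cbind(des$X, dup = des$X[, "imagination"])
  expect_warning(fit_ols(Xdup, y), "rank deficient")

  expect_error(fit_ols(des, y[-1]), "match")
})

test_that("pure-noise modulator betas are centred on zero", {
  ev <- toy_events(seq(0, 345, by = 15), gap = 8)
  des <- build_design(ev, fold_n = 6, tr_s = 1, duration_s = 320)
  set.seed(4)
  Y <- matrix(rnorm(400 * des$n_scans), 400)
  fit <- fit_ols(des, Y)
  for (m in c("mod_cos", "mod_sin")) {
    mb <- mean(fit$betas[, m])
    se <- sd(fit$betas[, m]) / sqrt(400)
    expect_lt(abs(mb), 4 * se)
  }
})

test_that("drift in the high-pass span leaves modulator betas alone", {
  ev <- toy_events(seq(0, 345, by = 15), gap = 8)
  des <- build_design(ev, fold_n = 6, tr_s = 1, duration_s = 320)
  set.seed(5)
  y <- rnorm(des$n_scans)
  f0 <- fit_ols(des, y)
  drift <- dct_basis(des$n_scans, 1, 1 / 128) %*% c(3, -2, 5, 1, 0.5)
  f1 <- fit_ols(des, y + drop(drift))
  for (m in c("mod_cos", "mod_sin")) {
    expect_lt(abs(f0$betas[1, m] - f1$betas[1, m]), 1e-8)
  }
})

test_that("fast-path design assembly equals the public builder", {
  s <- fix_session()
  run <- s$runs[[1]]
  tpl <- fix_templates()[[1]]
  X_fast <- gridclock:::glm1_design(tpl, 6)
  des <- build_design(run_events(run), fold_n = 6, tr_s = 1,
                      duration_s = run$duration_s)
  shared <- intersect(colnames(X_fast), colnames(des$X))
  expect_true(all(c("imagination", "mod_cos", "mod_sin", "cues",
                    "target_response", "intercept") %in% shared))
  expect_equal(X_fast[, shared], des$X[, shared], tolerance = 1e-12)

  # GLM-2 column is the exact linear combination of the quadrature pair
  phi <- 17.3
  X2 <- gridclock:::glm2_design(tpl, 6, phi)
  combo <- cos(6 * phi * pi / 180) * X_fast[, "mod_cos"] +
    sin(6 * phi * pi / 180) * X_fast[, "mod_sin"]
  expect_equal(unname(X2[, "mod_aligned"]), unname(combo),
               tolerance = 1e-10)
})
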