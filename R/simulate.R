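#' Directional tuning model for one voxel or ROI
#'
#' Neural amplitude during an imagination period with movement direction
#' `theta` is `baseline * (1 + gain * cos(fold_n * (theta - phase)))`:
#' an n-fold sinusoidal modulation with subject-specific orientation
#' `phase` (the grid orientation) and modulation depth `gain`.
#'
#' @param fold_n Rotational symmetry, one of 4..8.
#' @param phase_deg Orientation in degrees, reduced to the fundamental
#'   domain `[0, 360 / fold_n)`.
#' @param gain Modulation depth (>= 0, typically a few percent).
#' @param baseline Response amplitude in signal units.
#' @return An object of class `tuning_model`.
#' @export
tuning_model <- function(fold_n = 6L, phase_deg = 0, gain = 0.03,
                         baseline = 100) {
  stopifnot(fold_n %in% 4:8, gain >= 0, baseline >= 0)
  structure(list(fold_n = as.integer(fold_n),
                 phase_deg = phase_deg %% (360 / fold_n),
                 gain = gain, baseline = baseline),
            class = "tuning_model")
}

#' Noise model for simulated BOLD
#'
#' Voxel-private AR(1) Gaussian noise (innovation SD `sigma`,
#' stationary) plus an ROI-wide AR(1) component shared by every voxel
#' (innovation SD `sigma_shared`), plus slow drift built from the
#' leading discrete-cosine components with random per-voxel
#' coefficients scaled by `drift_amplitudes`.  The shared component is
#' what limits how much ROI averaging can improve a subject's estimate:
#' it absorbs the spatially correlated physiological and session-level
#' variance that an independent-voxel model would otherwise average
#' away, and it sets per-subject beta uncertainties to a realistic
#' fraction of the group mean.
#'
#' @param sigma Private innovation standard deviation in signal units.
#' @param ar1_rho Lag-1 autoregression coefficient, |rho| < 1 (shared
#'   by both components).
#' @param sigma_shared ROI-wide innovation standard deviation.
#' @param drift_amplitudes Per-component drift SDs (may be empty).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 10, ar1_rho = 0.3, sigma_shared = 30,
                        drift_amplitudes = c(30, 20, 10)) {
  stopifnot(sigma >= 0, sigma_shared >= 0, abs(ar1_rho) < 1)
  structure(list(sigma = sigma, ar1_rho = ar1_rho,
                 sigma_shared = sigma_shared,
                 drift_amplitudes = drift_amplitudes),
            class = "noise_model")
}

#' Simulation configuration
#'
#' @param tr_s Repetition time in seconds.
#' @param n_voxels ROI size (default 110, the scale of an entorhinal
#'   mask at 3 mm resolution).
#' @param phase_jitter_kappa Von Mises concentration of voxel phases
#'   around the ROI phase, in fold-space (`Inf` = no jitter).
#' @param gain_sdlog Log-normal SD of voxelwise modulation depth.
#' @param event_response_amplitude Response amplitude for auditory cue,
#'   target, response and jump events, in signal units.
#' @param microtime Microtime bins per TR for HRF convolution.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(tr_s = 1, n_voxels = 110L, phase_jitter_kappa = 8,
                       gain_sdlog = 0.3, event_response_amplitude = 2,
                       microtime = 16L) {
  stopifnot(tr_s > 0, n_voxels >= 1)
  structure(list(tr_s = tr_s, n_voxels = as.integer(n_voxels),
                 phase_jitter_kappa = phase_jitter_kappa,
                 gain_sdlog = gain_sdlog,
                 event_response_amplitude = event_response_amplitude,
                 microtime = as.integer(microtime)),
            class = "sim_config")
}

#' Von Mises random angles
#'
#' Best--Fisher rejection sampler; returns radians in (mu - pi, mu + pi].
#' `kappa = Inf` collapses to the mean, `kappa = 0` to uniform.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration (>= 0).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (is.infinite(kappa)) return(rep(mu, n))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(stats::runif(1) - 0.5) * acos(f) + mu
    }
  }
  out
}

# Per-run convolution template shared by simulation and analysis:
# one convolved boxcar per imagination period, a combined event response
# column, the fold-independent design columns, and the trial angles.
run_template <- function(events, duration_s, tr_s = 1,
                         highpass_cutoff_hz = 1 / 128, nuisance = NULL,
                         microtime = 16L) {
  n_scans <- as.integer(ceiling(duration_s / tr_s))
  hrf <- canonical_hrf(tr_s, microtime)
  conv <- function(u) convolve_sample(u, hrf, n_scans, microtime, tr_s / microtime)
  imag <- events[events$trial_type == "imagination", , drop = FALSE]
  trial_conv <- sapply(seq_len(nrow(imag)), function(i) {
    conv(boxcar_u(imag$onset[i], imag$duration[i], n_scans, tr_s,
                  microtime))
  })
  oth <- events[events$trial_type %in%
                  c("start_cue", "end_cue", "target", "response", "jump"),
                , drop = FALSE]
  event_conv <- conv(boxcar_u(oth$onset, oth$duration, n_scans, tr_s,
                              microtime))
  # fold-independent analysis columns (nuisance + drift + intercept)
  cu <- events[events$trial_type %in% c("start_cue", "end_cue"), ,
               drop = FALSE]
  tg <- events[events$trial_type == "target", , drop = FALSE]
  rs <- events[events$trial_type == "response", , drop = FALSE]
  jp <- events[events$trial_type == "jump", , drop = FALSE]
  xe <- list()
  if (nrow(cu) > 0) {
    xe$cues <- conv(boxcar_u(cu$onset, cu$duration, n_scans, tr_s,
                             microtime))
  }
  if (nrow(tg) > 0) {
    xe$target_response <- conv(boxcar_u(
      tg$onset, rs$onset + rs$duration - tg$onset, n_scans, tr_s,
      microtime))
  }
  if (nrow(jp) > 0) {
    xe$jump <- conv(boxcar_u(jp$onset, jp$duration, n_scans, tr_s,
                             microtime))
  }
  Xextra <- do.call(cbind, xe)
  colnames(Xextra) <- names(xe)
  D <- dct_basis(n_scans, tr_s, highpass_cutoff_hz)
  if (ncol(D) > 0) colnames(D) <- paste0("dct_", seq_len(ncol(D)))
  Xextra <- cbind(Xextra, D, intercept = 1)
  if (!is.null(nuisance) && ncol(as.matrix(nuisance)) > 0) {
    nz <- as.matrix(nuisance)
    nz <- nz[, apply(nz, 2, function(z) any(z != 0)), drop = FALSE]
    if (ncol(nz) > 0) Xextra <- cbind(Xextra, nz)
  }
  list(n_scans = n_scans, tr_s = tr_s, trial_conv = trial_conv,
       angle_deg = imag$angle_deg, event_conv = event_conv,
       Xextra = Xextra, dct = D)
}

# Templates for all runs of a session (reused across simulated subjects).
session_templates <- function(session, tr_s = 1,
                              highpass_cutoff_hz = 1 / 128,
                              microtime = 16L) {
  lapply(session$runs, function(run) {
    run_template(run_events(run), run$duration_s, tr_s,
                 highpass_cutoff_hz, NULL, microtime)
  })
}

# Stationary AR(1) noise, one column per voxel.
ar1_noise <- function(n_scans, n_voxels, sigma, rho) {
  if (sigma == 0) return(matrix(0, n_voxels, n_scans))
  e <- matrix(stats::rnorm(n_scans * n_voxels, 0, sigma), n_scans,
              n_voxels)
  if (rho != 0) {
    init <- stats::rnorm(n_voxels, 0, sigma / sqrt(1 - rho^2))
    e <- apply(rbind(init * rho, e), 2, function(z) {
      stats::filter(z[-1], rho, method = "recursive",
                    init = z[1] / rho)
    })
  }
  t(e)
}

#' Simulate one voxel's BOLD time series for a run
#'
#' The neural signal is a boxcar over each imagination period with
#' amplitude `baseline * (1 + gain * cos(fold_n * (theta_t - phase)))`,
#' plus fixed-amplitude boxcars for cue/target/response/jump events, all
#' convolved with the canonical HRF; low-frequency cosine drift and
#' stationary AR(1) Gaussian noise are added.
#'
#' @param run A `run_design` (or a template from internal machinery).
#' @param tuning A [tuning_model()].
#' @param noise A [noise_model()].
#' @param config A [sim_config()].
#' @return Numeric vector of length `ceiling(duration / tr_s)`.
#' @export
simulate_voxel_timeseries <- function(run, tuning, noise,
                                      config = sim_config()) {
  tpl <- if (inherits(run, "run_design")) {
    run_template(run_events(run), run$duration_s, config$tr_s,
                 microtime = config$microtime)
  } else run
  th <- tpl$angle_deg * pi / 180
  phi <- tuning$phase_deg * pi / 180
  amp <- tuning$baseline *
    (1 + tuning$gain * cos(tuning$fold_n * (th - phi)))
  y <- drop(tpl$trial_conv %*% amp) +
    config$event_response_amplitude * tpl$event_conv
  nd <- length(noise$drift_amplitudes)
  if (nd > 0) {
    nd <- min(nd, ncol(tpl$dct))
    if (nd > 0) {
      y <- y + drop(tpl$dct[, seq_len(nd), drop = FALSE] %*%
                      (noise$drift_amplitudes[seq_len(nd)] *
                         stats::rnorm(nd)))
    }
  }
  y <- y + drop(ar1_noise(tpl$n_scans, 1, noise$sigma, noise$ar1_rho))
  if (!is.null(noise$sigma_shared) && noise$sigma_shared > 0) {
    y <- y + drop(ar1_noise(tpl$n_scans, 1, noise$sigma_shared,
                            noise$ar1_rho))
  }
  y
}

#' Group-condition specification for subject simulation
#'
#' Bundles the tuning, noise and behavioural parameters defining a
#' simulated participant.  Defaults give a 6-fold subject at moderate
#' signal-to-noise (modulation amplitude / innovation SD = 0.3).
#'
#' @param fold_n Planted symmetry (4..8).
#' @param roi_phase_deg ROI grid orientation; `NULL` draws it uniformly
#'   over the fundamental domain.
#' @param gain,baseline Tuning parameters, see [tuning_model()].
#' @param gain_between_sdlog Log-normal SD of the subject-level
#'   modulation depth around `gain` (between-subject heterogeneity;
#'   0.8 puts group-level effect sizes in the range reported for
#'   entorhinal grid-like signals, Cohen's d around 1).
#' @param noise A [noise_model()].
#' @param config A [sim_config()].
#' @param p_correct Probability of a correct left/right response.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(fold_n = 6L, roi_phase_deg = NULL, gain = 0.03,
                       baseline = 100, gain_between_sdlog = 0.8,
                       noise = noise_model(), config = sim_config(),
                       p_correct = 0.92) {
  structure(list(fold_n = as.integer(fold_n),
                 roi_phase_deg = roi_phase_deg, gain = gain,
                 baseline = baseline,
                 gain_between_sdlog = gain_between_sdlog,
                 noise = noise, config = config,
                 p_correct = p_correct),
            class = "group_spec")
}

# draw one subject-level modulation depth around the group mean
draw_subject_gain <- function(spec) {
  s <- spec$gain_between_sdlog
  if (is.null(s) || s == 0 || spec$gain == 0) return(spec$gain)
  spec$gain * stats::rlnorm(1, -s^2 / 2, s)
}

#' Simulate a complete subject
#'
#' Draws voxelwise grid phases around the ROI phase (von Mises in
#' fold-space), voxelwise modulation depths (log-normal around `gain`),
#' generates all eight runs of voxel-by-time data, and simulates
#' behavioural left/right responses.
#'
#' @param session A [build_session()] result.
#' @param spec A [group_spec()].
#' @param seed Integer seed; the subject is deterministic given it.
#' @param templates Precomputed [session] templates (internal reuse).
#' @return An object of class `simulated_subject`: `runs` (each with
#'   `Y`, `events`, `nuisance`, `duration_s`, `tr_s`), `truth`,
#'   `behavior`, `session`.
#' @export
simulate_subject <- function(session, spec = group_spec(), seed = 1L,
                             templates = NULL) {
  cfg <- spec$config
  if (is.null(templates)) templates <- session_templates(session, cfg$tr_s)
  with_seed(seed, {
    nv <- cfg$n_voxels
    fd <- 360 / spec$fold_n
    roi_phase <- if (is.null(spec$roi_phase_deg)) {
      stats::runif(1, 0, fd)
    } else spec$roi_phase_deg %% fd
    jit <- rvonmises(nv, 0, cfg$phase_jitter_kappa) / spec$fold_n *
      180 / pi
    vox_phase <- (roi_phase + jit) %% fd
    vox_gain <- if (spec$gain > 0 && cfg$gain_sdlog > 0) {
      spec$gain * stats::rlnorm(nv, -cfg$gain_sdlog^2 / 2, cfg$gain_sdlog)
    } else rep(spec$gain, nv)

    runs <- vector("list", length(templates))
    for (r in seq_along(templates)) {
      tpl <- templates[[r]]
      th <- tpl$angle_deg * pi / 180
      # amplitude of every (trial, voxel) imagination response
      M <- cos(spec$fold_n * outer(th, vox_phase * pi / 180, "-"))
      amp <- spec$baseline * (1 + M * rep(vox_gain, each = nrow(M)))
      Y <- t(tpl$trial_conv %*% amp) + cfg$event_response_amplitude *
        matrix(tpl$event_conv, nv, tpl$n_scans, byrow = TRUE)
      nd <- min(length(spec$noise$drift_amplitudes), ncol(tpl$dct))
      if (nd > 0) {
        co <- matrix(stats::rnorm(nd * nv), nd, nv) *
          spec$noise$drift_amplitudes[seq_len(nd)]
        Y <- Y + t(tpl$dct[, seq_len(nd), drop = FALSE] %*% co)
      }
      Y <- Y + ar1_noise(tpl$n_scans, nv, spec$noise$sigma,
                         spec$noise$ar1_rho)
      if (!is.null(spec$noise$sigma_shared) &&
          spec$noise$sigma_shared > 0) {
        sh <- drop(ar1_noise(tpl$n_scans, 1, spec$noise$sigma_shared,
                             spec$noise$ar1_rho))
        Y <- Y + matrix(sh, nv, tpl$n_scans, byrow = TRUE)
      }
      runs[[r]] <- list(Y = Y, events = run_events(session$runs[[r]]),
                        nuisance = NULL,
                        duration_s = session$runs[[r]]$duration_s,
                        tr_s = cfg$tr_s)
    }

    beh <- do.call(rbind, lapply(seq_along(session$runs), function(r) {
      tr <- session$runs[[r]]$trials
      n <- nrow(tr)
      data.frame(run = r, trial = seq_len(n),
                 correct = stats::runif(n) < spec$p_correct,
                 rt_s = stats::runif(n, 0.5, 2.0))
    }))

    structure(list(session = session, runs = runs,
                   truth = list(fold_n = spec$fold_n,
                                roi_phase_deg = roi_phase,
                                voxel_phase_deg = vox_phase,
                                voxel_gain = vox_gain),
                   behavior = beh),
              class = "simulated_subject")
  })
}

#' Simulate a group of subjects
#'
#' ROI grid phases are drawn uniformly over the fundamental domain or
#' von Mises-clustered around a mean orientation, emulating the contrast
#' between unclustered 6-fold coding and environment-anchored 4-fold
#' coding.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param fold_n Planted symmetry.
#' @param phase_distribution `"uniform"` or `"clustered"`.
#' @param phase_mean_deg,phase_kappa Mean orientation and fold-space
#'   concentration for the clustered case.
#' @param seed Integer seed.
#' @param session Session design shared by all subjects (a fresh one is
#'   built from `seed` when `NULL`).
#' @param spec Base [group_spec()]; its `fold_n` and phase are
#'   overridden per subject.
#' @return List of `simulated_subject` objects.
#' @export
simulate_group <- function(n_subjects, fold_n = 6L,
                           phase_distribution = c("uniform", "clustered"),
                           phase_mean_deg = 0, phase_kappa = 8,
                           seed = 1L, session = NULL,
                           spec = group_spec()) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  phase_distribution <- match.arg(phase_distribution)
  if (is.null(session)) session <- build_session(seed)
  templates <- session_templates(session, spec$config$tr_s)
  fd <- 360 / fold_n
  with_seed(seed + 1L, {
    phases <- if (phase_distribution == "uniform") {
      stats::runif(n_subjects, 0, fd)
    } else {
      (phase_mean_deg +
         rvonmises(n_subjects, 0, phase_kappa) / fold_n * 180 / pi) %% fd
    }
    seeds <- sample.int(2^30, n_subjects)
    gains <- vapply(seq_len(n_subjects), function(i) {
      draw_subject_gain(spec)
    }, numeric(1))
    lapply(seq_len(n_subjects), function(i) {
      si <- spec
      si$fold_n <- as.integer(fold_n)
      si$roi_phase_deg <- phases[i]
      si$gain <- gains[i]
      simulate_subject(session, si, seed = seeds[i],
                       templates = templates)
    })
  })
}
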