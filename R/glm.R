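#' Canonical double-gamma haemodynamic response function
#'
#' The standard two-gamma HRF (response peak near 5 s, undershoot near
#' 16 s, peak:undershoot ratio 6, 32 s support), evaluated on a microtime
#' grid of `microtime` bins per TR and normalised to unit peak.
#'
#' @param tr_s Repetition time in seconds.
#' @param microtime Microtime bins per TR used for convolution.
#' @param length_s Kernel support in seconds.
#' @return Numeric vector sampled at `tr_s / microtime` resolution,
#'   starting at t = 0 (where the kernel is exactly zero).
#' @export
canonical_hrf <- function(tr_s = 1, microtime = 16L, length_s = 32) {
  stopifnot(tr_s > 0, microtime >= 1)
  dt <- tr_s / microtime
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

#' Discrete cosine high-pass basis
#'
#' The slow-drift basis used for high-pass filtering: cosines
#' `cos(pi * k * (2t + 1) / (2N))` for `k = 1 .. floor(2 * T * cutoff)`,
#' where `T` is run duration in seconds and `N` the number of volumes.
#'
#' @param n_scans Number of volumes.
#' @param tr_s Repetition time in seconds.
#' @param cutoff_hz High-pass cutoff frequency (e.g. 1/128).
#' @return Matrix `n_scans x K` (zero columns when the run is too short).
#' @export
dct_basis <- function(n_scans, tr_s, cutoff_hz) {
  stopifnot(n_scans >= 1, tr_s > 0, cutoff_hz > 0)
  if (cutoff_hz >= 1 / (2 * tr_s)) {
    stop("high-pass cutoff at or above Nyquist")
  }
  K <- floor(2 * n_scans * tr_s * cutoff_hz)
  if (K < 1) return(matrix(0, n_scans, 0))
  t <- seq_len(n_scans) - 1
  sapply(seq_len(K), function(k) cos(pi * k * (2 * t + 1) / (2 * n_scans)))
}

# Convolve a microtime-resolution stick/boxcar vector with the HRF and
# sample at the TR grid (slice-time midpoint, bin microtime/2).  The
# sum is scaled by the microtime step so it discretises the continuous
# convolution: a sustained unit boxcar then peaks near the HRF integral
# regardless of the microtime resolution.
convolve_sample <- function(u, hrf, n_scans, microtime, dt) {
  v <- stats::convolve(u, rev(hrf), type = "open")[seq_along(u)] * dt
  idx <- (seq_len(n_scans) - 1L) * microtime + microtime %/% 2L + 1L
  v[pmin(idx, length(v))]
}

# Microtime boxcar for (onset, duration) pairs within a run.
boxcar_u <- function(onset, duration, n_scans, tr_s, microtime,
                     weight = NULL) {
  n_u <- n_scans * microtime
  dt <- tr_s / microtime
  u <- numeric(n_u)
  if (is.null(weight)) weight <- rep(1, length(onset))
  for (i in seq_along(onset)) {
    a <- floor(onset[i] / dt) + 1L
    b <- min(n_u, ceiling((onset[i] + duration[i]) / dt))
    if (a <= n_u && b >= a) u[a:b] <- u[a:b] + weight[i]
  }
  u
}

#' Build a run-level GLM design matrix
#'
#' Constructs the design used for grid-like-coding estimation: an
#' imagination-period boxcar; two parametric modulators `cos(n * theta)`
#' and `sin(n * theta)` (estimation model) or a single realigned cosine
#' `cos(n * (theta - phi))` (test model, when `reference_phase_deg` is
#' given), mean-centred across trials before convolution; nuisance
#' boxcars for jump cues and the target-to-response period; a discrete
#' cosine high-pass basis; an intercept; and any user-supplied nuisance
#' columns (e.g. motion parameters).
#'
#' @param events Event data frame as produced by [run_events()] (columns
#'   `onset`, `duration`, `trial_type`, `angle_deg`).
#' @param fold_n Rotational symmetry factor n (4..8 in practice).
#' @param tr_s Repetition time in seconds.
#' @param duration_s Run duration in seconds.
#' @param highpass_cutoff_hz High-pass cutoff (default 1/128 Hz).
#' @param nuisance Optional numeric matrix of extra regressors
#'   (`n_scans` rows).
#' @param reference_phase_deg Optional grid orientation phi in degrees;
#'   when supplied the design carries the single test modulator.
#' @param microtime Microtime bins per TR.
#' @return An object of class `glm_design`: list with `X` (named
#'   matrix), `modulators` (column names of the modulator regressors),
#'   `n_scans`, `tr_s`.
#' @export
build_design <- function(events, fold_n = 6L, tr_s = 1, duration_s,
                         highpass_cutoff_hz = 1 / 128, nuisance = NULL,
                         reference_phase_deg = NULL, microtime = 16L) {
  n_scans <- as.integer(ceiling(duration_s / tr_s))
  if (any(events$onset < 0) ||
      any(events$onset + events$duration > duration_s + 1e-9)) {
    stop("events fall outside the run")
  }
  hrf <- canonical_hrf(tr_s, microtime)
  conv <- function(u) convolve_sample(u, hrf, n_scans, microtime, tr_s / microtime)

  imag <- events[events$trial_type == "imagination", , drop = FALSE]
  stopifnot(nrow(imag) > 0, !any(is.na(imag$angle_deg)))
  cols <- list()
  cols$imagination <- conv(boxcar_u(imag$onset, imag$duration,
                                    n_scans, tr_s, microtime))

  th <- imag$angle_deg * pi / 180
  center <- function(x) x - mean(x)
  modbox <- function(w) conv(boxcar_u(imag$onset, imag$duration, n_scans,
                                      tr_s, microtime, weight = w))
  if (is.null(reference_phase_deg)) {
    cols$mod_cos <- modbox(center(cos(fold_n * th)))
    cols$mod_sin <- modbox(center(sin(fold_n * th)))
    modulators <- c("mod_cos", "mod_sin")
  } else {
    phi <- reference_phase_deg * pi / 180
    cols$mod_aligned <- modbox(center(cos(fold_n * (th - phi))))
    modulators <- "mod_aligned"
  }

  cu <- events[events$trial_type %in% c("start_cue", "end_cue"), ,
               drop = FALSE]
  if (nrow(cu) > 0) {
    cols$cues <- conv(boxcar_u(cu$onset, cu$duration, n_scans, tr_s,
                               microtime))
  }
  tg <- events[events$trial_type == "target", , drop = FALSE]
  rs <- events[events$trial_type == "response", , drop = FALSE]
  if (nrow(tg) > 0) {
    # target onset through end of the response period
    dur <- if (nrow(rs) == nrow(tg)) {
      rs$onset + rs$duration - tg$onset
    } else {
      tg$duration + 2.5
    }
    cols$target_response <- conv(boxcar_u(tg$onset, dur, n_scans, tr_s,
                                          microtime))
  }
  jp <- events[events$trial_type == "jump", , drop = FALSE]
  if (nrow(jp) > 0) {
    cols$jump <- conv(boxcar_u(jp$onset, jp$duration, n_scans, tr_s,
                               microtime))
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  D <- dct_basis(n_scans, tr_s, highpass_cutoff_hz)
  if (ncol(D) > 0) colnames(D) <- paste0("dct_", seq_len(ncol(D)))
  X <- cbind(X, D, intercept = 1)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_scans) stop("nuisance rows != n_scans")
    keep <- apply(nuisance, 2, function(z) any(z != 0))
    if (any(keep)) {
      nm <- colnames(nuisance)
      if (is.null(nm)) nm <- paste0("nuis_", seq_len(ncol(nuisance)))
      nuisance <- nuisance[, keep, drop = FALSE]
      colnames(nuisance) <- nm[keep]
      X <- cbind(X, nuisance)
    }
  }
  structure(list(X = X, modulators = modulators, n_scans = n_scans,
                 tr_s = tr_s),
            class = "glm_design")
}

# Moore-Penrose pseudo-inverse via SVD.
pinv <- function(X, tol = 1e-10) {
  s <- svd(X)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Fit ordinary least squares per voxel
#'
#' @param design A `glm_design` from [build_design()] (or a plain
#'   matrix).
#' @param timeseries Voxel-by-time matrix (or a vector for one voxel).
#' @return An object of class `glm_fit`: `betas` (voxels x columns),
#'   `residual_variance` (per voxel, unbiased), `dof`, `rank`.
#' @export
fit_ols <- function(design, timeseries) {
  X <- if (inherits(design, "glm_design")) design$X else as.matrix(design)
  if (is.vector(timeseries)) timeseries <- matrix(timeseries, nrow = 1)
  Y <- t(timeseries)                      # time x voxels
  if (nrow(Y) != nrow(X)) stop("time points do not match the design")
  r <- qr(X)$rank
  if (r < ncol(X)) {
    warning("design matrix is rank deficient; using pseudo-inverse")
  }
  Xp <- pinv(X)
  B <- Xp %*% Y                           # columns x voxels
  res <- Y - X %*% B
  dof <- nrow(X) - r
  rv <- if (dof > 0) colSums(res^2) / dof else rep(NA_real_, ncol(Y))
  betas <- t(B)
  colnames(betas) <- colnames(X)
  structure(list(betas = betas, residual_variance = rv, dof = dof,
                 rank = r),
            class = "glm_fit")
}
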