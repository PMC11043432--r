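#' Voxelwise grid orientation from quadrature betas
#'
#' Converts the cosine and sine modulator betas into an orientation in
#' the fundamental domain `[0, 360/n)`, using the full-quadrant
#' `atan2(beta2, beta1) / n` (a plain arctangent would conflate
#' `(b1, b2)` with `(-b1, -b2)` and corrupt the weighted mean).
#'
#' @param beta1,beta2 Cosine and sine modulator betas (vectorised).
#' @param fold Symmetry factor n.
#' @return Orientation(s) in degrees in `[0, 360/fold)`.
#' @export
voxel_orientation <- function(beta1, beta2, fold = 6L) {
  if (any(beta1 == 0 & beta2 == 0)) {
    stop("orientation undefined when both betas are zero")
  }
  (atan2(beta2, beta1) * 180 / pi / fold) %% (360 / fold)
}

#' Voxelwise response amplitude
#'
#' Euclidean norm of the quadrature betas, `sqrt(beta1^2 + beta2^2)`;
#' used as the weight of the voxel in the ROI orientation mean.
#'
#' @inheritParams voxel_orientation
#' @export
voxel_amplitude <- function(beta1, beta2) {
  sqrt(beta1^2 + beta2^2)
}

#' Amplitude-weighted ROI orientation
#'
#' Weighted circular mean of voxel orientations computed in fold-space:
#' `atan2(sum(w * sin(n * phi)), sum(w * cos(n * phi))) / n`.  With
#' weights equal to the voxel amplitudes this is algebraically the
#' orientation of the summed beta vectors.
#'
#' @param phi_deg Voxel orientations in degrees.
#' @param weight Nonnegative voxel weights (amplitudes).
#' @param fold Symmetry factor n.
#' @return ROI orientation in degrees in `[0, 360/fold)`.
#' @export
roi_orientation <- function(phi_deg, weight, fold = 6L) {
  stopifnot(length(phi_deg) == length(weight))
  if (any(weight < 0)) stop("weights must be nonnegative")
  if (all(weight == 0)) stop("all weights are zero")
  a <- fold * phi_deg * pi / 180
  (atan2(sum(weight * sin(a)), sum(weight * cos(a))) * 180 / pi / fold) %%
    (360 / fold)
}

#' Four-fold cross-validation partition
#'
#' The eight runs are grouped into four held-out pairs, each combining a
#' forward and a backward run (runs 1+2, 3+4, 5+6, 7+8 under the
#' interleaved session layout).
#'
#' @return List of four integer pairs.
#' @export
cv_partition <- function() {
  list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(7L, 8L))
}

# Fold-independent per-run analysis cache (convolved trial regressors
# and non-modulator design columns) for a list of subject runs.
analysis_cache <- function(runs, highpass_cutoff_hz = 1 / 128,
                           microtime = 16L) {
  lapply(runs, function(run) {
    run_template(run$events, run$duration_s, run$tr_s,
                 highpass_cutoff_hz, run$nuisance, microtime)
  })
}

# GLM-1 design (cos/sin quadrature) for one cached run.
glm1_design <- function(tpl, fold) {
  th <- tpl$angle_deg * pi / 180
  cbind(imagination = drop(tpl$trial_conv %*% rep(1, length(th))),
        mod_cos = drop(tpl$trial_conv %*%
                         (cos(fold * th) - mean(cos(fold * th)))),
        mod_sin = drop(tpl$trial_conv %*%
                         (sin(fold * th) - mean(sin(fold * th)))),
        tpl$Xextra)
}

# Attach per-fold GLM-1 pseudo-inverses to a cache so that repeated
# cross-validation calls (many subjects sharing one session design) skip
# the decomposition.  Returns the augmented cache.
precompute_glm1 <- function(cache, folds) {
  lapply(cache, function(tpl) {
    if (is.null(tpl$glm1)) tpl$glm1 <- list()
    for (fold in folds) {
      key <- paste0("f", fold)
      X1 <- glm1_design(tpl, fold)
      tpl$glm1[[key]] <- list(X = X1, P = pinv(X1))
    }
    tpl
  })
}

# GLM-2 design (single realigned cosine) for one cached run.
glm2_design <- function(tpl, fold, phi_deg) {
  th <- tpl$angle_deg * pi / 180
  w <- cos(fold * (th - phi_deg * pi / 180))
  cbind(imagination = drop(tpl$trial_conv %*% rep(1, length(th))),
        mod_aligned = drop(tpl$trial_conv %*% (w - mean(w))),
        tpl$Xextra)
}

#' Cross-validated n-fold symmetry estimate
#'
#' The quadrature-filter estimator with four-way cross-validation: for
#' each iteration, the cosine/sine modulator betas are estimated per
#' voxel on six runs (per-run fits averaged), the ROI orientation `phi`
#' is their amplitude-weighted circular mean, and a test model with the
#' single regressor `cos(n * (theta - phi))` is fitted on the held-out
#' forward/backward pair; the held-out modulator beta, averaged over ROI
#' voxels and runs, is that iteration's test statistic.  The symmetry
#' magnitude `fold_beta` is the mean over the four iterations.
#'
#' @param runs List of eight runs, each a list with `Y` (voxel x time
#'   matrix), `events`, `nuisance`, `duration_s`, `tr_s` (a
#'   `simulated_subject$runs` works directly).
#' @param roi Integer vector of voxel indices (default: all voxels).
#' @param fold Symmetry factor n.
#' @param partition A [cv_partition()].
#' @param highpass_cutoff_hz High-pass cutoff (default 1/128 Hz).
#' @param profile Logical: also compute the 12-bin aligned/misaligned
#'   profile on the held-out runs.
#' @param cache Internal: precomputed [analysis_cache()].
#' @return An object of class `grid_estimate`: `fold`, `fold_beta`,
#'   `test_betas` (4), `per_fold_phis` (4), `aligned_profile` (12 bin
#'   means or `NULL`).
#' @export
crossval_symmetry <- function(runs, roi = NULL, fold = 6L,
                              partition = cv_partition(),
                              highpass_cutoff_hz = 1 / 128,
                              profile = FALSE, cache = NULL) {
  if (inherits(runs, "simulated_subject")) runs <- runs$runs
  if (length(runs) != 8) stop("eight runs are required")
  held <- sort(unlist(partition))
  if (!identical(held, 1:8)) stop("partition must cover all eight runs")
  if (is.null(cache)) cache <- analysis_cache(runs, highpass_cutoff_hz)
  nv <- nrow(runs[[1]]$Y)
  if (is.null(roi)) roi <- seq_len(nv)

  # per-run quadrature betas (estimated once, reused across iterations)
  key <- paste0("f", fold)
  b1 <- b2 <- matrix(NA_real_, length(roi), 8)
  for (r in 1:8) {
    g1 <- cache[[r]]$glm1[[key]]
    if (is.null(g1)) {
      X1 <- glm1_design(cache[[r]], fold)
      g1 <- list(X = X1, P = pinv(X1))
    }
    B <- g1$P %*% t(runs[[r]]$Y[roi, , drop = FALSE])
    rownames(B) <- colnames(g1$X)
    b1[, r] <- B["mod_cos", ]
    b2[, r] <- B["mod_sin", ]
  }

  n_iter <- length(partition)
  phis <- test_betas <- numeric(n_iter)
  prof <- if (profile) matrix(NA_real_, n_iter, 12) else NULL
  for (k in seq_len(n_iter)) {
    test_runs <- partition[[k]]
    train_runs <- setdiff(1:8, test_runs)
    mb1 <- rowMeans(b1[, train_runs, drop = FALSE])
    mb2 <- rowMeans(b2[, train_runs, drop = FALSE])
    phi <- roi_orientation(voxel_orientation(mb1, mb2, fold),
                           voxel_amplitude(mb1, mb2), fold)
    phis[k] <- phi
    tb <- vapply(test_runs, function(r) {
      fit <- fit_ols(glm2_design(cache[[r]], fold, phi),
                     runs[[r]]$Y[roi, , drop = FALSE])
      mean(fit$betas[, "mod_aligned"])
    }, numeric(1))
    test_betas[k] <- mean(tb)
    if (profile) {
      prof[k, ] <- colMeans(do.call(rbind, lapply(test_runs, function(r) {
        bin_profile_run(cache[[r]], runs[[r]]$Y[roi, , drop = FALSE],
                        phi, fold = 6L)
      })), na.rm = TRUE)
    }
  }
  structure(list(fold = as.integer(fold), fold_beta = mean(test_betas),
                 test_betas = test_betas, per_fold_phis = phis,
                 aligned_profile = if (profile) colMeans(prof,
                                                         na.rm = TRUE)),
            class = "grid_estimate")
}

#' @export
print.grid_estimate <- function(x, ...) {
  cat(sprintf("<grid_estimate> %d-fold: beta = %.4g (phis: %s)\n",
              x$fold, x$fold_beta,
              paste(sprintf("%.1f", x$per_fold_phis), collapse = ", ")))
  invisible(x)
}

# Held-out 12-bin directional profile for one run: trials are binned by
# (theta - phi) mod 360 into 30-degree bins centred on 0, 30, ..., 330;
# one convolved regressor per bin, fitted jointly with the nuisance
# columns.  Returns the 12 bin betas averaged over ROI voxels (NA for
# empty bins).
bin_profile_run <- function(tpl, Y, phi_deg, fold = 6L) {
  delta <- (tpl$angle_deg - phi_deg) %% 360
  bin <- (floor((delta + 15) / 30) %% 12) + 1L
  M <- matrix(0, length(bin), 12)
  M[cbind(seq_along(bin), bin)] <- 1
  B <- tpl$trial_conv %*% M
  colnames(B) <- paste0("bin_", 1:12)
  nonempty <- colSums(M) > 0
  X <- cbind(B[, nonempty, drop = FALSE], tpl$Xextra)
  fit <- fit_ols(X, Y)
  out <- rep(NA_real_, 12)
  out[nonempty] <- colMeans(
    fit$betas[, colnames(B)[nonempty], drop = FALSE])
  out
}

#' Aligned/misaligned directional profile
#'
#' Bins the held-out trials by their angle relative to an independently
#' estimated grid orientation `phi` into twelve contiguous 30-degree
#' bins and returns the bin regressor betas (averaged over runs and ROI
#' voxels).  For 6-fold coding the aligned bins are those centred on
#' multiples of 60 degrees (odd bin indices).
#'
#' @param runs List of runs as in [crossval_symmetry()].
#' @param roi Voxel indices (default: all).
#' @param phi_deg Grid orientation estimated from independent data.
#' @param fold Symmetry factor (alignment definition; default 6).
#' @param highpass_cutoff_hz High-pass cutoff.
#' @return Numeric vector of 12 bin means, names `bin_0` ... `bin_330`;
#'   attribute `aligned` marks the aligned bins.
#' @export
aligned_profile <- function(runs, roi = NULL, phi_deg, fold = 6L,
                            highpass_cutoff_hz = 1 / 128) {
  cache <- analysis_cache(runs, highpass_cutoff_hz)
  nv <- nrow(runs[[1]]$Y)
  if (is.null(roi)) roi <- seq_len(nv)
  prof <- colMeans(do.call(rbind, lapply(seq_along(runs), function(r) {
    bin_profile_run(cache[[r]], runs[[r]]$Y[roi, , drop = FALSE],
                    phi_deg, fold)
  })), na.rm = TRUE)
  names(prof) <- paste0("bin_", seq(0, 330, by = 30))
  centers <- seq(0, 330, by = 30)
  attr(prof, "aligned") <- centers %% (360 / fold) == 0
  prof
}

#' Circular difference between two orientations in fold-space
#'
#' Absolute angular distance between two orientations on the
#' `360/fold`-periodic domain, in degrees (at most `180/fold`).
#'
#' @param a,b Orientations in degrees.
#' @param fold Symmetry factor.
#' @export
phase_distance <- function(a, b, fold = 6L) {
  fd <- 360 / fold
  d <- (a - b) %% fd
  pmin(d, fd - d)
}
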