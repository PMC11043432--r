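# Shared fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

fix_session <- function() {
  if (is.null(.fix$session)) .fix$session <- build_session(seed = 1)
  .fix$session
}

fix_templates <- function() {
  if (is.null(.fix$templates)) {
    .fix$templates <- gridclock:::session_templates(fix_session())
  }
  .fix$templates
}

# deterministic limit of the generator: no noise, no drift, no voxel
# heterogeneity -- for exactness checks
det_spec <- function(fold_n = 6L, phase_deg = 23, gain = 0.03,
                     n_voxels = 3L) {
  group_spec(fold_n = fold_n, roi_phase_deg = phase_deg, gain = gain,
             noise = noise_model(sigma = 0, ar1_rho = 0,
                                 sigma_shared = 0,
                                 drift_amplitudes = numeric(0)),
             config = sim_config(n_voxels = n_voxels,
                                 phase_jitter_kappa = Inf,
                                 gain_sdlog = 0))
}

fix_det_subject <- function() {
  if (is.null(.fix$det_subject)) {
    .fix$det_subject <- simulate_subject(fix_session(), det_spec(),
                                         seed = 11,
                                         templates = fix_templates())
  }
  .fix$det_subject
}

# independent left/right oracle: rotate the frame so the heading points
# along +x and read the sign of the target's y coordinate
rotation_oracle_side <- function(start, end, target) {
  ps <- number_position(start)
  pe <- number_position(end)
  pt <- number_position(target)
  h <- atan2(pe[2] - ps[2], pe[1] - ps[1])
  rel <- pt - pe
  y_rot <- -sin(h) * rel[1] + cos(h) * rel[2]
  if (abs(y_rot) < 1e-9) return(NA_character_)
  if (y_rot > 0) "left" else "right"
}
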