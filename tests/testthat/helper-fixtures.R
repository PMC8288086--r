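# Shared fixtures: everything is built in code at test time.

# A miniature Experiment-2-like session: one run, one block (4 trials),
# shortened run length. Built by trimming the full schedule object so the
# timing and pulse-targeting logic under test is the production code.
tiny_exp2_schedule <- function(seed = 0L, n_runs = 1L) {
  sched <- build_exp2_session(seed)
  keep_ev <- sched$events$run <= n_runs & sched$events$block == 1
  sched$events <- sched$events[keep_ev, , drop = FALSE]
  keep_trials <- paste(sched$pulses$run, sched$pulses$condition)
  first_block <- sched$pulses$run <= n_runs &
    sched$pulses$volume < 10 + 4 * 25
  sched$pulses <- sched$pulses[first_block, , drop = FALSE]
  sched$n_volumes_per_run <- 140L
  sched
}

# Small clean volume_series with known values
toy_series <- function(dim = c(4, 4, 6), nt = 10, value = 0, tr_ms = 1000,
                       voxel_mm = c(3, 3, 3.5)) {
  volume_series(array(value, c(dim, nt)), make_affine(voxel_mm),
                tr_ms = tr_ms, slice_ms = 40)
}

# Regular hexagon + apex fiducial points (exact geometry, world mm)
exact_fiducials <- function(radius = 20, plane_z = 90, apex_h = 10,
                            centre = c(30, 30)) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6] + pi / 6
  rbind(cbind(centre[1] + radius * cos(ang),
              centre[2] + radius * sin(ang), plane_z),
        c(centre, plane_z + apex_h))
}

# Feature-level synthetic session in a 20-mm ROI around the entry point.
# Spatially white component maps (pattern_fwhm_mm = 0): the mechanism tests
# probe pattern geometry, and white maps give many effective dimensions so
# per-session accuracies concentrate.
feature_session <- function(w = 0.5, amp = 2, beta_noise_sd = 1, seed = 1L,
                            trials_per_run = 5, n_runs = 3) {
  cfg <- synth_config(seed = seed, shared_axis_weight = w, pattern_amp = amp)
  an <- make_anatomy(cfg)
  pats <- make_patterns(cfg, an$truth$entry_point, an$brain_mask,
                        names(exp2_frequencies()), pattern_fwhm_mm = 0)
  xyz <- grid_world_coords(cfg$grid, an$affine)
  dist <- sqrt(colSums((t(xyz) - an$truth$entry_point)^2))
  lin <- which(dist <= 20 & as.vector(an$brain_mask))
  upper <- dist[lin] <= stats::median(dist[lin])
  simulate_trial_betas(pats, lin, trials_per_run = trials_per_run,
                       n_runs = n_runs, beta_noise_sd = beta_noise_sd,
                       seed = seed + 500L,
                       voxel_coords = xyz[lin, , drop = FALSE], upper = upper)
}
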