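## Independent oracles used by the tests. These deliberately avoid the
## package's own implementations (brute force / direct convolution), so the
## two routes can disagree.

## time-domain Morlet convolution: amplitude scalogram oracle
morlet_conv_oracle <- function(x, frame_rate, freqs, omega0 = 6) {
  n <- length(x)
  x <- x - mean(x)
  out <- matrix(0, length(freqs), n)
  dt <- 1 / frame_rate
  for (fi in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[fi])
    half <- ceiling(4 * s / dt)
    tt <- (-half:half) * dt
    psi <- exp(1i * omega0 * tt / s) * exp(-0.5 * (tt / s)^2)
    psi <- Conj(psi) * dt / s   # analytic correlation kernel
    conv <- stats::convolve(x, Re(psi), type = "open") +
      1i * stats::convolve(x, Im(psi), type = "open")
    out[fi, ] <- Mod(conv[half + seq_len(n)]) / sqrt(s)
  }
  out
}

## brute-force per-edge length MAD outlier detection on a pose series
edge_outlier_oracle <- function(xyz, edges) {
  bad <- matrix(FALSE, dim(xyz)[1], dim(xyz)[2])
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    len <- sqrt(rowSums((xyz[, a, ] - xyz[, b, ])^2))
    med <- median(len)
    madv <- mad(len, center = med)
    out <- abs(len - med) > 3 * madv
    bad[out, a] <- TRUE
    bad[out, b] <- TRUE
  }
  bad
}

## cached small sessions shared between test files
.session_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .session_cache))
    assign(key, force(expr), envir = .session_cache)
  get(key, envir = .session_cache)
}

## standard planted-session fixtures
fixture_session <- function() cached("base", {
  generate_session(session_config(
    duration_s = 600, n_units = 40, K = 6, seed = 101,
    spatial_gain_hz = 8, syllable_gain_hz = 3, frame_weight_hz = 0,
    baseline_hz = 6))
})

fixture_features <- function() cached("base_feats", {
  ses <- fixture_session()
  sp <- smooth_and_constrain_pose(ses$pose)
  kin <- compute_kinematics(sp)
  feats <- compute_feature_groups(kin, ses$arena)
  list(smoothed = sp, kin = kin, feats = feats,
       labels = assign_spatial_labels(feats, ses$arena),
       design = build_design_matrix(feats),
       orient = bin_orientation(kin))
})

## session with planted anticipatory ramp + syllable gains; bouts long
## enough that baseline bins survive the transition-exclusion window
fixture_ramp <- function() cached("ramp", {
  generate_session(session_config(
    duration_s = 360, n_units = 40, K = 5, seed = 171,
    spatial_gain_hz = 0, syllable_gain_hz = 4, frame_weight_hz = 0,
    ramp_amp = 1, ramp_lead_s = 1, baseline_hz = 8,
    model = syllable_model(K = 5, dwell_s = 4)))
})

## three-motif behavioral fixture for segmentation tests: rest (still,
## crouched, slow head sweep), locomotion (fast, 2.5 Hz gait), and an
## in-place high-frequency movement; long bouts so each bout is long
## relative to the ~2 s wavelet support
motif_model <- function() syllable_model(
  K = 3, dwell_s = 10,
  speed_mps = c(0.01, 0.35, 0.05), z_target = c(0.3, 0.3, 0.3),
  heading_diff = c(0.02, 0.6, 0.1),
  crouch = c(0.45, 1, 1.4), stretch = c(0.8, 1.15, 1),
  osc_hz = c(0.6, 2.5, 7), osc_amp = c(0.002, 0.06, 0.08))

## mixed planted population: spatial fields + body-frame velocity drives
fixture_mixed <- function() cached("mixed", {
  ses <- generate_session(session_config(
    duration_s = 600, n_units = 50, K = 6, seed = 131,
    spatial_gain_hz = 8, syllable_gain_hz = 0,
    frame_weight_hz = 2, frame_mix = c(0, 1, 0, 0),
    frame_feature_mask = c(1, 1, 0, 0, 0, 0), baseline_hz = 8))
  sp <- smooth_and_constrain_pose(ses$pose)
  kin <- compute_kinematics(sp)
  feats <- compute_feature_groups(kin, ses$arena)
  list(ses = ses, feats = feats,
       labels = assign_spatial_labels(feats, ses$arena),
       design = build_design_matrix(feats))
})

fixture_motifs <- function() cached("motifs", {
  beh <- generate_behavior(arena_spec(), motif_model(), 360, 40, seed = 202)
  sp <- smooth_and_constrain_pose(beh$pose)
  nd <- normalize_and_distances(sp, "a1")
  list(beh = beh, smoothed = sp, nd = nd)
})
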