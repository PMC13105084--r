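#' Planted ground truth for a synthetic population
#'
#' Samples per-unit parameters for the five independently switchable response
#' components: a 3D Gaussian spatial field, a reference-frame-tuned linear
#' drive (allocentric / body-centric / head-centric velocity + displacement
#' features), per-syllable additive gains, a multiplicative syllable-by-tier
#' context interaction, and an anticipatory ramp that blends the firing
#' pattern toward the upcoming syllable before each transition.
#'
#' @param n_units number of units
#' @param arena an `arena_spec` (spatial field centers are sampled inside it)
#' @param K number of syllables in the behavioral model
#' @param baseline_hz mean baseline rate (Hz); per-unit baselines are drawn
#'   around this value
#' @param spatial_gain_hz peak rate of the spatial field (Hz); 0 disables
#' @param spatial_width_m Gaussian field width (m)
#' @param frame_weight_hz scale of frame-tuned linear weights (Hz per SD of
#'   the frame feature); 0 disables
#' @param frame_mix proportions of units tuned to (allo, body, head, none)
#' @param frame_feature_mask 6-vector multiplying the per-unit frame weights
#'   (velocity x/y/z then displacement x/y/z); e.g. `c(1,1,0,0,0,0)` plants
#'   horizontal-velocity-only (kinematic) drives with no positional component
#' @param syllable_gain_hz SD of per-syllable additive gains (Hz); 0 disables
#' @param context_gain multiplicative syllable-by-tier gain applied to half
#'   the units (1 disables)
#' @param transient_gain_hz SD of per-(unit, syllable) transient onset gains
#'   (Hz) applied only in the first bin of each bout (0 disables); plants a
#'   transient rather than sustained syllable code
#' @param ramp_amp blend fraction toward the next syllable's gains reached at
#'   transition onset (0 disables)
#' @param ramp_lead_s anticipatory lead time (s)
#' @param frame_tier_gate when TRUE, allocentric frame drives are gated to
#'   the floor (weights 1 / 0.5 / 0 over floor / bench / ceiling) and
#'   body-centric drives to the ceiling (0 / 0.5 / 1), planting a
#'   context-dependent reference-frame shift
#' @param com_samples optional matrix of visited center-of-mass positions;
#'   when given, spatial field centers are drawn from the occupancy
#'   distribution (with 10 cm jitter) instead of uniformly over the arena,
#'   so every planted field overlaps visited space
#' @param seed integer seed
#' @return a `ground_truth` object (list of per-unit parameter tables)
#' @export
ground_truth <- function(n_units, arena, K,
                         baseline_hz = 5,
                         spatial_gain_hz = 8, spatial_width_m = 0.5,
                         frame_weight_hz = 0, frame_mix = c(0.4, 0.4, 0.2, 0),
                         frame_feature_mask = rep(1, 6),
                         syllable_gain_hz = 3,
                         transient_gain_hz = 0,
                         context_gain = 1,
                         ramp_amp = 0, ramp_lead_s = 1,
                         frame_tier_gate = FALSE,
                         com_samples = NULL,
                         seed = 1) {
  stopifnot(n_units >= 1, ramp_lead_s >= 0, K >= 1)
  set.seed(substream_seed(seed, "truth"))
  frame_mix <- frame_mix / sum(frame_mix)
  frame_label <- sample(c("allo", "body", "head", "none"), n_units,
                        replace = TRUE, prob = frame_mix)
  centers <- matrix(NA_real_, n_units, 3)
  if (!is.null(com_samples)) {
    com_samples <- as.matrix(com_samples)
    idx <- sample.int(nrow(com_samples), n_units, replace = TRUE)
    centers <- com_samples[idx, , drop = FALSE] +
      matrix(stats::rnorm(n_units * 3, 0, 0.1), n_units, 3)
  } else {
    apo <- arena$side_m * sqrt(3) / 2
    for (u in seq_len(n_units)) {
      repeat {
        xy <- stats::runif(2, -apo, apo)
        if (in_hexagon(arena, rbind(arena$center[1:2] + xy))) break
      }
      centers[u, ] <- c(arena$center[1:2] + xy,
                        stats::runif(1, 0.2, arena$height_m - 0.2))
    }
  }
  fw <- matrix(stats::rnorm(n_units * 6, 0, frame_weight_hz), n_units, 6)
  fw <- sweep(fw, 2, rep_len(frame_feature_mask, 6), "*")
  fw[frame_label == "none", ] <- 0
  syl_gain <- matrix(stats::rnorm(n_units * K, 0, syllable_gain_hz),
                     n_units, K)
  trans_gain <- matrix(stats::rnorm(n_units * K, 0, transient_gain_hz),
                       n_units, K)
  ctx <- array(1, c(n_units, K, 3))
  if (context_gain != 1) {
    ctx_units <- seq_len(n_units) <= ceiling(n_units / 2)
    for (u in which(ctx_units)) {
      ## each context unit prefers one (syllable, tier) pattern
      g <- matrix(1, K, 3)
      g[, sample.int(3, 1)] <- context_gain
      ctx[u, , ] <- g
    }
  }
  structure(list(
    n_units = n_units, K = K,
    baseline_hz = pmax(stats::rnorm(n_units, baseline_hz, baseline_hz / 5),
                       0.5),
    spatial_center = centers,
    spatial_width_m = rep(spatial_width_m, n_units),
    spatial_gain_hz = rep(spatial_gain_hz, n_units),
    frame_label = frame_label,
    frame_weights = fw,
    syllable_gain = syl_gain,
    transient_gain = trans_gain,
    context_gain = ctx,
    ramp_amp = rep(ramp_amp, n_units),
    ramp_lead_s = rep(ramp_lead_s, n_units),
    frame_tier_gate = frame_tier_gate,
    seed = seed), class = "ground_truth")
}

## tier of com_z under the generator's fixed boundaries (floor < bench_lo,
## ceiling > bench_hi); these are the planted boundaries, estimation-side
## terciles are a separate choice.
truth_tiers <- function(com_z, arena) {
  lo <- arena$bench_z_m * 0.55
  hi <- (arena$bench_z_m + arena$ceiling_z_m) / 2
  findInterval(com_z, c(lo, hi)) + 1L
}

#' Plant a Poisson population on generated behavior
#'
#' Per 500 ms bin, each unit's rate is the rectified sum of baseline +
#' spatial field (Gaussian in the distance of the center of mass from the
#' planted field center) + frame-tuned linear drive + syllable gain times the
#' context gain + anticipatory blend toward the next syllable's gain starting
#' `ramp_lead_s` before each transition. Counts are Poisson; rates are stored
#' as counts / bin width.
#'
#' @param truth a `ground_truth`
#' @param behavior output of [generate_behavior()] (pose + ethogram +
#'   generator kinematics); pose and ethogram must share the frame clock
#' @param arena an `arena_spec`
#' @param bin_s bin width (s), default 0.5
#' @param seed integer seed (spikes substream derived internally)
#' @return a `binned_population`: `rate` (units x bins, Hz), `counts`,
#'   `bin_centers`, `valid`, `units` metadata, plus the per-bin true rate in
#'   `rate_true`
#' @export
plant_population <- function(truth, behavior, arena, bin_s = 0.5, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  pose <- behavior$pose
  eth <- behavior$ethogram
  if (length(pose$time_s) != length(eth$time_s) ||
      max(abs(pose$time_s - eth$time_s)) > 1e-9)
    stop("alignment error: pose and ethogram clocks differ")
  kin <- behavior$kin_true
  n_f <- length(pose$time_s)
  dt <- 1 / pose$frame_rate
  t_end <- pose$time_s[n_f] + dt
  n_bin <- floor(t_end / bin_s + 1e-9)
  bin_centers <- (seq_len(n_bin) - 0.5) * bin_s
  bin_of <- pmin(pmax(floor(pose$time_s / bin_s) + 1L, 1L), n_bin)

  bin_mean <- function(x) {
    s <- tapply(x, bin_of, mean)
    out <- rep(NA_real_, n_bin)
    out[as.integer(names(s))] <- s
    out
  }
  com <- cbind(bin_mean(kin$com_x), bin_mean(kin$com_y), bin_mean(kin$com_z))
  ## per-bin modal syllable
  syl <- as.integer(tapply(eth$labels, bin_of, function(l)
    as.integer(names(which.max(table(l))))))
  tier <- truth_tiers(com[, 3], arena)

  ## frame features from the generator's own kinematics (velocity +
  ## displacement-from-center in each unit's preferred frame)
  vel <- apply(com, 2, function(x) c(0, diff(x)) / bin_s)
  disp <- sweep(com, 2, arena$center)
  byaw <- as.numeric(tapply(kin$body_yaw, bin_of, circ_mean))
  hyaw <- as.numeric(tapply(kin$head_yaw, bin_of, circ_mean))
  hpit <- bin_mean(kin$head_pitch)
  hrol <- bin_mean(kin$head_roll)
  feats <- list(
    allo = cbind(vel, disp),
    body = cbind(rotate_yaw(vel, -byaw), rotate_yaw(disp, -byaw)),
    head = cbind(rotate_head_inv(vel, hyaw, hpit, hrol),
                 rotate_head_inv(disp, hyaw, hpit, hrol)))
  feats <- lapply(feats, function(f) scale(f))

  ## anticipatory blend weight per bin: ramps 0 -> ramp_amp over the lead
  ## window before each syllable change (computed on the bin-level labels)
  change <- which(diff(syl) != 0) + 1L
  next_syl <- syl
  w_ramp <- numeric(n_bin)
  lead_bins <- max(round(truth$ramp_lead_s[1] / bin_s), 1L)
  for (ci in change) {
    lo <- max(1L, ci - lead_bins)
    idx <- lo:(ci - 1L)
    w <- (seq_along(idx)) / lead_bins
    keep <- w > w_ramp[idx]
    w_ramp[idx][keep] <- w[keep]
    next_syl[idx][keep] <- syl[ci]
  }

  set.seed(substream_seed(seed, "spikes"))
  nU <- truth$n_units
  rate <- matrix(0, nU, n_bin)
  for (u in seq_len(nU)) {
    r <- rep(truth$baseline_hz[u], n_bin)
    if (truth$spatial_gain_hz[u] != 0) {
      d2 <- rowSums(sweep(com, 2, truth$spatial_center[u, ])^2)
      r <- r + truth$spatial_gain_hz[u] *
        exp(-d2 / (2 * truth$spatial_width_m[u]^2))
    }
    if (truth$frame_label[u] != "none") {
      f <- feats[[truth$frame_label[u]]]
      drive <- as.numeric(f %*% truth$frame_weights[u, ])
      if (isTRUE(truth$frame_tier_gate)) {
        gate <- switch(truth$frame_label[u],
                       allo = c(1, 0.5, 0)[tier],
                       body = c(0, 0.5, 1)[tier],
                       rep(1, length(tier)))
        drive <- drive * gate
      }
      r <- r + drive
    }
    if (any(truth$transient_gain[u, ] != 0)) {
      onset <- c(TRUE, diff(syl) != 0)
      r <- r + onset * truth$transient_gain[u, syl]
    }
    g_cur <- truth$syllable_gain[u, syl] * truth$context_gain[cbind(u, syl, tier)]
    g_nxt <- truth$syllable_gain[u, next_syl] *
      truth$context_gain[cbind(u, next_syl, tier)]
    a <- truth$ramp_amp[u] * w_ramp
    r <- r + (1 - a) * g_cur + a * g_nxt
    rate[u, ] <- pmax(r, 0)
  }
  rate[is.na(rate)] <- 0
  counts <- matrix(stats::rpois(nU * n_bin, rate * bin_s), nU, n_bin)
  units <- data.frame(
    unit_id = seq_len(nU),
    bank = rep(c("dorsal", "ventral"), length.out = nU),
    channel = ((seq_len(nU) - 1) %% 128) + 1L,
    unit_type = rep(c("SUA", "SUA", "MUA"), length.out = nU))
  structure(list(
    rate = counts / bin_s, counts = counts, rate_true = rate,
    bin_centers = bin_centers, bin_s = bin_s,
    valid = rep(TRUE, n_bin), units = units,
    syllable_bin = syl, tier_bin = tier), class = "binned_population")
}

## circular mean helper
circ_mean <- function(a) atan2(mean(sin(a)), mean(cos(a)))

## rotate row-vectors about z by per-row angles
rotate_yaw <- function(v, ang) {
  cbind(cos(ang) * v[, 1] - sin(ang) * v[, 2],
        sin(ang) * v[, 1] + cos(ang) * v[, 2],
        v[, 3])
}

## apply the inverse full head rotation to row-vectors
rotate_head_inv <- function(v, yaw, pitch, roll) {
  out <- v
  for (i in seq_len(nrow(v))) {
    if (anyNA(c(v[i, ], yaw[i], pitch[i], roll[i]))) { out[i, ] <- NA; next }
    R <- rot_z(yaw[i]) %*% rot_y(-pitch[i]) %*% rot_x(roll[i])
    out[i, ] <- as.numeric(t(R) %*% v[i, ])
  }
  out
}
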