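#' Markov syllable model for synthetic behavior
#'
#' Defines the discrete behavioral repertoire the generator realizes: a
#' bout-level Markov chain over K syllables, per-syllable movement kinematics
#' (mean horizontal speed, vertical set point driving tier occupancy, heading
#' diffusion), per-syllable posture templates, and mean dwell times.
#'
#' @param K number of syllables
#' @param transition K x K bout-level transition matrix (rows sum to 1;
#'   diagonal is ignored when sampling the next bout). Default: uniform over
#'   the other syllables.
#' @param dwell_s mean bout dwell per syllable (s), recycled to length K
#' @param speed_mps mean horizontal speed per syllable (m/s)
#' @param z_target vertical set point per syllable (m); drives tier occupancy
#' @param heading_diff heading diffusion per syllable (rad^2/s)
#' @param crouch,stretch,head_pitch per-syllable posture parameters
#' @param osc_hz,osc_amp per-syllable limb oscillation frequency (Hz) and
#'   amplitude (m); gives each syllable a distinct dynamical signature
#' @param z_jitter per-bout jitter of the vertical set point (sd, m); lets
#'   the same syllable be performed at different heights, as real animals do
#' @return a `syllable_model` object
#' @export
syllable_model <- function(K = 12,
                           transition = NULL,
                           dwell_s = 1.5,
                           speed_mps = NULL,
                           z_target = NULL,
                           heading_diff = 0.5,
                           crouch = NULL, stretch = NULL, head_pitch = NULL,
                           osc_hz = NULL, osc_amp = NULL,
                           z_jitter = 0) {
  stopifnot(K >= 1)
  if (is.null(transition)) {
    transition <- matrix(1 / max(K - 1, 1), K, K)
    diag(transition) <- 0
    if (K == 1) transition <- matrix(1, 1, 1)
  }
  stopifnot(nrow(transition) == K, ncol(transition) == K,
            all(abs(rowSums(transition) - 1) < 1e-8), all(transition >= 0))
  rcy <- function(x, def) if (is.null(x)) def else rep_len(x, K)
  i <- seq_len(K)
  m <- list(
    K = K,
    transition = transition,
    dwell_s = rep_len(dwell_s, K),
    speed_mps = rcy(speed_mps, 0.05 + 0.45 * ((i - 1) %% 4) / 3),
    z_target = rcy(z_target, c(0.3, 1.6, 2.2)[((i - 1) %% 3) + 1]),
    heading_diff = rep_len(heading_diff, K),
    crouch = rcy(crouch, 0.7 + 0.6 * ((i - 1) %% 3) / 2),
    stretch = rcy(stretch, 0.9 + 0.2 * ((i - 1) %% 2)),
    head_pitch = rcy(head_pitch, seq(-0.4, 0.5, length.out = K)),
    osc_hz = rcy(osc_hz, 1 + 10 * (i - 1) / max(K - 1, 1) / 2),
    osc_amp = rcy(osc_amp, 0.01 + 0.02 * ((i - 1) %% 3) / 2),
    z_jitter = z_jitter
  )
  if (any(m$dwell_s <= 0)) stop("dwell must be > 0")
  structure(m, class = "syllable_model")
}

#' Generate synthetic behavior: pose series plus ethogram
#'
#' Realizes the bout-level Markov chain (geometric frame-level dwell with the
#' specified mean), integrates a center-of-mass trajectory with per-syllable
#' speed, heading diffusion (wrapped Gaussian random walk) and vertical drift
#' toward per-syllable set points, reflects at the hexagonal walls, and
#' renders 17-keypoint pose frames from per-syllable posture templates plus
#' limb oscillation and isotropic keypoint noise. Head yaw differs from body
#' yaw by an AR(1) offset so head- and body-fixed frames are distinguishable.
#'
#' @param arena an `arena_spec`
#' @param model a `syllable_model`
#' @param duration_s session duration (s), at least 60
#' @param frame_rate frames per second (30 or 40)
#' @param seed integer seed (behavior substream derived internally)
#' @param keypoint_noise_sd isotropic keypoint noise (m)
#' @return a list with `pose` (a `pose_series`: `time_s`, `xyz`
#'   (frames x 17 x 3), `confidence`), `ethogram` (per-frame labels + bout
#'   table) and `kin_true` (the generator's own kinematic state, used to
#'   plant frame-tuned drives and in recovery tests)
#' @export
generate_behavior <- function(arena, model, duration_s, frame_rate = 40,
                              seed = 1, keypoint_noise_sd = 0.004) {
  stopifnot(inherits(arena, "arena_spec"), inherits(model, "syllable_model"))
  if (duration_s < 60) stop("duration must be >= 60 s")
  if (!frame_rate %in% c(30, 40)) stop("frame_rate must be 30 or 40")
  post_r <- max(abs(base_posture()[, 1:2]))
  if (arena$side_m * sqrt(3) / 2 <= post_r)
    stop("invalid arena: posture templates do not fit inside the hexagon")
  set.seed(substream_seed(seed, "behavior"))
  dt <- 1 / frame_rate
  n <- round(duration_s * frame_rate)
  time_s <- (seq_len(n) - 1) * dt
  K <- model$K

  ## frame-level Markov chain: stay with prob 1 - dt/dwell, else jump
  labels <- integer(n)
  state <- sample.int(K, 1)
  p_leave <- pmin(dt / model$dwell_s, 1)
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    labels[i] <- state
    if (u[i] < p_leave[state] && K > 1) {
      pr <- model$transition[state, ]
      pr[state] <- 0
      s <- sum(pr)
      if (s > 0) state <- sample.int(K, 1, prob = pr / s)
    }
  }

  ## per-bout vertical set points: the syllable's target plus bout jitter
  bout_id <- cumsum(c(1L, as.integer(diff(labels) != 0)))
  n_bouts <- bout_id[n]
  zj <- if (model$z_jitter > 0)
    stats::rnorm(n_bouts, 0, model$z_jitter) else numeric(n_bouts)
  z_star <- pmin(pmax(model$z_target[labels] + zj[bout_id], 0.15),
                 arena$height_m - 0.15)

  ## trajectory integration; heading angular velocity is an OU process and
  ## wall encounters steer smoothly back toward the center, so the planted
  ## kinematics are band-limited like real movement
  com <- matrix(0, n, 3)
  yaw <- numeric(n)
  pos <- c(arena$center[1], arena$center[2], 0.5)
  hd <- stats::runif(1, -pi, pi)
  omega <- 0
  rho <- exp(-dt / 0.5)
  ## multiplicative speed noise (~20% CV) so zero-speed syllables stay put
  spd_noise <- as.numeric(stats::filter(stats::rnorm(n, 0, 0.065), 0.95,
                                        method = "recursive"))
  yaw_noise <- stats::rnorm(n)
  ## vertical OU noise: stationary sd sigma_z / sqrt(2 * pull) ~ 5 cm
  z_noise <- stats::rnorm(n, 0, 0.08 * sqrt(dt))
  margin <- post_r + 0.05
  for (i in seq_len(n)) {
    k <- labels[i]
    ## OU angular velocity whose integrated long-run diffusion matches the
    ## syllable's heading diffusion (stationary sd = sqrt(D / 2 tau), tau 0.5)
    sd_om <- sqrt(model$heading_diff[k])
    omega <- rho * omega + sd_om * sqrt(1 - rho^2) * yaw_noise[i]
    hd <- wrap_angle(hd + omega * dt)
    sp <- max(model$speed_mps[k] * (1 + spd_noise[i]), 0)
    step <- c(cos(hd), sin(hd)) * sp * dt
    cand <- pos[1:2] + step
    if (!in_hexagon(arena, rbind(cand), margin = margin)) {
      ## steer toward the arena center at a bounded turn rate; no step
      to_c <- atan2(arena$center[2] - pos[2], arena$center[1] - pos[1])
      turn <- circ_diff(to_c, hd)
      hd <- wrap_angle(hd + sign(turn) * min(abs(turn), 4 * dt))
      omega <- 0
      cand <- pos[1:2]
    }
    z <- pos[3] + 1.2 * (z_star[i] - pos[3]) * dt + z_noise[i]
    z <- min(max(z, 0.1), arena$height_m - 0.1)
    pos <- c(cand, z)
    com[i, ] <- pos
    yaw[i] <- hd
  }

  ## head orientation: band-limited AR(1) yaw offset (frame-scale jitter
  ## removed, as real head movement is smooth at 40 Hz) + slow pitch/roll
  ## around the syllable's template pitch
  smooth_ar <- function(coef, target_sd) {
    x <- as.numeric(stats::filter(stats::rnorm(n), coef,
                                  method = "recursive"))
    w <- max(2L * floor(0.15 * frame_rate) + 1L, 3L)
    x <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    x[is.na(x)] <- 0
    x / max(stats::sd(x), 1e-12) * target_sd
  }
  hb_off <- smooth_ar(0.98, 0.5)
  pitch <- model$head_pitch[labels] + smooth_ar(0.95, 0.08)
  roll <- smooth_ar(0.95, 0.05)
  head_yaw <- wrap_angle(yaw + hb_off)

  ## render pose
  sk <- skeleton_def()
  templates <- lapply(seq_len(K), function(k)
    syllable_posture(model$crouch[k], model$stretch[k], 0))
  xyz <- array(NA_real_, c(n, 17, 3))
  noise <- array(stats::rnorm(n * 17 * 3, 0, keypoint_noise_sd), c(n, 17, 3))
  phase <- cumsum(2 * pi * model$osc_hz[labels] * dt)
  limb_ends <- c(10, 11, 16, 17)  # wrists and ankles swing in antiphase
  limb_sign <- c(1, -1, -1, 1)
  for (i in seq_len(n)) {
    k <- labels[i]
    tpl <- templates[[k]]
    tpl[limb_ends, 1] <- tpl[limb_ends, 1] +
      model$osc_amp[k] * sin(phase[i]) * limb_sign
    ## face block follows the head rotation relative to the body
    hc <- c(0.22, 0, 0.12)
    Rh <- rot_z(hb_off[i]) %*% rot_y(-pitch[i]) %*% rot_x(roll[i])
    tpl[sk$face, ] <- sweep(sweep(tpl[sk$face, ], 2, hc) %*% t(Rh), 2, hc, "+")
    xyz[i, , ] <- sweep(tpl %*% t(rot_z(yaw[i])), 2, com[i, ], "+") +
      noise[i, , ]
  }

  pose <- structure(list(
    time_s = time_s,
    xyz = xyz,
    confidence = matrix(1, n, 17),
    frame_rate = frame_rate,
    keypoints = sk$names), class = "pose_series")
  eth <- structure(list(
    time_s = time_s,
    labels = labels,
    frame_rate = frame_rate,
    bouts = label_bouts(labels, time_s)), class = "ethogram")
  kin_true <- data.frame(
    time_s = time_s,
    com_x = com[, 1], com_y = com[, 2], com_z = com[, 3],
    body_yaw = yaw, head_yaw = head_yaw, head_pitch = pitch, head_roll = roll)
  list(pose = pose, ethogram = eth, kin_true = kin_true)
}
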