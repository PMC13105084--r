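#' Default configuration for a synthetic session
#'
#' The defaults emulate the recorded sessions the pipeline is designed for: a
#' hexagonal arena 2.4 m tall with 1.5 m sides, 40 Hz pose at 17 keypoints, a
#' 12-syllable behavioral repertoire with ~1.5 s mean bouts spanning floor,
#' bench and ceiling tiers, and a Poisson population with baseline ~5 Hz and
#' mixed planted structure. Every planted effect is independently switchable.
#'
#' @param duration_s session duration (s)
#' @param frame_rate pose frame rate (Hz)
#' @param n_units number of units
#' @param K number of syllables
#' @param bin_s neural bin width (s)
#' @param seed global seed (substreams derived internally)
#' @param ... overrides passed to [ground_truth()] (e.g. `spatial_gain_hz`,
#'   `frame_weight_hz`, `syllable_gain_hz`, `context_gain`, `ramp_amp`) or
#'   [syllable_model()] via a `model` element
#' @return a config list
#' @export
session_config <- function(duration_s = 1800, frame_rate = 40, n_units = 100,
                           K = 12, bin_s = 0.5, seed = 1, ...) {
  c(list(duration_s = duration_s, frame_rate = frame_rate,
         n_units = n_units, K = K, bin_s = bin_s, seed = seed), list(...))
}

#' Generate a complete synthetic session
#'
#' Bundles arena, behavior (pose + ethogram), the planted Poisson population,
#' ground truth, and a valid-inference mask. Identical config + seed gives a
#' bit-identical session.
#'
#' @param config from [session_config()]
#' @return a `synthetic_session`
#' @export
generate_session <- function(config = session_config()) {
  arena <- if (!is.null(config$arena)) config$arena else arena_spec()
  model <- if (!is.null(config$model)) config$model else
    syllable_model(K = config$K)
  beh <- generate_behavior(arena, model, config$duration_s,
                           config$frame_rate, seed = config$seed)
  gt_args <- config[names(config) %in%
    c("baseline_hz", "spatial_gain_hz", "spatial_width_m", "frame_weight_hz",
      "frame_mix", "syllable_gain_hz", "transient_gain_hz",
      "context_gain", "ramp_amp",
      "ramp_lead_s", "frame_tier_gate", "frame_feature_mask")]
  truth <- do.call(ground_truth, c(list(
    n_units = config$n_units, arena = arena, K = model$K,
    com_samples = cbind(beh$kin_true$com_x, beh$kin_true$com_y,
                        beh$kin_true$com_z),
    seed = config$seed), gt_args))
  pop <- plant_population(truth, beh, arena, bin_s = config$bin_s,
                          seed = config$seed)
  mask <- data.frame(start_s = 0, end_s = config$duration_s)
  structure(list(arena = arena, model = model, pose = beh$pose,
                 ethogram = beh$ethogram, kin_true = beh$kin_true,
                 truth = truth, population = pop, valid_mask = mask,
                 config = config), class = "synthetic_session")
}

#' Write a session to a plain-text directory layout
#'
#' Files: `pose.csv` (frame, time_s, keypoint, x, y, z, confidence),
#' `spikes.csv` (unit_id, spike_time_s), `units.csv`, `arena.yaml`,
#' `truth.yaml` (synthetic only), `valid_mask.csv` (start_s, end_s),
#' `ethogram.csv`.
#'
#' @param session a `synthetic_session`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pose <- session$pose
  n <- length(pose$time_s)
  kp <- pose$keypoints
  pose_df <- data.frame(
    frame = rep(seq_len(n), each = 17),
    time_s = rep(pose$time_s, each = 17),
    keypoint = rep(kp, n),
    x = as.vector(t(pose$xyz[, , 1])),
    y = as.vector(t(pose$xyz[, , 2])),
    z = as.vector(t(pose$xyz[, , 3])),
    confidence = as.vector(t(pose$confidence)))
  utils::write.csv(pose_df, file.path(dir, "pose.csv"), row.names = FALSE)

  ## spike times: counts spread evenly within each bin (deterministic)
  pop <- session$population
  sp <- list()
  for (u in seq_len(nrow(pop$counts))) {
    cts <- pop$counts[u, ]
    idx <- which(cts > 0)
    if (!length(idx)) next
    tt <- unlist(lapply(idx, function(b) {
      k <- cts[b]
      pop$bin_centers[b] - pop$bin_s / 2 + (seq_len(k) - 0.5) / k * pop$bin_s
    }))
    sp[[length(sp) + 1]] <- data.frame(unit_id = u, spike_time_s = tt)
  }
  spikes <- if (length(sp)) do.call(rbind, sp) else
    data.frame(unit_id = integer(), spike_time_s = numeric())
  utils::write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(pop$units, file.path(dir, "units.csv"), row.names = FALSE)
  utils::write.csv(session$valid_mask, file.path(dir, "valid_mask.csv"),
                   row.names = FALSE)
  eth <- session$ethogram
  utils::write.csv(data.frame(frame = seq_along(eth$time_s),
                              time_s = eth$time_s, syllable = eth$labels),
                   file.path(dir, "ethogram.csv"), row.names = FALSE)
  yaml::write_yaml(list(side_m = session$arena$side_m,
                        height_m = session$arena$height_m,
                        bench_z_m = session$arena$bench_z_m,
                        ceiling_z_m = session$arena$ceiling_z_m,
                        center = session$arena$center,
                        floor_normal = session$arena$floor_normal),
                   file.path(dir, "arena.yaml"), precision = 12)
  tr <- session$truth
  yaml::write_yaml(list(
    n_units = tr$n_units, K = tr$K, seed = tr$seed,
    baseline_hz = tr$baseline_hz,
    spatial_center = as.numeric(t(tr$spatial_center)),
    spatial_width_m = tr$spatial_width_m,
    spatial_gain_hz = tr$spatial_gain_hz,
    frame_label = tr$frame_label,
    frame_weights = as.numeric(t(tr$frame_weights)),
    syllable_gain = as.numeric(t(tr$syllable_gain)),
    context_gain = as.numeric(tr$context_gain),
    ramp_amp = tr$ramp_amp, ramp_lead_s = tr$ramp_lead_s,
    frame_tier_gate = isTRUE(tr$frame_tier_gate)),
    file.path(dir, "truth.yaml"), precision = 12)
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#' @param dir session directory
#' @return a list with `pose`, `spikes` (data.frame), `units`, `arena`,
#'   `truth` (or NULL), `valid_mask`, `ethogram`
#' @export
read_session <- function(dir) {
  pose_df <- utils::read.csv(file.path(dir, "pose.csv"))
  kp <- unique(pose_df$keypoint)
  n <- nrow(pose_df) / length(kp)
  xyz <- array(NA_real_, c(n, length(kp), 3))
  m <- matrix(seq_len(nrow(pose_df)), nrow = length(kp))
  for (j in 1:3) xyz[, , j] <- t(matrix(pose_df[[c("x", "y", "z")[j]]],
                                        nrow = length(kp)))
  pose <- structure(list(
    time_s = pose_df$time_s[m[1, ]],
    xyz = xyz,
    confidence = t(matrix(pose_df$confidence, nrow = length(kp))),
    frame_rate = round(1 / stats::median(diff(pose_df$time_s[m[1, ]]))),
    keypoints = kp), class = "pose_series")
  ar <- yaml::read_yaml(file.path(dir, "arena.yaml"))
  arena <- arena_spec(ar$side_m, ar$height_m, ar$bench_z_m, ar$ceiling_z_m,
                      unlist(ar$center), unlist(ar$floor_normal))
  truth <- NULL
  tf <- file.path(dir, "truth.yaml")
  if (file.exists(tf)) {
    tr <- yaml::read_yaml(tf)
    truth <- structure(list(
      n_units = tr$n_units, K = tr$K, seed = tr$seed,
      baseline_hz = unlist(tr$baseline_hz),
      spatial_center = matrix(unlist(tr$spatial_center), ncol = 3,
                              byrow = TRUE),
      spatial_width_m = unlist(tr$spatial_width_m),
      spatial_gain_hz = unlist(tr$spatial_gain_hz),
      frame_label = unlist(tr$frame_label),
      frame_weights = matrix(unlist(tr$frame_weights), ncol = 6,
                             byrow = TRUE),
      syllable_gain = matrix(unlist(tr$syllable_gain), ncol = tr$K,
                             byrow = TRUE),
      context_gain = array(unlist(tr$context_gain),
                           c(tr$n_units, tr$K, 3)),
      ramp_amp = unlist(tr$ramp_amp),
      ramp_lead_s = unlist(tr$ramp_lead_s)), class = "ground_truth")
  }
  eth_df <- utils::read.csv(file.path(dir, "ethogram.csv"))
  eth <- structure(list(time_s = eth_df$time_s, labels = eth_df$syllable,
                        frame_rate = pose$frame_rate,
                        bouts = label_bouts(eth_df$syllable, eth_df$time_s)),
                   class = "ethogram")
  list(pose = pose,
       spikes = utils::read.csv(file.path(dir, "spikes.csv")),
       units = utils::read.csv(file.path(dir, "units.csv")),
       arena = arena, truth = truth,
       valid_mask = utils::read.csv(file.path(dir, "valid_mask.csv")),
       ethogram = eth)
}
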