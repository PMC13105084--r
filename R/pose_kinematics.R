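#' Smooth pose and enforce anatomical constraints
#'
#' Per coordinate: running median filter (0.2 s window) followed by a running
#' mean filter (0.4 s window). Skeleton edges whose instantaneous length
#' deviates more than 3x MAD from that edge's median length mark both end
#' keypoints missing for the frame; missing samples are linearly interpolated.
#' Elbow and knee angles outside [15, 170] degrees are flagged (not altered).
#'
#' @param pose a `pose_series`
#' @param frame_rate frames per second; defaults to the pose's own rate
#' @return a smoothed `pose_series` with attributes `edge_outlier_frames`
#'   (count of keypoint-frames marked missing) and `hinge_flags`
#'   (frames x hinges logical matrix)
#' @export
smooth_and_constrain_pose <- function(pose, frame_rate = pose$frame_rate) {
  n <- length(pose$time_s)
  if (n < frame_rate) stop("need at least 1 s of frames")
  sk <- skeleton_def()
  xyz <- pose$xyz

  ## odd window lengths nearest 0.2 s and 0.4 s
  w_med <- max(3L, 2L * floor(0.2 * frame_rate / 2) + 1L)
  w_mean <- max(3L, 2L * floor(0.4 * frame_rate / 2) + 1L)

  ## edge-length outlier rejection (before smoothing, on raw detections)
  miss <- matrix(FALSE, n, 17)
  n_out <- 0L
  for (e in seq_len(nrow(sk$edges))) {
    a <- sk$edges[e, 1]; b <- sk$edges[e, 2]
    len <- sqrt(rowSums((xyz[, a, ] - xyz[, b, ])^2))
    med <- stats::median(len, na.rm = TRUE)
    madv <- stats::mad(len, center = med, na.rm = TRUE)
    if (!is.finite(madv) || madv == 0) next
    bad <- which(abs(len - med) > 3 * madv)
    if (length(bad)) {
      miss[bad, a] <- TRUE
      miss[bad, b] <- TRUE
      n_out <- n_out + length(bad)
    }
  }
  dropped <- integer(0)
  for (k in 1:17) {
    for (j in 1:3) {
      v <- xyz[, k, j]
      v[miss[, k]] <- NA
      if (all(is.na(v))) { dropped <- c(dropped, k); next }
      if (anyNA(v)) v <- stats::approx(seq_len(n), v, seq_len(n),
                                       rule = 2)$y
      v <- stats::runmed(v, w_med, endrule = "median")
      v <- as.numeric(stats::filter(v, rep(1 / w_mean, w_mean), sides = 2))
      ## mean filter leaves NA at the edges; keep the median-filtered value
      na_e <- is.na(v)
      if (any(na_e)) {
        vm <- stats::runmed(xyz[, k, j], w_med, endrule = "median")
        v[na_e] <- vm[na_e]
      }
      xyz[, k, j] <- v
    }
  }
  if (length(unique(dropped)))
    warning("keypoints dropped (all missing): ",
            paste(pose$keypoints[unique(dropped)], collapse = ", "))

  ## hinge-angle flags
  hf <- matrix(FALSE, n, length(sk$hinges))
  colnames(hf) <- names(sk$hinges)
  for (h in seq_along(sk$hinges)) {
    tri <- sk$hinges[[h]]
    v1 <- xyz[, tri[1], ] - xyz[, tri[2], ]
    v2 <- xyz[, tri[3], ] - xyz[, tri[2], ]
    cosang <- rowSums(v1 * v2) /
      pmax(sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)), 1e-12)
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    hf[, h] <- ang < 15 | ang > 170
  }

  out <- pose
  out$xyz <- xyz
  attr(out, "edge_outlier_frames") <- n_out
  attr(out, "hinge_flags") <- hf
  out
}

#' Compute kinematic state from smoothed pose
#'
#' Center of mass = confidence-weighted mean of the 12 body joints; body yaw
#' from the horizontal hip-midpoint-to-shoulder-midpoint axis; head yaw/pitch
#' from the nose minus ear-midpoint vector and roll from the inter-ear axis;
#' velocities by central differences; forward/lateral velocity = horizontal
#' velocity rotated into the body frame.
#'
#' @param pose a (smoothed) `pose_series`
#' @return data.frame with one row per frame: `time_s`, `com_x/y/z`,
#'   `body_yaw`, `head_yaw`, `head_pitch`, `head_roll`, `vx/vy/vz`, `speed`,
#'   `forward`, `lateral`, `yaw_rate`, `pitch_rate`, `roll_rate`,
#'   `head_body_offset`
#' @export
compute_kinematics <- function(pose) {
  sk <- skeleton_def()
  xyz <- pose$xyz
  n <- length(pose$time_s)
  dt <- diff(pose$time_s)
  w <- pose$confidence[, sk$body, drop = FALSE]
  w <- w / pmax(rowSums(w), 1e-12)
  com <- sapply(1:3, function(j)
    rowSums(xyz[, sk$body, j, drop = FALSE][, , 1] * w))

  shoulder_mid <- (xyz[, 6, ] + xyz[, 7, ]) / 2
  hip_mid <- (xyz[, 12, ] + xyz[, 13, ]) / 2
  ax <- shoulder_mid - hip_mid
  body_yaw <- atan2(ax[, 2], ax[, 1])

  ear_mid <- (xyz[, 4, ] + xyz[, 5, ]) / 2
  g <- xyz[, 1, ] - ear_mid                      # nose - ear midpoint
  gn <- sqrt(rowSums(g^2))
  head_yaw <- atan2(g[, 2], g[, 1])
  head_pitch <- asin(pmin(pmax(g[, 3] / pmax(gn, 1e-12), -1), 1))
  ## degenerate face triad: nose collinear with the inter-ear axis
  ear_ax <- xyz[, 4, ] - xyz[, 5, ]              # left - right ear
  cr <- cbind(g[, 2] * ear_ax[, 3] - g[, 3] * ear_ax[, 2],
              g[, 3] * ear_ax[, 1] - g[, 1] * ear_ax[, 3],
              g[, 1] * ear_ax[, 2] - g[, 2] * ear_ax[, 1])
  degen <- sqrt(rowSums(cr^2)) <
    1e-6 * pmax(gn * sqrt(rowSums(ear_ax^2)), 1e-12)
  ## roll: undo head yaw then pitch, read the inter-ear axis elevation
  ex1 <- cos(head_yaw) * ear_ax[, 1] + sin(head_yaw) * ear_ax[, 2]
  ey1 <- -sin(head_yaw) * ear_ax[, 1] + cos(head_yaw) * ear_ax[, 2]
  ez1 <- ear_ax[, 3]
  ez2 <- -sin(head_pitch) * ex1 + cos(head_pitch) * ez1
  head_roll <- atan2(ez2, ey1)
  head_yaw[degen] <- NA
  head_pitch[degen] <- NA
  head_roll[degen] <- NA

  cdiff <- function(x) {
    d <- numeric(n)
    if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) /
      (pose$time_s[3:n] - pose$time_s[1:(n - 2)])
    d[1] <- (x[2] - x[1]) / dt[1]
    d[n] <- (x[n] - x[n - 1]) / dt[n - 1]
    d
  }
  vx <- cdiff(com[, 1]); vy <- cdiff(com[, 2]); vz <- cdiff(com[, 3])
  speed <- sqrt(vx^2 + vy^2 + vz^2)
  forward <- cos(body_yaw) * vx + sin(body_yaw) * vy
  lateral <- -sin(body_yaw) * vx + cos(body_yaw) * vy
  cdiff_circ <- function(a) {
    d <- numeric(n)
    if (n >= 3) d[2:(n - 1)] <- circ_diff(a[3:n], a[1:(n - 2)]) /
      (pose$time_s[3:n] - pose$time_s[1:(n - 2)])
    d[1] <- circ_diff(a[2], a[1]) / dt[1]
    d[n] <- circ_diff(a[n], a[n - 1]) / dt[n - 1]
    d
  }
  data.frame(
    time_s = pose$time_s,
    com_x = com[, 1], com_y = com[, 2], com_z = com[, 3],
    body_yaw = wrap_angle(body_yaw),
    head_yaw = wrap_angle(head_yaw), head_pitch = head_pitch,
    head_roll = wrap_angle(head_roll),
    vx = vx, vy = vy, vz = vz, speed = speed,
    forward = forward, lateral = lateral,
    yaw_rate = cdiff_circ(head_yaw), pitch_rate = cdiff(head_pitch),
    roll_rate = cdiff_circ(head_roll),
    head_body_offset = circ_diff(head_yaw, body_yaw))
}

#' Bin-averaged encoding feature groups
#'
#' Per 500 ms bin (bin-averaged over frames): VIS(5) = head-forward gaze unit
#' vector (3) + distance to the nearest wall along the horizontal gaze
#' direction (1) + looming proxy (1); BODY_KIN(3) = forward velocity, lateral
#' velocity, 3D speed; HEAD_KIN(4) = yaw/pitch/roll angular velocity +
#' head-body yaw offset; POS(3) = center-of-mass coordinates in the arena
#' frame. The looming proxy is the approach rate over distance,
#' `-d/dt(wall_dist) / max(wall_dist, 0.05)`, zero for a stationary animal.
#'
#' @param kin kinematics from [compute_kinematics()]
#' @param arena an `arena_spec`
#' @param bin_s bin width (s)
#' @param min_coverage minimum fraction of frames per bin for validity
#' @return data.frame with `bin_center_s`, the 15 feature columns (prefixed
#'   by group), and `valid`
#' @export
compute_feature_groups <- function(kin, arena, bin_s = 0.5,
                                   min_coverage = 0.5) {
  gaze <- cbind(cos(kin$head_pitch) * cos(kin$head_yaw),
                cos(kin$head_pitch) * sin(kin$head_yaw),
                sin(kin$head_pitch))
  wall <- ray_wall_distance(arena, cbind(kin$com_x, kin$com_y),
                            gaze[, 1:2, drop = FALSE])
  dt <- c(stats::median(diff(kin$time_s)), diff(kin$time_s))
  dwall <- c(0, diff(wall)) / dt
  loom <- -dwall / pmax(wall, 0.05)
  loom[!is.finite(loom)] <- NA

  feat <- data.frame(
    VIS.gaze_x = gaze[, 1], VIS.gaze_y = gaze[, 2], VIS.gaze_z = gaze[, 3],
    VIS.wall_dist = wall, VIS.loom = loom,
    BODY_KIN.forward = kin$forward, BODY_KIN.lateral = kin$lateral,
    BODY_KIN.speed = kin$speed,
    HEAD_KIN.yaw_rate = kin$yaw_rate, HEAD_KIN.pitch_rate = kin$pitch_rate,
    HEAD_KIN.roll_rate = kin$roll_rate,
    HEAD_KIN.hb_offset = kin$head_body_offset,
    POS.com_x = kin$com_x, POS.com_y = kin$com_y, POS.com_z = kin$com_z)

  t_end <- max(kin$time_s) + stats::median(diff(kin$time_s))
  n_bin <- floor(t_end / bin_s + 1e-9)
  bin_of <- pmin(pmax(floor(kin$time_s / bin_s) + 1L, 1L), n_bin)
  frames_per_bin <- tabulate(bin_of, n_bin)
  expected <- bin_s / stats::median(diff(kin$time_s))
  out <- data.frame(bin_center_s = (seq_len(n_bin) - 0.5) * bin_s)
  for (cn in names(feat)) {
    s <- tapply(feat[[cn]], bin_of, mean, na.rm = TRUE)
    v <- rep(NA_real_, n_bin)
    v[as.integer(names(s))] <- s
    out[[cn]] <- v
  }
  out$valid <- frames_per_bin >= min_coverage * expected &
    stats::complete.cases(out)
  out
}

#' Assign spatial labels: height tiers, angular sectors, composite zones
#'
#' Tiers split floor-relative center-of-mass height at its pooled terciles
#' (33.3rd / 66.7th percentiles) unless fixed boundaries are supplied.
#' Sectors are three 120-degree allocentric wedges from the arena center
#' (half-open edges at 0/120/240 degrees). Zone = tier * 3 + sector, giving
#' nine composite zones.
#'
#' @param features per-bin table from [compute_feature_groups()] (uses the
#'   POS columns), or any data.frame with `POS.com_x/y/z`
#' @param arena an `arena_spec`
#' @param tier_boundaries optional fixed `c(lo, hi)` height boundaries (m)
#' @return data.frame `bin_center_s`, `tier` (1 floor, 2 bench, 3 ceiling),
#'   `sector` (0..2), `zone` (0..8)
#' @export
assign_spatial_labels <- function(features, arena, tier_boundaries = NULL) {
  z <- features$POS.com_z
  if (is.null(tier_boundaries)) {
    if (length(unique(stats::na.omit(z))) < 3)
      stop("tier assignment error: fewer than 3 distinct heights")
    tier_boundaries <- stats::quantile(z, c(1 / 3, 2 / 3), na.rm = TRUE,
                                       names = FALSE)
  }
  tier <- findInterval(z, tier_boundaries) + 1L
  ang <- atan2(features$POS.com_y - arena$center[2],
               features$POS.com_x - arena$center[1]) * 180 / pi
  ang <- ang %% 360
  sector <- pmin(floor(ang / 120), 2L)
  data.frame(bin_center_s = features$bin_center_s,
             tier = tier, sector = as.integer(sector),
             zone = as.integer((tier - 1L) * 3L + sector))
}

#' Bin spike times into a population rate matrix
#'
#' @param spikes data.frame with `unit_id`, `spike_time_s`
#' @param t_end session end (s)
#' @param bin_s bin width (s)
#' @param valid_mask data.frame of valid windows (`start_s`, `end_s`); bins
#'   not fully inside a valid window are marked invalid
#' @param unit_ids units to include (default: those present)
#' @return a `binned_population` (`rate` units x bins in Hz, `counts`,
#'   `bin_centers`, `valid`)
#' @export
bin_spikes <- function(spikes, t_end, bin_s = 0.5, valid_mask = NULL,
                       unit_ids = sort(unique(spikes$unit_id))) {
  n_bin <- floor(t_end / bin_s + 1e-9)
  oob <- spikes$spike_time_s < 0 | spikes$spike_time_s >= n_bin * bin_s
  if (any(oob))
    warning(sum(oob), " spikes outside session bounds dropped")
  spikes <- spikes[!oob, ]
  counts <- matrix(0L, length(unit_ids), n_bin)
  b <- floor(spikes$spike_time_s / bin_s) + 1L
  u <- match(spikes$unit_id, unit_ids)
  keep <- !is.na(u)
  tb <- table(factor(u[keep], levels = seq_along(unit_ids)),
              factor(b[keep], levels = seq_len(n_bin)))
  counts[, ] <- as.integer(tb)
  centers <- (seq_len(n_bin) - 0.5) * bin_s
  valid <- rep(TRUE, n_bin)
  if (!is.null(valid_mask)) {
    valid <- rep(FALSE, n_bin)
    for (r in seq_len(nrow(valid_mask)))
      valid <- valid | (centers - bin_s / 2 >= valid_mask$start_s[r] - 1e-9 &
                        centers + bin_s / 2 <= valid_mask$end_s[r] + 1e-9)
  }
  structure(list(rate = counts / bin_s, counts = counts,
                 unit_ids = unit_ids,
                 bin_centers = centers, bin_s = bin_s, valid = valid),
            class = "binned_population")
}

#' Build the lagged, column-blocked design matrix
#'
#' VIS, BODY_KIN and HEAD_KIN columns are replicated at temporal lags of
#' -1.0, -0.5, 0, +0.5, +1.0 s (at 0.5 s bins); POS enters unlagged; a linear
#' time-drift column is appended. A column at lag L carries the feature value
#' from `bin_center_s + L`, so a positive lag pairs the neural bin with
#' future behavior. Edge bins lacking full lag context are masked invalid.
#'
#' @param features per-bin table from [compute_feature_groups()]
#' @param max_lag_s maximum lag magnitude (s); 0 disables lag expansion
#' @param bin_s bin width (s)
#' @return a `design_matrix`: `X` (bins x columns), `groups` per column,
#'   `lags` per column (s), `bin_centers`, `valid`
#' @export
build_design_matrix <- function(features, max_lag_s = 1.0, bin_s = 0.5) {
  lag_steps <- if (max_lag_s > 0) {
    k <- round(max_lag_s / bin_s)
    (-k):k
  } else 0L
  n <- nrow(features)
  if (n * bin_s < 2 * max_lag_s + bin_s)
    stop("session shorter than twice the maximum lag")
  fcols <- setdiff(names(features), c("bin_center_s", "valid"))
  grp <- sub("\\..*$", "", fcols)
  lagged_groups <- c("VIS", "BODY_KIN", "HEAD_KIN")

  shift <- function(v, s) {  # s bins: positive = future values
    if (s == 0) return(v)
    out <- rep(NA_real_, length(v))
    if (s > 0) out[seq_len(length(v) - s)] <- v[(s + 1):length(v)]
    else out[(-s + 1):length(v)] <- v[seq_len(length(v) + s)]
    out
  }

  cols <- list(); groups <- character(); lags <- numeric()
  for (ci in seq_along(fcols)) {
    if (grp[ci] %in% lagged_groups) {
      for (s in lag_steps) {
        cols[[length(cols) + 1]] <- shift(features[[fcols[ci]]], s)
        groups <- c(groups, grp[ci])
        lags <- c(lags, s * bin_s)
      }
    }
  }
  for (ci in which(grp == "POS")) {
    cols[[length(cols) + 1]] <- features[[fcols[ci]]]
    groups <- c(groups, "POS"); lags <- c(lags, 0)
  }
  cols[[length(cols) + 1]] <- seq_len(n) / n
  groups <- c(groups, "DRIFT"); lags <- c(lags, 0)
  X <- do.call(cbind, cols)
  nm <- character(ncol(X))
  idx <- 1
  for (ci in seq_along(fcols)) {
    if (grp[ci] %in% lagged_groups) {
      for (s in lag_steps) {
        nm[idx] <- sprintf("%s.lag%+.1f", fcols[ci], s * bin_s); idx <- idx + 1
      }
    }
  }
  for (ci in which(grp == "POS")) { nm[idx] <- fcols[ci]; idx <- idx + 1 }
  nm[idx] <- "DRIFT.time"
  colnames(X) <- nm

  base_valid <- if ("valid" %in% names(features)) features$valid else
    rep(TRUE, n)
  valid <- base_valid & stats::complete.cases(X)
  structure(list(X = X, groups = groups, lags = lags,
                 bin_centers = features$bin_center_s, bin_s = bin_s,
                 valid = valid), class = "design_matrix")
}
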