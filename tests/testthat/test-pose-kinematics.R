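test_that("smoothing is the identity on a constant pose and removes spikes", {
  n <- 200
  tpl <- base_posture()
  xyz <- aperm(array(t(tpl), c(3, 17, n)), c(3, 2, 1)) +
    array(rep(c(0, 0, 0.5), each = n * 17), c(n, 17, 3))
  pose <- structure(list(time_s = (0:(n - 1)) / 40, xyz = xyz,
                         confidence = matrix(1, n, 17), frame_rate = 40,
                         keypoints = skeleton_def()$names),
                    class = "pose_series")
  sm <- smooth_and_constrain_pose(pose)
  expect_equal(sm$xyz, xyz, tolerance = 1e-9)

  ## 1 m spike in one keypoint for one frame: flagged by the edge-length
  ## MAD rule (cross-checked against a brute-force oracle) and removed
  pose2 <- pose
  pose2$xyz[, , ] <- pose2$xyz[, , ] +
    array(rnorm(n * 17 * 3, 0, 0.003), c(n, 17, 3))
  pose2$xyz[100, 10, 3] <- pose2$xyz[100, 10, 3] + 1
  oracle_bad <- edge_outlier_oracle(pose2$xyz, skeleton_def()$edges)
  expect_true(oracle_bad[100, 10])
  sm2 <- smooth_and_constrain_pose(pose2)
  expect_lt(abs(sm2$xyz[100, 10, 3] - xyz[100, 10, 3]), 0.1)
  expect_gt(attr(sm2, "edge_outlier_frames"), 0)
})

test_that("out-of-range elbow angles are flagged", {
  n <- 120
  tpl <- base_posture()
  ## left elbow: fold the forearm up toward the shoulder for a sustained
  ## stretch (length-preserving, so the edge-outlier rule does not fire)
  xyz <- aperm(array(t(tpl), c(3, 17, n)), c(3, 2, 1))
  sh <- tpl[6, ]; el <- tpl[8, ]; wr <- tpl[10, ]
  len <- sqrt(sum((wr - el)^2))
  fold <- el + len * (sh - el) / sqrt(sum((sh - el)^2))
  for (i in 45:75) xyz[i, 10, ] <- fold
  pose <- structure(list(time_s = (0:(n - 1)) / 40, xyz = xyz,
                         confidence = matrix(1, n, 17), frame_rate = 40,
                         keypoints = skeleton_def()$names),
                    class = "pose_series")
  sm <- smooth_and_constrain_pose(pose)
  hf <- attr(sm, "hinge_flags")
  expect_true(any(hf[55:65, "left_elbow"]))
})

test_that("kinematics: translation maps to forward/lateral by body yaw", {
  n <- 200
  tpl <- base_posture()
  mk <- function(yaw) {
    xyz <- array(0, c(n, 17, 3))
    R <- matrix(c(cos(yaw), sin(yaw), 0, -sin(yaw), cos(yaw), 0, 0, 0, 1),
                3, 3)
    for (i in 1:n) xyz[i, , ] <- sweep(tpl %*% t(R), 2,
                                       c(0.5 * (i - 1) / 40, 0, 0.5), "+")
    structure(list(time_s = (0:(n - 1)) / 40, xyz = xyz,
                   confidence = matrix(1, n, 17), frame_rate = 40,
                   keypoints = skeleton_def()$names), class = "pose_series")
  }
  k0 <- compute_kinematics(mk(0))
  i <- 50:150
  expect_equal(mean(k0$forward[i]), 0.5, tolerance = 1e-6)
  expect_equal(mean(abs(k0$lateral[i])), 0, tolerance = 1e-6)
  k90 <- compute_kinematics(mk(pi / 2))
  expect_equal(mean(k90$forward[i]), 0, tolerance = 1e-6)
  expect_equal(mean(abs(k90$lateral[i])), 0.5, tolerance = 1e-6)
  expect_equal(k90$speed, sqrt(k90$vx^2 + k90$vy^2 + k90$vz^2))
})

test_that("planted orientation is recovered from rendered pose", {
  ses <- fixture_session()
  fx <- fixture_features()
  kin <- fx$kin
  expect_lt(circular_rmse(kin$body_yaw, ses$kin_true$body_yaw),
            5 * pi / 180)
  expect_lt(circular_rmse(kin$head_yaw, ses$kin_true$head_yaw),
            5 * pi / 180)
})

test_that("wall distance along gaze matches the ray-marching oracle", {
  arena <- arena_spec()
  set.seed(42)
  n <- 60
  pts <- matrix(NA_real_, n, 2)
  got <- 0
  while (got < n) {
    p <- runif(2, -1.3, 1.3)
    if (in_hexagon(arena, rbind(p), margin = 0.01)) {
      got <- got + 1
      pts[got, ] <- p
    }
  }
  ang <- runif(n, -pi, pi)
  dirs <- cbind(cos(ang), sin(ang))
  fast <- ray_wall_distance(arena, pts, dirs)
  slow <- ray_wall_distance_march(arena, pts, dirs, step = 5e-4)
  expect_lt(max(abs(fast - slow)), 1e-3)
})

test_that("feature groups: widths, stationary looming, validity", {
  fx <- fixture_features()
  feats <- fx$feats
  grp <- sub("\\..*$", "", setdiff(names(feats), c("bin_center_s", "valid")))
  expect_equal(as.integer(table(grp)[c("VIS", "BODY_KIN", "HEAD_KIN",
                                       "POS")]), c(5L, 3L, 4L, 3L))
  ## stationary animal: zero looming
  kin0 <- data.frame(time_s = (0:199) / 40, com_x = 0.2, com_y = 0,
                     com_z = 0.5, body_yaw = 0, head_yaw = 0.3,
                     head_pitch = 0, head_roll = 0, vx = 0, vy = 0, vz = 0,
                     speed = 0, forward = 0, lateral = 0, yaw_rate = 0,
                     pitch_rate = 0, roll_rate = 0, head_body_offset = 0.3)
  f0 <- compute_feature_groups(kin0, arena_spec())
  expect_equal(max(abs(f0$VIS.loom), na.rm = TRUE), 0)
})

test_that("tier/sector/zone labels partition valid bins", {
  fx <- fixture_features()
  labs <- fx$labels
  expect_true(all(labs$zone == (labs$tier - 1) * 3 + labs$sector,
                  na.rm = TRUE))
  v <- fx$feats$valid
  expect_true(all(labs$zone[v] %in% 0:8))
  ## sector edge cases via explicit positions
  f <- data.frame(bin_center_s = c(0.25, 0.75, 1.25),
                  POS.com_x = c(1, cos(121 * pi / 180), 0.5),
                  POS.com_y = c(0, sin(121 * pi / 180), -0.1),
                  POS.com_z = c(0.1, 1.0, 2.2))
  sl <- assign_spatial_labels(f, arena_spec(),
                              tier_boundaries = c(0.8, 1.8))
  expect_equal(sl$sector[1:2], c(0L, 1L))
  expect_equal(sl$tier, c(1L, 2L, 3L))
})

test_that("tercile tiers fall at the pooled 33/67 percentiles", {
  z <- c(rep(0.2, 30), rep(1.0, 30), rep(2.0, 30))
  f <- data.frame(bin_center_s = seq(0.25, by = 0.5, length.out = 90),
                  POS.com_x = 0.1, POS.com_y = 0.1, POS.com_z = z)
  sl <- assign_spatial_labels(f, arena_spec())
  expect_equal(as.integer(table(sl$tier)), c(30L, 30L, 30L))
  expect_error(assign_spatial_labels(
    within(f, POS.com_z <- 1), arena_spec()), "distinct")
})

test_that("spike binning: rates, empty units, mask handling", {
  spikes <- data.frame(unit_id = c(rep(1, 10), 2),
                       spike_time_s = c(seq(0.025, 0.475, length.out = 10),
                                        150))
  bp <- bin_spikes(spikes, t_end = 200, bin_s = 0.5, unit_ids = c(1, 2, 3))
  expect_equal(bp$rate[1, 1], 20)
  expect_true(all(bp$counts[3, ] == 0))
  mask <- data.frame(start_s = c(0, 110), end_s = c(100, 200))
  bp2 <- bin_spikes(spikes, t_end = 200, bin_s = 0.5, valid_mask = mask)
  expect_equal(sum(!bp2$valid), 20L)
  expect_warning(bin_spikes(data.frame(unit_id = 1, spike_time_s = 300),
                            t_end = 200), "outside")
})

test_that("design matrix: column counts, lag trimming, lag structure", {
  fx <- fixture_features()
  des <- fx$design
  expect_equal(ncol(des$X), (5 + 3 + 4) * 5 + 3 + 1)
  des0 <- build_design_matrix(fx$feats, max_lag_s = 0)
  expect_equal(ncol(des0$X), 5 + 3 + 4 + 3 + 1)
  ## first and last two bins are trimmed by the +/-1 s lags
  n <- nrow(fx$feats)
  expect_true(all(!des$valid[c(1, 2, n - 1, n)]))
  ## POS and DRIFT are unlagged
  expect_true(all(des$lags[des$groups %in% c("POS", "DRIFT")] == 0))
  expect_equal(sort(unique(des$lags[des$groups == "VIS"])),
               c(-1, -0.5, 0, 0.5, 1))
  ## lag structure: the lag L column of a feature equals the lag 0 column
  ## shifted by L / bin_s rows
  x0 <- des$X[, "VIS.gaze_x.lag+0.0"]
  xp <- des$X[, "VIS.gaze_x.lag+0.5"]
  expect_equal(xp[1:(n - 1)], x0[2:n])
  xm <- des$X[, "VIS.gaze_x.lag-0.5"]
  expect_equal(xm[2:n], x0[1:(n - 1)])
  expect_error(build_design_matrix(fx$feats[1:3, ], max_lag_s = 1), "lag")
})

test_that("arena-frame rotation invariance of kinematic magnitudes", {
  ## rotating the whole pose series about z leaves speed, forward/lateral
  ## and wall distance unchanged; positions rotate predictably
  ses <- fixture_session()
  pose <- ses$pose
  th <- 2 * pi / 3  # hexagon symmetry so wall distances are preserved
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pose_r <- pose
  take <- 1:2000
  pose$time_s <- pose$time_s[take]
  pose$xyz <- pose$xyz[take, , ]
  pose$confidence <- pose$confidence[take, ]
  pose_r$time_s <- pose$time_s
  pose_r$xyz <- pose$xyz
  pose_r$confidence <- pose$confidence
  for (i in seq_along(take))
    pose_r$xyz[i, , ] <- pose$xyz[i, , ] %*% t(R)
  ## rotation equivariance is exact for the kinematic map itself (the
  ## median filter is only approximately equivariant, so use raw pose)
  k1 <- compute_kinematics(pose)
  k2 <- compute_kinematics(pose_r)
  expect_equal(k2$speed, k1$speed, tolerance = 1e-9)
  expect_equal(k2$forward, k1$forward, tolerance = 1e-6)
  expect_equal(k2$lateral, k1$lateral, tolerance = 1e-6)
  f1 <- compute_feature_groups(k1, ses$arena)
  f2 <- compute_feature_groups(k2, ses$arena)
  expect_equal(f2$VIS.wall_dist, f1$VIS.wall_dist, tolerance = 1e-6)
  expect_equal(f2$POS.com_z, f1$POS.com_z, tolerance = 1e-9)
  ## horizontal position rotates by the applied angle
  expect_equal(f2$POS.com_x,
               cos(th) * f1$POS.com_x - sin(th) * f1$POS.com_y,
               tolerance = 1e-9)
})
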