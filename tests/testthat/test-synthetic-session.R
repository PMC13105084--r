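test_that("arena geometry: hexagon containment and wall distances", {
  arena <- arena_spec()
  expect_true(in_hexagon(arena, rbind(c(0, 0))))
  expect_false(in_hexagon(arena, rbind(c(2, 0))))
  ## from the center toward an edge midpoint the distance is the apothem
  d <- ray_wall_distance(arena, c(0, 0), c(cos(pi / 6), sin(pi / 6)))
  expect_equal(as.numeric(d), 1.5 * sqrt(3) / 2, tolerance = 1e-9)
  ## toward a vertex the distance is the side length
  d2 <- ray_wall_distance(arena, c(0, 0), c(1, 0))
  expect_equal(as.numeric(d2), 1.5, tolerance = 1e-9)
  ## origin outside -> 0 with flag
  d3 <- ray_wall_distance(arena, c(5, 0), c(1, 0))
  expect_equal(as.numeric(d3), 0)
  expect_true(attr(d3, "out_of_arena")[1])
})

test_that("invalid arena specifications are rejected", {
  expect_error(arena_spec(side_m = -1))
  expect_error(arena_spec(bench_z_m = 3, ceiling_z_m = 2.4))
  expect_error(arena_spec(floor_normal = c(0, 0, 2)), "unit norm")
})

test_that("degenerate one-syllable chain yields a constant pose and one bout", {
  arena <- arena_spec()
  model <- syllable_model(K = 1, speed_mps = 0, heading_diff = 0,
                          osc_amp = 0, z_target = 0.5)
  beh <- generate_behavior(arena, model, 60, 40, seed = 1,
                           keypoint_noise_sd = 0)
  expect_equal(nrow(beh$ethogram$bouts), 1L)
  expect_equal(beh$ethogram$bouts$n_frames, 2400L)
  ## body pose is fixed in x/y (zero speed, frozen heading); only the head
  ## orientation noise and vertical OU noise move anything
  expect_lt(diff(range(beh$pose$xyz[, 6, 1])), 1e-9)
  expect_lt(diff(range(beh$pose$xyz[, 6, 2])), 1e-9)
})

test_that("realized dwell matches the geometric expectation", {
  arena <- arena_spec()
  model <- syllable_model(K = 4, dwell_s = 2)
  beh <- generate_behavior(arena, model, 600, 40, seed = 3)
  mean_bout <- mean(beh$ethogram$bouts$n_frames) / 40
  expect_lt(abs(mean_bout - 2) / 2, 0.2)
})

test_that("same seed gives a bit-identical session; behavior stays inside the arena", {
  arena <- arena_spec()
  model <- syllable_model(K = 3)
  b1 <- generate_behavior(arena, model, 60, 40, seed = 7)
  b2 <- generate_behavior(arena, model, 60, 40, seed = 7)
  expect_identical(b1$pose$xyz, b2$pose$xyz)
  expect_identical(b1$ethogram$labels, b2$ethogram$labels)
  b3 <- generate_behavior(arena, model, 60, 40, seed = 8)
  expect_false(identical(b1$pose$xyz, b3$pose$xyz))
  com_xy <- cbind(b1$kin_true$com_x, b1$kin_true$com_y)
  expect_true(all(in_hexagon(arena, com_xy)))
  expect_true(all(diff(b1$pose$time_s) > 0))
})

test_that("generator rejects preconditions", {
  arena <- arena_spec()
  model <- syllable_model(K = 2)
  expect_error(generate_behavior(arena, model, 30, 40), ">= 60")
  expect_error(generate_behavior(arena, model, 60, 25), "30 or 40")
  expect_error(generate_behavior(arena_spec(side_m = 0.3), model, 60, 40),
               "invalid arena")
})

test_that("planted population: Poisson baseline and switchable components", {
  arena <- arena_spec()
  model <- syllable_model(K = 3)
  beh <- generate_behavior(arena, model, 300, 40, seed = 11)
  ## all gains zero, baseline-only: pooled mean within 3 SE of the true mean
  tr <- ground_truth(20, arena, 3, baseline_hz = 5, spatial_gain_hz = 0,
                     frame_weight_hz = 0, syllable_gain_hz = 0, seed = 11)
  pop <- plant_population(tr, beh, arena, seed = 11)
  mu_true <- mean(tr$baseline_hz)
  se <- sqrt(mean(tr$baseline_hz) / (0.5 * length(pop$rate)))
  expect_lt(abs(mean(pop$rate) - mu_true), 3 * se)
  ## no planted ramp: pre-transition rate equals non-transition rate
  syl <- pop$syllable_bin
  pre <- which(c(diff(syl) != 0, FALSE))
  rest <- setdiff(seq_along(syl), pre)
  expect_lt(abs(mean(pop$rate[, pre]) - mean(pop$rate[, rest])),
            4 * sqrt(mu_true / 0.5 / (length(pre) * 20)))
  ## mismatched clocks error
  beh_bad <- beh
  beh_bad$ethogram$time_s <- beh$ethogram$time_s + 0.01
  expect_error(plant_population(tr, beh_bad, arena), "alignment")
})

test_that("spatial-field-only unit peaks near its planted center", {
  ses <- fixture_session()
  pop <- ses$population
  tr <- ses$truth
  ok <- 0
  for (u in 1:10) {
    com <- cbind(tapply(ses$kin_true$com_x,
                        floor(ses$kin_true$time_s / 0.5) + 1, mean),
                 tapply(ses$kin_true$com_y,
                        floor(ses$kin_true$time_s / 0.5) + 1, mean),
                 tapply(ses$kin_true$com_z,
                        floor(ses$kin_true$time_s / 0.5) + 1, mean))
    ## brute-force rate map: mean rate in a ball around each visited point
    r <- pop$rate[u, seq_len(nrow(com))]
    best <- which.max(vapply(seq(1, nrow(com), by = 7), function(j) {
      d <- sqrt(rowSums(sweep(com, 2, com[j, ])^2))
      mean(r[d < 0.35])
    }, numeric(1)))
    peak <- com[seq(1, nrow(com), by = 7)[best], ]
    err <- sqrt(sum((peak - tr$spatial_center[u, ])^2))
    if (err < tr$spatial_width_m[u] * 1.5) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("sessions round-trip through the on-disk layout", {
  dir <- tempfile("ses")
  cfg <- session_config(duration_s = 60, n_units = 5, K = 3, seed = 5)
  ses <- generate_session(cfg)
  expect_equal(dim(ses$pose$xyz), c(60 * 40, 17, 3))
  write_session(ses, dir)
  back <- read_session(dir)
  expect_equal(back$pose$xyz, ses$pose$xyz, tolerance = 1e-12)
  expect_equal(back$arena$side_m, ses$arena$side_m)
  expect_equal(back$truth$baseline_hz, ses$truth$baseline_hz,
               tolerance = 1e-9)
  expect_equal(back$truth$frame_label, ses$truth$frame_label)
  expect_equal(back$ethogram$labels, ses$ethogram$labels)
  ## binning the written spike times reproduces the planted counts
  bp <- bin_spikes(back$spikes, t_end = 60, bin_s = 0.5)
  expect_equal(unname(bp$counts), unname(ses$population$counts))
  unlink(dir, recursive = TRUE)
})

test_that("duration and frame rate set the pose frame count", {
  cfg <- session_config(duration_s = 60, n_units = 2, K = 2, seed = 2,
                        frame_rate = 40)
  ses <- generate_session(cfg)
  expect_equal(length(ses$pose$time_s), 2400L)
  expect_equal(dim(ses$pose$xyz)[2], 17L)
})

test_that("empirical transition matrix converges to the specified chain", {
  arena <- arena_spec()
  Tm <- matrix(c(0, 0.7, 0.3,
                 0.2, 0, 0.8,
                 0.5, 0.5, 0), 3, 3, byrow = TRUE)
  model <- syllable_model(K = 3, transition = Tm, dwell_s = 0.5)
  beh <- generate_behavior(arena, model, 3000, 40, seed = 13)
  b <- rle(beh$ethogram$labels)$values
  emp <- matrix(0, 3, 3)
  for (i in seq_len(length(b) - 1)) emp[b[i], b[i + 1]] <- emp[b[i], b[i + 1]] + 1
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - Tm)), 0.05)
})
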