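test_that("spatial-lite supervision provably excludes vertical position", {
  fx <- fixture_features()
  sl <- embedding_labels(fx$feats, "spatial_lite")
  expect_equal(colnames(sl), c("com_x", "com_y", "speed", "yaw_rate"))
  expect_false("com_z" %in% colnames(sl))
  bh <- embedding_labels(fx$feats, "behavior")
  expect_true("com_z" %in% colnames(bh))
  expect_error(fit_embedding(matrix(1, 2, 10), bh, "spatial_lite", dim = 2,
                             plan = NULL), "vertical")
})

test_that("linear embedding: exact low rank, determinism, CV hygiene", {
  set.seed(51)
  n <- 600
  bt <- seq(0.25, by = 0.5, length.out = n)
  ## rank-2 rate matrix
  U <- matrix(rnorm(12 * 2), 12, 2)
  V <- matrix(rnorm(n * 2), n, 2)
  rates <- U %*% t(V)
  plan <- make_fold_plan(bt, k = 5)
  emb <- fit_embedding(rates, NULL, "behavior", dim = 8, plan = plan)
  ## all variance concentrates in 2 dimensions
  vr <- apply(emb$coords, 2, var)
  expect_gt(sum(vr[1:2]) / sum(vr), 0.999)
  emb2 <- fit_embedding(rates, NULL, "behavior", dim = 8, plan = plan)
  expect_identical(emb$coords, emb2$coords)
  ## embedding transforms never see test bins: replacing a fold's test bins
  ## with noise leaves other folds' projections unchanged
  rates_p <- rates
  te1 <- plan$folds[[1]]$test
  rates_p[, te1] <- rnorm(length(te1) * 12)
  emb_p <- fit_embedding(rates_p, NULL, "behavior", dim = 8, plan = plan)
  other <- setdiff(which(is.finite(emb$coords[, 1])), te1)
  ## folds whose training set excludes fold 1's test bins are untouched
  unaffected <- other[vapply(other, function(b) {
    f <- emb$fold_of[b]
    !any(te1 %in% plan$folds[[f]]$train)
  }, logical(1))]
  if (length(unaffected))
    expect_equal(emb_p$coords[unaffected, ], emb$coords[unaffected, ])
})

test_that("kNN decoding: separable clusters, shuffled labels, chance", {
  set.seed(52)
  n <- 600
  bt <- seq(0.25, by = 0.5, length.out = n)
  lab <- sample(1:3, n, replace = TRUE)
  coords <- cbind(lab * 5 + rnorm(n, 0, 0.3), rnorm(n), rnorm(n))
  plan <- make_fold_plan(bt, k = 5)
  kd <- knn_decode(coords, lab, plan)
  expect_gt(kd$balanced_accuracy, 0.98)
  expect_equal(kd$chance, 1 / 3)
  kd0 <- knn_decode(coords, sample(lab), plan)
  expect_lt(abs(kd0$balanced_accuracy - 1 / 3), 0.08)
})

test_that("tier separates in a spatial-lite embedding of a planted tier code", {
  fx <- fixture_mixed()   # spatial fields planted, com_z never supervised
  ses <- fx$ses
  plan <- make_fold_plan(ses$population$bin_centers, fx$design$valid, k = 5)
  sl <- embedding_labels(fx$feats, "spatial_lite")
  emb <- fit_embedding(ses$population$rate, sl, "spatial_lite", dim = 8,
                       plan = plan)
  kd <- knn_decode(emb, fx$labels$tier, plan)
  expect_gt(kd$balanced_accuracy, kd$chance + 0.1)
})

test_that("context ratio: planted interaction detected, null calibrated", {
  ses <- cached("ctx_session", generate_session(session_config(
    duration_s = 900, n_units = 60, K = 6, seed = 161,
    spatial_gain_hz = 0, syllable_gain_hz = 5, frame_weight_hz = 0,
    context_gain = 1.5, baseline_hz = 8,
    model = syllable_model(K = 6, dwell_s = 2.5, z_jitter = 0.7))))
  pop <- ses$population
  emb <- fit_embedding(pop$rate, NULL, "spatial_lite", dim = 8)
  cr <- context_ratio(emb$coords, pop$syllable_bin, pop$tier_bin,
                      n_perm = 199, seed = 161)
  expect_gt(cr$ratio, 1)
  expect_lt(cr$p, 0.01)
  ## cells below the bin floor are excluded from the statistic
  few <- pop$tier_bin
  cr19 <- context_ratio(emb$coords[1:100, , drop = FALSE],
                        pop$syllable_bin[1:100], pop$tier_bin[1:100],
                        min_bins = 1000, n_perm = 0)
  expect_true(isTRUE(cr19$undefined))
  ## no interaction: ratio stays near 1
  ses0 <- cached("ctx_null_session", generate_session(session_config(
    duration_s = 600, n_units = 40, K = 6, seed = 162,
    spatial_gain_hz = 0, syllable_gain_hz = 5, frame_weight_hz = 0,
    context_gain = 1, baseline_hz = 8,
    model = syllable_model(K = 6, dwell_s = 2.5, z_jitter = 0.7))))
  emb0 <- fit_embedding(ses0$population$rate, NULL, "spatial_lite", dim = 8)
  cr0 <- context_ratio(emb0$coords, ses0$population$syllable_bin,
                       ses0$population$tier_bin, n_perm = 99, seed = 162)
  expect_lt(abs(cr0$ratio - 1), 0.1)
  expect_gt(cr0$p, 0.05)
})

test_that("context ratio is invariant to rotation and scaling of the embedding", {
  set.seed(53)
  n <- 900
  syl <- sample(1:4, n, replace = TRUE)
  tier <- sample(1:3, n, replace = TRUE)
  coords <- matrix(rnorm(n * 3), n, 3) + 0.8 * outer(tier, c(1, 0, 0))
  r1 <- context_ratio(coords, syl, tier, n_perm = 0)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  r2 <- context_ratio(3.7 * coords %*% R, syl, tier, n_perm = 0)
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-9)
})

test_that("eta-squared: exact label copy, null bias, planted joint code", {
  set.seed(54)
  n <- 1000
  tier <- sample(1:3, n, replace = TRUE)
  syl <- sample(1:5, n, replace = TRUE)
  coords <- cbind(tier, rnorm(n),
                  0.8 * tier + 0.8 * syl + rnorm(n, 0, 0.5))
  v <- variance_per_dimension(coords, syl, tier)
  expect_equal(v$eta2_tier[1], 1)
  ## pure-noise dimension: eta2 near its small-sample bias (K-1)/(N-1)
  expect_lt(v$eta2_tier[2], 5 * (3 - 1) / (n - 1) + 0.01)
  ## joint code: both label families explain variance in dimension 3
  expect_gt(v$eta2_tier[3], 0.02)
  expect_gt(v$eta2_syllable[3], 0.02)
  ## single class: defined as 0
  v1 <- variance_per_dimension(coords, rep(1, n), tier)
  expect_equal(v1$eta2_syllable, rep(0, 3))
})

test_that("circular shift preserves the marginal distribution of steps", {
  set.seed(55)
  M <- matrix(rnorm(300), 100, 3)
  S <- arenaneuro:::circ_shift_rows(M, 37)
  d0 <- sort(sqrt(rowSums((M[-1, ] - M[-100, ])^2)))
  d1 <- sqrt(rowSums((S[-1, ] - S[-100, ])^2))
  ## all but the two wrap-boundary steps are the same multiset
  expect_gte(sum(round(d1, 12) %in% round(d0, 12)), 97)
  expect_equal(sort(S[, 1]), sort(M[, 1]))
})

test_that("anticipatory drift: planted ramp detected; current beats next early", {
  ses <- fixture_ramp()
  pop <- ses$population
  emb <- fit_embedding(pop$rate, NULL, "behavior", dim = 3)
  ad <- anticipatory_drift(emb$coords, pop$syllable_bin, pop$bin_centers,
                           n_shift = 199, seed = 171)
  expect_gt(ad$ramp_slope, 0)
  expect_lt(ad$p, 0.01)
  ## two seconds before onset the state still resembles the current
  ## syllable more than the next one
  i_first <- 1
  expect_gt(ad$sim_current[i_first], ad$sim_next[i_first])
})

test_that("transition velocity: planted steps elevate; stationary gives zero", {
  ## crisp state changes (no anticipatory blending, which smooths the step)
  ses <- cached("step_session", generate_session(session_config(
    duration_s = 360, n_units = 40, K = 5, seed = 173,
    spatial_gain_hz = 0, syllable_gain_hz = 5, frame_weight_hz = 0,
    ramp_amp = 0, baseline_hz = 8,
    model = syllable_model(K = 5, dwell_s = 4))))
  pop <- ses$population
  emb <- fit_embedding(pop$rate, NULL, "behavior", dim = 3)
  tv <- transition_velocity(emb$coords, pop$syllable_bin, pop$bin_centers,
                            n_shift = 199, seed = 172)
  expect_gt(tv$elevation_pct, 0)
  expect_lt(tv$p, 0.01)
  ## stationary embedding: elevation exactly 0
  n <- length(pop$syllable_bin)
  flat <- matrix(1, n, 3) + 1e-9 * matrix(rnorm(3 * n), n, 3)
  tv0 <- transition_velocity(flat, pop$syllable_bin, pop$bin_centers,
                             n_shift = 20, seed = 1)
  expect_lt(abs(tv0$elevation_pct), 5)
  ## a transition-free label series errors
  expect_error(transition_velocity(emb$coords, rep(1L, n),
                                   pop$bin_centers), "no transitions")
})
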