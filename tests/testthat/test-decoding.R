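test_that("balanced accuracy: constant classifier scores exactly 1/K", {
  truth <- c(rep("a", 90), rep("b", 9), rep("c", 1))
  expect_equal(balanced_accuracy(truth, rep("a", 100)), 1 / 3)
  expect_equal(balanced_accuracy(truth, truth), 1)
})

test_that("separable labels decode perfectly; shuffled labels sit at chance", {
  set.seed(21)
  n <- 600
  bt <- seq(0.25, by = 0.5, length.out = n)
  lab <- sample(1:3, n, replace = TRUE)
  rates <- rbind(lab * 100, matrix(rpois(5 * n, 5), 5, n))
  plan <- make_fold_plan(bt, k = 5)
  d <- decode_discrete(rates, lab, plan, n_perm = 0)
  expect_gt(d$balanced_accuracy, 0.99)
  expect_equal(d$chance, 1 / 3)
  ## noise-only decoding stays within the permutation null band
  rates0 <- matrix(rpois(8 * n, 5), 8, n)
  d0 <- decode_discrete(rates0, lab, plan, n_perm = 30, seed = 21)
  band <- quantile(d0$null, c(0.025, 0.975))
  expect_gt(d0$balanced_accuracy, band[1] - 0.02)
  expect_lt(d0$balanced_accuracy, band[2] + 0.02)
  expect_gt(d0$p, 0.05)
})

test_that("fold validity requires every class in train and test", {
  n <- 600
  bt <- seq(0.25, by = 0.5, length.out = n)
  plan <- make_fold_plan(bt, k = 5)
  lab <- rep(1L, n)
  lab[1:10] <- 2L   # class 2 exists only in fold 0's first block
  folds <- arenaneuro:::valid_label_folds(plan, lab)
  expect_length(folds, 0)
  expect_warning(d <- decode_discrete(matrix(rnorm(2 * n), 2, n), lab, plan,
                                      n_perm = 0), "no valid fold")
  expect_true(d$skipped)
})

test_that("residualization removes covariate-spanned signal and keeps the rest", {
  set.seed(23)
  n <- 600
  bt <- seq(0.25, by = 0.5, length.out = n)
  cov <- cbind(stats::filter(rnorm(n), rep(1 / 6, 6), circular = TRUE),
               stats::filter(rnorm(n), rep(1 / 6, 6), circular = TRUE))
  plan <- make_fold_plan(bt, k = 5)
  ## rates that are a pure covariate function -> residuals ~ 0 signal
  rates <- rbind(as.numeric(cov %*% c(2, -1)), as.numeric(cov %*% c(1, 3)))
  res <- residualize_rates(rates, cov, plan)
  tested <- !is.na(res[1, ])
  expect_lt(stats::sd(res[1, tested]), 0.05 * stats::sd(rates[1, tested]))
  ## zero covariate weights: residuals correlate > 0.99 with the original
  ind <- matrix(rnorm(2 * n), 2, n)
  res2 <- residualize_rates(ind, cov, plan)
  expect_gt(cor(res2[1, tested], ind[1, tested]), 0.99)
  ## residualizing twice equals once on noiseless covariate-spanned input
  ## (both passes leave essentially nothing)
  res_once <- res[, tested]
  res_twice <- residualize_rates(res, cov, plan)[, tested]
  expect_lt(max(abs(res_twice - res_once)), 1e-6)
})

test_that("planted tier code survives residualization; kinematic-only does not", {
  fx <- fixture_mixed()
  ses <- fx$ses
  des <- fx$design
  plan <- make_fold_plan(ses$population$bin_centers, des$valid, k = 5)
  cov <- des$X[, des$groups %in% c("VIS", "BODY_KIN", "HEAD_KIN", "DRIFT")]
  raw <- decode_discrete(ses$population$rate, fx$labels$tier, plan,
                         n_perm = 0)
  res_rates <- residualize_rates(ses$population$rate, cov, plan)
  res <- decode_discrete(res_rates, fx$labels$tier, plan, n_perm = 60,
                         perm = "block", seed = 131)
  expect_gt(raw$balanced_accuracy, 0.45)
  expect_gt(res$balanced_accuracy, res$chance)
  expect_lt(res$p, 0.05)
  expect_lt(res$balanced_accuracy, raw$balanced_accuracy)
})

test_that("9-zone decoding has chance 1/9 and skips unvisited zones", {
  fx <- fixture_mixed()
  ses <- fx$ses
  plan <- make_fold_plan(ses$population$bin_centers, fx$design$valid, k = 5)
  sd_res <- spatial_decode(ses$population$rate, fx$labels, plan,
                           n_perm = 10, seed = 7)
  expect_equal(sd_res$tier$chance, 1 / 3)
  if (!is.null(sd_res$zone)) expect_equal(sd_res$zone$chance, 1 / 9)
  ## drop one zone from the labels: the zone task is skipped
  labs2 <- fx$labels
  labs2$zone[labs2$zone == 8] <- NA
  sd2 <- spatial_decode(ses$population$rate, labs2, plan, n_perm = 0)
  expect_null(sd2$zone)
})

test_that("TGM separates sustained from transient planted codes", {
  mk <- function(sg, tg, seed) generate_session(session_config(
    duration_s = 600, n_units = 50, K = 4, seed = seed,
    spatial_gain_hz = 0, syllable_gain_hz = sg, transient_gain_hz = tg,
    frame_weight_hz = 0, baseline_hz = 8,
    model = syllable_model(K = 4, dwell_s = 4)))
  ses_s <- mk(5, 0, 141)
  pop <- ses_s$population
  tg_s <- temporal_generalization(pop$rate, pop$syllable_bin,
                                  pop$bin_centers, seed = 141)
  post <- which(tg_s$lags_s >= 0.5)
  A <- tg_s$accuracy[post, post]
  expect_gt(mean(diag(A)), tg_s$chance + 0.05)
  ## sustained code: broad generalization in the post-onset quadrant
  expect_gte(mean(A[row(A) != col(A)]), 0.8 * mean(diag(A)))

  ses_t <- mk(0, 10, 142)
  pop_t <- ses_t$population
  tg_t <- temporal_generalization(pop_t$rate, pop_t$syllable_bin,
                                  pop_t$bin_centers, seed = 142)
  i0 <- which(tg_t$lags_s == 0)
  far <- abs(tg_t$lags_s) >= 1
  ## transient code: accuracy confined to |train - test| < 1 s
  expect_gt(tg_t$accuracy[i0, i0], tg_t$chance + 0.3)
  expect_lt(mean(tg_t$accuracy[i0, far]), tg_t$chance + 0.05)
  expect_lt(mean(tg_t$accuracy[far, i0]), tg_t$chance + 0.05)
})

test_that("confusion-vs-transition: identity, null calibration, planted chain", {
  K <- 6
  set.seed(25)
  Tm <- matrix(runif(K * K), K, K)
  diag(Tm) <- 0
  Tm <- Tm / rowSums(Tm)
  ## confusion equal to the transition matrix: rho = 1
  cvt <- confusion_vs_transitions(Tm * 100, Tm, n_perm = 200, seed = 1)
  expect_equal(cvt$rho, 1)
  expect_lt(cvt$p, 0.05)
  ## independent random matrices: p roughly uniform over replicates
  ps <- replicate(60, {
    A <- matrix(runif(K * K), K, K)
    B <- matrix(runif(K * K), K, K); B <- B / rowSums(B)
    confusion_vs_transitions(A, B, n_perm = 60,
                             seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_true(confusion_vs_transitions(diag(3), diag(3) / 1,
                                       n_perm = 10)$flagged)
})

test_that("syllable tuning: planted gain structure appears in correlations", {
  set.seed(26)
  n <- 800
  lab <- sample(1:5, n, replace = TRUE)
  g1 <- c(0, 2, 4, -2, 1)
  g2 <- 2 * g1                       # same pattern, different gain
  g3 <- c(4, 4, -2, -2, 1)           # orthogonal pattern (centered)
  mk <- function(g) rpois(n, pmax(8 + g[lab], 0.1)) / 0.5
  rates <- rbind(mk(g1), mk(g2), mk(g3), rep(10, n))
  tun <- syllable_tuning(rates, lab)
  expect_equal(tun$excluded, 4L)      # zero-variance unit dropped
  expect_gt(tun$unit_similarity[1, 2], 0.9)
  expect_lt(abs(tun$unit_similarity[1, 3]), 0.5)
  ## selectivity of a planted 2-SD preferred syllable
  zsel <- tun$selectivity[1]
  z_expected <- max(abs(scale(8 + g1)))
  expect_lt(abs(zsel - z_expected), 0.4)
})

test_that("lagged label decoding peaks at zero shift", {
  set.seed(27)
  n <- 600
  bt <- seq(0.25, by = 0.5, length.out = n)
  lab <- rep(sample(1:3, n / 4, replace = TRUE), each = 4)[1:n]
  rates <- rbind(lab * 10 + rnorm(n, 0, 3),
                 -lab * 8 + rnorm(n, 0, 3),
                 matrix(rpois(3 * n, 5), 3, n))
  plan <- make_fold_plan(bt, k = 5)
  acc <- vapply(c(-4, 0, 4), function(s) {
    ls <- if (s == 0) lab else
      if (s > 0) c(lab[-seq_len(s)], rep(NA, s)) else
        c(rep(NA, -s), lab[seq_len(n + s)])
    decode_discrete(rates, ls, plan, n_perm = 0)$balanced_accuracy
  }, numeric(1))
  expect_gt(acc[2], acc[1])
  expect_gt(acc[2], acc[3])
})
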