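#' Build the three frame-specific feature sets
#'
#' Six per-bin features per frame: center-of-mass velocity (3) and
#' displacement from the arena center (3), expressed in allocentric (world),
#' body-centric (rotation by minus body yaw; gravity axis preserved) or
#' head-centric (inverse of the full 3D head rotation) axes. All three sets
#' are derived from the same underlying vectors, so vector norms are
#' frame-invariant and the three design matrices are dimension-matched. Bins
#' invalid in any frame (e.g. missing head orientation) are excluded from all
#' three for sample-matched comparisons.
#'
#' @param features per-bin feature table from [compute_feature_groups()]
#' @param kin_bin per-bin orientation table with `body_yaw`, `head_yaw`,
#'   `head_pitch`, `head_roll` (see [bin_orientation()])
#' @param arena an `arena_spec`
#' @param displacement "center" (displacement from the arena center, the
#'   default) or "step" (per-bin position change)
#' @return list of three `frame_feature_set`s (`allo`, `body`, `head`), each
#'   a bins x 6 matrix, plus shared `valid` and `speed`
#' @export
build_frame_features <- function(features, kin_bin, arena,
                                 displacement = c("center", "step")) {
  displacement <- match.arg(displacement)
  pos <- cbind(features$POS.com_x, features$POS.com_y, features$POS.com_z)
  bin_s <- stats::median(diff(features$bin_center_s))
  vel <- apply(pos, 2, function(x) c(NA, diff(x)) / bin_s)
  disp <- if (displacement == "center") sweep(pos, 2, arena$center) else
    apply(pos, 2, function(x) c(NA, diff(x)))
  allo <- cbind(vel, disp)
  colnames(allo) <- c("vel_x", "vel_y", "vel_z", "disp_x", "disp_y", "disp_z")
  body <- cbind(rotate_yaw(vel, -kin_bin$body_yaw),
                rotate_yaw(disp, -kin_bin$body_yaw))
  head <- cbind(rotate_head_inv(vel, kin_bin$head_yaw, kin_bin$head_pitch,
                                kin_bin$head_roll),
                rotate_head_inv(disp, kin_bin$head_yaw, kin_bin$head_pitch,
                                kin_bin$head_roll))
  colnames(body) <- colnames(head) <- colnames(allo)
  valid <- (if ("valid" %in% names(features)) features$valid else TRUE) &
    stats::complete.cases(allo) & stats::complete.cases(body) &
    stats::complete.cases(head)
  list(allo = allo, body = body, head = head, valid = valid,
       speed = sqrt(rowSums(vel^2)),
       bin_centers = features$bin_center_s)
}

#' Bin-average orientation angles onto the neural bin grid
#' @param kin frame-level kinematics from [compute_kinematics()]
#' @param bin_s bin width (s)
#' @return data.frame of per-bin circular-mean `body_yaw`, `head_yaw`,
#'   `head_pitch`, `head_roll`
#' @export
bin_orientation <- function(kin, bin_s = 0.5) {
  t_end <- max(kin$time_s) + stats::median(diff(kin$time_s))
  n_bin <- floor(t_end / bin_s + 1e-9)
  bin_of <- pmin(pmax(floor(kin$time_s / bin_s) + 1L, 1L), n_bin)
  cm <- function(a) {
    s <- tapply(a, bin_of, function(x) circ_mean(x[is.finite(x)]))
    v <- rep(NA_real_, n_bin); v[as.integer(names(s))] <- s; v
  }
  data.frame(bin_center_s = (seq_len(n_bin) - 0.5) * bin_s,
             body_yaw = cm(kin$body_yaw), head_yaw = cm(kin$head_yaw),
             head_pitch = cm(kin$head_pitch), head_roll = cm(kin$head_roll))
}

#' Compare reference-frame encoding models for units
#'
#' Fits a base model (speed + linear time drift) and three complexity-matched
#' frame models (base + 6 frame features each), each selecting its own
#' regularization by nested cross-validation. The winner frame is the model
#' with the largest cross-validated R^2 improvement over base; winner is
#' "none" if no frame improves on base. Ties break allo > body > head.
#'
#' @param Y bins x units rate matrix
#' @param frames from [build_frame_features()]
#' @param plan a `fold_plan` (build it with the frames' shared valid mask)
#' @param min_bins inclusion threshold
#' @return data.frame per unit: dR2_allo/body/head, r2_base, winner, rf_index
#' @export
compare_frames <- function(Y, frames, plan, min_bins = 150) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  base_X <- cbind(speed = frames$speed, drift = seq_len(n) / n)
  fit_base <- fit_ridge_encoder(Y, base_X, plan, min_bins = min_bins)
  d <- list()
  for (fr in c("allo", "body", "head")) {
    Xf <- cbind(base_X, frames[[fr]])
    fit_f <- fit_ridge_encoder(Y, Xf, plan, min_bins = min_bins)
    d[[fr]] <- fit_f$r2 - fit_base$r2
  }
  winner <- character(ncol(Y))
  rf <- rep(NA_real_, ncol(Y))
  for (u in seq_len(ncol(Y))) {
    dr <- c(allo = d$allo[u], body = d$body[u], head = d$head[u])
    if (anyNA(dr)) { winner[u] <- NA_character_; next }
    if (all(dr <= 0)) winner[u] <- "none"
    else winner[u] <- names(dr)[which.max(dr)]  # ties: allo > body > head
    rf[u] <- rf_index(dr["allo"], dr["body"])
  }
  out <- data.frame(unit = seq_len(ncol(Y)),
                    dR2_allo = d$allo, dR2_body = d$body, dR2_head = d$head,
                    r2_base = fit_base$r2, winner = winner, rf_index = rf)
  class(out) <- c("frame_comparison", "data.frame")
  out
}

#' Reference-frame index
#'
#' Normalized contrast of rectified unique variance:
#' `RF = (U_a - U_b) / (U_a + U_b)` with `U = max(dR2, 0)`. +1 is purely
#' allocentric, -1 purely body-centric; undefined (NA) when both are <= 0.
#'
#' @param dr2_allo,dr2_body improvements over base for the two frames
#' @return value in `[-1, 1]` or NA
#' @export
rf_index <- function(dr2_allo, dr2_body) {
  ua <- pmax(dr2_allo, 0)
  ub <- pmax(dr2_body, 0)
  ifelse(ua + ub <= 0, NA_real_, (ua - ub) / (ua + ub))
}

#' Tier-stratified reference-frame comparison
#'
#' Temporal folds are constructed on the full session timeline and
#' intersected with the bins of each height tier, preserving temporal
#' blocking while restricting train and test to one tier. A unit-tier cell is
#' valid when the tier has >= 50 bins, >= 2 folds remain non-empty, >= 20
#' test bins remain, and the unit's rate variance in the tier exceeds 1e-6.
#' Floor-to-ceiling RF-index differences over units valid in all three tiers
#' are assessed with a paired Wilcoxon signed-rank test.
#'
#' @param Y bins x units rate matrix
#' @param frames from [build_frame_features()]
#' @param plan full-session `fold_plan`
#' @param tiers per-bin tier labels (1, 2, 3)
#' @param min_bins_tier minimum bins per tier (50)
#' @param min_test_bins minimum pooled test bins (20)
#' @param min_folds minimum valid folds (2)
#' @return list: `table` (unit x tier rows with dR2s, rf_index, valid flag),
#'   `wilcoxon` (the paired floor-vs-ceiling test, or NULL)
#' @export
tier_stratified_compare <- function(Y, frames, plan, tiers,
                                    min_bins_tier = 50, min_test_bins = 20,
                                    min_folds = 2) {
  Y <- as.matrix(Y)
  rows <- list()
  for (tr in sort(unique(stats::na.omit(tiers)))) {
    in_tier <- which(!is.na(tiers) & tiers == tr)
    tier_plan <- plan
    n_ok <- 0L
    test_n <- 0L
    tier_plan$folds <- lapply(plan$folds, function(f)
      list(test = intersect(f$test, in_tier),
           train = intersect(f$train, in_tier)))
    for (f in tier_plan$folds)
      if (length(f$test) && length(f$train)) {
        n_ok <- n_ok + 1L
        test_n <- test_n + length(f$test)
      }
    tier_plan$folds <- Filter(function(f)
      length(f$test) > 0 && length(f$train) > 0, tier_plan$folds)
    enough <- length(in_tier) >= min_bins_tier && n_ok >= min_folds &&
      test_n >= min_test_bins
    if (enough) {
      cmp <- compare_frames(Y, frames, tier_plan, min_bins = min_test_bins)
      vvar <- apply(Y[in_tier, , drop = FALSE], 2, stats::var)
      cmp$valid <- vvar > 1e-6 & !is.na(cmp$dR2_allo)
    } else {
      cmp <- data.frame(unit = seq_len(ncol(Y)), dR2_allo = NA_real_,
                        dR2_body = NA_real_, dR2_head = NA_real_,
                        r2_base = NA_real_, winner = NA_character_,
                        rf_index = NA_real_, valid = FALSE)
    }
    cmp$tier <- tr
    rows[[length(rows) + 1]] <- cmp
  }
  tab <- do.call(rbind, rows)
  ## paired test over units valid (and with defined RF-index) in all tiers
  wtest <- NULL
  tl <- sort(unique(tab$tier))
  if (all(c(1, 3) %in% tl)) {
    f1 <- tab[tab$tier == 1 & tab$valid, c("unit", "rf_index")]
    f3 <- tab[tab$tier == 3 & tab$valid, c("unit", "rf_index")]
    m <- merge(f1, f3, by = "unit", suffixes = c("_floor", "_ceiling"))
    m <- m[stats::complete.cases(m), ]
    if (nrow(m) >= 3) {
      wtest <- stats::wilcox.test(m$rf_index_floor, m$rf_index_ceiling,
                                  paired = TRUE, exact = FALSE)
      wtest$n_pairs <- nrow(m)
    }
  }
  list(table = tab, wilcoxon = wtest)
}
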