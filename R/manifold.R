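#' Continuous label matrix for supervised embedding families
#'
#' Spatial-lite: horizontal center-of-mass position, locomotor speed and head
#' yaw rate (com_x, com_y, speed, yaw_rate) — vertical position is never
#' included, so height-related structure in the embedding cannot come from
#' supervision. Behavior: the full set including com_z.
#'
#' @param features per-bin feature table from [compute_feature_groups()]
#' @param family "spatial_lite" or "behavior"
#' @return bins x p numeric label matrix
#' @export
embedding_labels <- function(features, family = c("spatial_lite", "behavior")) {
  family <- match.arg(family)
  lab <- cbind(com_x = features$POS.com_x, com_y = features$POS.com_y,
               speed = features$BODY_KIN.speed,
               yaw_rate = features$HEAD_KIN.yaw_rate)
  if (family == "behavior")
    lab <- cbind(lab[, 1:2, drop = FALSE], com_z = features$POS.com_z,
                 lab[, 3:4, drop = FALSE])
  stopifnot(family == "behavior" || !("com_z" %in% colnames(lab)))
  lab
}

#' Fit per-fold population embeddings
#'
#' The mandatory backend is a linear principal-component embedding of the
#' z-scored rate matrix, fit on each training fold only (component signs
#' fixed by the largest-loading rule) with test bins projected through the
#' train-fold transform. A contrastive backend slot exists for supervised
#' alternatives; when unavailable the linear baseline is returned with a
#' warning. The `labels` matrix documents the supervision a contrastive
#' backend would receive (and is audited for the spatial_lite family).
#'
#' @param rates units x bins rate matrix
#' @param labels label matrix from [embedding_labels()] (not used by the
#'   linear backend)
#' @param family "spatial_lite" or "behavior"
#' @param dim embedding dimension (8 for decoding parity, 3 for context /
#'   drift analyses)
#' @param plan a `fold_plan` (2 s embargo) for held-out quantitative use, or
#'   NULL for a single all-data fit (the visualization-quality space used by
#'   the context-ratio and transition-dynamics statistics, whose geometry
#'   must live in one common coordinate system)
#' @param backend "linear" or "contrastive"
#' @return an `embedding_model`: `coords` (bins x dim; held-out when a plan
#'   is given), `fold_of` per bin, `transforms` per fold, `family`, `dim`,
#'   `backend`
#' @export
fit_embedding <- function(rates, labels, family = "spatial_lite", dim = 8,
                          plan = NULL, backend = c("linear", "contrastive")) {
  backend <- match.arg(backend)
  if (backend == "contrastive") {
    warning("contrastive backend unavailable; returning linear embedding")
    backend <- "linear"
  }
  if (family == "spatial_lite" && "com_z" %in% colnames(labels))
    stop("spatial_lite labels must not contain vertical position")
  rt <- t(rates)
  dim <- min(dim, ncol(rt))
  if (is.null(plan)) {
    ok <- which(stats::complete.cases(rt))
    st <- std_fit(rt[ok, , drop = FALSE])
    Xs <- std_apply(rt[ok, , drop = FALSE], st)
    pc <- stats::prcomp(Xs, center = FALSE, rank. = dim)
    rot <- pc$rotation
    for (j in seq_len(ncol(rot))) {
      i <- which.max(abs(rot[, j]))
      if (rot[i, j] < 0) rot[, j] <- -rot[, j]
    }
    coords <- matrix(NA_real_, nrow(rt), dim)
    coords[ok, ] <- Xs %*% rot
    return(structure(list(coords = coords, fold_of = rep(NA_integer_,
                                                         nrow(rt)),
                          transforms = list(list(std = st, rotation = rot)),
                          family = family, dim = dim, backend = backend),
                     class = "embedding_model"))
  }
  coords <- matrix(NA_real_, nrow(rt), dim)
  fold_of <- rep(NA_integer_, nrow(rt))
  transforms <- vector("list", length(plan$folds))
  for (fi in seq_along(plan$folds)) {
    f <- plan$folds[[fi]]
    if (!length(f$test) || !length(f$train)) next
    st <- std_fit(rt[f$train, , drop = FALSE])
    Xs <- std_apply(rt[f$train, , drop = FALSE], st)
    pc <- stats::prcomp(Xs, center = FALSE, rank. = dim)
    rot <- pc$rotation
    for (j in seq_len(ncol(rot))) {
      i <- which.max(abs(rot[, j]))
      if (rot[i, j] < 0) rot[, j] <- -rot[, j]
    }
    coords[f$test, ] <- std_apply(rt[f$test, , drop = FALSE], st) %*% rot
    fold_of[f$test] <- fi
    transforms[[fi]] <- list(std = st, rotation = rot)
  }
  structure(list(coords = coords, fold_of = fold_of, transforms = transforms,
                 family = family, dim = dim, backend = backend),
            class = "embedding_model")
}

#' k-nearest-neighbor decoding in embedding space
#'
#' Labels of test bins are predicted from the k nearest training-bin
#' embedding coordinates (Euclidean metric); balanced accuracy per fold.
#'
#' @param embedding an `embedding_model` or bins x d coordinate matrix
#' @param labels per-bin discrete labels
#' @param plan the `fold_plan` used for the embedding
#' @param k neighbors (5)
#' @return a `decode_result`-like list: `balanced_accuracy`, `per_fold`,
#'   `chance`, `pred`
#' @export
knn_decode <- function(embedding, labels, plan, k = 5) {
  coords <- if (inherits(embedding, "embedding_model")) embedding$coords
            else as.matrix(embedding)
  folds <- valid_label_folds(plan, labels)
  preds <- rep(NA_character_, length(labels))
  per_fold <- numeric(0)
  for (f in folds) {
    tr <- f$train[stats::complete.cases(coords[f$train, , drop = FALSE])]
    te <- f$test[stats::complete.cases(coords[f$test, , drop = FALSE])]
    if (!length(tr) || !length(te)) next
    p <- as.character(class::knn(coords[tr, , drop = FALSE],
                                 coords[te, , drop = FALSE],
                                 factor(labels[tr]), k = k))
    preds[te] <- p
    per_fold <- c(per_fold, balanced_accuracy(labels[te], p))
  }
  tested <- !is.na(preds) & !is.na(labels)
  classes <- unique(labels[!is.na(labels)])
  list(balanced_accuracy = balanced_accuracy(labels[tested], preds[tested]),
       per_fold = per_fold, chance = 1 / length(classes), pred = preds)
}

#' Context ratio: does the same behavior occupy different population space
#' in different spatial contexts?
#'
#' For each syllable present in at least two tiers with `min_bins` bins
#' each, between-context separation is the root-mean-square distance between
#' bins of the same syllable in different tiers, and within-context spread
#' is the RMS distance between bins of the same (syllable, tier) cell (both
#' computed in closed form from per-cell means and variances:
#' `E||x - y||^2 = tr(S_1) + tr(S_2) + ||mu_1 - mu_2||^2` for cross-cell
#' pairs). Their ratio is exactly 1 when the same syllable occupies the same
#' region of population space in every tier, and grows with between-tier
#' centroid separation. The session statistic averages the per-syllable
#' ratios; the null permutes tier assignments within each syllable.
#'
#' @param coords bins x d embedding coordinates (3D spatial_lite space)
#' @param syllables per-bin syllable labels
#' @param tiers per-bin tier labels
#' @param min_bins minimum bins per (syllable, tier) cell (20)
#' @param n_perm permutations (500)
#' @param aggregate "mean" (default) over tier pairs or "max"
#' @param seed integer seed
#' @return list: `ratio`, `p`, `per_syllable`, `null`, `n_cells`
#' @export
context_ratio <- function(coords, syllables, tiers, min_bins = 20,
                          n_perm = 500, aggregate = c("mean", "max"),
                          seed = 1) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else max
  ok <- !is.na(syllables) & !is.na(tiers) &
    stats::complete.cases(coords)
  coords <- as.matrix(coords)[ok, , drop = FALSE]
  syl <- syllables[ok]; tr <- tiers[ok]

  ratio_of <- function(tr_vec) {
    per <- c(); ncell <- 0L
    for (s in unique(syl)) {
      i <- which(syl == s)
      tt <- table(tr_vec[i])
      use <- as.integer(names(tt)[tt >= min_bins])
      if (length(use) < 2) next
      mus <- lapply(use, function(z)
        colMeans(coords[i[tr_vec[i] == z], , drop = FALSE]))
      sp2 <- vapply(use, function(z) {
        C <- coords[i[tr_vec[i] == z], , drop = FALSE]
        sum(apply(C, 2, stats::var))
      }, numeric(1))
      pw <- utils::combn(length(use), 2)
      bet2 <- apply(pw, 2, function(p2)
        sp2[p2[1]] + sp2[p2[2]] +
          sum((mus[[p2[1]]] - mus[[p2[2]]])^2))
      win2 <- apply(pw, 2, function(p2) sp2[p2[1]] + sp2[p2[2]])
      per <- c(per, agg(sqrt(bet2 / win2)))
      ncell <- ncell + length(use)
    }
    if (!length(per)) return(NULL)
    list(per = per, ratio = mean(per), n_cells = ncell)
  }
  obs <- ratio_of(tr)
  if (is.null(obs)) return(list(ratio = NA_real_, p = NA_real_,
                                undefined = TRUE))
  set.seed(substream_seed(seed, "context-perm"))
  null <- numeric(n_perm)
  for (s in seq_len(n_perm)) {
    trp <- tr
    for (sy in unique(syl)) {
      i <- which(syl == sy)
      trp[i] <- tr[sample(i)]
    }
    r <- ratio_of(trp)
    null[s] <- if (is.null(r)) NA_real_ else r$ratio
  }
  null <- null[is.finite(null)]
  list(ratio = obs$ratio, per_syllable = obs$per,
       p = perm_pvalue(obs$ratio, null), null = null,
       n_cells = obs$n_cells, undefined = FALSE)
}

#' Variance attribution per embedding dimension (eta-squared)
#'
#' Per dimension and label family, eta^2 = SS_between / SS_total for a
#' one-way grouping by the label.
#'
#' @param coords bins x d embedding coordinates
#' @param syllables,tiers per-bin labels
#' @return data.frame: dim, eta2_syllable, eta2_tier
#' @export
variance_per_dimension <- function(coords, syllables, tiers) {
  coords <- as.matrix(coords)
  eta2 <- function(x, g) {
    ok <- !is.na(x) & !is.na(g)
    x <- x[ok]; g <- g[ok]
    if (length(unique(g)) < 2) return(0)
    mu <- mean(x)
    ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - mu)^2))
    sst <- sum((x - mu)^2)
    if (sst <= 0) 0 else ssb / sst
  }
  data.frame(
    dim = seq_len(ncol(coords)),
    eta2_syllable = apply(coords, 2, eta2, g = syllables),
    eta2_tier = apply(coords, 2, eta2, g = tiers))
}

## circular shift of rows by k (wraps)
circ_shift_rows <- function(M, k) {
  n <- nrow(M)
  k <- ((k - 1) %% n) + 1
  if (k == n) return(M)
  M[c((k + 1):n, 1:k), , drop = FALSE]
}

#' Anticipatory drift toward the upcoming syllable centroid
#'
#' In a +/- `window_s` window around each syllable onset, computes the mean
#' cosine similarity (about the global mean state) between the embedded
#' neural state and the centroids of the next and current syllables, per
#' lag. The ramp statistic is the least-squares slope of the next-centroid
#' similarity over pre-onset lags `[-window_s, 0]`. The null recomputes the
#' statistic under uniform circular shifts of the embedding series relative
#' to the transition times, preserving temporal autocorrelation.
#'
#' @param coords bins x d embedding coordinates (3D behavior space)
#' @param labels per-bin syllable labels
#' @param bin_centers bin-center times (s)
#' @param window_s half window (2 s)
#' @param n_shift circular shifts for the null (500)
#' @param min_transitions required transitions (20)
#' @param seed integer seed
#' @return a `drift_result`: `lags_s`, `sim_next`, `sim_current`,
#'   `ramp_slope`, `p`, `null`, `n_transitions`
#' @export
anticipatory_drift <- function(coords, labels, bin_centers, window_s = 2,
                               n_shift = 500, min_transitions = 20,
                               seed = 1) {
  coords <- as.matrix(coords)
  bin_s <- stats::median(diff(bin_centers))
  half <- round(window_s / bin_s)
  lags <- (-half):half
  n <- length(labels)
  trans <- which(!is.na(labels[-1]) & !is.na(labels[-n]) &
                 labels[-1] != labels[-n]) + 1L
  trans <- trans[trans + min(lags) >= 1 & trans + max(lags) <= n]
  ## clean transitions only: the outgoing bout must span the whole
  ## pre-onset window, so pre-onset similarity reflects the current
  ## syllable's state rather than older bouts
  clean <- vapply(trans, function(b0) {
    pre <- labels[b0 + min(lags):(-1)]
    !anyNA(pre) && all(pre == labels[b0 - 1L])
  }, logical(1))
  trans <- trans[clean]
  flagged <- length(trans) < min_transitions
  ## session-wide syllable centroids (all bins of each syllable)
  cls <- sort(unique(stats::na.omit(labels)))
  cent <- t(vapply(cls, function(k) {
    i <- which(labels == k & stats::complete.cases(coords))
    colMeans(coords[i, , drop = FALSE])
  }, numeric(ncol(coords))))
  mu <- colMeans(coords, na.rm = TRUE)
  cosim <- function(a, b) {
    a <- a - mu; b <- b - mu
    sum(a * b) / max(sqrt(sum(a^2)) * sqrt(sum(b^2)), 1e-12)
  }
  drift_stat <- function(C) {
    sn <- matrix(NA_real_, length(trans), length(lags))
    sc <- matrix(NA_real_, length(trans), length(lags))
    for (ti in seq_along(trans)) {
      b0 <- trans[ti]
      nx <- match(labels[b0], cls)
      cu <- match(labels[b0 - 1L], cls)
      for (li in seq_along(lags)) {
        x <- C[b0 + lags[li], ]
        if (anyNA(x)) next
        sn[ti, li] <- cosim(x, cent[nx, ])
        sc[ti, li] <- cosim(x, cent[cu, ])
      }
    }
    m_next <- colMeans(sn, na.rm = TRUE)
    m_cur <- colMeans(sc, na.rm = TRUE)
    pre <- which(lags < 0)  # strictly pre-onset bins
    ## per-transition pre-onset slope; the ramp statistic is its t-score
    ## across transitions, so the circular-shift null is exchangeable even
    ## though aligned and shifted states differ in variability
    lp <- lags[pre] * bin_s
    lc <- lp - mean(lp)
    den <- sum(lc^2)
    sl_i <- as.numeric(sn[, pre, drop = FALSE] %*% lc) / den
    sl_i <- sl_i[is.finite(sl_i)]
    slope <- mean(sl_i)
    tstat <- if (length(sl_i) > 2 && stats::sd(sl_i) > 0)
      slope / (stats::sd(sl_i) / sqrt(length(sl_i))) else 0
    list(sim_next = m_next, sim_current = m_cur,
         slope = slope, tstat = tstat)
  }
  obs <- drift_stat(coords)
  set.seed(substream_seed(seed, "drift-shift"))
  shifts <- sample.int(n - 1, min(n_shift, n - 1), replace = n_shift > n - 1)
  null <- vapply(shifts, function(k)
    drift_stat(circ_shift_rows(coords, k))$tstat, numeric(1))
  null <- null[is.finite(null)]
  structure(list(lags_s = lags * bin_s, sim_next = obs$sim_next,
                 sim_current = obs$sim_current, ramp_slope = obs$slope,
                 ramp_t = obs$tstat,
                 p = perm_pvalue(obs$tstat, null), null = null,
                 n_transitions = length(trans), flagged = flagged),
            class = "drift_result")
}

#' Neural state velocity elevation at behavioral transitions
#'
#' Compares the mean Euclidean step between consecutive embedding states in
#' transition windows against non-transition baseline bins (all bins within
#' +/- `exclude_s` of any transition are excluded from the baseline).
#' Elevation is in percent above baseline; the null circularly shifts the
#' embedding series relative to the transitions.
#'
#' @param coords bins x d embedding coordinates
#' @param labels per-bin syllable labels
#' @param bin_centers bin-center times
#' @param exclude_s exclusion half-width for baseline (2 s)
#' @param n_shift circular shifts (500)
#' @param min_baseline required baseline bins (100)
#' @param seed integer seed
#' @return list: `elevation_pct`, `p`, `null`, `n_baseline`
#' @export
transition_velocity <- function(coords, labels, bin_centers, exclude_s = 2,
                                n_shift = 500, min_baseline = 100,
                                seed = 1) {
  coords <- as.matrix(coords)
  n <- length(labels)
  if (n < 3) stop("too few bins")
  trans <- which(!is.na(labels[-1]) & !is.na(labels[-n]) &
                 labels[-1] != labels[-n]) + 1L
  if (!length(trans)) stop("no transitions in session")
  bin_s <- stats::median(diff(bin_centers))
  half <- round(exclude_s / bin_s)
  near <- rep(FALSE, n)
  for (d in -half:half)
    near[pmin(pmax(trans + d, 1L), n)] <- TRUE
  step_of <- function(C) {
    d <- sqrt(rowSums((C[-1, , drop = FALSE] - C[-nrow(C), , drop = FALSE])^2))
    c(NA, d)  # step into bin i
  }
  stat_of <- function(C) {
    st <- step_of(C)
    base <- st[!near & is.finite(st)]
    twin <- st[trans][is.finite(st[trans])]
    if (!length(base) || !length(twin)) return(NA_real_)
    (mean(twin) - mean(base)) / mean(base) * 100
  }
  st0 <- step_of(coords)
  n_base <- sum(!near & is.finite(st0))
  if (n_base < min_baseline)
    return(list(elevation_pct = NA_real_, p = NA_real_, undefined = TRUE,
                n_baseline = n_base))
  obs <- stat_of(coords)
  set.seed(substream_seed(seed, "velocity-shift"))
  shifts <- sample.int(n - 1, min(n_shift, n - 1), replace = n_shift > n - 1)
  null <- vapply(shifts, function(k) stat_of(circ_shift_rows(coords, k)),
                 numeric(1))
  null <- null[is.finite(null)]
  list(elevation_pct = obs, p = perm_pvalue(obs, null), null = null,
       n_baseline = n_base, undefined = FALSE)
}
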