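## multinomial logistic decoder with balanced class weights; features are
## z-scored with training statistics inside each fold
fit_multinom <- function(Xtr, ytr, maxit = 120) {
  ytr <- factor(ytr)
  tab <- table(ytr)
  w <- as.numeric(length(ytr) / (length(tab) * tab[ytr]))
  df <- data.frame(Xtr)
  df$.y <- ytr
  utils::capture.output(
    m <- nnet::multinom(.y ~ ., data = df, weights = w, maxit = maxit,
                        MaxNWts = 100000, trace = FALSE))
  m
}
predict_multinom <- function(m, Xte) {
  as.character(stats::predict(m, newdata = data.frame(Xte)))
}

## folds restricted to bins with labels; a fold is valid only when train and
## test both contain every class
valid_label_folds <- function(plan, labels) {
  ok_bins <- which(!is.na(labels))
  classes <- unique(labels[ok_bins])
  folds <- lapply(plan$folds, function(f)
    list(test = intersect(f$test, ok_bins),
         train = intersect(f$train, ok_bins)))
  keep <- vapply(folds, function(f)
    length(f$test) > 0 && length(f$train) > 0 &&
      all(classes %in% labels[f$train]) && all(classes %in% labels[f$test]),
    logical(1))
  folds[keep]
}

decode_once <- function(rates_t, labels, folds, maxit = 120) {
  preds <- rep(NA_character_, length(labels))
  per_fold <- numeric(0)
  for (f in folds) {
    st <- std_fit(rates_t[f$train, , drop = FALSE])
    m <- fit_multinom(std_apply(rates_t[f$train, , drop = FALSE], st),
                      labels[f$train], maxit = maxit)
    p <- predict_multinom(m, std_apply(rates_t[f$test, , drop = FALSE], st))
    preds[f$test] <- p
    per_fold <- c(per_fold, balanced_accuracy(labels[f$test], p))
  }
  tested <- !is.na(preds)
  list(balanced_accuracy = balanced_accuracy(labels[tested], preds[tested]),
       per_fold = per_fold, pred = preds)
}

#' Decode discrete labels from population rates
#'
#' Multinomial logistic regression with balanced class weights, blocked /
#' embargoed temporal cross-validation, per-fold train-statistics z-scoring,
#' and a permutation null sharing the identical fold structure.
#'
#' @param rates units x bins rate matrix (or a `binned_population`)
#' @param labels per-bin discrete labels (NA = unused bin)
#' @param plan a `fold_plan`
#' @param n_perm permutations for the null (label series permuted; use
#'   `perm = "block"` with `chunk_s` for contiguous block permutation)
#' @param perm "full" (uniform permutation) or "block" (10 s chunks)
#' @param chunk_s chunk length for block permutation
#' @param seed integer seed
#' @return a `decode_result`: `balanced_accuracy`, `per_fold`, `chance`,
#'   `null`, `p`, `pred`, `confusion`
#' @export
decode_discrete <- function(rates, labels, plan, n_perm = 100,
                            perm = c("full", "block"), chunk_s = 10,
                            seed = 1) {
  perm <- match.arg(perm)
  if (inherits(rates, "binned_population")) rates <- rates$rate
  rt <- t(rates)
  folds <- valid_label_folds(plan, labels)
  if (!length(folds)) {
    warning("no valid fold: some class missing from train or test")
    return(structure(list(balanced_accuracy = NA_real_, skipped = TRUE),
                     class = "decode_result"))
  }
  obs <- decode_once(rt, labels, folds)
  classes <- sort(unique(labels[!is.na(labels)]))
  chance <- 1 / length(classes)
  null <- numeric(n_perm)
  if (n_perm > 0) {
    set.seed(substream_seed(seed, "decode-perm"))
    lab_idx <- which(!is.na(labels))
    for (s in seq_len(n_perm)) {
      pl <- labels
      if (perm == "full") {
        pl[lab_idx] <- labels[sample(lab_idx)]
      } else {
        ord <- block_permutation(plan$bin_times[lab_idx], chunk_s)
        pl[lab_idx] <- labels[lab_idx][ord]
      }
      pf <- valid_label_folds(plan, pl)
      null[s] <- if (length(pf))
        decode_once(rt, pl, pf)$balanced_accuracy else NA_real_
    }
  }
  null <- null[is.finite(null)]
  p <- if (length(null)) perm_pvalue(obs$balanced_accuracy, null) else NA_real_
  tested <- !is.na(obs$pred) & !is.na(labels)
  conf <- table(factor(labels[tested], levels = classes),
                factor(obs$pred[tested], levels = classes))
  structure(list(balanced_accuracy = obs$balanced_accuracy,
                 per_fold = obs$per_fold, chance = chance, null = null,
                 p = p, pred = obs$pred, confusion = conf, skipped = FALSE),
            class = "decode_result")
}

#' Residualize unit rates against covariates with held-out fits
#'
#' Per unit, the covariate model (e.g. VIS + BODY_KIN + HEAD_KIN + drift
#' columns) is fit on each fold's training bins by ridge at a near-zero
#' penalty (the ridge acts as a fallback for singular covariates) and
#' residuals are formed from held-out predictions only.
#'
#' @param rates units x bins rate matrix
#' @param covariates bins x p covariate design
#' @param plan a `fold_plan`
#' @param alpha ridge penalty (small; reported)
#' @return units x bins residual matrix (NA outside tested bins)
#' @export
residualize_rates <- function(rates, covariates, plan, alpha = 1e-6) {
  Y <- t(rates)
  res <- ridge_cv_fixed_alpha(Y, covariates, plan, alpha)
  out <- t(Y - res$pred)
  attr(out, "alpha") <- alpha
  out
}

#' Spatial decoding: height tiers and composite zones
#'
#' Tier (3-class) and zone (9-class) decoding with a block-permutation null
#' (contiguous 10 s label chunks). The zone variant is skipped when a zone is
#' never visited.
#'
#' @param rates units x bins rate matrix
#' @param spatial per-bin labels from [assign_spatial_labels()]
#' @param plan a `fold_plan`
#' @param n_perm block permutations (100)
#' @param seed integer seed
#' @return list with `tier` and `zone` `decode_result`s (zone may be NULL)
#' @export
spatial_decode <- function(rates, spatial, plan, n_perm = 100, seed = 1) {
  tier <- decode_discrete(rates, spatial$tier, plan, n_perm = n_perm,
                          perm = "block", seed = seed)
  zone <- NULL
  zl <- spatial$zone
  if (length(unique(stats::na.omit(zl))) == 9) {
    zone <- decode_discrete(rates, zl, plan, n_perm = n_perm,
                            perm = "block", seed = seed + 1)
  }
  list(tier = tier, zone = zone)
}

#' Temporal generalization matrix around syllable transitions
#'
#' Extracts peri-transition windows (default +/- 4 s at the bin resolution),
#' trains a classifier at each train lag and tests it at every test lag,
#' using stratified folds over transitions with a temporal embargo (train
#' transitions within `embargo_s` of a test transition are dropped). Features
#' are z-scored and reduced to at most `max_pc` principal components with
#' train-fold statistics.
#'
#' @param rates units x bins rate matrix
#' @param labels per-bin syllable labels (NA allowed)
#' @param bin_centers bin-center times
#' @param window_s half window (4 s)
#' @param k folds (5)
#' @param embargo_s embargo between train and test transitions (2 s)
#' @param max_pc maximum principal components (50)
#' @param min_per_class classes with fewer transitions are dropped
#' @param seed integer seed
#' @return a `tgm_result`: `accuracy` (lags x lags), `lags_s`, `diag`,
#'   `chance`, `n_transitions`
#' @export
temporal_generalization <- function(rates, labels, bin_centers,
                                    window_s = 4, k = 5, embargo_s = 2,
                                    max_pc = 50, min_per_class = 2 * 5,
                                    seed = 1) {
  bin_s <- stats::median(diff(bin_centers))
  half <- round(window_s / bin_s)
  lags <- (-half):half
  n_bin <- length(labels)
  ## transitions: first bin of a new syllable after a different one
  tr_idx <- which(!is.na(labels[-1]) & !is.na(labels[-n_bin]) &
                  labels[-1] != labels[-n_bin]) + 1L
  tr_idx <- tr_idx[tr_idx + min(lags) >= 1 & tr_idx + max(lags) <= n_bin]
  cls <- labels[tr_idx]
  keep_cls <- names(which(table(cls) >= min_per_class))
  sel <- cls %in% keep_cls
  tr_idx <- tr_idx[sel]; cls <- as.character(cls[sel])
  if (length(unique(cls)) < 2) stop("fewer than 2 decodable classes")

  set.seed(substream_seed(seed, "tgm"))
  ## stratified fold assignment over transitions
  fold_of <- integer(length(tr_idx))
  for (cc in unique(cls)) {
    i <- which(cls == cc)
    fold_of[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  ## peri-event tensor: transitions x lags x units
  nL <- length(lags)
  acc <- array(0, c(nL, nL))
  cnt <- array(0, c(nL, nL))
  rt <- t(rates)
  for (f in seq_len(k)) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    ## embargo: drop train transitions within embargo_s of any test one
    tt <- bin_centers[tr_idx[te]]
    keep <- vapply(bin_centers[tr_idx[tr]],
                   function(t) min(abs(t - tt)) >= embargo_s, logical(1))
    tr <- tr[keep]
    if (!length(tr) || length(unique(cls[tr])) < 2) next
    for (li in seq_len(nL)) {
      Xtr <- rt[tr_idx[tr] + lags[li], , drop = FALSE]
      st <- std_fit(Xtr)
      Xs <- std_apply(Xtr, st)
      npc <- min(max_pc, ncol(Xs), nrow(Xs) - 1)
      pc <- stats::prcomp(Xs, center = FALSE, rank. = npc)
      m <- fit_multinom(Xs %*% pc$rotation, cls[tr])
      for (lj in seq_len(nL)) {
        Xte <- std_apply(rt[tr_idx[te] + lags[lj], , drop = FALSE], st)
        p <- predict_multinom(m, Xte %*% pc$rotation)
        acc[li, lj] <- acc[li, lj] +
          balanced_accuracy(cls[te], p) * length(te)
        cnt[li, lj] <- cnt[li, lj] + length(te)
      }
    }
  }
  A <- acc / pmax(cnt, 1)
  structure(list(accuracy = A, lags_s = lags * bin_s, diag = diag(A),
                 chance = 1 / length(unique(cls)),
                 n_transitions = length(tr_idx)), class = "tgm_result")
}

#' Compare decoder confusion with behavioral transition structure
#'
#' Spearman rank correlation between the symmetrized confusion matrix and
#' the empirical syllable transition probability matrix over off-diagonal
#' pairs, with a class-label permutation null.
#'
#' @param confusion K x K confusion matrix (held-out counts)
#' @param transition K x K empirical transition probability matrix (rows sum
#'   to 1), same class order
#' @param n_perm permutations
#' @param seed integer seed
#' @return list: `rho`, `p`, `n_classes`, `flagged` (TRUE when < 4 classes)
#' @export
confusion_vs_transitions <- function(confusion, transition, n_perm = 1000,
                                     seed = 1) {
  K <- nrow(confusion)
  stopifnot(ncol(confusion) == K, all(dim(transition) == K))
  C <- as.matrix(confusion)
  C <- C / pmax(rowSums(C), 1)
  Cs <- (C + t(C)) / 2
  Ts <- (as.matrix(transition) + t(as.matrix(transition))) / 2
  off <- upper.tri(Cs)
  safe_cor <- function(a, b)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
      stats::cor(a, b, method = "spearman")
  rho <- safe_cor(Cs[off], Ts[off])
  set.seed(substream_seed(seed, "confusion-perm"))
  null <- replicate(n_perm, {
    pm <- sample(K)
    safe_cor(Cs[pm, pm][off], Ts[off])
  })
  null <- null[is.finite(null)]
  p <- if (is.finite(rho) && length(null)) perm_pvalue(rho, null) else
    NA_real_
  list(rho = rho, p = p, n_classes = K, flagged = K < 4 || !is.finite(rho))
}

#' Empirical bout-level syllable transition matrix on the bin grid
#' @param labels per-bin syllable labels
#' @param classes class order for the output
#' @return K x K row-stochastic matrix
#' @export
empirical_transitions <- function(labels, classes = sort(unique(
  stats::na.omit(labels)))) {
  l <- labels[!is.na(labels)]
  r <- rle(l)$values
  K <- length(classes)
  Tm <- matrix(0, K, K, dimnames = list(classes, classes))
  if (length(r) > 1) {
    from <- match(r[-length(r)], classes)
    to <- match(r[-1], classes)
    for (i in seq_along(from)) Tm[from[i], to[i]] <- Tm[from[i], to[i]] + 1
  }
  Tm / pmax(rowSums(Tm), 1)
}

#' Syllable tuning similarity and per-unit selectivity
#'
#' Per unit, the tuning vector is the z-scored vector of mean rates per
#' syllable (z across syllables). Returns unit-by-unit and
#' syllable-by-syllable Pearson correlation views and per-unit selectivity =
#' maximum absolute z-score across syllables. Zero-variance units are
#' excluded.
#'
#' @param rates units x bins rate matrix
#' @param labels per-bin syllable labels
#' @return list: `tuning` (units x syllables, z-scored), `unit_similarity`,
#'   `syllable_similarity`, `selectivity`, `excluded`
#' @export
syllable_tuning <- function(rates, labels) {
  classes <- sort(unique(stats::na.omit(labels)))
  if (length(classes) < 2) stop("need at least 2 syllables")
  M <- t(vapply(seq_len(nrow(rates)), function(u)
    vapply(classes, function(k)
      mean(rates[u, !is.na(labels) & labels == k]), numeric(1)),
    numeric(length(classes))))
  sds <- apply(M, 1, stats::sd)
  excluded <- which(!is.finite(sds) | sds < 1e-12)
  keep <- setdiff(seq_len(nrow(M)), excluded)
  Z <- t(scale(t(M[keep, , drop = FALSE])))
  colnames(Z) <- classes
  list(tuning = Z,
       unit_similarity = stats::cor(t(Z)),
       syllable_similarity = stats::cor(Z),
       selectivity = apply(abs(Z), 1, max),
       excluded = excluded)
}
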