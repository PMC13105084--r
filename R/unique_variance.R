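## block-permute the rows of one feature group: the series is cut into
## contiguous chunks of chunk_s seconds and the chunk order is permuted
## uniformly at random (chunks kept intact; the remainder chunk is permuted
## with the rest). Returns a row-index permutation.
block_permutation <- function(bin_times, chunk_s) {
  chunk <- floor((bin_times - bin_times[1]) / chunk_s)
  ids <- unique(chunk)
  new_order <- sample(ids)
  unlist(lapply(new_order, function(cid) which(chunk == cid)),
         use.names = FALSE)
}

#' Shuffle-based unique variance decomposition
#'
#' One feature group at a time is block-permuted in 10 s chunks to destroy
#' its alignment with the neural response while preserving local
#' autocorrelation; the unique contribution of a group is the average drop in
#' cross-validated R^2 relative to the intact model. The regularization is
#' selected once on the full model (from `fit`) and held fixed for all
#' shuffled refits. Empirical one-sided p-values come from the shuffle
#' distribution of R^2 drops; Benjamini-Hochberg correction across units is
#' applied per group.
#'
#' @param fit an `encoding_fit` from [fit_ridge_encoder()] (frozen alphas)
#' @param Y bins x units response matrix (same as used for `fit`)
#' @param design a `design_matrix` (uses `X` and `groups`)
#' @param plan a `fold_plan`
#' @param groups character vector of groups to test (default all except
#'   DRIFT)
#' @param n_shuffle number of shuffles (default 100; the smallest attainable
#'   p is 1 / (n_shuffle + 1))
#' @param chunk_s shuffle chunk length (s)
#' @param seed integer seed for the shuffle substream
#' @return a `unique_variance` data.frame: unit, group, dR2, p, q, r2_full
#' @export
unique_variance <- function(fit, Y, design, plan, groups = NULL,
                            n_shuffle = 100, chunk_s = 10, seed = 1) {
  Y <- as.matrix(Y)
  X <- design$X
  if (is.null(groups))
    groups <- setdiff(unique(design$groups), "DRIFT")
  missing_g <- setdiff(groups, unique(design$groups))
  if (length(missing_g))
    stop("groups absent from design: ", paste(missing_g, collapse = ", "))
  inc <- which(fit$included)
  if (!length(inc)) stop("no included units")
  Yi <- Y[, inc, drop = FALSE]
  alphas <- fit$alpha[inc]

  ## intact R^2 at the frozen alphas
  r2_intact <- ridge_cv_fixed_alpha(Yi, X, plan, alphas)$r2

  set.seed(substream_seed(seed, "shuffles"))
  vb <- which(plan$valid)  # permute the valid-bin series only
  res <- list()
  for (g in groups) {
    cols <- which(design$groups == g)
    drops <- matrix(NA_real_, n_shuffle, length(inc))
    for (s in seq_len(n_shuffle)) {
      perm <- block_permutation(design$bin_centers[vb], chunk_s)
      Xs <- X
      Xs[vb, cols] <- X[vb[perm], cols, drop = FALSE]
      r2s <- ridge_cv_fixed_alpha(Yi, Xs, plan, alphas)$r2
      drops[s, ] <- r2_intact - r2s
    }
    dR2 <- colMeans(drops)
    ## one-sided empirical p: fraction of shuffled models matching or beating
    ## the intact model (drop <= 0), i.e. the intact R^2 treated as one more
    ## draw from the shuffle distribution; min attainable p = 1/(n+1)
    p <- vapply(seq_along(inc), function(u)
      (1 + sum(drops[, u] <= 0)) / (n_shuffle + 1), numeric(1))
    res[[g]] <- data.frame(unit = inc, group = g, dR2 = dR2, p = p,
                           q = fdr_adjust(p), r2_full = fit$r2[inc])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("unique_variance", "data.frame")
  out
}

#' Classify units by encoding category
#'
#' A group is significant for a unit when FDR-corrected p < 0.05, unique
#' dR2 >= 0.005, and full-model R^2 > 0.01. Units failing the R^2 gate are
#' excluded from categories.
#'
#' @param uv a `unique_variance` table (must contain VIS and POS rows)
#' @param q_thresh FDR threshold
#' @param dr2_thresh minimum unique dR2
#' @param r2_gate full-model R^2 gate
#' @return data.frame: unit, category in both / POS-only / VIS-only /
#'   neither / excluded
#' @export
classify_encoding_units <- function(uv, q_thresh = 0.05, dr2_thresh = 0.005,
                                    r2_gate = 0.01) {
  stopifnot(all(c("VIS", "POS") %in% uv$group))
  units <- sort(unique(uv$unit))
  sig <- function(g) {
    d <- uv[uv$group == g, ]
    d <- d[match(units, d$unit), ]
    d$q < q_thresh & d$dR2 >= dr2_thresh
  }
  r2 <- uv$r2_full[match(units, uv$unit)]
  vis <- sig("VIS"); pos <- sig("POS")
  cat <- ifelse(r2 <= r2_gate, "excluded",
         ifelse(vis & pos, "both",
         ifelse(pos, "POS-only",
         ifelse(vis, "VIS-only", "neither"))))
  data.frame(unit = units, r2_full = r2, category = cat)
}
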