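#' The 20-point log-spaced regularization grid
#' @return numeric vector, 20 log-spaced values from 1e-2 to 1e4
#' @export
alpha_grid <- function() 10^seq(-2, 4, length.out = 20)

## standardize train columns, apply train statistics to test; zero-variance
## columns are centered only (scale 1) so they drop out of the fit
std_fit <- function(Xtr) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}
std_apply <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

## SVD ridge: coefficients for every alpha from one decomposition.
## Y may be a matrix (columns = units); returns per-alpha predictions.
ridge_svd <- function(Xs, Y) {
  sv <- svd(Xs)
  ybar <- colMeans(Y)
  Uty <- crossprod(sv$u, sweep(Y, 2, ybar))
  list(sv = sv, Uty = Uty, ybar = ybar)
}
ridge_predict <- function(fit, Xte_s, alpha) {
  f <- fit$sv$d / (fit$sv$d^2 + alpha)
  B <- fit$sv$v %*% (f * fit$Uty)
  sweep(Xte_s %*% B, 2, fit$ybar, "+")
}
ridge_coef <- function(fit, alpha) {
  f <- fit$sv$d / (fit$sv$d^2 + alpha)
  fit$sv$v %*% (f * fit$Uty)
}

## pooled held-out R^2: SS_tot about the pooled held-out mean
pooled_r2 <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Cross-validated ridge R^2 at fixed per-unit alphas
#'
#' Shared engine: per outer fold, features are z-scored with training
#' statistics, the SVD is computed once, and held-out predictions for every
#' unit are produced at that unit's alpha. Returns pooled held-out R^2.
#'
#' @param Y bins x units response matrix (valid-bin rows only are used)
#' @param X bins x features design
#' @param plan a `fold_plan`
#' @param alphas per-unit alpha vector (recycled)
#' @return list: `r2` per unit, `pred` (bins x units held-out predictions,
#'   NA outside test bins)
#' @export
ridge_cv_fixed_alpha <- function(Y, X, plan, alphas) {
  Y <- as.matrix(Y)
  nU <- ncol(Y)
  alphas <- rep_len(alphas, nU)
  pred <- matrix(NA_real_, nrow(Y), nU)
  ua <- sort(unique(alphas))
  for (f in plan$folds) {
    if (!length(f$test) || !length(f$train)) next
    st <- std_fit(X[f$train, , drop = FALSE])
    fit <- ridge_svd(std_apply(X[f$train, , drop = FALSE], st),
                     Y[f$train, , drop = FALSE])
    Xte <- std_apply(X[f$test, , drop = FALSE], st)
    for (a in ua) {
      cols <- which(alphas == a)
      P <- ridge_predict(list(sv = fit$sv, Uty = fit$Uty[, cols, drop = FALSE],
                              ybar = fit$ybar[cols]), Xte, a)
      pred[f$test, cols] <- P
    }
  }
  tested <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  r2 <- vapply(seq_len(nU), function(u)
    pooled_r2(Y[tested, u], pred[tested, u]), numeric(1))
  list(r2 = r2, pred = pred)
}

#' Fit ridge encoding models with nested alpha selection
#'
#' For each unit: per outer fold, the regularization strength is chosen on
#' the training bins only by an inner blocked/embargoed cross-validation
#' (k_inner = k - 1) over the 20-point grid, then the model is refit on the
#' full outer-training set and held-out predictions are pooled into a single
#' cross-validated R^2. Units with fewer than `min_bins` valid bins, or zero
#' response variance, are excluded (reported, not fatal).
#'
#' @param Y bins x units response matrix (rates, Hz), or a vector
#' @param X bins x features design (e.g. `design$X`)
#' @param plan a `fold_plan` built on the same bins
#' @param alphas alpha grid
#' @param min_bins inclusion threshold on valid bins (default 150)
#' @return an `encoding_fit`: `r2` (per unit, NA if excluded), `alpha`
#'   (selected per unit; grid mode over outer folds), `alpha_fold` (k x units),
#'   `pred`, `included`, `n_valid`
#' @export
fit_ridge_encoder <- function(Y, X, plan, alphas = alpha_grid(),
                              min_bins = 150) {
  Y <- as.matrix(Y)
  nU <- ncol(Y)
  tested <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  n_valid <- length(tested)
  sds <- apply(Y[tested, , drop = FALSE], 2, stats::sd)
  included <- rep(n_valid >= min_bins, nU) & sds > 0
  pred <- matrix(NA_real_, nrow(Y), nU)
  alpha_fold <- matrix(NA_real_, plan$k, nU)
  if (any(included)) {
    Yi <- Y[, included, drop = FALSE]
    for (fi in seq_along(plan$folds)) {
      f <- plan$folds[[fi]]
      if (!length(f$test) || !length(f$train)) next
      ip <- inner_fold_plan(plan, f$train, plan$k - 1L)
      ## inner CV error per (alpha, unit)
      sse <- matrix(0, length(alphas), ncol(Yi))
      sst <- rep(0, ncol(Yi))
      for (g in ip$folds) {
        if (!length(g$test) || !length(g$train)) next
        st <- std_fit(X[g$train, , drop = FALSE])
        fit <- ridge_svd(std_apply(X[g$train, , drop = FALSE], st),
                         Yi[g$train, , drop = FALSE])
        Xte <- std_apply(X[g$test, , drop = FALSE], st)
        Yte <- Yi[g$test, , drop = FALSE]
        for (ai in seq_along(alphas)) {
          P <- ridge_predict(fit, Xte, alphas[ai])
          sse[ai, ] <- sse[ai, ] + colSums((Yte - P)^2)
        }
      }
      best <- apply(sse, 2, which.min)
      alpha_fold[fi, included] <- alphas[best]
      ## outer refit at the selected alpha
      st <- std_fit(X[f$train, , drop = FALSE])
      fit <- ridge_svd(std_apply(X[f$train, , drop = FALSE], st),
                       Yi[f$train, , drop = FALSE])
      Xte <- std_apply(X[f$test, , drop = FALSE], st)
      for (a in unique(alphas[best])) {
        cols <- which(alphas[best] == a)
        P <- ridge_predict(list(sv = fit$sv,
                                Uty = fit$Uty[, cols, drop = FALSE],
                                ybar = fit$ybar[cols]), Xte, a)
        pred[f$test, which(included)[cols]] <- P
      }
    }
  }
  r2 <- rep(NA_real_, nU)
  for (u in which(included))
    r2[u] <- pooled_r2(Y[tested, u], pred[tested, u])
  ## selected alpha: grid mode over outer folds (ties -> smaller alpha)
  alpha_sel <- rep(NA_real_, nU)
  for (u in which(included)) {
    av <- alpha_fold[, u]
    tb <- table(av)
    alpha_sel[u] <- as.numeric(names(tb)[which.max(tb)])
  }
  structure(list(r2 = r2, alpha = alpha_sel, alpha_fold = alpha_fold,
                 pred = pred, included = included, n_valid = n_valid),
            class = "encoding_fit")
}
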