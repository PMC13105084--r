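#' Blocked temporal cross-validation plan with embargo
#'
#' Valid bins are divided into contiguous 30 s blocks assigned cyclically to
#' folds; a trailing partial block is appended to the last full block. For
#' each fold, the test set is the fold's blocks and the training set is every
#' other valid bin at least `embargo_s` away (in time) from every test bin.
#'
#' @param bin_times bin-center times (s)
#' @param valid_mask logical per-bin validity
#' @param k number of folds (>= 2)
#' @param block_s block length (s)
#' @param embargo_s guard interval excluded from training on either side of
#'   each test block (s)
#' @return a `fold_plan`: `k`, `fold_id` per bin (NA if invalid), `folds`
#'   (list of `test` / `train` index vectors), `block_s`, `embargo_s`
#' @export
make_fold_plan <- function(bin_times, valid_mask = rep(TRUE, length(bin_times)),
                           k = 5, block_s = 30, embargo_s = 2) {
  stopifnot(k >= 2, length(valid_mask) == length(bin_times))
  block <- floor((bin_times - bin_times[1]) / block_s)
  n_blocks <- max(block) + 1L
  ## a trailing partial block (shorter than block_s) merges into the last one
  span_last <- max(bin_times[block == max(block)]) -
    min(bin_times[block == max(block)])
  spacing <- stats::median(diff(bin_times))
  full_blocks <- n_blocks
  if (n_blocks > 1 && span_last < block_s - spacing - 1e-9) {
    block[block == max(block)] <- max(block) - 1L
    full_blocks <- n_blocks - 1L
  }
  if (full_blocks < k)
    stop("fewer blocks (", full_blocks, ") than folds (", k, ")")
  fold_id <- block %% k
  fold_id[!valid_mask] <- NA
  folds <- lapply(0:(k - 1), function(f) {
    test <- which(valid_mask & fold_id == f)
    tt <- bin_times[test]
    cand <- which(valid_mask & fold_id != f)
    keep <- vapply(bin_times[cand],
                   function(t) min(abs(t - tt)) >= embargo_s, logical(1))
    list(test = test, train = cand[keep])
  })
  structure(list(k = k, fold_id = fold_id, folds = folds,
                 bin_times = bin_times, valid = valid_mask,
                 block_s = block_s, embargo_s = embargo_s),
            class = "fold_plan")
}

#' Exhaustively check the embargo contract of a fold plan
#'
#' Asserts that test sets partition the valid bins and that no training bin
#' lies within the embargo of any test bin of its fold.
#'
#' @param plan a `fold_plan`
#' @return TRUE (invisibly); stops on violation
#' @export
check_fold_plan <- function(plan) {
  all_test <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  if (!identical(all_test, which(plan$valid)))
    stop("test sets do not partition the valid bins")
  for (f in plan$folds) {
    if (!length(f$test) || !length(f$train)) next
    dmin <- min(abs(outer(plan$bin_times[f$train],
                          plan$bin_times[f$test], "-")))
    if (dmin < plan$embargo_s - 1e-9)
      stop("embargo violated: min train-test separation ", dmin)
  }
  invisible(TRUE)
}

## inner fold plan on the training bins of an outer fold: reuse the outer
## block structure, reassign the training blocks cyclically to k_inner folds,
## embargo applied on time as in the outer plan
inner_fold_plan <- function(plan, train_idx, k_inner) {
  bt <- plan$bin_times
  block <- floor((bt - bt[1]) / plan$block_s)
  tr_blocks <- sort(unique(block[train_idx]))
  if (length(tr_blocks) < k_inner) k_inner <- max(2L, length(tr_blocks))
  bmap <- match(block[train_idx], tr_blocks) - 1L
  fold_id <- bmap %% k_inner
  folds <- lapply(0:(k_inner - 1), function(f) {
    test <- train_idx[fold_id == f]
    tt <- bt[test]
    cand <- train_idx[fold_id != f]
    keep <- vapply(bt[cand], function(t) min(abs(t - tt)) >= plan$embargo_s,
                   logical(1))
    list(test = test, train = cand[keep])
  })
  list(k = k_inner, folds = folds)
}
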