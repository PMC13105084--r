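#' @keywords internal
"_PACKAGE"

#' Derive a named substream seed from a global seed
#'
#' One global seed fans out to named substreams (behavior, spikes, shuffles,
#' ...) so pipeline stages can be regenerated independently without sharing
#' RNG state. The derived seed is kept below 2^31 so it is a valid R integer.
#'
#' @param seed integer global seed
#' @param name character substream name
#' @return integer seed
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003L
  as.integer((abs(seed) %% 1000003L) * 2038L + h) %% 2147483587L + 1L
}

#' Wrap angles to (-pi, pi]
#' @param x angles in radians
#' @return wrapped angles
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

## circular difference a - b wrapped to (-pi, pi]
circ_diff <- function(a, b) wrap_angle(a - b)

#' Circular root-mean-square error between two angle series
#' @param a,b angle vectors (radians)
#' @return scalar RMSE in radians
#' @export
circular_rmse <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  sqrt(mean(circ_diff(a[ok], b[ok])^2))
}

## Sliding-window mode filter for integer label series (used for categorical
## "median" filtering of ethograms; the median of label integers is
## meaningless). Window is centered, truncated at the edges. Ties go to the
## label already present at the center frame if tied, else the smallest id.
mode_filter <- function(labels, window) {
  n <- length(labels)
  half <- window %/% 2L
  out <- labels
  levs <- sort(unique(labels))
  lmat <- outer(labels, levs, "==")
  cs <- rbind(0, apply(lmat, 2, cumsum))
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    cnt <- cs[hi + 1L, ] - cs[lo, ]
    best <- which(cnt == max(cnt))
    if (length(best) > 1L && (match(labels[i], levs) %in% best)) {
      out[i] <- labels[i]
    } else {
      out[i] <- levs[best[1L]]
    }
  }
  out
}

## run-length bouts of a label series on a time grid
label_bouts <- function(labels, times) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  dt <- if (length(times) > 1L) stats::median(diff(times)) else 0
  data.frame(
    label = r$values,
    start_s = times[starts],
    end_s = times[ends] + dt,
    n_frames = r$lengths
  )
}

## benjamini-hochberg wrapper kept for clarity at call sites
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Balanced accuracy (mean per-class recall)
#'
#' Insensitive to class imbalance; a constant classifier scores exactly 1/K
#' over the K classes present in `truth`.
#'
#' @param truth true labels
#' @param pred predicted labels
#' @return scalar in `[0, 1]`
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- unique(truth)
  mean(vapply(classes, function(k) mean(pred[truth == k] == k), numeric(1)))
}

## empirical one-sided p with the observed value included in the null set
perm_pvalue <- function(observed, null_values) {
  (1 + sum(null_values >= observed)) / (length(null_values) + 1)
}
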