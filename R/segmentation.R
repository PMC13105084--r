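#' Per-animal scale normalization and pairwise-distance features
#'
#' Coordinates are divided by a per-animal scale scalar — the geometric mean
#' of the animal's median torso length (shoulder-midpoint to hip-midpoint)
#' and median shoulder width — making features invariant to body size. All
#' pairwise Euclidean distances over the 12 non-face body joints are then
#' computed, 66 features per frame.
#'
#' @param pose a (cleaned) `pose_series`
#' @param animal_id single id for the whole series
#' @param scale_stat "median" (default) or "q975" (97.5th percentile of the
#'   two body measurements instead of the median)
#' @return list: `distances` (frames x 66), `heights` (frames x 13, signed
#'   distance of the height/speed joints to the floor plane), `speeds`
#'   (frames x 13), `scale`, `animal_id`, `time_s`
#' @export
normalize_and_distances <- function(pose, animal_id = "a1",
                                    scale_stat = c("median", "q975")) {
  scale_stat <- match.arg(scale_stat)
  sk <- skeleton_def()
  xyz <- pose$xyz
  stat <- if (scale_stat == "median") function(x)
    stats::median(x, na.rm = TRUE) else function(x)
    stats::quantile(x, 0.975, na.rm = TRUE, names = FALSE)
  torso <- sqrt(rowSums(((xyz[, 6, ] + xyz[, 7, ]) / 2 -
                         (xyz[, 12, ] + xyz[, 13, ]) / 2)^2))
  shoulder <- sqrt(rowSums((xyz[, 6, ] - xyz[, 7, ])^2))
  sc <- sqrt(stat(torso) * stat(shoulder))
  xyz <- xyz / sc

  body <- sk$body
  pairs <- utils::combn(length(body), 2)
  D <- matrix(NA_real_, dim(xyz)[1], ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- body[pairs[1, p]]; b <- body[pairs[2, p]]
    D[, p] <- sqrt(rowSums((xyz[, a, ] - xyz[, b, ])^2))
  }
  colnames(D) <- apply(pairs, 2, function(pp)
    paste(sk$names[body[pp[1]]], sk$names[body[pp[2]]], sep = "-"))

  hs <- sk$height_speed
  H <- xyz[, hs, 3]
  dt <- c(stats::median(diff(pose$time_s)), diff(pose$time_s))
  S <- matrix(NA_real_, dim(xyz)[1], length(hs))
  for (j in seq_along(hs)) {
    d <- rbind(0, diff(xyz[, hs[j], ]))
    S[, j] <- sqrt(rowSums(d^2)) / dt
  }
  colnames(H) <- colnames(S) <- sk$names[hs]

  ## frames with missing distances: carry last valid value within 0.25 s
  bad <- !stats::complete.cases(D)
  if (any(bad)) {
    max_gap <- ceiling(0.25 * pose$frame_rate)
    last_ok <- NA_integer_
    drop <- logical(nrow(D))
    for (i in seq_len(nrow(D))) {
      if (!bad[i]) last_ok <- i
      else if (!is.na(last_ok) && i - last_ok <= max_gap) {
        D[i, ] <- D[last_ok, ]; H[i, ] <- H[last_ok, ]; S[i, ] <- S[last_ok, ]
      } else drop[i] <- TRUE
    }
    time_s <- pose$time_s
    if (any(drop)) {
      D <- D[!drop, , drop = FALSE]; H <- H[!drop, , drop = FALSE]
      S <- S[!drop, , drop = FALSE]
      time_s <- time_s[!drop]
    }
  } else time_s <- pose$time_s
  list(distances = D, heights = H, speeds = S, scale = sc,
       animal_id = rep(animal_id, nrow(D)), time_s = time_s,
       frame_rate = pose$frame_rate)
}

#' PCA reduction with an animal-identity filter
#'
#' The pooled distance features are reduced to `n_pc` principal components;
#' components whose point-biserial correlation with binary animal identity
#' exceeds `r_thresh` in magnitude are removed, so retained components carry
#' behavior rather than individual morphology. With a single animal the
#' filter is skipped.
#'
#' @param distances frames x 66 matrix (pooled across animals)
#' @param animal_ids per-frame animal id
#' @param n_pc components to extract (20)
#' @param r_thresh removal threshold on |point-biserial r| (0.3)
#' @return list: `scores` (frames x retained), `removed` (indices among the
#'   first `n_pc`), `rotation`, `center`, `r_identity`
#' @export
reduce_with_identity_filter <- function(distances, animal_ids, n_pc = 20,
                                        r_thresh = 0.3) {
  pc <- stats::prcomp(distances, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  ids <- unique(animal_ids)
  r <- rep(0, n_pc)
  if (length(ids) >= 2) {
    bin <- as.numeric(animal_ids == ids[1])
    if (stats::sd(bin) > 0)
      r <- apply(scores, 2, function(s) stats::cor(s, bin))
  }
  removed <- which(abs(r) > r_thresh)
  if (length(removed) == n_pc)
    stop("all components correlate with identity; review r_thresh")
  keep <- setdiff(seq_len(n_pc), removed)
  list(scores = scores[, keep, drop = FALSE], removed = removed,
       rotation = pc$rotation[, seq_len(n_pc), drop = FALSE],
       center = pc$center, r_identity = r)
}

#' Morlet continuous wavelet amplitude scalogram
#'
#' FFT-based CWT with the analytic Morlet wavelet (center frequency
#' `omega0 = 6`). Returns the amplitude at each requested frequency; a
#' sinusoid produces a ridge at the nearest grid frequency. Rows are meant
#' to be z-normalized downstream, so the absolute amplitude scale carries
#' no information.
#'
#' @param x signal
#' @param frame_rate sampling rate (Hz)
#' @param freqs analysis frequencies (Hz)
#' @param omega0 Morlet center frequency parameter
#' @return length(freqs) x length(x) amplitude matrix
#' @export
morlet_cwt <- function(x, frame_rate, freqs, omega0 = 6) {
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  xf <- stats::fft(c(x - mean(x), rep(0, nfft - n)))
  ## angular frequencies of the FFT grid (positive branch then negative)
  w <- 2 * pi * frame_rate * ifelse(0:(nfft - 1) <= nfft / 2,
                                    (0:(nfft - 1)) / nfft,
                                    ((0:(nfft - 1)) - nfft) / nfft)
  out <- matrix(0, length(freqs), n)
  for (fi in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[fi])       # scale for this frequency
    psi <- exp(-0.5 * (s * w - omega0)^2)    # analytic Morlet, freq domain
    psi[w <= 0] <- 0
    conv <- stats::fft(xf * psi, inverse = TRUE) / nfft
    out[fi, ] <- Mod(conv[seq_len(n)]) / sqrt(s)
  }
  out
}

#' Build the wavelet + heights + speeds feature stack
#'
#' A Morlet scalogram (20 geometrically spaced frequencies, 0.5-12 Hz) of
#' each retained PC, amplitude output z-normalized per frequency row, then
#' concatenated with z-scored per-joint heights (weight x3.0) and speeds
#' (weight x2.0). With 6 retained PCs this yields 120 wavelet + 13 + 13 =
#' 146 features per frame.
#'
#' @param pc_scores frames x n_pc retained PC scores
#' @param frame_rate Hz
#' @param heights frames x 13 joint heights
#' @param speeds frames x 13 joint speeds
#' @param freqs wavelet frequency grid
#' @param height_weight,speed_weight block weights (3.0, 2.0)
#' @param norm_frames optional index of training frames whose statistics are
#'   used for all z-normalizations (avoids leakage); default all frames
#' @return list: `stack` (frames x total), `blocks` (named column ranges)
#' @export
wavelet_stack <- function(pc_scores, frame_rate, heights, speeds,
                          freqs = exp(seq(log(0.5), log(12), length.out = 20)),
                          height_weight = 3.0, speed_weight = 2.0,
                          norm_frames = NULL) {
  pc_scores <- as.matrix(pc_scores)
  n <- nrow(pc_scores)
  if (is.null(norm_frames)) norm_frames <- seq_len(n)
  wl <- list()
  for (j in seq_len(ncol(pc_scores))) {
    amp <- t(morlet_cwt(pc_scores[, j], frame_rate, freqs))
    mu <- colMeans(amp[norm_frames, , drop = FALSE])
    sdv <- apply(amp[norm_frames, , drop = FALSE], 2, stats::sd)
    zero <- !is.finite(sdv) | sdv < 1e-12
    sdv[zero] <- 1
    amp <- sweep(sweep(amp, 2, mu), 2, sdv, "/")
    amp[, zero] <- 0
    colnames(amp) <- sprintf("pc%d_f%.2f", j, freqs)
    wl[[j]] <- amp
  }
  W <- do.call(cbind, wl)
  zs <- function(M, wgt) {
    mu <- colMeans(M[norm_frames, , drop = FALSE], na.rm = TRUE)
    sdv <- apply(M[norm_frames, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
    sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
    sweep(sweep(M, 2, mu), 2, sdv, "/") * wgt
  }
  H <- zs(as.matrix(heights), height_weight)
  S <- zs(as.matrix(speeds), speed_weight)
  stack <- cbind(W, H, S)
  list(stack = stack,
       blocks = list(wavelet = seq_len(ncol(W)),
                     heights = ncol(W) + seq_len(ncol(H)),
                     speeds = ncol(W) + ncol(H) + seq_len(ncol(S))))
}

#' Coverage-balanced training-frame sampling
#'
#' Samples up to `n_train` frames stratified over animals with at most 40%
#' from any single animal.
#'
#' @param animal_ids per-frame animal ids
#' @param n_train target number of training frames
#' @param max_animal_frac per-animal cap (0.4); ignored for a single animal
#' @param seed integer seed
#' @return integer frame indices
#' @export
sample_training_frames <- function(animal_ids, n_train,
                                   max_animal_frac = 0.4, seed = 1) {
  set.seed(substream_seed(seed, "train-frames"))
  ids <- unique(animal_ids)
  n_train <- min(n_train, length(animal_ids))
  cap <- if (length(ids) > 1) ceiling(max_animal_frac * n_train) else n_train
  take <- lapply(ids, function(a) {
    idx <- which(animal_ids == a)
    sample(idx, min(length(idx), cap))
  })
  idx <- unlist(take)
  if (length(idx) > n_train) idx <- sample(idx, n_train)
  sort(idx)
}

#' Embed the feature stack in 2D and watershed-segment the density
#'
#' The embedding is fit on the training frames and the remaining frames are
#' projected into the same reference space. The default backend is a
#' deterministic linear (principal-component) 2D embedding with signs fixed
#' by the largest-loading rule; the backend is pluggable via a function
#' `function(train_stack) -> list(project = function(stack) n x 2)`. The 2D
#' embedding is rasterized onto a `grid` x `grid` density map,
#' Gaussian-smoothed (`sigma`), and segmented by watershed from the density
#' peaks, with the minimum peak separation increased from 1 until the number
#' of initial regions stops exceeding `max_regions`. Initial regions are
#' consolidated to `k_final` syllables by Ward-linkage hierarchical merging
#' of the region centroids.
#'
#' @param stack feature stack (frames x features)
#' @param train_frames indices used to fit the embedding
#' @param grid raster resolution (300)
#' @param sigma Gaussian smoothing of the density grid (1.5 cells)
#' @param k_final target number of final syllables
#' @param max_regions cap used by the peak-separation auto-tuning (40)
#' @param backend NULL for the spectral default, or a backend function
#' @param merge_method basin consolidation criterion: "persistence"
#'   (default; merge lowest-prominence peaks across their saddles) or
#'   "ward" (Ward linkage on mass-weighted basin centroids)
#' @return a `segmentation_map`: `embedding` (frames x 2), `density`,
#'   `region_image`, `n_initial`, `merge` (initial -> final id map),
#'   `labels` (per-frame final syllable id), `xlim`, `ylim`
#' @export
embed_and_segment <- function(stack, train_frames = seq_len(nrow(stack)),
                              grid = 300, sigma = 1.5, k_final = 12,
                              max_regions = 40, backend = NULL,
                              merge_method = c("persistence", "ward")) {
  merge_method <- match.arg(merge_method)
  if (is.null(backend)) backend <- spectral_embedding_backend()
  fitted <- backend(stack[train_frames, , drop = FALSE])
  emb <- fitted$project(stack)

  ## robust raster limits: a handful of projected outliers must not stretch
  ## the grid and compress the density modes
  xlim <- stats::quantile(emb[, 1], c(0.001, 0.999), names = FALSE)
  ylim <- stats::quantile(emb[, 2], c(0.001, 0.999), names = FALSE)
  pad <- c(diff(xlim), diff(ylim)) * 0.05 + 1e-9
  xlim <- xlim + c(-1, 1) * pad[1]; ylim <- ylim + c(-1, 1) * pad[2]
  gx <- pmin(pmax(ceiling((emb[, 1] - xlim[1]) / diff(xlim) * grid), 1), grid)
  gy <- pmin(pmax(ceiling((emb[, 2] - ylim[1]) / diff(ylim) * grid), 1), grid)
  dens <- matrix(0, grid, grid)
  tb <- table(factor(gx, levels = 1:grid), factor(gy, levels = 1:grid))
  dens[, ] <- as.numeric(tb)
  dens <- EBImage::gblur(dens, sigma = sigma)
  dens[dens < 0] <- 0

  ## watershed basins of the density peaks; ext is the peak-separation
  ## radius, auto-tuned upward until the region count is at most max_regions
  seg <- NULL
  for (ext in 1:20) {
    seg <- EBImage::watershed(dens, tolerance = max(dens) * 1e-3, ext = ext)
    n_reg <- max(seg)
    if (n_reg <= max_regions) break
  }
  n_initial <- max(seg)
  if (n_initial < 1) stop("no density regions found")
  if (n_initial < k_final)
    stop("fewer watershed regions (", n_initial, ") than k_final (",
         k_final, "); try a smaller sigma")

  ## assign every occupied cell to its nearest labelled basin (watershed can
  ## leave boundary cells 0)
  region_of_frame <- seg[cbind(gx, gy)]
  if (any(region_of_frame == 0)) {
    lab_idx <- which(seg > 0, arr.ind = TRUE)
    need <- which(region_of_frame == 0)
    for (i in need) {
      d2 <- (lab_idx[, 1] - gx[i])^2 + (lab_idx[, 2] - gy[i])^2
      region_of_frame[i] <- seg[lab_idx[which.min(d2), , drop = FALSE]]
    }
  }

  ## Consolidate initial basins to k_final syllables. The default criterion
  ## is topological persistence: the basin whose density peak has the lowest
  ## prominence (peak height minus the highest saddle to a neighbour) merges
  ## into the neighbour across that saddle, repeatedly, so fragments of one
  ## diffuse behavior coalesce while modes separated by deep valleys
  ## persist. A Ward-linkage alternative on mass-weighted basin centroids
  ## is available via `merge_method = "ward"`.
  merge_map <- seq_len(n_initial)
  if (k_final < n_initial) {
    if (merge_method == "ward") {
      cent <- t(vapply(seq_len(n_initial), function(r) {
        cells <- which(seg == r, arr.ind = TRUE)
        w <- dens[cells]
        c(sum(cells[, 1] * w), sum(cells[, 2] * w)) / sum(w)
      }, numeric(2)))
      sizes <- tabulate(region_of_frame, n_initial)
      hc <- stats::hclust(stats::dist(cent), method = "ward.D2",
                          members = pmax(sizes, 1))
      merge_map <- stats::cutree(hc, k = k_final)
    } else {
      merge_map <- persistence_merge(seg, dens, k_final)
    }
  }
  labels <- merge_map[region_of_frame]
  structure(list(embedding = emb, density = dens, region_image = seg,
                 n_initial = n_initial, merge = merge_map, labels = labels,
                 xlim = xlim, ylim = ylim), class = "segmentation_map")
}

## persistence-based basin consolidation: repeatedly merge the cluster
## whose maximum density peak has the lowest prominence (peak minus the
## highest saddle shared with any neighbour) into the neighbour across that
## saddle, until k_final clusters remain. Returns initial-region -> final id.
persistence_merge <- function(seg, dens, k_final) {
  n_initial <- max(seg)
  nr <- nrow(dens); nc <- ncol(dens)
  peak <- numeric(n_initial)
  cent <- matrix(0, n_initial, 2)
  for (r in seq_len(n_initial)) {
    cells <- which(seg == r, arr.ind = TRUE)
    w <- dens[cells]
    peak[r] <- max(w)
    cent[r, ] <- c(sum(cells[, 1] * w), sum(cells[, 2] * w)) / sum(w)
  }
  ## saddle heights between adjacent regions: max over boundary cell pairs
  ## of the lower of the two densities; regions touching only through
  ## zero-density background share a saddle at height 0
  sad <- matrix(0, n_initial, n_initial)
  scan_pairs <- function(a_idx, b_idx) {
    la <- seg[a_idx]; lb <- seg[b_idx]
    keep <- la > 0 & lb > 0 & la != lb
    if (!any(keep)) return()
    h <- pmin(dens[a_idx], dens[b_idx])[keep]
    la <- la[keep]; lb <- lb[keep]
    for (i in seq_along(h)) {
      if (h[i] > sad[la[i], lb[i]]) {
        sad[la[i], lb[i]] <<- h[i]
        sad[lb[i], la[i]] <<- h[i]
      }
    }
  }
  idx <- matrix(seq_len(nr * nc), nr, nc)
  scan_pairs(idx[-nr, ], idx[-1, ])
  scan_pairs(idx[, -nc], idx[, -1])
  scan_pairs(idx[-nr, -nc], idx[-1, -1])
  scan_pairs(idx[-nr, -1], idx[-1, -nc])

  cluster <- seq_len(n_initial)
  repeat {
    ids <- unique(cluster)
    if (length(ids) <= k_final) break
    cpeak <- vapply(ids, function(cid) max(peak[cluster == cid]), numeric(1))
    ccent <- t(vapply(ids, function(cid) {
      rs <- which(cluster == cid)
      w <- peak[rs]
      c(sum(cent[rs, 1] * w), sum(cent[rs, 2] * w)) / sum(w)
    }, numeric(2)))
    ## for each cluster: its best (highest-saddle) neighbour and prominence
    nI <- length(ids)
    best_nb <- integer(nI); prom <- numeric(nI)
    for (ai in seq_len(nI)) {
      ra <- which(cluster == ids[ai])
      s_ab <- vapply(seq_len(nI), function(bi) {
        if (bi == ai) return(-Inf)
        max(sad[ra, which(cluster == ids[bi]), drop = FALSE])
      }, numeric(1))
      top <- max(s_ab)
      cand <- which(s_ab >= top - 1e-12 & seq_len(nI) != ai)
      if (length(cand) > 1) {  # ties (e.g. background): nearest centroid
        d2 <- rowSums(sweep(ccent[cand, , drop = FALSE], 2,
                            ccent[ai, ])^2)
        cand <- cand[which.min(d2)]
      }
      best_nb[ai] <- cand[1]
      prom[ai] <- cpeak[ai] - max(top, 0)
    }
    ai <- which.min(prom)
    cluster[cluster == ids[ai]] <- ids[best_nb[ai]]
  }
  match(cluster, unique(cluster))
}

#' Deterministic neighbor-graph (spectral) 2D embedding backend
#'
#' Builds a k-nearest-neighbor graph over the training frames (cosine
#' metric, 15 neighbors by default), forms the symmetric normalized graph
#' Laplacian, and uses its two smallest non-trivial eigenvectors as the 2D
#' embedding (Laplacian eigenmaps). Frames outside the training set are
#' projected by similarity-weighted averaging of their nearest training
#' frames' coordinates. Fully deterministic given the training frames.
#'
#' @param n_neighbors neighbors for the graph (15)
#' @param max_train training frames are subsampled (evenly, deterministic)
#'   to at most this many before the eigendecomposition
#' @return a backend function for [embed_and_segment()]
#' @export
spectral_embedding_backend <- function(n_neighbors = 15, max_train = 2500) {
  function(train_stack) {
    X <- as.matrix(train_stack)
    if (nrow(X) > max_train) {
      idx <- round(seq(1, nrow(X), length.out = max_train))
      X <- X[idx, , drop = FALSE]
    }
    n <- nrow(X)
    Xn <- X / pmax(sqrt(rowSums(X^2)), 1e-12)
    S <- tcrossprod(Xn)                      # cosine similarity
    diag(S) <- -Inf
    k <- min(n_neighbors, n - 1)
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(S[i, ], decreasing = TRUE)[seq_len(k)]
      W[i, nb] <- pmax(S[i, nb], 0)
    }
    W <- pmax(W, t(W))                       # union of neighborhoods
    d <- pmax(rowSums(W), 1e-12)
    Ls <- -W / sqrt(d) / rep(sqrt(d), each = n)
    diag(Ls) <- diag(Ls) + 1
    eg <- eigen((Ls + t(Ls)) / 2, symmetric = TRUE)
    take <- ncol(eg$vectors) - c(1, 2)       # skip the trivial eigenvector
    emb_tr <- eg$vectors[, take, drop = FALSE] / sqrt(d)
    emb_tr <- scale(emb_tr)
    for (j in 1:2) {                         # deterministic sign convention
      i <- which.max(abs(emb_tr[, j]))
      if (emb_tr[i, j] < 0) emb_tr[, j] <- -emb_tr[, j]
    }
    proj_k <- min(10, n)
    list(project = function(stack) {
      Y <- as.matrix(stack)
      Yn <- Y / pmax(sqrt(rowSums(Y^2)), 1e-12)
      out <- matrix(0, nrow(Y), 2)
      chunk <- 2000L
      for (lo in seq(1, nrow(Y), by = chunk)) {
        hi <- min(lo + chunk - 1L, nrow(Y))
        Sim <- tcrossprod(Yn[lo:hi, , drop = FALSE], Xn)
        for (r in seq_len(hi - lo + 1L)) {
          nb <- order(Sim[r, ], decreasing = TRUE)[seq_len(proj_k)]
          w <- pmax(Sim[r, nb], 1e-8)
          out[lo + r - 1L, ] <- colSums(emb_tr[nb, , drop = FALSE] * w) /
            sum(w)
        }
      }
      out
    })
  }
}

#' Deterministic linear 2D embedding backend
#'
#' Principal components of the (training) feature stack, first two
#' dimensions, component signs fixed so the largest-magnitude loading of
#' each component is positive.
#'
#' @return a backend function for [embed_and_segment()]
#' @export
linear_embedding_backend <- function() {
  function(train_stack) {
    pc <- stats::prcomp(train_stack, center = TRUE, scale. = FALSE, rank. = 2)
    rot <- pc$rotation
    for (j in seq_len(ncol(rot))) {
      i <- which.max(abs(rot[, j]))
      if (rot[i, j] < 0) rot[, j] <- -rot[, j]
    }
    ctr <- pc$center
    list(project = function(stack)
      sweep(as.matrix(stack), 2, ctr) %*% rot)
  }
}

#' Post-process a frame-level label series into an ethogram
#'
#' Sliding-window mode filter over a 1 s window, then bouts shorter than
#' `min_bout_s` are absorbed into the longer temporally adjacent bout (ties
#' to the preceding bout), iterated until no short bout remains.
#'
#' @param labels per-frame syllable labels
#' @param time_s per-frame times
#' @param frame_rate Hz
#' @param min_bout_s minimum bout duration (1 s)
#' @return an `ethogram`: `time_s`, `labels`, `bouts`
#' @export
postprocess_ethogram <- function(labels, time_s, frame_rate,
                                 min_bout_s = 1.0) {
  w <- max(2L * floor(min_bout_s * frame_rate / 2) + 1L, 3L)
  lab <- mode_filter(as.integer(labels), w)
  min_frames <- round(min_bout_s * frame_rate)
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1 || all(r$lengths >= min_frames)) break
    i <- which.min(r$lengths)
    left_len <- if (i > 1) r$lengths[i - 1] else -1L
    right_len <- if (i < length(r$lengths)) r$lengths[i + 1] else -1L
    absorb_into <- if (left_len >= right_len) i - 1L else i + 1L
    r$values[i] <- r$values[absorb_into]
    lab <- inverse.rle(r)
  }
  structure(list(time_s = time_s, labels = lab, frame_rate = frame_rate,
                 bouts = label_bouts(lab, time_s)), class = "ethogram")
}

#' Align frame-level syllable labels to neural bins
#'
#' Each bin takes the label of the nearest behavioral frame within `window`
#' of the bin center; bins without a frame in the window are NA. The
#' `top_k` most frequent syllables are retained; rarer syllables are
#' collapsed to "other" and then excluded (NA).
#'
#' @param ethogram an `ethogram`
#' @param bin_centers neural bin centers (s)
#' @param window maximum frame distance (0.5 s)
#' @param top_k retained class count (10)
#' @return integer per-bin labels (NA = missing or rare)
#' @export
align_labels_to_bins <- function(ethogram, bin_centers, window = 0.5,
                                 top_k = 10) {
  ft <- ethogram$time_s
  idx <- findInterval(bin_centers, ft)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(ft))
  d_lo <- abs(bin_centers - ft[lo])
  d_hi <- abs(bin_centers - ft[hi])
  nearest <- ifelse(d_lo <= d_hi, lo, hi)
  dist <- pmin(d_lo, d_hi)
  lab <- ethogram$labels[nearest]
  lab[dist > window] <- NA
  tb <- sort(table(lab), decreasing = TRUE)
  keep <- as.integer(names(tb))[seq_len(min(top_k, length(tb)))]
  lab[!(lab %in% keep)] <- NA
  lab
}
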