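# Independent oracle implementations used to cross-check the package.
# These deliberately use naive algorithms (flood fill, per-pixel loops)
# distinct from the implementation paths they verify.

# count 8-connected components by explicit flood fill
flood_fill_count <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  count <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] > 0 && !seen[i, j]) {
      count <- count + 1L
      stack <- list(c(i, j))
      seen[i, j] <- TRUE
      while (length(stack) > 0) {
        px <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ni <- px[1] + di; nj <- px[2] + dj
          if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
              mask[ni, nj] > 0 && !seen[ni, nj]) {
            seen[ni, nj] <- TRUE
            stack[[length(stack) + 1L]] <- c(ni, nj)
          }
        }
      }
    }
  }
  count
}

# brute-force bilinear interpolation of `img` at a single 0-based
# (r, c) position with edge clamping
bilinear_at <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- min(max(r, 0), H - 1); c <- min(max(c, 0), W - 1)
  r0 <- min(floor(r), H - 2); c0 <- min(floor(c), W - 2)
  if (H == 1) r0 <- 0
  if (W == 1) c0 <- 0
  fr <- r - r0; fc <- c - c0
  v00 <- img[r0 + 1, c0 + 1]
  v10 <- img[min(r0 + 2, H), c0 + 1]
  v01 <- img[r0 + 1, min(c0 + 2, W)]
  v11 <- img[min(r0 + 2, H), min(c0 + 2, W)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# per-pixel raster-walk evaluation oracle: assigns every prediction to a
# ground-truth bead or background by scanning all beads per pixel, then
# computes the metrics from first principles
oracle_evaluate <- function(gt, preds, shape, hw = 3L, seed_size = 2L,
                            margin = 4L) {
  H <- shape[1]; W <- shape[2]
  n_gt <- nrow(gt)
  region_of <- function(pr, pc) {
    best_k <- 0L; best_d <- Inf
    for (k in seq_len(n_gt)) {
      r0 <- ceiling(gt$row[k] - (seed_size - 1) / 2 - 0.5) - hw
      c0 <- ceiling(gt$col[k] - (seed_size - 1) / 2 - 0.5) - hw
      side <- seed_size + 2L * hw
      if (pr >= r0 && pr <= r0 + side - 1 && pc >= c0 && pc <= c0 + side - 1) {
        d <- (pr - gt$row[k])^2 + (pc - gt$col[k])^2
        if (d < best_d) { best_d <- d; best_k <- k }
      }
    }
    best_k
  }
  seeds <- integer(n_gt); added <- 0L; border <- 0L
  if (nrow(preds) > 0) for (i in seq_len(nrow(preds))) {
    pr <- floor(preds$row[i] + 0.5); pc <- floor(preds$col[i] + 0.5)
    if (pr < 0 || pr > H - 1 || pc < 0 || pc > W - 1) { border <- border + 1L; next }
    k <- region_of(pr, pc)
    if (k > 0) seeds[k] <- seeds[k] + 1L
    else if (pr < margin || pr > H - 1 - margin ||
             pc < margin || pc > W - 1 - margin) border <- border + 1L
    else added <- added + 1L
  }
  miss <- sum(seeds == 0); split <- sum(seeds >= 2)
  extra <- sum(pmax(seeds - 1, 0))
  tp <- n_gt - miss; fp <- added + extra; fn <- miss
  qp <- if (tp + fp > 0) tp / (tp + fp) else 0
  qr <- tp / (tp + fn)
  list(Q_P = qp, Q_R = qr,
       Q_F = if (tp == 0) 0 else 2 * qp * qr / (qp + qr),
       Q_split = 100 * split / n_gt, Q_miss = 100 * miss / n_gt,
       Q_add = 100 * added / n_gt,
       detections = 100 * (tp + extra + added) / n_gt,
       seeds = seeds, added = added, border = border)
}

# exhaustive-search Otsu oracle: tries every candidate bin boundary and
# computes the between-class variance directly from the two classes
oracle_otsu <- function(values, n_bins = 256L) {
  breaks <- seq(0, 1, length.out = n_bins + 1)
  best_t <- NA; best_v <- -Inf
  bin <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  x <- centers[bin]                    # values quantized to bin centers
  for (t in seq_len(n_bins - 1)) {
    thr <- breaks[t + 1]
    lo <- x[bin <= t]; hi <- x[bin > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-15) { best_v <- v; best_t <- thr }
  }
  best_t
}

# small reusable synthetic splits
make_scenes <- function(n, seed0, ...) {
  lapply(seq_len(n), function(i)
    generate_scene(scene_config(rng_seed = seed0 + i, ...)))
}
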