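#' Parameters for the classical baseline detectors
#'
#' @param diameter_range Length-2 numeric, bead diameter range in px *at
#'   the resolution the detector runs on* (pass the upsampled-frame range
#'   when detecting on upsampled images).
#' @param log_rel_threshold Blob response threshold as a fraction of the
#'   global maximum response.
#' @param hough_sensitivity Accumulator peak threshold as a fraction of the
#'   accumulator maximum.
#' @param min_distance Minimum distance between detections in px; defaults
#'   to the minimum diameter.
#' @return Object of class `baseline_params`.
#' @export
baseline_params <- function(diameter_range = c(8, 16),
                            log_rel_threshold = 0.1,
                            hough_sensitivity = 0.5,
                            min_distance = NULL) {
  stopifnot(length(diameter_range) == 2, diameter_range[1] > 0,
            diameter_range[2] >= diameter_range[1])
  if (log_rel_threshold <= 0 || log_rel_threshold > 1 ||
      hough_sensitivity <= 0 || hough_sensitivity > 1)
    stop("thresholds must lie in (0, 1]")
  if (is.null(min_distance)) min_distance <- diameter_range[1]
  if (min_distance < 1) stop("min_distance must be >= 1")
  structure(list(diameter_range = as.numeric(diameter_range),
                 log_rel_threshold = log_rel_threshold,
                 hough_sensitivity = hough_sensitivity,
                 min_distance = min_distance),
            class = "baseline_params")
}

# local maxima of a response raster: pixels >= all 8 neighbours and above
# `thr`, reduced by greedy non-maximum suppression (strongest first, ties
# by smallest row then col, so plateau ties resolve to the smallest
# coordinates) at Euclidean distance `min_distance`. Returns 0-based
# (row, col, value).
find_local_maxima <- function(resp, thr, min_distance, mask = NULL) {
  H <- nrow(resp); W <- ncol(resp)
  padded <- matrix(-Inf, H + 2, W + 2)
  padded[2:(H + 1), 2:(W + 1)] <- resp
  nb_max <- matrix(-Inf, H, W)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb_max <- pmax(nb_max, padded[(2 + di):(H + 1 + di),
                                  (2 + dj):(W + 1 + dj)])
  }
  cand <- resp >= nb_max & resp >= thr & is.finite(resp)
  if (!is.null(mask)) cand <- cand & (mask > 0)
  idx <- which(cand)
  if (length(idx) == 0)
    return(data.frame(row = numeric(0), col = numeric(0), value = numeric(0)))
  r <- (idx - 1L) %% H
  c <- (idx - 1L) %/% H
  v <- resp[idx]
  o <- order(-v, r, c)
  r <- r[o]; c <- c[o]; v <- v[o]
  keep <- logical(length(r))
  alive <- rep(TRUE, length(r))
  for (i in seq_along(r)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    d2 <- (r - r[i])^2 + (c - c[i])^2
    alive[d2 < min_distance^2] <- FALSE
  }
  data.frame(row = r[keep], col = c[keep], value = v[keep])
}

as_detection_set <- function(rows, cols, areas, source) {
  out <- data.frame(row = as.numeric(rows), col = as.numeric(cols),
                    area = as.integer(areas))
  attr(out, "source") <- source
  class(out) <- c("detection_set", class(out))
  out
}

# scale-normalized Laplacian-of-Gaussian kernel (zero-sum); responds
# negatively at the center of bright blobs of matched size
log_kernel <- function(sigma) {
  R <- max(2L, as.integer(ceiling(3.5 * sigma)))
  x <- -R:R
  g2 <- outer(x^2, x^2, `+`)
  k <- (g2 - 2 * sigma^2) / sigma^4 * exp(-g2 / (2 * sigma^2))
  k <- sigma^2 * k / (2 * pi * sigma^2)   # scale-normalized
  k - mean(k)                              # exact zero response on constants
}

#' Laplacian-of-Gaussian blob detection
#'
#' Computes scale-normalized LoG responses at sigma = d / (2 sqrt(2)) for
#' three diameters spanning `diameter_range`, takes the pixelwise maximum
#' of the negated responses (bright blobs), and keeps local maxima above
#' `log_rel_threshold` times the global maximum, greedily separated by
#' `min_distance` (strongest first). This is the seed-detection stage of
#' classical LoG spot-detection pipelines.
#'
#' @param image Normalized numeric matrix.
#' @param params A [baseline_params()] with diameters in the input frame.
#' @return A `detection_set` (coordinates in the input image frame).
#' @export
detect_log <- function(image, params = baseline_params()) {
  stopifnot(is.matrix(image))
  diam <- seq(params$diameter_range[1], params$diameter_range[2],
              length.out = 3)
  resp <- NULL
  for (d in diam) {
    sigma <- d / (2 * sqrt(2))
    r <- -EBImage::filter2(image, log_kernel(sigma), boundary = "replicate")
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  mx <- max(resp)
  # absolute floor: constant or near-constant images carry no blob signal
  if (!is.finite(mx) || mx <= 1e-6)
    return(as_detection_set(numeric(0), numeric(0), integer(0), "log"))
  peaks <- find_local_maxima(resp, params$log_rel_threshold * mx,
                             params$min_distance)
  as_detection_set(peaks$row, peaks$col, rep(1L, nrow(peaks)), "log")
}

#' Circular Hough transform detection
#'
#' Classic gradient-vote circle detection: an edge map is formed by
#' thresholding the gradient magnitude at its Otsu threshold; each edge
#' pixel casts one vote per candidate integer radius at the position
#' `radius` px along its (uphill) gradient direction, where the center of a
#' bright disk of that radius would lie. Per-radius accumulators are
#' lightly smoothed and combined by pixelwise maximum; detections are
#' accumulator peaks above `hough_sensitivity` times the maximum,
#' non-maximum-suppressed at `min_distance`.
#'
#' @inheritParams detect_log
#' @return A `detection_set`.
#' @export
detect_hough <- function(image, params = baseline_params()) {
  stopifnot(is.matrix(image))
  radii <- seq(max(1L, as.integer(round(params$diameter_range[1] / 2))),
               as.integer(round(params$diameter_range[2] / 2)))
  if (length(radii) == 0 || radii[1] > radii[length(radii)])
    stop("radius range is empty after rounding")
  H <- nrow(image); W <- ncol(image)
  gr <- matrix(0, H, W); gc <- matrix(0, H, W)
  gr[2:(H - 1), ] <- (image[3:H, ] - image[1:(H - 2), ]) / 2
  gc[, 2:(W - 1)] <- (image[, 3:W] - image[, 1:(W - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  mmax <- max(mag)
  if (mmax <= 0)
    return(as_detection_set(numeric(0), numeric(0), integer(0), "hough"))
  thr <- otsu_threshold(mag / mmax) * mmax
  edge <- which(mag > thr)
  if (length(edge) == 0)
    return(as_detection_set(numeric(0), numeric(0), integer(0), "hough"))
  er <- (edge - 1L) %% H
  ec <- (edge - 1L) %/% H
  ur <- gr[edge] / mag[edge]
  uc <- gc[edge] / mag[edge]
  # votes are normalized by the expected peak support of a true circle of
  # that radius (a fraction of its circumference, accounting for vote
  # scatter and smoothing), so the sensitivity acts as an absolute
  # confidence: circles with radii outside the searched range spread
  # their votes over an annulus and stay below it
  concentration <- 0.15
  acc_max <- matrix(0, H, W)
  for (rad in radii) {
    vr <- as.integer(round(er + rad * ur))
    vc <- as.integer(round(ec + rad * uc))
    ok <- vr >= 0 & vr <= H - 1 & vc >= 0 & vc <= W - 1
    acc <- matrix(0, H, W)
    if (any(ok)) {
      tab <- table(vr[ok] + vc[ok] * H + 1L)
      acc[as.integer(names(tab))] <- as.numeric(tab)
    }
    acc_max <- pmax(acc_max,
                    gauss_blur(acc, 1) / (concentration * 2 * pi * rad))
  }
  if (max(acc_max) <= 0)
    return(as_detection_set(numeric(0), numeric(0), integer(0), "hough"))
  peaks <- find_local_maxima(acc_max, params$hough_sensitivity,
                             params$min_distance)
  as_detection_set(peaks$row, peaks$col, rep(1L, nrow(peaks)), "hough")
}

#' Otsu threshold of an intensity raster
#'
#' Computes the global threshold maximizing the between-class variance over
#' a 256-bin histogram of values in \[0, 1\]. Returned is the bin boundary
#' separating the two classes (smallest maximizer on ties); use
#' `image > threshold` for the foreground mask.
#'
#' @param image Numeric matrix (or vector) with values in \[0, 1\].
#' @param n_bins Number of histogram bins.
#' @return Threshold value in \[0, 1\].
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  stopifnot(all(v >= 0 & v <= 1))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  h <- tabulate(bin, n_bins)
  n <- length(v)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w0 <- cumsum(h) / n                       # class 0: bins 1..t
  mu_cum <- cumsum(h * centers) / n
  mu_t <- mu_cum[n_bins]
  sb2 <- rep(-Inf, n_bins - 1)
  t <- seq_len(n_bins - 1)
  valid <- w0[t] > 0 & w0[t] < 1
  sb2[valid] <- (mu_t * w0[t][valid] - mu_cum[t][valid])^2 /
    (w0[t][valid] * (1 - w0[t][valid]))
  if (!any(is.finite(sb2))) return(breaks[2])   # degenerate: one class
  best <- which.max(sb2)                        # smallest index on ties
  breaks[best + 1]
}

#' Otsu thresholding with Euclidean distance transform
#'
#' The simplest baseline: a global Otsu threshold yields a foreground mask,
#' the Euclidean distance transform of the mask is computed, and local
#' maxima of the distance map inside the foreground (separated by
#' `min_distance`) become detections. Foreground components left without
#' any surviving maximum contribute their centroid instead. Touching beads
#' merged by the threshold frequently yield a single distance maximum --
#' the under-segmentation failure mode this baseline is known for.
#'
#' @inheritParams detect_log
#' @return A `detection_set`.
#' @export
detect_otsu_edt <- function(image, params = baseline_params()) {
  stopifnot(is.matrix(image))
  thr <- otsu_threshold(pmin(pmax(image, 0), 1))
  fg <- matrix(as.integer(image > thr), nrow(image))
  if (!any(fg > 0))
    return(as_detection_set(numeric(0), numeric(0), integer(0), "otsu_edt"))
  edt <- matrix(as.numeric(EBImage::distmap(fg, metric = "euclidean")),
                nrow(fg))
  peaks <- find_local_maxima(edt, thr = .Machine$double.eps,
                             min_distance = params$min_distance, mask = fg)
  labels <- label_components(fg)
  hit <- rep(FALSE, max(labels))
  if (nrow(peaks) > 0)
    hit[labels[cbind(peaks$row + 1L, peaks$col + 1L)]] <- TRUE
  rows <- peaks$row; cols <- peaks$col
  if (!all(hit)) {
    cent <- extract_centroids(labels)
    missed <- which(!hit)
    rows <- c(rows, cent$row[missed])
    cols <- c(cols, cent$col[missed])
  }
  as_detection_set(rows, cols, rep(1L, length(rows)), "otsu_edt")
}

# separable Gaussian blur with replicate boundary, implemented as banded
# interpolation matrices so results are bit-reproducible
gauss_blur_matrix <- function(n, sigma) {
  R <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(-R:R)^2 / (2 * sigma^2))
  k <- k / sum(k)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + (-R:R), 1L), n)    # replicate edges
    for (m in seq_along(j)) A[i, j[m]] <- A[i, j[m]] + k[m]
  }
  A
}

gauss_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  A <- gauss_blur_matrix(nrow(image), sigma)
  B <- gauss_blur_matrix(ncol(image), sigma)
  A %*% image %*% t(B)
}
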