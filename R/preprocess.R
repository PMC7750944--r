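#' Robust percentile min-max intensity normalization
#'
#' Maps the 1st percentile to 0 and the 99th percentile to 1, then clips to
#' \[0, 1\]. Robust against hot pixels and dead pixels. Constant images map
#' to all zeros.
#'
#' @param image Numeric matrix.
#' @param probs Length-2 percentile pair used as the min/max anchors.
#' @return Numeric matrix in \[0, 1\].
#' @export
normalize_intensity <- function(image, probs = c(0.01, 0.99)) {
  stopifnot(is.matrix(image), length(image) > 0)
  q <- stats::quantile(image, probs, names = FALSE)
  if (q[2] <= q[1]) return(matrix(0, nrow(image), ncol(image)))
  pmin(pmax((image - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Map the bead diameter range to an upsampling factor
#'
#' Chooses the integer factor that brings the smallest bead to about 8 px,
#' `ceiling(8 / min_diameter)`, so that 2 px beads get a fourfold
#' upsampling.
#'
#' @param diameter_range Length-2 numeric, bead FWHM range in px.
#' @return Positive integer factor.
#' @export
diameter_to_factor <- function(diameter_range) {
  stopifnot(diameter_range[1] > 0)
  max(1L, as.integer(ceiling(8 / diameter_range[1])))
}

# 1-D bilinear interpolation matrix under pixel-area alignment: output
# pixel R (0-based) samples the input at (R + 0.5)/factor - 0.5, clamped to
# the valid coordinate range.
bilinear_matrix <- function(n_in, factor) {
  n_out <- n_in * factor
  x <- ((0:(n_out - 1)) + 0.5) / factor - 0.5
  x <- pmin(pmax(x, 0), n_in - 1)
  x0 <- pmin(floor(x), n_in - 2)
  if (n_in == 1) x0 <- rep(0, n_out)
  w <- x - x0
  A <- matrix(0, n_out, n_in)
  if (n_in == 1) {
    A[, 1] <- 1
  } else {
    A[cbind(seq_len(n_out), x0 + 1)] <- 1 - w
    A[cbind(seq_len(n_out), x0 + 2)] <- A[cbind(seq_len(n_out), x0 + 2)] + w
  }
  A
}

#' Bilinear image upsampling
#'
#' Enlarges the image by an integer factor with bilinear interpolation
#' under pixel-area alignment: original pixel `c` maps to the block
#' `[factor*c, factor*c + factor - 1]`, whose center sits at
#' `factor*c + (factor-1)/2`. This makes touching beads separable before
#' seed detection. Interpolation is separable and exact (output values are
#' the bilinear interpolant of the input evaluated at output pixel
#' centers, with edge clamping).
#'
#' @param image Numeric matrix.
#' @param factor Positive integer upsampling factor.
#' @return Matrix of size `factor*nrow` x `factor*ncol`.
#' @export
upsample_bilinear <- function(image, factor = 4L) {
  stopifnot(is.matrix(image))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("upsampling factor must be >= 1")
  if (factor == 1L) return(image)
  A <- bilinear_matrix(nrow(image), factor)
  B <- bilinear_matrix(ncol(image), factor)
  A %*% image %*% t(B)
}

#' Map a centroid from original to upsampled coordinates
#'
#' Under pixel-area alignment an original position `p` maps to
#' `factor*p + (factor-1)/2`, the center of its pixel block.
#'
#' @param centroid Numeric `(row, col)` or a matrix/data.frame with `row`,
#'   `col` columns, 0-based.
#' @param factor Positive integer upsampling factor.
#' @return Same shape as the input, in upsampled 0-based coordinates.
#' @export
map_centroid_up <- function(centroid, factor = 4L) {
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  off <- (factor - 1) / 2
  if (is.data.frame(centroid)) {
    centroid$row <- factor * centroid$row + off
    centroid$col <- factor * centroid$col + off
    centroid
  } else {
    factor * centroid + off
  }
}

# start index (0-based) of the length-s block whose center is nearest x;
# ties broken toward the smaller index
seed_block_start <- function(x, s) ceiling(x - (s - 1) / 2 - 0.5)

#' Render a binary seed mask from centroids
#'
#' Each centroid (in upsampled coordinates) paints a `seed_size` x
#' `seed_size` block of ones, placed so the block center is nearest the
#' centroid (ties toward smaller indices); blocks are clipped at the image
#' edge. For the default fourfold upsampling of an integer original
#' centroid `(r, c)`, the 2 x 2 seed covers rows `{4r+1, 4r+2}` and columns
#' `{4c+1, 4c+2}`, so seeds of beads one original pixel apart keep a 2 px
#' gap.
#'
#' @param centroids data.frame with `row`, `col` (upsampled 0-based) or a
#'   2-column matrix.
#' @param shape `(height, width)` of the upsampled raster.
#' @param seed_size Seed side length in px.
#' @return Binary matrix of class `seed_mask`, with attributes `seed_size`,
#'   `dilated = FALSE` and `n_skipped` (centroids outside the image).
#' @export
render_seed_mask <- function(centroids, shape, seed_size = 2L) {
  if (is.data.frame(centroids)) {
    rows <- centroids$row; cols <- centroids$col
  } else if (is.matrix(centroids)) {
    rows <- centroids[, 1]; cols <- centroids[, 2]
  } else if (length(centroids) == 0) {
    rows <- cols <- numeric(0)
  } else stop("centroids must be a data.frame or matrix")
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  s <- as.integer(seed_size)
  mask <- matrix(0L, H, W)
  n_skipped <- 0L
  for (i in seq_along(rows)) {
    if (is.na(rows[i]) || rows[i] < 0 || rows[i] > H - 1 ||
        cols[i] < 0 || cols[i] > W - 1) {
      n_skipped <- n_skipped + 1L
      next
    }
    r0 <- seed_block_start(rows[i], s)
    c0 <- seed_block_start(cols[i], s)
    rr <- max(r0, 0L):min(r0 + s - 1L, H - 1L)
    cc <- max(c0, 0L):min(c0 + s - 1L, W - 1L)
    mask[rr + 1L, cc + 1L] <- 1L
  }
  if (n_skipped > 0)
    warning(n_skipped, " centroid(s) outside the image were skipped")
  structure(mask, seed_size = s, dilated = FALSE, n_skipped = n_skipped,
            class = c("seed_mask", class(mask)))
}

#' Dilate a seed mask with a 3x3 cross
#'
#' Morphological dilation with a plus-shaped structuring element. Enlarged
#' seeds make the detector more robust, but seeds of nearby beads may merge
#' into one component, which can increase missing detections.
#'
#' @param mask Binary matrix (typically a `seed_mask`).
#' @return Dilated mask with attribute `dilated = TRUE`.
#' @export
dilate_seeds_cross <- function(mask) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  out <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask)),
                         EBImage::makeBrush(3L, "diamond"))
  out <- matrix(as.integer(out > 0.5), nrow(mask))
  structure(out, seed_size = attr(mask, "seed_size"), dilated = TRUE,
            class = c("seed_mask", class(out)))
}

#' Read/write a seed mask as 8-bit TIFF (0/255 on disk, 0/1 in memory)
#'
#' @param mask Binary matrix.
#' @param path TIFF path.
#' @export
write_seed_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_seed_mask
#' @export
read_seed_mask <- function(path) {
  m <- read_image(path)
  matrix(as.integer(m > 0.5), nrow(m))
}
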