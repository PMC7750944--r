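#' Binarize a probability raster
#'
#' Applies the global detection threshold: a pixel is foreground iff its
#' probability is strictly greater than `threshold` (default 0.5; exact
#' ties are background).
#'
#' @param prob Numeric matrix with values in \[0, 1\].
#' @param threshold Threshold in \[0, 1\].
#' @return Integer 0/1 matrix.
#' @export
binarize <- function(prob, threshold = 0.5) {
  stopifnot(is.matrix(prob))
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  matrix(as.integer(prob > threshold), nrow(prob))
}

#' Label 8-connected components
#'
#' Connected-component labeling of a binary raster under 8-connectivity
#' (diagonal neighbours belong to the same component). Labels are
#' 1..K with background 0, numbered by first occurrence in column-major
#' scan order. Implemented as 4-connectivity labeling followed by a
#' union-find merge of labels that touch diagonally.
#'
#' @param binary Binary (0/1) matrix.
#' @return Integer matrix of labels.
#' @export
label_components <- function(binary) {
  stopifnot(is.matrix(binary))
  if (!any(binary > 0)) return(matrix(0L, nrow(binary), ncol(binary)))
  lab4 <- EBImage::bwlabel(matrix(as.numeric(binary > 0), nrow(binary)))
  lab4 <- matrix(as.integer(lab4), nrow(binary))
  K <- max(lab4)
  parent <- seq_len(K)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  H <- nrow(lab4); W <- ncol(lab4)
  # diagonal adjacencies: compare the two diagonal shifts
  dl <- lab4[-H, -W]; dr <- lab4[-1, -1]   # down-right pairs
  sel <- dl > 0 & dr > 0 & dl != dr
  if (any(sel)) mapply(union, dl[sel], dr[sel])
  ul <- lab4[-1, -W]; ur <- lab4[-H, -1]   # up-right pairs
  sel <- ul > 0 & ur > 0 & ul != ur
  if (any(sel)) mapply(union, ul[sel], ur[sel])
  roots <- vapply(seq_len(K), find, integer(1))
  # renumber roots by first occurrence in column-major order
  fg <- which(lab4 > 0)
  root_per_px <- roots[lab4[fg]]
  new_id <- integer(K)
  next_id <- 0L
  for (r in root_per_px) {
    if (new_id[r] == 0L) { next_id <- next_id + 1L; new_id[r] <- next_id }
  }
  out <- matrix(0L, H, W)
  out[fg] <- new_id[root_per_px]
  out
}

#' Extract component centroids
#'
#' Per labeled component, the centroid is the unweighted mean of member
#' pixel coordinates (0-based row/col, pixel centers at integers).
#'
#' @param labeled Integer label matrix from [label_components()].
#' @param source Provenance string stored on the result.
#' @param min_area Minimum component size in px; smaller components are
#'   dropped (default 1 keeps everything).
#' @return data.frame of class `detection_set` with columns `row`, `col`,
#'   `area`, one row per component.
#' @export
extract_centroids <- function(labeled, source = "detector", min_area = 1L) {
  stopifnot(is.matrix(labeled))
  fg <- which(labeled > 0)
  if (length(fg) == 0) {
    out <- data.frame(row = numeric(0), col = numeric(0), area = integer(0))
  } else {
    lab <- labeled[fg]
    r <- (fg - 1L) %% nrow(labeled)        # 0-based row
    c <- (fg - 1L) %/% nrow(labeled)       # 0-based col
    area <- as.integer(tapply(lab, lab, length))
    out <- data.frame(row = as.numeric(tapply(r, lab, mean)),
                      col = as.numeric(tapply(c, lab, mean)),
                      area = area)
    out <- out[out$area >= min_area, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "source") <- source
  class(out) <- c("detection_set", class(out))
  out
}

#' Count detected beads
#'
#' @param detections A `detection_set` from [extract_centroids()].
#' @return Non-negative integer, the number of centroids.
#' @export
count_beads <- function(detections) {
  nrow(detections)
}

#' Probability raster to detections in one call
#'
#' Threshold, label 8-connected components and extract centroids.
#'
#' @inheritParams binarize
#' @inheritParams extract_centroids
#' @return A `detection_set`.
#' @export
prob_to_detections <- function(prob, threshold = 0.5, source = "detector",
                               min_area = 1L) {
  extract_centroids(label_components(binarize(prob, threshold)),
                    source = source, min_area = min_area)
}
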