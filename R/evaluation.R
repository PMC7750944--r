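#' Construct a match table from raw counts
#'
#' A match table holds, for one image or a pooled set of images, the number
#' of ground-truth beads, the number of predicted seeds that fell inside
#' each bead's enlarged region, the number of added predictions (in the
#' ground-truth background, away from the border), and the number of
#' background predictions ignored because they lie in the border area.
#'
#' @param n_gt Number of ground-truth beads.
#' @param seeds_per_bead Integer vector of length `n_gt`.
#' @param n_added Background predictions outside the border area.
#' @param n_border_ignored Background predictions inside the border area.
#' @return Object of class `match_table`.
#' @export
match_table <- function(n_gt, seeds_per_bead = integer(n_gt), n_added = 0L,
                        n_border_ignored = 0L) {
  n_gt <- as.integer(n_gt)
  seeds_per_bead <- as.integer(seeds_per_bead)
  if (n_gt < 0 || length(seeds_per_bead) != n_gt)
    stop("seeds_per_bead must have one entry per ground-truth bead")
  if (any(seeds_per_bead < 0) || n_added < 0 || n_border_ignored < 0)
    stop("counts must be non-negative")
  structure(list(n_gt = n_gt, seeds_per_bead = seeds_per_bead,
                 n_added = as.integer(n_added),
                 n_border_ignored = as.integer(n_border_ignored)),
            class = "match_table")
}

#' Enlarge ground-truth seeds into evaluation regions
#'
#' For scoring, each ground-truth bead's 2 x 2 seed is grown into a square
#' region of side `2*halfwidth + 2` (8 x 8 by default), so that a predicted
#' centroid anywhere near the true center counts as hitting that bead.
#' Where regions would overlap, each pixel is assigned to the nearest
#' ground-truth centroid (Euclidean distance; ties go to the lower bead
#' index). Regions are clipped at the image edge.
#'
#' @param gt_centroids data.frame with `row`, `col` in upsampled 0-based
#'   coordinates (one row per bead; bead index = row order).
#' @param shape `(height, width)` of the upsampled raster.
#' @param enlargement_halfwidth Growth in px on each side of the seed.
#' @param seed_size Seed side length in px (the region is centered on the
#'   seed block).
#' @return Integer label matrix: 0 background, k for bead k.
#' @export
enlarge_gt <- function(gt_centroids, shape, enlargement_halfwidth = 3L,
                       seed_size = 2L) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  hw <- as.integer(enlargement_halfwidth)
  s <- as.integer(seed_size)
  labels <- matrix(0L, H, W)
  if (nrow(gt_centroids) == 0) return(labels)
  best <- matrix(Inf, H, W)
  for (k in seq_len(nrow(gt_centroids))) {
    rk <- gt_centroids$row[k]; ck <- gt_centroids$col[k]
    r0 <- seed_block_start(rk, s) - hw
    c0 <- seed_block_start(ck, s) - hw
    rr <- max(r0, 0L):min(r0 + s + 2L * hw - 1L, H - 1L)
    cc <- max(c0, 0L):min(c0 + s + 2L * hw - 1L, W - 1L)
    if (length(rr) == 0 || length(cc) == 0) next
    d2 <- outer((rr - rk)^2, (cc - ck)^2, `+`)
    sub_best <- best[rr + 1L, cc + 1L, drop = FALSE]
    take <- d2 < sub_best     # strict: earlier (lower-index) bead keeps ties
    if (any(take)) {
      sub_lab <- labels[rr + 1L, cc + 1L, drop = FALSE]
      sub_lab[take] <- k
      sub_best[take] <- d2[take]
      labels[rr + 1L, cc + 1L] <- sub_lab
      best[rr + 1L, cc + 1L] <- sub_best
    }
  }
  labels
}

#' Match predicted centroids against enlarged ground truth
#'
#' Each predicted centroid is rounded to its nearest pixel and assigned to
#' the ground-truth region containing it, or to background. Background
#' predictions within `border_margin` px of any image edge are ignored
#' (only fully visible beads are annotated, so near-border predictions
#' cannot be scored fairly); the rest count as added. Predictions outside
#' the raster are counted as border-ignored with a warning.
#'
#' @param gt_regions Label matrix from [enlarge_gt()].
#' @param predictions A `detection_set` (or data.frame with `row`, `col`)
#'   in the same upsampled coordinate frame.
#' @param border_margin Border width in px.
#' @return A [match_table()].
#' @export
match_detections <- function(gt_regions, predictions, border_margin = 4L) {
  H <- nrow(gt_regions); W <- ncol(gt_regions)
  n_gt <- max(gt_regions, 0L)
  seeds <- integer(n_gt)
  n_added <- 0L; n_border <- 0L; n_outside <- 0L
  m <- as.integer(border_margin)
  if (nrow(predictions) > 0) {
    pr <- floor(predictions$row + 0.5)   # round half up, deterministic
    pc <- floor(predictions$col + 0.5)
    for (i in seq_along(pr)) {
      if (pr[i] < 0 || pr[i] > H - 1 || pc[i] < 0 || pc[i] > W - 1) {
        n_border <- n_border + 1L
        n_outside <- n_outside + 1L
        next
      }
      lab <- gt_regions[pr[i] + 1L, pc[i] + 1L]
      if (lab > 0L) {
        seeds[lab] <- seeds[lab] + 1L
      } else if (pr[i] < m || pr[i] > H - 1 - m ||
                 pc[i] < m || pc[i] > W - 1 - m) {
        n_border <- n_border + 1L
      } else {
        n_added <- n_added + 1L
      }
    }
  }
  if (n_outside > 0)
    warning(n_outside, " prediction(s) outside the raster counted as ",
            "border-ignored")
  match_table(n_gt, seeds, n_added, n_border)
}

#' Pool match tables across images
#'
#' Counts are summed (micro-averaging), so pooled metrics weight every bead
#' equally rather than every image.
#'
#' @param tables List of [match_table()] objects.
#' @return A single `match_table`.
#' @export
pool_match_tables <- function(tables) {
  stopifnot(length(tables) > 0)
  match_table(sum(vapply(tables, `[[`, 0L, "n_gt")),
              unlist(lapply(tables, `[[`, "seeds_per_bead")),
              sum(vapply(tables, `[[`, 0L, "n_added")),
              sum(vapply(tables, `[[`, 0L, "n_border_ignored")))
}

#' Compute detection metrics from a match table
#'
#' With `miss` the number of beads with no predicted seed, `split` the
#' number with more than one, `extra` the surplus seeds on split beads
#' (count minus one per bead), and `added` the background predictions:
#' `TP = n_gt - miss`, `FP = added + extra`, `FN = miss`. Reported are
#' precision `Q_P`, recall `Q_R`, F-score `Q_F`, and the percentages of
#' split, missing and added beads relative to `n_gt`, plus the total
#' counted detections as a percentage of `n_gt`
#' (`100 * (TP + extra + added) / n_gt`).
#'
#' @param table A [match_table()] with `n_gt > 0`.
#' @return Object of class `eval_report`: named list with `Q_F`, `Q_P`,
#'   `Q_R`, `Q_split`, `Q_miss`, `Q_add`, `detections`, and the underlying
#'   counts.
#' @export
compute_metrics <- function(table) {
  stopifnot(inherits(table, "match_table"))
  if (table$n_gt == 0)
    stop("metrics are undefined for zero ground-truth beads")
  n_gt <- table$n_gt
  miss <- sum(table$seeds_per_bead == 0L)
  split <- sum(table$seeds_per_bead >= 2L)
  extra <- sum(pmax(table$seeds_per_bead - 1L, 0L))
  tp <- n_gt - miss
  fp <- table$n_added + extra
  fn <- miss
  q_p <- if (tp + fp > 0) tp / (tp + fp) else 0
  q_r <- tp / (tp + fn)
  q_f <- if (tp == 0) 0 else 2 * q_p * q_r / (q_p + q_r)
  structure(list(
    Q_F = q_f, Q_P = q_p, Q_R = q_r,
    Q_split = 100 * split / n_gt,
    Q_miss = 100 * miss / n_gt,
    Q_add = 100 * table$n_added / n_gt,
    detections = 100 * (tp + extra + table$n_added) / n_gt,
    counts = list(n_gt = n_gt, miss = miss, split = split, extra = extra,
                  added = table$n_added, tp = tp, fp = fp, fn = fn,
                  border_ignored = table$n_border_ignored)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "bead detection report (n_gt = %d)\n  F-score  Q_F     %.3f\n  precision Q_P    %.3f\n  recall    Q_R    %.3f\n  split     %%      %.2f\n  missing   %%      %.2f\n  added     %%      %.2f\n  detections %%     %.2f\n",
    x$counts$n_gt, x$Q_F, x$Q_P, x$Q_R, x$Q_split, x$Q_miss, x$Q_add,
    x$detections))
  invisible(x)
}

#' Convert an evaluation report to a one-row data.frame
#'
#' Columns follow the standard summary-table order: F-score, precision,
#' recall, split %, missing %, added %, detections %.
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row data.frame.
#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(Q_F = x$Q_F, Q_P = x$Q_P, Q_R = x$Q_R, Q_split = x$Q_split,
             Q_miss = x$Q_miss, Q_add = x$Q_add, detections = x$detections)
}

#' Evaluate a detector over a set of annotated images
#'
#' Runs `detector` on each image, matches its detections against the
#' enlarged ground truth, pools the match tables across images
#' (micro-averaging, so the result equals the metrics of the concatenated
#' counts, not the mean of per-image metrics) and computes one report.
#'
#' @param scenes List of scenes, each a list with `image` (original
#'   resolution matrix) and `annotation` (data.frame with `row`, `col`,
#'   original-resolution 0-based; rows with `fully_visible == FALSE` are
#'   dropped).
#' @param detector Function `(image_upsampled) -> detection_set` operating
#'   on the normalized, upsampled image.
#' @param factor Upsampling factor applied before detection.
#' @param enlargement_halfwidth,seed_size,border_margin Evaluation
#'   geometry; see [enlarge_gt()] and [match_detections()].
#' @return List with `report` (pooled `eval_report`), `per_image` (list of
#'   `match_table`), and `per_image_reports` (data.frame, one row per
#'   image; `NA` metrics where an image has no ground truth).
#' @export
evaluate_detector <- function(scenes, detector, factor = 4L,
                              enlargement_halfwidth = 3L, seed_size = 2L,
                              border_margin = 4L) {
  stopifnot(length(scenes) >= 1)
  tables <- list()
  rows <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    ann <- sc$annotation
    if (is.null(ann)) {
      warning("image ", i, " has no ground truth; skipped")
      next
    }
    if ("fully_visible" %in% names(ann))
      ann <- ann[is.na(ann$fully_visible) | ann$fully_visible, , drop = FALSE]
    up <- upsample_bilinear(normalize_intensity(sc$image), factor)
    det <- detector(up)
    gt_up <- map_centroid_up(ann[, c("row", "col"), drop = FALSE], factor)
    regions <- enlarge_gt(gt_up, dim(up), enlargement_halfwidth, seed_size)
    tab <- match_detections(regions, det, border_margin)
    tables[[length(tables) + 1L]] <- tab
    rows[[length(rows) + 1L]] <-
      if (tab$n_gt > 0) as.data.frame(compute_metrics(tab)) else
        data.frame(Q_F = NA_real_, Q_P = NA_real_, Q_R = NA_real_,
                   Q_split = NA_real_, Q_miss = NA_real_, Q_add = NA_real_,
                   detections = NA_real_)
  }
  if (length(tables) == 0) stop("no usable annotated images")
  pooled <- pool_match_tables(tables)
  list(report = compute_metrics(pooled), per_image = tables,
       per_image_reports = do.call(rbind, rows))
}
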