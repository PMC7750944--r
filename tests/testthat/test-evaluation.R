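test_that("ground-truth enlargement builds nearest-centroid regions", {
  # single seed: one 8x8 region (halfwidth 3 around a 2x2 seed)
  gt <- data.frame(row = 15.5, col = 15.5)
  reg <- enlarge_gt(gt, c(32, 32))
  expect_equal(sum(reg == 1), 64)
  px <- which(reg == 1)
  expect_equal(range((px - 1) %% 32), c(12, 19))
  expect_equal(range((px - 1) %/% 32), c(12, 19))
  # two far-apart seeds: two disjoint equal regions
  gt2 <- data.frame(row = c(7.5, 24.5), col = c(7.5, 24.5))
  reg2 <- enlarge_gt(gt2, c(32, 32))
  expect_equal(sum(reg2 == 1), 64)
  expect_equal(sum(reg2 == 2), 64)
  # two seeds 4 px apart: pixels split by the perpendicular bisector,
  # no pixel double-labeled; verified per pixel against nearest-centroid
  gt3 <- data.frame(row = c(15.5, 19.5), col = c(15.5, 15.5))
  reg3 <- enlarge_gt(gt3, c(40, 40))
  for (px in which(reg3 > 0)) {
    r <- (px - 1) %% 40; c <- (px - 1) %/% 40
    d1 <- (r - 15.5)^2 + (c - 15.5)^2
    d2 <- (r - 19.5)^2 + (c - 15.5)^2
    if (d1 < d2) expect_equal(reg3[px], 1L)
    if (d2 < d1) expect_equal(reg3[px], 2L)
    if (d1 == d2) expect_equal(reg3[px], 1L)  # ties to the lower index
  }
})

test_that("matching assigns predictions to beads, background and border", {
  gt <- data.frame(row = c(15.5, 40.5), col = c(15.5, 40.5))
  reg <- enlarge_gt(gt, c(64, 64))
  # perfect predictions: one seed per bead, nothing added
  perfect <- data.frame(row = gt$row, col = gt$col, area = c(4L, 4L))
  tab <- match_detections(reg, perfect)
  expect_equal(tab$seeds_per_bead, c(1L, 1L))
  expect_equal(tab$n_added, 0L)
  # a background prediction near the corner is border-ignored at margin 4
  withcorner <- rbind(perfect, data.frame(row = 2, col = 2, area = 1L))
  tab2 <- match_detections(reg, withcorner, border_margin = 4)
  expect_equal(tab2$n_border_ignored, 1L)
  expect_equal(tab2$n_added, 0L)
  # the same prediction away from the border counts as added
  withadded <- rbind(perfect, data.frame(row = 30, col = 8, area = 1L))
  tab3 <- match_detections(reg, withadded, border_margin = 4)
  expect_equal(tab3$n_added, 1L)
  # two predictions in one region make a split bead
  split <- rbind(perfect, data.frame(row = 17.5, col = 13.5, area = 4L))
  tab4 <- match_detections(reg, split)
  expect_equal(sort(tab4$seeds_per_bead), c(1L, 2L))
  # a prediction outside the raster is border-ignored with a warning
  expect_warning(tab5 <- match_detections(
    reg, rbind(perfect, data.frame(row = 99, col = 10, area = 1L))),
    "outside")
  expect_equal(tab5$n_border_ignored, 1L)
})

test_that("metrics reproduce the published baseline summary rows", {
  # LoG-based detector row: 670 beads, 54 missed, 26 added
  twang <- compute_metrics(match_table(670, c(rep(0L, 54), rep(1L, 616)),
                                       n_added = 26))
  expect_equal(round(twang$Q_F, 3), 0.939)
  expect_equal(round(twang$Q_P, 3), 0.960)
  expect_equal(round(twang$Q_R, 3), 0.919)
  expect_equal(round(twang$Q_miss, 2), 8.06)
  expect_equal(round(twang$Q_add, 2), 3.88)
  expect_equal(round(twang$detections, 2), 95.82)
  # Hough row: 79 missed, 14 added
  hough <- compute_metrics(match_table(670, c(rep(0L, 79), rep(1L, 591)),
                                       n_added = 14))
  expect_equal(round(hough$Q_F, 3), 0.927)
  expect_equal(round(hough$detections, 2), 90.30)
  # Otsu row: 290 missed, 14 split (2 seeds each), 102 added
  otsu <- compute_metrics(match_table(
    670, c(rep(0L, 290), rep(2L, 14), rep(1L, 366)), n_added = 102))
  expect_equal(round(otsu$Q_P, 3), 0.766)
  expect_equal(round(otsu$Q_R, 3), 0.567)
  expect_equal(round(otsu$detections, 2), 74.03)
  # perfect detection
  perfect <- compute_metrics(match_table(10, rep(1L, 10)))
  expect_equal(perfect$Q_F, 1)
  expect_equal(perfect$detections, 100)
  expect_error(compute_metrics(match_table(0)), "undefined")
})

test_that("the detections identity holds when splits have two seeds", {
  # detections = 100 - Q_miss + Q_add + Q_split for two-seed splits
  set.seed(5)
  for (trial in 1:25) {
    n <- sample(20:200, 1)
    seeds <- sample(c(0L, 1L, 2L), n, replace = TRUE,
                    prob = c(0.2, 0.7, 0.1))
    added <- sample(0:20, 1)
    r <- compute_metrics(match_table(n, seeds, n_added = added))
    expect_equal(r$detections, 100 - r$Q_miss + r$Q_add + r$Q_split,
                 tolerance = 1e-10)
  }
})

test_that("adding a background prediction never helps precision", {
  seeds <- c(rep(1L, 8), 0L, 2L)
  base <- compute_metrics(match_table(10, seeds, n_added = 2))
  more <- compute_metrics(match_table(10, seeds, n_added = 3))
  expect_lte(more$Q_P, base$Q_P)
  expect_equal(more$Q_R, base$Q_R)
})

test_that("matching and metrics agree with the raster-walk oracle", {
  set.seed(99)
  shape <- c(48, 48)
  for (trial in 1:100) {
    n_gt <- sample(1:8, 1)
    gt <- data.frame(row = runif(n_gt, 2, 45), col = runif(n_gt, 2, 45))
    n_pred <- sample(0:12, 1)
    preds <- data.frame(row = runif(n_pred, -1, 48),
                        col = runif(n_pred, -1, 48),
                        area = rep(1L, n_pred))
    reg <- enlarge_gt(gt, shape)
    tab <- suppressWarnings(match_detections(reg, preds))
    got <- compute_metrics(tab)
    want <- oracle_evaluate(gt, preds, shape)
    expect_equal(tab$seeds_per_bead, want$seeds)
    expect_equal(tab$n_added, want$added)
    expect_equal(tab$n_border_ignored, want$border)
    for (m in c("Q_F", "Q_P", "Q_R", "Q_split", "Q_miss", "Q_add",
                "detections"))
      expect_equal(got[[m]], want[[m]], tolerance = 1e-12)
  }
})

test_that("pooled evaluation sums counts rather than averaging metrics", {
  t1 <- match_table(2, c(1L, 1L), n_added = 0)       # perfect, 2 beads
  t2 <- match_table(8, rep(0L, 8), n_added = 4)      # all missed, 8 beads
  pooled <- compute_metrics(pool_match_tables(list(t1, t2)))
  mean_of <- mean(c(compute_metrics(t1)$Q_R, compute_metrics(t2)$Q_R))
  expect_equal(pooled$Q_R, 2 / 10)
  expect_false(isTRUE(all.equal(pooled$Q_R, mean_of)))
})

test_that("evaluate_detector pools across images and flags empty input", {
  scenes <- make_scenes(2, 600)
  # oracle detector that returns the true (mapped) seed centroids
  oracle_det <- function(scene) {
    function(up) {
      cen <- map_centroid_up(scene$annotation[, c("row", "col")], 4)
      data.frame(row = cen$row, col = cen$col,
                 area = rep(4L, nrow(cen)))
    }
  }
  ev1 <- evaluate_detector(scenes[1], oracle_det(scenes[[1]]))
  expect_equal(ev1$report$Q_F, 1)
  expect_error(suppressWarnings(
    evaluate_detector(list(list(image = matrix(0, 4, 4))),
                      function(up) NULL)), "no usable")
})
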