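test_that("percentile normalization maps robustly into [0, 1]", {
  expect_true(all(normalize_intensity(matrix(5, 4, 4)) == 0))
  # 16-bit style values spread between 100 and 5000
  set.seed(1)
  img <- matrix(runif(10000, 100, 5000), 100, 100)
  nm <- normalize_intensity(img)
  expect_true(all(nm >= 0 & nm <= 1))
  q <- quantile(img, c(0.01, 0.99), names = FALSE)
  mid <- (img > q[1]) & (img < q[2])
  expect_equal(nm[mid], (img[mid] - q[1]) / (q[2] - q[1]))
  # an image already spanning [0,1] changes only in the clipped tails
  flat <- matrix(seq(0, 1, length.out = 64), 8, 8)
  nf <- normalize_intensity(flat)
  inner <- flat > quantile(flat, 0.01) & flat < quantile(flat, 0.99)
  expect_equal(cor(as.vector(nf[inner]), as.vector(flat[inner])), 1)
})

test_that("bilinear upsampling matches the closed-form interpolant", {
  img <- matrix(runif(4), 2, 2)
  expect_identical(upsample_bilinear(img, 1), img)
  expect_equal(upsample_bilinear(matrix(0.3, 3, 3), 4),
               matrix(0.3, 12, 12), tolerance = 1e-12)
  expect_error(upsample_bilinear(img, 0), "factor")
  # oracle: direct evaluation of the interpolation formula at output
  # pixel centers, for several random rasters and factors
  set.seed(42)
  for (trial in 1:5) {
    H <- sample(2:5, 1); W <- sample(2:5, 1); f <- sample(2:4, 1)
    img <- matrix(runif(H * W), H, W)
    up <- upsample_bilinear(img, f)
    expect_equal(dim(up), c(f * H, f * W))
    for (R in 0:(f * H - 1)) for (C in 0:(f * W - 1)) {
      r <- (R + 0.5) / f - 0.5
      c <- (C + 0.5) / f - 0.5
      expect_equal(up[R + 1, C + 1], bilinear_at(img, r, c),
                   tolerance = 1e-10)
    }
  }
})

test_that("centroid mapping follows pixel-area alignment", {
  expect_equal(map_centroid_up(c(3.2, 7.9), 1), c(3.2, 7.9))
  expect_equal(map_centroid_up(c(0, 0), 4), c(1.5, 1.5))
  # linearity: 1 px apart at original scale -> factor px apart upsampled
  a <- map_centroid_up(c(2, 5), 4)
  b <- map_centroid_up(c(3, 5), 4)
  expect_equal(b - a, c(4, 0))
  df <- map_centroid_up(data.frame(row = c(0, 1), col = c(0, 2)), 4)
  expect_equal(df$row, c(1.5, 5.5))
  expect_equal(df$col, c(1.5, 9.5))
})

test_that("seed masks paint nearest 2x2 blocks and keep gaps", {
  expect_true(all(render_seed_mask(data.frame(row = numeric(0),
                                              col = numeric(0)),
                                   c(8, 8)) == 0))
  m <- render_seed_mask(data.frame(row = 1.5, col = 1.5), c(8, 8))
  expect_equal(which(m == 1),
               which(row(m) %in% 2:3 & col(m) %in% 2:3))
  # integer original centroids (r, c) map to rows {4r+1, 4r+2} after 4x
  up <- map_centroid_up(data.frame(row = 2, col = 3), 4)
  m2 <- render_seed_mask(up, c(32, 32))
  expect_equal(sort(which(m2 == 1)),
               sort(as.vector(outer((4 * 2 + 1):(4 * 2 + 2) + 1,
                                    ((4 * 3 + 1):(4 * 3 + 2)) * 32, `+`))))
  # original-adjacent beads: disjoint seeds with a 2 px gap
  cen <- map_centroid_up(data.frame(row = c(3, 4), col = c(3, 3)), 4)
  m3 <- render_seed_mask(cen, c(32, 32))
  expect_equal(max(label_components(m3)), 2)
  rows_set <- sort(unique((which(m3 == 1) - 1) %% 32))
  expect_equal(rows_set, c(13, 14, 17, 18))   # 2 px gap at rows 15, 16
  # out-of-image centroids are skipped with a warning
  expect_warning(m4 <- render_seed_mask(data.frame(row = c(2, 50),
                                                   col = c(2, 2)),
                                        c(8, 8)), "skipped")
  expect_equal(sum(m4), 4)
})

test_that("separation: centers >= 1 px apart give disjoint seeds at 4x", {
  set.seed(7)
  trials <- 0
  while (trials < 50) {
    r1 <- runif(1, 3, 6); c1 <- runif(1, 3, 6)
    ang <- runif(1, 0, 2 * pi); d <- runif(1, 1, 3)
    cen <- data.frame(row = c(r1, r1 + d * sin(ang)),
                      col = c(c1, c1 + d * cos(ang)))
    if (any(cen < 0.5) || any(cen > 8.5)) next   # keep both in frame
    trials <- trials + 1
    m <- render_seed_mask(map_centroid_up(cen, 4), c(40, 40))
    expect_equal(max(label_components(m)), 2)
  }
})

test_that("cross dilation grows a 2x2 seed into a 12-px plus shape", {
  expect_true(all(dilate_seeds_cross(matrix(0L, 6, 6)) == 0))
  m <- render_seed_mask(data.frame(row = 3.5, col = 3.5), c(9, 9))
  dm <- dilate_seeds_cross(m)
  expect_equal(sum(dm), 12)
  # 2x2 core plus four 1x2 flanks
  expect_true(all(dm[4:5, 4:5] == 1))
  expect_true(all(dm[3, 4:5] == 1) && all(dm[6, 4:5] == 1))
  expect_true(all(dm[4:5, 3] == 1) && all(dm[4:5, 6] == 1))
  expect_equal(dm[3, 3], 0L)
  expect_true(attr(dm, "dilated"))
})

test_that("dilation is monotone and can merge adjacent-bead seeds", {
  set.seed(3)
  for (trial in 1:20) {
    m <- matrix(as.integer(runif(100) < 0.2), 10, 10)
    dm <- dilate_seeds_cross(m)
    expect_true(all(dm >= m))
  }
  # original-adjacent beads: undilated seeds separate, dilated merge
  cen <- map_centroid_up(data.frame(row = c(3, 4), col = c(3, 3)), 4)
  m <- render_seed_mask(cen, c(32, 32))
  expect_equal(max(label_components(m)), 2)
  expect_equal(max(label_components(dilate_seeds_cross(m))), 1)
})

test_that("diameter range selects the upsampling factor", {
  expect_equal(diameter_to_factor(c(2, 4)), 4L)
  expect_equal(diameter_to_factor(c(8, 10)), 1L)
  expect_equal(diameter_to_factor(c(3, 5)), 3L)
})
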