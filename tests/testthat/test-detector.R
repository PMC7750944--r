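small_cfg <- function(...) {
  do.call(net_config, utils::modifyList(
    list(depth = 2L, base_channels = 4L, input_size = 64L,
         batch_size = 2L, max_epochs = 2L, learning_rate = 5e-3,
         rng_seed = 3L),
    list(...)))
}

small_scenes <- function(n, seed0) {
  make_scenes(n, seed0, width = 16, height = 16, n_beads = 3,
              touching_fraction = 0, noise_sigma = 0.01,
              poisson_scale = 500)
}

test_that("the detector outputs per-pixel probabilities at input size", {
  model <- build_detector(small_cfg())
  img <- matrix(0, 64, 64)
  pr <- predict(model, img)
  expect_equal(dim(pr), c(64, 64))
  expect_true(all(pr > 0 & pr < 1))
  expect_true(all(is.finite(pr)))
  # non-divisible sizes are padded and cropped back
  odd <- matrix(runif(63 * 61), 63, 61)
  expect_equal(dim(predict(model, odd)), c(63, 61))
  # inference is deterministic
  expect_identical(predict(model, odd), predict(model, odd))
  expect_error(net_config(depth = 3, input_size = 100), "divisible")
})

test_that("parameter count grows about fourfold when width doubles", {
  n1 <- n_parameters(build_detector(small_cfg()))
  n2 <- n_parameters(build_detector(net_config(depth = 2, base_channels = 8,
                                               input_size = 64)))
  expect_gt(n2 / n1, 3.3)
  expect_lt(n2 / n1, 4.3)
})

test_that("the compound loss matches its closed forms", {
  # identical hard masks: both terms vanish up to clamping/smoothing
  m <- matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1, 0, 0, 0), 3, 4)
  l <- bce_dice_loss(m, m)
  expect_lt(l$bce, 1e-5)
  expect_lt(l$dice, 0.2)          # smoothing keeps it near s/(2A+s)
  # uniform 0.5 prediction on all-zero target: BCE = ln 2 per pixel
  l2 <- bce_dice_loss(matrix(0.5, 8, 8), matrix(0, 8, 8))
  expect_equal(l2$bce, log(2), tolerance = 1e-12)
  # disjoint equal-area hard masks with area >> smoothing: Dice -> 1
  a <- matrix(0, 40, 40); a[1:20, ] <- 1
  b <- matrix(0, 40, 40); b[21:40, ] <- 1
  l3 <- bce_dice_loss(a, b)
  expect_gt(l3$dice, 0.99)
  expect_error(bce_dice_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "shape")
  # loss is non-negative for random inputs
  set.seed(1)
  for (i in 1:10) {
    l4 <- bce_dice_loss(matrix(runif(64), 8, 8),
                        matrix(rbinom(64, 1, 0.3), 8, 8))
    expect_gte(l4$loss, 0)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(10)
  depth <- 2L; H <- W <- 8L; N <- 2L
  p <- beadspot:::unet_init_params(depth, 3L)
  X <- matrix(rnorm(H * W * N), H * W * N, 1)
  Y <- matrix(rbinom(H * W * N, 1, 0.2), H * W * N, 1)
  lossfn <- function(p) {
    fw <- beadspot:::unet_forward(p, X, H, W, N, depth, train = TRUE)
    beadspot:::nn_loss_grad(fw$logits, Y)$loss
  }
  fw <- beadspot:::unet_forward(p, X, H, W, N, depth, train = TRUE)
  g <- beadspot:::unet_backward(p, fw$tape,
                                beadspot:::nn_loss_grad(fw$logits, Y)$dlogits,
                                depth)
  for (nm in c("enc1.c1.W", "enc2.b2.gamma", "bott.c2.W", "dec1.c1.W",
               "dec2.b1.beta", "head.W", "head.b")) {
    for (i in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      h <- 1e-5
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (lossfn(pp) - lossfn(pm)) / (2 * h)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("augmentation keeps masks binary and geometry involutive", {
  sc <- small_scenes(1, 50)[[1]]
  up <- upsample_bilinear(normalize_intensity(sc$image), 4)
  mask <- matrix(as.numeric(render_seed_mask(
    map_centroid_up(sc$annotation[, c("row", "col")], 4), dim(up))),
    nrow(up))
  # empty op set is the identity
  id <- augment_pair(up, mask, ops = character(0))
  expect_identical(id$image, up)
  expect_identical(id$mask, mask)
  # flipping twice restores the original
  f1 <- up[nrow(up):1, ]
  expect_identical(f1[nrow(f1):1, ], up)
  # masks remain binary under 100 random augmentations
  set.seed(77)
  for (i in 1:100) {
    a <- augment_pair(up, mask)
    expect_true(all(a$mask %in% c(0, 1)))
    expect_equal(sum(a$mask), sum(mask))  # geometry preserves seed count
    expect_true(all(a$image >= 0 & a$image <= 1))
  }
  # fixed seed gives identical draws
  a1 <- augment_pair(up, mask, rng_seed = 9)
  a2 <- augment_pair(up, mask, rng_seed = 9)
  expect_identical(a1, a2)
})

test_that("short training runs record history and reduce the loss", {
  train <- small_scenes(5, 300)
  val <- small_scenes(2, 400)
  b <- train_model(train, val, small_cfg(), use_dilation = FALSE)
  expect_s3_class(b, "model_bundle")
  expect_equal(nrow(b$history), 2)
  expect_lt(b$history$train_loss[2], b$history$train_loss[1])
  expect_false(b$dilation_used)
  expect_error(train_model(list(), val, small_cfg()), "empty")
})

test_that("training is reproducible under a fixed seed", {
  train <- small_scenes(3, 310)
  val <- small_scenes(1, 410)
  b1 <- train_model(train, val, small_cfg())
  b2 <- train_model(train, val, small_cfg())
  expect_equal(b1$history, b2$history, tolerance = 1e-12)
  expect_equal(b1$params, b2$params, tolerance = 1e-12)
})

test_that("the model zoo trains per option with distinct derived seeds", {
  train <- small_scenes(2, 320)
  val <- small_scenes(1, 420)
  cfg <- small_cfg()
  cfg$max_epochs <- 1L
  zoo <- train_zoo(train, val, cfg, n_inits = 2,
                   dilation_options = c(FALSE, TRUE))
  expect_length(zoo, 4)
  expect_equal(vapply(zoo, function(b) b$dilation_used, logical(1)),
               c(FALSE, FALSE, TRUE, TRUE))
  seeds <- vapply(zoo, function(b) b$config$rng_seed, integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  one <- train_zoo(train, val, cfg, n_inits = 1, dilation_options = FALSE)
  expect_length(one, 1)
})

test_that("dilation toggles only the labels, never the images", {
  scenes <- small_scenes(2, 330)
  pairs_plain <- beadspot:::prepare_pairs(scenes, 4L, 2L, FALSE)
  pairs_dil <- beadspot:::prepare_pairs(scenes, 4L, 2L, TRUE)
  for (i in seq_along(pairs_plain)) {
    expect_identical(pairs_plain[[i]]$image, pairs_dil[[i]]$image)
    expect_true(all(pairs_dil[[i]]$mask >= pairs_plain[[i]]$mask))
    expect_gt(sum(pairs_dil[[i]]$mask), sum(pairs_plain[[i]]$mask))
  }
})

test_that("model selection prefers higher F-score, then fewer additions", {
  scenes <- small_scenes(2, 340)
  # stub bundles whose predictions we control through class dispatch is
  # heavyweight here; instead check the ranking rule on real bundles by
  # constructing one clearly better model: an untrained net vs a net
  # trained a few epochs on the same easy data
  cfg <- small_cfg()
  cfg$max_epochs <- 6L
  good <- train_model(small_scenes(6, 350), small_scenes(2, 450), cfg)
  bad <- train_model(small_scenes(6, 350), small_scenes(2, 450),
                     small_cfg(max_epochs = 1L, learning_rate = 1e-6))
  best <- select_model(list(bad, good), scenes)
  sel <- attr(best, "selection")
  expect_equal(nrow(sel), 2)
  expect_true(best$selection_score >= max(sel$Q_F) - 1e-12)
  expect_error(select_model(list(), scenes), "no bundles")
})

test_that("selection ties on F-score break by added rate then index", {
  # the ranking rule itself, isolated from training: order(-Q_F, Q_add, i)
  scores <- data.frame(bundle = 1:3, Q_F = c(0.9, 0.9, 0.9),
                       Q_add = c(5, 2, 2))
  o <- order(-scores$Q_F, scores$Q_add, scores$bundle)
  expect_equal(o[1], 2L)
})

test_that("models survive a save/load round trip", {
  train <- small_scenes(2, 360)
  cfg <- small_cfg()
  cfg$max_epochs <- 1L
  b <- train_model(train, small_scenes(1, 460), cfg)
  base <- file.path(withr::local_tempdir(), "model")
  save_model(b, base)
  b2 <- load_model(base)
  expect_equal(b2$params, b$params, tolerance = 1e-12)
  expect_equal(b2$config$depth, b$config$depth)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(predict(b2, img), predict(b, img), tolerance = 1e-12)
})

test_that("ten epochs on easy noise-free data halve the validation loss", {
  train <- make_scenes(16, 500, width = 16, height = 16, n_beads = 4,
                       touching_fraction = 0, noise_sigma = 0,
                       poisson_scale = 0)
  val <- make_scenes(3, 520, width = 16, height = 16, n_beads = 4,
                     touching_fraction = 0, noise_sigma = 0,
                     poisson_scale = 0)
  cfg <- small_cfg(base_channels = 8L, batch_size = 1L,
                   max_epochs = 10L, learning_rate = 1e-2)
  b <- train_model(train, val, cfg,
                   augment_ops = c("flip", "rot", "intensity"))
  expect_lt(min(b$history$val_loss), 0.5 * b$history$val_loss[1])
})
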