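#' Network and training configuration for the seed detector
#'
#' The detector is a compact U-shaped encoder-decoder: per level two 3x3
#' convolutions with batch normalization and ReLU, 2x2 max-pool
#' downsampling, nearest-neighbour upsampling with skip connections, and a
#' 1x1 sigmoid head producing a per-pixel seed probability at the input
#' resolution.
#'
#' @param depth Number of encoder levels (pooling steps).
#' @param base_channels Channels at the first level; doubled per level.
#' @param input_size Training crop side length in px at the upsampled
#'   resolution; must be divisible by `2^depth`.
#' @param batch_size Images per gradient step.
#' @param max_epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param rng_seed Seed controlling weight init, shuffling and
#'   augmentation; fixed seed gives identical training runs on CPU.
#' @return Object of class `net_config`.
#' @export
net_config <- function(depth = 3L, base_channels = 32L, input_size = 128L,
                       batch_size = 4L, max_epochs = 20L,
                       learning_rate = 1e-3, rng_seed = 1L) {
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  input_size <- as.integer(input_size)
  if (depth < 1 || base_channels < 1 || input_size < 1 || batch_size < 1 ||
      max_epochs < 1 || learning_rate <= 0)
    stop("all counts must be positive")
  if (input_size %% 2^depth != 0)
    stop("input_size must be divisible by 2^depth")
  structure(list(depth = depth, base_channels = base_channels,
                 input_size = input_size, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "net_config")
}

#' Build an untrained seed-detector model
#'
#' @param config A [net_config()].
#' @return Object of class `seed_detector` holding the initialized
#'   parameters and the config.
#' @export
build_detector <- function(config) {
  stopifnot(inherits(config, "net_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$rng_seed)
  params <- unet_init_params(config$depth, config$base_channels)
  structure(list(params = params, config = config),
            class = "seed_detector")
}

#' Number of trainable parameters of a detector
#'
#' @param model A `seed_detector` or `model_bundle`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  p <- model$params
  sum(vapply(p[nn_trainable(p)], length, integer(1)))
}

#' Combined binary cross-entropy and Dice loss
#'
#' `L = BCE(pred, target) + (1 - (2*sum(pred*target) + s) /
#' (sum(pred) + sum(target) + s))` with smoothing `s = 1` and predictions
#' clamped to `[1e-7, 1 - 1e-7]` inside the cross-entropy. The
#' cross-entropy term handles the severe class imbalance between the few
#' seed pixels and the background; the Dice term directly rewards overlap
#' with the seed regions.
#'
#' @param pred Numeric raster of probabilities in (0, 1).
#' @param target Binary raster of the same shape.
#' @param smooth Dice smoothing constant.
#' @return List with `loss`, `bce` and `dice` components (all >= 0).
#' @export
bce_dice_loss <- function(pred, target, smooth = 1) {
  if (!identical(dim(pred), dim(target)) &&
      length(pred) != length(target))
    stop("pred and target shapes differ")
  eps <- 1e-7
  p <- pmin(pmax(as.numeric(pred), eps), 1 - eps)
  t <- as.numeric(target)
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  dice <- 1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
  list(loss = bce + dice, bce = bce, dice = dice)
}

rot90m <- function(m, k) {
  k <- k %% 4
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

#' Online training-pair augmentation
#'
#' Geometric operations (horizontal/vertical flips, 90-degree rotations)
#' are applied identically to image and mask; intensity operations
#' (multiplicative scaling U(0.8, 1.2), additive Gaussian noise with
#' sd ~ U(0, 0.05), Gaussian blur with sigma ~ U(0, 1)) touch the image
#' only, so masks stay binary. Draws come from R's RNG stream: seed it (or
#' pass `rng_seed`) for reproducibility.
#'
#' @param image Numeric matrix.
#' @param mask Binary matrix of the same shape.
#' @param ops Character subset of `c("flip", "rot", "intensity", "noise",
#'   "blur")`; an empty vector returns the pair unchanged.
#' @param rng_seed Optional seed applied locally.
#' @return List with `image` and `mask`.
#' @export
augment_pair <- function(image, mask,
                         ops = c("flip", "rot", "intensity", "noise", "blur"),
                         rng_seed = NULL) {
  stopifnot(identical(dim(image), dim(mask)))
  if (!is.null(rng_seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(rng_seed)
  }
  if ("flip" %in% ops) {
    if (stats::runif(1) < 0.5) {
      image <- image[nrow(image):1, , drop = FALSE]
      mask <- mask[nrow(mask):1, , drop = FALSE]
    }
    if (stats::runif(1) < 0.5) {
      image <- image[, ncol(image):1, drop = FALSE]
      mask <- mask[, ncol(mask):1, drop = FALSE]
    }
  }
  if ("rot" %in% ops && nrow(image) == ncol(image)) {
    k <- sample(0:3, 1)
    image <- rot90m(image, k)
    mask <- rot90m(mask, k)
  }
  if ("intensity" %in% ops)
    image <- image * stats::runif(1, 0.8, 1.2)
  if ("noise" %in% ops) {
    sd <- stats::runif(1, 0, 0.05)
    if (sd > 0)
      image <- image + matrix(stats::rnorm(length(image), 0, sd), nrow(image))
  }
  if ("blur" %in% ops) {
    sigma <- stats::runif(1, 0, 1)
    if (sigma > 0.05) image <- gauss_blur(image, sigma)
  }
  image <- pmin(pmax(image, 0), 1)
  list(image = image, mask = mask)
}

# Preprocess scenes into aligned (image, mask) pairs at upsampled
# resolution. Labels are the rendered 2x2 seeds, cross-dilated on request.
prepare_pairs <- function(scenes, factor, seed_size, use_dilation) {
  lapply(scenes, function(sc) {
    up <- upsample_bilinear(normalize_intensity(sc$image), factor)
    cen <- map_centroid_up(sc$annotation[, c("row", "col"), drop = FALSE],
                           factor)
    mask <- render_seed_mask(cen, dim(up), seed_size)
    if (use_dilation) mask <- dilate_seeds_cross(mask)
    list(image = up, mask = matrix(as.numeric(mask), nrow(mask)))
  })
}

# random crop of a pair to side `size` (identity if already that size)
crop_pair <- function(pair, size) {
  H <- nrow(pair$image); W <- ncol(pair$image)
  if (H == size && W == size) return(pair)
  if (H < size || W < size)
    stop("image smaller than the training crop size")
  r0 <- sample.int(H - size + 1L, 1L)
  c0 <- sample.int(W - size + 1L, 1L)
  list(image = pair$image[r0:(r0 + size - 1L), c0:(c0 + size - 1L)],
       mask = pair$mask[r0:(r0 + size - 1L), c0:(c0 + size - 1L)])
}

stack_batch <- function(pairs) {
  X <- do.call(rbind, lapply(pairs, function(p) cbind(as.numeric(p$image))))
  Y <- do.call(rbind, lapply(pairs, function(p) cbind(as.numeric(p$mask))))
  list(X = X, Y = Y)
}

#' Train one seed-detector model
#'
#' Renders seed labels for the training scenes at upsampled resolution
#' (cross-dilated iff `use_dilation`; the images themselves are never
#' dilated), then minimizes the combined BCE + Dice loss with Adam under
#' online augmentation. After each epoch the validation loss is computed
#' in inference mode; the parameters of the best validation epoch are
#' kept. Fully deterministic for a fixed `config$rng_seed`.
#'
#' @param train_set,val_set Lists of scenes (`image` at original
#'   resolution plus `annotation` with 0-based `row`, `col`).
#' @param config A [net_config()].
#' @param use_dilation Logical: train on cross-dilated seed labels.
#' @param factor Upsampling factor.
#' @param seed_size Seed side length in px.
#' @param augment_ops Augmentations applied online (see [augment_pair()]).
#' @param verbose Print per-epoch losses.
#' @return Object of class `model_bundle`: `params` (best-epoch weights),
#'   `config`, `dilation_used`, `history` (data.frame epoch/train_loss/
#'   val_loss), `factor`, `seed_size`, `selection_score` (`NA` until
#'   [select_model()]).
#' @export
train_model <- function(train_set, val_set, config, use_dilation = FALSE,
                        factor = 4L, seed_size = 2L,
                        augment_ops = c("flip", "rot", "intensity",
                                        "noise", "blur"),
                        verbose = FALSE) {
  stopifnot(inherits(config, "net_config"))
  if (length(train_set) == 0) stop("empty training set")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$rng_seed)
  train_pairs <- prepare_pairs(train_set, factor, seed_size, use_dilation)
  val_pairs <- prepare_pairs(val_set, factor, seed_size, use_dilation)
  p <- unet_init_params(config$depth, config$base_channels)
  opt <- nn_adam_init(p)
  size <- config$input_size
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best_val <- Inf
  best_p <- p
  val_loss_of <- function(p) {
    if (length(val_pairs) == 0) return(NA_real_)
    tot <- 0; nb <- 0L
    for (start in seq(1, length(val_pairs), by = config$batch_size)) {
      ids <- start:min(start + config$batch_size - 1L, length(val_pairs))
      sb <- stack_batch(val_pairs[ids])
      H <- nrow(val_pairs[[ids[1]]]$image)
      W <- ncol(val_pairs[[ids[1]]]$image)
      fw <- unet_forward(p, sb$X, H, W, length(ids), config$depth,
                         train = FALSE)
      tot <- tot + nn_loss_grad(fw$logits, sb$Y)$loss
      nb <- nb + 1L
    }
    tot / nb
  }
  lr <- config$learning_rate
  since_best <- 0L
  # when training on crops smaller than the image, one epoch draws enough
  # random crops per image to cover its area in expectation
  crops_per_image <- max(1L, as.integer(ceiling(
    prod(dim(train_pairs[[1]]$image)) / size^2)))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(rep(seq_along(train_pairs), crops_per_image))
    ep_loss <- 0; n_steps <- 0L
    for (start in seq(1, length(ord), by = config$batch_size)) {
      ids <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      batch <- lapply(train_pairs[ids], function(pr) {
        pr <- crop_pair(pr, size)
        augment_pair(pr$image, pr$mask, ops = augment_ops)
      })
      sb <- stack_batch(batch)
      fw <- unet_forward(p, sb$X, size, size, length(ids), config$depth,
                         train = TRUE)
      p <- fw$p                                   # BN running stats updated
      lg <- nn_loss_grad(fw$logits, sb$Y)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", epoch,
             " (lr too high or corrupt data)")
      g <- unet_backward(p, fw$tape, lg$dlogits, config$depth)
      st <- nn_adam_step(p, g, opt, lr)
      p <- st$p; opt <- st$state
      ep_loss <- ep_loss + lg$loss; n_steps <- n_steps + 1L
    }
    vl <- val_loss_of(p)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / n_steps,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d  train %.4f  val %.4f", epoch,
                      ep_loss / n_steps, vl))
    if (!is.na(vl) && vl < best_val) {
      best_val <- vl
      best_p <- p
      since_best <- 0L
    } else {
      # reduce on plateau: halve the step size after 3 stale epochs
      since_best <- since_best + 1L
      if (since_best >= 3L) {
        lr <- max(lr / 2, 1e-5)
        since_best <- 0L
      }
    }
  }
  if (length(val_pairs) == 0) best_p <- p
  structure(list(params = best_p, config = config,
                 dilation_used = use_dilation, history = hist,
                 factor = as.integer(factor),
                 seed_size = as.integer(seed_size),
                 selection_score = NA_real_),
            class = c("model_bundle", "seed_detector"))
}

#' Train a zoo of models with and without label dilation
#'
#' Trains `n_inits` models per dilation option with distinct seeds derived
#' from `config$rng_seed`, mirroring the practice of training several
#' initializations and selecting the best afterwards.
#'
#' @inheritParams train_model
#' @param n_inits Models per dilation option.
#' @param dilation_options Logical vector of dilation settings to train.
#' @return List of `model_bundle` objects.
#' @export
train_zoo <- function(train_set, val_set, config, n_inits = 5L,
                      dilation_options = c(FALSE, TRUE), factor = 4L,
                      seed_size = 2L,
                      augment_ops = c("flip", "rot", "intensity",
                                      "noise", "blur"),
                      verbose = FALSE) {
  stopifnot(n_inits >= 1)
  bundles <- list()
  k <- 0L
  for (dil in dilation_options) {
    for (i in seq_len(n_inits)) {
      k <- k + 1L
      cfg <- config
      cfg$rng_seed <- derive_seed(config$rng_seed, k)
      bundles[[k]] <- train_model(train_set, val_set, cfg,
                                  use_dilation = dil, factor = factor,
                                  seed_size = seed_size,
                                  augment_ops = augment_ops,
                                  verbose = verbose)
    }
  }
  bundles
}

# reflect-pad a matrix on the bottom/right to multiples of `m`
pad_to_multiple <- function(img, m) {
  H <- nrow(img); W <- ncol(img)
  H2 <- as.integer(ceiling(H / m) * m)
  W2 <- as.integer(ceiling(W / m) * m)
  if (H2 == H && W2 == W) return(list(img = img, H = H, W = W))
  ri <- c(seq_len(H), rev(seq_len(H))[seq_len(H2 - H)])
  ci <- c(seq_len(W), rev(seq_len(W))[seq_len(W2 - W)])
  list(img = img[ri, ci, drop = FALSE], H = H, W = W)
}

#' Predict seed probabilities for one image
#'
#' Runs the detector in inference mode on a normalized, upsampled image.
#' Inputs whose side is not divisible by `2^depth` are reflect-padded and
#' the output cropped back, so the returned raster always matches the
#' input shape.
#'
#' @param object A `seed_detector` or `model_bundle`.
#' @param image Numeric matrix (normalized, upsampled resolution).
#' @param ... Unused.
#' @return Probability matrix in (0, 1) with `dim(image)`.
#' @export
predict.seed_detector <- function(object, image, ...) {
  stopifnot(is.matrix(image))
  m <- 2^object$config$depth
  pd <- pad_to_multiple(image, m)
  H <- nrow(pd$img); W <- ncol(pd$img)
  fw <- unet_forward(object$params, cbind(as.numeric(pd$img)), H, W, 1L,
                     object$config$depth, train = FALSE)
  prob <- matrix(stats::plogis(fw$logits), H, W)
  prob[seq_len(pd$H), seq_len(pd$W), drop = FALSE]
}

# full inference for one original-resolution image: normalize, upsample,
# predict, threshold, label, centroids
detect_beads <- function(bundle, image, threshold = 0.5, min_area = 1L) {
  up <- upsample_bilinear(normalize_intensity(image), bundle$factor)
  prob <- predict(bundle, up)
  prob_to_detections(prob, threshold, source = "detector",
                     min_area = min_area)
}

#' Select the best model from a zoo
#'
#' Runs the full inference and evaluation pipeline for every bundle on an
#' annotated evaluation split and returns the bundle with the highest
#' F-score; ties are broken by lower added-bead rate, then by lower bundle
#' index.
#'
#' @param bundles List of `model_bundle` objects.
#' @param eval_set List of annotated scenes.
#' @param threshold Binarization threshold for predictions.
#' @param enlargement_halfwidth,border_margin Evaluation geometry.
#' @return The selected `model_bundle`, with `selection_score` set and an
#'   attribute `selection` holding the per-bundle score table.
#' @export
select_model <- function(bundles, eval_set, threshold = 0.5,
                         enlargement_halfwidth = 3L, border_margin = 4L) {
  if (length(bundles) == 0) stop("no bundles to select from")
  scores <- data.frame(bundle = seq_along(bundles), Q_F = NA_real_,
                       Q_add = NA_real_, dilation = NA)
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    ev <- evaluate_detector(
      eval_set,
      detector = function(up) prob_to_detections(predict(b, up), threshold),
      factor = b$factor,
      enlargement_halfwidth = enlargement_halfwidth,
      seed_size = b$seed_size, border_margin = border_margin)
    scores$Q_F[i] <- ev$report$Q_F
    scores$Q_add[i] <- ev$report$Q_add
    scores$dilation[i] <- b$dilation_used
  }
  o <- order(-scores$Q_F, scores$Q_add, scores$bundle)
  best <- bundles[[o[1]]]
  best$selection_score <- scores$Q_F[o[1]]
  attr(best, "selection") <- scores
  best
}

#' Save / load a trained model
#'
#' Weights go into a single serialized file; the network config and
#' provenance are written alongside as a JSON sidecar and the training
#' history as CSV.
#'
#' @param bundle A `model_bundle`.
#' @param path Base path (extensions are appended).
#' @export
save_model <- function(bundle, path) {
  saveRDS(bundle$params, paste0(path, ".weights.rds"))
  jsonlite::write_json(
    list(config = unclass(bundle$config),
         dilation_used = bundle$dilation_used,
         factor = bundle$factor, seed_size = bundle$seed_size,
         selection_score = bundle$selection_score),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(bundle$history, paste0(path, ".history.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  cfg <- do.call(net_config, meta$config)
  structure(list(params = readRDS(paste0(path, ".weights.rds")),
                 config = cfg, dilation_used = meta$dilation_used,
                 history = utils::read.csv(paste0(path, ".history.csv")),
                 factor = as.integer(meta$factor),
                 seed_size = as.integer(meta$seed_size),
                 selection_score = suppressWarnings(
                   if (is.null(meta$selection_score)) NA_real_
                   else as.numeric(meta$selection_score))),
            class = c("model_bundle", "seed_detector"))
}
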