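#' Scene configuration for the synthetic bead-image generator
#'
#' Describes one simulated low-resolution field of view: image size, number
#' of beads, the bead diameter range (full width at half maximum of the
#' fluorescent-spot profile, in pixels), how many beads are placed touching
#' a neighbour, intensity levels, and the noise model.
#'
#' Beads are rendered as isotropic Gaussian spots (the standard
#' diffraction-limited approximation for sub-resolution emitters) on a
#' constant background. Shot noise is modelled by scaling the noise-free
#' image to expected photon counts (`poisson_scale` photons at intensity 1),
#' drawing Poisson counts, and rescaling; Gaussian read noise of standard
#' deviation `noise_sigma` is then added and the image is clipped to
#' \[0, 1\].
#'
#' @param width,height Image size in pixels.
#' @param n_beads Number of beads to place (>= 0).
#' @param diameter_range Length-2 numeric, min and max bead FWHM in px.
#' @param touching_fraction Fraction of beads placed with their center
#'   1-2 px from an already-placed bead, so that neighbouring beads touch.
#' @param amplitude_range Length-2 numeric, peak spot intensity range in
#'   normalized units.
#' @param background_level Constant background intensity in \[0, 1).
#' @param noise_sigma Standard deviation of additive Gaussian read noise.
#' @param poisson_scale Photon-count scale for shot noise; 0 disables it.
#' @param rng_seed Integer seed; the same config and seed always produce
#'   the same scene.
#' @return An object of class `scene_config` (a named list).
#' @export
scene_config <- function(width = 32L, height = 32L, n_beads = 8L,
                         diameter_range = c(2, 4),
                         touching_fraction = 0.25,
                         amplitude_range = c(0.4, 0.9),
                         background_level = 0.1,
                         noise_sigma = 0.02,
                         poisson_scale = 200,
                         rng_seed = 1L) {
  stopifnot(length(diameter_range) == 2, length(amplitude_range) == 2)
  width <- as.integer(width); height <- as.integer(height)
  n_beads <- as.integer(n_beads)
  if (width < 1 || height < 1)
    stop("image dimensions must be positive")
  if (n_beads < 0)
    stop("n_beads must be >= 0")
  if (diameter_range[1] <= 0 || diameter_range[2] < diameter_range[1] ||
      diameter_range[2] >= min(width, height) / 2)
    stop("diameter_range must lie within (0, min(width, height)/2)")
  if (touching_fraction < 0 || touching_fraction > 1)
    stop("touching_fraction must be in [0, 1]")
  if (noise_sigma < 0 || poisson_scale < 0)
    stop("noise parameters must be non-negative")
  structure(list(width = width, height = height, n_beads = n_beads,
                 diameter_range = as.numeric(diameter_range),
                 touching_fraction = touching_fraction,
                 amplitude_range = as.numeric(amplitude_range),
                 background_level = background_level,
                 noise_sigma = noise_sigma,
                 poisson_scale = poisson_scale,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Render one Gaussian bead spot
#'
#' Evaluates an isotropic Gaussian intensity profile at pixel centers.
#' The full width at half maximum equals `diameter`
#' (sigma = diameter / 2.3548) and the peak value at the centroid equals
#' `amplitude`. Coordinates are 0-based `(row, col)` with pixel centers at
#' integer positions; sub-pixel centroids are allowed.
#'
#' @param centroid Length-2 numeric `(row, col)` in px.
#' @param diameter Spot FWHM in px (> 0).
#' @param amplitude Peak intensity (> 0).
#' @param shape Length-2 integer `(height, width)` of the output raster.
#' @return A `height x width` numeric matrix.
#' @export
render_bead <- function(centroid, diameter, amplitude, shape) {
  if (diameter <= 0) stop("diameter must be positive")
  if (amplitude <= 0) stop("amplitude must be positive")
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 1)) stop("invalid raster shape")
  sigma <- diameter * FWHM_TO_SIGMA
  rows <- 0:(shape[1] - 1)
  cols <- 0:(shape[2] - 1)
  dr2 <- (rows - centroid[1])^2
  dc2 <- (cols - centroid[2])^2
  amplitude * exp(-outer(dr2, dc2, `+`) / (2 * sigma^2))
}

# Rejection-sample bead positions. Non-touching beads keep >= 3 px center
# distance from all placed beads; touching beads are anchored 1-2 px from a
# random placed bead. All beads are constrained to keep their nominal
# radius inside the image.
place_beads <- function(cfg) {
  n <- cfg$n_beads
  if (n == 0L)
    return(data.frame(row = numeric(0), col = numeric(0),
                      diameter = numeric(0)))
  d <- stats::runif(n, cfg$diameter_range[1], cfg$diameter_range[2])
  n_touch <- round(cfg$touching_fraction * n)
  if (n_touch >= n) n_touch <- n - 1L  # first bead can have no anchor
  touch <- rep(FALSE, n)
  if (n_touch > 0) touch[sample(2:n, n_touch)] <- TRUE
  rows <- cols <- numeric(n)
  budget <- 200L
  for (i in seq_len(n)) {
    margin <- d[i] / 2
    ok <- FALSE
    for (try in seq_len(budget)) {
      if (touch[i]) {
        j <- if (i == 2L) 1L else sample(seq_len(i - 1L), 1L)
        ang <- stats::runif(1, 0, 2 * pi)
        sep <- stats::runif(1, 1, 2)
        r <- rows[j] + sep * sin(ang)
        c <- cols[j] + sep * cos(ang)
      } else {
        r <- stats::runif(1, margin, cfg$height - 1 - margin)
        c <- stats::runif(1, margin, cfg$width - 1 - margin)
      }
      in_bounds <- r >= margin && r <= cfg$height - 1 - margin &&
        c >= margin && c <= cfg$width - 1 - margin
      if (!in_bounds) next
      if (i > 1L) {
        dist <- sqrt((rows[1:(i - 1)] - r)^2 + (cols[1:(i - 1)] - c)^2)
        if (touch[i]) {
          # must not collapse onto a third bead
          if (any(dist < 1)) next
        } else {
          if (any(dist < 3)) next
        }
      }
      rows[i] <- r; cols[i] <- c; ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place ", cfg$n_beads, " beads within the retry budget; ",
           "reduce n_beads or enlarge the image")
  }
  data.frame(row = rows, col = cols, diameter = d)
}

#' Generate one synthetic bead scene with exact ground truth
#'
#' Builds `background + sum of Gaussian beads`, applies optional Poisson
#' shot noise and Gaussian read noise, clips to \[0, 1\], and returns both
#' the image and its annotation. A fixed `rng_seed` in the config makes the
#' scene fully reproducible.
#'
#' @param config A [scene_config()].
#' @return A list of class `bead_scene` with elements
#'   * `image`: `height x width` numeric matrix in \[0, 1\];
#'   * `annotation`: data.frame with columns `bead_id`, `row`, `col`,
#'     `diameter`, `fully_visible` (0-based original-resolution
#'     coordinates);
#'   * `config`: the config used.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$rng_seed)
  beads <- place_beads(config)
  img <- matrix(config$background_level, config$height, config$width)
  if (nrow(beads) > 0) {
    amp <- stats::runif(nrow(beads), config$amplitude_range[1],
                        config$amplitude_range[2])
    for (i in seq_len(nrow(beads)))
      img <- img + render_bead(c(beads$row[i], beads$col[i]),
                               beads$diameter[i], amp[i],
                               c(config$height, config$width))
  }
  if (config$poisson_scale > 0)
    img <- matrix(stats::rpois(length(img), pmax(img, 0) * config$poisson_scale),
                  nrow(img)) / config$poisson_scale
  if (config$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, config$noise_sigma),
                        nrow(img))
  img <- pmin(pmax(img, 0), 1)
  fully_visible <- if (nrow(beads) > 0) {
    beads$row - beads$diameter / 2 >= -0.5 &
      beads$row + beads$diameter / 2 <= config$height - 0.5 &
      beads$col - beads$diameter / 2 >= -0.5 &
      beads$col + beads$diameter / 2 <= config$width - 0.5
  } else logical(0)
  ann <- data.frame(bead_id = seq_len(nrow(beads)) - 1L,
                    row = beads$row, col = beads$col,
                    diameter = beads$diameter,
                    fully_visible = fully_visible)
  structure(list(image = img, annotation = ann, config = config),
            class = "bead_scene")
}

# save/restore the global RNG state so generator calls do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# derive a per-image seed from a master seed; stays below 2^31
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + index * 104729) %% 2147483647)
}

#' Generate a synthetic bead dataset on disk
#'
#' Writes train/validation/test splits of synthetic scenes as single-channel
#' TIFF images with matching centroid CSVs, plus a JSON manifest recording
#' split membership and the per-image seeds (derived deterministically from
#' `master_seed`). The default split sizes follow the 60/15/25 layout of a
#' typical annotated low-resolution bead dataset.
#'
#' @param n_train,n_val,n_test Number of images per split.
#' @param config A [scene_config()]; its `rng_seed` is ignored in favour of
#'   per-image derived seeds.
#' @param out_dir Output directory (created if needed).
#' @param master_seed Integer master seed.
#' @param bits Bit depth for written TIFFs (16 or 32 for float).
#' @return The manifest, invisibly: a list with `splits` (named list of
#'   data.frames with `image`, `csv`, `seed`) and the generator settings.
#' @export
generate_dataset <- function(n_train = 60L, n_val = 15L, n_test = 25L,
                             config = scene_config(), out_dir,
                             master_seed = 1L, bits = 16L) {
  splits <- list(train = n_train, val = n_val, test = n_test)
  manifest <- list(master_seed = as.integer(master_seed),
                   config = unclass(config)[setdiff(names(config), "rng_seed")],
                   splits = list())
  idx <- 0L
  for (sp in names(splits)) {
    dir.create(file.path(out_dir, sp), recursive = TRUE, showWarnings = FALSE)
    entries <- list()
    for (k in seq_len(splits[[sp]])) {
      idx <- idx + 1L
      seed <- derive_seed(master_seed, idx)
      cfg <- config
      cfg$rng_seed <- seed
      scene <- generate_scene(cfg)
      img_file <- file.path(sp, sprintf("img_%03d.tif", k))
      csv_file <- file.path(sp, sprintf("img_%03d.csv", k))
      write_image(scene$image, file.path(out_dir, img_file), bits = bits)
      write_centroids(scene$annotation, file.path(out_dir, csv_file))
      entries[[k]] <- list(image = img_file, csv = csv_file, seed = seed)
    }
    manifest$splits[[sp]] <- entries
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a dataset split written by [generate_dataset()]
#'
#' @param dir Dataset root containing `manifest.json`.
#' @param split One of `"train"`, `"val"`, `"test"`.
#' @return List of scenes, each with `image` and `annotation`.
#' @export
read_dataset_split <- function(dir, split = c("train", "val", "test")) {
  split <- match.arg(split)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  entries <- manifest$splits[[split]]
  lapply(entries, function(e)
    list(image = read_image(file.path(dir, e$image)),
         annotation = read_centroids(file.path(dir, e$csv))))
}
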