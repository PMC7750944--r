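#' Scaled-down end-to-end detection benchmark
#'
#' Generates a synthetic dataset under the default study conditions
#' (60/15/25 train/validation/test images of 32 x 32 px with 2-4 px
#' beads and moderate noise), trains a small zoo of seed detectors with
#' and without cross-dilated labels, auto-selects the best model, and
#' evaluates it together with the three classical baselines on the test
#' split. All randomness derives from `master_seed`.
#'
#' @param master_seed Integer seed for dataset generation and training.
#' @param n_train,n_val,n_test Images per split.
#' @param scene A [scene_config()] describing the imaging conditions
#'   (its `rng_seed` is ignored; per-image seeds derive from
#'   `master_seed`).
#' @param net A [net_config()] for the detectors; the default is a
#'   compact two-level network sized for CPU training at these image
#'   sizes.
#' @param n_inits Initializations per dilation option.
#' @param augment_ops Augmentations used during training.
#' @param select_on `"val"` (default; avoids test leakage) or `"test"`
#'   to select the model on the test split.
#' @param baselines Run the classical baselines as well.
#' @param verbose Print progress.
#' @return List with `selected` (the chosen `model_bundle`), `selection`
#'   (per-bundle score table), and `reports` (named list of pooled
#'   `eval_report`s on the test split: `detector` plus, if requested,
#'   `log`, `hough`, `otsu`).
#' @export
benchmark_detectors <- function(master_seed = 1L, n_train = 60L,
                                n_val = 15L, n_test = 25L,
                                scene = scene_config(),
                                net = net_config(depth = 2L,
                                                 base_channels = 8L,
                                                 input_size = 128L,
                                                 batch_size = 2L,
                                                 max_epochs = 10L,
                                                 learning_rate = 5e-3),
                                n_inits = 2L,
                                augment_ops = c("flip", "rot", "intensity"),
                                select_on = c("val", "test"),
                                baselines = TRUE, verbose = FALSE) {
  select_on <- match.arg(select_on)
  gen_split <- function(n, offset) lapply(seq_len(n), function(i) {
    cfg <- scene
    cfg$rng_seed <- derive_seed(master_seed, offset + i)
    generate_scene(cfg)
  })
  train <- gen_split(n_train, 0L)
  val <- gen_split(n_val, n_train)
  test <- gen_split(n_test, n_train + n_val)
  factor <- diameter_to_factor(scene$diameter_range)
  net$rng_seed <- as.integer(master_seed)
  zoo <- train_zoo(train, val, net, n_inits = n_inits,
                   dilation_options = c(FALSE, TRUE), factor = factor,
                   augment_ops = augment_ops, verbose = verbose)
  best <- select_model(zoo, if (select_on == "val") val else test)
  reports <- list()
  reports$detector <- evaluate_detector(
    test, function(up) prob_to_detections(predict(best, up)),
    factor = factor)$report
  if (baselines) {
    params <- baseline_params(diameter_range = factor * scene$diameter_range)
    for (m in c("log", "hough", "otsu")) {
      det <- switch(m,
                    log = function(up) detect_log(up, params),
                    hough = function(up) detect_hough(up, params),
                    otsu = function(up) detect_otsu_edt(up, params))
      reports[[m]] <- evaluate_detector(test, det, factor = factor)$report
    }
  }
  list(selected = best, selection = attr(best, "selection"),
       reports = reports)
}
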