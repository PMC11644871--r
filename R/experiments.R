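# Scaled-down benchmark experiments used by the test suite and the
# acceptance script. Sizes are chosen so each experiment runs in minutes
# on a single CPU; the methods vignette discusses what they do and do not
# demonstrate.

#' Scaled-down segmentation benchmark on easy phantoms
#'
#' Generates high-contrast noise-free phantoms, trains the pixel-head
#' model on `n_train` of them, and reports the Dice coefficient on
#' `n_test` held-out phantoms.
#'
#' @param n_train,n_test Number of training / held-out phantoms.
#' @param side Phantom side length (px).
#' @param seed Master seed (data, initialization, training).
#' @param cfg A [train_config()]; defaults to the standard configuration
#'   with this seed.
#' @return List with `model`, `dice` (per-case vector), `mean_dice`,
#'   `history`.
#' @export
run_easy_benchmark <- function(n_train = 200L, n_test = 50L, side = 64L,
                               seed = 42L,
                               cfg = train_config(epochs = 20L,
                                                  patience = 10L,
                                                  seed = seed)) {
  ds <- generate_dataset(n_train + n_test, phantom_preset("easy", side),
                         seed = seed)
  model <- build_model(seg_model_config(input_side = side), seed = seed)
  model <- train_model(model, ds$images[seq_len(n_train)],
                       ds$masks[seq_len(n_train)], cfg)
  test_idx <- n_train + seq_len(n_test)
  dd <- vapply(test_idx, function(i)
    dice(confusion(predict_mask(model, ds$images[[i]]), ds$masks[[i]])),
    numeric(1))
  list(model = model, dice = dd, mean_dice = mean(dd),
       history = model$history)
}

#' Enhancement-effect benchmark on low-contrast phantoms
#'
#' The directional experiment behind the pipeline's premise: on
#' contrast-starved noisy phantoms, select common CLAHE parameters with
#' the fallback quality scorer (grid search + frequency aggregation),
#' enhance the dataset, and train one model on raw and one on enhanced
#' inputs under identical configuration. Reports held-out Dice for both
#' arms.
#'
#' @param seed Master seed.
#' @param n_train,n_test Number of training / held-out phantoms.
#' @param side Phantom side length (px; at least 64 so the quality
#'   features have two valid scales).
#' @param epochs Training epochs per arm.
#' @param n_select Images sampled for the parameter search.
#' @param grid Reduced [param_grid()] for the search.
#' @return List with `params` (the selected common parameters or `NULL`),
#'   `dice_raw`, `dice_enhanced` (per-case vectors) and their means.
#' @export
run_enhancement_benchmark <- function(seed, n_train = 60L, n_test = 15L,
                                      side = 64L, epochs = 10L,
                                      n_select = 8L,
                                      grid = param_grid(
                                        c(2L, 4L, 8L),
                                        c(0.01, 0.05, 0.25, 1))) {
  ds <- generate_dataset(n_train + n_test, phantom_preset("low_contrast", side),
                         seed = seed)
  tr <- seq_len(n_train)
  te <- n_train + seq_len(n_test)
  scorer <- scorer_spec("fallback")

  sels <- lapply(tr[seq_len(n_select)], function(i)
    select_best(evaluate_candidates(ds$images[[i]], grid, scorer,
                                    image_id = i)))
  common <- tryCatch(aggregate_common(sels), error = function(e) NULL)
  enhance <- function(img) {
    if (is.null(common)) img
    else apply_clahe(img, clahe_params(common$nt, common$cl))
  }

  cfg <- train_config(epochs = epochs, patience = max(1L, epochs - 1L),
                      seed = seed)
  arm <- function(images) {
    m <- build_model(seg_model_config(input_side = side), seed = seed)
    m <- train_model(m, images[tr], ds$masks[tr], cfg)
    vapply(te, function(i)
      dice(confusion(predict_mask(m, images[[i]]), ds$masks[[i]])),
      numeric(1))
  }
  dice_raw <- arm(ds$images)
  dice_enh <- arm(lapply(ds$images, enhance))
  list(params = common, dice_raw = dice_raw, dice_enhanced = dice_enh,
       mean_raw = mean(dice_raw), mean_enhanced = mean(dice_enh))
}
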