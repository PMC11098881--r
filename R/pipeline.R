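#' End-to-end aorta recovery experiment on synthetic phantoms
#'
#' The package's key self-check: generate abdominal phantoms, simulate
#' boundary-only IR images with the default machine parametrization, train
#' the desk-preset U-Net purely on the simulated IRs, and evaluate held-out
#' phantoms by Dice overlap and the anterior-posterior diameter MAE against
#' the generator's true diameters.
#'
#' @param n_train,n_test Number of training and held-out phantoms.
#' @param phantom_seeds Integer seeds for phantom generation (defaults to
#'   `0:(n_train + n_test - 1)`).
#' @param seed Seed for network init, split and augmentation.
#' @param image_size Simulated image side, px.
#' @param mp [machine_params()] used for simulation.
#' @param cfg [seg_train_config()]; defaults to the desk preset with
#'   `image_size` and `seed` filled in.
#' @param aaa_class Optional AAA class name; when given, each phantom's
#'   aorta is additionally dilated to an aneurysmal diameter.
#' @param verbose Print progress.
#' @return List with `report` (an `eval_report`), `model`, `images`,
#'   `masks`, `gt_diameters` and the train/test index split.
#' @export
recovery_experiment <- function(n_train = 200L, n_test = 40L,
                                phantom_seeds = NULL, seed = 1L,
                                image_size = 128L,
                                mp = machine_params(),
                                cfg = NULL, aaa_class = NULL,
                                verbose = FALSE) {
  n <- n_train + n_test
  if (is.null(phantom_seeds)) phantom_seeds <- seq_len(n) - 1L
  stopifnot(length(phantom_seeds) == n)
  if (is.null(cfg))
    cfg <- seg_train_config(preset = "desk", seed = seed)
  cfg$image_size <- as.integer(image_size)

  images <- vector("list", n)
  masks <- vector("list", n)
  gt_dia <- numeric(n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(phantom_config(seed = phantom_seeds[i]))
    lm <- ph$labelmap; amask <- ph$aorta_mask; dia <- ph$diameter_mm
    if (!is.null(aaa_class)) {
      aaa <- synthesize_aaa(lm, aaa_class, seed = phantom_seeds[i] + 1L)
      lm <- aaa$labelmap; amask <- aaa$aorta_mask; dia <- aaa$diameter_mm
    }
    images[[i]] <- simulate_us(lm, mp = mp, mode = "IR",
                               seed = phantom_seeds[i], out_size = image_size)
    masks[[i]] <- simulate_mask(amask, lm, mp, image_size)
    gt_dia[i] <- dia
    if (verbose && i %% 50 == 0) message("simulated ", i, "/", n)
  }

  idx_train <- seq_len(n_train)
  idx_test <- n_train + seq_len(n_test)
  model <- train_segmenter(images[idx_train], masks[idx_train], cfg,
                           verbose = verbose)
  preds <- lapply(idx_test, function(i) predict_mask(model, images[[i]]))
  report <- evaluate(preds, masks[idx_test],
                     pixel_spacing = images[[1]]$pixel_spacing,
                     gt_diameters = gt_dia[idx_test])
  list(report = report, model = model, images = images, masks = masks,
       gt_diameters = gt_dia, idx_train = idx_train, idx_test = idx_test)
}
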