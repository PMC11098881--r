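#' Segmentation training configuration
#'
#' Defaults follow the reference training recipe: 50 epochs, learning
#' rate 1e-3, Adam, Dice loss, batch size 64, random 80-20 train/val
#' split, with rotation/translation/scaling/noise augmentations applied
#' on the fly. The `"desk"` preset scales the run to a single CPU:
#' 128 x 128 images, 8 epochs, batch size 8, 4-level U-Net with 16 base
#' channels.
#'
#' @param epochs Training epochs (>= 1).
#' @param learning_rate Adam learning rate.
#' @param batch_size Images per optimization step.
#' @param split Train fraction of the train/val split, in (0, 1).
#' @param image_size Network input side, px (divisible by
#'   `2^(levels - 1)`).
#' @param levels U-Net resolution levels (including the bottleneck).
#' @param base_channels Channels of the first encoder block.
#' @param augment List with `rotate_deg`, `translate_frac`, `scale_range`,
#'   `noise_sd` and optionally `p_geometric` (probability that the
#'   geometric transforms fire, default 0.5); set `NULL` to disable
#'   augmentation.
#' @param seed Seed for weight init, split and augmentation.
#' @param preset `NULL` or `"desk"`.
#' @param lr_decay `NULL` for a constant learning rate, or two fractions
#'   of the epoch budget after which the rate is stepped down tenfold in
#'   two half-decade steps (the desk preset uses `c(0.6, 0.85)`); a
#'   sharpening schedule for short noisy single-image-batch runs.
#' @return A `seg_train_config` list.
#' @export
seg_train_config <- function(epochs = 50L, learning_rate = 1e-3,
                             batch_size = 64L, split = 0.8,
                             image_size = 256L, levels = 4L,
                             base_channels = 16L,
                             augment = list(rotate_deg = 15,
                                            translate_frac = 0.1,
                                            scale_range = c(0.9, 1.1),
                                            noise_sd = 0.02),
                             seed = 1L, preset = NULL, lr_decay = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "desk")
    epochs <- 8L; batch_size <- 1L; image_size <- 128L
    if (is.null(lr_decay)) lr_decay <- c(0.6, 0.85)
  }
  if (split <= 0 || split >= 1) stop("split must lie in (0, 1)")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 lr_decay = lr_decay,
                 batch_size = as.integer(batch_size), split = split,
                 image_size = as.integer(image_size),
                 levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 augment = augment, seed = as.integer(seed)),
            class = "seg_train_config")
}

as_pixel_matrix <- function(x) {
  if (inherits(x, "ultrasound_image")) x$pixels else x
}

#' Bilinear image resize
#'
#' @param img Numeric matrix.
#' @param out_h,out_w Output dimensions.
#' @param nearest Use nearest-neighbour lookup (for masks).
#' @return Resized matrix.
#' @export
resize_bilinear <- function(img, out_h, out_w, nearest = FALSE) {
  d <- dim(img)
  if (d[1] == out_h && d[2] == out_w) return(img)
  u <- (seq_len(out_h) - 0.5) * d[1] / out_h + 0.5
  v <- (seq_len(out_w) - 0.5) * d[2] / out_w + 0.5
  if (nearest) {
    ri <- pmin(pmax(round(u - 0.5 + 0.5), 1), d[1])
    ci <- pmin(pmax(round(v - 0.5 + 0.5), 1), d[2])
    return(img[ri, ci, drop = FALSE])
  }
  u <- pmin(pmax(u, 1), d[1]); v <- pmin(pmax(v, 1), d[2])
  r0 <- floor(u); r1 <- pmin(r0 + 1, d[1]); fr <- u - r0
  c0 <- floor(v); c1 <- pmin(c0 + 1, d[2]); fc <- v - c0
  A <- img[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
       img[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
       img[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
       img[r1, c1, drop = FALSE] * outer(fr, fc)
  A
}

# random affine (rotation/translation/scale) + noise; same geometric
# transform for the image (bilinear) and its mask (nearest)
augment_pair <- function(img, mask, aug) {
  d <- dim(img)
  # geometric transforms fire with probability p_geometric (default 0.5)
  # so the network also trains on unperturbed geometry; noise is always on
  p_geo <- if (is.null(aug$p_geometric)) 0.5 else aug$p_geometric
  if (stats::runif(1) > p_geo) {
    im2 <- img
    if (aug$noise_sd > 0)
      im2 <- pmin(pmax(im2 + stats::rnorm(length(im2), sd = aug$noise_sd),
                       0), 1)
    return(list(img = im2, mask = mask > 0))
  }
  th <- stats::runif(1, -aug$rotate_deg, aug$rotate_deg) * pi / 180
  tr <- stats::runif(2, -aug$translate_frac, aug$translate_frac) * d
  s <- stats::runif(1, aug$scale_range[1], aug$scale_range[2])
  ctr <- (d + 1) / 2
  rr <- matrix(seq_len(d[1]), d[1], d[2])
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  dr <- rr - ctr[1] - tr[1]
  dc <- cc - ctr[2] - tr[2]
  sr <- ctr[1] + (cos(th) * dr - sin(th) * dc) / s
  sc <- ctr[2] + (sin(th) * dr + cos(th) * dc) / s
  ri <- pmin(pmax(round(sr), 1), d[1])
  ci <- pmin(pmax(round(sc), 1), d[2])
  inside <- sr >= 0.5 & sr <= d[1] + 0.5 & sc >= 0.5 & sc <= d[2] + 0.5
  im2 <- matrix(0, d[1], d[2])
  mk2 <- matrix(FALSE, d[1], d[2])
  im2[inside] <- img[cbind(ri[inside], ci[inside])]
  mk2[inside] <- mask[cbind(ri[inside], ci[inside])] > 0
  if (aug$noise_sd > 0)
    im2 <- pmin(pmax(im2 + stats::rnorm(length(im2), sd = aug$noise_sd), 0), 1)
  list(img = im2, mask = mk2)
}

#' Train the U-Net aorta segmenter
#'
#' Random (seeded) train/validation split, on-the-fly augmentation, Dice
#' loss and Adam; after every epoch the validation Dice is measured and
#' the best-epoch weights are kept.
#'
#' @param images List of numeric matrices or [ultrasound_image()]s.
#' @param masks List of binary masks, aligned with `images`.
#' @param cfg A [seg_train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `unet_segmenter`: list with the fitted network, `cfg`,
#'   `history` (tibble of epoch, training loss, validation Dice),
#'   `best_val_dice` and the split indices.
#' @export
train_segmenter <- function(images, masks, cfg = seg_train_config(),
                            verbose = FALSE) {
  if (length(images) == 0) stop("empty dataset")
  if (length(images) != length(masks)) stop("images and masks differ in length")
  n <- length(images)
  sz <- cfg$image_size
  xs <- lapply(images, function(im) {
    m <- as_pixel_matrix(im)
    if (!identical(dim(m), dim(as_pixel_matrix(images[[1]]))))
      stop("images have inconsistent shapes")
    resize_bilinear(m, sz, sz)
  })
  ys <- lapply(seq_len(n), function(i) {
    mk <- masks[[i]]
    if (!identical(dim(mk), dim(as_pixel_matrix(images[[i]]))))
      stop("image/mask shape mismatch at index ", i)
    resize_bilinear(mk * 1, sz, sz, nearest = TRUE) > 0
  })

  withr::with_seed(cfg$seed, {
    perm <- sample(n)
    n_train <- max(1L, floor(cfg$split * n))
    idx_train <- perm[seq_len(n_train)]
    idx_val <- if (n_train < n) perm[(n_train + 1):n] else idx_train

    net <- unet_create(1L, cfg$base_channels, cfg$levels, cfg$seed)
    x_val <- simplify2array(xs[idx_val])
    val_dice <- function() {
      pr <- unet_predict_cpp(net, x_val)
      mean(vapply(seq_along(idx_val), function(i)
        dsc(pr[, , i] > 0.5, ys[[idx_val[i]]]), numeric(1)))
    }
    hist <- list(tibble::tibble(epoch = 0L, loss = NA_real_,
                                val_dice = val_dice()))
    best <- list(dice = -Inf, weights = NULL)
    for (ep in seq_len(cfg$epochs)) {
      lr_ep <- cfg$learning_rate
      if (!is.null(cfg$lr_decay)) {
        if (ep > cfg$lr_decay[1] * cfg$epochs) lr_ep <- lr_ep * 10^-0.5
        if (ep > cfg$lr_decay[2] * cfg$epochs) lr_ep <- lr_ep * 10^-0.5
      }
      ord <- sample(idx_train)
      losses <- c()
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        xb <- array(0, c(sz, sz, length(bi)))
        yb <- array(0, c(sz, sz, length(bi)))
        for (k in seq_along(bi)) {
          if (is.list(cfg$augment)) {
            ai <- augment_pair(xs[[bi[k]]], ys[[bi[k]]], cfg$augment)
            xb[, , k] <- ai$img; yb[, , k] <- ai$mask * 1
          } else {
            xb[, , k] <- xs[[bi[k]]]; yb[, , k] <- ys[[bi[k]]] * 1
          }
        }
        losses <- c(losses, unet_train_batch(net, xb, yb, lr_ep))
      }
      vd <- val_dice()
      if (vd > best$dice) best <- list(dice = vd, weights = unet_get_weights(net))
      hist[[ep + 1L]] <- tibble::tibble(epoch = ep, loss = mean(losses),
                                        val_dice = vd)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val Dice %.4f",
                        ep, mean(losses), vd))
    }
    if (!is.null(best$weights)) unet_set_weights(net, best$weights)
    structure(list(net = net, cfg = cfg,
                   history = do.call(rbind, hist),
                   best_val_dice = best$dice,
                   idx_train = idx_train, idx_val = idx_val),
              class = "unet_segmenter")
  })
}

#' @export
print.unet_segmenter <- function(x, ...) {
  cat("<unet_segmenter> ", x$cfg$levels, " levels x ",
      x$cfg$base_channels, " base channels, input ",
      x$cfg$image_size, " px\n  best validation Dice: ",
      round(x$best_val_dice, 4), " over ", x$cfg$epochs, " epochs\n",
      sep = "")
  invisible(x)
}

#' @method glance unet_segmenter
#' @export
glance.unet_segmenter <- function(x, ...) {
  tibble::tibble(epochs = x$cfg$epochs,
                 n_train = length(x$idx_train), n_val = length(x$idx_val),
                 best_val_dice = x$best_val_dice,
                 final_loss = utils::tail(x$history$loss, 1))
}

#' @method tidy unet_segmenter
#' @export
tidy.unet_segmenter <- function(x, ...) x$history

#' Predict a binary aorta mask
#'
#' Runs the segmenter on an image (resampled to the network input size if
#' needed), thresholds the probability map at 0.5, keeps the largest
#' connected component with holes filled (a single structure is sought)
#' and restricts the mask to the fan region. Deterministic.
#'
#' @param model A `unet_segmenter` from [train_segmenter()].
#' @param image Numeric matrix or [ultrasound_image()].
#' @param fan_mask Optional logical matrix; defaults to the image's own
#'   fan mask when an `ultrasound_image` is supplied.
#' @return Logical mask with the input image's dimensions.
#' @export
predict_mask <- function(model, image, fan_mask = NULL) {
  stopifnot(inherits(model, "unet_segmenter"))
  if (is.null(fan_mask) && inherits(image, "ultrasound_image"))
    fan_mask <- image$fan_mask
  px <- as_pixel_matrix(image)
  d <- dim(px)
  sz <- model$cfg$image_size
  x <- array(resize_bilinear(px, sz, sz), c(sz, sz, 1))
  pr <- unet_predict_cpp(model$net, x)[, , 1]
  mask <- resize_bilinear((pr > 0.5) * 1, d[1], d[2], nearest = TRUE) > 0
  if (any(mask)) {
    # one structure is sought: keep the largest component, fill holes
    mask <- EBImage::fillHull(largest_component(mask) * 1) > 0
  }
  if (!is.null(fan_mask)) mask <- mask & fan_mask
  mask
}
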