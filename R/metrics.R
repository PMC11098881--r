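#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` for two binary masks of identical shape. Two
#' empty masks score 1; an empty versus a non-empty mask scores 0.
#'
#' @param a,b Logical (or 0/1) matrices of the same shape.
#' @return Overlap fraction in \[0, 1\].
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:4, 2:4] <- TRUE
#' dsc(m, m)
#' @export
dsc <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  a <- a > 0; b <- b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}

#' Anterior-posterior diameter of a segmentation mask
#'
#' The AP axis is the image depth (vertical) axis. The diameter is the
#' maximum contiguous vertical run length over the columns of the largest
#' connected component, times the pixel spacing.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param pixel_spacing Pixel size, mm.
#' @return Diameter in mm.
#' @export
ap_diameter <- function(mask, pixel_spacing) {
  mask <- mask > 0
  if (!any(mask)) stop("no aorta found: mask is empty")
  comp <- largest_component(mask)
  best <- 0L
  for (cc in which(colSums(comp) > 0)) {
    col <- comp[, cc]
    r <- rle(col)
    best <- max(best, max(r$lengths[r$values]))
  }
  best * pixel_spacing
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) <= 1L) return(mask)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Evaluate predicted aorta masks against ground truth
#'
#' Per-image Dice and AP diameters, the mean absolute diameter error (MAE)
#' over images with a non-empty prediction, the failure fraction (empty
#' predictions), and the clinical acceptability flag: an MAE strictly below
#' 8 mm is considered acceptable for AAA diagnosis.
#'
#' @param preds,gts Equal-length lists of binary masks.
#' @param pixel_spacing Pixel size, mm.
#' @param gt_diameters Optional numeric vector of reference diameters (mm);
#'   if omitted, diameters are measured from `gts`.
#' @return An `eval_report`: list with `per_image` (tibble), `mean_dsc`,
#'   `sd_dsc`, `mae_mm`, `sd_ae_mm`, `failure_fraction`,
#'   `clinically_acceptable`.
#' @export
evaluate <- function(preds, gts, pixel_spacing, gt_diameters = NULL) {
  if (length(preds) != length(gts)) stop("preds and gts differ in length")
  n <- length(preds)
  d_pred <- d_gt <- rep(NA_real_, n)
  dice <- numeric(n)
  for (i in seq_len(n)) {
    dice[i] <- dsc(preds[[i]], gts[[i]])
    d_gt[i] <- if (!is.null(gt_diameters)) gt_diameters[i]
               else ap_diameter(gts[[i]], pixel_spacing)
    if (any(preds[[i]] > 0))
      d_pred[i] <- ap_diameter(preds[[i]], pixel_spacing)
  }
  ok <- !is.na(d_pred)
  ae <- abs(d_pred[ok] - d_gt[ok])
  mae <- if (any(ok)) mean(ae) else NA_real_
  rep <- list(
    per_image = tibble::tibble(image = seq_len(n), dsc = dice,
                               diameter_pred_mm = d_pred,
                               diameter_gt_mm = d_gt,
                               abs_error_mm = abs(d_pred - d_gt)),
    mean_dsc = mean(dice), sd_dsc = stats::sd(dice),
    mae_mm = mae, sd_ae_mm = if (sum(ok) > 1) stats::sd(ae) else NA_real_,
    failure_fraction = mean(!ok),
    clinically_acceptable = isTRUE(mae < 8)
  )
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", nrow(x$per_image), " images\n",
      "  mean DSC: ", round(x$mean_dsc, 4),
      " (sd ", round(x$sd_dsc, 4), ")\n",
      "  MAE: ", round(x$mae_mm, 3), " mm (sd ", round(x$sd_ae_mm, 3),
      "), failures: ", round(100 * x$failure_fraction, 1), "%\n",
      "  clinically acceptable (< 8 mm): ", x$clinically_acceptable, "\n",
      sep = "")
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_image

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(mean_dsc = x$mean_dsc, sd_dsc = x$sd_dsc,
                 mae_mm = x$mae_mm, sd_ae_mm = x$sd_ae_mm,
                 failure_fraction = x$failure_fraction,
                 clinically_acceptable = x$clinically_acceptable)
}
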