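## Segmentation evaluation.
##
## Scores follow the standard confusion-matrix definitions: with n_ij the
## number of pixels of true class i predicted as j and t_i the true pixel
## count of class i,
##   pixel accuracy = sum_i n_ii / sum_i t_i
##   mean accuracy  = (1/C') sum_i n_ii / t_i
##   mean IoU       = (1/C') sum_i n_ii / (t_i + sum_j n_ji - n_ii)
## where C' counts only classes present in the ground truth.  Pixels with
## the ignore label (a void class) are excluded everywhere.

#' Segmentation prediction scores
#'
#' Pixel accuracy, mean per-class accuracy and mean IoU from the confusion
#' matrix of predicted versus true label maps.  Classes absent from the
#' ground truth are excluded from the class means; ignore-labelled pixels
#' are excluded entirely.
#'
#' @param predicted,true Integer label maps (vectors or arrays of equal
#'   shape) with values in `[0, n_classes)` outside ignored pixels.
#' @param n_classes Number of classes `C`.
#' @param ignore Void label value excluded from scoring (default 255).
#' @return A one-row tibble `(pixel_accuracy, mean_accuracy, mean_iou,
#'   n_pixels, n_classes_present)`.
#' @export
segmentation_scores <- function(predicted, true, n_classes, ignore = 255L) {
  if (length(predicted) != length(true)) {
    abort("predicted and true label maps must have equal shape.",
          class = "mcdc_structural_error")
  }
  p <- as.integer(predicted); y <- as.integer(true)
  keep <- y != ignore & p != ignore
  if (!any(keep)) {
    abort("no unignored pixels to score.", class = "mcdc_invalid_input")
  }
  p <- p[keep]; y <- y[keep]
  if (any(p < 0 | p >= n_classes) || any(y < 0 | y >= n_classes)) {
    abort("labels outside [0, n_classes) among unignored pixels.",
          class = "mcdc_invalid_input")
  }
  lev <- 0:(n_classes - 1L)
  cm <- table(factor(y, levels = lev), factor(p, levels = lev))
  cm <- matrix(as.numeric(cm), n_classes, n_classes)
  t_i <- rowSums(cm)
  present <- t_i > 0
  diag_i <- diag(cm)
  iou_den <- t_i + colSums(cm) - diag_i
  tibble(
    pixel_accuracy = sum(diag_i) / sum(cm),
    mean_accuracy = mean(diag_i[present] / t_i[present]),
    mean_iou = mean(diag_i[present] / iou_den[present]),
    n_pixels = sum(cm),
    n_classes_present = sum(present))
}

#' Accuracy of the most certain pixels at a confidence percentile
#'
#' Keeps the `(100 - q)`% pixels with the lowest uncertainty (stable order,
#' lowest index first on ties) and returns their prediction accuracy;
#' `q = 0` scores all pixels.
#'
#' @param i_norm Per-pixel normalized uncertainties.
#' @param correct Per-pixel logical correctness.
#' @param q Confidence percentile in `[0, 100)`.
#' @return Accuracy over the retained pixels (scalar).
#' @export
confidence_percentile_accuracy <- function(i_norm, correct, q) {
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q >= 100) {
    abort("`q` must lie in [0, 100).", class = "mcdc_invalid_parameter")
  }
  n <- length(i_norm)
  k <- ceiling((100 - q) / 100 * n)
  ord <- order(i_norm)
  mean(correct[ord[seq_len(k)]])
}

#' Render correctness and confidence maps
#'
#' Builds the two binary maps of the qualitative evaluation: white (1)
#' where the prediction is correct, and white where it is certain
#' (`i_norm < threshold`); ignored pixels are rendered neutral gray (0.5).
#' Optionally writes single-channel PNG files.
#'
#' @param predicted,true Integer label matrices (`H x W`).
#' @param i_norm Matrix of per-pixel normalized uncertainties (`H x W`).
#' @param threshold Certainty threshold `I_T` in `[0, 1]`; typically the
#'   validation threshold maximizing uncertainty accuracy, see
#'   [select_operating_threshold()].
#' @param ignore Void label value rendered gray (default 255).
#' @param correctness_file,confidence_file Optional PNG output paths.
#' @return A list with numeric matrices `correctness` and `confidence`
#'   (values 0, 0.5 or 1).
#' @export
render_maps <- function(predicted, true, i_norm, threshold, ignore = 255L,
                        correctness_file = NULL, confidence_file = NULL) {
  if (threshold < 0 || threshold > 1) {
    abort("`threshold` must lie in [0, 1].",
          class = "mcdc_invalid_parameter")
  }
  stopifnot(identical(dim(predicted), dim(true)),
            identical(dim(predicted), dim(i_norm)))
  void <- true == ignore
  corr <- matrix(as.numeric(predicted == true), nrow(true), ncol(true))
  conf <- matrix(as.numeric(i_norm < threshold), nrow(true), ncol(true))
  corr[void] <- 0.5
  conf[void] <- 0.5
  if (!is.null(correctness_file)) png::writePNG(corr, correctness_file)
  if (!is.null(confidence_file)) png::writePNG(conf, confidence_file)
  list(correctness = corr, confidence = conf)
}

#' Reshape flat per-pixel values into per-image maps
#'
#' Segmentation MC predictions index pixels row-major per image; this
#' utility folds a flat per-pixel vector back into a list of `H x W`
#' matrices using the spatial metadata of an `mc_prediction_set`.
#'
#' @param values Flat vector over all pixels of all images.
#' @param spatial `c(n_images, H, W)` (e.g. `mcset$spatial`).
#' @return A list of `n_images` matrices of dimension `H x W`.
#' @export
as_label_maps <- function(values, spatial) {
  n <- spatial[1]; h <- spatial[2]; w <- spatial[3]
  stopifnot(length(values) == n * h * w)
  arr <- array(values, c(n, h, w))
  lapply(seq_len(n), function(i) matrix(arr[i, , ], h, w))
}
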