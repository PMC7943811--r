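## Uncertainty-quality evaluation.
##
## A threshold I_T on the normalized uncertainty splits predictions into
## certain (i_norm < I_T) and uncertain groups; crossing with correctness
## gives four counts (cc, ic, cu, iu) and three ratios:
##   R_cc = N_cc / (N_cc + N_ic)   correct given certain
##   R_iu = N_iu / (N_iu + N_ic)   uncertain given incorrect
##   UA   = (N_cc + N_iu) / N      uncertainty accuracy
## Each is swept over a threshold grid and summarized by the trapezoidal
## area under the curve, reported in percent.  Ties (i_norm == I_T) count
## as uncertain — the conservative choice for safety-critical screening.

#' Elementwise correctness of predictions
#'
#' @param predicted_labels,true_labels Equal-length integer vectors (or
#'   arrays) of labels.
#' @return Logical vector: `TRUE` where they agree.
#' @export
correctness_map <- function(predicted_labels, true_labels) {
  if (length(predicted_labels) != length(true_labels)) {
    abort("predicted and true labels must have equal length.",
          class = "mcdc_structural_error")
  }
  as.vector(predicted_labels == true_labels)
}

#' Split items into certain and uncertain at a threshold
#'
#' Certain means `i_norm < threshold` (strict); values equal to the
#' threshold are classed uncertain.
#'
#' @param i_norm Normalized uncertainties in `[0, 1]`.
#' @param threshold Threshold `I_T` in `[0, 1]`.
#' @return Logical vector: `TRUE` where certain.
#' @export
certainty_split <- function(i_norm, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    abort("`threshold` must lie in [0, 1].",
          class = "mcdc_invalid_parameter")
  }
  i_norm < threshold
}

#' Four-way counts of correctness by certainty
#'
#' @param correct,certain Equal-length logical vectors.
#' @return Named integer vector `(n_cc, n_ic, n_cu, n_iu)` partitioning `N`.
#' @export
confusion_counts <- function(correct, certain) {
  if (length(correct) != length(certain)) {
    abort("`correct` and `certain` must have equal length.",
          class = "mcdc_structural_error")
  }
  c(n_cc = sum(correct & certain), n_ic = sum(!correct & certain),
    n_cu = sum(correct & !certain), n_iu = sum(!correct & !certain))
}

#' Uncertainty-quality ratios from four-way counts
#'
#' Undefined ratios (0/0 denominators) are returned as `NA` markers, never
#' silently replaced.
#'
#' @param counts Named vector as returned by [confusion_counts()].
#' @return A one-row tibble `(n_cc, n_ic, n_cu, n_iu, r_cc, r_iu, ua)`.
#' @export
ratio_metrics <- function(counts) {
  counts <- as.numeric(counts[c("n_cc", "n_ic", "n_cu", "n_iu")])
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("`counts` must be four nonnegative counts named n_cc, n_ic, n_cu, n_iu.",
          class = "mcdc_invalid_input")
  }
  n <- sum(counts)
  if (n == 0) {
    abort("all counts are zero.", class = "mcdc_invalid_input")
  }
  rcc_den <- counts[1] + counts[2]
  riu_den <- counts[4] + counts[2]
  tibble(n_cc = counts[1], n_ic = counts[2], n_cu = counts[3],
         n_iu = counts[4],
         r_cc = if (rcc_den > 0) counts[1] / rcc_den else NA_real_,
         r_iu = if (riu_den > 0) counts[4] / riu_den else NA_real_,
         ua = (counts[1] + counts[4]) / n)
}

#' Evaluate the uncertainty at a single threshold
#'
#' @param i_norm Normalized uncertainties in `[0, 1]`.
#' @param correct Logical correctness vector.
#' @param threshold Threshold `I_T`.
#' @return A one-row tibble with the threshold, the four counts and the
#'   three ratios.
#' @export
threshold_evaluation <- function(i_norm, correct, threshold) {
  cnt <- confusion_counts(correct, certainty_split(i_norm, threshold))
  dplyr::bind_cols(tibble(threshold = threshold), ratio_metrics(cnt))
}

trapezoid_auc <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Sweep the uncertainty-quality metrics over a threshold grid
#'
#' Evaluates the four-way counts and the three ratios at every threshold of
#' an ascending grid spanning `[0, 1]`, and summarizes each ratio by its
#' trapezoidal area under the curve in percent.  Undefined ratio values are
#' kept as `NA` in the table; for the AUC they are filled with 1 —
#' vacuously perfect for `R_cc` when nothing is certain and for `R_iu` when
#' nothing is incorrect — a convention recorded in the result's
#' `auc_fill` attribute.
#'
#' @inheritParams threshold_evaluation
#' @param thresholds Strictly increasing grid; must start at 0 and end at 1
#'   (default: 101 evenly spaced points).
#' @param auc_fill Value substituted for undefined ratios in the AUC
#'   integration (default 1).
#' @return A tibble of class `"metric_curves"` with one row per threshold;
#'   AUCs (percent) are available via [glance()] and as attribute `auc`.
#' @export
metric_curves <- function(i_norm, correct,
                          thresholds = seq(0, 1, length.out = 101L),
                          auc_fill = 1) {
  if (is.unsorted(thresholds, strictly = TRUE) ||
      thresholds[1] != 0 || thresholds[length(thresholds)] != 1) {
    abort("`thresholds` must be strictly increasing from 0 to 1.",
          class = "mcdc_invalid_parameter")
  }
  rows <- purrr::map_dfr(thresholds, function(th)
    threshold_evaluation(i_norm, correct, th))
  fill <- function(v) ifelse(is.na(v), auc_fill, v)
  auc <- c(r_cc = 100 * trapezoid_auc(thresholds, fill(rows$r_cc)),
           r_iu = 100 * trapezoid_auc(thresholds, fill(rows$r_iu)),
           ua = 100 * trapezoid_auc(thresholds, rows$ua))
  structure(rows, class = c("metric_curves", class(rows)),
            auc = auc, auc_fill = auc_fill)
}

#' @export
glance.metric_curves <- function(x, ...) {
  auc <- attr(x, "auc")
  tibble(r_cc_auc = auc[["r_cc"]], r_iu_auc = auc[["r_iu"]],
         ua_auc = auc[["ua"]])
}

#' @export
tidy.metric_curves <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), c("r_cc", "r_iu", "ua"),
                      names_to = "metric", values_to = "value")
}

#' Kolmogorov-Smirnov separation of correct and incorrect uncertainties
#'
#' Two-sample KS test of the uncertainty values of correct versus incorrect
#' predictions; a large statistic with a small p-value means the epistemic
#' uncertainty distinguishes errors from successes.
#'
#' @param u_correct,u_incorrect Nonempty numeric vectors of uncertainty
#'   values for the two groups.
#' @return A one-row tibble `(statistic, p_value, n_correct, n_incorrect)`.
#' @export
ks_separation <- function(u_correct, u_incorrect) {
  if (length(u_correct) == 0L || length(u_incorrect) == 0L) {
    abort("both groups must be nonempty.", class = "mcdc_invalid_input")
  }
  kt <- suppressWarnings(ks.test(u_correct, u_incorrect))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         n_correct = length(u_correct), n_incorrect = length(u_incorrect))
}
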