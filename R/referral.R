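## Uncertainty-informed referral (selective prediction).
##
## Sort predictions by epistemic uncertainty and hand the most uncertain
## ones to a fallback (e.g. a human reader); score accuracy on what is
## retained, either as a function of the tolerated uncertainty or of the
## retained-data fraction, against a random-rejection baseline that removes
## the same number of items with no use of uncertainty.

new_referral_curve <- function(df, mode) {
  structure(df, class = c("referral_curve", class(df)), mode = mode)
}

#' Accuracy as a function of tolerated uncertainty
#'
#' At tolerance `tau`, accuracy is computed over the items with
#' `i_norm <= tau`; an empty retained set yields `NA`.
#'
#' @param i_norm Normalized uncertainties in `[0, 1]`.
#' @param correct Logical correctness vector.
#' @param tolerance_grid Tolerances in `[0, 1]` (default 20 evenly spaced
#'   values from 1 down the unit interval, ascending).
#' @return A tibble `(tolerance, accuracy, n_retained)` of class
#'   `"referral_curve"`.
#' @export
referral_by_tolerance <- function(i_norm, correct,
                                  tolerance_grid = seq(0.05, 1,
                                                       length.out = 20L)) {
  df <- purrr::map_dfr(tolerance_grid, function(tau) {
    keep <- i_norm <= tau
    tibble(tolerance = tau,
           accuracy = if (any(keep)) mean(correct[keep]) else NA_real_,
           n_retained = sum(keep))
  })
  new_referral_curve(df, "by_tolerance")
}

#' Accuracy as a function of the retained-data fraction
#'
#' Retains the `ceiling(f * N)` items with smallest uncertainty (stable
#' order on ties: lowest index first) and scores accuracy on them.
#'
#' @inheritParams referral_by_tolerance
#' @param fraction_grid Retained fractions in `(0, 1]` (default 20 evenly
#'   spaced values ending at 1).
#' @return A tibble `(fraction, accuracy, n_retained)` of class
#'   `"referral_curve"`.
#' @export
referral_by_fraction <- function(i_norm, correct,
                                 fraction_grid = seq(0.05, 1,
                                                     length.out = 20L)) {
  if (any(fraction_grid <= 0) || any(fraction_grid > 1)) {
    abort("`fraction_grid` must lie in (0, 1].",
          class = "mcdc_invalid_parameter")
  }
  n <- length(i_norm)
  ord <- order(i_norm) # stable: ties keep original order
  df <- purrr::map_dfr(fraction_grid, function(f) {
    k <- ceiling(f * n)
    tibble(fraction = f, accuracy = mean(correct[ord[seq_len(k)]]),
           n_retained = k)
  })
  new_referral_curve(df, "by_retained_fraction")
}

#' Random-rejection baseline for referral curves
#'
#' For each retained fraction, removes the same number of items uniformly
#' at random (no use of uncertainty) and reports the mean and standard
#' deviation of the retained-set accuracy over repeated samplings.
#'
#' @param correct Logical correctness vector.
#' @param fraction_grid Retained fractions in `(0, 1]`.
#' @param repetitions Number of random samplings (default 20).
#' @param seed Seed for the sampling stream.
#' @return A tibble `(fraction, mean_accuracy, sd_accuracy, n_retained)`.
#' @export
random_rejection_baseline <- function(correct,
                                      fraction_grid = seq(0.05, 1,
                                                          length.out = 20L),
                                      repetitions = 20L, seed = 0L) {
  if (repetitions < 2L) {
    abort("`repetitions` must be >= 2.", class = "mcdc_invalid_parameter")
  }
  n <- length(correct)
  purrr::map_dfr(seq_along(fraction_grid), function(gi) {
    f <- fraction_grid[gi]
    k <- ceiling(f * n)
    accs <- vapply(seq_len(repetitions), function(r) {
      keep <- if (k == n) seq_len(n) else
        with_local_seed(mix_seed(seed, gi * 1000L + r),
                        sample.int(n, k))
      mean(correct[keep])
    }, numeric(1))
    tibble(fraction = f, mean_accuracy = mean(accs),
           sd_accuracy = sd(accs), n_retained = k)
  })
}

#' Choose an operating uncertainty threshold on validation data
#'
#' Grid-searches the threshold maximizing an uncertainty-quality objective
#' (uncertainty accuracy by default) on a validation set; the returned
#' value is frozen and then applied unchanged to test data.  Within the
#' optimal plateau — the longest contiguous run of grid points attaining
#' the maximum — the midpoint is returned.  An all-correct validation set
#' has nothing to reject and yields the maximum threshold.
#'
#' @param i_norm Validation normalized uncertainties.
#' @param correct Validation correctness vector.
#' @param objective `"ua"`, `"r_cc"` or `"r_iu"`.
#' @param thresholds Search grid (default 101 points on `[0, 1]`).
#' @return The selected threshold (scalar).
#' @export
select_operating_threshold <- function(i_norm, correct, objective = "ua",
                                       thresholds = seq(0, 1,
                                                        length.out = 101L)) {
  if (length(i_norm) == 0L) {
    abort("validation set must be nonempty.", class = "mcdc_invalid_input")
  }
  objective <- match.arg(objective, c("ua", "r_cc", "r_iu"))
  # nothing to reject: with an all-correct validation set every prediction
  # should be kept, so the most permissive threshold is returned
  if (all(correct)) return(thresholds[length(thresholds)])
  vals <- vapply(thresholds, function(th)
    threshold_evaluation(i_norm, correct, th)[[objective]], numeric(1))
  vals[is.na(vals)] <- -Inf
  best <- max(vals)
  at_best <- abs(vals - best) < 1e-12
  runs <- rle(at_best)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  pick <- cand[which.max(runs$lengths[cand])]
  lo <- thresholds[starts[pick]]
  hi <- thresholds[ends[pick]]
  (lo + hi) / 2
}

#' @export
glance.referral_curve <- function(x, ...) {
  full <- x[x$n_retained == max(x$n_retained), , drop = FALSE]
  tibble(mode = attr(x, "mode"),
         full_retention_accuracy = full$accuracy[nrow(full)],
         best_accuracy = max(x$accuracy, na.rm = TRUE))
}
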