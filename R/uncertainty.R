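## Epistemic uncertainty from MC samples.
##
## For an item with T softmax samples p_t:
##   predictive entropy  H = -sum_c pbar_c log pbar_c,  pbar = mean_t p_t
##   mutual information  I = H - (1/T) sum_t H(p_t)
## H is the total predictive uncertainty; the expected per-pass entropy is
## its aleatoric part, and their difference I — the disagreement among the
## posterior draws — is the epistemic part: the mutual information between
## the prediction and the weights.  I is min-max normalized over an
## evaluation set to I_norm in [0, 1] so thresholds are comparable across
## datasets, architectures and T.

check_prob_vector <- function(p, tol = 1e-6) {
  if (any(p < -tol) || abs(sum(p) - 1) > tol) {
    abort("input must be a probability vector (nonnegative, summing to 1).",
          class = "mcdc_invalid_input")
  }
}

entropy_rows <- function(p) {
  -rowSums(p * log(pmax(p, 1e-12)))
}

#' Predictive entropy of a class-probability vector
#'
#' `-sum_c p_c log p_c` in nats, with `0 log 0 := 0`.  Accepts a single
#' probability vector or a matrix of row vectors.
#'
#' @param p Probability vector of length `C`, or an `N x C` matrix.
#' @return A scalar (or length-`N` vector) of entropies in nats.
#' @export
#' @examples
#' predictive_entropy(c(0.25, 0.25, 0.25, 0.25)) # log(4)
predictive_entropy <- function(p) {
  if (is.matrix(p)) {
    apply(p, 1L, check_prob_vector)
    return(entropy_rows(p))
  }
  check_prob_vector(p)
  -sum(ifelse(p > 0, p * log(pmax(p, 1e-12)), 0))
}

#' Mutual information between prediction and weights for one item
#'
#' The epistemic uncertainty of one item from its `T x C` sample matrix:
#' entropy of the mean minus mean of the per-sample entropies.  Tiny
#' negative values from floating point are clamped to zero.
#'
#' @param samples `T x C` matrix; each row a probability vector.
#' @return Mutual information in nats (scalar, >= 0).
#' @export
#' @examples
#' mutual_information(rbind(c(1, 0), c(0, 1))) # log(2)
mutual_information <- function(samples) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  if (nrow(samples) == 0L) {
    abort("need at least one MC sample.", class = "mcdc_invalid_input")
  }
  apply(samples, 1L, check_prob_vector)
  h_mean <- predictive_entropy(colMeans(samples))
  mean_h <- mean(entropy_rows(samples))
  max(h_mean - mean_h, 0)
}

#' Per-class variance of the MC samples for one item
#'
#' The variance-based alternative uncertainty measure: the population
#' variance of each class probability over the `T` draws.
#'
#' @param samples `T x C` matrix with `T >= 2`.
#' @return A length-`C` vector of variances (each in `[0, 0.25]`).
#' @export
classwise_variance <- function(samples) {
  if (is.null(dim(samples)) || nrow(samples) < 2L) {
    abort("need at least two MC samples for a variance.",
          class = "mcdc_invalid_input")
  }
  m <- colMeans(samples)
  colMeans(sweep(samples, 2L, m)^2)
}

#' Min-max normalize mutual-information values over a dataset
#'
#' Maps raw MI values to `I_norm in [0, 1]` using the dataset minimum and
#' maximum.  In frozen-normalizer mode a reference `(i_min, i_max)` pair
#' (e.g. from a validation set) is reused and out-of-range values are
#' clipped, which is what a validation-chosen threshold applied to test
#' data requires.  A constant input maps to all zeros.
#'
#' @param raw Nonnegative vector of MI values.
#' @param i_min,i_max Optional frozen normalization bounds.
#' @return Numeric vector in `[0, 1]` with attributes `i_min` and `i_max`.
#' @export
normalize_uncertainty <- function(raw, i_min = NULL, i_max = NULL) {
  if (length(raw) == 0L) {
    abort("`raw` must be nonempty.", class = "mcdc_invalid_input")
  }
  if (any(raw < 0)) {
    abort("`raw` must be nonnegative.", class = "mcdc_invalid_input")
  }
  frozen <- !is.null(i_min) || !is.null(i_max)
  if (frozen && (is.null(i_min) || is.null(i_max))) {
    abort("provide both `i_min` and `i_max` or neither.",
          class = "mcdc_invalid_parameter")
  }
  if (!frozen) { i_min <- min(raw); i_max <- max(raw) }
  out <- if (i_max > i_min) (raw - i_min) / (i_max - i_min)
         else rep(0, length(raw))
  if (frozen) out <- pmin(pmax(out, 0), 1)
  structure(out, i_min = i_min, i_max = i_max)
}

#' Per-item uncertainty scores for an MC sample set
#'
#' Computes, for every item (pixel, for segmentation) of an
#' [mc_predict()] result: the predictive entropy of the MC mean, the mean
#' per-pass entropy, the mutual information, and its dataset-normalized
#' value.
#'
#' @param mcset An `mc_prediction_set`, or a list with `mean_probs` and
#'   `mean_sample_entropy` as returned by [mc_predict_moments()].
#' @param i_min,i_max Optional frozen normalization bounds, passed to
#'   [normalize_uncertainty()].
#' @return A tibble of class `"uncertainty_result"` with columns `item`,
#'   `entropy`, `mean_sample_entropy`, `mutual_information`, `i_norm`, and
#'   attributes `i_min` / `i_max`.
#' @export
uncertainty_scores <- function(mcset, i_min = NULL, i_max = NULL) {
  if (inherits(mcset, "mc_prediction_set")) {
    pbar <- predictive_mean(mcset)
    h <- entropy_rows(pbar)
    tn <- mcset$T
    mean_h <- 0
    for (t in seq_len(tn)) {
      st <- mcset$samples[t, , , drop = FALSE]
      dim(st) <- dim(st)[2:3]
      mean_h <- mean_h + entropy_rows(st)
    }
    mean_h <- mean_h / tn
    ids <- mcset$item_ids
  } else if (is.list(mcset) && !is.null(mcset$mean_probs)) {
    h <- entropy_rows(mcset$mean_probs)
    mean_h <- mcset$mean_sample_entropy
    ids <- seq_len(nrow(mcset$mean_probs))
  } else {
    abort("`mcset` must be an mc_prediction_set or a moments list.",
          class = "mcdc_invalid_input")
  }
  mi <- pmax(h - mean_h, 0)
  inorm <- normalize_uncertainty(mi, i_min = i_min, i_max = i_max)
  out <- tibble(item = ids, entropy = h, mean_sample_entropy = mean_h,
                mutual_information = mi, i_norm = as.numeric(inorm))
  structure(out, class = c("uncertainty_result", class(out)),
            i_min = attr(inorm, "i_min"), i_max = attr(inorm, "i_max"))
}

#' @export
glance.uncertainty_result <- function(x, ...) {
  tibble(n = nrow(x), i_min = attr(x, "i_min"), i_max = attr(x, "i_max"),
         mean_entropy = mean(x$entropy),
         mean_mutual_information = mean(x$mutual_information))
}
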