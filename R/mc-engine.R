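## Monte Carlo prediction engine.
##
## At test time the Bernoulli masks stay active; each forward pass is one
## draw from the approximate weight posterior, and averaging T passes gives
## the Monte Carlo posterior predictive.  Samples are kept in full
## (T x N x C) because the mutual-information decomposition needs per-pass
## entropies; a streaming moment accumulator is provided as an equivalent
## alternative for large inputs.

new_mc_prediction_set <- function(samples, item_ids = NULL, spatial = NULL,
                                  seed = NA_integer_, draw_offset = 0L) {
  stopifnot(length(dim(samples)) == 3L)
  structure(list(samples = samples, T = dim(samples)[1],
                 n_items = dim(samples)[2], n_classes = dim(samples)[3],
                 item_ids = item_ids %||% seq_len(dim(samples)[2]),
                 spatial = spatial, seed = seed,
                 draw_offset = as.integer(draw_offset)),
            class = "mc_prediction_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mc_prediction_set <- function(x, ...) {
  cat(sprintf("<mc_prediction_set: T = %d passes, %d items, %d classes%s>\n",
              x$T, x$n_items, x$n_classes,
              if (is.null(x$spatial)) "" else
                sprintf(", spatial %s", paste(x$spatial, collapse = "x"))))
  invisible(x)
}

#' Monte Carlo prediction with active masks
#'
#' Runs `T` stochastic forward passes, each under a fresh, reproducible mask
#' configuration.  For segmentation models items are pixels; the spatial
#' shape is kept as metadata.  Passing the same `seed` always reproduces the
#' same sample set, and `draw_offset` lets a run be continued: passes
#' `a+1, ..., a+b` of a longer run equal a fresh run with `draw_offset = a`.
#'
#' @param model An `mcdc_network`.
#' @param data Feature matrix or image array matching the model input.
#' @param T Number of stochastic passes (default 100).
#' @param seed Seed for the mask streams.
#' @param draw_offset Index of the last already-consumed pass (default 0).
#' @return An object of class `"mc_prediction_set"` holding the
#'   `T x N x C` array of softmax samples.
#' @export
mc_predict <- function(model, data, T = 100L, seed = 0L, draw_offset = 0L) {
  stopifnot(inherits(model, "mcdc_network"))
  if (T < 1L) abort("`T` must be >= 1.", class = "mcdc_invalid_parameter")
  stochastic <- has_stochastic_layers(model)
  if (!stochastic) {
    warn("model has no stochastic layers (all keep_prob = 1); the T samples are identical.")
  }
  out1 <- NULL
  samples <- NULL
  spatial <- NULL
  for (t in seq_len(T)) {
    if (stochastic) {
      masks <- draw_network_masks(model, seed, draw_offset + t)
      probs <- network_forward(model, data, masks)$probs
    } else {
      if (is.null(out1)) out1 <- network_forward(model, data, NULL)$probs
      probs <- out1
    }
    if (is.null(samples)) {
      spatial <- attr(probs, "spatial")
      samples <- array(NA_real_, c(T, nrow(probs), ncol(probs)))
    }
    samples[t, , ] <- probs
  }
  new_mc_prediction_set(samples, spatial = spatial, seed = seed,
                        draw_offset = draw_offset)
}

#' Posterior predictive mean of an MC sample set
#'
#' The elementwise mean over the `T` passes; rows remain probability
#' vectors, and their argmax (lowest class index on ties) is the model
#' prediction.
#'
#' @param mcset An [mc_predict()] result.
#' @return An `N x C` matrix of mean class probabilities.
#' @export
predictive_mean <- function(mcset) {
  stopifnot(inherits(mcset, "mc_prediction_set"))
  colMeans(mcset$samples, dims = 1L)
}

#' Predicted class labels from mean probabilities
#'
#' @param probs `N x C` probability matrix (e.g. [predictive_mean()]).
#' @return Integer labels in `[0, C)`; ties resolve to the lowest index.
#' @export
predicted_labels <- function(probs) {
  max.col(probs, ties.method = "first") - 1L
}

#' Deterministic forward pass (no drops)
#'
#' The standard test: every mask entry is one and no `1/keep_prob`
#' rescaling is applied, i.e. the plain network evaluated once.
#'
#' @inheritParams mc_predict
#' @return An `N x C` probability matrix (with spatial metadata for
#'   segmentation models).
#' @export
deterministic_predict <- function(model, data) {
  stopifnot(inherits(model, "mcdc_network"))
  network_forward(model, data, NULL)$probs
}

#' Streaming moment accumulator for MC prediction
#'
#' Computes, without storing the `T x N x C` sample array, the two
#' sufficient statistics of the uncertainty decomposition: the running mean
#' of the softmax samples and the running mean of the per-pass entropies.
#' Equivalent to [mc_predict()] followed by [uncertainty_scores()].
#'
#' @inheritParams mc_predict
#' @return A list with `mean_probs` (`N x C`) and `mean_sample_entropy`
#'   (length `N`, nats).
#' @export
mc_predict_moments <- function(model, data, T = 100L, seed = 0L,
                               draw_offset = 0L) {
  stopifnot(inherits(model, "mcdc_network"))
  if (T < 1L) abort("`T` must be >= 1.", class = "mcdc_invalid_parameter")
  sum_p <- NULL; sum_h <- NULL
  for (t in seq_len(T)) {
    masks <- if (has_stochastic_layers(model))
      draw_network_masks(model, seed, draw_offset + t) else NULL
    probs <- network_forward(model, data, masks)$probs
    h <- -rowSums(probs * log(pmax(probs, 1e-12)))
    if (is.null(sum_p)) { sum_p <- probs; sum_h <- h }
    else { sum_p <- sum_p + probs; sum_h <- sum_h + h }
  }
  list(mean_probs = sum_p / T, mean_sample_entropy = sum_h / T)
}

#' Prediction-error convergence in the number of MC passes
#'
#' For each `T` in `T_grid`, repeats the MC prediction with independent mask
#' streams and reports the mean and standard deviation of the error of the
#' predictive-mean argmax against `labels`, together with the two summary
#' statistics of the convergence analysis: the smallest `T` whose mean
#' error drops below the deterministic (no-drop) baseline, and the smallest
#' `T` whose mean error is within one standard deviation of the best mean
#' error over the grid.
#'
#' @param model An `mcdc_network` classifier.
#' @param data Input features.
#' @param labels True integer labels in `[0, C)`.
#' @param T_grid Ascending vector of pass counts.
#' @param repetitions Number of independent repetitions per `T`
#'   (default 10).
#' @param seed Root seed.
#' @return A tibble `(T, mean_error, sd_error)` of class
#'   `"convergence_curve"`, with attributes `deterministic_error`,
#'   `first_T_below_baseline` and `first_T_within_sd`.
#' @export
convergence_curve <- function(model, data, labels, T_grid,
                              repetitions = 10L, seed = 0L) {
  if (length(T_grid) == 0L) {
    abort("`T_grid` must be nonempty.", class = "mcdc_invalid_parameter")
  }
  if (is.unsorted(T_grid, strictly = TRUE)) {
    abort("`T_grid` must be strictly ascending.",
          class = "mcdc_invalid_parameter")
  }
  if (repetitions < 2L) {
    abort("`repetitions` must be >= 2.", class = "mcdc_invalid_parameter")
  }
  det_err <- mean(predicted_labels(deterministic_predict(model, data))
                  != labels)
  res <- purrr::map_dfr(seq_along(T_grid), function(gi) {
    tt <- T_grid[gi]
    errs <- vapply(seq_len(repetitions), function(r) {
      ms <- mc_predict(model, data, T = tt,
                       seed = mix_seed(seed, r * 10000L + gi))
      mean(predicted_labels(predictive_mean(ms)) != labels)
    }, numeric(1))
    tibble(T = tt, mean_error = mean(errs), sd_error = sd(errs))
  })
  best_i <- which.min(res$mean_error)
  within <- res$mean_error <= res$mean_error[best_i] + res$sd_error[best_i]
  below <- res$mean_error < det_err
  structure(res,
            class = c("convergence_curve", class(res)),
            deterministic_error = det_err,
            first_T_below_baseline =
              if (any(below)) res$T[which(below)[1]] else NA_integer_,
            first_T_within_sd = res$T[which(within)[1]])
}

#' @export
glance.convergence_curve <- function(x, ...) {
  tibble(deterministic_error = attr(x, "deterministic_error"),
         best_T = x$T[which.min(x$mean_error)],
         best_mean_error = min(x$mean_error),
         first_T_below_baseline = attr(x, "first_T_below_baseline"),
         first_T_within_sd = attr(x, "first_T_within_sd"))
}
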