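## Bernoulli-masked layer primitives.
##
## A layer carries a matrix of variational weight parameters theta with the
## bias folded in as an extra row fed by a fixed input of one.  At every
## forward pass a fresh binary mask Z is drawn, elementwise Bernoulli(p):
##
##   weight mode (DropConnect):  a = sigma(((Z . theta) s)' v)
##   unit mode   (Dropout):      a = sigma(z . (theta' v) s)
##
## where p is the keep probability and s an optional 1/p rescaling.  Masks
## stay active at test time; that is what turns the network into an
## approximate Bayesian model.

ACTIVATIONS <- c("identity", "relu", "softmax")

#' Specify a stochastic (DropConnect / Dropout) layer
#'
#' Builds the specification of one Bernoulli-masked layer: an affine (dense)
#' layer, or a convolution applied through patch extraction.  The bias is
#' stored as the last row of `theta` and is masked together with the weights
#' by default, matching the convention of folding biases into the weight
#' matrix with a fixed input of one.
#'
#' @param theta Numeric matrix of variational parameters, `(d_in + 1) x d_out`
#'   for an affine layer (last row is the bias row).  For a convolution,
#'   `(kernel^2 * in_channels + 1) x out_channels`.
#' @param keep_prob Probability `p` in `(0, 1]` that a weight (weight mode) or
#'   an output unit (unit mode) is kept on a given pass.
#' @param mask_mode `"weight"` draws one Bernoulli variate per element of
#'   `theta` (DropConnect); `"unit"` draws one per output unit (Dropout).
#' @param kind `"affine"` or `"convolution"`.
#' @param kernel Kernel side length (convolution only; square kernels,
#'   stride 1, zero "same" padding).
#' @param in_channels,out_channels Channel counts (convolution only).
#' @param activation Nonlinearity applied to the pre-activation: one of
#'   `"identity"`, `"relu"`, `"softmax"`.
#' @param scale_by_inverse_p If `TRUE` (default) kept weights are rescaled by
#'   `1/keep_prob`, so the all-ones-mask deterministic pass equals the
#'   expected stochastic activation.  Set `FALSE` for the unscaled
#'   parameterization.
#' @param mask_bias Whether the bias row participates in weight-mode masking
#'   (default `TRUE`).
#' @param seed_stream Integer RNG stream identifier for this layer's masks.
#' @return An object of class `"stochastic_layer"`.
#' @seealso [sample_mask()], [stochastic_forward()]
#' @export
#' @examples
#' lay <- stochastic_layer(matrix(rnorm(6), 3, 2), keep_prob = 0.5,
#'                         seed_stream = 1)
#' m <- sample_mask(lay, draw_index = 1)
#' stochastic_forward(lay, matrix(1, 1, 2), m)
stochastic_layer <- function(theta,
                             keep_prob = 0.5,
                             mask_mode = c("weight", "unit"),
                             kind = c("affine", "convolution"),
                             kernel = NULL,
                             in_channels = NULL,
                             out_channels = NULL,
                             activation = "identity",
                             scale_by_inverse_p = TRUE,
                             mask_bias = TRUE,
                             seed_stream = 0L) {
  mask_mode <- match.arg(mask_mode)
  kind <- match.arg(kind)
  if (!is.matrix(theta) || !is.numeric(theta)) {
    abort("`theta` must be a numeric matrix (bias folded in as the last row).",
          class = "mcdc_structural_error")
  }
  if (!is.numeric(keep_prob) || length(keep_prob) != 1L ||
      is.na(keep_prob) || keep_prob <= 0 || keep_prob > 1) {
    abort("`keep_prob` must lie in (0, 1].",
          class = "mcdc_invalid_parameter")
  }
  if (!activation %in% ACTIVATIONS) {
    abort(paste0("`activation` must be one of: ",
                 paste(ACTIVATIONS, collapse = ", ")),
          class = "mcdc_invalid_parameter")
  }
  if (kind == "convolution") {
    if (is.null(kernel) || is.null(in_channels) || is.null(out_channels)) {
      abort("convolution layers need `kernel`, `in_channels`, `out_channels`.",
            class = "mcdc_invalid_parameter")
    }
    if (nrow(theta) != kernel^2 * in_channels + 1L ||
        ncol(theta) != out_channels) {
      abort("`theta` must be (kernel^2 * in_channels + 1) x out_channels.",
            class = "mcdc_structural_error")
    }
  }
  structure(
    list(kind = kind, theta = theta, keep_prob = keep_prob,
         mask_mode = mask_mode, kernel = kernel,
         in_channels = in_channels, out_channels = out_channels,
         activation = activation,
         scale_by_inverse_p = isTRUE(scale_by_inverse_p),
         mask_bias = isTRUE(mask_bias),
         seed_stream = as.integer(seed_stream)),
    class = "stochastic_layer"
  )
}

#' @export
print.stochastic_layer <- function(x, ...) {
  cat(sprintf(
    "<stochastic_layer: %s, %s-mode, p = %g, theta %d x %d, activation %s>\n",
    x$kind, x$mask_mode, x$keep_prob, nrow(x$theta), ncol(x$theta),
    x$activation))
  invisible(x)
}

#' Draw a Bernoulli mask for a stochastic layer
#'
#' One mask is drawn per forward pass and shared across all items in the
#' batch.  The draw is fully reproducible: the same `(seed_stream,
#' draw_index)` pair always produces the same mask, which is how Monte Carlo
#' runs are made replayable and continuable.
#'
#' @param spec A [stochastic_layer()].
#' @param draw_index Nonnegative integer index of the pass within the layer's
#'   seed stream.
#' @return An object of class `"mask_draw"`: a binary matrix shaped like
#'   `theta` (weight mode) or a binary vector over output units (unit mode),
#'   with the derived `draw_seed` attached.
#' @export
sample_mask <- function(spec, draw_index = 0L) {
  stopifnot(inherits(spec, "stochastic_layer"))
  p <- spec$keep_prob
  draw_seed <- mix_seed(spec$seed_stream, draw_index)
  if (spec$mask_mode == "weight") {
    n <- length(spec$theta)
    z <- if (p == 1) rep(1, n) else
      with_local_seed(draw_seed, as.numeric(runif(n) < p))
    z <- matrix(z, nrow(spec$theta), ncol(spec$theta))
    if (!spec$mask_bias) z[nrow(z), ] <- 1
  } else {
    n <- ncol(spec$theta)
    z <- if (p == 1) rep(1, n) else
      with_local_seed(draw_seed, as.numeric(runif(n) < p))
  }
  structure(list(z = z, draw_seed = draw_seed, mask_mode = spec$mask_mode),
            class = "mask_draw")
}

apply_activation <- function(pre, activation) {
  switch(activation,
         identity = pre,
         relu = pmax(pre, 0),
         softmax = row_softmax(pre))
}

row_softmax <- function(pre) {
  m <- apply(pre, 1L, max)
  e <- exp(pre - m)
  e / rowSums(e)
}

## Effective weight matrix for a given mask (weight mode folds the mask and
## scaling into the weights; unit mode leaves theta untouched).
effective_weights <- function(spec, mask) {
  s <- if (spec$scale_by_inverse_p) 1 / spec$keep_prob else 1
  if (spec$mask_mode == "weight") spec$theta * mask$z * s else spec$theta
}

#' Run one masked forward pass through a layer
#'
#' Applies the layer to a batch of activations under a given mask draw.
#' In weight mode the mask multiplies the weights (DropConnect); in unit mode
#' it multiplies the pre-activation output units (Dropout).  With
#' `scale_by_inverse_p = TRUE` kept entries are rescaled by `1/keep_prob`.
#'
#' @param spec A [stochastic_layer()] of kind `"affine"`.
#' @param input Numeric matrix `n x d_in` (a vector is treated as one row).
#' @param mask A [sample_mask()] draw for this spec.
#' @return The `n x d_out` activation matrix.
#' @export
stochastic_forward <- function(spec, input, mask) {
  stopifnot(inherits(spec, "stochastic_layer"), inherits(mask, "mask_draw"))
  if (spec$kind != "affine") {
    abort("stochastic_forward() operates on affine layers; convolutions run inside a network.",
          class = "mcdc_invalid_parameter")
  }
  if (is.null(dim(input))) input <- matrix(input, nrow = 1L)
  if (ncol(input) != nrow(spec$theta) - 1L) {
    abort(sprintf("input has %d columns but the layer expects %d.",
                  ncol(input), nrow(spec$theta) - 1L),
          class = "mcdc_structural_error")
  }
  if (mask$mask_mode != spec$mask_mode ||
      (spec$mask_mode == "weight" &&
       !identical(dim(mask$z), dim(spec$theta))) ||
      (spec$mask_mode == "unit" && length(mask$z) != ncol(spec$theta))) {
    abort("mask does not match the layer specification.",
          class = "mcdc_structural_error")
  }
  x1 <- cbind(input, 1)
  if (spec$mask_mode == "weight") {
    pre <- x1 %*% effective_weights(spec, mask)
  } else {
    s <- if (spec$scale_by_inverse_p) 1 / spec$keep_prob else 1
    pre <- x1 %*% spec$theta
    pre <- pre * matrix(mask$z * s, nrow(pre), ncol(pre), byrow = TRUE)
  }
  apply_activation(pre, spec$activation)
}
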