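## Tiny reference architectures.
##
## Deliberately small stand-ins: a two-hidden-layer MLP for vector inputs, a
## three-block convolutional classifier (two 3x3 convolutions per block,
## mean-pooled between blocks), and a one-level encoder-decoder segmenter.
## Every weight-bearing layer is stochastic, so each architecture has a
## DropConnect (weight-mode) and a Dropout (unit-mode) variant with
## identical shapes and parameter counts.

init_theta <- function(d_in_plus_1, d_out, seed) {
  fan_in <- d_in_plus_1 - 1L
  th <- with_local_seed(seed, matrix(rnorm(d_in_plus_1 * d_out,
                                           sd = sqrt(2 / fan_in)),
                                     d_in_plus_1, d_out))
  th[d_in_plus_1, ] <- 0 # biases start at zero
  th
}

#' Build a tiny stochastic multilayer perceptron
#'
#' Fully-connected classifier for low-dimensional feature vectors; every
#' layer (biases included) is Bernoulli-masked.
#'
#' @param d_in Input dimension.
#' @param hidden Integer vector of hidden-layer widths.
#' @param n_classes Number of classes.
#' @param keep_prob Keep probability shared by all layers.
#' @param mask_mode `"weight"` (DropConnect) or `"unit"` (Dropout).
#' @param scale_by_inverse_p Rescale kept entries by `1/keep_prob`.
#' @param init_seed Seed for the weight-initialization stream.
#' @return An `mcdc_network` for classification.
#' @export
tiny_mlp <- function(d_in = 10L, hidden = c(64L, 64L), n_classes = 3L,
                     keep_prob = 0.5, mask_mode = "weight",
                     scale_by_inverse_p = TRUE, init_seed = 0L) {
  widths <- c(d_in, hidden, n_classes)
  nodes <- vector("list", length(widths) - 1L)
  s <- seed_stream(init_seed, "init")
  for (i in seq_len(length(widths) - 1L)) {
    act <- if (i == length(widths) - 1L) "softmax" else "relu"
    nodes[[i]] <- list(
      type = "dense",
      spec = stochastic_layer(
        init_theta(widths[i] + 1L, widths[i + 1L], mix_seed(s, i)),
        keep_prob = keep_prob, mask_mode = mask_mode,
        activation = act, scale_by_inverse_p = scale_by_inverse_p,
        seed_stream = mix_seed(s, 1000L + i)))
  }
  new_network(nodes, input_kind = "dense", task = "classification",
              n_classes = n_classes)
}

conv_node <- function(kernel, in_ch, out_ch, keep_prob, mask_mode,
                      scale_by_inverse_p, activation, seed, tag) {
  list(type = "conv",
       spec = stochastic_layer(
         init_theta(kernel^2 * in_ch + 1L, out_ch, mix_seed(seed, tag)),
         keep_prob = keep_prob, mask_mode = mask_mode,
         kind = "convolution", kernel = kernel, in_channels = in_ch,
         out_channels = out_ch, activation = activation,
         scale_by_inverse_p = scale_by_inverse_p,
         seed_stream = mix_seed(seed, 1000L + tag)))
}

#' Build a small stochastic convolutional classifier
#'
#' Three blocks of two 3x3 convolutions (ReLU) followed by 2x2 mean
#' pooling, then global average pooling and a dense softmax head.  A
#' miniature of the fully-convolutional classifier family, sized for CPU
#' experiments.
#'
#' @param input_shape `c(H, W, channels)`; `H` and `W` must be divisible by 8.
#' @param filters Filter counts of the three blocks.
#' @inheritParams tiny_mlp
#' @return An `mcdc_network` for classification.
#' @export
small_cnn <- function(input_shape = c(16L, 16L, 1L), n_classes = 3L,
                      filters = c(4L, 8L, 8L), keep_prob = 0.5,
                      mask_mode = "weight", scale_by_inverse_p = TRUE,
                      init_seed = 0L) {
  stopifnot(length(input_shape) == 3L, input_shape[1] %% 8L == 0L,
            input_shape[2] %% 8L == 0L, length(filters) == 3L)
  s <- seed_stream(init_seed, "init")
  nodes <- list(); ch <- input_shape[3]; tag <- 0L
  for (b in 1:3) {
    for (j in 1:2) {
      tag <- tag + 1L
      nodes[[length(nodes) + 1L]] <-
        conv_node(3L, ch, filters[b], keep_prob, mask_mode,
                  scale_by_inverse_p, "relu", s, tag)
      ch <- filters[b]
    }
    nodes[[length(nodes) + 1L]] <- list(type = "pool")
  }
  nodes[[length(nodes) + 1L]] <- list(type = "gap")
  nodes[[length(nodes) + 1L]] <- list(
    type = "dense",
    spec = stochastic_layer(
      init_theta(ch + 1L, n_classes, mix_seed(s, 99L)),
      keep_prob = keep_prob, mask_mode = mask_mode, activation = "softmax",
      scale_by_inverse_p = scale_by_inverse_p,
      seed_stream = mix_seed(s, 1099L)))
  new_network(nodes, input_kind = "image", task = "classification",
              n_classes = n_classes, input_shape = input_shape)
}

#' Build a tiny stochastic encoder-decoder segmenter
#'
#' A one-level miniature U-Net: a full-resolution 3x3 convolution, a 2x2
#' mean-pooled 3x3 convolution for context, nearest-neighbour upsampling,
#' a skip connection concatenating the full-resolution features, and a
#' 3x3 softmax convolution producing per-pixel class probabilities.
#'
#' @param input_shape `c(H, W, channels)`; `H` and `W` must be even.
#' @param filters Width of the two hidden convolutions.
#' @inheritParams tiny_mlp
#' @return An `mcdc_network` for segmentation.
#' @export
tiny_segmenter <- function(input_shape = c(24L, 24L, 1L), n_classes = 4L,
                           filters = 8L, keep_prob = 0.5,
                           mask_mode = "weight", scale_by_inverse_p = TRUE,
                           init_seed = 0L) {
  stopifnot(length(input_shape) == 3L, input_shape[1] %% 2L == 0L,
            input_shape[2] %% 2L == 0L)
  s <- seed_stream(init_seed, "init")
  nodes <- list(
    conv_node(3L, input_shape[3], filters, keep_prob, mask_mode,
              scale_by_inverse_p, "relu", s, 1L),
    list(type = "save"),
    list(type = "pool"),
    conv_node(3L, filters, filters, keep_prob, mask_mode,
              scale_by_inverse_p, "relu", s, 2L),
    list(type = "upsample"),
    list(type = "concat"),
    conv_node(3L, 2L * filters, n_classes, keep_prob, mask_mode,
              scale_by_inverse_p, "softmax", s, 3L))
  new_network(nodes, input_kind = "image", task = "segmentation",
              n_classes = n_classes, input_shape = input_shape)
}

#' Construct the suite of tiny reference models
#'
#' Returns the MLP, convolutional classifier, and encoder-decoder segmenter
#' in both masking variants, all under 100k parameters, with DropConnect and
#' Dropout variants sharing identical architectures and parameter counts.
#'
#' @param keep_prob Keep probability for every stochastic layer.
#' @param init_seed Seed for weight initialization.
#' @return A named list of `mcdc_network` objects: `mlp_dropconnect`,
#'   `mlp_dropout`, `cnn_dropconnect`, `cnn_dropout`,
#'   `segmenter_dropconnect`, `segmenter_dropout`.
#' @export
reference_models <- function(keep_prob = 0.5, init_seed = 0L) {
  list(
    mlp_dropconnect = tiny_mlp(keep_prob = keep_prob, mask_mode = "weight",
                               init_seed = init_seed),
    mlp_dropout = tiny_mlp(keep_prob = keep_prob, mask_mode = "unit",
                           init_seed = init_seed),
    cnn_dropconnect = small_cnn(keep_prob = keep_prob, mask_mode = "weight",
                                init_seed = init_seed),
    cnn_dropout = small_cnn(keep_prob = keep_prob, mask_mode = "unit",
                            init_seed = init_seed),
    segmenter_dropconnect = tiny_segmenter(keep_prob = keep_prob,
                                           mask_mode = "weight",
                                           init_seed = init_seed),
    segmenter_dropout = tiny_segmenter(keep_prob = keep_prob,
                                       mask_mode = "unit",
                                       init_seed = init_seed))
}
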