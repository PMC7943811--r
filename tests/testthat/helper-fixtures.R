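# Shared fixtures built in code.

# a fixed valid weight-mode layer: 3 inputs, 2 outputs, bias row last
make_layer <- function(keep_prob = 0.5, mask_mode = "weight",
                       activation = "identity", scale = TRUE,
                       seed_stream = 42L) {
  theta <- matrix(c(1, -2, 0.5, 3, 0.25, -1, 0.1, -0.2), 4, 2)
  stochastic_layer(theta, keep_prob = keep_prob, mask_mode = mask_mode,
                   activation = activation, scale_by_inverse_p = scale,
                   seed_stream = seed_stream)
}

# random T x C matrix of probability rows
random_prob_samples <- function(T, C) {
  g <- matrix(rexp(T * C), T, C)
  g / rowSums(g)
}

# a quickly trained blob classifier shared by engine-level tests
trained_blob_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      task <- generate_blob_task(n = 600, seed = 123)
      model <- tiny_mlp(hidden = c(32L, 32L), init_seed = 123)
      cache <<- list(
        model = train_model(model, task$features[1:300, ],
                            task$labels[1:300],
                            training_config(seed = 123, epochs = 60)),
        task = task)
    }
    cache
  }
})
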