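## SGD trainer for the stochastic networks.
##
## Objective: mean cross-entropy over items (pixels for segmentation) plus
## an L2 penalty lambda * sum_i ||theta_i||^2 over all layers — exactly the
## DropConnect-regularized loss whose minimization corresponds to the
## variational objective of the Bernoulli weight posterior.  A fresh mask
## is drawn for every gradient step.

#' Training configuration
#'
#' @param keep_prob Keep probability `p` recorded with the run (the model's
#'   layers carry their own `p`; this field documents the run and is used by
#'   config-driven model construction).
#' @param weight_decay L2 coefficient `lambda` (>= 0) on all layer weights.
#' @param epochs Number of passes over the training data.
#' @param learning_rate SGD step size.
#' @param batch_size Minibatch size (items; images for segmentation).
#' @param momentum Classical momentum coefficient.
#' @param seed Root seed; split internally into shuffle and mask streams.
#' @return A list of class `"training_config"`.
#' @export
training_config <- function(keep_prob = 0.5, weight_decay = 1e-4,
                            epochs = 300L, learning_rate = 0.02,
                            batch_size = 100L, momentum = 0.9, seed = 0L) {
  if (weight_decay < 0) {
    abort("`weight_decay` must be nonnegative.",
          class = "mcdc_invalid_parameter")
  }
  if (keep_prob <= 0 || keep_prob > 1) {
    abort("`keep_prob` must lie in (0, 1].", class = "mcdc_invalid_parameter")
  }
  structure(list(keep_prob = keep_prob, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed)),
            class = "training_config")
}

slice_input <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE]
  else x[idx, , , , drop = FALSE]
}

one_hot <- function(y, n_classes) {
  oh <- matrix(0, length(y), n_classes)
  oh[cbind(seq_along(y), y + 1L)] <- 1
  oh
}

l2_penalty <- function(model) {
  sum(vapply(model$nodes, function(nd)
    if (!is.null(nd$spec)) sum(nd$spec$theta^2) else 0, numeric(1)))
}

#' Train a stochastic network by SGD
#'
#' Minimizes mean cross-entropy plus `weight_decay * sum(||theta||^2)` with
#' momentum SGD, drawing a fresh Bernoulli mask configuration at every
#' step.  All randomness (shuffling, masks) derives from `config$seed`.
#'
#' @param model An `mcdc_network`.
#' @param x Features: `n x d` matrix (dense models) or `n x H x W x C` array.
#' @param y Integer labels in `[0, n_classes)`: a vector of length `n`
#'   (classification) or an `n x H x W` array of pixel labels
#'   (segmentation).  Pixels equal to `ignore` are excluded from the loss.
#' @param config A [training_config()].
#' @param ignore Ignore label for segmentation targets (default 255).
#' @return The trained model, with `loss_trace` set to a tibble of
#'   `(epoch, loss)` where `loss` includes the L2 penalty.
#' @export
train_model <- function(model, x, y, config = training_config(),
                        ignore = 255L) {
  stopifnot(inherits(model, "mcdc_network"),
            inherits(config, "training_config"))
  n <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  seg <- model$task == "segmentation"
  if (seg && length(dim(y)) != 3L) {
    abort("segmentation targets must be an n x H x W label array.",
          class = "mcdc_structural_error")
  }
  shuffle_seed <- seed_stream(config$seed, "shuffle")
  mask_seed <- seed_stream(config$seed, "masks")
  lam <- config$weight_decay
  lr <- config$learning_rate
  mom <- config$momentum
  sto <- stochastic_node_idx(model)
  vel <- lapply(model$nodes[sto], function(nd) nd$spec$theta * 0)
  names(vel) <- as.character(sto)
  step <- 0L
  trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    # step schedule: x0.1 at 60% and 85% of the epoch budget
    lr <- config$learning_rate *
      if (ep > 0.85 * config$epochs) 0.01
      else if (ep > 0.6 * config$epochs) 0.1 else 1
    ord <- with_local_seed(mix_seed(shuffle_seed, ep), sample.int(n))
    ep_loss <- 0; ep_count <- 0
    for (start in seq(1L, n, config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- slice_input(x, idx)
      step <- step + 1L
      masks <- if (has_stochastic_layers(model))
        draw_network_masks(model, mask_seed, step) else NULL
      fw <- network_forward(model, xb, masks, keep_cache = TRUE)
      probs <- fw$probs
      if (seg) {
        yb <- as.integer(y[idx, , , drop = FALSE])
        keep <- yb != ignore
        oh <- matrix(0, length(yb), model$n_classes)
        oh[cbind(which(keep), yb[keep] + 1L)] <- 1
        m_eff <- sum(keep)
      } else {
        yb <- y[idx]
        oh <- one_hot(yb, model$n_classes)
        keep <- rep(TRUE, length(yb))
        m_eff <- length(yb)
      }
      p_clamp <- pmax(probs, 1e-12)
      batch_ce <- -sum(oh * log(p_clamp)) / m_eff
      if (!is.finite(batch_ce)) {
        abort("training diverged: non-finite loss.",
              class = "mcdc_training_failure",
              trace = tibble(epoch = seq_len(ep - 1L),
                             loss = trace[seq_len(ep - 1L)]))
      }
      d_final <- (probs * as.numeric(keep) - oh) / m_eff
      grads <- network_backward(model, fw$cache, d_final)
      for (i in sto) {
        key <- as.character(i)
        g <- grads[[i]] + 2 * lam * model$nodes[[i]]$spec$theta
        vel[[key]] <- mom * vel[[key]] - lr * g
        model$nodes[[i]]$spec$theta <-
          model$nodes[[i]]$spec$theta + vel[[key]]
      }
      ep_loss <- ep_loss + batch_ce * m_eff
      ep_count <- ep_count + m_eff
    }
    trace[ep] <- ep_loss / ep_count + lam * l2_penalty(model)
    if (!is.finite(trace[ep])) {
      abort("training diverged: non-finite loss.",
            class = "mcdc_training_failure",
            trace = tibble(epoch = seq_len(ep), loss = trace[seq_len(ep)]))
    }
  }
  model$loss_trace <- tibble(epoch = seq_len(config$epochs), loss = trace)
  model$config <- config
  model
}

#' Value of the training objective at the current weights
#'
#' Mean cross-entropy of the deterministic pass plus the L2 penalty; with
#' `weight_decay = 0` this is exactly the mean cross-entropy.
#'
#' @inheritParams train_model
#' @return A single number (nats).
#' @export
training_objective <- function(model, x, y, config = training_config(),
                               ignore = 255L) {
  fw <- network_forward(model, x, NULL)
  probs <- pmax(fw$probs, 1e-12)
  if (model$task == "segmentation") {
    yy <- as.integer(y)
    keep <- yy != ignore
    ce <- -mean(log(probs[cbind(which(keep), yy[keep] + 1L)]))
  } else {
    ce <- -mean(log(probs[cbind(seq_along(y), y + 1L)]))
  }
  ce + config$weight_decay * l2_penalty(model)
}

#' @export
tidy.mcdc_network <- function(x, ...) {
  sto <- stochastic_node_idx(x)
  purrr::map_dfr(sto, function(i) {
    sp <- x$nodes[[i]]$spec
    tibble(layer = i, kind = sp$kind, mask_mode = sp$mask_mode,
           keep_prob = sp$keep_prob, n_weights = length(sp$theta),
           weight_norm = sqrt(sum(sp$theta^2)))
  })
}

#' @export
glance.mcdc_network <- function(x, ...) {
  tibble(task = x$task, n_layers = length(stochastic_node_idx(x)),
         n_parameters = n_parameters(x),
         trained = !is.null(x$loss_trace),
         final_loss = if (is.null(x$loss_trace)) NA_real_
                      else x$loss_trace$loss[nrow(x$loss_trace)])
}
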