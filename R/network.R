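## Tiny stochastic networks.
##
## A network is an ordered list of nodes.  Weight-bearing nodes ("dense",
## "conv") wrap a stochastic_layer; plumbing nodes ("pool", "upsample",
## "gap", and the "save"/"concat" pair forming a skip connection) carry no
## parameters.  Convolutions are evaluated through patch
## extraction (im2col): each output pixel sees a flattened k x k x C_in
## patch, so a convolution is an affine stochastic layer shared across
## pixels, with one mask per forward pass shared across the whole batch.
## Images travel as N x H x W x C arrays, dense activations as N x d
## matrices.

new_network <- function(nodes, input_kind, task, n_classes,
                        input_shape = NULL) {
  structure(
    list(nodes = nodes, input_kind = input_kind, task = task,
         n_classes = n_classes, input_shape = input_shape,
         loss_trace = NULL, config = NULL),
    class = "mcdc_network"
  )
}

#' @export
print.mcdc_network <- function(x, ...) {
  cat(sprintf("<mcdc_network: %s, %d nodes, %d parameters%s>\n",
              x$task, length(x$nodes), n_parameters(x),
              if (is.null(x$loss_trace)) " (untrained)" else " (trained)"))
  invisible(x)
}

#' Number of trainable parameters in a network
#' @param model An `mcdc_network`.
#' @return Integer parameter count (biases included).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$nodes, function(nd)
    if (!is.null(nd$spec)) length(nd$spec$theta) else 0L, numeric(1)))
}

stochastic_node_idx <- function(model) {
  which(vapply(model$nodes, function(nd) !is.null(nd$spec), logical(1)))
}

has_stochastic_layers <- function(model) {
  any(vapply(model$nodes, function(nd)
    !is.null(nd$spec) && nd$spec$keep_prob < 1, logical(1)))
}

## ---- im2col ------------------------------------------------------------

## x: N x H x W x C array -> (N*H*W) x (k*k*C) matrix, zero "same" padding.
## Patch column order: offsets (di, dj) in row-major di-then-dj order, the
## C input channels contiguous within each offset.  theta rows follow the
## same order, with the bias last.
im2col <- function(x, k) {
  d <- dim(x); n <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  pad <- (k - 1L) %/% 2L
  xp <- array(0, c(n, h + 2L * pad, w + 2L * pad, cc))
  xp[, pad + seq_len(h), pad + seq_len(w), ] <- x
  cols <- array(0, c(n, h, w, k * k * cc))
  off <- 0L
  for (di in 0:(k - 1L)) {
    for (dj in 0:(k - 1L)) {
      cols[, , , off + seq_len(cc)] <-
        xp[, di + seq_len(h), dj + seq_len(w), , drop = FALSE]
      off <- off + cc
    }
  }
  dim(cols) <- c(n * h * w, k * k * cc)
  cols
}

## Reverse of im2col: scatter-add patch gradients back onto the input.
col2im <- function(dcols, k, n, h, w, cc) {
  pad <- (k - 1L) %/% 2L
  dim(dcols) <- c(n, h, w, k * k * cc)
  dxp <- array(0, c(n, h + 2L * pad, w + 2L * pad, cc))
  off <- 0L
  for (di in 0:(k - 1L)) {
    for (dj in 0:(k - 1L)) {
      dxp[, di + seq_len(h), dj + seq_len(w), ] <-
        dxp[, di + seq_len(h), dj + seq_len(w), , drop = FALSE] +
        dcols[, , , off + seq_len(cc), drop = FALSE]
      off <- off + cc
    }
  }
  dxp[, pad + seq_len(h), pad + seq_len(w), , drop = FALSE]
}

## ---- node forward / backward -------------------------------------------

pool2 <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[2], 2L); i2 <- seq(2L, d[2], 2L)
  j1 <- seq(1L, d[3], 2L); j2 <- seq(2L, d[3], 2L)
  (x[, i1, j1, , drop = FALSE] + x[, i2, j1, , drop = FALSE] +
   x[, i1, j2, , drop = FALSE] + x[, i2, j2, , drop = FALSE]) / 4
}

pool2_back <- function(dout, d_in) {
  dx <- array(0, d_in)
  i1 <- seq(1L, d_in[2], 2L); i2 <- seq(2L, d_in[2], 2L)
  j1 <- seq(1L, d_in[3], 2L); j2 <- seq(2L, d_in[3], 2L)
  q <- dout / 4
  dx[, i1, j1, ] <- q; dx[, i2, j1, ] <- q
  dx[, i1, j2, ] <- q; dx[, i2, j2, ] <- q
  dx
}

upsample2 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], 2L * d[2], 2L * d[3], d[4]))
  i1 <- seq(1L, 2L * d[2], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * d[3], 2L); j2 <- j1 + 1L
  out[, i1, j1, ] <- x; out[, i2, j1, ] <- x
  out[, i1, j2, ] <- x; out[, i2, j2, ] <- x
  out
}

upsample2_back <- function(dout) {
  d <- dim(dout)
  i1 <- seq(1L, d[2], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[3], 2L); j2 <- j1 + 1L
  dout[, i1, j1, , drop = FALSE] + dout[, i2, j1, , drop = FALSE] +
    dout[, i1, j2, , drop = FALSE] + dout[, i2, j2, , drop = FALSE]
}

## Forward through the whole network.
## masks: list indexed like nodes (NULL entries for plumbing nodes); when
## NULL entirely, the deterministic pass is run (all-ones masks, no 1/p
## rescaling), the baseline "keep everything in place" evaluation.
## Returns list(probs, cache) where probs is (n_items_or_pixels) x C and,
## for image tasks, carries the spatial dims as attribute "spatial".
network_forward <- function(model, x, masks = NULL, keep_cache = FALSE) {
  a <- x
  skip_stack <- list()
  cache <- if (keep_cache) vector("list", length(model$nodes)) else NULL
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    if (!is.null(nd$spec)) {
      spec <- nd$spec
      if (nd$type == "dense") {
        x1 <- cbind(a, 1)
        spatial <- NULL
      } else { # conv
        dd <- dim(a)
        cols <- im2col(a, spec$kernel)
        x1 <- cbind(cols, 1)
        spatial <- dd
      }
      if (is.null(masks)) {
        pre <- x1 %*% spec$theta
        mk <- NULL
      } else {
        mk <- masks[[i]]
        if (spec$mask_mode == "weight") {
          pre <- x1 %*% effective_weights(spec, mk)
        } else {
          s <- if (spec$scale_by_inverse_p) 1 / spec$keep_prob else 1
          pre <- x1 %*% spec$theta
          pre <- pre * matrix(mk$z * s, nrow(pre), ncol(pre), byrow = TRUE)
        }
      }
      out <- apply_activation(pre, spec$activation)
      if (keep_cache) {
        cache[[i]] <- list(x1 = x1, pre = pre, mask = mk, spatial = spatial)
      }
      if (nd$type == "conv") {
        if (i == length(model$nodes) && model$task == "segmentation") {
          attr(out, "spatial") <- c(spatial[1:3])
          a <- out # keep as pixel-row matrix for the loss
        } else {
          dim(out) <- c(spatial[1:3], ncol(spec$theta))
          a <- out
        }
      } else {
        a <- out
      }
    } else if (nd$type == "pool") {
      if (keep_cache) cache[[i]] <- list(d_in = dim(a))
      a <- pool2(a)
    } else if (nd$type == "upsample") {
      a <- upsample2(a)
    } else if (nd$type == "save") {
      skip_stack[[length(skip_stack) + 1L]] <- a
    } else if (nd$type == "concat") {
      saved <- skip_stack[[length(skip_stack)]]
      skip_stack[[length(skip_stack)]] <- NULL
      d_a <- dim(a)
      if (keep_cache) cache[[i]] <- list(n_main = d_a[4])
      joined <- array(0, c(d_a[1:3], d_a[4] + dim(saved)[4]))
      joined[, , , seq_len(d_a[4])] <- a
      joined[, , , d_a[4] + seq_len(dim(saved)[4])] <- saved
      a <- joined
    } else if (nd$type == "gap") {
      dd <- dim(a)
      if (keep_cache) cache[[i]] <- list(d_in = dd)
      a <- apply(a, c(1L, 4L), mean)
    } else {
      abort(paste0("unknown node type: ", nd$type),
            class = "mcdc_structural_error")
    }
  }
  list(probs = a, cache = cache)
}

## Backward pass for the cross-entropy objective.  d_final is the gradient
## at the final pre-activation, (probs - onehot) / n_rows for softmax loss.
## Returns a list of theta gradients indexed like nodes.
network_backward <- function(model, cache, d_final) {
  grads <- vector("list", length(model$nodes))
  pending_skip <- list()
  d <- d_final
  for (i in rev(seq_along(model$nodes))) {
    nd <- model$nodes[[i]]
    if (!is.null(nd$spec)) {
      spec <- nd$spec
      cc <- cache[[i]]
      if (!is.matrix(d)) { # image-shaped gradient arriving at a conv node
        dd <- dim(d)
        dim(d) <- c(dd[1] * dd[2] * dd[3], dd[4])
      }
      d_pre <- switch(spec$activation,
                      softmax = d, # caller supplied the softmax-CE shortcut
                      identity = d,
                      relu = d * (cc$pre > 0))
      if (spec$mask_mode == "weight") {
        if (is.null(cc$mask)) {
          w_eff <- spec$theta
          grads[[i]] <- crossprod(cc$x1, d_pre)
        } else {
          w_eff <- effective_weights(spec, cc$mask)
          s <- if (spec$scale_by_inverse_p) 1 / spec$keep_prob else 1
          grads[[i]] <- crossprod(cc$x1, d_pre) * cc$mask$z * s
        }
        d_in_full <- d_pre %*% t(w_eff)
      } else {
        if (is.null(cc$mask)) {
          d_pre0 <- d_pre
        } else {
          s <- if (spec$scale_by_inverse_p) 1 / spec$keep_prob else 1
          d_pre0 <- d_pre * matrix(cc$mask$z * s, nrow(d_pre), ncol(d_pre),
                                   byrow = TRUE)
        }
        grads[[i]] <- crossprod(cc$x1, d_pre0)
        d_in_full <- d_pre0 %*% t(spec$theta)
      }
      d_cols <- d_in_full[, -ncol(d_in_full), drop = FALSE]
      if (nd$type == "conv") {
        sp <- cc$spatial
        d <- col2im(d_cols, spec$kernel, sp[1], sp[2], sp[3], sp[4])
      } else {
        d <- d_cols
      }
    } else if (nd$type == "pool") {
      d <- pool2_back(d, cache[[i]]$d_in)
    } else if (nd$type == "upsample") {
      d <- upsample2_back(d)
    } else if (nd$type == "concat") {
      nm <- cache[[i]]$n_main
      pending_skip[[length(pending_skip) + 1L]] <-
        d[, , , (nm + 1L):dim(d)[4], drop = FALSE]
      d <- d[, , , seq_len(nm), drop = FALSE]
    } else if (nd$type == "save") {
      d <- d + pending_skip[[length(pending_skip)]]
      pending_skip[[length(pending_skip)]] <- NULL
    } else if (nd$type == "gap") {
      dd <- cache[[i]]$d_in
      dx <- array(0, dd)
      per <- d / (dd[2] * dd[3])
      for (ch in seq_len(dd[4])) dx[, , , ch] <- rep(per[, ch], dd[2] * dd[3])
      d <- dx
    }
  }
  grads
}

## Draw one mask per stochastic node for pass `draw_index`, with per-node
## streams derived from `seed` so independent runs are reproducible and a
## run of T passes can be continued via `draw_index` offsets.
draw_network_masks <- function(model, seed, draw_index) {
  masks <- vector("list", length(model$nodes))
  for (i in stochastic_node_idx(model)) {
    spec <- model$nodes[[i]]$spec
    spec$seed_stream <- mix_seed(seed, i)
    masks[[i]] <- sample_mask(spec, draw_index)
  }
  masks
}
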