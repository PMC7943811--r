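## Synthetic study tasks.
##
## The classification task is a mixture of isotropic Gaussian blobs in a
## moderately high-dimensional space (10-D by default), with the mean
## separation chosen so classes overlap enough that a trained model
## misclassifies 10-20% of items — misclassifications are the raw material
## of every uncertainty metric here.  The dimension matters: in high
## dimension the between-class overlap region is sparsely populated, so
## posterior draws disagree exactly where errors occur, the regime in
## which epistemic uncertainty flags misclassification.  Out-of-
## distribution probes emulate domain-shifted inputs (e.g. distorted
## digits) by lying far outside every class.  The segmentation task renders intensity-coded
## shapes on a noisy background, including one rare class under 2% of
## pixels, mimicking the frequent-background / rare-small-class structure
## of street-scene and organ data.

#' Generate the overlapping-blobs classification task
#'
#' Balanced Gaussian blobs with equal isotropic covariance.  With
#' `dim >= n_classes` the means sit on orthogonal axes at distance
#' `radius` from the origin (pairwise separation `radius * sqrt(2)`);
#' with `dim = 2` they sit on a circle of that radius.  Defaults
#' (`dim = 10`, `radius = 1.96`, `sigma = 1`) put the Bayes error of the
#' three-class mixture near 14%.  Out-of-distribution probes are placed
#' beyond the 99th in-distribution distance percentile from every class
#' mean, scaled outward until that holds by construction.
#'
#' @param n Total number of labelled points (balanced to +-1 per class).
#' @param n_classes Number of classes.
#' @param dim Feature-space dimension (2, or at least `n_classes`).
#' @param radius Distance of every class mean from the origin.
#' @param sigma Isotropic standard deviation of every class (> 0).
#' @param n_ood Number of out-of-distribution probe points.
#' @param ood_offset Initial distance multiplier for the probes.
#' @param seed Seed for the data stream.
#' @return A list of class `"blob_task"`: `features` (`n x dim` matrix),
#'   `labels` (integers in `[0, n_classes)`), `ood_probes` (matrix),
#'   `means`, and the generating parameters.
#' @export
generate_blob_task <- function(n = 2000L, n_classes = 3L, dim = 10L,
                               radius = 1.96, sigma = 1, n_ood = 60L,
                               ood_offset = 4, seed = 0L) {
  if (sigma <= 0) {
    abort("`sigma` must be positive (degenerate covariance).",
          class = "mcdc_invalid_parameter")
  }
  if (dim != 2L && dim < n_classes) {
    abort("`dim` must be 2 or at least `n_classes`.",
          class = "mcdc_invalid_parameter")
  }
  if (dim == 2L) {
    ang <- 2 * pi * (seq_len(n_classes) - 1L) / n_classes
    means <- cbind(cos(ang), sin(ang)) * radius
  } else {
    means <- matrix(0, n_classes, dim)
    means[cbind(seq_len(n_classes), seq_len(n_classes))] <- radius
  }
  per <- rep(n %/% n_classes, n_classes)
  extra <- n %% n_classes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  labels <- rep(seq_len(n_classes) - 1L, times = per)
  ds <- seed_stream(seed, "data")
  out <- with_local_seed(ds, {
    x <- means[labels + 1L, , drop = FALSE] +
      matrix(rnorm(dim * n, sd = sigma), n, dim)
    ord <- sample.int(n)
    dirs <- matrix(rnorm(dim * n_ood), n_ood, dim)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    list(x = x, ord = ord, dirs = dirs)
  })
  x <- out$x[out$ord, , drop = FALSE]
  labels <- labels[out$ord]
  # 99th percentile of in-distribution distance from each class mean
  q99 <- vapply(seq_len(n_classes), function(j)
    quantile(sqrt(rowSums(sweep(x, 2L, means[j, ])^2)), 0.99,
             names = FALSE), numeric(1))
  r <- ood_offset * max(radius, 1)
  repeat {
    probes <- out$dirs * r
    d <- vapply(seq_len(n_classes), function(j)
      min(sqrt(rowSums(sweep(probes, 2L, means[j, ])^2)) - q99[j]),
      numeric(1))
    if (all(d > 0)) break
    r <- r * 1.25
  }
  structure(list(features = x, labels = labels, ood_probes = probes,
                 means = means, n_classes = n_classes, dim = dim,
                 radius = radius,
                 sigma = sigma, ood_offset = ood_offset, seed = seed),
            class = "blob_task")
}

#' Generate toy segmentation scenes
#'
#' Single-channel images of intensity-coded shapes on a background: a
#' rectangle (class 1), a disk (class 2), and a rare small square
#' (class 3) occupying under 2% of the pixels.  Class intensities are
#' separated by `contrast` and corrupted by Gaussian pixel noise; shape
#' positions jitter between images, so class boundaries are ambiguous at
#' the noise level.
#'
#' @param n_images Number of scenes.
#' @param size Square image side length (must fit the shape inventory).
#' @param noise_sd Pixel noise standard deviation.
#' @param contrast Intensity separation between consecutive classes.
#' @param seed Seed for the data stream.
#' @return A list of class `"toy_seg_task"`: `images`
#'   (`n x size x size x 1` array), `labels` (`n x size x size` integer
#'   array with classes 0-3), and the generating parameters.
#' @export
generate_toy_segmentation <- function(n_images = 6L, size = 24L,
                                      noise_sd = 0.4, contrast = 0.8,
                                      seed = 0L) {
  rect_w <- max(6L, size %/% 3L); rect_h <- max(4L, size %/% 4L)
  disk_r <- max(2L, size %/% 8L)
  rare_side <- 2L
  if (rect_w >= size || rect_h >= size || 2L * disk_r + 1L >= size ||
      rare_side >= size) {
    abort("shape inventory does not fit in the image.",
          class = "mcdc_invalid_parameter")
  }
  ds <- seed_stream(seed, "data")
  labels <- array(0L, c(n_images, size, size))
  images <- array(0, c(n_images, size, size, 1L))
  with_local_seed(ds, {
    for (i in seq_len(n_images)) {
      lab <- matrix(0L, size, size)
      # rectangle, jittered position
      r0 <- sample.int(size - rect_h, 1L)
      c0 <- sample.int(size %/% 2L, 1L)
      lab[r0 + seq_len(rect_h), c0 + seq_len(rect_w)] <- 1L
      # disk in the right half
      cy <- sample((disk_r + 1L):(size - disk_r), 1L)
      cx <- sample((size %/% 2L + disk_r):(size - disk_r), 1L)
      for (rr in (cy - disk_r):(cy + disk_r)) {
        for (cc in (cx - disk_r):(cx + disk_r)) {
          if ((rr - cy)^2 + (cc - cx)^2 <= disk_r^2) lab[rr, cc] <- 2L
        }
      }
      # rare small square (under 2% of pixels by construction)
      rr0 <- sample.int(size - rare_side, 1L)
      cc0 <- sample.int(size - rare_side, 1L)
      lab[rr0 + seq_len(rare_side), cc0 + seq_len(rare_side)] <- 3L
      img <- contrast * lab + matrix(rnorm(size * size, sd = noise_sd),
                                     size, size)
      labels[i, , ] <- lab
      images[i, , , 1L] <- img
    }
  })
  structure(list(images = images, labels = labels, n_images = n_images,
                 size = size, noise_sd = noise_sd, contrast = contrast,
                 n_classes = 4L, rare_class = 3L, seed = seed),
            class = "toy_seg_task")
}
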