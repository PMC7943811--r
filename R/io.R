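## File plumbing: MC sample sets and score tables as plain CSV, run
## manifests as YAML sidecars carrying the seed, T and config hash.

#' Write an MC prediction set to CSV with a manifest sidecar
#'
#' Samples are stored in long format (`t`, `item`, `class`, `p`); the
#' sidecar `<path>.manifest.yaml` records dimensions, seed, draw offset,
#' spatial shape and an optional config hash, so evaluation-only workflows
#' can reload and validate the samples without the model.
#'
#' @param mcset An `mc_prediction_set`.
#' @param path CSV output path.
#' @param config Optional `run_config` whose hash is recorded.
#' @return `path`, invisibly.
#' @export
write_mc_samples <- function(mcset, path, config = NULL) {
  stopifnot(inherits(mcset, "mc_prediction_set"))
  d <- dim(mcset$samples)
  df <- data.frame(
    t = rep(seq_len(d[1]), times = d[2] * d[3]),
    item = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    class = rep(seq_len(d[3]) - 1L, each = d[1] * d[2]),
    p = as.vector(mcset$samples))
  utils::write.csv(df, path, row.names = FALSE)
  manifest <- list(T = d[1], n_items = d[2], n_classes = d[3],
                   seed = mcset$seed, draw_offset = mcset$draw_offset,
                   spatial = if (is.null(mcset$spatial)) NULL
                             else as.integer(mcset$spatial),
                   config_hash = if (is.null(config)) NULL
                                 else config_hash(config))
  yaml::write_yaml(manifest[!vapply(manifest, is.null, logical(1))],
                   paste0(path, ".manifest.yaml"))
  invisible(path)
}

#' Read an MC prediction set written by [write_mc_samples()]
#'
#' Row sums of every sample are validated to be 1 within `1e-6` on load.
#'
#' @param path CSV path.
#' @return An `mc_prediction_set`.
#' @export
read_mc_samples <- function(path) {
  df <- utils::read.csv(path)
  man_path <- paste0(path, ".manifest.yaml")
  man <- if (file.exists(man_path)) yaml::read_yaml(man_path) else NULL
  tn <- max(df$t); n <- max(df$item); cc <- max(df$class) + 1L
  samples <- array(NA_real_, c(tn, n, cc))
  samples[cbind(df$t, df$item, df$class + 1L)] <- df$p
  sums <- apply(samples, c(1L, 2L), sum)
  if (any(abs(sums - 1) > 1e-6)) {
    abort("loaded samples are not probability vectors (row sums differ from 1).",
          class = "mcdc_invalid_input")
  }
  new_mc_prediction_set(samples,
                        spatial = man$spatial,
                        seed = man$seed %||% NA_integer_,
                        draw_offset = man$draw_offset %||% 0L)
}

#' Verify a manifest against a configuration
#'
#' Recomputes the config hash and compares it to the one recorded in a
#' manifest sidecar.
#'
#' @param manifest_path Path to a `.manifest.yaml` file.
#' @param config The `run_config` to verify against.
#' @return `TRUE` if the hashes match, else `FALSE`.
#' @export
verify_manifest <- function(manifest_path, config) {
  man <- yaml::read_yaml(manifest_path)
  identical(man$config_hash, config_hash(config))
}
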