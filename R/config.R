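## Run configuration.
##
## YAML-backed config with a fixed schema: unknown keys are rejected with
## the offending field path, and a config round-trips through write/read
## losslessly.  CLI flags override file values (flag > file > default).

config_schema <- list(
  task = NULL,
  seed = NULL,
  model = c("type", "d_in", "hidden", "n_classes", "keep_prob",
            "mask_mode", "scale_by_inverse_p", "input_size", "filters"),
  data = c("n", "n_classes", "dim", "radius", "sigma", "n_ood",
           "ood_offset", "n_images", "size", "noise_sd", "contrast"),
  training = c("weight_decay", "epochs", "learning_rate", "batch_size",
               "momentum"),
  mc = c("T"),
  evaluation = c("n_thresholds", "auc_fill"),
  referral = c("n_fractions", "repetitions"),
  paths = c("out_dir")
)

default_run_config <- function() {
  list(task = "classification", seed = 0L,
       model = list(type = "mlp", d_in = 10L, hidden = c(64L, 64L),
                    n_classes = 3L, keep_prob = 0.5, mask_mode = "weight",
                    scale_by_inverse_p = TRUE),
       data = list(n = 2000L, n_classes = 3L, dim = 10L, radius = 1.96,
                   sigma = 1,
                   n_ood = 60L, ood_offset = 4),
       training = list(weight_decay = 1e-4, epochs = 300L,
                       learning_rate = 0.02, batch_size = 100L,
                       momentum = 0.9),
       mc = list(T = 100L),
       evaluation = list(n_thresholds = 101L, auc_fill = 1),
       referral = list(n_fractions = 20L, repetitions = 20L),
       paths = list(out_dir = "."))
}

validate_run_config <- function(cfg) {
  bad_top <- setdiff(names(cfg), names(config_schema))
  if (length(bad_top) > 0) {
    abort(paste0("unknown config field: ", bad_top[1]),
          class = "mcdc_config_error")
  }
  for (blk in names(cfg)) {
    allowed <- config_schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[blk]]), allowed)
    if (length(bad) > 0) {
      abort(paste0("unknown config field: ", blk, ".", bad[1]),
            class = "mcdc_config_error")
    }
  }
  for (req in c("task", "seed")) {
    if (is.null(cfg[[req]])) {
      abort(paste0("missing required config field: ", req),
            class = "mcdc_config_error")
    }
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Missing blocks are filled from the package defaults; unknown keys are
#' rejected with the offending field path.
#'
#' @param path YAML file path.
#' @return A validated named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  base <- default_run_config()
  for (blk in names(cfg)) {
    if (is.list(base[[blk]]) && is.list(cfg[[blk]])) {
      for (k in names(cfg[[blk]])) base[[blk]][[k]] <- cfg[[blk]][[k]]
    } else {
      base[[blk]] <- cfg[[blk]]
    }
  }
  structure(base, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config` (or plain named list).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stable content hash of a configuration
#'
#' 32-bit FNV-1a hash of the canonical YAML serialization; recorded in run
#' manifests so artifacts can be verified against the config that produced
#' them.
#'
#' @param config A `run_config` or named list.
#' @return An 8-character hex string.
#' @export
config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

build_model_from_config <- function(cfg) {
  m <- cfg$model
  switch(m$type,
    mlp = tiny_mlp(d_in = m$d_in, hidden = unlist(m$hidden),
                   n_classes = m$n_classes, keep_prob = m$keep_prob,
                   mask_mode = m$mask_mode,
                   scale_by_inverse_p = m$scale_by_inverse_p %||% TRUE,
                   init_seed = cfg$seed),
    cnn = small_cnn(input_shape = c(m$input_size, m$input_size, 1L),
                    n_classes = m$n_classes,
                    filters = unlist(m$filters %||% c(4L, 8L, 8L)),
                    keep_prob = m$keep_prob, mask_mode = m$mask_mode,
                    init_seed = cfg$seed),
    segmenter = tiny_segmenter(
      input_shape = c(m$input_size, m$input_size, 1L),
      n_classes = m$n_classes, keep_prob = m$keep_prob,
      mask_mode = m$mask_mode, init_seed = cfg$seed),
    abort(paste0("unknown model type: ", m$type),
          class = "mcdc_config_error"))
}
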