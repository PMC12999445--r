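# Experiment configuration: nested blocks {data, env, agents, fusion, train,
# eval} serialised as YAML. Unknown keys are rejected with their key path.

#' Default experiment configuration
#'
#' @return Nested configuration list with blocks `data`, `env`, `agents`,
#'   `fusion`, `train` and `eval`.
#' @export
default_config <- function() {
  list(
    data = list(source = "synthetic", n_per_class = 50L, k_classes = 2L,
                sequences = FALSE, seed = 42L, manifest = NULL),
    env = list(image_size = 224L, patch_size = 64L, stride = 32L,
               t_max = 16L, gamma = 0.99, sinusoidal_pos = FALSE),
    agents = list(spatial_backbone = "small-cnn", temporal_backbone = "gru",
                  d_emb = 32L, d_hidden = 32L, seed = 1L),
    fusion = list(rule = "vdn-sum"),
    train = list(episodes = 500L, gamma = 0.99, tau = 1.0,
                 epsilon_start = 1.0, epsilon_end = 0.05, epsilon_frac = 0.6,
                 batch_size = 32L, target_sync = 200L, lr = 1e-4,
                 replay_capacity = 10000L, grad_steps_per_episode = 1L,
                 seed = 7L),
    eval = list(k_folds = 5L, positive_class = 2L, dca_prevalence = 0.2,
                dca_threshold_min = 0.01, dca_threshold_max = 0.30,
                dca_threshold_step = 0.01)
  )
}

# recursively overlay user values on the defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      stop_domain("unknown configuration key: ", here)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop_domain("configuration block expected at: ", here)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      # single-bracket assignment keeps keys whose new value is NULL
      defaults[key] <- list(user[[key]])
    }
  }
  defaults
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML file, overlays it on [default_config()] and validates;
#' unknown keys raise an error naming the key path.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @param overrides optional named list overlaid after the file.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_domain("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#' @param config configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(cfg) {
  if (!cfg$data$source %in% c("synthetic", "manifest")) {
    stop_domain("data.source must be 'synthetic' or 'manifest'")
  }
  if (cfg$data$source == "manifest" && is.null(cfg$data$manifest)) {
    stop_domain("data.manifest is required when data.source = 'manifest'")
  }
  if (cfg$data$k_classes < 2) stop_domain("data.k_classes must be >= 2")
  build_grid(cfg$env$image_size, cfg$env$patch_size, cfg$env$stride)
  if (!cfg$fusion$rule %in% FUSION_KINDS) {
    stop_domain("fusion.rule must be one of ",
                paste(FUSION_KINDS, collapse = ", "))
  }
  make_backbone(cfg$agents$spatial_backbone)
  make_backbone(cfg$agents$temporal_backbone)
  do.call(train_config, cfg$train)
  if (cfg$eval$k_folds < 2) stop_domain("eval.k_folds must be >= 2")
  invisible(cfg)
}

config_grid <- function(cfg) {
  build_grid(cfg$env$image_size, cfg$env$patch_size, cfg$env$stride)
}

config_dca_thresholds <- function(cfg) {
  seq(cfg$eval$dca_threshold_min, cfg$eval$dca_threshold_max,
      by = cfg$eval$dca_threshold_step)
}
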