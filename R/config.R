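# Run configuration: one YAML file drives every stage. A single top-level
# seed fans out to per-module streams by fixed offsets.

config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "runs/default",
    version = "1.0",
    data = list(tile = 256L, n_stained = 400L, n_unstained = 80L,
                density = 12, n_classes = 4L, noise_sd = 0.02),
    augment = list(jitter_px = 8L, p_hflip = 0.5, p_vflip = 0.5,
                   rot_max_deg = 10, zoom = 1.1,
                   elastic_alpha = 1.5, elastic_sigma = 8),
    network = list(base_width = 64L, feature_width = 512L, in_channels = 3L,
                   out_channels = 3L, n_blocks = 6L, unet_depth = 8L),
    loss = list(lambda_gp = 10, lambda_pix = 100, lambda_fm = 10,
                lambda_cyc = 10, lambda_dc = 1, gamma_r1 = 10,
                adv_variant = "wgan_gp"),
    train = list(stage = 1L, steps = 100L, batch = 2L, lr = 2e-4,
                 beta1 = 0.5, beta2 = 0.9, critic_steps = 1L,
                 buffer_capacity = 256L)
  )
}

merge_validate <- function(user, defaults, path = character(0)) {
  if (!is.list(user))
    vs_stop(paste0("config section '", paste(path, collapse = "."),
                   "' must be a mapping"), "vs_validation_error")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    vs_stop(paste0("unknown config key: ",
                   paste(c(path, unknown[1]), collapse = ".")),
            "vs_validation_error")
  out <- defaults
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      out[[k]] <- merge_validate(user[[k]], defaults[[k]], c(path, k))
    } else {
      v <- user[[k]]
      if (is.numeric(defaults[[k]]) && !is.numeric(v))
        vs_stop(paste0("config key ", paste(c(path, k), collapse = "."),
                       " must be numeric"), "vs_validation_error")
      if (is.character(defaults[[k]]) && !is.character(v))
        vs_stop(paste0("config key ", paste(c(path, k), collapse = "."),
                       " must be a string"), "vs_validation_error")
      out[[k]] <- if (is.integer(defaults[[k]])) as.integer(v) else v
    }
  }
  out
}

#' Load and validate a run configuration
#'
#' Reads a YAML config, rejects unknown keys (naming the offending key
#' path), type-checks values against the defaults and fills every missing
#' key with its documented default.
#'
#' @param path YAML file path.
#' @return A validated config list of class `vs_run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    vs_stop(paste0("config file not found: ", path), "vs_io_error")
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_validate(user, config_defaults())
  structure(cfg, class = "vs_run_config")
}

#' Write a configuration to YAML
#' @param cfg A config list (validated or partial).
#' @param path Output YAML path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' The fully defaulted configuration
#' @return The default `vs_run_config`.
#' @export
default_config <- function() structure(config_defaults(), class = "vs_run_config")
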