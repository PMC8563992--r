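config_defaults <- function() {
  list(
    detection = unclass(detection_params()),
    metrics = list(match_radius = 25, round_digits = 2, gsd = 0.2),
    simulation = list(mode = "perturb", levels = NULL, replicates = 100,
                      base_seed = 1, rows = 15, cols = 15, pd = 30, rd = 20),
    scene = list(width = 320, height = 320, gsd = 0.2, blades_per_cluster = 7,
                 blade_length_px = 18, blade_width_px = 3,
                 bubble_density = 2e-5, speckle_density = 5e-4),
    output_dir = ".",
    seed = NULL,
    log_level = "info"
  )
}

#' Load and validate a run configuration
#'
#' Merges a YAML file (and/or an override list) over the package defaults.
#' Unknown keys — at the top level or inside any section — are rejected, so
#' typos fail loudly instead of silently using a default. The default
#' `metrics$match_radius` of 25 px is half the nominal plant spacing
#' (30 cm at 0.2 cm/px = 150 px would be a whole spacing; scenes rendered
#' at smaller spacings use the same half-spacing logic).
#'
#' @param path Optional YAML file.
#' @param overrides Optional named list merged last.
#' @return A validated `rice_config` list.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  merge_section <- function(base, new, where) {
    if (is.null(new)) return(base)
    if (!is.list(new)) {
      abort(sprintf("Config section '%s' must be a mapping.", where),
            class = "ricevor_validation_error")
    }
    unknown <- setdiff(names(new), names(base))
    if (length(unknown)) {
      abort(sprintf("Unknown config key(s) in '%s': %s", where,
                    paste(unknown, collapse = ", ")),
            class = "ricevor_validation_error")
    }
    modifyList(base, new)
  }
  apply_layer <- function(cfg, layer, label) {
    if (is.null(layer)) return(cfg)
    unknown <- setdiff(names(layer), names(cfg))
    if (length(unknown)) {
      abort(sprintf("Unknown top-level config key(s) in %s: %s", label,
                    paste(unknown, collapse = ", ")),
            class = "ricevor_validation_error")
    }
    for (key in names(layer)) {
      cfg[[key]] <- if (is.list(cfg[[key]]) && key != "simulation") {
        merge_section(cfg[[key]], layer[[key]], key)
      } else if (key == "simulation") {
        merge_section(cfg[[key]], layer[[key]], key)
      } else {
        layer[[key]]
      }
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("Config file not found: %s", path), class = "ricevor_io_error")
    }
    cfg <- apply_layer(cfg, yaml::read_yaml(path), path)
  }
  cfg <- apply_layer(cfg, overrides, "overrides")
  # re-validate the detection block through the typed constructor
  cfg$detection <- unclass(do.call(detection_params, cfg$detection))
  structure(cfg, class = "rice_config")
}

#' Write the resolved configuration next to run outputs
#'
#' @param config A [run_config()] list.
#' @param dir Output directory (created if needed).
#' @return The YAML path, invisibly.
#' @export
write_resolved_config <- function(config, dir) {
  stopifnot(inherits(config, "rice_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "resolved_config.yaml")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
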