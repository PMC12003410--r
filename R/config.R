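#' Default run configuration
#'
#' Consolidates every tunable parameter of the pipeline with its default:
#' fascicle filter bounds 75/6000 px and eccentricity 0.90, thickness
#' sampling at the 20/50/80% aperture positions, limits-of-agreement
#' multiplier 1.96, adaptive-threshold sensitivity 0.5, aponeurosis
#' small-region cutoff 100 px, and the 10.2 px/mm default calibration.
#' Configurations round-trip unchanged through [write_config()] /
#' [read_config()].
#'
#' @return Nested named list of class `musclearch_config`.
#' @export
default_config <- function() {
  structure(list(
    image = list(
      calibration_default = 10.2
    ),
    aponeurosis = list(
      threshold_method = "otsu",
      min_area_px = 100,
      closing_radius = 3
    ),
    fascicle = list(
      area_min_px = 75,
      area_max_px = 6000,
      eccentricity_min = 0.90,
      adaptive_sensitivity = 0.5,
      window_divisor = 8,
      max_extrapolation_widths = 4
    ),
    thickness = list(
      positions = c(0.2, 0.5, 0.8),
      mode = "vertical"
    ),
    reliability = list(
      loa_multiplier = 1.96,
      conf_level = 0.95
    ),
    seed = 1L
  ), class = "musclearch_config")
}

#' Read / write a YAML configuration
#'
#' Unknown keys are errors (protects against silently ignored typos in
#' threshold names); missing keys take their defaults.
#'
#' @param path YAML file path.
#' @param cfg Configuration list to write.
#' @return `read_config()`: a validated `musclearch_config`;
#'   `write_config()`: the path, invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  class(cfg) <- "musclearch_config"
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

merge_config <- function(base, user, prefix = "") {
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]],
                                prefix = paste0(prefix, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}
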