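#' Load and validate a run configuration
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration with the
#' blocks `protocol`, `geometry`, `population`, `noise`, `perfusion`
#' (`msm`/`fpa` subsections), `sweep`, `dose`, `output` and `seed`. The
#' schema is checked before anything runs: unknown keys at any validated
#' level are rejected with an error naming them. Missing blocks fall back to
#' package defaults.
#'
#' @param path configuration file path.
#' @return a validated named list (class `ctperf_config`).
#' @seealso [config_objects()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop(sprintf("unsupported config format '.%s' (use yaml or json)", ext)))
  validate_config(cfg)
}

config_schema <- list(
  protocol = c("n_frames", "frame_spacing", "start_delay",
               "injection_volume", "injection_rate", "trigger_threshold"),
  geometry = c("image_shape"),
  population = c("parenchyma", "carcinoma", "bf_floor", "mtt", "aif"),
  noise = c("sigma"),
  perfusion = c("msm", "fpa"),
  sweep = c("d_values", "r_threshold_mean", "r_threshold_voxel"),
  dose = c("dlp_dynamic", "conversion_k", "acq_time",
           "monitor_lead", "fpa_last_delay"),
  output = c("dir"),
  seed = NULL,
  log_level = NULL
)

#' Validate a configuration list against the package schema
#'
#' @param cfg named list (parsed YAML/JSON).
#' @return `cfg` with class `ctperf_config`, or an error naming offending keys.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a mapping (named list)")
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  for (block in intersect(names(cfg), names(config_schema))) {
    allowed <- config_schema[[block]]
    if (is.null(allowed) || !is.list(cfg[[block]])) next
    bad <- setdiff(names(cfg[[block]]), allowed)
    if (length(bad)) {
      stop(sprintf("unknown keys in '%s' block: %s", block,
                   paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(cfg$perfusion)) {
    for (sub in intersect(names(cfg$perfusion), c("msm", "fpa"))) {
      allowed <- switch(sub,
                        msm = c("slope_window", "rho_t", "aif_reference", "fit"),
                        fpa = c("variant", "trigger_threshold", "t_i",
                                "dispersion_d", "aif_reference"))
      bad <- setdiff(names(cfg$perfusion[[sub]]), allowed)
      if (length(bad)) {
        stop(sprintf("unknown keys in 'perfusion$%s': %s", sub,
                     paste(bad, collapse = ", ")))
      }
    }
  }
  structure(cfg, class = "ctperf_config")
}

# merge user values over defaults of a constructor-style function
call_with <- function(fun, args) do.call(fun, args[!vapply(args, is.null, logical(1))])

#' Materialize configuration blocks into package objects
#'
#' @param cfg a `ctperf_config` from [load_config()].
#' @return list with `protocol`, `geometry`, `population`, `noise_sigma`,
#'   `msm`, `fpa`, `sweep`, `dose`, `seed`, `output_dir`.
#' @export
config_objects <- function(cfg) {
  stopifnot(inherits(cfg, "ctperf_config"))
  protocol <- call_with(acquisition_protocol, as.list(cfg$protocol))
  geometry <- if (!is.null(cfg$geometry$image_shape)) {
    phantom_geometry(image_shape = unlist(cfg$geometry$image_shape))
  } else {
    phantom_geometry()
  }
  population <- call_with(default_population, as.list(cfg$population))
  msm <- call_with(msm_config, as.list(cfg$perfusion$msm))
  fpa_args <- as.list(cfg$perfusion$fpa)
  if (is.null(fpa_args$t_i)) fpa_args$t_i <- protocol$t_i
  if (is.null(fpa_args$trigger_threshold)) {
    fpa_args$trigger_threshold <- protocol$trigger_threshold
  }
  fpa <- call_with(fpa_config, fpa_args)
  sweep_args <- as.list(cfg$sweep)
  if (!is.null(sweep_args$d_values)) {
    sweep_args$d_values <- unlist(sweep_args$d_values)
  }
  sweep <- call_with(sweep_config, sweep_args)
  list(
    protocol = protocol, geometry = geometry, population = population,
    noise_sigma = if (!is.null(cfg$noise$sigma)) cfg$noise$sigma else 5,
    msm = msm, fpa = fpa, sweep = sweep,
    dose = cfg$dose,
    seed = if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L,
    output_dir = if (!is.null(cfg$output$dir)) cfg$output$dir else "results"
  )
}
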