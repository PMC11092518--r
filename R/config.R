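#' Load the packaged model configuration
#'
#' Reads the YAML configuration shipped with the package (or a user-supplied
#' file with the same structure). The configuration holds the per-population
#' Izhikevich excitability tables, the per-connection Tsodyks-Markram synapse
#' tables, receptor-channel conventions, arena geometry and the scale presets
#' (`small`, `intermediate`, `large`, plus the reduced `desk` bench preset).
#'
#' @param path Optional path to a YAML configuration file. Defaults to the
#'   configuration shipped in `inst/extdata/model_config.yaml`.
#' @return A named list with components `populations`, `connections`,
#'   `receptors`, `arena`, `delay_ms`, `presets` and `trajectory`.
#' @export
#' @examples
#' cfg <- load_model_config()
#' names(cfg$populations)
load_model_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "model_config.yaml", package = "gridcan")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("model configuration file not found: ", path)
  }
  cfg <- yaml::read_yaml(path)
  required <- c("populations", "connections", "receptors", "arena",
                "delay_ms", "presets", "trajectory")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("configuration is missing sections: ", paste(missing, collapse = ", "))
  }
  cfg
}

#' Retrieve a scale preset from a configuration
#'
#' @param cfg Configuration list from [load_model_config()].
#' @param name Preset name (e.g. `"intermediate"`, `"desk"`).
#' @return The preset as a named list, with a `name` field attached.
#' @export
get_preset <- function(cfg, name) {
  if (!name %in% names(cfg$presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(cfg$presets), collapse = ", "))
  }
  preset <- cfg$presets[[name]]
  preset$name <- name
  if (preset$annulus_inner >= preset$annulus_outer) {
    stop("preset '", name, "' has a degenerate center-surround annulus ",
         "(inner radius must be smaller than outer radius)")
  }
  preset
}

#' Izhikevich parameters for a named population
#'
#' Looks up the nine-parameter excitability row of one population from the
#' configuration tables and returns it as an [izh_params()] object.
#'
#' @param cfg Configuration list from [load_model_config()].
#' @param name Exact population name, e.g. `"MEC LII Stellate"`.
#' @return An `izh_params` object.
#' @export
population_params <- function(cfg, name) {
  if (!name %in% names(cfg$populations)) {
    stop("unknown population '", name, "'; available: ",
         paste(names(cfg$populations), collapse = ", "))
  }
  p <- cfg$populations[[name]]
  izh_params(C = p$C, k = p$k, Vr = p$Vr, Vt = p$Vt, a = p$a, b = p$b,
             Vpeak = p$Vpeak, Vreset = p$Vreset, d = p$d)
}

#' Tsodyks-Markram parameters for a named connection
#'
#' @param cfg Configuration list from [load_model_config()].
#' @param name Exact connection name, e.g.
#'   `"MEC LII Stellate to MEC LII Basket"`.
#' @return A `tm_params` object (see [tm_params()]).
#' @export
connection_params <- function(cfg, name) {
  if (!name %in% names(cfg$connections)) {
    stop("unknown connection '", name, "'; available: ",
         paste(names(cfg$connections), collapse = ", "))
  }
  p <- cfg$connections[[name]]
  tm_params(g_fast = p$g_fast, tau_d_fast = p$tau_d_fast, U = p$U,
            tau_u = p$tau_u, tau_x = p$tau_x, g_slow = p$g_slow,
            tau_d_slow = cfg$receptors$tau_d_slow)
}
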