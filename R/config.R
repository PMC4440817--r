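#' Default model configuration
#'
#' The configuration is a nested list with five blocks:
#' \describe{
#'   \item{landscape}{`source` (path to a parcel file, or `NULL` to use
#'     the synthetic generator), `seed` (landscape-generation seed; fixed
#'     in the default config so every run of a scenario ensemble shares
#'     one landscape, which parcel-level probabilities require),
#'     `min_area_ha` (farm filter, strict), `generator` (see
#'     [default_gen_config()]).}
#'   \item{economics}{`coefficients` (data.frame) or `coefficients_path`
#'     (CSV), `annual_price_growth` (real commodity price growth per
#'     year), `years_per_step`.}
#'   \item{behaviour}{`initial_likelihood` (base conversion likelihood,
#'     reset after every decision), `dairy_penalty` (proportional
#'     reduction applied to proposals to convert into Dairy),
#'     `forest_lock_steps` (rotation lock after converting into a forest
#'     enterprise), `k_social` (social network size),
#'     `network_effects` (endorsement/imitation toggle).}
#'   \item{demography}{`succession_rate`, `steps_per_stage`,
#'     `initial_stages`.}
#'   \item{scenario}{`ghg_price` (NZD/tCO2e, constant over the horizon),
#'     `n_steps`.}
#' }
#'
#' @return A nested configuration list of class `fs_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' names(cfg)
default_config <- function() {
  structure(list(
    landscape = list(
      source = NULL,
      seed = 1959L,
      min_area_ha = 100,
      generator = default_gen_config()
    ),
    economics = list(
      coefficients = NULL,
      coefficients_path = NULL,
      annual_price_growth = 0.02,
      years_per_step = 5
    ),
    behaviour = list(
      initial_likelihood = 0.2,
      dairy_penalty = 0.75,
      forest_lock_steps = 5L,
      k_social = 10L,
      network_effects = TRUE
    ),
    demography = list(
      succession_rate = 0.75,
      steps_per_stage = 1L,
      initial_stages = 1:5
    ),
    scenario = list(
      ghg_price = 0,
      n_steps = 10L
    )
  ), class = "fs_config")
}

#' Load a model configuration from YAML
#'
#' Values given in the file override the corresponding defaults;
#' everything else keeps its default.
#'
#' @param path Path to a YAML file mirroring the [default_config()]
#'   structure.
#' @return An `fs_config` list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), user)
  structure(validate_config(cfg), class = "fs_config")
}

validate_config <- function(config) {
  beh <- config$behaviour
  if (beh$initial_likelihood < 0 || beh$initial_likelihood > 1) {
    stop("initial_likelihood must be in [0, 1]", call. = FALSE)
  }
  if (beh$dairy_penalty < 0 || beh$dairy_penalty > 1) {
    stop("dairy_penalty must be in [0, 1]", call. = FALSE)
  }
  if (beh$forest_lock_steps < 0) {
    stop("forest_lock_steps must be >= 0", call. = FALSE)
  }
  dem <- config$demography
  if (dem$succession_rate < 0 || dem$succession_rate > 1) {
    stop("succession_rate must be in [0, 1]", call. = FALSE)
  }
  if (config$scenario$ghg_price < 0) {
    stop("ghg_price must be >= 0", call. = FALSE)
  }
  if (config$scenario$n_steps < 0) {
    stop("n_steps must be >= 0", call. = FALSE)
  }
  if (is.null(config$landscape$source)) {
    validate_gen_config(config$landscape$generator)
  }
  config
}

resolve_coefficients <- function(config) {
  eco <- config$economics
  if (!is.null(eco$coefficients)) {
    validate_coefficients(eco$coefficients)
  } else if (!is.null(eco$coefficients_path)) {
    read_coefficients(eco$coefficients_path)
  } else {
    default_coefficients()
  }
}
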