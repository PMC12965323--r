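#' Default run configuration
#'
#' All tunable parameters of the pipeline with their default values. The
#' defaults encode the study conditions: a growing-period month is a month
#' with grass GPP above 100 g C m-2, a cell is suitable for multiple cropping
#' when at least nine months qualify, off-season yields and water use are
#' dampened by 25%, water may be conveyed over at most 100 km, and a carbon
#' fraction of 0.45 converts grass carbon to dry matter.
#'
#' @return A named list of class `mc_config`:
#' \describe{
#'   \item{gpp_threshold}{growing-period month threshold, g C m-2 month-1 (100)}
#'   \item{min_growing_months}{months required for suitability, 1..12 (9)}
#'   \item{consecutive_months}{require the growing months to be consecutive?
#'     (FALSE; the count rule does not care about runs)}
#'   \item{offseason_dampening}{fractional reduction of off-season yield and
#'     water use for turnaround/fallow time (0.25)}
#'   \item{radius_km}{water access radius around a demand cell (100)}
#'   \item{carbon_fraction}{grass carbon per unit dry matter (0.45)}
#'   \item{calibration_cap}{upper bound on country-crop yield calibration
#'     factors, `Inf` = uncapped}
#'   \item{efficiency}{irrigation-system efficiency table, see
#'     [default_efficiency_table()]}
#' }
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$gpp_threshold
default_config <- function() {
  structure(list(
    gpp_threshold = 100,
    min_growing_months = 9L,
    consecutive_months = FALSE,
    offseason_dampening = 0.25,
    radius_km = 100,
    carbon_fraction = 0.45,
    calibration_cap = Inf,
    efficiency = default_efficiency_table()
  ), class = "mc_config")
}

#' Irrigation system efficiency table
#'
#' Field and conveyance efficiencies per irrigation system, and the share of
#' conveyance losses that is consumed (evaporated in transit) rather than
#' returned to the river. Defaults are representative of the parameterisations
#' used in global hydrology/crop modelling: surface systems lose most water in
#' unlined canals and on-field percolation, drip systems very little.
#'
#' @param field named numeric, field application efficiency per system
#' @param conveyance named numeric, conveyance efficiency per system
#' @param consumptive_loss_share fraction of conveyance losses that is
#'   consumptive (default 0.5)
#' @return tibble with columns system, field_eff, conveyance_eff,
#'   consumptive_loss_share
#' @export
default_efficiency_table <- function(
    field = c(surface = 0.60, sprinkler = 0.75, drip = 0.90),
    conveyance = c(surface = 0.70, sprinkler = 0.95, drip = 0.95),
    consumptive_loss_share = 0.5) {
  stopifnot(identical(names(field), names(conveyance)))
  tibble::tibble(
    system = names(field),
    field_eff = unname(field),
    conveyance_eff = unname(conveyance),
    consumptive_loss_share = consumptive_loss_share
  )
}

config_keys <- function() names(default_config())

#' Validate a raw configuration mapping
#'
#' Takes a plain named list (e.g. parsed from YAML), fills unspecified keys
#' with the defaults of [default_config()], type- and range-checks every
#' value, and rejects unknown keys. Error messages name the offending key.
#'
#' @param raw named list (possibly empty) of configuration overrides
#' @return a validated `mc_config` list
#' @export
#' @examples
#' validate_config(list())$min_growing_months  # 9
#' validate_config(list(radius_km = 50))$radius_km
validate_config <- function(raw = list()) {
  if (inherits(raw, "mc_config")) raw <- unclass(raw)
  stopifnot(is.list(raw))
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(unclass(default_config()), raw)

  check_num <- function(key, lo, hi, integerish = FALSE) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi) {
      stop(sprintf("configuration key '%s' must be a number in [%s, %s]",
                   key, lo, hi))
    }
    if (integerish && v != round(v)) {
      stop(sprintf("configuration key '%s' must be a whole number", key))
    }
  }
  check_num("gpp_threshold", 0, Inf)
  check_num("min_growing_months", 1, 12, integerish = TRUE)
  check_num("offseason_dampening", 0, 1)
  check_num("radius_km", 1e-9, Inf)
  check_num("carbon_fraction", 1e-12, 1)
  check_num("calibration_cap", 0, Inf)
  if (!is.logical(cfg$consecutive_months) || length(cfg$consecutive_months) != 1) {
    stop("configuration key 'consecutive_months' must be TRUE or FALSE")
  }
  eff <- tibble::as_tibble(cfg$efficiency)
  required <- c("system", "field_eff", "conveyance_eff", "consumptive_loss_share")
  if (!all(required %in% names(eff))) {
    stop("configuration key 'efficiency' must have columns: ",
         paste(required, collapse = ", "))
  }
  for (col in required[-1]) {
    if (any(eff[[col]] <= 0 & col != "consumptive_loss_share") ||
        any(eff[[col]] < 0) || any(eff[[col]] > 1)) {
      stop("configuration key 'efficiency': column '", col,
           "' must lie in (0, 1]")
    }
  }
  cfg$min_growing_months <- as.integer(cfg$min_growing_months)
  cfg$efficiency <- eff
  structure(cfg, class = "mc_config")
}

#' Read / write a configuration as YAML
#'
#' @param path file path
#' @param cfg an `mc_config`
#' @return `read_config` returns a validated `mc_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$efficiency)) {
    raw$efficiency <- tibble::as_tibble(as.data.frame(raw$efficiency))
  }
  validate_config(raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  out <- unclass(cfg)
  out$efficiency <- as.list(as.data.frame(cfg$efficiency))
  yaml::write_yaml(out, path)
  invisible(path)
}
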