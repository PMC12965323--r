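#' Off-season to main-season grass productivity ratio
#'
#' Ratio of total grass GPP in the months outside a crop's growing season to
#' total grass GPP inside it. Sums (not means) are used, so the ratio
#' represents the total productivity available outside the main season.
#' Returns 0 when the off-season sum is 0. A main-season sum of 0 with
#' positive off-season GPP is a degenerate input (the cell supports no main
#' crop); it yields 0 with a warning.
#'
#' @param gpp_12 12 monthly grass GPP values
#' @param season integer vector of main-season month indices (nonempty
#'   subset of 1..12)
#' @return non-negative ratio
#' @export
#' @examples
#' offseason_ratio(rep(100, 12), 1:6)               # 1
#' offseason_ratio(c(rep(200, 4), rep(50, 8)), 1:4) # 0.5
offseason_ratio <- function(gpp_12, season) {
  stopifnot(length(gpp_12) == 12, all(gpp_12 >= 0))
  season <- as.integer(season)
  if (length(season) == 0 || anyDuplicated(season) ||
      any(season < 1) || any(season > 12)) {
    stop("season must be a nonempty set of month indices in 1..12")
  }
  main <- sum(gpp_12[season])
  off <- sum(gpp_12[-season])
  if (off == 0) return(0)
  if (main == 0) {
    warning("degenerate cell: zero main-season GPP with nonzero off-season; ",
            "off-season ratio set to 0")
    return(0)
  }
  off / main
}

#' Off-season yield from the main-season yield
#'
#' Scales the explicitly modelled main-season yield by the off-season to
#' main-season grass productivity ratio, reduced by the dampening fraction
#' that accounts for turnaround time between harvest and the next sowing.
#' Callers mask the result to 0 where the cell-regime is not suitable for
#' multiple cropping.
#'
#' @param y_main main-season yield, t DM/ha
#' @param ratio off-season to main-season grass GPP ratio
#' @param dampening fractional reduction of the off-season potential
#'   (default 0.25)
#' @return off-season yield, t DM/ha
#' @export
#' @examples
#' offseason_yield(4, 0.5)  # 1.5
offseason_yield <- function(y_main, ratio, dampening = 0.25) {
  stopifnot(all(y_main >= 0), all(ratio >= 0),
            dampening >= 0, dampening <= 1)
  y_main * ratio * (1 - dampening)
}

#' Annual yield table for a world
#'
#' Computes, per cell x crop x regime, the main-season yield, the off-season
#' yield (zero where the cell-regime is unsuitable for multiple cropping),
#' and the annual yields under single cropping (= main) and under multiple
#' cropping (= main + off-season).
#'
#' @param world an `mc_world`
#' @param suitability output of [classify_suitability()]
#' @param config an `mc_config`
#' @return tibble (cell_id, crop, regime, y_main, y_off, y_annual_single,
#'   y_annual_mc)
#' @export
build_yield_table <- function(world, suitability,
                              config = default_config()) {
  config <- validate_config(config)
  gpp_mat <- grass_matrix(world$grass, "gpp")
  crops <- dplyr::distinct(
    world$crops, .data$cell_id, .data$crop, .data$regime,
    .data$season_start, .data$season_len, .data$main_yield)
  ratio <- vapply(seq_len(nrow(crops)), function(i) {
    season <- season_months(crops$season_start[i], crops$season_len[i])
    offseason_ratio(
      gpp_mat[[crops$regime[i]]][crops$cell_id[i], ], season)
  }, 0)
  crops |>
    dplyr::left_join(suitability[, c("cell_id", "regime", "suitable")],
                     by = c("cell_id", "regime")) |>
    dplyr::mutate(
      y_main = .data$main_yield,
      y_off = ifelse(.data$suitable,
                     offseason_yield(.data$main_yield, ratio,
                                     config$offseason_dampening), 0),
      y_annual_single = .data$y_main,
      y_annual_mc = .data$y_main + .data$y_off) |>
    dplyr::select("cell_id", "crop", "regime", "y_main", "y_off",
                  "y_annual_single", "y_annual_mc")
}

# named list of cell x month matrices per regime for one grass variable
grass_matrix <- function(grass, var) {
  out <- list()
  for (reg in c("rainfed", "irrigated")) {
    sub <- grass[grass$regime == reg, ]
    m <- matrix(0, max(sub$cell_id), 12)
    m[cbind(sub$cell_id, sub$month)] <- sub[[var]]
    out[[reg]] <- m
  }
  out
}

#' Calibrate yields to country-level reported yields
#'
#' Computes one multiplicative factor per country x crop so that the
#' area-weighted mean calibrated main-season yield over the country's cells
#' (weights = physical crop area, both regimes) equals the reported yield.
#' The factor is applied uniformly to main- and off-season yields, so
#' within-country cell-to-cell yield ratios are preserved.
#'
#' @param yields an annual yield table from [build_yield_table()]
#' @param world the `mc_world` providing areas and the country layer
#' @param reported tibble (country, crop, reported_yield) in t DM/ha; must
#'   be positive for every country-crop with nonzero modelled area
#' @param cap optional upper bound on calibration factors (default `Inf`)
#' @return list: `yields` (calibrated table) and `factors`
#'   (country, crop, factor)
#' @export
calibrate_yields <- function(yields, world, reported, cap = Inf) {
  areas <- world$crops |>
    dplyr::left_join(world$grid[, c("cell_id", "country")], by = "cell_id")
  modeled <- yields |>
    dplyr::left_join(
      areas[, c("cell_id", "crop", "regime", "physical_area_ha", "country")],
      by = c("cell_id", "crop", "regime")) |>
    dplyr::group_by(.data$country, .data$crop) |>
    dplyr::summarise(
      area = sum(.data$physical_area_ha),
      mean_yield = ifelse(area > 0,
                          sum(.data$y_main * .data$physical_area_ha) / area,
                          NA_real_),
      .groups = "drop")
  factors <- modeled |>
    dplyr::inner_join(reported, by = c("country", "crop")) |>
    dplyr::filter(.data$area > 0)
  bad <- factors$mean_yield <= 0 & factors$reported_yield > 0
  if (any(bad)) {
    stop("calibration error: zero modelled area-weighted yield for ",
         paste(factors$country[bad], factors$crop[bad],
               sep = "/", collapse = ", "))
  }
  factors <- factors |>
    dplyr::mutate(factor = pmin(.data$reported_yield / .data$mean_yield,
                                cap)) |>
    dplyr::select("country", "crop", "factor")

  calibrated <- yields |>
    dplyr::left_join(world$grid[, c("cell_id", "country")], by = "cell_id") |>
    dplyr::left_join(factors, by = c("country", "crop")) |>
    dplyr::mutate(factor = dplyr::coalesce(.data$factor, 1)) |>
    dplyr::mutate(dplyr::across(
      c("y_main", "y_off", "y_annual_single", "y_annual_mc"),
      ~ .x * factor)) |>
    dplyr::select(-"country", -"factor")
  list(yields = calibrated, factors = factors)
}

#' Multiple-cropping area share from cropping intensity
#'
#' Cropping intensity CI is harvested area over physical area; CI - 1 is the
#' share of the physical area harvested more than once, capped at 1 (the
#' off-season is one aggregate: triple cropping is not resolved separately).
#'
#' @param physical_area physical crop area, ha (> 0)
#' @param harvested_area harvested crop area, ha (>= physical)
#' @return fraction of the physical area under multiple cropping, in [0, 1]
#' @export
#' @examples
#' ci_to_mc_share(100, 150)  # 0.5
#' ci_to_mc_share(100, 230)  # 1
ci_to_mc_share <- function(physical_area, harvested_area) {
  stopifnot(length(physical_area) == length(harvested_area))
  if (any(physical_area <= 0)) {
    stop("physical_area must be positive (CI undefined otherwise)")
  }
  if (any(harvested_area < physical_area - 1e-9 * pmax(physical_area, 1))) {
    stop("harvested_area below physical_area: cropping intensity < 1")
  }
  ci <- harvested_area / physical_area
  pmin(pmax(ci - 1, 0), 1)
}

# vectorised MC share that treats zero physical area as share 0
mc_share_safe <- function(physical_area, harvested_area) {
  ifelse(physical_area > 0,
         pmin(pmax(harvested_area / pmax(physical_area, .Machine$double.xmin)
                   - 1, 0), 1),
         0)
}
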