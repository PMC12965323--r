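#' @title Scenario assembly
#' @description
#' Three scenarios share one physical cropland extent and differ only in how
#' much of it is managed under multiple cropping (MC):
#' REF keeps the reference-year management (MC shares from cropping
#' intensity); NWL expands MC to every suitable area, converting rainfed
#' land to irrigated MC wherever only irrigation enables a second season,
#' with no water constraint; POT realises the same expansion but limits the
#' irrigated part by the river-network water allocation.
#' @name scenarios
NULL

# per cell x crop wide table joining areas, REF MC shares, suitability,
# yields and per-ha water demands
scenario_base <- function(world, suitability, yields, demands) {
  areas <- world$crops |>
    dplyr::select("cell_id", "crop", "regime", "physical_area_ha",
                  "harvested_area_ha") |>
    dplyr::mutate(ref_mc = mc_share_safe(.data$physical_area_ha,
                                         .data$harvested_area_ha)) |>
    tidyr::pivot_wider(names_from = "regime",
                       values_from = c("physical_area_ha",
                                       "harvested_area_ha", "ref_mc"))
  suit <- suitability |>
    dplyr::select("cell_id", "regime", "suitable") |>
    tidyr::pivot_wider(names_from = "regime", values_from = "suitable",
                       names_prefix = "suit_")
  yld <- yields |>
    dplyr::select("cell_id", "crop", "regime", "y_main", "y_annual_mc") |>
    tidyr::pivot_wider(names_from = "regime",
                       values_from = c("y_main", "y_annual_mc"))
  dem <- demands |>
    dplyr::select("cell_id", "crop", "withdrawal_single_mm",
                  "withdrawal_mc_mm", "consumption_single_mm",
                  "consumption_mc_mm")
  areas |>
    dplyr::left_join(suit, by = "cell_id") |>
    dplyr::left_join(yld, by = c("cell_id", "crop")) |>
    dplyr::left_join(dem, by = c("cell_id", "crop"))
}

# area and production accounting shared by all scenarios. `expand` switches
# MC expansion on; `f` is the per-cell fulfilled fraction of irrigated
# expansion (NWL: all 1). Uses exact branches at f == 1 so that a fully
# served POT reproduces NWL bit for bit.
assemble_areas <- function(base, expand, f_by_cell) {
  f <- if (expand) f_by_cell[base$cell_id] else rep(0, nrow(base))
  suit_rf <- base$suit_rainfed
  suit_irr <- base$suit_irrigated
  a_rf <- base$physical_area_ha_rainfed
  a_irr <- base$physical_area_ha_irrigated

  enabled <- ifelse(expand & !suit_rf & suit_irr,
                    ifelse(f == 1, a_rf, f * a_rf), 0)
  rf_rest <- ifelse(enabled == a_rf, 0, a_rf - enabled)
  rf_mc <- ifelse(expand & suit_rf, rf_rest, rf_rest * base$ref_mc_rainfed)
  rf_single <- rf_rest - rf_mc
  irr_mc_ref <- a_irr * base$ref_mc_irrigated
  irr_mc <- ifelse(expand & suit_irr,
                   ifelse(f == 1, a_irr,
                          irr_mc_ref + f * (a_irr - irr_mc_ref)),
                   irr_mc_ref)
  irr_single <- a_irr - irr_mc

  tibble::tibble(
    cell_id = base$cell_id, crop = base$crop,
    rainfed_single = rf_single, rainfed_mc = rf_mc,
    irrigated_single = irr_single, irrigated_mc = irr_mc,
    irrigation_enabled_mc = enabled,
    p_rainfed_single = rf_single * base$y_main_rainfed,
    p_rainfed_mc = rf_mc * base$y_annual_mc_rainfed,
    p_irrigated_single = irr_single * base$y_main_irrigated,
    p_irrigated_mc = irr_mc * base$y_annual_mc_irrigated,
    p_irrigation_enabled_mc = enabled * base$y_annual_mc_irrigated)
}

# long (cell, crop, system, area, production) view; irrigation-enabled MC is
# kept as its own flagged irrigated-MC system class
areas_long <- function(at) {
  systems <- c("rainfed_single", "rainfed_mc", "irrigated_single",
               "irrigated_mc", "irrigation_enabled_mc")
  purrr::map_dfr(systems, function(s) {
    tibble::tibble(
      cell_id = at$cell_id, crop = at$crop, system = s,
      area_ha = at[[s]], production_t = at[[paste0("p_", s)]])
  })
}

# committed (REF-pattern) and full expansion water demand per cell, km3
water_demands_by_cell <- function(base) {
  committed_single <- (1 - base$ref_mc_irrigated) *
    base$physical_area_ha_irrigated
  committed_mc <- base$ref_mc_irrigated * base$physical_area_ha_irrigated
  exp_area_irr <- ifelse(base$suit_irrigated,
                         base$physical_area_ha_irrigated - committed_mc, 0)
  enabled_area <- ifelse(!base$suit_rainfed & base$suit_irrigated,
                         base$physical_area_ha_rainfed, 0)
  tibble::tibble(
    cell_id = base$cell_id,
    committed_w = mm_ha_to_km3(base$withdrawal_single_mm, committed_single) +
      mm_ha_to_km3(base$withdrawal_mc_mm, committed_mc),
    committed_c = mm_ha_to_km3(base$consumption_single_mm, committed_single) +
      mm_ha_to_km3(base$consumption_mc_mm, committed_mc),
    expansion_w = mm_ha_to_km3(
      base$withdrawal_mc_mm - base$withdrawal_single_mm, exp_area_irr) +
      mm_ha_to_km3(base$withdrawal_mc_mm, enabled_area),
    expansion_c = mm_ha_to_km3(
      base$consumption_mc_mm - base$consumption_single_mm, exp_area_irr) +
      mm_ha_to_km3(base$consumption_mc_mm, enabled_area)) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum),
                     .groups = "drop")
}

new_scenario_result <- function(scenario, areas, fallow, water,
                                expansion = NULL) {
  structure(list(scenario = scenario, areas = areas, fallow = fallow,
                 water = water, expansion = expansion),
            class = "mc_scenario")
}

#' @export
print.mc_scenario <- function(x, ...) {
  tot <- x$areas |>
    dplyr::group_by(.data$system) |>
    dplyr::summarise(area_ha = sum(.data$area_ha),
                     production_t = sum(.data$production_t),
                     .groups = "drop")
  cat("<mc_scenario> ", x$scenario, "\n", sep = "")
  print(tot)
  invisible(x)
}

#' Build the reference-state scenario
#'
#' Management as observed in the reference year: the multiple-cropping share
#' of every cell-crop-regime is its cropping intensity minus one (capped at
#' one), production is area times the annual yield of the respective
#' system, and irrigation water demand covers the existing irrigated areas
#' under those reference cropping patterns.
#'
#' @param world an `mc_world`
#' @param suitability from [classify_suitability()]
#' @param yields from [build_yield_table()]
#' @param demands from [annual_irrigation_demand()]
#' @return an `mc_scenario`
#' @export
build_ref <- function(world, suitability, yields, demands) {
  base <- scenario_base(world, suitability, yields, demands)
  at <- assemble_areas(base, expand = FALSE,
                       f_by_cell = rep(0, nrow(world$grid)))
  wd <- water_demands_by_cell(base)
  water <- dplyr::bind_rows(
    tibble::tibble(cell_id = world$nonag$cell_id, purpose = "non_ag",
                   withdrawal_km3 = world$nonag$withdrawal_km3,
                   consumption_km3 = world$nonag$consumption_km3,
                   groundwater_km3 = 0),
    tibble::tibble(cell_id = wd$cell_id, purpose = "committed",
                   withdrawal_km3 = wd$committed_w,
                   consumption_km3 = wd$committed_c,
                   groundwater_km3 = 0))
  new_scenario_result("REF", areas_long(at), world$fallow, water)
}

#' Build the no-water-limit expansion scenario
#'
#' Multiple cropping is expanded to its maximum extent on the same physical
#' cropland: every rainfed-suitable cell-crop goes fully to rainfed MC,
#' every irrigated area in an irrigated-suitable cell goes fully to
#' irrigated MC, and rainfed areas in cells suitable only under irrigation
#' convert entirely to irrigated MC (flagged irrigation-enabled). Areas not
#' suitable under any applicable regime keep their reference management.
#' Water demand is reported unconstrained (committed plus the full
#' expansion requirement).
#'
#' @inheritParams build_ref
#' @return an `mc_scenario`
#' @export
build_nwl <- function(world, suitability, yields, demands) {
  base <- scenario_base(world, suitability, yields, demands)
  at <- assemble_areas(base, expand = TRUE,
                       f_by_cell = rep(1, nrow(world$grid)))
  wd <- water_demands_by_cell(base)
  water <- dplyr::bind_rows(
    tibble::tibble(cell_id = world$nonag$cell_id, purpose = "non_ag",
                   withdrawal_km3 = world$nonag$withdrawal_km3,
                   consumption_km3 = world$nonag$consumption_km3,
                   groundwater_km3 = 0),
    tibble::tibble(cell_id = wd$cell_id, purpose = "committed",
                   withdrawal_km3 = wd$committed_w,
                   consumption_km3 = wd$committed_c,
                   groundwater_km3 = 0),
    tibble::tibble(cell_id = wd$cell_id, purpose = "expansion",
                   withdrawal_km3 = wd$expansion_w,
                   consumption_km3 = wd$expansion_c,
                   groundwater_km3 = 0))
  new_scenario_result("NWL", areas_long(at), world$fallow, water)
}

#' Build the water-constrained expansion scenario
#'
#' Rainfed multiple-cropping expansion proceeds as in the no-water-limit
#' scenario (it needs no irrigation water). Irrigated expansion — both
#' additional MC on already-irrigated areas and irrigation-enabled
#' conversion of rainfed areas — is limited by the river allocation:
#' non-agricultural demand is served first, then committed reference
#' irrigation (shortfalls booked as non-renewable groundwater), then
#' per-cell expansion requests ranked by the irrigation yield gain. Each
#' cell's fulfilled fraction scales its expansion areas proportionally
#' across crops.
#'
#' @inheritParams build_ref
#' @param radius_km water access radius (default from `config`)
#' @param config an `mc_config`
#' @return an `mc_scenario`; component `expansion` holds the allocation
#'   result
#' @export
build_pot <- function(world, suitability, yields, demands,
                      config = default_config(),
                      radius_km = config$radius_km) {
  config <- validate_config(config)
  base <- scenario_base(world, suitability, yields, demands)
  wd <- water_demands_by_cell(base)
  rank <- rank_expansion_cells(world, yields)

  nonag <- world$nonag[world$nonag$withdrawal_km3 > 0, ]
  committed <- wd[wd$committed_w > 0, ]
  expansion <- wd[wd$expansion_w > 0, ] |>
    dplyr::left_join(rank, by = "cell_id")
  requests <- dplyr::bind_rows(
    tibble::tibble(cell_id = nonag$cell_id, purpose = "non_ag",
                   withdrawal_km3 = nonag$withdrawal_km3,
                   consumption_km3 = nonag$consumption_km3, rank_key = 0),
    tibble::tibble(cell_id = committed$cell_id, purpose = "committed",
                   withdrawal_km3 = committed$committed_w,
                   consumption_km3 = committed$committed_c, rank_key = 0),
    tibble::tibble(cell_id = expansion$cell_id, purpose = "expansion",
                   withdrawal_km3 = expansion$expansion_w,
                   consumption_km3 = expansion$expansion_c,
                   rank_key = expansion$rank_key))
  requests <- sort_requests(requests)
  state <- route_discharge(world$grid)
  alloc <- allocate(requests, state, world$grid, radius_km)

  f_by_cell <- rep(1, nrow(world$grid))
  exp_res <- alloc$requests[alloc$requests$purpose == "expansion", ]
  f_by_cell[exp_res$cell_id] <- exp_res$fraction

  at <- assemble_areas(base, expand = TRUE, f_by_cell = f_by_cell)
  res <- alloc$requests |>
    dplyr::mutate(
      withdrawal_served = ifelse(.data$purpose == "expansion",
                                 .data$granted_km3, .data$withdrawal_km3),
      consumption_served = ifelse(
        .data$purpose == "expansion", .data$consumption_surface_km3,
        .data$consumption_km3))
  water <- tibble::tibble(cell_id = res$cell_id, purpose = res$purpose,
                          withdrawal_km3 = res$withdrawal_served,
                          consumption_km3 = res$consumption_served,
                          groundwater_km3 = res$groundwater_km3)
  new_scenario_result("POT", areas_long(at), world$fallow, water,
                      expansion = alloc)
}
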