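#' Main-season consumptive irrigation water requirement
#'
#' The water an irrigated crop actually evapotranspires beyond what the same
#' crop would evapotranspire rainfed over the same (irrigated) growing
#' season: the difference of the transpiration + evaporation + interception
#' sums under the two regimes, clamped at zero.
#'
#' @param et_irr irrigated-season evapotranspiration, mm (scalar/vector)
#' @param et_rf rainfed evapotranspiration over the same season, mm
#' @return consumptive irrigation water requirement, mm
#' @export
#' @examples
#' main_season_consumptive_iwr(500, 300)  # 200
main_season_consumptive_iwr <- function(et_irr, et_rf) {
  stopifnot(all(et_irr >= 0), all(et_rf >= 0))
  pmax(et_irr - et_rf, 0)
}

#' Fit the crop-on-grass consumptive water regression
#'
#' Ordinary least squares of crop consumptive irrigation water use on grass
#' consumptive irrigation water use across cells during the main growing
#' season. The fitted line is later applied to off-season grass water use to
#' estimate off-season crop water consumption.
#'
#' @param crop_iwc crop consumptive IWR per cell, mm
#' @param grass_iwc grass consumptive IWR per cell (same cells), mm
#' @return list (slope, intercept, r2, n)
#' @export
#' @examples
#' fit_offseason_regression(c(2, 4, 6), c(1, 2, 3))  # slope 2, intercept 0
fit_offseason_regression <- function(crop_iwc, grass_iwc) {
  if (length(crop_iwc) != length(grass_iwc)) {
    stop("crop_iwc and grass_iwc must have equal length")
  }
  if (length(crop_iwc) < 3) stop("regression needs at least 3 points")
  if (stats::var(grass_iwc) == 0) {
    stop("regression error: zero variance in grass consumptive IWR")
  }
  fit <- stats::lm(crop_iwc ~ grass_iwc)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r2 = suppressWarnings(summary(fit)$r.squared), n = length(crop_iwc))
}

#' Off-season consumptive irrigation water requirement
#'
#' Applies the main-season crop-on-grass regression to off-season grass
#' consumptive water use, clamps negative predictions at zero, and dampens
#' by the same fallow/turnaround factor used for off-season yields.
#'
#' @param grass_iwc_off off-season grass consumptive IWR, mm
#' @param regression list with slope and intercept
#'   (see [fit_offseason_regression()])
#' @param dampening fractional reduction (default 0.25)
#' @return off-season crop consumptive IWR, mm
#' @export
#' @examples
#' offseason_consumptive_iwr(100, list(slope = 2, intercept = 0))  # 150
offseason_consumptive_iwr <- function(grass_iwc_off, regression,
                                      dampening = 0.25) {
  stopifnot(all(grass_iwc_off >= 0), dampening >= 0, dampening <= 1)
  pred <- regression$slope * grass_iwc_off + regression$intercept
  pmax(pred, 0) * (1 - dampening)
}

#' Convert field consumption to withdrawal and total consumption
#'
#' Withdrawals exceed field-level consumptive use by field and conveyance
#' losses of the irrigation-system mix. A stated fraction of conveyance
#' losses evaporates in transit and is counted as additional consumption;
#' the remainder (and all field losses) returns to the river.
#'
#' @param consumption field-level consumptive requirement (any volume unit;
#'   scalar or vector)
#' @param shares tibble/list with elements surface, sprinkler, drip summing
#'   to 1 (recycled over `consumption`)
#' @param efficiency efficiency table, see [default_efficiency_table()]
#' @return list (withdrawal, consumption_total) in the unit of `consumption`
#' @export
#' @examples
#' eff <- default_efficiency_table(field = c(surface = 0.5),
#'                                 conveyance = c(surface = 1))
#' consumption_to_withdrawal(1, list(surface = 1), eff)$withdrawal  # 2
consumption_to_withdrawal <- function(consumption, shares, efficiency) {
  stopifnot(all(consumption >= 0))
  sys <- efficiency$system
  sh <- matrix(unlist(lapply(sys, function(s) {
    v <- shares[[s]]; if (is.null(v)) 0 else v
  })), ncol = length(sys))
  if (any(abs(rowSums(sh) - 1) > 1e-9)) {
    stop("irrigation system shares must sum to 1")
  }
  if (any(efficiency$field_eff <= 0) || any(efficiency$conveyance_eff <= 0)) {
    stop("configuration error: zero irrigation efficiency")
  }
  withdrawal <- numeric(length(consumption))
  extra_consumed <- numeric(length(consumption))
  for (j in seq_along(sys)) {
    fe <- efficiency$field_eff[j]
    ce <- efficiency$conveyance_eff[j]
    fc <- efficiency$consumptive_loss_share[j]
    w_j <- sh[, j] * consumption / (fe * ce)
    withdrawal <- withdrawal + w_j
    extra_consumed <- extra_consumed + fc * w_j * (1 - ce)
  }
  list(withdrawal = withdrawal,
       consumption_total = consumption + extra_consumed)
}

#' Fit off-season regressions for every crop
#'
#' Pools cells per crop: crop consumptive IWR over the irrigated main season
#' against grass consumptive IWR over the same months. Cells without
#' irrigated-season signal still enter; crops whose grass IWC has zero
#' variance raise an error.
#'
#' @param world an `mc_world`
#' @return tibble (crop, system, slope, intercept, r2, n); `system` is
#'   "all" (consumptive field-level water use is system-independent here)
#' @export
fit_world_regressions <- function(world) {
  iwc <- crop_grass_iwc(world)
  iwc |>
    dplyr::group_by(.data$crop) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_offseason_regression(d$crop_iwc, d$grass_iwc_main)
      tibble::tibble(system = "all", slope = fit$slope,
                     intercept = fit$intercept, r2 = fit$r2, n = fit$n)
    }) |>
    dplyr::ungroup()
}

# per cell x crop: main-season crop and grass consumptive IWR plus
# off-season grass consumptive IWR (mm), on the irrigated season
crop_grass_iwc <- function(world) {
  et <- grass_matrix(world$grass, "et_mm")
  iwc_grass <- et$irrigated - et$rainfed   # cell x month, >= 0
  crops <- world$crops |>
    dplyr::select("cell_id", "crop", "regime", "season_start", "season_len",
                  "et_transp_mm", "et_evap_mm", "et_intercept_mm") |>
    dplyr::mutate(et_total = .data$et_transp_mm + .data$et_evap_mm +
                    .data$et_intercept_mm) |>
    dplyr::select(-"et_transp_mm", -"et_evap_mm", -"et_intercept_mm") |>
    tidyr::pivot_wider(names_from = "regime", values_from = "et_total")
  n <- nrow(crops)
  g_main <- numeric(n); g_off <- numeric(n)
  for (i in seq_len(n)) {
    season <- season_months(crops$season_start[i], crops$season_len[i])
    row <- iwc_grass[crops$cell_id[i], ]
    g_main[i] <- sum(row[season])
    g_off[i] <- sum(row[-season])
  }
  tibble::tibble(
    cell_id = crops$cell_id, crop = crops$crop,
    crop_iwc = main_season_consumptive_iwr(crops$irrigated, crops$rainfed),
    grass_iwc_main = g_main, grass_iwc_off = g_off)
}

#' Annual irrigation demand per cell and crop
#'
#' Combines main-season consumptive irrigation water requirements with
#' regression-based off-season estimates into per-hectare consumptive
#' demand for single cropping (main season only) and multiple cropping
#' (main + off-season), then converts to withdrawals under the cell's
#' irrigation-system mix. Off-season demand is masked to zero where the
#' cell is not suitable for multiple cropping under irrigation.
#'
#' Units: per-ha demands in mm; multiply by area in ha and 1e-8 to obtain
#' km3 (1 mm on 1 ha = 10 m3).
#'
#' @param world an `mc_world`
#' @param suitability output of [classify_suitability()]
#' @param regressions output of [fit_world_regressions()]
#' @param config an `mc_config`
#' @return tibble (cell_id, crop, iwc_main_mm, iwc_off_mm, iwc_single_mm,
#'   iwc_mc_mm, withdrawal_single_mm, withdrawal_mc_mm,
#'   consumption_single_mm, consumption_mc_mm); `consumption_*` include the
#'   consumptive share of conveyance losses
#' @export
annual_irrigation_demand <- function(world, suitability, regressions,
                                     config = default_config()) {
  config <- validate_config(config)
  iwc <- crop_grass_iwc(world)
  suit_irr <- suitability[suitability$regime == "irrigated",
                          c("cell_id", "suitable")]
  sys <- world$systems
  out <- iwc |>
    dplyr::left_join(regressions[, c("crop", "slope", "intercept")],
                     by = "crop") |>
    dplyr::left_join(suit_irr, by = "cell_id") |>
    dplyr::mutate(
      iwc_main_mm = .data$crop_iwc,
      iwc_off_mm = ifelse(
        .data$suitable,
        offseason_consumptive_iwr(
          .data$grass_iwc_off,
          list(slope = .data$slope, intercept = .data$intercept),
          config$offseason_dampening),
        0),
      iwc_single_mm = .data$iwc_main_mm,
      iwc_mc_mm = .data$iwc_main_mm + .data$iwc_off_mm)
  shares <- sys[match(out$cell_id, sys$cell_id), ]
  single <- consumption_to_withdrawal(out$iwc_single_mm, shares,
                                      config$efficiency)
  mc <- consumption_to_withdrawal(out$iwc_mc_mm, shares, config$efficiency)
  out$withdrawal_single_mm <- single$withdrawal
  out$withdrawal_mc_mm <- mc$withdrawal
  out$consumption_single_mm <- single$consumption_total
  out$consumption_mc_mm <- mc$consumption_total
  dplyr::select(out, "cell_id", "crop", dplyr::starts_with("iwc_"),
                dplyr::starts_with("withdrawal_"),
                dplyr::starts_with("consumption_"))
}

#' Convert a per-hectare water depth to a volume
#' @param mm depth in mm
#' @param area_ha area in ha
#' @return volume in km3
#' @export
mm_ha_to_km3 <- function(mm, area_ha) mm * area_ha * 1e-8
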