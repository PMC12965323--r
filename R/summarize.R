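#' Percentage share of a part in a total
#'
#' Division-by-zero shares are undefined (`NA`), never 0.
#'
#' @param part,total numbers in the same unit
#' @return share in percent (unrounded)
#' @export
#' @examples
#' pct_share(260, 1235)  # ~21.05
pct_share <- function(part, total) {
  out <- 100 * part / total
  out[rep_len(total == 0, length(out))] <- NA_real_
  out
}

#' Percentage change from a reference value
#' @param ref reference value
#' @param new new value
#' @return change in percent of `ref` (unrounded); `NA` if `ref` is 0
#' @export
#' @examples
#' pct_change(4200, 5400)  # ~28.6
pct_change <- function(ref, new) {
  out <- 100 * (new - ref) / ref
  out[rep_len(ref == 0, length(out))] <- NA_real_
  out
}

#' Round a percentage to the nearest integer for reporting
#' @param pct percentage value(s)
#' @return integer percent (half-up commercial rounding)
#' @export
round_pct <- function(pct) {
  ifelse(is.na(pct), NA_real_, floor(pct + 0.5))
}

#' Summarise scenario results
#'
#' Aggregates one or more scenario results to global totals: area and
#' production by management system (with irrigation-enabled MC folded into
#' irrigated MC and also reported separately), average yields by system,
#' water withdrawals/consumption/groundwater by purpose, and derived shares
#' (irrigated share of active cropland, MC share of rainfed and irrigated
#' land, production change relative to the first scenario). All shares are
#' unrounded percents; use [round_pct()] for display.
#'
#' @param results list of `mc_scenario` objects (nonempty); by convention
#'   the first is the reference
#' @return list of class `mc_summary`: tibbles `systems`, `water`, `totals`
#' @export
summarize_scenarios <- function(results) {
  if (length(results) == 0) stop("empty scenario list")
  stopifnot(all(vapply(results, inherits, TRUE, "mc_scenario")))

  systems <- purrr::map_dfr(results, function(r) {
    r$areas |>
      dplyr::group_by(.data$system) |>
      dplyr::summarise(area_ha = sum(.data$area_ha),
                       production_t = sum(.data$production_t),
                       .groups = "drop") |>
      dplyr::mutate(scenario = r$scenario,
                    mean_yield = ifelse(.data$area_ha > 0,
                                        .data$production_t / .data$area_ha,
                                        NA_real_)) |>
      dplyr::select("scenario", "system", "area_ha", "production_t",
                    "mean_yield")
  })

  water <- purrr::map_dfr(results, function(r) {
    r$water |>
      dplyr::group_by(.data$purpose) |>
      dplyr::summarise(withdrawal_km3 = sum(.data$withdrawal_km3),
                       consumption_km3 = sum(.data$consumption_km3),
                       groundwater_km3 = sum(.data$groundwater_km3),
                       .groups = "drop") |>
      dplyr::mutate(scenario = r$scenario) |>
      dplyr::select("scenario", dplyr::everything())
  })

  totals <- purrr::map_dfr(results, function(r) {
    s <- systems[systems$scenario == r$scenario, ]
    val <- function(sys, col) {
      v <- s[[col]][s$system == sys]
      if (length(v) == 0) 0 else v
    }
    rainfed <- val("rainfed_single", "area_ha") + val("rainfed_mc", "area_ha")
    irrigated <- val("irrigated_single", "area_ha") +
      val("irrigated_mc", "area_ha") + val("irrigation_enabled_mc", "area_ha")
    active <- rainfed + irrigated
    mc_rainfed <- val("rainfed_mc", "area_ha")
    mc_irrigated <- val("irrigated_mc", "area_ha") +
      val("irrigation_enabled_mc", "area_ha")
    w <- water[water$scenario == r$scenario, ]
    tibble::tibble(
      scenario = r$scenario,
      active_cropland_ha = active,
      fallow_ha = sum(r$fallow$fallow_area_ha),
      physical_cropland_ha = active + sum(r$fallow$fallow_area_ha),
      rainfed_ha = rainfed,
      irrigated_ha = irrigated,
      mc_rainfed_ha = mc_rainfed,
      mc_irrigated_ha = mc_irrigated,
      irrigation_enabled_mc_ha = val("irrigation_enabled_mc", "area_ha"),
      production_t = sum(s$production_t),
      irrigation_withdrawal_km3 = sum(
        w$withdrawal_km3[w$purpose %in% c("committed", "expansion")]),
      irrigation_consumption_km3 = sum(
        w$consumption_km3[w$purpose %in% c("committed", "expansion")]),
      groundwater_km3 = sum(w$groundwater_km3),
      irrigated_share_pct = pct_share(irrigated, active),
      rainfed_share_pct = pct_share(rainfed, active),
      mc_share_rainfed_pct = pct_share(mc_rainfed, rainfed),
      mc_share_irrigated_pct = pct_share(mc_irrigated, irrigated))
  })
  ref_prod <- totals$production_t[1]
  totals$production_change_pct <- pct_change(ref_prod, totals$production_t)

  structure(list(systems = systems, water = water, totals = totals),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat("<mc_summary>\n")
  print(x$totals[, c("scenario", "active_cropland_ha", "production_t",
                     "irrigation_withdrawal_km3", "production_change_pct")])
  invisible(x)
}

#' Write a summary to CSV and JSON
#'
#' Writes `systems.csv`, `water.csv` and `totals.csv` plus a machine-
#' readable `summary.json` with the totals. Outputs are deterministic:
#' identical summaries produce byte-identical files.
#'
#' @param summary an `mc_summary`
#' @param dir output directory (created if missing)
#' @return `dir` invisibly
#' @export
write_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "mc_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(summary$systems, file.path(dir, "systems.csv"))
  readr::write_csv(summary$water, file.path(dir, "water.csv"))
  readr::write_csv(summary$totals, file.path(dir, "totals.csv"))
  jsonlite::write_json(summary$totals, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full pipeline on a world
#'
#' Suitability classification, yield table, off-season water regressions,
#' annual irrigation demand, the three scenarios, and the global summary.
#'
#' @param world an `mc_world`
#' @param config an `mc_config`
#' @return list (suitability, yields, regressions, demands, ref, nwl, pot,
#'   summary)
#' @export
#' @examples
#' w <- generate_world(seed = 7, n_cells = 60, n_basins = 5)
#' res <- run_pipeline(w)
#' res$summary$totals[, c("scenario", "production_change_pct")]
run_pipeline <- function(world, config = default_config()) {
  config <- validate_config(config)
  suitability <- classify_suitability(world$grass, config)
  yields <- build_yield_table(world, suitability, config)
  regressions <- fit_world_regressions(world)
  demands <- annual_irrigation_demand(world, suitability, regressions,
                                      config)
  ref <- build_ref(world, suitability, yields, demands)
  nwl <- build_nwl(world, suitability, yields, demands)
  pot <- build_pot(world, suitability, yields, demands, config)
  summary <- summarize_scenarios(list(ref, pot, nwl))
  list(suitability = suitability, yields = yields,
       regressions = regressions, demands = demands,
       ref = ref, nwl = nwl, pot = pot, summary = summary)
}
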