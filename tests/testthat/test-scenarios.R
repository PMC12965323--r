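pipeline_parts <- function(w, config = default_config(), regs = NULL) {
  suit <- classify_suitability(w$grass, config)
  yields <- build_yield_table(w, suit, config)
  if (is.null(regs)) regs <- fit_world_regressions(w)
  demands <- annual_irrigation_demand(w, suit, regs, config)
  list(suit = suit, yields = yields, demands = demands)
}

unit_regs <- tibble::tibble(crop = "crop_1", system = "all", slope = 1,
                            intercept = 0, r2 = 1, n = 2)

test_that("a world with CI = 1 has no reference MC area", {
  w <- make_world()
  w$crops$harvested_area_ha <- w$crops$physical_area_ha
  p <- pipeline_parts(w, regs = unit_regs)
  ref <- build_ref(w, p$suit, p$yields, p$demands)
  mc <- ref$areas[ref$areas$system %in%
                    c("rainfed_mc", "irrigated_mc",
                      "irrigation_enabled_mc"), ]
  expect_equal(sum(mc$area_ha), 0)
  # production = sum physical x main yield
  expected <- sum(w$crops$physical_area_ha *
                    p$yields$y_main[match(
                      paste(w$crops$cell_id, w$crops$crop, w$crops$regime),
                      paste(p$yields$cell_id, p$yields$crop,
                            p$yields$regime))])
  expect_equal(sum(ref$areas$production_t), expected, tolerance = 1e-12)
})

test_that("reference accounting matches hand arithmetic", {
  # one cell-crop: 100 ha irrigated at CI 1.5, y_main 4, y_off 2
  w <- make_world()
  w$crops <- w$crops[w$crops$cell_id == 1, ]
  w$crops$physical_area_ha <- ifelse(w$crops$regime == "irrigated", 100, 0)
  w$crops$harvested_area_ha <- ifelse(w$crops$regime == "irrigated", 150, 0)
  w$fallow <- w$fallow[w$fallow$cell_id == 1, ]
  w$grid <- w$grid[1, ]
  w$grid$downstream <- NA_integer_
  w$grass <- w$grass[w$grass$cell_id == 1, ]
  w$systems <- w$systems[w$systems$cell_id == 1, ]
  w$nonag <- w$nonag[w$nonag$cell_id == 1, ]
  suit <- classify_suitability(w$grass)
  yields <- tidyr::expand_grid(cell_id = 1L, crop = "crop_1",
                               regime = c("irrigated", "rainfed")) |>
    dplyr::mutate(y_main = 4, y_off = 2, y_annual_single = 4,
                  y_annual_mc = 6)
  regs <- tibble::tibble(crop = "crop_1", slope = 1, intercept = 0)
  demands <- annual_irrigation_demand(w, suit, regs)
  ref <- build_ref(w, suit, yields, demands)
  a <- ref$areas
  expect_equal(a$area_ha[a$system == "irrigated_mc"], 50)
  expect_equal(a$area_ha[a$system == "irrigated_single"], 50)
  expect_equal(sum(a$production_t), 50 * 4 + 50 * 6)
})

test_that("reference production equals a per-cell loop oracle", {
  w <- generate_world(seed = 14, n_cells = 50, n_basins = 4)
  p <- pipeline_parts(w)
  ref <- build_ref(w, p$suit, p$yields, p$demands)
  expect_equal(sum(ref$areas$production_t),
               ref_production_oracle(w, p$suit, p$yields),
               tolerance = 1e-9)
})

test_that("full suitability sends all active cropland to MC in NWL", {
  w <- make_world()   # both regimes suitable everywhere
  p <- pipeline_parts(w, regs = unit_regs)
  nwl <- build_nwl(w, p$suit, p$yields, p$demands)
  tot <- scenario_area_totals(nwl)
  mc <- sum(tot$area_ha[tot$system %in% c("rainfed_mc", "irrigated_mc")])
  expect_equal(mc, sum(w$crops$physical_area_ha))
  expect_equal(sum(tot$area_ha[tot$system %in%
                                 c("rainfed_single", "irrigated_single",
                                   "irrigation_enabled_mc")]), 0)
})

test_that("without suitable cells NWL keeps the reference layout", {
  grass <- tidyr::expand_grid(cell_id = 1:2,
                              regime = c("rainfed", "irrigated"),
                              month = 1:12) |>
    dplyr::mutate(gpp = ifelse(regime == "irrigated", 90, 50), et_mm = 50)
  w <- make_world(grass = grass)
  w$crops$harvested_area_ha <- w$crops$physical_area_ha * 1.2
  p <- pipeline_parts(w, regs = unit_regs)
  nwl <- build_nwl(w, p$suit, p$yields, p$demands)
  ref <- build_ref(w, p$suit, p$yields, p$demands)
  expect_equal(nwl$areas$area_ha, ref$areas$area_ha)
  expect_equal(nwl$areas$production_t, ref$areas$production_t)
})

test_that("irrigation-enabled conversion happens only where it should", {
  w <- generate_world(seed = 15, n_cells = 80, n_basins = 6)
  p <- pipeline_parts(w)
  nwl <- build_nwl(w, p$suit, p$yields, p$demands)
  enabled <- nwl$areas[nwl$areas$system == "irrigation_enabled_mc" &
                         nwl$areas$area_ha > 0, ]
  suit <- tidyr::pivot_wider(
    p$suit[, c("cell_id", "regime", "suitable")],
    names_from = "regime", values_from = "suitable")
  for (cell in unique(enabled$cell_id)) {
    expect_false(suit$rainfed[suit$cell_id == cell])
    expect_true(suit$irrigated[suit$cell_id == cell])
  }
  # stratified bookkeeping: enabled area equals the rainfed area of the
  # irrigated-only stratum
  only <- w$grid$cell_id[w$grid$stratum == "irrigated_only"]
  expected <- sum(w$crops$physical_area_ha[
    w$crops$cell_id %in% only & w$crops$regime == "rainfed"])
  expect_equal(sum(enabled$area_ha), expected, tolerance = 1e-9)
})

test_that("unlimited water makes POT identical to NWL", {
  w <- generate_world(seed = 16, n_cells = 60, n_basins = 5)
  w$grid$runoff_km3 <- w$grid$runoff_km3 * 1e6 + 1
  p <- pipeline_parts(w)
  nwl <- build_nwl(w, p$suit, p$yields, p$demands)
  pot <- build_pot(w, p$suit, p$yields, p$demands)
  expect_identical(pot$areas$area_ha, nwl$areas$area_ha)
  expect_identical(pot$areas$production_t, nwl$areas$production_t)
})

test_that("zero water stops irrigated expansion but not rainfed MC", {
  w <- generate_world(seed = 17, n_cells = 60, n_basins = 5)
  w$grid$runoff_km3 <- 0
  w$nonag$withdrawal_km3 <- 0
  w$nonag$consumption_km3 <- 0
  p <- pipeline_parts(w)
  ref <- build_ref(w, p$suit, p$yields, p$demands)
  pot <- build_pot(w, p$suit, p$yields, p$demands)
  tot_ref <- scenario_area_totals(ref)
  tot_pot <- scenario_area_totals(pot)
  pick <- function(tt, s) tt$area_ha[tt$system == s]
  # no irrigated expansion beyond REF
  expect_equal(pick(tot_pot, "irrigated_mc"), pick(tot_ref, "irrigated_mc"),
               tolerance = 1e-12)
  expect_equal(pick(tot_pot, "irrigation_enabled_mc"), 0)
  # rainfed expansion unaffected
  expect_gt(pick(tot_pot, "rainfed_mc"), pick(tot_ref, "rainfed_mc"))
  # committed demand fully booked to groundwater
  committed <- sum(ref$water$withdrawal_km3[ref$water$purpose == "committed"])
  booked <- sum(pot$water$groundwater_km3[pot$water$purpose == "committed"])
  expect_equal(booked, committed, tolerance = 1e-12)
})

test_that("moderate scarcity scales expansion by the oracle fractions", {
  w <- generate_world(seed = 18, n_cells = 40, n_basins = 3)
  w$grid$runoff_km3 <- w$grid$runoff_km3 * 0.05
  p <- pipeline_parts(w)
  nwl <- build_nwl(w, p$suit, p$yields, p$demands)
  ref <- build_ref(w, p$suit, p$yields, p$demands)
  pot <- build_pot(w, p$suit, p$yields, p$demands)
  alloc <- pot$expansion$requests
  exp_req <- alloc[alloc$purpose == "expansion", ]
  oracle <- oracle_allocate(alloc, w$grid, radius_km = 100)
  expect_equal(exp_req$fraction,
               oracle$fraction[alloc$purpose == "expansion"],
               tolerance = 1e-9)
  # per cell: POT enabled area = fraction x NWL enabled area
  nwl_en <- nwl$areas[nwl$areas$system == "irrigation_enabled_mc", ]
  pot_en <- pot$areas[pot$areas$system == "irrigation_enabled_mc", ]
  f <- setNames(rep(1, nrow(w$grid)), w$grid$cell_id)
  f[as.character(exp_req$cell_id)] <- exp_req$fraction
  expect_equal(pot_en$area_ha,
               nwl_en$area_ha * f[as.character(nwl_en$cell_id)],
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("scenario orderings and conservation hold on random worlds", {
  for (seed in c(21, 22, 23)) {
    w <- generate_world(seed = seed, n_cells = 70, n_basins = 5)
    res <- run_pipeline(w)
    tots <- res$summary$totals
    expect_equal(tots$physical_cropland_ha,
                 rep(tots$physical_cropland_ha[1], 3),
                 tolerance = 1e-9)
    ref <- tots[tots$scenario == "REF", ]
    pot <- tots[tots$scenario == "POT", ]
    nwl <- tots[tots$scenario == "NWL", ]
    mc <- function(t) t$mc_rainfed_ha + t$mc_irrigated_ha
    expect_lte(mc(ref), mc(pot) + 1e-9)
    expect_lte(mc(pot), mc(nwl) + 1e-9)
    expect_lte(ref$production_t, pot$production_t + 1e-6)
    expect_lte(pot$production_t, nwl$production_t + 1e-6)
    expect_lte(pot$irrigation_withdrawal_km3,
               nwl$irrigation_withdrawal_km3 + 1e-12)
    expect_lte(ref$irrigation_withdrawal_km3,
               pot$irrigation_withdrawal_km3 + 1e-12)
    w_all <- dplyr::bind_rows(res$ref$water, res$pot$water, res$nwl$water)
    expect_true(all(w_all$withdrawal_km3 >= w_all$consumption_km3 - 1e-12))
  }
})

test_that("average MC yields exceed single-cropping yields per regime", {
  w <- generate_world(seed = 24, n_cells = 80, n_basins = 5)
  res <- run_pipeline(w)
  sys <- res$summary$systems
  for (sc in unique(sys$scenario)) {
    s <- sys[sys$scenario == sc, ]
    y <- function(name) s$mean_yield[s$system == name]
    if (!is.na(y("rainfed_mc")) && !is.na(y("rainfed_single"))) {
      expect_gte(y("rainfed_mc"), y("rainfed_single"))
    }
  }
})

test_that("summaries are deterministic and re-aggregable", {
  run_once <- function() {
    w <- generate_world(seed = 25, n_cells = 50, n_basins = 4)
    res <- run_pipeline(w)
    dir <- tempfile("summary")
    write_summary(res$summary, dir)
    list(bytes = lapply(file.path(dir, c("systems.csv", "water.csv",
                                         "totals.csv", "summary.json")),
                        readBin, what = "raw", n = 1e6),
         summary = res$summary, dir = dir)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$bytes, b$bytes)
  # any summary CSV re-reads to the same global totals
  sys <- readr::read_csv(file.path(a$dir, "systems.csv"),
                         show_col_types = FALSE)
  re <- sys |>
    dplyr::group_by(scenario) |>
    dplyr::summarise(production_t = sum(production_t), .groups = "drop")
  orig <- a$summary$totals
  expect_equal(re$production_t[match(orig$scenario, re$scenario)],
               orig$production_t, tolerance = 1e-12)
})

test_that("summarize rejects an empty scenario list and NA shares", {
  expect_error(summarize_scenarios(list()), "empty")
  expect_true(is.na(pct_share(5, 0)))
  expect_true(is.na(pct_change(0, 5)))
})
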