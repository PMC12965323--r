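#' Default generation parameters for synthetic worlds
#'
#' Controls the statistical structure of generated worlds. The stratum
#' fractions partition cells by construction into the climatic strata the
#' analysis distinguishes: suitable for multiple cropping already under
#' rainfed conditions, suitable only with irrigation (seasonally dry),
#' and unsuitable (too short a growing period even with water). A share of
#' basins is made dry (very low runoff) so that water scarcity actually
#' binds somewhere.
#'
#' @param n_crops number of crop types
#' @param n_countries number of synthetic countries (latitude bands,
#'   independent of river basins)
#' @param frac_rainfed_suitable,frac_irrigated_only,frac_unsuitable stratum
#'   fractions, must sum to 1
#' @param dry_basin_frac fraction of basins with near-zero runoff
#' @param runoff_mean_km3 mean annual runoff per cell in wet basins
#' @param nonag_cell_frac fraction of cells with non-agricultural demand
#' @param nonag_intensity non-agricultural withdrawal scale relative to mean
#'   cell runoff
#' @param cropland_frac_range range of the cropland fraction of cell area
#' @param fallow_share_range range of the fallow share of cropland
#' @param basin_spread_deg spatial scatter (s.d., degrees) of cells around
#'   their basin centre; ~1 degree is ~111 km, so the default mixes
#'   within-radius and out-of-radius neighbours
#' @param irrigation_hotspots number of irrigation cluster centres
#' @return named list of generation parameters
#' @export
default_world_config <- function(
    n_crops = 4,
    n_countries = 6,
    frac_rainfed_suitable = 0.3,
    frac_irrigated_only = 0.4,
    frac_unsuitable = 0.3,
    dry_basin_frac = 0.25,
    runoff_mean_km3 = 0.05,
    nonag_cell_frac = 0.2,
    nonag_intensity = 0.2,
    cropland_frac_range = c(0.05, 0.45),
    fallow_share_range = c(0.10, 0.30),
    basin_spread_deg = 1.0,
    irrigation_hotspots = 3) {
  list(
    n_crops = as.integer(n_crops),
    n_countries = as.integer(n_countries),
    strata = c(rainfed_suitable = frac_rainfed_suitable,
               irrigated_only = frac_irrigated_only,
               unsuitable = frac_unsuitable),
    dry_basin_frac = dry_basin_frac,
    runoff_mean_km3 = runoff_mean_km3,
    nonag_cell_frac = nonag_cell_frac,
    nonag_intensity = nonag_intensity,
    cropland_frac_range = cropland_frac_range,
    fallow_share_range = fallow_share_range,
    basin_spread_deg = basin_spread_deg,
    irrigation_hotspots = as.integer(irrigation_hotspots)
  )
}

check_world_config <- function(wc) {
  if (abs(sum(wc$strata) - 1) > 1e-9) {
    stop("stratum fractions must sum to 1")
  }
  if (any(wc$strata < 0) || wc$n_crops < 1 || wc$n_countries < 1 ||
      wc$runoff_mean_km3 < 0 || any(wc$cropland_frac_range < 0) ||
      any(wc$fallow_share_range < 0) || any(wc$fallow_share_range > 1)) {
    stop("invalid world configuration: negative areas or out-of-range shares")
  }
  invisible(wc)
}

#' Generate a synthetic gridded world
#'
#' Builds a self-contained input bundle with the statistical structure the
#' multiple-cropping analysis assumes: 0.5-degree-style cells clustered into
#' river basins (random spanning trees with a single outlet per basin),
#' monthly grass GPP and evapotranspiration under rainfed and irrigated
#' conditions (irrigation removes the dry-season limitation, so irrigated
#' GPP >= rainfed GPP in every month), per-crop main-season yields and
#' evapotranspiration components, physical and harvested crop areas split
#' rainfed/irrigated with cropping intensity in [1, 2], fallow land,
#' spatially clustered irrigation-system shares, annual runoff, and
#' non-agricultural water demand. Generation is a pure function of
#' `(seed, n_cells, n_basins, world_config)`.
#'
#' @param seed integer RNG seed
#' @param n_cells number of grid cells (>= n_basins)
#' @param n_basins number of river basins (>= 1)
#' @param world_config generation parameters, see [default_world_config()]
#' @return an `mc_world`: a list of layers
#' \describe{
#'   \item{grid}{cell_id, lat, lon, cell_area_ha, basin_id, downstream
#'     (NA at basin outlets), runoff_km3, country, stratum}
#'   \item{grass}{cell_id, regime, month, gpp, et_mm}
#'   \item{crops}{cell_id, crop, regime, season_start, season_len,
#'     main_yield, et_transp_mm, et_evap_mm, et_intercept_mm,
#'     physical_area_ha, harvested_area_ha}
#'   \item{fallow}{cell_id, fallow_area_ha}
#'   \item{systems}{cell_id, surface, sprinkler, drip (shares summing to 1)}
#'   \item{nonag}{cell_id, withdrawal_km3, consumption_km3}
#' }
#' @export
#' @examples
#' w <- generate_world(seed = 1, n_cells = 40, n_basins = 4)
#' table(w$grid$stratum)
generate_world <- function(seed, n_cells, n_basins,
                           world_config = default_world_config()) {
  stopifnot(n_cells >= n_basins, n_basins >= 1)
  wc <- check_world_config(world_config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  n_cells <- as.integer(n_cells)
  n_basins <- as.integer(n_basins)
  cell_id <- seq_len(n_cells)

  ## --- grid, basins, river forest -----------------------------------------
  basin_lat <- stats::runif(n_basins, -45, 55)
  basin_lon <- stats::runif(n_basins, -170, 170)
  basin_id <- sort(c(seq_len(n_basins),
                     sample.int(n_basins, n_cells - n_basins, replace = TRUE)))
  lat <- basin_lat[basin_id] + stats::rnorm(n_cells, 0, wc$basin_spread_deg)
  lon <- basin_lon[basin_id] + stats::rnorm(n_cells, 0, wc$basin_spread_deg)
  lat <- pmin(pmax(lat, -60), 65)

  downstream <- rep(NA_integer_, n_cells)
  for (b in seq_len(n_basins)) {
    members <- cell_id[basin_id == b]
    if (length(members) == 1) next
    ord <- sample(members)           # first member becomes the outlet
    connected <- ord[1]
    for (i in seq(2, length(ord))) {
      me <- ord[i]
      d <- greatcircle_km(lat[me], lon[me], lat[connected], lon[connected])
      downstream[me] <- connected[which.min(d)]
      connected <- c(connected, me)
    }
  }

  dry_basin <- stats::runif(n_basins) < wc$dry_basin_frac
  runoff_scale <- ifelse(dry_basin[basin_id], 0.002, 1) * wc$runoff_mean_km3
  runoff <- runoff_scale * stats::rlnorm(n_cells, meanlog = -0.5, sdlog = 1)

  country <- as.integer(cut(rank(lat, ties.method = "first"),
                            breaks = wc$n_countries, labels = FALSE))

  grid <- tibble::tibble(
    cell_id = cell_id, lat = lat, lon = lon,
    cell_area_ha = cell_area_ha(lat),
    basin_id = basin_id, downstream = downstream,
    runoff_km3 = runoff,
    country = paste0("country_", country)
  )

  ## --- stratum assignment and monthly grass GPP/ET ------------------------
  stratum <- sample(names(wc$strata), n_cells, replace = TRUE,
                    prob = wc$strata)

  gpp_irr <- matrix(0, n_cells, 12)
  gpp_rf <- matrix(0, n_cells, 12)
  for (i in cell_id) {
    n_warm <- if (stratum[i] == "unsuitable") sample(5:7, 1) else
      sample(10:12, 1)
    warm_start <- sample.int(12, 1)
    warm <- season_months(warm_start, n_warm)
    g <- stats::runif(12, 5, 60)               # cold months stay below 100
    g[warm] <- stats::runif(n_warm, 140, 260)  # warm months safely above
    gpp_irr[i, ] <- g
    g_rf <- g
    n_dry <- switch(stratum[i],
                    rainfed_suitable = sample(0:max(0, n_warm - 9), 1),
                    irrigated_only = sample(4:6, 1),
                    unsuitable = sample(2:4, 1))
    if (n_dry > 0) {
      dry <- warm[season_months(1, n_dry)]     # leading block of warm months
      g_rf[dry] <- stats::runif(n_dry, 10, 80) # water-limited, below 100
    }
    gpp_rf[i, ] <- g_rf
  }
  # grass ET tracks GPP; shared additive term keeps irrigated >= rainfed
  et_base <- matrix(stats::runif(n_cells * 12, 0, 10), n_cells, 12)
  et_irr <- 0.45 * gpp_irr + et_base
  et_rf <- 0.45 * gpp_rf + et_base

  grass <- dplyr::bind_rows(
    tidyr::expand_grid(cell_id = cell_id, month = 1:12) |>
      dplyr::mutate(regime = "rainfed",
                    gpp = gpp_rf[cbind(.data$cell_id, .data$month)],
                    et_mm = et_rf[cbind(.data$cell_id, .data$month)]),
    tidyr::expand_grid(cell_id = cell_id, month = 1:12) |>
      dplyr::mutate(regime = "irrigated",
                    gpp = gpp_irr[cbind(.data$cell_id, .data$month)],
                    et_mm = et_irr[cbind(.data$cell_id, .data$month)])
  ) |>
    dplyr::select("cell_id", "regime", "month", "gpp", "et_mm") |>
    dplyr::arrange(.data$cell_id, .data$regime, .data$month)

  ## --- suitability as the generator itself sees it (for CI and yields) ----
  months_above <- function(m) rowSums(m > 100)
  suit_rf_gen <- months_above(gpp_rf) >= 9
  suit_irr_gen <- months_above(gpp_irr) >= 9

  ## --- crop areas ----------------------------------------------------------
  cropland_frac <- stats::runif(n_cells, wc$cropland_frac_range[1],
                                wc$cropland_frac_range[2])
  fallow_share <- stats::runif(n_cells, wc$fallow_share_range[1],
                               wc$fallow_share_range[2])
  cropland <- cropland_frac * grid$cell_area_ha
  fallow_area <- fallow_share * cropland
  active <- cropland - fallow_area

  hot <- sample.int(n_cells, min(wc$irrigation_hotspots, n_cells))
  dist_hot <- sapply(hot, function(h)
    greatcircle_km(lat, lon, lat[h], lon[h]))
  d_min <- if (is.matrix(dist_hot)) apply(dist_hot, 1, min) else dist_hot
  irr_share <- stats::runif(n_cells, 0.4, 0.95) * exp(-d_min / 500)

  crop_names <- paste0("crop_", seq_len(wc$n_crops))
  crop_share <- matrix(stats::rexp(n_cells * wc$n_crops), n_cells)
  crop_share <- crop_share / rowSums(crop_share)

  mc_adoption <- stats::runif(n_cells, 0.2, 0.8)

  crops_list <- vector("list", wc$n_crops)
  for (k in seq_len(wc$n_crops)) {
    season_start <- sample.int(12, n_cells, replace = TRUE)
    season_len <- sample(4:6, n_cells, replace = TRUE)
    phys <- active * crop_share[, k]
    phys_irr <- phys * irr_share
    phys_rf <- phys - phys_irr

    base_yield <- stats::runif(1, 2, 5)
    season_sum <- function(m) {
      vapply(cell_id, function(i)
        sum(m[i, season_months(season_start[i], season_len[i])]), 0)
    }
    gsum_rf <- season_sum(gpp_rf)
    gsum_irr <- season_sum(gpp_irr)
    noise <- stats::rlnorm(n_cells, 0, 0.15)
    y_rf <- base_yield * (gsum_rf / 900) * noise
    y_irr <- y_rf * ifelse(gsum_rf > 0, gsum_irr / gsum_rf, 1) *
      stats::runif(n_cells, 1.0, 1.4)
    y_irr <- pmax(y_irr, y_rf)

    # crop ET over the irrigated main season; irrigated - rainfed is tied
    # linearly to grass consumptive IWR over the same months so the
    # off-season regression has signal
    grass_iwc <- season_sum(et_irr - et_rf)
    et_crop_rf <- season_sum(et_rf) * stats::runif(n_cells, 0.8, 1.1)
    slope_k <- stats::runif(1, 0.8, 1.3)
    iwc_crop <- pmax(slope_k * grass_iwc +
                       stats::rnorm(n_cells, 0, 5), 0)
    et_crop_irr <- et_crop_rf + iwc_crop

    ci_rf <- 1 + ifelse(suit_rf_gen, mc_adoption * stats::runif(n_cells), 0)
    ci_irr <- 1 + ifelse(suit_irr_gen, mc_adoption * stats::runif(n_cells), 0)

    comp <- function(total) tibble::tibble(
      et_transp_mm = 0.7 * total, et_evap_mm = 0.2 * total,
      et_intercept_mm = 0.1 * total)

    crops_list[[k]] <- dplyr::bind_rows(
      tibble::tibble(cell_id = cell_id, crop = crop_names[k],
                     regime = "rainfed",
                     season_start = season_start, season_len = season_len,
                     main_yield = y_rf, comp(et_crop_rf),
                     physical_area_ha = phys_rf,
                     harvested_area_ha = phys_rf * ci_rf),
      tibble::tibble(cell_id = cell_id, crop = crop_names[k],
                     regime = "irrigated",
                     season_start = season_start, season_len = season_len,
                     main_yield = y_irr, comp(et_crop_irr),
                     physical_area_ha = phys_irr,
                     harvested_area_ha = phys_irr * ci_irr)
    )
  }
  crops <- dplyr::bind_rows(crops_list) |>
    dplyr::arrange(.data$cell_id, .data$crop, .data$regime)

  ## --- irrigation systems, non-ag demand ----------------------------------
  sys_raw <- matrix(stats::rexp(n_cells * 3), n_cells)
  sys <- sys_raw / rowSums(sys_raw)
  systems <- tibble::tibble(cell_id = cell_id, surface = sys[, 1],
                            sprinkler = sys[, 2], drip = sys[, 3])

  has_nonag <- stats::runif(n_cells) < wc$nonag_cell_frac
  withdrawal <- ifelse(has_nonag,
                       wc$nonag_intensity * wc$runoff_mean_km3 *
                         stats::rlnorm(n_cells, 0, 0.8), 0)
  nonag <- tibble::tibble(
    cell_id = cell_id,
    withdrawal_km3 = withdrawal,
    consumption_km3 = withdrawal * stats::runif(n_cells, 0.3, 0.7))

  grid$stratum <- stratum
  world <- structure(list(
    grid = grid, grass = grass, crops = crops,
    fallow = tibble::tibble(cell_id = cell_id, fallow_area_ha = fallow_area),
    systems = systems, nonag = nonag,
    seed = as.integer(seed), world_config = wc
  ), class = "mc_world")
  validate_world(world)
  world
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Validate a world's layer invariants
#'
#' Checks every structural invariant the pipeline relies on: positive cell
#' areas, unique cell ids, an acyclic river forest with consistent basin
#' labels, non-negative runoff and GPP, irrigated grass GPP >= rainfed GPP in
#' every cell-month, harvested >= physical >= 0 (cropping intensity >= 1),
#' cropland + fallow within the cell area, system shares summing to 1, and
#' non-agricultural consumption <= withdrawal.
#'
#' @param world an `mc_world`
#' @return `world` invisibly; errors on the first violated invariant
#' @export
validate_world <- function(world) {
  g <- world$grid
  stopifnot(!anyDuplicated(g$cell_id), all(g$cell_area_ha > 0))

  # forest check: following downstream pointers must terminate
  down <- g$downstream
  for (start in g$cell_id) {
    seen <- integer(0); cur <- start
    while (!is.na(down[cur])) {
      if (cur %in% seen) stop("river network contains a cycle at cell ", cur)
      seen <- c(seen, cur); cur <- down[cur]
    }
  }
  root_of <- river_roots(g)
  if (any(g$basin_id != g$basin_id[root_of])) {
    stop("cells do not share basin_id with their outlet")
  }
  stopifnot(all(g$runoff_km3 >= 0))

  gr <- world$grass
  stopifnot(all(gr$gpp >= 0), all(gr$et_mm >= 0))
  wide <- tidyr::pivot_wider(gr[, c("cell_id", "regime", "month", "gpp")],
                             names_from = "regime", values_from = "gpp")
  if (any(wide$irrigated < wide$rainfed - 1e-9)) {
    stop("irrigated grass GPP below rainfed GPP")
  }

  cr <- world$crops
  stopifnot(all(cr$physical_area_ha >= 0),
            all(cr$harvested_area_ha >= cr$physical_area_ha - 1e-9),
            all(cr$main_yield >= 0),
            all(cr$season_len >= 1))
  tot <- cr |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(phys = sum(.data$physical_area_ha), .groups = "drop") |>
    dplyr::left_join(world$fallow, by = "cell_id") |>
    dplyr::left_join(g[, c("cell_id", "cell_area_ha")], by = "cell_id")
  if (any(tot$phys + tot$fallow_area_ha > tot$cell_area_ha * (1 + 1e-9))) {
    stop("cropland plus fallow exceeds cell area")
  }

  sy <- world$systems
  share_sum <- sy$surface + sy$sprinkler + sy$drip
  stopifnot(all(abs(share_sum - 1) < 1e-9),
            all(sy$surface >= 0 & sy$sprinkler >= 0 & sy$drip >= 0))

  na_ <- world$nonag
  stopifnot(all(na_$consumption_km3 >= 0),
            all(na_$consumption_km3 <= na_$withdrawal_km3 + 1e-12))
  invisible(world)
}

#' Outlet (root) cell of every cell's drainage path
#' @param grid a world grid tibble with cell_id and downstream
#' @return integer vector: root_of[i] is the outlet cell id of cell i
#' @keywords internal
river_roots <- function(grid) {
  down <- grid$downstream
  root <- grid$cell_id
  repeat {
    nxt <- ifelse(is.na(down[root]), root, down[root])
    if (all(nxt == root)) break
    root <- nxt
  }
  root
}
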