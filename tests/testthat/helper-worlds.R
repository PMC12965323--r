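# Hand-assembled minimal world for exact-arithmetic oracles.
# Defaults: two cells in one basin (cell 1 drains into cell 2), one crop,
# uniform systems, no non-ag demand. Every layer can be overridden.
make_world <- function(grid = NULL, grass = NULL, crops = NULL,
                       fallow = NULL, systems = NULL, nonag = NULL) {
  if (is.null(grid)) {
    grid <- tibble::tibble(
      cell_id = 1:2, lat = c(10, 10.2), lon = c(20, 20),
      cell_area_ha = cell_area_ha(c(10, 10.2)),
      basin_id = c(1L, 1L), downstream = c(2L, NA),
      runoff_km3 = c(1, 1), country = "country_1", stratum = "manual")
  }
  if (is.null(grass)) {
    grass <- tidyr::expand_grid(cell_id = grid$cell_id,
                                regime = c("rainfed", "irrigated"),
                                month = 1:12) |>
      dplyr::mutate(gpp = ifelse(regime == "irrigated", 150, 120),
                    et_mm = ifelse(regime == "irrigated", 80, 60))
  }
  if (is.null(crops)) {
    crops <- tidyr::expand_grid(cell_id = grid$cell_id,
                                crop = "crop_1",
                                regime = c("rainfed", "irrigated")) |>
      dplyr::mutate(season_start = 1L, season_len = 6L,
                    main_yield = ifelse(regime == "irrigated", 5, 3),
                    et_transp_mm = ifelse(regime == "irrigated", 350, 250),
                    et_evap_mm = ifelse(regime == "irrigated", 100, 80),
                    et_intercept_mm = ifelse(regime == "irrigated", 50, 30),
                    physical_area_ha = 100,
                    harvested_area_ha = 100)
  }
  if (is.null(fallow)) {
    fallow <- tibble::tibble(cell_id = grid$cell_id, fallow_area_ha = 0)
  }
  if (is.null(systems)) {
    systems <- tibble::tibble(cell_id = grid$cell_id,
                              surface = 1, sprinkler = 0, drip = 0)
  }
  if (is.null(nonag)) {
    nonag <- tibble::tibble(cell_id = grid$cell_id,
                            withdrawal_km3 = 0, consumption_km3 = 0)
  }
  w <- structure(list(grid = grid, grass = grass, crops = crops,
                      fallow = fallow, systems = systems, nonag = nonag,
                      seed = NA_integer_, world_config = NULL),
                 class = "mc_world")
  validate_world(w)
  w
}

# grid of n cells in a single chain basin, cells spaced `spacing_deg`
# apart in latitude (1 deg ~ 111 km great-circle)
chain_grid <- function(n, runoff = rep(1, n), spacing_deg = 0.2,
                       lat0 = 0) {
  lat <- lat0 + spacing_deg * (seq_len(n) - 1)
  tibble::tibble(
    cell_id = seq_len(n), lat = lat, lon = 0,
    cell_area_ha = cell_area_ha(lat),
    basin_id = 1L,
    downstream = c(seq_len(n)[-1], NA),  # cell i drains into i+1
    runoff_km3 = runoff, country = "country_1", stratum = "manual")
}

# random spanning forest over n cells in b basins, clustered coordinates
random_forest_grid <- function(n, b, seed) {
  set.seed(seed)
  basin_id <- sort(c(seq_len(b), sample.int(b, n - b, replace = TRUE)))
  lat <- stats::runif(b, -40, 50)[basin_id] + stats::rnorm(n, 0, 0.4)
  lon <- stats::runif(b, -150, 150)[basin_id] + stats::rnorm(n, 0, 0.4)
  downstream <- rep(NA_integer_, n)
  for (k in seq_len(b)) {
    members <- which(basin_id == k)
    if (length(members) > 1) {
      ord <- sample(members)
      for (i in seq(2, length(ord))) {
        earlier <- ord[seq_len(i - 1)]
        downstream[ord[i]] <- earlier[sample.int(length(earlier), 1)]
      }
    }
  }
  tibble::tibble(cell_id = seq_len(n), lat = lat, lon = lon,
                 cell_area_ha = cell_area_ha(lat), basin_id = basin_id,
                 downstream = downstream,
                 runoff_km3 = stats::rlnorm(n, -1, 1),
                 country = "country_1", stratum = "manual")
}

# Independent brute-force water allocation simulator. Availability is never
# updated incrementally: after every tapping event it is re-derived from the
# natural discharge and the full event log (source cells lose the whole
# withdrawal, strictly downstream cells lose the consumed fraction).
oracle_allocate <- function(requests, grid, radius_km = 100) {
  n <- nrow(grid)
  natural <- numeric(n)
  # naive recursive discharge: runoff plus discharge of direct upstream
  upstream_of <- function(cell) grid$cell_id[!is.na(grid$downstream) &
                                               grid$downstream == cell]
  disc <- function(cell) {
    ups <- upstream_of(cell)
    grid$runoff_km3[grid$cell_id == cell] +
      (if (length(ups) > 0) sum(vapply(ups, disc, 0)) else 0)
  }
  for (c_ in grid$cell_id) natural[c_] <- disc(c_)

  is_downstream_of <- function(target, source) {
    cur <- grid$downstream[source]
    while (!is.na(cur)) {
      if (cur == target) return(TRUE)
      cur <- grid$downstream[cur]
    }
    FALSE
  }
  events <- list()
  avail_of <- function(cell) {
    a <- natural[cell]
    for (e in events) {
      if (e$source == cell) a <- a - e$w
      else if (is_downstream_of(cell, e$source)) a <- a - e$c
    }
    a
  }
  fraction <- numeric(nrow(requests))
  groundwater <- numeric(nrow(requests))
  for (r in seq_len(nrow(requests))) {
    cell <- requests$cell_id[r]
    wd <- requests$withdrawal_km3[r]
    cd <- requests$consumption_km3[r]
    if (wd <= 0) { fraction[r] <- 1; next }
    kappa <- cd / wd
    me <- grid[grid$cell_id == cell, ]
    cand <- grid[grid$basin_id == me$basin_id, ]
    d <- geosphere::distHaversine(cbind(me$lon, me$lat),
                                  cbind(cand$lon, cand$lat)) / 1000
    nbrs <- cand$cell_id[d <= radius_km][order(d[d <= radius_km],
                                               cand$cell_id[d <= radius_km])]
    remaining <- wd
    for (s in nbrs) {
      if (remaining <= 0) break
      cap <- avail_of(s)
      if (kappa > 0) {
        ds_cells <- grid$cell_id[vapply(grid$cell_id, is_downstream_of, TRUE,
                                        source = s) &
                                   grid$cell_id != s]
        ds_cells <- setdiff(ds_cells, s)
        if (length(ds_cells) > 0) {
          cap <- min(cap, min(vapply(ds_cells, avail_of, 0)) / kappa)
        }
      }
      w <- min(remaining, cap)
      if (w <= 0) next
      events[[length(events) + 1]] <- list(source = s, w = w, c = kappa * w)
      remaining <- remaining - w
    }
    granted <- wd - remaining
    if (requests$purpose[r] == "expansion") {
      fraction[r] <- if (remaining <= 0) 1 else granted / wd
    } else {
      groundwater[r] <- remaining
      fraction[r] <- 1
    }
  }
  list(fraction = fraction, groundwater = groundwater,
       natural = natural)
}

# loop-based expected REF production for one scenario result
ref_production_oracle <- function(world, suitability, yields) {
  total <- 0
  for (i in seq_len(nrow(world$crops))) {
    row <- world$crops[i, ]
    y <- yields[yields$cell_id == row$cell_id & yields$crop == row$crop &
                  yields$regime == row$regime, ]
    mc <- if (row$physical_area_ha > 0) {
      min(max(row$harvested_area_ha / row$physical_area_ha - 1, 0), 1)
    } else 0
    a_mc <- row$physical_area_ha * mc
    total <- total + (row$physical_area_ha - a_mc) * y$y_main +
      a_mc * y$y_annual_mc
  }
  total
}

scenario_area_totals <- function(res) {
  stats::aggregate(area_ha ~ system, data = res$areas, FUN = sum)
}
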