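#' Route runoff to discharge along the river network
#'
#' Natural discharge of a cell is its own runoff plus the discharge of all
#' direct upstream cells, computed in topological order from headwaters to
#' basin outlets.
#'
#' @param grid a world grid tibble (cell_id, downstream, runoff_km3, ...)
#' @return list of class `mc_discharge`: `natural` and `available`
#'   discharge vectors (km3/yr, indexed by cell_id), both equal until
#'   allocation starts
#' @export
#' @examples
#' g <- tibble::tibble(cell_id = 1:3, downstream = c(2L, 3L, NA),
#'                     runoff_km3 = c(1, 1, 1))
#' route_discharge(g)$natural  # 1 2 3
route_discharge <- function(grid) {
  n <- nrow(grid)
  down <- grid$downstream
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; cur <- grid$cell_id[i]
    while (!is.na(down[cur])) {
      d <- d + 1L
      if (d > n) stop("river network contains a cycle")
      cur <- down[cur]
    }
    depth[grid$cell_id[i]] <- d
  }
  disc <- numeric(n)
  disc[grid$cell_id] <- grid$runoff_km3
  for (cell in grid$cell_id[order(depth[grid$cell_id], decreasing = TRUE)]) {
    if (!is.na(down[cell])) disc[down[cell]] <- disc[down[cell]] + disc[cell]
  }
  structure(list(natural = disc, available = disc), class = "mc_discharge")
}

# strict downstream chain per cell (list indexed by cell_id)
downstream_paths <- function(grid) {
  down <- grid$downstream
  lapply(grid$cell_id, function(cell) {
    path <- integer(0); cur <- down[cell]
    while (!is.na(cur)) {
      path <- c(path, cur)
      cur <- down[cur]
    }
    path
  })
}

#' Water-accessible neighbourhood of a cell
#'
#' Cells of the same river basin whose centres lie within the access radius
#' (great-circle distance), ordered nearest-first with ties broken by cell
#' id. Always contains the cell itself.
#'
#' @param cell requesting cell id
#' @param grid world grid tibble
#' @param radius_km access radius in km (default 100)
#' @return integer vector of cell ids, nearest first
#' @export
neighborhood <- function(cell, grid, radius_km = 100) {
  stopifnot(radius_km > 0)
  me <- grid[grid$cell_id == cell, ]
  cand <- grid[grid$basin_id == me$basin_id, ]
  d <- greatcircle_km(me$lat, me$lon, cand$lat, cand$lon)
  keep <- d <= radius_km
  ord <- order(d[keep], cand$cell_id[keep])
  cand$cell_id[keep][ord]
}

#' Order allocation requests by priority
#'
#' Non-agricultural demands first, then committed irrigation, then
#' expansion requests by descending rank key (ties by cell id).
#'
#' @param requests tibble (cell_id, purpose, withdrawal_km3,
#'   consumption_km3, rank_key)
#' @return the requests, sorted
#' @export
sort_requests <- function(requests) {
  stopifnot(all(requests$purpose %in% c("non_ag", "committed", "expansion")))
  cls <- match(requests$purpose, c("non_ag", "committed", "expansion"))
  requests[order(cls, -requests$rank_key, requests$cell_id), ]
}

#' Allocate water to prioritised requests along the river network
#'
#' Processes requests strictly in priority order. Each request withdraws
#' from the available discharge of its neighbourhood cells, nearest source
#' first. A withdrawal removes the full withdrawn volume from the source
#' cell's availability; strictly downstream cells lose only the consumed
#' fraction, because the unconsumed remainder returns to the river at the
#' source's downstream neighbour. A source withdrawal is capped so that no
#' downstream availability turns negative. Shortfalls of non-agricultural
#' and committed requests are booked as non-renewable groundwater (those
#' users are always fully served); expansion requests receive a fulfilled
#' fraction in [0, 1] and no groundwater.
#'
#' @param requests tibble (cell_id, purpose in non_ag/committed/expansion,
#'   withdrawal_km3, consumption_km3 <= withdrawal_km3, rank_key), already
#'   sorted as by [sort_requests()]
#' @param state an `mc_discharge` from [route_discharge()], freshly routed
#' @param grid world grid tibble
#' @param radius_km access radius (default 100)
#' @return list of class `mc_allocation`:
#'   `requests` with columns granted_km3, fraction, groundwater_km3,
#'   consumption_surface_km3 appended; `events` (request, source_cell,
#'   withdrawal_km3, consumption_km3); `state` the final discharge state
#' @export
allocate <- function(requests, state, grid, radius_km = 100) {
  stopifnot(inherits(state, "mc_discharge"))
  if (nrow(requests) > 0) {
    sorted <- sort_requests(requests)
    if (!identical(sorted$cell_id, requests$cell_id) ||
        !identical(sorted$purpose, requests$purpose)) {
      stop("requests are not in priority order; use sort_requests()")
    }
  }
  if (any(requests$consumption_km3 > requests$withdrawal_km3 + 1e-12)) {
    stop("request consumption exceeds withdrawal")
  }
  avail <- state$available
  paths <- downstream_paths(grid)
  nbr_cache <- list()
  ev_req <- integer(0); ev_src <- integer(0)
  ev_w <- numeric(0); ev_c <- numeric(0)

  n_req <- nrow(requests)
  granted <- numeric(n_req); groundwater <- numeric(n_req)
  fraction <- numeric(n_req)
  for (r in seq_len(n_req)) {
    cell <- requests$cell_id[r]
    wd <- requests$withdrawal_km3[r]
    cd <- requests$consumption_km3[r]
    if (wd <= 0) { fraction[r] <- 1; next }
    kappa <- cd / wd
    key <- as.character(cell)
    if (is.null(nbr_cache[[key]])) {
      nbr_cache[[key]] <- neighborhood(cell, grid, radius_km)
    }
    remaining <- wd
    for (s in nbr_cache[[key]]) {
      if (remaining <= 0) break
      ds <- paths[[s]]
      cap <- avail[s]
      if (kappa > 0 && length(ds) > 0) {
        cap <- min(cap, min(avail[ds]) / kappa)
      }
      w <- min(remaining, cap)
      if (w <= 0) next
      avail[s] <- avail[s] - w
      if (length(ds) > 0) avail[ds] <- avail[ds] - kappa * w
      remaining <- remaining - w
      ev_req <- c(ev_req, r); ev_src <- c(ev_src, s)
      ev_w <- c(ev_w, w); ev_c <- c(ev_c, kappa * w)
    }
    if (any(avail < -1e-9)) {
      stop("internal consistency error: negative availability")
    }
    avail[avail < 0] <- 0
    granted[r] <- wd - remaining
    if (requests$purpose[r] == "expansion") {
      fraction[r] <- if (remaining <= 0) 1 else granted[r] / wd
    } else {
      groundwater[r] <- remaining
      fraction[r] <- 1
    }
  }
  out <- requests
  out$granted_km3 <- granted
  out$fraction <- fraction
  out$groundwater_km3 <- groundwater
  out$consumption_surface_km3 <- ifelse(requests$withdrawal_km3 > 0,
                                        granted / requests$withdrawal_km3 *
                                          requests$consumption_km3, 0)
  state$available <- avail
  structure(list(
    requests = out,
    events = tibble::tibble(request = ev_req, source_cell = ev_src,
                            withdrawal_km3 = ev_w, consumption_km3 = ev_c),
    state = state
  ), class = "mc_allocation")
}

#' Rank cells for irrigation expansion
#'
#' The rank key of a cell is the total yield gain from irrigating it with
#' multiple cropping: the sum over crops of physical crop area times the
#' difference between the annual irrigated multiple-cropping yield and the
#' annual rainfed yield under the reference cropping system (main-season
#' yield plus the reference multiple-cropping share of the off-season
#' yield), in t DM per cell. Higher keys are served first within a basin.
#'
#' @param world an `mc_world`
#' @param yields annual yield table from [build_yield_table()]
#' @return tibble (cell_id, rank_key) sorted by descending key, ties by
#'   cell id
#' @export
rank_expansion_cells <- function(world, yields) {
  areas <- world$crops |>
    dplyr::group_by(.data$cell_id, .data$crop) |>
    dplyr::summarise(
      physical_area_ha = sum(.data$physical_area_ha),
      .groups = "drop")
  ref_rf <- world$crops |>
    dplyr::filter(.data$regime == "rainfed") |>
    dplyr::mutate(mc_share = mc_share_safe(.data$physical_area_ha,
                                           .data$harvested_area_ha)) |>
    dplyr::select("cell_id", "crop", "mc_share")
  wide <- yields |>
    dplyr::select("cell_id", "crop", "regime", "y_main", "y_off",
                  "y_annual_mc") |>
    tidyr::pivot_wider(names_from = "regime",
                       values_from = c("y_main", "y_off", "y_annual_mc"))
  wide |>
    dplyr::left_join(ref_rf, by = c("cell_id", "crop")) |>
    dplyr::left_join(areas, by = c("cell_id", "crop")) |>
    dplyr::mutate(
      y_rf_ref = .data$y_main_rainfed +
        .data$mc_share * .data$y_off_rainfed,
      gain = .data$physical_area_ha *
        (.data$y_annual_mc_irrigated - .data$y_rf_ref)) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(rank_key = sum(.data$gain), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$rank_key), .data$cell_id)
}
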