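world_layer_files <- function() {
  c(grid = "grid.csv", grass = "grass.csv", crops = "crops.csv",
    fallow = "fallow.csv", systems = "systems.csv", nonag = "nonag.csv")
}

world_layer_columns <- function() {
  list(
    grid = c("cell_id", "lat", "lon", "cell_area_ha", "basin_id",
             "downstream", "runoff_km3", "country", "stratum"),
    grass = c("cell_id", "regime", "month", "gpp", "et_mm"),
    crops = c("cell_id", "crop", "regime", "season_start", "season_len",
              "main_yield", "et_transp_mm", "et_evap_mm", "et_intercept_mm",
              "physical_area_ha", "harvested_area_ha"),
    fallow = c("cell_id", "fallow_area_ha"),
    systems = c("cell_id", "surface", "sprinkler", "drip"),
    nonag = c("cell_id", "withdrawal_km3", "consumption_km3")
  )
}

#' Write a world to a run directory
#'
#' One tidy CSV per layer (full double precision) plus a YAML file with the
#' generation parameters and seed. [load_world()] restores the bundle;
#' the round trip is exact to within float-printing precision (1e-12).
#'
#' @param world an `mc_world`
#' @param dir directory (created if missing)
#' @return `dir` invisibly
#' @export
world_to_files <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- world_layer_files()
  for (layer in names(files)) {
    readr::write_csv(world[[layer]], file.path(dir, files[[layer]]))
  }
  meta <- list(seed = world$seed, world_config = world$world_config)
  meta$world_config$strata <- as.list(meta$world_config$strata)
  yaml::write_yaml(meta, file.path(dir, "world.yaml"))
  invisible(dir)
}

#' @rdname world_to_files
#' @export
load_world <- function(dir) {
  files <- world_layer_files()
  missing <- names(files)[!file.exists(file.path(dir, files))]
  if (length(missing) > 0) {
    stop("missing world layer file(s): ", paste(missing, collapse = ", "))
  }
  cols <- world_layer_columns()
  layers <- lapply(names(files), function(layer) {
    x <- readr::read_csv(file.path(dir, files[[layer]]),
                         show_col_types = FALSE, progress = FALSE)
    need <- cols[[layer]]
    if (!all(need %in% names(x))) {
      stop("layer '", layer, "' is missing column(s): ",
           paste(setdiff(need, names(x)), collapse = ", "))
    }
    x[, need]
  })
  names(layers) <- names(files)
  layers$grid$cell_id <- as.integer(layers$grid$cell_id)
  layers$grid$downstream <- as.integer(layers$grid$downstream)
  layers$grid$basin_id <- as.integer(layers$grid$basin_id)

  meta_path <- file.path(dir, "world.yaml")
  seed <- NA_integer_; wcfg <- NULL
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    seed <- meta$seed
    wcfg <- meta$world_config
    if (!is.null(wcfg$strata)) wcfg$strata <- unlist(wcfg$strata)
  }
  world <- structure(c(layers, list(seed = seed, world_config = wcfg)),
                     class = "mc_world")
  validate_world(world)
  world
}

#' @export
print.mc_world <- function(x, ...) {
  cat("<mc_world> ", nrow(x$grid), " cells, ",
      length(unique(x$grid$basin_id)), " basins, ",
      length(unique(x$crops$crop)), " crops, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
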