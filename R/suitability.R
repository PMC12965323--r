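#' Count growing-period months
#'
#' A month counts as a growing-period month when monthly grass GPP strictly
#' exceeds the threshold (a value exactly at the threshold does not count).
#' With `consecutive = TRUE` the length of the longest run of qualifying
#' months (December wrapping into January) is returned instead of the plain
#' count; the default is the plain count.
#'
#' @param gpp_12 numeric vector of 12 monthly grass GPP values
#'   (g C m-2 month-1), all non-negative
#' @param threshold growing-period threshold (default 100 g C m-2 month-1)
#' @param consecutive count the longest consecutive run instead of all months
#' @return integer in 0..12
#' @export
#' @examples
#' growing_period_months(rep(150, 12))        # 12
#' growing_period_months(c(rep(101, 9), 0, 0, 0))  # 9
#' growing_period_months(rep(100, 12))        # 0: strictly "exceeds"
growing_period_months <- function(gpp_12, threshold = 100,
                                  consecutive = FALSE) {
  if (length(gpp_12) != 12) {
    stop("gpp_12 must have exactly 12 monthly values, got ", length(gpp_12))
  }
  if (any(is.na(gpp_12)) || any(gpp_12 < 0)) {
    stop("gpp_12 must be non-negative and free of missing values")
  }
  ok <- gpp_12 > threshold
  if (!consecutive) return(sum(ok))
  if (all(ok)) return(12L)
  # longest run on the circularly doubled sequence, capped at 12
  r <- rle(c(ok, ok))
  runs <- r$lengths[r$values]
  if (length(runs) == 0) return(0L)
  as.integer(min(max(runs), 12L))
}

#' Classify multiple-cropping suitability
#'
#' A cell is suitable for multiple cropping under a water regime when at
#' least `min_growing_months` months of its monthly grass GPP under that
#' regime exceed the GPP threshold. Irrigated suitability is evaluated on
#' grass GPP simulated with unlimited irrigation supply; actual water limits
#' enter only later through the allocation stage.
#'
#' @param grass long tibble with columns cell_id, regime, month, gpp (the
#'   `grass` layer of a world)
#' @param config an `mc_config` (see [default_config()]); relevant keys:
#'   gpp_threshold, min_growing_months, consecutive_months
#' @return tibble (cell_id, regime, growing_months, suitable)
#' @export
classify_suitability <- function(grass, config = default_config()) {
  config <- validate_config(config)
  stopifnot(all(c("cell_id", "regime", "month", "gpp") %in% names(grass)))
  grass |>
    dplyr::arrange(.data$cell_id, .data$regime, .data$month) |>
    dplyr::group_by(.data$cell_id, .data$regime) |>
    dplyr::summarise(
      growing_months = growing_period_months(
        .data$gpp, config$gpp_threshold, config$consecutive_months),
      .groups = "drop") |>
    dplyr::mutate(suitable = .data$growing_months >= config$min_growing_months)
}

#' Convert the GPP threshold to dry matter per hectare
#'
#' Translates a grass GPP threshold in g C m-2 into the equivalent
#' above-ground dry-matter productivity in t DM ha-1, assuming a fixed
#' carbon fraction of dry matter. 100 g C m-2 at a carbon fraction of 0.45
#' corresponds to about 2.2 t DM ha-1.
#'
#' @param threshold_gC_m2 threshold in g C m-2
#' @param carbon_fraction g carbon per g dry matter, in (0, 1]
#' @return threshold in t DM ha-1
#' @export
#' @examples
#' gpp_threshold_in_dm(100)       # ~2.22
#' gpp_threshold_in_dm(45, 0.45)  # 1
gpp_threshold_in_dm <- function(threshold_gC_m2, carbon_fraction = 0.45) {
  if (!is.numeric(carbon_fraction) || carbon_fraction <= 0 ||
      carbon_fraction > 1) {
    stop("carbon_fraction must lie in (0, 1]")
  }
  stopifnot(threshold_gC_m2 >= 0)
  # g m-2 -> t ha-1 is a factor 0.01 (1 g/m2 = 10 kg/ha)
  threshold_gC_m2 / carbon_fraction * 0.01
}
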