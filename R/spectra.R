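#' Log2 dry-mass size class
#'
#' The size class of an individual of dry mass `m` ug is the integer `n` with
#' `2^n <= m < 2^(n+1)` (half-open, lower-inclusive): class 4 spans
#' [16, 32) ug. Implemented as `floor(log2(m))` with an explicit boundary
#' correction so exact powers of two land in the class whose lower bound they
#' equal, immune to floating-point log round-off.
#'
#' @param dm_ug Positive dry mass(es) in ug.
#' @return Integer class index (vectorized).
#' @examples
#' size_class(16) # 4
#' size_class(1)  # 0
#' @export
size_class <- function(dm_ug) {
  if (any(!is.finite(dm_ug)) || any(dm_ug <= 0)) {
    abort("size_class() needs strictly positive finite dry masses")
  }
  n <- floor(log2(dm_ug))
  # boundary correction: log2 may land an exact power of two a ULP off
  n <- ifelse(2^(n + 1) <= dm_ug, n + 1, n)
  n <- ifelse(2^n > dm_ug, n - 1, n)
  as.integer(n)
}

#' Size class width
#'
#' Class `n` spans `[2^n, 2^(n+1))` ug, so its width is `2^n` ug (class 4 is
#' 16 ug wide). This is the normalization divisor of the NBSS.
#'
#' @param n Integer class index (vectorized).
#' @return Width in ug.
#' @examples
#' class_width(4) # 16
#' @export
class_width <- function(n) {
  2^n
}

#' Build abundance and biomass size spectra
#'
#' Bins every organism record into its log2 dry-mass class and sums
#' `count_weight` (abundance) and `count_weight * dry_mass_ug` (biomass) per
#' class, standardized to 0.1 m^2 with the gear-specific area factor. Classes
#' with no members are absent, not zero. One spectrum row per
#' (fjord, station[, group]) and class.
#'
#' @param samples A `station_samples` object with `dry_mass_ug` filled (see
#'   [compute_dry_mass()]), or an organism tibble already joined to
#'   `sampled_area_cm2`.
#' @param by_group Keep faunal components (`group`) separate? Default `TRUE`;
#'   use [combine_components()] to merge them.
#' @return A `size_spectrum` tibble with columns `fjord_id`, `station_id`,
#'   (`group`,) `class_index`, `abundance`, `biomass_ug`, all per 0.1 m^2.
#' @export
build_spectra <- function(samples, by_group = TRUE) {
  if (inherits(samples, "station_samples")) {
    org <- dplyr::left_join(
      samples$organisms,
      dplyr::select(samples$stations, "fjord_id", "station_id", "gear",
                    "sampled_area_cm2"),
      by = c("fjord_id", "station_id", "gear")
    )
  } else {
    org <- tibble::as_tibble(samples)
    require_columns(org, c("fjord_id", "station_id", "group", "count_weight",
                           "dry_mass_ug", "sampled_area_cm2"), "organisms")
  }
  if (anyNA(org$dry_mass_ug)) {
    abort("every record needs dry_mass_ug; run compute_dry_mass() first")
  }
  org$class_index <- size_class(org$dry_mass_ug)
  org$.scale <- area_factor(org$sampled_area_cm2)
  keys <- c("fjord_id", "station_id", if (by_group) "group", "class_index")
  out <- dplyr::summarise(
    dplyr::group_by(org, dplyr::across(dplyr::all_of(keys))),
    abundance = sum(.data$count_weight * .data$.scale),
    biomass_ug = sum(.data$count_weight * .data$dry_mass_ug * .data$.scale),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(keys)))
  new_size_spectrum(out)
}

new_size_spectrum <- function(df, unit_area_cm2 = 1000) {
  structure(
    df,
    class = c("size_spectrum", class(tibble::as_tibble(df))),
    unit_area_cm2 = unit_area_cm2
  )
}

#' Combine faunal components of a spectrum
#'
#' Sums meiofauna, macrofaunal nematodes and macrofauna (or any set of
#' component spectra) classwise, per station: abundances and biomasses add,
#' class support is the union. All inputs must be standardized to the same
#' unit area. Accepts either one grouped spectrum or several spectra.
#'
#' @param ... One or more `size_spectrum` tibbles.
#' @return A `size_spectrum` tibble without a `group` column.
#' @export
combine_components <- function(...) {
  parts <- list(...)
  areas <- vapply(parts, function(p) {
    a <- attr(p, "unit_area_cm2")
    if (is.null(a)) 1000 else a
  }, numeric(1))
  if (length(unique(areas)) > 1) {
    abort("cannot combine spectra standardized to different unit areas")
  }
  df <- dplyr::bind_rows(lapply(parts, function(p) {
    tibble::as_tibble(as.data.frame(p))
  }))
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$fjord_id, .data$station_id, .data$class_index),
    abundance = sum(.data$abundance),
    biomass_ug = sum(.data$biomass_ug),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$fjord_id, .data$station_id, .data$class_index)
  new_size_spectrum(out, unit_area_cm2 = areas[1])
}

#' Normalize a biomass spectrum by class width
#'
#' Adds the normalized biomass `nb = biomass_ug / 2^class_index` (biomass in
#' a class divided by the class width in ug, so e.g. class-4 biomass is
#' divided by 16). De-normalizing (`nb * 2^n`) recovers the biomass spectrum
#' exactly.
#'
#' @param spectrum A `size_spectrum` tibble.
#' @return The spectrum with an `nb` column (dimensionless density per ug).
#' @export
normalize_spectrum <- function(spectrum) {
  spectrum$nb <- spectrum$biomass_ug / class_width(spectrum$class_index)
  spectrum
}

#' Pool station spectra to fjord level
#'
#' Classwise mean (default, mirroring replicate-station averaging) or sum of
#' the station spectra within each fjord. Absent classes are treated as
#' absent, not zero: the mean divides by the number of stations in the fjord,
#' so a class seen at one of three stations contributes a third of its value.
#'
#' @param spectrum A station-level `size_spectrum` (no `group` column).
#' @param method `"mean"` (default) or `"sum"`.
#' @return A fjord-level `size_spectrum` with `station_id = "pooled"`.
#' @export
pool_stations <- function(spectrum, method = c("mean", "sum")) {
  method <- match.arg(method)
  n_st <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(spectrum), .data$fjord_id),
    n_stations = dplyr::n_distinct(.data$station_id), .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(spectrum), .data$fjord_id, .data$class_index),
    abundance = sum(.data$abundance),
    biomass_ug = sum(.data$biomass_ug),
    .groups = "drop"
  )
  if (method == "mean") {
    out <- dplyr::left_join(out, n_st, by = "fjord_id")
    out$abundance <- out$abundance / out$n_stations
    out$biomass_ug <- out$biomass_ug / out$n_stations
    out$n_stations <- NULL
  }
  out <- dplyr::mutate(out, station_id = "pooled", .after = "fjord_id")
  new_size_spectrum(out, unit_area_cm2 = attr(spectrum, "unit_area_cm2"))
}

#' Total benthic dry mass per station
#'
#' Converts summed biomass per 0.1 m^2 to g DM m^-2 (ug per 0.1 m^2 x 10 to
#' reach 1 m^2, then x 1e-6 ug-to-g) and reports the macrofauna share of the
#' total when the spectrum carries a `group` column.
#'
#' @param spectrum A `size_spectrum` tibble (grouped by component or not).
#' @return A tibble with `fjord_id`, `station_id`, `total_g_m2` and, when
#'   components are present, `macrofauna_fraction` (share of the
#'   `macrofauna` group in total DM).
#' @export
total_benthic_dm <- function(spectrum) {
  df <- tibble::as_tibble(as.data.frame(spectrum))
  has_group <- "group" %in% names(df)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$fjord_id, .data$station_id),
    total_g_m2 = sum(.data$biomass_ug) * 10 * 1e-6,
    macrofauna_fraction = if (has_group) {
      sum(.data$biomass_ug[.data$group == "macrofauna"]) / sum(.data$biomass_ug)
    } else {
      NA_real_
    },
    .groups = "drop"
  )
  if (!has_group) out$macrofauna_fraction <- NULL
  out
}
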