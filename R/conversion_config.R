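#' Conversion configuration for dimension-to-mass allometry
#'
#' Bundles every constant used on the path from measured body dimensions to
#' individual dry mass: taxon-specific biovolume shape coefficients
#' (`V = L * W^2 * c`), the specific-gravity factor turning biovolume into wet
#' mass, wet-to-dry mass conversions, direct dimension-to-wet-mass factors for
#' taxa measured without a biovolume step (e.g. Crustacea, Ophiuroidea), and
#' the subsampling rule for abundant species.
#'
#' The shipped coefficient tables are illustrative defaults in the spirit of
#' the classic meiofaunal biovolume coefficients of Feller & Warwick (1988)
#' and compilation-style dry/wet mass ratios (Brey-type); they are *not*
#' measured values and any real analysis should override them with
#' study-specific tables via the arguments below.
#'
#' @param taxon_coefficients Named numeric vector of dimensionless shape
#'   coefficients `c` by taxon, used in the biovolume formula `L * W^2 * c`.
#' @param specific_gravity Wet-mass density factor; biovolume in mm^3 times
#'   this factor gives wet mass in mg (1 mm^3 of water = 1 mg). Default 1.13.
#' @param meiofauna_dm_fraction Dry mass as a fraction of wet mass for
#'   meiofauna and macrofaunal nematodes. Default 0.25.
#' @param macrofauna_dm_factors Named numeric vector of DM/WM ratios by
#'   macrofaunal taxon.
#' @param direct_mass_table Data frame with columns `taxon`, `slope_ug_per_mm`,
#'   `intercept_ug`: linear length-to-wet-mass conversions (`WM[ug] =
#'   intercept + slope * L[mm]`) for taxa whose wet mass is obtained directly
#'   from dimensions rather than via biovolume.
#' @param cylinder_taxa Character vector of taxa whose biovolume uses the
#'   cylinder formula `pi * (W/2)^2 * L` instead of `L * W^2 * c`.
#'   Default `"Nematoda"`.
#' @param subsample_threshold Species with more individuals than this per
#'   sample are subsampled before measurement. Default 250.
#' @param subsample_size Number of individuals measured when subsampling.
#'   Default 200.
#' @param sg_scope Whether the specific-gravity factor applies to all
#'   biovolume-derived wet masses (`"all"`, default) or only to meiofauna
#'   (`"meiofauna"`).
#'
#' @return An object of class `conversion_config` (a named list).
#' @examples
#' cfg <- conversion_config()
#' cfg$specific_gravity
#' @export
conversion_config <- function(taxon_coefficients = default_taxon_coefficients(),
                              specific_gravity = 1.13,
                              meiofauna_dm_fraction = 0.25,
                              macrofauna_dm_factors = default_macrofauna_dm_factors(),
                              direct_mass_table = default_direct_mass_table(),
                              cylinder_taxa = "Nematoda",
                              subsample_threshold = 250L,
                              subsample_size = 200L,
                              sg_scope = c("all", "meiofauna")) {
  sg_scope <- match.arg(sg_scope)
  stopifnot(
    is.numeric(taxon_coefficients), all(taxon_coefficients > 0),
    is.numeric(specific_gravity), specific_gravity > 0,
    meiofauna_dm_fraction > 0,
    all(macrofauna_dm_factors > 0),
    subsample_size <= subsample_threshold
  )
  structure(
    list(
      taxon_coefficients = taxon_coefficients,
      specific_gravity = specific_gravity,
      meiofauna_dm_fraction = meiofauna_dm_fraction,
      macrofauna_dm_factors = macrofauna_dm_factors,
      direct_mass_table = tibble::as_tibble(direct_mass_table),
      cylinder_taxa = cylinder_taxa,
      subsample_threshold = as.integer(subsample_threshold),
      subsample_size = as.integer(subsample_size),
      sg_scope = sg_scope
    ),
    class = "conversion_config"
  )
}

#' Default biovolume shape coefficients (illustrative)
#'
#' Dimensionless `c` in `V = L * W^2 * c` by taxon. Values are plausible
#' defaults of the magnitude used for meiofaunal and small macrofaunal body
#' plans; override with measured coefficients for real data.
#' @return Named numeric vector.
#' @export
default_taxon_coefficients <- function() {
  c(
    Copepoda      = 0.560,
    Ostracoda     = 0.450,
    Kinorhyncha   = 0.295,
    Tardigrada    = 0.614,
    Polychaeta    = 0.530,
    Maldanidae    = 0.530,
    Spionidae     = 0.530,
    Cirratulidae  = 0.530,
    Paraonidae    = 0.530,
    Oweniidae     = 0.530,
    Nephtyidae    = 0.530,
    Cossuridae    = 0.530,
    Onuphidae     = 0.530,
    Mollusca      = 0.700,
    Oligochaeta   = 0.530,
    Sipuncula     = 0.590
  )
}

#' Default macrofauna dry/wet mass factors (illustrative)
#'
#' DM/WM ratios by macrofaunal taxon, compilation-style defaults.
#' @return Named numeric vector.
#' @export
default_macrofauna_dm_factors <- function() {
  c(
    Polychaeta    = 0.155,
    Maldanidae    = 0.155,
    Spionidae     = 0.155,
    Cirratulidae  = 0.155,
    Paraonidae    = 0.155,
    Oweniidae     = 0.155,
    Nephtyidae    = 0.155,
    Cossuridae    = 0.155,
    Onuphidae     = 0.155,
    Mollusca      = 0.085,
    Crustacea     = 0.220,
    Ophiuroidea   = 0.350,
    Oligochaeta   = 0.155,
    Sipuncula     = 0.130,
    Nematoda      = 0.250
  )
}

#' Default direct length-to-wet-mass table (illustrative)
#'
#' Linear conversions `WM[ug] = intercept_ug + slope_ug_per_mm * L[mm]` for
#' taxa whose wet mass is taken from dimensions with published factors rather
#' than via a biovolume formula.
#' @return A tibble with columns `taxon`, `slope_ug_per_mm`, `intercept_ug`.
#' @export
default_direct_mass_table <- function() {
  tibble::tibble(
    taxon = c("Crustacea", "Ophiuroidea"),
    slope_ug_per_mm = c(180, 420),
    intercept_ug = c(0, 0)
  )
}

#' Read or write a conversion configuration as JSON
#'
#' @param path File path.
#' @return `read_conversion_config()` returns a `conversion_config`;
#'   `write_conversion_config()` returns `path` invisibly.
#' @export
read_conversion_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  conversion_config(
    taxon_coefficients = unlist(raw$taxon_coefficients),
    specific_gravity = raw$specific_gravity,
    meiofauna_dm_fraction = raw$meiofauna_dm_fraction,
    macrofauna_dm_factors = unlist(raw$macrofauna_dm_factors),
    direct_mass_table = raw$direct_mass_table,
    cylinder_taxa = raw$cylinder_taxa,
    subsample_threshold = raw$subsample_threshold,
    subsample_size = raw$subsample_size,
    sg_scope = raw$sg_scope
  )
}

#' @rdname read_conversion_config
#' @param config A `conversion_config` object.
#' @export
write_conversion_config <- function(config, path) {
  stopifnot(inherits(config, "conversion_config"))
  out <- unclass(config)
  # named numeric vectors must become JSON objects, not bare arrays
  out$taxon_coefficients <- as.list(out$taxon_coefficients)
  out$macrofauna_dm_factors <- as.list(out$macrofauna_dm_factors)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.conversion_config <- function(x, ...) {
  cat("<conversion_config>\n")
  cat("  specific gravity:", x$specific_gravity,
      "| meiofauna DM fraction:", x$meiofauna_dm_fraction, "\n")
  cat("  taxon biovolume coefficients:", length(x$taxon_coefficients),
      "| macrofauna DM/WM factors:", length(x$macrofauna_dm_factors), "\n")
  cat("  cylinder taxa:", paste(x$cylinder_taxa, collapse = ", "), "\n")
  cat("  subsample:", x$subsample_size, "of >", x$subsample_threshold, "\n")
  invisible(x)
}
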