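#' @keywords internal
GROUP_LEVELS <- c("meiofauna", "macrofauna", "macrofaunal_nematode")

#' @keywords internal
GEAR_LEVELS <- c("van_veen_grab", "syringe_core")

#' @keywords internal
FEEDING_LEVELS <- c(
  "surface_deposit", "subsurface_deposit", "carnivore",
  "omnivore", "suspension", "herbivore", "grazer"
)

# Expected gear per faunal group: meiofauna comes from syringe cores pushed
# into box-corer sediment, everything retained on the 500 um sieve from the
# van Veen grab.
gear_for_group <- function(group) {
  ifelse(group == "meiofauna", "syringe_core", "van_veen_grab")
}

delim_for_path <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

read_table_auto <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  readr::read_delim(
    path,
    delim = delim_for_path(path),
    show_col_types = FALSE,
    progress = FALSE
  )
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "schema violation in ", what, ": missing column(s) ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

fail_rows <- function(bad, what, reason) {
  if (any(bad, na.rm = TRUE)) {
    rows <- which(bad | is.na(bad))
    abort(paste0(
      "schema violation in ", what, ", column ", reason, ": row(s) ",
      paste(head(rows, 10), collapse = ", "),
      if (length(rows) > 10) paste0(" (and ", length(rows) - 10, " more)") else ""
    ))
  }
}

#' Read and validate a per-organism measurement table
#'
#' One row per measured individual (or subsample representative). Mandatory
#' columns: `fjord_id`, `station_id`, `taxon_id`, `group`, `length_mm`,
#' `width_mm`, `count_weight`. Optional: `species`, `genus`, `family`,
#' `is_fragment`, `feeding_type`, `dry_mass_ug`, `gear`. Delimiter is chosen
#' by extension (`.csv` comma, `.tsv`/`.txt` tab). Rows violating the schema
#' are rejected with row-numbered diagnostics.
#'
#' @param path Path to a delimited text file.
#' @return A tibble of organism records with `gear` filled from `group`
#'   where absent.
#' @export
read_organisms <- function(path) {
  df <- read_table_auto(path)
  validate_organisms(df, what = basename(path))
}

#' @rdname read_organisms
#' @param organisms A data frame of organism records to validate in place.
#' @param what Label used in error messages.
#' @export
validate_organisms <- function(organisms, what = "organisms") {
  df <- tibble::as_tibble(organisms)
  require_columns(
    df,
    c("fjord_id", "station_id", "taxon_id", "group",
      "length_mm", "width_mm", "count_weight"),
    what
  )
  for (col in c("species", "genus", "family")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  if (!"is_fragment" %in% names(df)) df$is_fragment <- FALSE
  if (!"feeding_type" %in% names(df)) df$feeding_type <- NA_character_
  if (!"dry_mass_ug" %in% names(df)) df$dry_mass_ug <- NA_real_
  if (!"gear" %in% names(df)) df$gear <- gear_for_group(df$group)

  bad_group <- !(df$group %in% GROUP_LEVELS)
  fail_rows(bad_group, what, "group (unknown label)")
  bad_gear <- !(df$gear %in% GEAR_LEVELS)
  fail_rows(bad_gear, what, "gear (unknown label)")
  bad_feed <- !is.na(df$feeding_type) & !(df$feeding_type %in% FEEDING_LEVELS)
  fail_rows(bad_feed, what, "feeding_type (unknown label)")

  # dimensions must be positive wherever mass still has to be derived
  needs_dims <- is.na(df$dry_mass_ug)
  fail_rows(needs_dims & (is.na(df$length_mm) | df$length_mm <= 0),
            what, "length_mm (must be > 0)")
  fail_rows(needs_dims & (is.na(df$width_mm) | df$width_mm <= 0),
            what, "width_mm (must be > 0)")
  fail_rows(is.na(df$count_weight) | df$count_weight < 1,
            what, "count_weight (must be >= 1)")
  fail_rows(!is.na(df$dry_mass_ug) & df$dry_mass_ug <= 0,
            what, "dry_mass_ug (must be > 0)")
  # a missing fragment flag means the specimen is intact
  df$is_fragment <- !is.na(df$is_fragment) & as.logical(df$is_fragment)
  df
}

#' Read a station metadata table
#'
#' Mandatory columns: `fjord_id`, `station_id`, `gear`, `sampled_area_cm2`.
#' One row per (fjord, station, gear) combination.
#'
#' @param path Path to a delimited text file.
#' @return A tibble of station rows.
#' @export
read_stations <- function(path) {
  df <- read_table_auto(path)
  validate_stations(df, what = basename(path))
}

#' @rdname read_stations
#' @param stations A data frame of station rows to validate in place.
#' @param what Label used in error messages.
#' @export
validate_stations <- function(stations, what = "stations") {
  df <- tibble::as_tibble(stations)
  require_columns(df, c("fjord_id", "station_id", "gear", "sampled_area_cm2"), what)
  fail_rows(!(df$gear %in% GEAR_LEVELS), what, "gear (unknown label)")
  fail_rows(is.na(df$sampled_area_cm2) | df$sampled_area_cm2 <= 0,
            what, "sampled_area_cm2 (must be > 0)")
  df
}

#' Read a station-level environmental covariate table
#'
#' Mandatory columns: `fjord_id`, `station_id`, `temperature_C`, `salinity`,
#' `c_org_pct`, `delta13C`, `chl_a_ug_g`, `cpe_ug_g`, `mud_pct`. Chlorophyll a
#' must not exceed total chloroplastic pigments, and mud content is a
#' percentage.
#'
#' @param path Path to a delimited text file.
#' @return A tibble of environmental profiles.
#' @export
read_environment <- function(path) {
  df <- read_table_auto(path)
  validate_environment(df, what = basename(path))
}

#' @rdname read_environment
#' @param environment_tbl A data frame of environmental rows to validate.
#' @param what Label used in error messages.
#' @export
validate_environment <- function(environment_tbl, what = "environment") {
  df <- tibble::as_tibble(environment_tbl)
  require_columns(
    df,
    c("fjord_id", "station_id", "temperature_C", "salinity", "c_org_pct",
      "delta13C", "chl_a_ug_g", "cpe_ug_g", "mud_pct"),
    what
  )
  fail_rows(df$c_org_pct < 0, what, "c_org_pct (must be >= 0)")
  fail_rows(df$chl_a_ug_g < 0, what, "chl_a_ug_g (must be >= 0)")
  fail_rows(df$chl_a_ug_g > df$cpe_ug_g, what,
            "chl_a_ug_g (cannot exceed cpe_ug_g)")
  fail_rows(df$mud_pct < 0 | df$mud_pct > 100, what, "mud_pct (must be in [0,100])")
  df
}

#' Read a full sample set (organisms plus station metadata)
#'
#' Convenience wrapper bundling [read_organisms()] and [read_stations()] into
#' a `station_samples` object, the unit most downstream functions consume.
#' Every organism row must match a station row on (fjord_id, station_id,
#' gear).
#'
#' @param organisms_path,stations_path Paths to delimited text files.
#' @return A `station_samples` object: a list with tibbles `organisms` and
#'   `stations`.
#' @export
read_samples <- function(organisms_path, stations_path) {
  station_samples(read_organisms(organisms_path), read_stations(stations_path))
}

#' Construct a station_samples object from tibbles
#'
#' @param organisms Organism records (see [read_organisms()] for the schema).
#' @param stations Station rows (see [read_stations()]).
#' @return A `station_samples` object.
#' @export
station_samples <- function(organisms, stations) {
  organisms <- validate_organisms(organisms)
  stations <- validate_stations(stations)
  key <- function(d) paste(d$fjord_id, d$station_id, d$gear, sep = "\r")
  orphan <- !(key(organisms) %in% key(stations))
  if (any(orphan)) {
    abort(paste0(
      "organism row(s) without a matching station record: row(s) ",
      paste(head(which(orphan), 10), collapse = ", ")
    ))
  }
  structure(
    list(organisms = organisms, stations = stations),
    class = "station_samples"
  )
}

#' @export
print.station_samples <- function(x, ...) {
  cat("<station_samples>\n")
  cat("  ", nrow(x$organisms), "organism records,",
      nrow(x$stations), "station/gear rows,",
      dplyr::n_distinct(x$stations$fjord_id), "fjords\n")
  invisible(x)
}

#' Write a sample set back to delimited text
#'
#' Inverse of [read_samples()]: field-for-field round trips are exact for
#' text and logical columns and to full double precision for numerics.
#'
#' @param samples A `station_samples` object.
#' @param organisms_path,stations_path Output file paths (extension selects
#'   the delimiter).
#' @return `samples`, invisibly.
#' @export
write_samples <- function(samples, organisms_path, stations_path) {
  stopifnot(inherits(samples, "station_samples"))
  write_one <- function(df, path) {
    if (delim_for_path(path) == "\t") {
      readr::write_tsv(df, path, progress = FALSE)
    } else {
      readr::write_csv(df, path, progress = FALSE)
    }
  }
  write_one(samples$organisms, organisms_path)
  write_one(samples$stations, stations_path)
  invisible(samples)
}

#' Check a sample set against the standard sampling design
#'
#' Report-only audit of the field design: three stations per fjord, both gear
#' types present at every station, and gear-consistent sampled areas
#' (1000 cm^2 for the 0.1 m^2 van Veen grab, 10 cm^2 for the meiofauna
#' syringe core). Never mutates the data.
#'
#' @param samples A `station_samples` object.
#' @param expected_stations Expected number of stations per fjord (default 3).
#' @return A tibble of flags with columns `fjord_id`, `station_id`, `flag`,
#'   `detail`; zero rows when the design is clean.
#' @export
validate_design <- function(samples, expected_stations = 3L) {
  stopifnot(inherits(samples, "station_samples"))
  st <- samples$stations
  flags <- list()

  per_fjord <- dplyr::summarise(
    dplyr::group_by(st, .data$fjord_id),
    n_stations = dplyr::n_distinct(.data$station_id),
    .groups = "drop"
  )
  bad <- dplyr::filter(per_fjord, .data$n_stations != expected_stations)
  if (nrow(bad) > 0) {
    flags <- c(flags, list(tibble::tibble(
      fjord_id = bad$fjord_id, station_id = NA_character_,
      flag = "station_count",
      detail = paste0(bad$n_stations, " stations (expected ", expected_stations, ")")
    )))
  }

  per_station <- dplyr::summarise(
    dplyr::group_by(st, .data$fjord_id, .data$station_id),
    missing_gear = paste(setdiff(GEAR_LEVELS, .data$gear), collapse = ", "),
    .groups = "drop"
  )
  bad <- dplyr::filter(per_station, nchar(.data$missing_gear) > 0)
  if (nrow(bad) > 0) {
    flags <- c(flags, list(tibble::tibble(
      fjord_id = bad$fjord_id, station_id = bad$station_id,
      flag = "missing_gear",
      detail = paste0("no ", bad$missing_gear, " sample")
    )))
  }

  expected_area <- c(van_veen_grab = 1000, syringe_core = 10)
  anom <- dplyr::filter(
    st, .data$sampled_area_cm2 != expected_area[.data$gear]
  )
  if (nrow(anom) > 0) {
    flags <- c(flags, list(tibble::tibble(
      fjord_id = anom$fjord_id, station_id = anom$station_id,
      flag = "area_anomaly",
      detail = paste0(
        anom$gear, " area ", anom$sampled_area_cm2, " cm2 (expected ",
        expected_area[anom$gear], ")"
      )
    )))
  }

  if (length(flags) == 0) {
    tibble::tibble(
      fjord_id = character(), station_id = character(),
      flag = character(), detail = character()
    )
  } else {
    dplyr::bind_rows(flags)
  }
}
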