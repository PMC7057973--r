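#' Biovolume from length and width
#'
#' `biovolume_feller_warwick()` computes `V = L * W^2 * c` with a
#' taxon-specific dimensionless shape coefficient; `biovolume_cylinder()`
#' computes the cylinder volume `pi * (W/2)^2 * L` used for nematodes.
#' All dimensions in mm, volumes in mm^3. Vectorized.
#'
#' @param length_mm,width_mm Positive body dimensions in mm.
#' @param c_coef Taxon-specific shape coefficient (dimensionless), or a
#'   taxon name to look up in `config$taxon_coefficients`.
#' @param config A [conversion_config()] used for taxon lookups.
#' @return Biovolume in mm^3.
#' @examples
#' biovolume_feller_warwick(2, 1, 0.5) # 1 mm^3
#' biovolume_cylinder(1, 2)            # pi mm^3
#' @export
biovolume_feller_warwick <- function(length_mm, width_mm, c_coef,
                                     config = conversion_config()) {
  if (is.character(c_coef)) {
    missing <- setdiff(unique(c_coef), names(config$taxon_coefficients))
    if (length(missing) > 0) {
      abort(paste0(
        "no biovolume coefficient configured for taxon: ",
        paste(missing, collapse = ", ")
      ))
    }
    c_coef <- unname(config$taxon_coefficients[c_coef])
  }
  stopifnot(all(length_mm > 0), all(width_mm > 0), all(c_coef > 0))
  length_mm * width_mm^2 * c_coef
}

#' @rdname biovolume_feller_warwick
#' @export
biovolume_cylinder <- function(length_mm, width_mm) {
  stopifnot(all(length_mm > 0), all(width_mm > 0))
  pi * (width_mm / 2)^2 * length_mm
}

#' Wet mass from biovolume
#'
#' Multiplies biovolume by the specific-gravity factor (default 1.13).
#' With 1 mm^3 of water weighing 1 mg, a biovolume in mm^3 maps directly to
#' wet mass in mg: `WM[mg] = V[mm^3] * specific_gravity`.
#'
#' @param volume_mm3 Positive biovolume in mm^3.
#' @param config A [conversion_config()].
#' @return Wet mass in mg.
#' @examples
#' wet_mass(1) # 1.13 mg
#' @export
wet_mass <- function(volume_mm3, config = conversion_config()) {
  stopifnot(all(volume_mm3 > 0))
  volume_mm3 * config$specific_gravity
}

#' Dry mass from wet mass
#'
#' Meiofauna and macrofaunal nematodes: `DM = meiofauna_dm_fraction * WM`
#' (default 0.25). Macrofauna: `DM = factor(taxon) * WM` using the configured
#' DM/WM ratios. Input and output share the same mass unit; the pipeline
#' applies this at the microgram stage.
#'
#' @param wm_ug Wet mass (same unit returned; the pipeline uses ug).
#' @param group Faunal group, one of `"meiofauna"`, `"macrofauna"`,
#'   `"macrofaunal_nematode"`. Vectorized with `wm_ug`.
#' @param taxon Taxon name(s), needed for the macrofauna factor lookup.
#' @param config A [conversion_config()].
#' @return Dry mass, same unit as `wm_ug`.
#' @examples
#' dry_mass(4, "meiofauna") # 1
#' @export
dry_mass <- function(wm_ug, group, taxon = NULL, config = conversion_config()) {
  stopifnot(all(wm_ug > 0), all(group %in% GROUP_LEVELS))
  n <- max(length(wm_ug), length(group))
  wm_ug <- rep_len(wm_ug, n)
  group <- rep_len(group, n)
  is_meio <- group %in% c("meiofauna", "macrofaunal_nematode")
  out <- numeric(n)
  out[is_meio] <- config$meiofauna_dm_fraction * wm_ug[is_meio]
  if (any(!is_meio)) {
    if (is.null(taxon)) {
      abort("macrofauna dry mass needs `taxon` for the DM/WM factor lookup")
    }
    taxon <- rep_len(taxon, n)
    missing <- setdiff(unique(taxon[!is_meio]), names(config$macrofauna_dm_factors))
    if (length(missing) > 0) {
      abort(paste0(
        "no macrofauna DM/WM factor configured for taxon: ",
        paste(missing, collapse = ", ")
      ))
    }
    out[!is_meio] <-
      unname(config$macrofauna_dm_factors[taxon[!is_meio]]) * wm_ug[!is_meio]
  }
  out
}

#' Direct dimension-to-wet-mass conversion
#'
#' For taxa (e.g. Crustacea, Ophiuroidea) whose wet mass is obtained from
#' measured dimensions with published linear factors instead of a biovolume
#' formula: `WM[ug] = intercept_ug + slope_ug_per_mm * L[mm]`.
#'
#' @param taxon Taxon name(s) to look up in `config$direct_mass_table`.
#' @param length_mm Body length(s) in mm.
#' @param config A [conversion_config()].
#' @return Wet mass in ug.
#' @export
direct_mass_taxa <- function(taxon, length_mm, config = conversion_config()) {
  stopifnot(all(length_mm > 0))
  tbl <- config$direct_mass_table
  idx <- match(taxon, tbl$taxon)
  if (anyNA(idx)) {
    abort(paste0(
      "no direct mass conversion configured for taxon: ",
      paste(unique(taxon[is.na(idx)]), collapse = ", ")
    ))
  }
  tbl$intercept_ug[idx] + tbl$slope_ug_per_mm[idx] * length_mm
}

#' Fragment length calibration
#'
#' Fragmented polychaetes lose their posterior end, so intact body length is
#' predicted from the width of a designated chaetiger using an ordinary
#' least-squares line fitted on intact specimens of the same taxon.
#' `fit_fragment_calibration()` fits the line; `estimate_fragment_length()`
#' applies it.
#'
#' @param taxon Taxon the calibration belongs to.
#' @param width_mm Chaetiger widths (mm) of intact calibration specimens, or
#'   of fragments to predict for.
#' @param length_mm Intact body lengths (mm) of the calibration specimens.
#' @param min_n Minimum number of intact specimens required (default 5).
#' @return `fit_fragment_calibration()` returns a `fragment_calibration`
#'   object (taxon, slope, intercept, n_calibration, r2);
#'   `estimate_fragment_length()` returns predicted lengths in mm.
#' @export
fit_fragment_calibration <- function(taxon, width_mm, length_mm, min_n = 5L) {
  stopifnot(length(width_mm) == length(length_mm))
  if (length(width_mm) < min_n) {
    abort(paste0(
      "fragment calibration for ", taxon, " needs >= ", min_n,
      " intact specimens, got ", length(width_mm)
    ))
  }
  fit <- lm(length_mm ~ width_mm)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    abort(paste0("fragment calibration for ", taxon,
                 " has non-positive slope; widths do not predict length"))
  }
  structure(
    list(
      taxon = taxon,
      slope = slope,
      intercept = unname(coef(fit)[1]),
      n_calibration = length(width_mm),
      r2 = summary(fit)$r.squared
    ),
    class = "fragment_calibration"
  )
}

#' @rdname fit_fragment_calibration
#' @param calibration A `fragment_calibration` object.
#' @export
estimate_fragment_length <- function(width_mm, calibration) {
  stopifnot(inherits(calibration, "fragment_calibration"), all(width_mm > 0))
  pred <- calibration$intercept + calibration$slope * width_mm
  if (any(pred <= 0)) {
    abort(paste0(
      "fragment length prediction non-positive for taxon ",
      calibration$taxon, " at width(s) ",
      paste(signif(width_mm[pred <= 0], 4), collapse = ", ")
    ))
  }
  pred
}

#' Expand measured subsamples to full counts
#'
#' Abundant species are measured on a random subsample (200 of any species
#' exceeding 250 individuals per sample; 500 for meiofaunal nematodes). Each
#' measured record's `count_weight` is scaled by `total_count / n_measured`
#' so the measured individuals represent the full count and total abundance
#' is conserved exactly.
#'
#' @param measured A data frame of measured organism records (rows of one
#'   species in one sample) with a `count_weight` column.
#' @param total_count Total number of individuals of that species in the
#'   sample; must be at least the number measured.
#' @return `measured` with `count_weight` rescaled.
#' @export
expand_subsample <- function(measured, total_count) {
  n_measured <- sum(measured$count_weight)
  if (total_count < n_measured) {
    abort(paste0(
      "total_count (", total_count, ") is below the number measured (",
      n_measured, ")"
    ))
  }
  measured$count_weight <- measured$count_weight * (total_count / n_measured)
  measured
}

#' Area standardization factor
#'
#' Abundance and biomass are reported per 0.1 m^2 (= 1000 cm^2), the area of
#' the van Veen grab. A sample covering `a` cm^2 is scaled by `1000 / a`
#' (so the 10 cm^2 syringe core scales by 100, the grab by 1).
#'
#' @param sampled_area_cm2 Positive sampled area(s) in cm^2.
#' @return Multiplicative scaling factor(s) to 0.1 m^2.
#' @export
area_factor <- function(sampled_area_cm2) {
  stopifnot(all(sampled_area_cm2 > 0))
  1000 / sampled_area_cm2
}

#' Fill dry mass for every organism record
#'
#' Runs the full conversion chain on an organism table: biovolume from
#' dimensions (cylinder for configured cylinder taxa, `L * W^2 * c`
#' otherwise), wet mass via the specific-gravity factor (mg, converted to ug
#' at this single point), then the group-appropriate wet-to-dry conversion.
#' Taxa in the direct-mass table bypass the biovolume step. Records that
#' already carry `dry_mass_ug` are left untouched.
#'
#' Fragmented records (`is_fragment = TRUE`) have their intact length
#' predicted from the measured chaetiger width via the matching entry of
#' `fragment_calibrations`; fragments of taxa without a calibration are
#' excluded with a warning naming them.
#'
#' @param organisms An organism tibble (see [read_organisms()]).
#' @param config A [conversion_config()].
#' @param fragment_calibrations Named list of `fragment_calibration`
#'   objects, keyed by taxon (see [fit_fragment_calibration()]).
#' @return `organisms` with `dry_mass_ug` filled for every row (minus any
#'   excluded uncalibrated fragments).
#' @export
compute_dry_mass <- function(organisms, config = conversion_config(),
                             fragment_calibrations = list()) {
  df <- validate_organisms(organisms)

  frag <- df$is_fragment & is.na(df$dry_mass_ug)
  if (any(frag)) {
    has_cal <- df$taxon_id %in% names(fragment_calibrations)
    drop <- frag & !has_cal
    if (any(drop)) {
      warn(paste0(
        "excluding ", sum(drop), " fragment record(s) without a length ",
        "calibration: ", paste(unique(df$taxon_id[drop]), collapse = ", ")
      ))
      df <- df[!drop, , drop = FALSE]
      frag <- df$is_fragment & is.na(df$dry_mass_ug)
    }
    for (tx in unique(df$taxon_id[frag])) {
      i <- which(frag & df$taxon_id == tx)
      df$length_mm[i] <- estimate_fragment_length(
        df$width_mm[i], fragment_calibrations[[tx]]
      )
    }
  }

  todo <- is.na(df$dry_mass_ug)
  if (!any(todo)) return(df)

  sub <- df[todo, ]
  wm_ug <- numeric(nrow(sub))

  direct <- sub$taxon_id %in% config$direct_mass_table$taxon
  cylinder <- !direct & sub$taxon_id %in% config$cylinder_taxa

  if (any(direct)) {
    wm_ug[direct] <- direct_mass_taxa(
      sub$taxon_id[direct], sub$length_mm[direct], config
    )
  }
  if (any(cylinder)) {
    v <- biovolume_cylinder(sub$length_mm[cylinder], sub$width_mm[cylinder])
    wm_ug[cylinder] <- wet_mass(v, config) * 1000
  }
  rest <- !direct & !cylinder
  if (any(rest)) {
    v <- biovolume_feller_warwick(
      sub$length_mm[rest], sub$width_mm[rest], sub$taxon_id[rest], config
    )
    if (config$sg_scope == "meiofauna") {
      # optionally restrict the gravity factor to meiofauna
      is_meio <- sub$group[rest] %in% c("meiofauna", "macrofaunal_nematode")
      wm <- ifelse(is_meio, wet_mass(v, config), v)
      wm_ug[rest] <- wm * 1000
    } else {
      wm_ug[rest] <- wet_mass(v, config) * 1000
    }
  }

  df$dry_mass_ug[todo] <- dry_mass(
    wm_ug, sub$group, taxon = sub$taxon_id, config = config
  )
  df
}
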