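#' Scenario configuration for the synthetic community generator
#'
#' Defines the statistical structure of a simulated benthic community:
#' number of fjords and replicate stations, the true NBSS slope and
#' intercept per fjord, the log2 size-class range, class-level noise, the
#' mode/trough modulation that shapes bimodal meiofauna/macrofauna spectra,
#' the taxon pool with feeding types and body aspect ratios, and the model
#' linking environmental covariates to station biomass.
#'
#' The defaults describe a community of the kind sampled in high-latitude
#' fjord soft sediments: 6 fjords x 3 stations, classes -11..21, NBSS slope
#' -0.53 and intercept 11 (log2 normalized biomass at 1 ug), class noise sd
#' 0.5, meiofauna and macrofauna abundance modes separated by a trough at
#' classes 2-5, and bottom temperatures spanning -2 to 8 C across fjords.
#'
#' The mode/trough modulation is constructed as three Gaussian bumps and
#' then made exactly orthogonal to `{1, n}` over the class range, so it
#' shapes the spectra without changing the generator's true NBSS slope or
#' intercept.
#'
#' @param n_fjords,n_stations Design size (defaults 6 and 3).
#' @param true_slope,true_intercept NBSS truth per fjord (recycled if length
#'   1). Intercept is log2 normalized biomass at class 0.
#' @param class_range Integer `c(lo, hi)` within -11..21.
#' @param noise_sd SD of Gaussian noise on log2 normalized biomass per
#'   station x class (default 0.5).
#' @param modulation List of four Gaussian components (`amp`, `center`,
#'   `sd`): `meio_mode` and `macro_mode` are added, `low_tail_dip` and
#'   `trough` subtracted. The meio mode sits at classes -5..-1 (typical
#'   meiofaunal body masses), the dip suppresses the vestigial smallest
#'   classes, the trough separates the modes at classes 2-5.
#' @param occurrence_cap Size class above which organisms become rare
#'   detections: expected counts beyond it are multiplied by `tail_factor`
#'   (defaults 19 and 0.02), reflecting that a 0.1 m^2 grab catches the
#'   very largest animals only sporadically.
#' @param rare_factor Presence rate scaling for classes whose expected
#'   normalized biomass falls below the contribution of a single organism
#'   (default 0.05): such classes appear only occasionally, as in field
#'   samples.
#' @param max_measured Measurement cap per station, class and component;
#'   larger counts are represented by fewer records with proportionally
#'   larger `count_weight`, mirroring field subsampling (default 15).
#' @param sampling `"stochastic"` (default: integer counts, log-uniform
#'   within-class masses) or `"exact"` (class-midpoint masses, fractional
#'   count weights, one component per class: a closed-form round trip used
#'   for analytic checks).
#' @param env_model Coefficients linking station covariates to log2 total
#'   dry mass, plus noise SDs and the per-fjord temperature range.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_fjords = 6L,
                            n_stations = 3L,
                            true_slope = -0.53,
                            true_intercept = 11,
                            class_range = c(-11L, 21L),
                            noise_sd = 0.5,
                            modulation = list(
                              meio_mode = list(amp = 5.0, center = -3, sd = 1.6),
                              low_tail_dip = list(amp = 5.0, center = -9.5, sd = 1.6),
                              trough = list(amp = 2.0, center = 3.5, sd = 1.5),
                              macro_mode = list(amp = 1.5, center = 8.5, sd = 2.0)
                            ),
                            occurrence_cap = 19L,
                            tail_factor = 0.02,
                            rare_factor = 0.05,
                            max_measured = 15L,
                            sampling = c("stochastic", "exact"),
                            env_model = list(
                              temperature_range = c(-2, 8),
                              ref_log2_dm = 21,
                              chl_base = 3.0, chl_slope = 1.2, chl_sd = 0.8,
                              d13c_base = -23.5, d13c_slope = 0.6, d13c_sd = 0.5
                            )) {
  sampling <- match.arg(sampling)
  stopifnot(
    n_stations >= 2, n_fjords >= 1,
    class_range[1] >= -11, class_range[2] <= 21,
    class_range[1] < class_range[2],
    noise_sd >= 0
  )
  structure(
    list(
      n_fjords = as.integer(n_fjords),
      n_stations = as.integer(n_stations),
      true_slope = rep_len(true_slope, n_fjords),
      true_intercept = rep_len(true_intercept, n_fjords),
      class_range = as.integer(class_range),
      noise_sd = noise_sd,
      modulation = modulation,
      occurrence_cap = as.integer(occurrence_cap),
      tail_factor = tail_factor,
      rare_factor = rare_factor,
      max_measured = as.integer(max_measured),
      sampling = sampling,
      env_model = env_model
    ),
    class = "scenario_config"
  )
}

#' Class-level spectrum modulation, orthogonal to the linear trend
#'
#' Evaluates the configured Gaussian components (meiofauna mode, low-tail
#' dip, trough, macrofauna mode) over the class range and projects out the
#' part lying in the span of `{1, n}` over the effectively sampled classes
#' (those up to `occurrence_cap`), so adding the result to a linear
#' log2-NBSS leaves the least-squares slope and intercept of the expected
#' spectrum unchanged.
#'
#' @param config A [scenario_config()].
#' @return A tibble with `class_index` and `d` (log2 units).
#' @export
class_modulation <- function(config) {
  n <- seq(config$class_range[1], config$class_range[2])
  g <- function(p) p$amp * exp(-(n - p$center)^2 / (2 * p$sd^2))
  d <- g(config$modulation$meio_mode) -
    g(config$modulation$low_tail_dip) -
    g(config$modulation$trough) +
    g(config$modulation$macro_mode)
  eff <- n <= config$occurrence_cap
  if (sum(eff) >= 3) {
    X <- cbind(1, n[eff])
    d[eff] <- d[eff] - X %*% solve(crossprod(X), crossprod(X, d[eff]))
  } else {
    X <- cbind(1, n)
    d <- as.numeric(d - X %*% solve(crossprod(X), crossprod(X, d)))
  }
  tibble::tibble(class_index = as.integer(n), d = as.numeric(d))
}

# component weights by class: meiofauna below the 500 um boundary classes,
# a small macrofaunal-nematode share across -6..6, macrofauna above
component_weights <- function(class_index) {
  w_meio <- dplyr::case_when(
    class_index <= -7 ~ 1.0,
    class_index <= -1 ~ 0.95,
    class_index <= 2 ~ 0.30,
    class_index <= 5 ~ 0.10,
    TRUE ~ 0
  )
  w_nem <- ifelse(class_index >= -6 & class_index <= 6, 0.05, 0)
  w_nem <- pmin(w_nem, 1 - w_meio)
  w_macro <- ifelse(class_index >= 0, 1 - w_meio - w_nem, 0)
  tibble::tibble(
    component = rep(c("meiofauna", "macrofaunal_nematode", "macrofauna"),
                    each = length(class_index)),
    class_index = rep(class_index, 3),
    weight = c(w_meio, w_nem, w_macro)
  )
}

# conditional mean of log2(sum of k masses drawn log2-uniformly in a class),
# in class units: exactly 0.5 for k = 1, and log2(k/ln 2) minus a second-order
# Jensen correction for k > 1
log2_sum_mean <- function(k) {
  ifelse(k <= 1, 0.5, log2(k / log(2)) - 0.0287 / k)
}

# invert the conditional mean: expected count lambda such that, given at
# least one organism is drawn (counts are stochastically rounded), the mean
# of log2 normalized biomass equals `target`; undefined below the
# single-organism floor of 0.5
match_lambda <- function(target) {
  ks <- seq_len(5000)
  gs <- log2_sum_mean(ks)
  out <- 2^target * log(2) # large-count limit: biomass / mean mass
  hi <- target >= gs[length(gs)]
  out[hi] <- 2^target[hi] * log(2)
  mid <- !hi & target >= 0.5
  if (any(mid)) {
    i <- findInterval(target[mid], gs)
    out[mid] <- ks[i] + (target[mid] - gs[i]) / (gs[i + 1] - gs[i])
  }
  out[target < 0.5] <- NA_real_
  out
}

# taxon pools per component; macrofauna direct-mass taxa are restricted to
# classes <= 12 where a linear length-mass law stays plausible
taxon_pool <- function(component, big_class) {
  if (component == "meiofauna") {
    tibble::tibble(
      taxon_id = c("Nematoda", "Copepoda", "Ostracoda", "Kinorhyncha"),
      weight = c(0.5, 0.3, 0.1, 0.1)
    )
  } else if (component == "macrofaunal_nematode") {
    tibble::tibble(taxon_id = "Nematoda", weight = 1)
  } else if (big_class) {
    tibble::tibble(
      taxon_id = c("Maldanidae", "Spionidae", "Cirratulidae", "Paraonidae",
                   "Oweniidae", "Nephtyidae", "Cossuridae", "Onuphidae",
                   "Mollusca"),
      weight = c(0.16, 0.15, 0.13, 0.11, 0.11, 0.09, 0.09, 0.07, 0.09)
    )
  } else {
    tibble::tibble(
      taxon_id = c("Maldanidae", "Spionidae", "Cirratulidae", "Paraonidae",
                   "Oweniidae", "Nephtyidae", "Cossuridae", "Onuphidae",
                   "Mollusca", "Crustacea", "Ophiuroidea"),
      weight = c(0.14, 0.14, 0.12, 0.10, 0.10, 0.08, 0.08, 0.06,
                 0.08, 0.06, 0.04)
    )
  }
}

FEEDING_BY_TAXON <- c(
  Maldanidae = "subsurface_deposit",
  Spionidae = "surface_deposit",
  Cirratulidae = "surface_deposit",
  Paraonidae = "subsurface_deposit",
  Oweniidae = "suspension",
  Nephtyidae = "carnivore",
  Cossuridae = "subsurface_deposit",
  Onuphidae = "omnivore",
  Mollusca = "surface_deposit",
  Crustacea = "carnivore",
  Ophiuroidea = "omnivore"
)

ASPECT_RATIO <- c(
  Nematoda = 20, Copepoda = 2.5, Ostracoda = 1.8, Kinorhyncha = 4,
  Maldanidae = 10, Spionidae = 8, Cirratulidae = 8, Paraonidae = 9,
  Oweniidae = 8, Nephtyidae = 7, Cossuridae = 9, Onuphidae = 8,
  Mollusca = 2, Crustacea = 3, Ophiuroidea = 1.5
)

# invert the allometric chain: given target dry mass, component and taxon,
# find (L, W) that the conversion pipeline maps back onto that mass
invert_allometry <- function(dm_ug, taxon, group, config) {
  n <- length(dm_ug)
  is_meio <- group %in% c("meiofauna", "macrofaunal_nematode")
  fraction <- ifelse(
    is_meio, config$meiofauna_dm_fraction,
    unname(config$macrofauna_dm_factors[taxon])
  )
  wm_ug <- dm_ug / fraction
  ar <- unname(ASPECT_RATIO[taxon])
  L <- numeric(n); W <- numeric(n)

  direct <- taxon %in% config$direct_mass_table$taxon
  if (any(direct)) {
    i <- match(taxon[direct], config$direct_mass_table$taxon)
    L[direct] <- (wm_ug[direct] - config$direct_mass_table$intercept_ug[i]) /
      config$direct_mass_table$slope_ug_per_mm[i]
    W[direct] <- L[direct] / ar[direct]
  }
  volume <- wm_ug / 1000 / config$specific_gravity
  cylinder <- !direct & taxon %in% config$cylinder_taxa
  if (any(cylinder)) {
    W[cylinder] <- (4 * volume[cylinder] / (pi * ar[cylinder]))^(1 / 3)
    L[cylinder] <- ar[cylinder] * W[cylinder]
  }
  fw <- !direct & !cylinder
  if (any(fw)) {
    cc <- unname(config$taxon_coefficients[taxon[fw]])
    W[fw] <- (volume[fw] / (ar[fw] * cc))^(1 / 3)
    L[fw] <- ar[fw] * W[fw]
  }
  list(length_mm = L, width_mm = W)
}

stoch_round <- function(x) {
  f <- floor(x)
  f + rbinom(length(x), 1, x - f)
}

#' Generate a synthetic benthic community
#'
#' Draws per-station organism records whose expected binned, normalized
#' biomass follows `log2 NB = intercept + slope * n` plus the orthogonal
#' mode/trough modulation and Gaussian class noise. A class's biomass is
#' split among faunal components (meiofauna / macrofaunal nematodes /
#' macrofauna), realized as integer organism counts at the gear's native
#' sampled area (10 cm^2 syringe cores for meiofauna, the 0.1 m^2 grab for
#' the rest), capped at `max_measured` measured records per class and
#' component with proportional `count_weight` — the generator therefore
#' reproduces field subsampling. Body length and width are back-computed
#' from each target dry mass through the configured conversion chain, so
#' running [compute_dry_mass()] on the output reproduces the intended
#' masses. Environmental covariates are drawn with chlorophyll a and
#' delta13C linked to station log2 biomass per `env_model`.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; identical seeds give identical output.
#' @param conv A [conversion_config()] used for the dimension inversion.
#' @return A list: `samples` (a `station_samples`), `environment` (an
#'   env-profile tibble), and `truth` (per-fjord NBSS parameters, the
#'   modulation table, the env model and the seed).
#' @export
generate_community <- function(config = scenario_config(), seed = 1,
                               conv = conversion_config()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  classes <- seq(config$class_range[1], config$class_range[2])
  mod <- class_modulation(config)
  fjords <- sprintf("F%d", seq_len(config$n_fjords))
  temps <- seq(config$env_model$temperature_range[1],
               config$env_model$temperature_range[2],
               length.out = max(config$n_fjords, 2))[seq_len(config$n_fjords)]

  grid <- tidyr::crossing(
    tibble::tibble(
      fjord_id = fjords,
      true_slope = config$true_slope,
      true_intercept = config$true_intercept
    ),
    station_id = sprintf("S%d", seq_len(config$n_stations)),
    tibble::tibble(class_index = as.integer(classes), d = mod$d)
  )
  grid$eps <- rnorm(nrow(grid), 0, config$noise_sd)
  grid$log2_nb <- grid$true_intercept + grid$true_slope * grid$class_index +
    grid$d + grid$eps
  grid$biomass_target <- 2^(grid$log2_nb + grid$class_index)

  if (config$sampling == "exact") {
    comp <- grid
    comp$component <- ifelse(comp$class_index < 0, "meiofauna", "macrofauna")
    comp$weight <- 1
  } else {
    comp <- dplyr::inner_join(
      grid, component_weights(classes),
      by = "class_index", relationship = "many-to-many"
    )
    comp <- dplyr::filter(comp, .data$weight > 0)
  }
  comp$gear <- gear_for_group(comp$component)
  comp$sampled_area_cm2 <- ifelse(comp$gear == "syringe_core", 10, 1000)

  if (config$sampling == "exact") {
    mean_mass <- 2^(comp$class_index + 0.5)
    comp$lambda_native <- comp$weight * comp$biomass_target / mean_mass /
      area_factor(comp$sampled_area_cm2)
    comp$count <- comp$lambda_native
    if (any(comp$count < 1)) {
      abort(paste0(
        "infeasible exact-sampling scenario: expected native count below 1 ",
        "in class ", comp$class_index[which(comp$count < 1)[1]],
        "; narrow class_range or raise the intercept"
      ))
    }
    comp$n_records <- 1L
  } else {
    # expected counts at the gear's native area, moment-matched so the
    # conditional mean of log2 normalized biomass given presence equals the
    # target; components below the single-organism floor become rare
    # detections, as do classes beyond the occurrence cap
    target_nat <- comp$log2_nb + log2(comp$weight) -
      log2(area_factor(comp$sampled_area_cm2))
    lam <- match_lambda(target_nat)
    floor_gap <- is.na(lam)
    lam[floor_gap] <- config$rare_factor * 2^(target_nat[floor_gap] - 0.5)
    lam <- lam * ifelse(comp$class_index > config$occurrence_cap,
                        config$tail_factor, 1)
    comp$lambda_native <- lam
    comp$count <- stoch_round(comp$lambda_native)
    comp <- dplyr::filter(comp, .data$count > 0)
    comp$n_records <- pmin(comp$count, config$max_measured)
  }
  comp$cw <- comp$count / comp$n_records

  rec <- tidyr::uncount(comp, weights = .data$n_records)
  if (config$sampling == "exact") {
    rec$dry_mass_target <- 2^(rec$class_index + 0.5)
  } else {
    rec$dry_mass_target <- 2^(rec$class_index + runif(nrow(rec)))
  }

  # draw taxa stratum-wise (component x large-class restriction)
  rec$taxon_id <- NA_character_
  for (component in unique(rec$component)) {
    for (big in c(FALSE, TRUE)) {
      sel <- rec$component == component &
        (rec$class_index > 12) == big
      if (!any(sel)) next
      pool <- taxon_pool(component, big)
      rec$taxon_id[sel] <- sample(
        pool$taxon_id, sum(sel), replace = TRUE, prob = pool$weight
      )
    }
  }

  dims <- invert_allometry(rec$dry_mass_target, rec$taxon_id, rec$component,
                           conv)
  organisms <- tibble::tibble(
    fjord_id = rec$fjord_id,
    station_id = rec$station_id,
    taxon_id = rec$taxon_id,
    species = NA_character_,
    genus = NA_character_,
    family = ifelse(rec$taxon_id %in% names(FEEDING_BY_TAXON),
                    rec$taxon_id, NA_character_),
    group = rec$component,
    length_mm = dims$length_mm,
    width_mm = dims$width_mm,
    count_weight = rec$cw,
    is_fragment = FALSE,
    feeding_type = unname(FEEDING_BY_TAXON[rec$taxon_id]),
    dry_mass_ug = NA_real_,
    gear = rec$gear
  )

  stations <- tidyr::crossing(
    tibble::tibble(fjord_id = fjords),
    station_id = sprintf("S%d", seq_len(config$n_stations)),
    tibble::tibble(
      gear = c("van_veen_grab", "syringe_core"),
      sampled_area_cm2 = c(1000, 10)
    )
  )

  # station-level environmental covariates, chl a and d13C linked to biomass
  per_station <- dplyr::summarise(
    dplyr::group_by(grid, .data$fjord_id, .data$station_id),
    log2_dm = log2(sum(.data$biomass_target)),
    .groups = "drop"
  )
  em <- config$env_model
  env <- dplyr::mutate(
    per_station,
    temperature_C = temps[match(.data$fjord_id, fjords)] +
      rnorm(dplyr::n(), 0, 0.15),
    salinity = rnorm(dplyr::n(), 34.8, 0.3),
    chl_a_ug_g = pmax(
      0.05,
      em$chl_base + em$chl_slope * (.data$log2_dm - em$ref_log2_dm) +
        rnorm(dplyr::n(), 0, em$chl_sd)
    ),
    delta13C = em$d13c_base +
      em$d13c_slope * (.data$log2_dm - em$ref_log2_dm) +
      rnorm(dplyr::n(), 0, em$d13c_sd),
    c_org_pct = pmax(
      0.2, 1.5 + 0.25 * (.data$log2_dm - em$ref_log2_dm) +
        rnorm(dplyr::n(), 0, 0.4)
    ),
    cpe_ug_g = .data$chl_a_ug_g * runif(dplyr::n(), 2.2, 3.2),
    mud_pct = runif(dplyr::n(), 50, 95)
  )
  env <- dplyr::select(
    env, "fjord_id", "station_id", "temperature_C", "salinity",
    "c_org_pct", "delta13C", "chl_a_ug_g", "cpe_ug_g", "mud_pct"
  )

  truth <- list(
    nbss = tibble::tibble(
      fjord_id = fjords,
      true_slope = config$true_slope,
      true_intercept = config$true_intercept,
      temperature_C = temps
    ),
    modulation = mod,
    env_model = em,
    noise_sd = config$noise_sd,
    seed = seed
  )

  list(
    samples = station_samples(organisms, stations),
    environment = validate_environment(env),
    truth = truth
  )
}

#' Apply a deterministic perturbation to a sample set
#'
#' Sensitivity-scenario edits of a generated community, motivated by the
#' classic warming motifs: disappearance of the largest organisms
#' (`"remove_large"`), inflation of small size classes (`"inflate_small"`),
#' a single gross outlier added to the top of the spectrum (`"outlier"`),
#' or no change (`"none"`). Deterministic given its arguments.
#'
#' @param samples A `station_samples` object.
#' @param kind Perturbation type.
#' @param cutoff_class Class boundary: records above it are removed
#'   (`remove_large`, default 17) or below it inflated (`inflate_small`,
#'   default 5).
#' @param factor Multiplier applied to `count_weight` of classes below the
#'   cutoff in `inflate_small` (default 4).
#' @param conv A [conversion_config()] used to fill dry masses if absent.
#' @return A perturbed `station_samples`.
#' @export
inject_perturbation <- function(samples,
                                kind = c("none", "remove_large",
                                         "inflate_small", "outlier"),
                                cutoff_class = NULL, factor = 4,
                                conv = conversion_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(samples, "station_samples"))
  if (kind == "none") return(samples)
  org <- samples$organisms
  if (anyNA(org$dry_mass_ug)) org <- compute_dry_mass(org, conv)
  cls <- size_class(org$dry_mass_ug)
  if (kind == "remove_large") {
    if (is.null(cutoff_class)) cutoff_class <- 17L
    org <- org[cls <= cutoff_class, , drop = FALSE]
  } else if (kind == "inflate_small") {
    if (is.null(cutoff_class)) cutoff_class <- 5L
    org$count_weight <- ifelse(cls < cutoff_class,
                               org$count_weight * factor, org$count_weight)
  } else if (kind == "outlier") {
    st <- samples$stations[samples$stations$gear == "van_veen_grab", ][1, ]
    extra <- org[1, ]
    extra$fjord_id <- st$fjord_id
    extra$station_id <- st$station_id
    extra$gear <- "van_veen_grab"
    extra$group <- "macrofauna"
    extra$taxon_id <- "Onuphidae"
    extra$family <- "Onuphidae"
    extra$feeding_type <- unname(FEEDING_BY_TAXON["Onuphidae"])
    extra$count_weight <- 1
    extra$is_fragment <- FALSE
    extra$dry_mass_ug <- NA_real_
    dims <- invert_allometry(2^20.5, "Onuphidae", "macrofauna", conv)
    extra$length_mm <- dims$length_mm
    extra$width_mm <- dims$width_mm
    org <- dplyr::bind_rows(org, extra)
  }
  station_samples(org, samples$stations)
}
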