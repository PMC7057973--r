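#' Compare NBSS slopes and intercepts across groups
#'
#' Analysis of covariance with size class as a continuous covariate and the
#' grouping factor (typically fjord) as a categorical covariate. The
#' class-by-group interaction F-test assesses slope homogeneity; when the
#' interaction is not significant the common-slope model
#' `log2(nb) ~ class_index + group` is refit and its per-group intercepts
#' (at class 0) reported. The pooled slope of that refit is the "fixed
#' slope" whose standard error is reported alongside.
#'
#' @param points A data frame with columns `class_index`, `nb` and the
#'   grouping column.
#' @param group Name of the grouping column (default `"fjord_id"`).
#' @param log_base Logarithm base for `nb` (default 2).
#' @param alpha Significance level used to decide whether the common-slope
#'   refit intercepts are the headline result (default 0.05). Both models
#'   are always fitted and returned.
#' @return An `nbss_comparison` object: interaction F, numerator/denominator
#'   df and p-value; common slope with SE; per-group intercepts with SE
#'   (from the common-slope model, at class 0); the two `lm` fits; and the
#'   `emmeans` grid used for pairwise contrasts.
#' @export
compare_slopes <- function(points, group = "fjord_id", log_base = 2,
                           alpha = 0.05) {
  points <- tibble::as_tibble(points)
  require_columns(points, c("class_index", "nb", group), "NBSS points")
  if (any(points$nb <= 0)) {
    abort("all normalized biomasses must be > 0 to take logarithms")
  }
  points$log_nb <- log(points$nb, base = log_base)
  points$.group <- factor(points[[group]])
  k <- nlevels(points$.group)
  if (k < 1) abort("need at least one group")

  if (k == 1) {
    fit <- fit_nbss(points, log_base = log_base)
    return(structure(
      list(
        group = group, n_groups = 1L,
        interaction_F = NA_real_, df_num = NA_integer_, df_den = NA_integer_,
        p_interaction = NA_real_,
        common_slope = fit$slope, common_slope_se = fit$slope_se,
        intercepts = tibble::tibble(
          group = levels(points$.group),
          intercept = fit$intercept, se = fit$intercept_se
        ),
        slopes_homogeneous = TRUE,
        full_model = fit$fit, common_model = fit$fit, emm = NULL,
        log_base = log_base, data = points
      ),
      class = "nbss_comparison"
    ))
  }

  full <- lm(log_nb ~ class_index * .group, data = points)
  reduced <- lm(log_nb ~ class_index + .group, data = points)
  if (any(!is.finite(coef(full)))) {
    abort("singular design: some group has too few distinct size classes")
  }
  cmp <- anova(reduced, full)
  f_int <- cmp$F[2]
  df_num <- cmp$Df[2]
  df_den <- cmp$Res.Df[2]
  p_int <- cmp$`Pr(>F)`[2]

  s_red <- summary(reduced)
  emm <- emmeans::emmeans(
    reduced, ".group",
    at = list(class_index = 0),
    data = points
  )
  emm_df <- as.data.frame(emm)
  intercepts <- tibble::tibble(
    group = as.character(emm_df$.group),
    intercept = emm_df$emmean,
    se = emm_df$SE
  )

  structure(
    list(
      group = group, n_groups = k,
      interaction_F = f_int, df_num = df_num, df_den = df_den,
      p_interaction = p_int,
      common_slope = unname(coef(reduced)["class_index"]),
      common_slope_se = s_red$coefficients["class_index", 2],
      intercepts = intercepts,
      slopes_homogeneous = p_int >= alpha,
      full_model = full, common_model = reduced, emm = emm,
      log_base = log_base, data = points
    ),
    class = "nbss_comparison"
  )
}

#' @export
print.nbss_comparison <- function(x, ...) {
  cat("<nbss_comparison>", x$n_groups, "groups (", x$group, ")\n")
  if (x$n_groups > 1) {
    cat(sprintf(
      "  slope homogeneity: F_%d,%d = %.3f, p = %.4g\n",
      x$df_num, x$df_den, x$interaction_F, x$p_interaction
    ))
  }
  cat(sprintf("  common slope: %.4f +/- %.4f SE\n",
              x$common_slope, x$common_slope_se))
  print(x$intercepts)
  invisible(x)
}

#' @export
tidy.nbss_comparison <- function(x, ...) {
  dplyr::mutate(x$intercepts,
                common_slope = x$common_slope,
                common_slope_se = x$common_slope_se)
}

#' @export
glance.nbss_comparison <- function(x, ...) {
  tibble::tibble(
    n_groups = x$n_groups,
    interaction_F = x$interaction_F,
    df_num = x$df_num,
    df_den = x$df_den,
    p_interaction = x$p_interaction,
    common_slope = x$common_slope,
    common_slope_se = x$common_slope_se
  )
}

#' Tukey-adjusted pairwise intercept contrasts
#'
#' All-pairs comparison of the per-group NBSS intercepts from the
#' common-slope model, with familywise error controlled by the Tukey
#' studentized-range adjustment on the residual degrees of freedom of that
#' model. With two groups the adjusted p equals the unadjusted p.
#'
#' @param comparison An `nbss_comparison` from [compare_slopes()].
#' @return A tibble with columns `group_1`, `group_2`, `estimate`,
#'   `std.error`, `statistic`, `p.value` (Tukey-adjusted).
#' @export
pairwise_intercepts <- function(comparison) {
  stopifnot(inherits(comparison, "nbss_comparison"))
  if (is.null(comparison$emm)) {
    abort("pairwise contrasts need at least two groups")
  }
  ctr <- as.data.frame(
    emmeans::contrast(comparison$emm, method = "pairwise", adjust = "tukey")
  )
  parts <- strsplit(as.character(ctr$contrast), " - ", fixed = TRUE)
  tibble::tibble(
    group_1 = gsub("^\\(|\\)$", "", vapply(parts, `[`, "", 1)),
    group_2 = gsub("^\\(|\\)$", "", vapply(parts, `[`, "", 2)),
    estimate = ctr$estimate,
    std.error = ctr$SE,
    statistic = ctr$t.ratio,
    p.value = ctr$p.value
  )
}

#' Correlate station NBSS intercepts with standing stock
#'
#' Fits a station-level NBSS per station (free slopes by default), then
#' computes Spearman rank correlations of the station intercepts with (a)
#' total dry mass and (b) mean normalized biomass per station. When
#' `class_range` is given the spectra are truncated to that class interval
#' *before* both the intercept refits and the total/mean recomputation —
#' this is how a size-class range common to every site is enforced, since
#' intercepts are sensitive to differing class extents.
#'
#' @param spectrum A station-level normalized `size_spectrum` (columns
#'   `fjord_id`, `station_id`, `class_index`, `biomass_ug`, `nb`).
#' @param class_range Optional integer vector `c(lo, hi)`; classes outside
#'   are dropped first.
#' @param slope `"free"` (default): each station keeps its own slope;
#'   `"common"`: stations share one slope via the common-slope ANCOVA and
#'   intercepts are the per-station adjusted means at class 0.
#' @param log_base Logarithm base (default 2).
#' @return A tibble with one row per response (`total_dm`, `mean_nb`):
#'   `rho`, `p.value`, `n_stations`.
#' @export
intercept_biomass_correlation <- function(spectrum, class_range = NULL,
                                          slope = c("free", "common"),
                                          log_base = 2) {
  slope <- match.arg(slope)
  df <- tibble::as_tibble(as.data.frame(spectrum))
  require_columns(df, c("fjord_id", "station_id", "class_index", "biomass_ug"),
                  "spectrum")
  if (!"nb" %in% names(df)) df <- normalize_spectrum(df)
  if (!is.null(class_range)) {
    df <- dplyr::filter(df, .data$class_index >= class_range[1],
                        .data$class_index <= class_range[2])
  }
  df$.station <- paste(df$fjord_id, df$station_id, sep = "/")
  stations <- unique(df$.station)
  if (length(stations) < 5) {
    abort("need at least 5 stations for a rank correlation")
  }

  if (slope == "free") {
    per_station <- purrr::map_dfr(stations, function(s) {
      sub <- df[df$.station == s, ]
      fit <- fit_nbss(sub, log_base = log_base)
      tibble::tibble(station = s, intercept = fit$intercept)
    })
  } else {
    cmp <- compare_slopes(dplyr::rename(df, station = ".station"),
                          group = "station", log_base = log_base)
    per_station <- dplyr::rename(cmp$intercepts, station = "group")
  }

  totals <- dplyr::summarise(
    dplyr::group_by(df, .data$.station),
    total_dm = sum(.data$biomass_ug),
    mean_nb = mean(.data$nb),
    .groups = "drop"
  )
  merged <- dplyr::inner_join(per_station, totals,
                              by = c(station = ".station"))
  corr_one <- function(y, label) {
    if (sd(merged$intercept) == 0 || sd(y) == 0) {
      abort(paste0("rank correlation undefined: constant ", label, " vector"))
    }
    ct <- suppressWarnings(
      cor.test(merged$intercept, y, method = "spearman", exact = FALSE)
    )
    tibble::tibble(
      response = label,
      rho = unname(ct$estimate),
      p.value = ct$p.value,
      n_stations = nrow(merged)
    )
  }
  dplyr::bind_rows(
    corr_one(merged$total_dm, "total_dm"),
    corr_one(merged$mean_nb, "mean_nb")
  )
}
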