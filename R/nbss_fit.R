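#' Fit a normalized biomass size spectrum
#'
#' Ordinary least-squares regression of `log2(nb)` on the integer size-class
#' index. The intercept is taken at class 0 (individual dry mass 1 ug), with
#' no centering. An undisturbed community in energetic steady state is
#' expected to have a slope near -1; shallower (less negative) slopes are
#' typical of subsidized benthic systems.
#'
#' @param points A data frame with columns `class_index` and `nb`
#'   (normalized biomass, > 0), e.g. from [normalize_spectrum()]. Extra
#'   columns are carried through to the augmented data.
#' @param log_base Base of the logarithm applied to `nb` (default 2, keeping
#'   the y-axis commensurate with the log2 class axis).
#' @return An `nbss_fit` object: slope, intercept, their standard errors,
#'   `r2`, `n_points`, the underlying `lm`, and per-point residuals and
#'   Cook's distances.
#' @examples
#' pts <- tibble::tibble(class_index = 0:15, nb = 2^(-(0:15)))
#' fit_nbss(pts)$slope # exactly -1
#' @export
fit_nbss <- function(points, log_base = 2) {
  points <- tibble::as_tibble(points)
  require_columns(points, c("class_index", "nb"), "NBSS points")
  if (any(points$nb <= 0)) {
    abort("all normalized biomasses must be > 0 to take logarithms")
  }
  if (nrow(points) < 3) {
    abort("NBSS regression needs at least 3 points")
  }
  points$log_nb <- log(points$nb, base = log_base)
  fit <- lm(log_nb ~ class_index, data = points)
  # exact analytic spectra (e.g. equal biomass per class) fit perfectly;
  # the stock lm warning about that is expected here, not a problem
  s <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  points$.fitted <- fitted(fit)
  points$.resid <- residuals(fit)
  points$.cooksd <- cooks.distance(fit)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      slope_se = s$coefficients[2, 2],
      intercept_se = s$coefficients[1, 2],
      r2 = s$r.squared,
      n_points = nrow(points),
      log_base = log_base,
      data = points,
      fit = fit
    ),
    class = "nbss_fit"
  )
}

#' @export
print.nbss_fit <- function(x, ...) {
  cat("<nbss_fit> log", x$log_base, "NB ~ size class, n =", x$n_points, "\n")
  cat(sprintf("  slope     %8.4f +/- %.4f SE\n", x$slope, x$slope_se))
  cat(sprintf("  intercept %8.4f +/- %.4f SE\n", x$intercept, x$intercept_se))
  cat(sprintf("  R^2       %8.4f\n", x$r2))
  invisible(x)
}

#' @export
tidy.nbss_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se),
    statistic = c(x$intercept / x$intercept_se, x$slope / x$slope_se),
    p.value = summary(x$fit)$coefficients[, 4]
  )
}

#' @export
glance.nbss_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2,
    sigma = summary(x$fit)$sigma,
    n = x$n_points,
    slope = x$slope,
    intercept = x$intercept
  )
}

#' @export
augment.nbss_fit <- function(x, ...) {
  x$data
}

#' Residual and influence diagnostics for an NBSS fit
#'
#' Flags points whose Cook's distance exceeds a threshold (default `4/n`),
#' summarizes residual normality (Shapiro-Wilk), and marks influential
#' points sitting in the extreme (lowest or highest) size classes, which are
#' the classes most prone to undersampling.
#'
#' @param fit An `nbss_fit`.
#' @param threshold Cook's distance threshold; default `4 / n_points`.
#' @return A `nbss_diagnostics` list: `threshold`, `flagged` (tibble of
#'   influential points with an `extreme_class` marker), and
#'   `shapiro_p` for the residuals.
#' @export
diagnose_fit <- function(fit, threshold = NULL) {
  stopifnot(inherits(fit, "nbss_fit"))
  if (is.null(threshold)) threshold <- 4 / fit$n_points
  d <- fit$data
  rng <- range(d$class_index)
  # an essentially perfect fit has no influential points; Cook's distances
  # computed from near-zero residuals are numerical noise
  scale_y <- max(abs(d$log_nb), 1)
  if (all(abs(d$.resid) < 1e-10 * scale_y)) {
    d$.cooksd <- 0
  }
  flagged <- d[d$.cooksd > threshold, , drop = FALSE]
  flagged$extreme_class <- flagged$class_index %in% rng
  sh <- if (fit$n_points >= 3 && fit$n_points <= 5000) {
    tryCatch(shapiro.test(d$.resid)$p.value, error = function(e) NA_real_)
  } else {
    NA_real_
  }
  structure(
    list(
      threshold = threshold,
      flagged = tibble::as_tibble(flagged),
      shapiro_p = sh
    ),
    class = "nbss_diagnostics"
  )
}

#' @export
print.nbss_diagnostics <- function(x, ...) {
  cat("<nbss_diagnostics> Cook's D threshold", signif(x$threshold, 3), "\n")
  cat("  influential points:", nrow(x$flagged),
      "| residual Shapiro-Wilk p:", signif(x$shapiro_p, 3), "\n")
  if (nrow(x$flagged) > 0) print(x$flagged)
  invisible(x)
}
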