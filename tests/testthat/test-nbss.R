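test_that("analytic limits: equal biomass gives slope -1, unit organisms give slope 0", {
  # same total biomass B in every class: NB_n = B / 2^n, log2 NB = log2 B - n
  sp <- new_size_spectrum(spectrum_tbl(0:15, 1, 7))
  fit <- fit_nbss(normalize_spectrum(sp))
  expect_equal(fit$slope, -1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, log2(7), tolerance = 1e-12)

  # one organism of mass 2^n per class: biomass_n = 2^n, NB = 1 everywhere
  sp0 <- new_size_spectrum(spectrum_tbl(0:12, 1, 2^(0:12)))
  fit0 <- fit_nbss(normalize_spectrum(sp0))
  expect_equal(fit0$slope, 0, tolerance = 1e-12)

  expect_error(fit_nbss(tibble::tibble(class_index = 1:2, nb = c(1, 2))),
               "at least 3")
  expect_error(fit_nbss(tibble::tibble(class_index = 1:5, nb = c(1, 2, 0, 1, 1))),
               "> 0")
})

test_that("multiplying biomass by k shifts the intercept by log2 k, slope unchanged", {
  set.seed(3)
  sp <- spectrum_tbl(-5:15, 1, 2^runif(21, 0, 15))
  f1 <- fit_nbss(normalize_spectrum(new_size_spectrum(sp)))
  spk <- dplyr::mutate(sp, biomass_ug = biomass_ug * 37)
  f2 <- fit_nbss(normalize_spectrum(new_size_spectrum(spk)))
  expect_equal(f2$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f2$intercept - f1$intercept, log2(37), tolerance = 1e-10)
})

test_that("slope estimates cover the truth at the nominal rate", {
  # direct simulation from the regression model: log2 NB = 11 - 0.53 n + eps
  set.seed(101)
  classes <- rep(-11:16, times = 3)
  hits2se <- slope_cover <- int_cover <- logical(1000)
  for (r in 1:1000) {
    nb <- 2^(11 - 0.53 * classes + rnorm(length(classes), 0, 0.5))
    fit <- fit_nbss(tibble::tibble(class_index = classes, nb = nb))
    hits2se[r] <- abs(fit$slope + 0.53) < 2 * fit$slope_se
    ci <- confint(fit$fit)
    slope_cover[r] <- ci[2, 1] <= -0.53 && -0.53 <= ci[2, 2]
    int_cover[r] <- ci[1, 1] <= 11 && 11 <= ci[1, 2]
  }
  expect_gte(mean(hits2se), 0.95)
  # 95% CIs for slope and intercept cover truth within 3% of nominal
  expect_gte(mean(slope_cover), 0.92)
  expect_lte(mean(slope_cover), 0.98)
  expect_gte(mean(int_cover), 0.92)
  expect_lte(mean(int_cover), 0.98)
})

test_that("fit diagnostics flag influential points, especially extreme classes", {
  clean <- fit_nbss(tibble::tibble(class_index = 0:19, nb = 2^(8 - 0.7 * (0:19))))
  dg <- diagnose_fit(clean)
  expect_equal(dg$threshold, 4 / 20)
  expect_equal(nrow(dg$flagged), 0)

  # gross outlier in the top class: must be the most influential point,
  # verified against a leave-one-out slope-change oracle
  pts <- tibble::tibble(class_index = 0:19, nb = 2^(8 - 0.7 * (0:19)))
  pts$nb[20] <- pts$nb[20] * 2^5
  fit <- fit_nbss(pts)
  dg2 <- diagnose_fit(fit)
  expect_true(20 %in% which(fit$data$.cooksd > dg2$threshold))
  expect_true(any(dg2$flagged$extreme_class))

  loo <- vapply(seq_len(20), function(i) {
    abs(coef(lm(log2(nb) ~ class_index, data = pts[-i, ]))[2] - fit$slope)
  }, numeric(1))
  expect_equal(unname(which.max(loo)), unname(which.max(fit$data$.cooksd)))
})

test_that("interaction p-values are uniform when groups share one line", {
  set.seed(202)
  classes <- rep(0:14, times = 2)
  group <- rep(c("A", "B"), each = 15)
  pvals <- replicate(1000, {
    nb <- 2^(6 - 0.8 * classes + rnorm(30, 0, 0.4))
    cmp <- compare_slopes(
      tibble::tibble(class_index = classes, nb = nb, fjord_id = group)
    )
    cmp$p_interaction
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("distinct slopes are detected and one reduces to the plain fit", {
  set.seed(303)
  classes <- rep(0:14, times = 2)
  group <- rep(c("A", "B"), each = 15)
  rejections <- replicate(100, {
    nb <- 2^(ifelse(group == "A", 6 - 0.5 * classes, 6 - 1.0 * classes) +
               rnorm(30, 0, 0.05))
    compare_slopes(
      tibble::tibble(class_index = classes, nb = nb, fjord_id = group)
    )$p_interaction < 0.05
  })
  expect_gte(mean(rejections), 0.99)

  pts <- tibble::tibble(class_index = 0:10, nb = 2^(5 - 0.6 * (0:10) +
                                                      rnorm(11, 0, 0.2)),
                        fjord_id = "only")
  solo <- compare_slopes(pts)
  ref <- fit_nbss(pts)
  expect_equal(solo$common_slope, ref$slope)
  expect_equal(solo$common_slope_se, ref$slope_se)
  expect_equal(solo$intercepts$intercept, ref$intercept)
})

test_that("a shifted group keeps the common slope but moves its intercept", {
  set.seed(404)
  classes <- rep(-5:15, times = 6)
  group <- rep(sprintf("F%d", 1:6), each = 21)
  shift <- ifelse(group == "F3", 2, 0)
  nb <- 2^(9 - 0.53 * classes + shift + rnorm(length(classes), 0, 0.4))
  cmp <- compare_slopes(tibble::tibble(class_index = classes, nb = nb,
                                       fjord_id = group))
  expect_gt(cmp$p_interaction, 0.05)
  pw <- pairwise_intercepts(cmp)
  f3 <- pw[pw$group_1 == "F3" | pw$group_2 == "F3", ]
  rest <- pw[pw$group_1 != "F3" & pw$group_2 != "F3", ]
  expect_true(all(f3$p.value < 0.05))
  expect_true(mean(rest$p.value > 0.05) >= 0.8)
})

test_that("Tukey adjustment is monotone and collapses for two groups", {
  set.seed(509)
  classes <- rep(0:12, times = 4)
  group <- rep(c("A", "B", "C", "D"), each = 13)
  nb <- 2^(6 - 0.7 * classes + rnorm(52, 0, 0.3))
  cmp <- compare_slopes(tibble::tibble(class_index = classes, nb = nb,
                                       fjord_id = group))
  pw <- pairwise_intercepts(cmp)
  unadj <- 2 * pt(-abs(pw$statistic), df = stats::df.residual(cmp$common_model))
  expect_true(all(pw$p.value >= unadj - 1e-12))
  expect_true(all(pw$p.value > 0.05))

  two <- compare_slopes(tibble::tibble(
    class_index = rep(0:12, 2), nb = 2^(6 - 0.7 * rep(0:12, 2) +
                                          rnorm(26, 0, 0.3)),
    fjord_id = rep(c("A", "B"), each = 13)
  ))
  pw2 <- pairwise_intercepts(two)
  unadj2 <- 2 * pt(-abs(pw2$statistic), df = stats::df.residual(two$common_model))
  expect_equal(pw2$p.value, unadj2, tolerance = 1e-9)
})

test_that("intercept-standing stock rank correlations behave at the extremes", {
  # intercepts strictly increasing with totals: rho = 1 on both responses
  sp <- dplyr::bind_rows(lapply(1:6, function(i) {
    spectrum_tbl(0:10, 1, (2 + i) * 2^(8 - 0.5 * (0:10)), station = paste0("S", i))
  }))
  out <- suppressWarnings(intercept_biomass_correlation(new_size_spectrum(sp)))
  expect_equal(out$rho, c(1, 1))

  # anti-monotone construction: bigger totals, lower intercepts
  sp2 <- dplyr::bind_rows(lapply(1:6, function(i) {
    base <- 2^(8 - 0.5 * (0:10)) * 2^(-i)   # falling intercept
    extra <- spectrum_tbl(15, 1, i * 3e5, station = paste0("S", i)) # rising total
    dplyr::bind_rows(spectrum_tbl(0:10, 1, base, station = paste0("S", i)), extra)
  }))
  out2 <- suppressWarnings(intercept_biomass_correlation(new_size_spectrum(sp2)))
  expect_equal(out2$rho[out2$response == "total_dm"], -1)

  expect_error(
    intercept_biomass_correlation(new_size_spectrum(
      spectrum_tbl(0:10, 1, 2^(8 - 0.5 * (0:10)))
    )),
    "at least 5 stations"
  )
})

test_that("restricting to a common class range strengthens the correlation", {
  # stations share a common range whose intercept tracks base biomass, but a
  # random subset carries extra top-heavy classes that inflate totals while
  # dragging the free-slope intercept down
  set.seed(606)
  rhos <- replicate(500, {
    sp <- dplyr::bind_rows(lapply(1:18, function(i) {
      base_int <- 6 + i / 6
      common <- spectrum_tbl(-10:16, 1,
                             2^(base_int - 0.53 * (-10:16) +
                                  rnorm(27, 0, 0.3) + (-10:16)),
                             station = paste0("S", i))
      if (i %% 3 == 0) {
        top <- spectrum_tbl(17:21, 1, 2^(17:21 + 3), station = paste0("S", i))
        dplyr::bind_rows(common, top)
      } else {
        common
      }
    }))
    sp <- new_size_spectrum(sp)
    full <- intercept_biomass_correlation(sp)
    trunc <- intercept_biomass_correlation(sp, class_range = c(-10, 16))
    c(full$rho[1], trunc$rho[1])
  })
  expect_gt(mean(rhos[2, ]), mean(rhos[1, ]))
})
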