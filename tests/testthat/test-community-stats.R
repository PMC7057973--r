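test_that("Bray-Curtis similarities match the direct formula", {
  m <- tibble::tibble(
    station_id = c("a", "b", "c"),
    t1 = c(4, 4, 0), t2 = c(1, 1, 0), t3 = c(0, 0, 9), t4 = c(9, 9, 1)
  )
  r <- bray_curtis(m)
  direct <- bray_curtis_direct(as.matrix(m[, -1]) |>
                                 `rownames<-`(m$station_id))
  expect_equal(r$values, direct, tolerance = 1e-12)
  expect_equal(r$values["a", "b"], 100)       # identical rows
  expect_equal(r$values["a", "a"], 100)

  disjoint <- tibble::tibble(station_id = c("a", "b"),
                             t1 = c(3, 0), t2 = c(0, 5))
  expect_equal(bray_curtis(disjoint)$values["a", "b"], 0)

  set.seed(8)
  big <- tibble::as_tibble(matrix(rpois(60, 4), nrow = 6),
                           .name_repair = ~paste0("t", 1:10))
  big$station_id <- paste0("s", 1:6)
  r2 <- bray_curtis(big)
  d2 <- bray_curtis_direct(as.matrix(big[, 1:10]) |>
                             `rownames<-`(big$station_id))
  expect_equal(r2$values, d2, tolerance = 1e-12)

  zero <- tibble::tibble(station_id = c("a", "b"), t1 = c(0, 1), t2 = c(0, 2))
  expect_error(bray_curtis(zero), "all-zero")
})

test_that("Bray-Curtis is invariant to an all-zero taxon column", {
  set.seed(9)
  m <- tibble::as_tibble(matrix(rpois(24, 3), nrow = 4),
                         .name_repair = ~paste0("t", 1:6))
  m$station_id <- paste0("s", 1:4)
  with_zero <- dplyr::mutate(m, t_extra = 0)
  expect_equal(bray_curtis(m)$values, bray_curtis(with_zero)$values)
})

test_that("PERMANOVA pseudo-F matches the direct partition and vegan", {
  set.seed(10)
  x <- matrix(rnorm(6 * 4), nrow = 6)
  tbl <- tibble::as_tibble(x, .name_repair = ~paste0("v", 1:4))
  tbl$station_id <- paste0("s", 1:6)
  r <- euclidean_resemblance(tbl)
  groups <- rep(c("g1", "g2"), each = 3)

  res <- permanova_oneway(r, groups, seed = 1)
  expect_equal(res$statistic, pseudo_f_direct(dist(x), groups))

  veg <- vegan::adonis2(dist(x) ~ g, data = data.frame(g = groups),
                        permutations = 99)
  expect_equal(res$statistic, veg$F[1], tolerance = 1e-10)
})

test_that("small designs are enumerated exhaustively and match brute force", {
  set.seed(12)
  x <- matrix(rnorm(6 * 3), nrow = 6)
  tbl <- tibble::as_tibble(x, .name_repair = ~paste0("v", 1:3))
  tbl$station_id <- paste0("s", 1:6)
  r <- euclidean_resemblance(tbl)
  groups <- rep(c("g1", "g2"), each = 3)

  res <- permanova_oneway(r, groups, seed = 1)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$n_permutations, 20)

  # independent brute force over every 3-of-6 labelling
  d <- dist(x)
  fs <- apply(utils::combn(6, 3), 2, function(idx) {
    g <- rep("g2", 6); g[idx] <- "g1"
    pseudo_f_direct(d, g)
  })
  expect_equal(res$p_perm, mean(fs >= res$statistic - 1e-12))

  # two well-separated clusters: observed split is uniquely extreme
  sep <- rbind(matrix(rnorm(9, 0, 0.1), 3), matrix(rnorm(9, 50, 0.1), 3))
  tbl2 <- tibble::as_tibble(sep, .name_repair = ~paste0("v", 1:3))
  tbl2$station_id <- paste0("s", 1:6)
  # with equal group sizes every split appears twice (group labels swap),
  # so the attainable floor is 2/20
  res2 <- permanova_oneway(euclidean_resemblance(tbl2), groups, seed = 1)
  expect_equal(res2$p_perm, 2 / 20)

  expect_error(permanova_oneway(r, c("a", "a", "a", "a", "a", "b"), seed = 1),
               "at least 2 members")
})

test_that("PERMANOVA is invariant to station order and seed-deterministic", {
  set.seed(13)
  x <- matrix(rnorm(12 * 3), nrow = 12)
  tbl <- tibble::as_tibble(x, .name_repair = ~paste0("v", 1:3))
  tbl$station_id <- paste0("s", 1:12)
  groups <- rep(c("g1", "g2", "g3"), each = 4)
  r <- euclidean_resemblance(tbl)

  perm <- sample(12)
  r2 <- euclidean_resemblance(tbl[perm, ])
  a <- permanova_oneway(r, groups, n_perm = 499, seed = 7)
  b <- permanova_oneway(r2, groups[perm], n_perm = 499, seed = 7)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)

  a2 <- permanova_oneway(r, groups, n_perm = 499, seed = 7)
  expect_identical(a$p_perm, a2$p_perm)
  expect_gte(a$p_perm, 1 / (a$n_permutations + 1))
})

test_that("matrix rank correlation hits the trivial extremes and matches vegan", {
  set.seed(14)
  x <- matrix(rnorm(7 * 3), nrow = 7)
  tbl <- tibble::as_tibble(x, .name_repair = ~paste0("v", 1:3))
  tbl$station_id <- paste0("s", 1:7)
  r <- euclidean_resemblance(tbl)

  self <- relate_mantel(r, r, n_perm = 99, seed = 1)
  expect_equal(self$statistic, 1)

  # rank-reversed copy: distances replaced by (max - d), reversing all ranks
  rev <- r
  rev$values <- max(r$values) - r$values
  diag(rev$values) <- 0
  flipped <- relate_mantel(r, rev, n_perm = 99, seed = 1)
  expect_equal(flipped$statistic, -1)

  other <- euclidean_resemblance(dplyr::mutate(tbl, v1 = rnorm(7)))
  ours <- relate_mantel(r, other, n_perm = 999, seed = 3)
  veg <- vegan::mantel(resemblance_as_dist_test(r), resemblance_as_dist_test(other),
                       method = "spearman", permutations = 99)
  expect_equal(ours$statistic, unname(veg$statistic), tolerance = 1e-12)

  bad <- euclidean_resemblance(dplyr::mutate(tbl, station_id = paste0("x", 1:7)))
  expect_error(relate_mantel(r, bad), "same stations")
})

test_that("shared-gradient strength separates strong from weak matrix correlation", {
  set.seed(15)
  strong <- weak <- numeric(30)
  for (r in 1:30) {
    grad <- seq(0, 1, length.out = 12)
    m_of <- function(noise_sd) {
      tbl <- tibble::tibble(
        station_id = paste0("s", 1:12),
        a = grad + rnorm(12, 0, noise_sd),
        b = 2 * grad + rnorm(12, 0, noise_sd)
      )
      euclidean_resemblance(tbl)
    }
    base <- m_of(0.05)
    strong[r] <- relate_mantel(base, m_of(0.15), n_perm = 9, seed = r)$statistic
    weak[r] <- relate_mantel(base, m_of(1.5), n_perm = 9, seed = r)$statistic
  }
  expect_gt(mean(strong), 0.5)
  expect_lt(mean(weak), 0.4)
  expect_gt(mean(strong) - mean(weak), 0.2)
})

test_that("DistLM marginal tests find a constructed driver and match forward start", {
  set.seed(16)
  pred <- tibble::tibble(
    station_id = paste0("s", 1:15),
    driver = rnorm(15),
    noise = rnorm(15)
  )
  # distance matrix generated by the driver alone
  r <- euclidean_resemblance(dplyr::select(pred, "station_id", "driver"))
  out <- distlm(r, pred, mode = "forward_adjR2", n_perm = 199, seed = 2)

  marg <- out$marginal
  expect_gt(marg$pct_var[marg$predictor == "driver"], 99)
  expect_lt(marg$p.value[marg$predictor == "driver"], 0.05)
  expect_equal(out$selected$predictor[1], "driver")

  # single predictor: forward selection reproduces the marginal test exactly
  solo <- distlm(r, dplyr::select(pred, "station_id", "driver"),
                 mode = "forward_adjR2", n_perm = 199, seed = 2)
  expect_equal(solo$selected$pseudo_F[1],
               solo$marginal$pseudo_F[solo$marginal$predictor == "driver"])
  expect_equal(solo$selected$p.value[1],
               solo$marginal$p.value[solo$marginal$predictor == "driver"])
})

test_that("two constructed predictors jointly explaining ~41% are both selected", {
  set.seed(17)
  shares <- replicate(40, {
    n <- 18
    p1 <- rnorm(n); p2 <- rnorm(n)
    # response with population R2 = 0.41, split between two predictors
    signal <- sqrt(0.28) * p1 + sqrt(0.13) * p2
    y <- signal + rnorm(n, 0, sqrt(1 - 0.41))
    tbl <- tibble::tibble(station_id = paste0("s", 1:n), y = y)
    r <- euclidean_resemblance(tbl)
    pred <- tibble::tibble(station_id = tbl$station_id, p1 = p1, p2 = p2,
                           junk = rnorm(n))
    out <- distlm(r, pred, mode = "forward_adjR2", n_perm = 99, seed = 3)
    if (all(c("p1", "p2") %in% out$selected$predictor)) {
      max(out$selected$pct_var_cum[out$selected$predictor %in% c("p1", "p2")])
    } else {
      NA_real_
    }
  })
  expect_gt(mean(!is.na(shares)), 0.7)         # both drivers usually recovered
  expect_equal(mean(shares, na.rm = TRUE), 41, tolerance = 0.25)
})

test_that("collinear and constant predictors are dropped with a warning", {
  set.seed(18)
  pred <- tibble::tibble(
    station_id = paste0("s", 1:10),
    a = rnorm(10)
  )
  pred$b <- 2 * pred$a + 3       # perfectly collinear
  pred$flat <- 1                  # constant
  r <- euclidean_resemblance(dplyr::select(pred, "station_id", "a"))
  expect_warning(
    expect_warning(distlm(r, pred, n_perm = 49, seed = 1), "constant"),
    "collinear"
  )
})

test_that("gamma GLM recovers temperature effects on body mass", {
  set.seed(19)
  # flat relation: no direction
  temp <- rep(c(0, 4, 8), length.out = 120)
  flat <- taxon_temp_glm(rgamma(120, shape = 20, rate = 20 / 50), temp)
  expect_equal(flat$direction, "none")
  expect_lt(abs(flat$estimate), 0.05)

  # dm = exp(a - 0.1 T) with gamma noise: negative direction, estimate near -0.1
  temp2 <- runif(500, -2, 8)
  mu <- exp(4 - 0.1 * temp2)
  dm <- rgamma(500, shape = 8, rate = 8 / mu)
  fit <- taxon_temp_glm(dm, temp2)
  expect_equal(fit$direction, "negative")
  expect_lt(abs(fit$estimate + 0.1), 2 * fit$std.error)

  # two temperature levels: sign equals the log mean ratio
  t2 <- rep(c(1, 5), each = 100)
  dm2 <- rgamma(200, shape = 10, rate = 10 / exp(3 + 0.08 * t2))
  fit2 <- taxon_temp_glm(dm2, t2)
  ratio_sign <- sign(log(mean(dm2[t2 == 5]) / mean(dm2[t2 == 1])))
  expect_equal(sign(fit2$estimate), ratio_sign)
  # closed form for the two-group gamma GLM with log link: the slope is
  # log(mean ratio) / (T2 - T1)
  expect_equal(fit2$estimate,
               log(mean(dm2[t2 == 5]) / mean(dm2[t2 == 1])) / 4,
               tolerance = 1e-6)

  expect_error(taxon_temp_glm(c(-1, rep(1, 20)), rep(c(1, 2), length.out = 21)),
               "positive")
  expect_error(taxon_temp_glm(rep(1, 20), rep(3, 20)), "temperature levels")
  expect_error(taxon_temp_glm(rep(1, 5), rep(c(1, 2), length.out = 5)),
               "at least 10")
})
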