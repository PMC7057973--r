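#' Resemblance matrices between stations
#'
#' A `resemblance` is a labeled symmetric matrix of either Euclidean
#' distances or Bray-Curtis similarities (stored on the 0-100 similarity
#' scale, converted internally to dissimilarity where needed).
#'
#' `euclidean_resemblance()` computes Euclidean distances between station
#' rows of a numeric table. `bray_curtis()` computes Bray-Curtis
#' similarities `S = 100 * (1 - sum|x_i - x_j| / sum(x_i + x_j))` after an
#' optional square-root transform (the standard treatment for biomass data).
#'
#' @param data A data frame with one row per station: an id column plus
#'   numeric columns (taxa, size classes, traits or environmental
#'   variables).
#' @param id_col Name of the station identifier column (default
#'   `"station_id"`).
#' @param transform `"sqrt"` (default for `bray_curtis`) or `"none"`.
#' @return A `resemblance` object.
#' @export
euclidean_resemblance <- function(data, id_col = "station_id") {
  m <- resemblance_input(data, id_col)
  d <- as.matrix(dist(m, method = "euclidean"))
  new_resemblance(d, kind = "euclidean_distance")
}

#' @rdname euclidean_resemblance
#' @export
bray_curtis <- function(data, id_col = "station_id",
                        transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  m <- resemblance_input(data, id_col)
  if (any(m < 0)) abort("Bray-Curtis needs a nonnegative table")
  if (any(rowSums(m) == 0)) {
    abort(paste0(
      "Bray-Curtis similarity undefined for all-zero row(s): ",
      paste(rownames(m)[rowSums(m) == 0], collapse = ", ")
    ))
  }
  if (transform == "sqrt") m <- sqrt(m)
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  new_resemblance(100 * (1 - d), kind = "bray_curtis_similarity")
}

resemblance_input <- function(data, id_col) {
  df <- tibble::as_tibble(data)
  require_columns(df, id_col, "resemblance input")
  if (nrow(df) < 2) abort("need at least 2 rows")
  if (anyDuplicated(df[[id_col]])) abort("duplicate station labels")
  m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  if (!is.numeric(m)) abort("all non-id columns must be numeric")
  rownames(m) <- df[[id_col]]
  m
}

new_resemblance <- function(values, kind) {
  stopifnot(isSymmetric(unname(values)))
  structure(
    list(values = values, labels = rownames(values), kind = kind),
    class = "resemblance"
  )
}

#' @export
print.resemblance <- function(x, ...) {
  cat("<resemblance>", x$kind, "among", length(x$labels), "stations\n")
  print(round(x$values[seq_len(min(6, nrow(x$values))),
                       seq_len(min(6, ncol(x$values)))], 2))
  invisible(x)
}

#' @export
tidy.resemblance <- function(x, ...) {
  idx <- which(lower.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    station_1 = x$labels[idx[, 2]],
    station_2 = x$labels[idx[, 1]],
    value = x$values[idx],
    kind = x$kind
  )
}

# distance form of any resemblance: similarities flip to dissimilarity in [0,1]
resemblance_as_dist <- function(r) {
  stopifnot(inherits(r, "resemblance"))
  if (r$kind == "bray_curtis_similarity") {
    as.dist(1 - r$values / 100)
  } else {
    as.dist(r$values)
  }
}

# all labeled assignments of n items to groups with the given sizes,
# as a matrix of group indices (rows = assignments)
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  rec <- function(free, sizes_left) {
    if (length(sizes_left) == 1) {
      return(list(list(free)))
    }
    g <- sizes_left[1]
    picks <- combn(free, g, simplify = FALSE)
    out <- list()
    for (p in picks) {
      for (rest in rec(setdiff(free, p), sizes_left[-1])) {
        out[[length(out) + 1]] <- c(list(p), rest)
      }
    }
    out
  }
  assignments <- rec(seq_len(n), sizes)
  t(vapply(assignments, function(a) {
    lab <- integer(n)
    for (g in seq_along(a)) lab[a[[g]]] <- g
    lab
  }, integer(n)))
}

permanova_pseudo_f <- function(d2, groups) {
  n <- nrow(d2)
  k <- nlevels(groups)
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  (ss_among / (k - 1)) / (ss_within / (n - k))
}

#' One-way PERMANOVA
#'
#' Partitions a distance matrix into among- and within-group sums of squared
#' interpoint distances (the standard semimetric partitioning) and tests the
#' pseudo-F statistic by permutation of group labels. When the number of
#' distinct labeled assignments is at most `max_exhaustive` the permutation
#' distribution is enumerated exhaustively (the p-value is then exact);
#' otherwise `n_perm` random permutations are drawn from the given seed.
#'
#' @param resemblance A `resemblance` object (distances; similarities are
#'   converted).
#' @param groups Group membership, one per station, in label order; or a
#'   data frame with `station_id` and a grouping column.
#' @param group Grouping column name when `groups` is a data frame.
#' @param n_perm Number of random permutations (default 9999).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param max_exhaustive Enumerate exhaustively when the assignment count is
#'   at most this (default 1e5).
#' @return A `permutation_result`: `statistic` (pseudo-F), `p_perm`,
#'   `n_permutations` (effective), `seed`, `method`, `df` and sums of
#'   squares.
#' @export
permanova_oneway <- function(resemblance, groups, group = NULL,
                             n_perm = 9999, seed = 1,
                             max_exhaustive = 1e5) {
  d <- as.matrix(resemblance_as_dist(resemblance))
  if (is.data.frame(groups)) {
    stopifnot(!is.null(group))
    idx <- match(resemblance$labels, groups$station_id)
    if (anyNA(idx)) abort("groups table does not cover all stations")
    groups <- groups[[group]][idx]
  }
  groups <- factor(groups)
  if (length(groups) != nrow(d)) abort("one group label per station required")
  sizes <- table(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) abort("every group needs at least 2 members")

  d2 <- d^2
  f_obs <- permanova_pseudo_f(d2, groups)
  n <- nrow(d)
  k <- nlevels(groups)

  n_assign <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (n_assign <= max_exhaustive) {
    perms <- enumerate_assignments(as.integer(sizes))
    # map enumerated group indices onto the observed sizes/levels
    f_perm <- apply(perms, 1, function(lab) {
      permanova_pseudo_f(d2, factor(lab))
    })
    p <- mean(f_perm >= f_obs - 1e-12)
    method <- "exhaustive"
    n_eff <- nrow(perms)
  } else {
    set.seed(seed)
    f_perm <- replicate(n_perm, {
      permanova_pseudo_f(d2, sample(groups))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (n_perm + 1)
    method <- "sampled"
    n_eff <- n_perm
  }

  structure(
    list(
      statistic = f_obs, p_perm = p, n_permutations = n_eff, seed = seed,
      method = method, df_num = k - 1, df_den = n - k,
      kind = "pseudo-F"
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result>", x$kind, "=", signif(x$statistic, 5),
      "| p =", signif(x$p_perm, 4),
      "(", x$method, ",", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p.value = x$p_perm,
    n_permutations = x$n_permutations,
    method = x$method
  )
}

#' Matrix rank correlation (RELATE / Mantel-type test)
#'
#' Spearman rank correlation between the off-diagonal elements of two
#' resemblance matrices over the same stations, with significance assessed
#' by jointly permuting the rows and columns of the second matrix. This is
#' the nonparametric matrix-matching test commonly used to compare
#' community and environmental resemblance patterns.
#'
#' @param m1,m2 `resemblance` objects with identical labels in identical
#'   order.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @return A `permutation_result` with `statistic` = rho and a one-sided
#'   permutation p-value.
#' @export
relate_mantel <- function(m1, m2, n_perm = 9999, seed = 1) {
  stopifnot(inherits(m1, "resemblance"), inherits(m2, "resemblance"))
  if (!identical(m1$labels, m2$labels)) {
    abort("resemblance matrices must share the same stations in the same order")
  }
  a <- as.matrix(resemblance_as_dist(m1))
  b <- as.matrix(resemblance_as_dist(m2))
  lt <- lower.tri(a)
  rho_obs <- cor(a[lt], b[lt], method = "spearman")
  set.seed(seed)
  rho_perm <- replicate(n_perm, {
    p <- sample(nrow(b))
    cor(a[lt], b[p, p][lt], method = "spearman")
  })
  p <- (1 + sum(rho_perm >= rho_obs - 1e-12)) / (n_perm + 1)
  structure(
    list(
      statistic = rho_obs, p_perm = p, n_permutations = n_perm, seed = seed,
      method = "sampled", kind = "rho"
    ),
    class = "permutation_result"
  )
}

#' Distance-based linear model (DistLM)
#'
#' Relates a resemblance matrix to station-level predictors. Marginal mode
#' tests each predictor alone (permutational pseudo-F and the share of
#' variation it explains). Forward mode performs forward selection using
#' the adjusted-R^2 criterion: at each step the candidate giving the
#' largest adjusted R^2 is added, stopping when no candidate improves it;
#' each added term also receives a sequential permutation test. Predictors
#' are z-scored by default; of a perfectly collinear pair the later one is
#' dropped with a warning.
#'
#' @param resemblance A `resemblance` object.
#' @param predictors Data frame with `station_id` plus numeric predictor
#'   columns, covering every station.
#' @param mode `"marginal"` or `"forward_adjR2"`.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @param normalize z-score the predictors first? Default `TRUE`.
#' @return A `distlm_result` with a `marginal` tibble (always computed) and,
#'   in forward mode, a `selected` tibble (step, predictor, cumulative R^2
#'   and adjusted R^2, sequential pseudo-F and p).
#' @export
distlm <- function(resemblance, predictors, mode = c("marginal", "forward_adjR2"),
                   n_perm = 9999, seed = 1, normalize = TRUE) {
  mode <- match.arg(mode)
  d <- resemblance_as_dist(resemblance)
  pred <- tibble::as_tibble(predictors)
  require_columns(pred, "station_id", "predictors")
  idx <- match(resemblance$labels, pred$station_id)
  if (anyNA(idx)) abort("predictors must cover every station in the resemblance")
  pred <- pred[idx, ]
  x <- pred[, setdiff(names(pred), c("station_id", "fjord_id")), drop = FALSE]
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  if (ncol(x) == 0) abort("no numeric predictors supplied")
  constant <- vapply(x, function(v) sd(v) == 0, logical(1))
  if (any(constant)) {
    warn(paste0("dropping constant predictor(s): ",
                paste(names(x)[constant], collapse = ", ")))
    x <- x[, !constant, drop = FALSE]
  }
  if (ncol(x) > 1) {
    cm <- abs(cor(as.matrix(x)))
    drop <- rep(FALSE, ncol(x))
    for (j in 2:ncol(x)) {
      if (any(cm[j, seq_len(j - 1)][!drop[seq_len(j - 1)]] >= 1 - 1e-12)) {
        drop[j] <- TRUE
      }
    }
    if (any(drop)) {
      warn(paste0("dropping perfectly collinear predictor(s): ",
                  paste(names(x)[drop], collapse = ", ")))
      x <- x[, !drop, drop = FALSE]
    }
  }
  if (normalize) x <- as.data.frame(scale(as.matrix(x)))
  vars <- names(x)
  if (nrow(x) <= length(vars) + 1 && mode == "forward_adjR2") {
    warn("few stations relative to predictors; forward selection may saturate")
  }

  dat <- as.data.frame(x)

  marginal <- purrr::map_dfr(vars, function(v) {
    set.seed(seed)
    a <- vegan::adonis2(
      stats::as.formula(paste("d ~", v)),
      data = dat, permutations = n_perm
    )
    tibble::tibble(
      predictor = v,
      pseudo_F = a$F[1],
      p.value = a$`Pr(>F)`[1],
      pct_var = 100 * a$R2[1]
    )
  })

  selected <- NULL
  if (mode == "forward_adjR2") {
    chosen <- character(0)
    current_adj <- 0
    steps <- list()
    repeat {
      cands <- setdiff(vars, chosen)
      if (length(cands) == 0) break
      adj <- vapply(cands, function(v) {
        f <- stats::as.formula(paste("d ~", paste(c(chosen, v), collapse = " + ")))
        vegan::RsquareAdj(vegan::dbrda(f, data = dat))$adj.r.squared
      }, numeric(1))
      best <- cands[which.max(adj)]
      if (max(adj) <= current_adj + 1e-12 && length(chosen) > 0) break
      if (length(chosen) == 0 && max(adj) <= 0) break
      # sequential test of the added term
      set.seed(seed)
      f <- stats::as.formula(paste("d ~", paste(c(chosen, best), collapse = " + ")))
      a <- vegan::adonis2(f, data = dat, permutations = n_perm, by = "terms")
      i <- length(chosen) + 1
      steps[[i]] <- tibble::tibble(
        step = i,
        predictor = best,
        adj_r2 = max(adj),
        pseudo_F = a$F[i],
        p.value = a$`Pr(>F)`[i],
        pct_var_cum = 100 * sum(a$R2[seq_len(i)])
      )
      chosen <- c(chosen, best)
      current_adj <- max(adj)
    }
    selected <- if (length(steps)) dplyr::bind_rows(steps) else
      tibble::tibble(step = integer(), predictor = character(),
                     adj_r2 = numeric(), pseudo_F = numeric(),
                     p.value = numeric(), pct_var_cum = numeric())
  }

  structure(
    list(marginal = marginal, selected = selected, mode = mode,
         n_perm = n_perm, seed = seed),
    class = "distlm_result"
  )
}

#' @export
print.distlm_result <- function(x, ...) {
  cat("<distlm_result> mode:", x$mode, "|", x$n_perm, "permutations\n")
  cat("marginal tests:\n"); print(x$marginal)
  if (!is.null(x$selected)) {
    cat("forward selection (adjusted R^2 criterion):\n"); print(x$selected)
  }
  invisible(x)
}

#' @export
tidy.distlm_result <- function(x, ...) {
  if (!is.null(x$selected)) x$selected else x$marginal
}

#' Gamma GLM of individual dry mass against temperature
#'
#' Log-link gamma regression of individual dry mass on near-bottom
#' temperature, the standard model for positive right-skewed body-mass data.
#' Reports the temperature coefficient (per degree C, on the log scale), its
#' standard error and p-value, and a direction call at the given alpha.
#'
#' @param dm_ug Positive individual dry masses (ug).
#' @param temperature_C Temperature for each individual (station value).
#' @param min_n Minimum number of individuals (default 10).
#' @param alpha Significance level for the direction call (default 0.05).
#' @return A one-row tibble: `estimate`, `std.error`, `p.value`,
#'   `direction` (`"positive"`, `"negative"`, `"none"` or
#'   `"nonestimable"`), `n`.
#' @export
taxon_temp_glm <- function(dm_ug, temperature_C, min_n = 10, alpha = 0.05) {
  if (any(dm_ug <= 0)) abort("gamma GLM needs strictly positive dry masses")
  if (length(dm_ug) < min_n) {
    abort(paste0("need at least ", min_n, " individuals"))
  }
  if (length(unique(temperature_C)) < 2) {
    abort("taxon must occur at >= 2 temperature levels")
  }
  fit <- tryCatch(
    glm(dm_ug ~ temperature_C, family = Gamma(link = "log")),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit) || !fit$converged) {
    return(tibble::tibble(
      estimate = NA_real_, std.error = NA_real_, p.value = NA_real_,
      direction = "nonestimable", n = length(dm_ug)
    ))
  }
  s <- summary(fit)$coefficients
  est <- s["temperature_C", 1]
  se <- s["temperature_C", 2]
  p <- s["temperature_C", 4]
  tibble::tibble(
    estimate = est, std.error = se, p.value = p,
    direction = if (p >= alpha) "none" else if (est > 0) "positive" else "negative",
    n = length(dm_ug)
  )
}
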