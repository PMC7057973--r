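# small in-code fixtures shared across test files

tiny_organisms <- function() {
  tibble::tibble(
    fjord_id = "F1",
    station_id = "S1",
    taxon_id = c("Copepoda", "Nematoda", "Maldanidae"),
    group = c("meiofauna", "meiofauna", "macrofauna"),
    length_mm = c(0.5, 1.2, 12),
    width_mm = c(0.12, 0.04, 1.1),
    count_weight = c(2, 1, 1),
    gear = c("syringe_core", "syringe_core", "van_veen_grab")
  )
}

tiny_stations <- function(fjords = "F1", stations = "S1") {
  tidyr::crossing(
    fjord_id = fjords,
    station_id = stations,
    tibble::tibble(
      gear = c("van_veen_grab", "syringe_core"),
      sampled_area_cm2 = c(1000, 10)
    )
  )
}

# a spectrum tibble built by hand (per 0.1 m^2)
spectrum_tbl <- function(classes, abundance, biomass,
                         fjord = "F1", station = "S1") {
  tibble::tibble(
    fjord_id = fjord, station_id = station,
    class_index = as.integer(classes),
    abundance = abundance, biomass_ug = biomass
  )
}

# organisms whose dry mass is given directly (pre-converted records)
organisms_with_dm <- function(dm_ug, count_weight = 1, group = "macrofauna",
                              fjord = "F1", station = "S1") {
  tibble::tibble(
    fjord_id = fjord, station_id = station,
    taxon_id = "Maldanidae", group = group,
    length_mm = 1, width_mm = 1,
    count_weight = count_weight,
    dry_mass_ug = dm_ug,
    gear = gear_for_group_test(group),
    sampled_area_cm2 = ifelse(group == "meiofauna", 10, 1000)
  )
}

gear_for_group_test <- function(group) {
  ifelse(group == "meiofauna", "syringe_core", "van_veen_grab")
}

# independent brute-force size-class oracle: linear scan over interval bounds
size_class_scan <- function(m) {
  vapply(m, function(x) {
    for (j in -40:40) {
      if (2^j <= x && x < 2^(j + 1)) return(j)
    }
    stop("mass out of scanned range")
  }, numeric(1))
}

# direct-formula Bray-Curtis similarity (percent) on a raw matrix
bray_curtis_direct <- function(m, sqrt_transform = TRUE) {
  if (sqrt_transform) m <- sqrt(m)
  n <- nrow(m)
  s <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s[i, j] <- 100 * (1 - sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ]))
    }
  }
  s
}

# distance view of a euclidean resemblance, for vegan cross-checks
resemblance_as_dist_test <- function(r) {
  stats::as.dist(r$values)
}

# direct one-way PERMANOVA pseudo-F from a distance matrix
pseudo_f_direct <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  groups <- factor(groups)
  k <- nlevels(groups)
  sst <- sum(d2[lower.tri(d2)]) / n
  ssw <- 0
  for (g in levels(groups)) {
    i <- which(groups == g)
    sub <- d2[i, i, drop = FALSE]
    ssw <- ssw + sum(sub[lower.tri(sub)]) / length(i)
  }
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}
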