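# Fixture builders and independent brute-force oracles shared by the tests.

# A straight equatorial track: n points, one per minute, spaced dlon degrees.
mk_track <- function(n, dlon = 0.001, lat = 0, t0 = "2021-06-01 07:00:00") {
  tibble::tibble(
    lon = seq(0, by = dlon, length.out = n),
    lat = lat,
    time = lubridate::ymd_hms(t0, tz = "UTC") + 60 * (seq_len(n) - 1)
  )
}

mk_gpx <- function(track) write_gpx_text(track)

# Minimal single-species registry.
mk_registry <- function(a = 0.01, b = 3, lmin = 1, lmax = 50, mcrs = NA,
                        code = "SPX", group = "fish") {
  tibble::tibble(code = code, scientific_name = "Species x", a = a, b = b,
                 length_min_cm = lmin, length_max_cm = lmax, mcrs_cm = mcrs,
                 group = group)
}

# Hand-assembled miniature survey: n_hauls hauls with explicit geometry, one
# landed (+ optionally one discarded) sample per haul, individuals supplied by
# the caller as a list of tibbles per haul.
mk_mini_survey <- function(hauls, samples, individuals,
                           registry = mk_registry()) {
  list(species = registry, hauls = hauls, samples = samples,
       individuals = individuals, tracks = NULL, onboard = NULL)
}

# Independent Eq-3/Eq-4 oracle: base-R loops over a fully materialized
# (group, key, sample) table; sum of per-sample values divided by the number
# of hauls in the group.
oracle_aggregate <- function(values, hauls, by, keys) {
  hauls <- as.data.frame(hauls)
  values <- as.data.frame(merge(values, hauls[, c("haul_id", by),
                                              drop = FALSE], by = "haul_id"))
  grp_of <- function(df) {
    if (length(by) == 0) rep("all", nrow(df)) else
      do.call(paste, c(df[, by, drop = FALSE], sep = "\r"))
  }
  values$.g <- grp_of(values)
  hauls$.g <- grp_of(hauls)
  out <- list()
  for (g in unique(values$.g)) {
    n_hauls <- sum(hauls$.g == g)
    sub <- values[values$.g == g, , drop = FALSE]
    key_str <- do.call(paste, c(sub[, keys, drop = FALSE], sep = "\r"))
    for (k in unique(key_str)) {
      rows <- sub[key_str == k, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        .g = g, .k = k, value = sum(rows$value) / n_hauls,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Key string matching oracle_aggregate for a package aggregation result.
agg_key <- function(agg, by, keys) {
  g <- if (length(by) == 0) rep("all", nrow(agg)) else
    do.call(paste, c(agg[, by, drop = FALSE], sep = "\r"))
  k <- do.call(paste, c(agg[, keys, drop = FALSE], sep = "\r"))
  paste(g, k, sep = "\v")
}

# Randomized miniature standardized-values fixture over <= 20 hauls.
mk_random_fixture <- function(seed, n_hauls = 12, n_species = 5,
                              categories = c("landed", "discarded",
                                             "natural_debris")) {
  set.seed(seed)
  ports <- c("PA", "PB", "PC")
  hauls <- tibble::tibble(
    haul_id = sprintf("h%02d", seq_len(n_hauls)),
    port = sample(ports, n_hauls, replace = TRUE),
    date = as.Date("2021-03-01") + sample(0:300, n_hauls)
  )
  rows <- list()
  sid <- 0
  for (h in hauls$haul_id) {
    for (cat in sample(categories, sample(1:3, 1))) {
      sid <- sid + 1
      for (sp in sample(sprintf("S%d", seq_len(n_species)),
                        sample(1:n_species, 1))) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          haul_id = h, sample_id = sprintf("smp%03d", sid),
          category = cat, species_code = sp,
          length_class = sample(c(1, 2, 5), 1),
          value = round(runif(1, 0, 50), 3))
      }
    }
  }
  list(hauls = hauls, values = dplyr::bind_rows(rows))
}

expect_issue_rules <- function(issues, rules) {
  expect_setequal(unique(issues$rule_id), rules)
}
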