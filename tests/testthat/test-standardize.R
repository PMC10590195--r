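test_that("bin_lengths uses half-open classes labelled by lower bound", {
  ind <- tibble::tibble(species_code = "SPX",
                        length_cm = c(2.1, 2.9, 3.0),
                        sample_id = "s1")
  out <- bin_lengths(ind, bin_width = 1)
  expect_equal(out$length_class, c(2, 3))
  expect_equal(out$count, c(2L, 1L))  # boundary 3.0 falls in bin 3
  expect_equal(sum(out$count), nrow(ind))
  empty <- bin_lengths(ind[0, ], bin_width = 1)
  expect_equal(nrow(empty), 0)
  expect_error(bin_lengths(ind, bin_width = 0), "positive")
})

test_that("bin widths come from the taxon group when not forced", {
  reg <- dplyr::bind_rows(mk_registry(code = "FSH", group = "fish"),
                          mk_registry(code = "CRU", group = "crustacean"))
  ind <- tibble::tibble(species_code = c("FSH", "CRU"),
                        length_cm = c(10.7, 2.7), sample_id = "s1")
  out <- bin_lengths(ind, registry = reg)
  expect_equal(out$length_class[out$species_code == "FSH"], 10)   # 1 cm bins
  expect_equal(out$length_class[out$species_code == "CRU"], 2.5)  # 0.5 cm
})

test_that("abundance_density implements the swept-area standardization", {
  expect_equal(abundance_density(10, sp = 2, dp = 1, sd_km = 2,
                                 gw_km = 0.05), 200)
  expect_equal(abundance_density(0, 1, 1, 1, 1), 0)
  expect_equal(abundance_density(5, 1, 1, 1, 1), 5)
  expect_error(abundance_density(5, 1, 1, 0, 1), "degenerate")
  expect_error(abundance_density(5, 0.5, 1, 1, 1), ">= 1")
})

test_that("abundance is linear in the raising factor", {
  base <- abundance_density(7, sp = 1.3, dp = 1.5, sd_km = 3, gw_km = 0.02)
  for (c_scale in c(1.5, 2, 4)) {
    expect_equal(
      abundance_density(7, sp = 1.3 * c_scale, dp = 1.5, sd_km = 3,
                        gw_km = 0.02),
      base * c_scale)
  }
})

test_that("biomass_density handles measured and converted weights", {
  # one laboratory individual of 1000 g over 0.5 km^2 swept
  lab <- tibble::tibble(length_cm = 20, weight_g = 1000,
                        measured_in = "laboratory")
  expect_equal(biomass_density(lab, a = NA, b = NA, sp = 1, dp = 1,
                               sd_km = 10, gw_km = 0.05), 2)
  # one field individual, L = 10 cm, a = 0.01, b = 3 -> 10 g; SP = 2;
  # area 0.02 km^2 -> 1 kg/km^2
  fld <- tibble::tibble(length_cm = 10, weight_g = NA_real_,
                        measured_in = "field")
  expect_equal(biomass_density(fld, a = 0.01, b = 3, sp = 2, dp = 1,
                               sd_km = 0.4, gw_km = 0.05), 1)
  expect_equal(biomass_density(fld[0, ], 0.01, 3, 1, 1, 1, 1), 0)
  expect_error(biomass_density(fld, a = NA, b = NA, sp = 1, dp = 1,
                               sd_km = 1, gw_km = 1), "missing")
})

test_that("biomass with all weights measured ignores (a, b)", {
  ind <- tibble::tibble(length_cm = c(8, 12), weight_g = c(50, 160),
                        measured_in = "laboratory")
  v1 <- biomass_density(ind, a = 0.01, b = 3, sp = 1.5, dp = 1,
                        sd_km = 2, gw_km = 0.03)
  v2 <- biomass_density(ind, a = 99, b = 0.1, sp = 1.5, dp = 1,
                        sd_km = 2, gw_km = 0.03)
  expect_identical(v1, v2)
})

test_that("length-class abundances conserve the raised count exactly", {
  set.seed(21)
  n <- 400
  sp <- 2.5
  dp <- 1.75
  sd_km <- 4.2
  gw_km <- 0.047
  ind <- tibble::tibble(species_code = "SPX",
                        length_cm = rlnorm(n, log(12), 0.4),
                        sample_id = "s1")
  counts <- bin_lengths(ind, bin_width = 1)
  dens <- abundance_density(counts$count, sp, dp, sd_km, gw_km)
  expect_equal(sum(dens) * (sd_km * gw_km), n * sp * dp,
               tolerance = 1e-12)
})

test_that("standardize_abundance composes binning and the density equation", {
  hauls <- tibble::tibble(haul_id = "h1", gear_width_m = 50,
                          swept_distance_km = 2)
  samples <- tibble::tibble(sample_id = "s1", haul_id = "h1",
                            category = "landed", sp = 2, dp = 1,
                            subsample_weight_kg = 1, fraction_weight_kg = 2)
  ind <- tibble::tibble(species_code = "SPX",
                        length_cm = c(10.2, 10.9, 11.1, 12.0),
                        weight_g = NA_real_, measured_in = "field",
                        sample_id = "s1")
  survey <- mk_mini_survey(hauls, samples, ind)
  out <- standardize_abundance(survey, bin_width = 1)
  expect_equal(out$value[out$length_class == 10], 2 * 2 / 0.1)
  expect_equal(out$value[out$length_class == 12], 1 * 2 / 0.1)
  expect_equal(sum(out$count), 4)
})

test_that("aggregation divides group sums by the number of hauls", {
  hauls <- tibble::tibble(haul_id = c("h1", "h2"), port = "P",
                          date = as.Date("2021-04-01"))
  vals <- tibble::tibble(haul_id = c("h1", "h2"),
                         sample_id = c("s1", "s2"),
                         species_code = "SPX", length_class = 10,
                         value = c(10, 20))
  agg <- aggregate_abundance(vals, hauls)
  expect_equal(agg$value, 15)
  expect_equal(agg$n_hauls, 2L)
  expect_equal(agg$n_samples, 2L)
  # single haul, single sample: identity
  agg1 <- aggregate_abundance(vals[1, ], hauls[1, ])
  expect_equal(agg1$value, 10)
  # two samples in ONE haul are summed, then divided by N = 1
  vals2 <- tibble::tibble(haul_id = "h1", sample_id = c("s1", "s1b"),
                          species_code = "SPX", length_class = 10,
                          value = c(10, 5))
  agg2 <- aggregate_abundance(vals2, hauls[1, ])
  expect_equal(agg2$value, 15)
  expect_equal(agg2$n_samples, 2L)
})

test_that("a species absent from hauls still divides by the full N", {
  hauls <- tibble::tibble(haul_id = c("h1", "h2", "h3"), port = "P",
                          date = as.Date("2021-04-01"))
  vals <- tibble::tibble(haul_id = "h1", sample_id = "s1",
                         species_code = "SPX", category = "landed",
                         value = 30)
  agg <- aggregate_biomass(vals, hauls, by = "port")
  expect_equal(agg$value, 10)
  expect_equal(agg$n_hauls, 3L)
})

test_that("aggregations match the brute-force oracle on random fixtures", {
  for (seed in c(101, 202, 303)) {
    fx <- mk_random_fixture(seed)
    for (by in list(NULL, "port", c("year", "season"))) {
      agg <- aggregate_abundance(fx$values, fx$hauls, by = by)
      hauls_lab <- trawlmetrics:::add_time_labels(fx$hauls)
      oracle <- oracle_aggregate(fx$values, hauls_lab, by %||% character(),
                                 keys = c("species_code", "length_class"))
      ok <- setNames(oracle$value, paste(oracle$.g, oracle$.k, sep = "\v"))
      got <- setNames(agg$value,
                      agg_key(agg, by %||% character(),
                              c("species_code", "length_class")))
      expect_equal(sort(names(got)), sort(names(ok)))
      expect_equal(got[names(ok)], ok, tolerance = 1e-9)

      aggb <- aggregate_biomass(fx$values, fx$hauls, by = by)
      oracleb <- oracle_aggregate(fx$values, hauls_lab, by %||% character(),
                                  keys = c("species_code", "category"))
      okb <- setNames(oracleb$value, paste(oracleb$.g, oracleb$.k, sep = "\v"))
      gotb <- setNames(aggb$value,
                       agg_key(aggb, by %||% character(),
                               c("species_code", "category")))
      expect_equal(gotb[names(okb)], okb, tolerance = 1e-9)
    }
  }
})

test_that("aggregation errors on unknown group labels", {
  hauls <- tibble::tibble(haul_id = "h1", port = NA_character_,
                          date = as.Date("2021-04-01"))
  vals <- tibble::tibble(haul_id = "h1", sample_id = "s1",
                         species_code = "SPX", category = "landed", value = 1)
  expect_error(aggregate_biomass(vals, hauls, by = "port"), "missing group")
  expect_error(aggregate_biomass(vals, hauls, by = "harbour"), "unknown")
})
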