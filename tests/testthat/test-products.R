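local_survey <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- generate_survey(sim_config(seed = 55,
                                                     n_vessels = 2,
                                                     n_days = 2))
    s
  }
})

test_that("length-frequency of a single-haul survey is that haul's series", {
  s1 <- generate_survey(sim_config(seed = 60, n_vessels = 1, n_days = 1,
                                   hauls_per_trip = 1))
  ab <- standardize_abundance(s1)
  lf <- build_length_frequency(s1, abundance = ab)
  per_class <- ab |>
    dplyr::group_by(species_code, length_class) |>
    dplyr::summarise(v = sum(value), .groups = "drop")
  j <- dplyr::inner_join(lf, per_class,
                         by = c("species_code", "length_class"))
  expect_equal(nrow(j), nrow(lf))
  expect_equal(j$abundance_n_km2, j$v, tolerance = 1e-12)
})

test_that("multi-species requests give independent series", {
  s <- local_survey()
  both <- build_length_frequency(s, species = c("HKE", "DPS"))
  one <- build_length_frequency(s, species = "HKE")
  expect_setequal(unique(both$species_code), c("HKE", "DPS"))
  hke_b <- both[both$species_code == "HKE", ]
  expect_equal(hke_b$abundance_n_km2, one$abundance_n_km2)
  expect_error(build_length_frequency(s, species = "NOPE"), "unknown")
})

test_that("length-frequency matches brute-force recomputation", {
  s <- local_survey()
  ab <- standardize_abundance(s)
  lf <- build_length_frequency(s, abundance = ab)
  oracle <- oracle_aggregate(ab, s$hauls, character(0),
                             keys = c("species_code", "length_class"))
  ok <- setNames(oracle$value, oracle$.k)
  got <- setNames(lf$abundance_n_km2,
                  paste(lf$species_code, lf$length_class, sep = "\r"))
  expect_equal(got[names(ok)], ok, tolerance = 1e-9)
  # classes are sorted ascending within species and abundances non-negative
  expect_true(all(lf$abundance_n_km2 >= 0))
  expect_true(all(unlist(tapply(lf$length_class, lf$species_code,
                                function(x) diff(x) > 0))))
})

test_that("composition trees conserve biomass from leaves to root", {
  s <- local_survey()
  for (mode in c("port", "season")) {
    tree <- build_catch_composition(s, mode = mode)
    leaves <- composition_leaves(tree)
    expect_equal(tree$value, sum(leaves$biomass_kg_km2), tolerance = 1e-9)
    for (n1 in tree$children) {
      kid_sum <- sum(purrr::map_dbl(n1$children, "value"))
      expect_equal(n1$value, kid_sum, tolerance = 1e-9)
    }
    # exactly 4 levels to the leaves
    leaf <- tree$children[[1]]$children[[1]]$children[[1]]$children[[1]]
    expect_equal(leaf$level, "species")
    expect_null(leaf$children)
  }
})

test_that("composition leaves equal the per-port biomass aggregation", {
  s <- local_survey()
  bio <- standardize_biomass(s)
  tree <- build_catch_composition(s, mode = "port", biomass = bio)
  leaves <- composition_leaves(tree)
  agg <- aggregate_biomass(bio, s$hauls, s$samples, by = "port")
  j <- dplyr::inner_join(
    leaves, agg,
    by = c(level2 = "port", category = "category",
           species_code = "species_code"))
  expect_equal(nrow(j), nrow(leaves))
  expect_equal(j$biomass_kg_km2, signif(j$value, 6), tolerance = 1e-9)
})

test_that("species filters prune leaves before summation", {
  s <- local_survey()
  tree <- build_catch_composition(s, mode = "port", species = "HKE")
  leaves <- composition_leaves(tree)
  expect_true(all(leaves$species_code == "HKE"))
  expect_equal(tree$value, sum(leaves$biomass_kg_km2), tolerance = 1e-9)
  expect_error(build_catch_composition(s, mode = "port", species = "NOPE"),
               "unknown")
})

test_that("composition artifacts round-trip through CSV", {
  s <- local_survey()
  tree <- build_catch_composition(s, mode = "season")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_catch_composition(tree, js, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE,
                          col_types = readr::cols(level1 = "c", level2 = "c"))
  leaves <- composition_leaves(tree)
  expect_equal(as.data.frame(back), as.data.frame(leaves))
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$value, tree$value, tolerance = 1e-12)
})

test_that("haul geolocation documents are consistent GeoJSON features", {
  s <- local_survey()
  h <- s$hauls$haul_id[1]
  doc <- build_haul_geolocation(s, h)
  expect_equal(doc$type, "Feature")
  expect_equal(doc$geometry$type, "LineString")
  expect_length(doc$geometry$coordinates,
                sum(s$cut_tracks$haul_id == h))
  trk <- s$cut_tracks[s$cut_tracks$haul_id == h, ]
  expect_equal(doc$properties$duration_min,
               as.numeric(difftime(max(trk$time), min(trk$time),
                                   units = "mins")))
  # composition sums equal the haul's per-sample biomass sums
  bio <- standardize_biomass(s)
  haul_total <- sum(bio$value[bio$haul_id == h])
  doc_total <- sum(unlist(doc$properties$composition_kg_km2))
  expect_equal(doc_total, haul_total, tolerance = 1e-4)
  expect_error(build_haul_geolocation(s, "H999"), "unknown haul")
})

test_that("product export is reproducible byte for byte", {
  s <- local_survey()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_products(s, d1)
  export_products(s, d2)
  for (f in c("length_frequency.json", "composition_port.json",
              "composition_port.csv", "composition_season.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  g1 <- list.files(file.path(d1, "hauls"))
  expect_equal(length(g1), nrow(s$hauls))
  expect_identical(
    readLines(file.path(d1, "hauls", g1[1])),
    readLines(file.path(d2, "hauls", g1[1])))
})
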