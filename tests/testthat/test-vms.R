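mk_pings <- function(times_min, lon, lat, speed = 3,
                     vessel = "V1", t0 = "2021-06-01 04:00:00") {
  tibble::tibble(
    vessel_id = vessel,
    time = lubridate::ymd_hms(t0, tz = "UTC") + times_min * 60,
    lon = lon, lat = lat,
    speed_kn = rep_len(speed, length(times_min)),
    course_deg = 0, origin = "reported"
  )
}

test_that("clean_pings collapses duplicates and removes points on land", {
  p <- mk_pings(c(0, 0, 10), lon = c(2, 2, 2.1), lat = 41)
  p$lon[1:2] <- 2
  out <- suppressMessages(clean_pings(p))
  expect_equal(nrow(out), 2)
  # square land polygon around (0.5, 40.5)
  land <- cbind(c(0, 1, 1, 0, 0), c(40, 40, 41.2, 41.2, 40))
  p2 <- mk_pings(c(0, 10), lon = c(0.5, 2), lat = c(40.5, 40.5))
  out2 <- suppressMessages(clean_pings(p2, land_polygons = land))
  expect_equal(out2$lon, 2)
  expect_equal(nrow(suppressMessages(clean_pings(p2[0, ]))), 0)
})

test_that("trip codes partition pings by vessel and local day", {
  p <- dplyr::bind_rows(
    mk_pings(c(0, 60), lon = 2, lat = 41, vessel = "V1"),
    mk_pings(c(0, 60), lon = 2, lat = 41, vessel = "V1",
             t0 = "2021-06-02 04:00:00"),
    mk_pings(c(0, 60), lon = 2, lat = 41, vessel = "V2"))
  out <- assign_trip_codes(p)
  expect_equal(dplyr::n_distinct(out$trip_code), 3)
  one_day <- assign_trip_codes(mk_pings(seq(0, 530, by = 10), 2, 41))
  expect_equal(dplyr::n_distinct(one_day$trip_code), 1)
})

test_that("two pings 60 min apart gain exactly 5 interior mesh points", {
  p <- assign_trip_codes(mk_pings(c(0, 60), lon = c(2, 2.1), lat = 41))
  out <- interpolate_pings(p)
  expect_equal(nrow(out), 7)
  expect_equal(sum(out$origin == "interpolated"), 5)
  expect_equal(sum(out$origin == "reported"), 2)
  # interpolated timestamps are whole multiples of 10 min
  expect_true(all(as.numeric(out$time) %% 600 == 0))
})

test_that("interpolation is linear: the 30-min point is the midpoint", {
  p <- assign_trip_codes(
    mk_pings(c(0, 60), lon = c(0, 1), lat = 0, t0 = "2021-06-01 04:00:00"))
  out <- interpolate_pings(p)
  mid <- out[out$time == p$time[1] + 30 * 60, ]
  expect_equal(mid$lon, 0.5, tolerance = 1e-9)
  expect_equal(mid$lat, 0, tolerance = 1e-9)
})

test_that("interpolation is idempotent on a 10-min mesh", {
  p <- assign_trip_codes(mk_pings(seq(0, 120, by = 10), lon = 2, lat = 41))
  once <- interpolate_pings(p)
  expect_equal(nrow(once), nrow(p))
  p2 <- assign_trip_codes(mk_pings(c(0, 47), lon = c(2, 2.05), lat = 41))
  once2 <- interpolate_pings(p2)
  twice <- interpolate_pings(once2)
  expect_equal(nrow(twice), nrow(once2))
  expect_equal(twice$lon, once2$lon, tolerance = 1e-12)
})

test_that("interpolated positions are collinear with their brackets", {
  p <- assign_trip_codes(
    mk_pings(c(0, 55), lon = c(2, 2.3), lat = c(41, 41.2)))
  out <- interpolate_pings(p)
  interp <- out[out$origin == "interpolated", ]
  # in the linear coordinate model the cross product with the segment is 0
  cross <- (interp$lon - 2) * (41.2 - 41) - (interp$lat - 41) * (2.3 - 2)
  expect_true(all(abs(cross) < 1e-9))
})

test_that("a single-ping trip is returned unchanged with a warning", {
  p <- assign_trip_codes(mk_pings(0, lon = 2, lat = 41))
  expect_warning(out <- interpolate_pings(p), "single ping")
  expect_equal(nrow(out), 1)
})

test_that("classify_fishing applies speed and depth filters jointly", {
  bath <- shelf_bathymetry(coast_lon = 1, m_per_km = 25)
  # 300 m depth is 12 km offshore; 2000 m is beyond 50 km (lat 0 for ease)
  lon300 <- 1 + 12 / (6371 * pi / 180)
  lon2000 <- 1 + 80 / (6371 * pi / 180)
  p <- mk_pings(c(0, 10, 20), lon = c(lon300, lon300, lon2000), lat = 0,
                speed = c(10, 3, 3))
  out <- classify_fishing(p, bathymetry = bath)
  expect_equal(out$is_fishing, c(FALSE, TRUE, FALSE))
})

test_that("widening a filter never unmarks a fishing ping", {
  set.seed(8)
  bath <- shelf_bathymetry()
  p <- mk_pings(seq(0, 590, by = 10),
                lon = 1 + runif(60, 0, 60) / (6371 * pi / 180) /
                  cos(41 * pi / 180),
                lat = 41, speed = runif(60, 0, 12))
  narrow <- classify_fishing(p, speed_range = c(2, 4),
                             depth_range = c(100, 600), bathymetry = bath)
  wide <- classify_fishing(p, speed_range = c(1, 5),
                           depth_range = c(50, 1000), bathymetry = bath)
  expect_true(all(wide$is_fishing[narrow$is_fishing]))
})

test_that("fishing time counts 10 minutes per fishing ping", {
  p <- tibble::tibble(is_fishing = rep(TRUE, 12))
  expect_equal(fishing_time(p), 2)
  expect_equal(fishing_time(tibble::tibble(is_fishing = logical(0))), 0)
  long <- tibble::tibble(is_fishing = rep(TRUE, 80))
  expect_warning(h <- fishing_time(long), "12 h")
  expect_equal(h, 80 / 6, tolerance = 1e-9)
})

test_that("landings are split equally over fishing pings and conserved", {
  p <- mk_pings(seq(0, 90, by = 10), lon = 2, lat = 41)
  p <- assign_trip_codes(p)
  p$is_fishing <- TRUE
  land <- tibble::tibble(date = p$trip_date[1], vessel_id = "V1", port = "P",
                         species_code = c("HKE", "MUT"),
                         weight_kg = c(100, 40), revenue_eur = c(650, 360))
  alloc <- allocate_landings(p, land)
  expect_equal(nrow(alloc), 20)  # 10 pings x 2 species
  expect_equal(unique(alloc$weight_kg[alloc$species_code == "HKE"]), 10)
  expect_equal(unique(alloc$weight_kg[alloc$species_code == "MUT"]), 4)
  expect_equal(sum(alloc$weight_kg), 140, tolerance = 1e-9)
  expect_equal(sum(alloc$revenue_eur), 1010, tolerance = 1e-9)
  # a trip with no fishing pings leaves its landings unallocated
  p$is_fishing <- FALSE
  expect_warning(alloc0 <- allocate_landings(p, land), "unallocated")
  expect_equal(nrow(alloc0), 0)
  expect_equal(nrow(attr(alloc0, "unallocated")), 2)
})

test_that("rasterization conserves time, mass and revenue", {
  p <- assign_trip_codes(mk_pings(seq(0, 110, by = 10), lon = 2, lat = 41))
  p$is_fishing <- TRUE
  land <- tibble::tibble(date = p$trip_date[1], vessel_id = "V1", port = "P",
                         species_code = "HKE", weight_kg = 60,
                         revenue_eur = 390)
  alloc <- allocate_landings(p, land)
  # all pings share one position: a single cell holds the whole 2-h trip
  g <- rasterize_effort(p, alloc, cell_km = 1)
  expect_equal(nrow(g), 1)
  expect_equal(g$effort_h_km2, 2)
  expect_equal(g$landings_kg_km2, 60)
  expect_equal(g$rpue_eur_h_km2, 390 / 2)
  # conservation across spread-out pings
  set.seed(77)
  p2 <- assign_trip_codes(mk_pings(seq(0, 590, by = 10),
                                   lon = 2 + runif(60, 0, 0.3),
                                   lat = 41 + runif(60, 0, 0.3)))
  p2$is_fishing <- runif(60) < 0.7
  land2 <- tibble::tibble(date = p2$trip_date[1], vessel_id = "V1",
                          port = "P", species_code = c("HKE", "DPS"),
                          weight_kg = c(123.4, 55.5),
                          revenue_eur = c(800, 999))
  alloc2 <- allocate_landings(p2, land2)
  g2 <- rasterize_effort(p2, alloc2, cell_km = 1)
  cell_area <- 1
  expect_equal(sum(g2$landings_kg_km2) * cell_area, sum(land2$weight_kg),
               tolerance = 1e-9)
  expect_equal(sum(g2$revenue_eur), sum(land2$revenue_eur), tolerance = 1e-9)
  expect_equal(sum(g2$effort_h_km2) * cell_area,
               sum(p2$is_fishing) * 10 / 60, tolerance = 1e-9)
  # empty input gives an empty grid
  g0 <- rasterize_effort(p2[0, ], NULL)
  expect_equal(nrow(g0), 0)
})

test_that("effort grids export to CSV and GeoJSON", {
  p <- assign_trip_codes(mk_pings(seq(0, 50, by = 10), lon = 2, lat = 41))
  p$is_fishing <- TRUE
  g <- rasterize_effort(p, NULL)
  csv <- withr::local_tempfile(fileext = ".csv")
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_effort_grid(g, csv, gj)
  long <- readr::read_csv(csv, show_col_types = FALSE)
  expect_setequal(unique(long$layer),
                  c("effort_h_km2", "landings_kg_km2", "rpue_eur_h_km2"))
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_equal(parsed$features[[1]]$geometry$type, "Polygon")
  p1 <- autoplot(g)
  expect_s3_class(p1, "ggplot")
})

test_that("fleet-scale allocation conserves totals end to end", {
  cfg <- sim_config(seed = 31, n_vessels = 4, n_days = 3)
  survey <- generate_survey(cfg)
  pings <- suppressMessages(
    clean_pings(survey$vms) |>
      assign_trip_codes() |>
      interpolate_pings() |>
      classify_fishing(bathymetry = shelf_bathymetry()))
  alloc <- allocate_landings(pings, survey$landings)
  expect_equal(sum(alloc$weight_kg), sum(survey$landings$weight_kg),
               tolerance = 1e-9)
  expect_equal(sum(alloc$revenue_eur), sum(survey$landings$revenue_eur),
               tolerance = 1e-9)
  g <- rasterize_effort(pings, alloc, cell_km = 1)
  expect_equal(sum(g$landings_kg_km2), sum(survey$landings$weight_kg),
               tolerance = 1e-6)
})
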