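# Seeded synthetic survey and fleet generator.
#
# Emulates the structure of the monitored fishery: daily scientific sampling
# aboard commercial trawlers with one haul at each of three depth strata,
# 1-min GPS tracks, 15-min manual onboard fixes, subsampled and raised catch
# fractions, a laboratory subsample with measured weights, plus a commercial
# fleet emitting 2-h VMS pings and daily landings. Geography is a synthetic
# north-south coast with a linear shelf so the depth at any position is a
# known function of distance offshore.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated lognormal draw via inverse-CDF so lengths respect the registry
# range without rejection loops.
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(runif(n, plo, phi), meanlog, sdlog)
}

#' Linear-shelf bathymetry
#'
#' Synthetic seabed model: the coast is a meridian at `coast_lon` and depth
#' grows linearly with distance offshore (eastward) at `m_per_km` metres per
#' km. Used both by the simulator (to place hauls at target depths) and as the
#' depth lookup of [classify_fishing()] in tests and examples.
#'
#' @param coast_lon longitude of the coastline (degrees).
#' @param m_per_km depth gradient (m of depth per km offshore).
#' @return a vectorized function `(lon, lat) -> depth (m)`.
#' @export
shelf_bathymetry <- function(coast_lon = 1.0, m_per_km = 25) {
  force(coast_lon); force(m_per_km)
  function(lon, lat) {
    dist_km <- (lon - coast_lon) * EARTH_RADIUS_KM * pi / 180 *
      cos(lat * pi / 180)
    pmax(0, dist_km * m_per_km)
  }
}

#' Default synthetic species registry
#'
#' Six demersal taxa typical of a NW Mediterranean bottom-trawl fishery, with
#' synthetic but literature-plausible length-weight parameters (`a` for grams
#' and cm), usual length ranges, and MCRS where one applies. Entirely
#' synthetic: values are not measurements.
#'
#' @return a registry tibble (see [read_species_registry()]).
#' @export
default_species_registry <- function() {
  tibble::tribble(
    ~code, ~scientific_name, ~a, ~b, ~length_min_cm, ~length_max_cm,
    ~mcrs_cm, ~group,
    "HKE", "Merluccius merluccius", 0.0051, 3.06, 5, 90, 20, "fish",
    "MUT", "Mullus barbatus", 0.0094, 3.08, 5, 30, 11, "fish",
    "EOI", "Eledone cirrhosa", 0.52, 2.62, 2, 25, NA, "cephalopod",
    "NEP", "Nephrops norvegicus", 0.43, 3.16, 1, 8, 2, "crustacean",
    "ARA", "Aristeus antennatus", 0.78, 2.96, 1, 7, NA, "crustacean",
    "DPS", "Parapenaeus longirostris", 0.72, 2.89, 0.8, 4.5, 2, "crustacean"
  )
}

# Per-species simulation parameters: lognormal length distribution, relative
# abundance weight per depth stratum, discard rate and ex-vessel price.
default_species_dynamics <- function() {
  tibble::tribble(
    ~code, ~meanlog_len, ~sdlog_len, ~w_shelf, ~w_upper, ~w_lower,
    ~discard_rate, ~price_eur_kg,
    "HKE", log(22), 0.35, 1.0, 0.8, 0.2, 0.15, 6.5,
    "MUT", log(14), 0.25, 1.2, 0.1, 0.0, 0.10, 9.0,
    "EOI", log(9), 0.30, 0.6, 0.5, 0.1, 0.05, 5.0,
    "NEP", log(3.5), 0.25, 0.0, 0.6, 0.8, 0.10, 35.0,
    "ARA", log(3.2), 0.30, 0.0, 0.1, 1.2, 0.05, 45.0,
    "DPS", log(2.4), 0.28, 0.2, 1.0, 0.1, 0.10, 18.0
  )
}

# The nine sampled ports with their coast areas, north to south along the
# synthetic coastline.
default_ports <- function() {
  tibble::tibble(
    port = c("Roses", "Palamos", "Blanes", "Arenys", "Barcelona", "Vilanova",
             "Tarragona", "Cambrils", "Sant Carles"),
    area = rep(c("north", "central", "south"), each = 3),
    lat = seq(42.3, 40.6, length.out = 9),
    lon = 1.0
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic survey and fleet. Defaults describe
#' a small but complete monitoring campaign: three vessels sampling on four
#' dates (spaced `day_spacing_days` apart so several seasons appear), three
#' hauls per trip — one per depth stratum — 60-minute tows at 3 knots with a
#' 25 m gear, 1-min GPS and 15-min onboard cadences, and a commercial fleet
#' reporting VMS pings every 2 h.
#'
#' @param seed master seed; every pseudo-random stream is derived from it.
#' @param n_vessels,n_days fleet size and number of sampling dates.
#' @param hauls_per_trip hauls per vessel-day, one per stratum.
#' @param start_date first sampling date.
#' @param day_spacing_days days between sampling dates.
#' @param tow_minutes tow duration (min).
#' @param tow_speed_kn towing speed (knots).
#' @param gear_width_m gear horizontal opening (m).
#' @param strata_depths_m target depth (m) of each stratum.
#' @param n_per_haul expected measured individuals per haul at unit stratum
#'   weight.
#' @param lab_fraction share of measured individuals sent to the laboratory
#'   (these carry measured weights).
#' @param weight_noise_sd lognormal sd of individual weight around `a * L^b`.
#' @param speed_range_kn,depth_range_m fishing filters assumed by the fleet.
#' @param vms_interval_h reported VMS cadence (h).
#' @param coast_lon,shelf_m_per_km synthetic coastline and shelf gradient.
#' @param defect_rate expected number of injected QC defects per survey
#'   (0 = clean).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_vessels = 3L,
                       n_days = 4L,
                       hauls_per_trip = 3L,
                       start_date = as.Date("2021-01-15"),
                       day_spacing_days = 45L,
                       tow_minutes = 60L,
                       tow_speed_kn = 3,
                       gear_width_m = 25,
                       strata_depths_m = c(shelf = 80, upper_slope = 350,
                                           lower_slope = 600),
                       n_per_haul = 60,
                       lab_fraction = 0.25,
                       weight_noise_sd = 0.05,
                       speed_range_kn = c(1, 4.5),
                       depth_range_m = c(50, 1000),
                       vms_interval_h = 2,
                       coast_lon = 1.0,
                       shelf_m_per_km = 25,
                       defect_rate = 0) {
  cfg <- list(
    seed = as.integer(seed), n_vessels = as.integer(n_vessels),
    n_days = as.integer(n_days), hauls_per_trip = as.integer(hauls_per_trip),
    start_date = as.Date(start_date),
    day_spacing_days = as.integer(day_spacing_days),
    tow_minutes = as.integer(tow_minutes), tow_speed_kn = tow_speed_kn,
    gear_width_m = gear_width_m, strata_depths_m = strata_depths_m,
    n_per_haul = n_per_haul, lab_fraction = lab_fraction,
    weight_noise_sd = weight_noise_sd, speed_range_kn = speed_range_kn,
    depth_range_m = depth_range_m, vms_interval_h = vms_interval_h,
    coast_lon = coast_lon, shelf_m_per_km = shelf_m_per_km,
    defect_rate = defect_rate,
    species = default_species_registry(),
    dynamics = default_species_dynamics(),
    ports = default_ports()
  )
  if (cfg$hauls_per_trip > length(cfg$strata_depths_m)) {
    abort("hauls_per_trip exceeds the number of depth strata")
  }
  if (any(c(cfg$n_vessels, cfg$n_days, cfg$tow_minutes) < 1)) {
    abort("n_vessels, n_days and tow_minutes must be >= 1")
  }
  structure(cfg, class = "sim_config")
}

# Home port of a vessel: vessels are spread along the whole coast so every
# area is sampled even by small fleets.
home_port_index <- function(v, n_ports) ((v - 1) * 4) %% n_ports + 1

# km offshore at which the shelf reaches a target depth.
offshore_km_for_depth <- function(cfg, depth_m) depth_m / cfg$shelf_m_per_km

# Longitude at a given offshore distance from the coast at latitude lat.
lon_at_offshore <- function(cfg, dist_km, lat) {
  cfg$coast_lon + dist_km / (EARTH_RADIUS_KM * pi / 180 * cos(lat * pi / 180))
}

#' Simulate one haul
#'
#' Generates a tow at the configured speed with per-minute heading noise,
#' 1-min GPS points with a 5-min steaming margin on either side of the haul,
#' 15-min onboard fixes spanning the tow, and the catch: per-species counts
#' drawn from the stratum's abundance weights, lengths from truncated
#' lognormal distributions, a laboratory subsample with measured weights
#' `a * L^b` times lognormal noise, and landed/discarded samples with their
#' raising factors.
#'
#' @param config a [sim_config()].
#' @param stratum stratum name (a name of `config$strata_depths_m`).
#' @param seed seed for this haul.
#' @param haul_id,vessel_id,date,port identifiers stamped on the output.
#' @param start_hour local start hour of the tow.
#' @return list with `haul` (one-row tibble), `track` (raw GPS tibble),
#'   `onboard`, `samples`, `individuals`, `gpx` (GPX text) and `truth`.
#' @export
simulate_haul <- function(config, stratum, seed, haul_id = "H1",
                          vessel_id = "V1", date = config$start_date,
                          port = config$ports$port[1], start_hour = 7) {
  if (!stratum %in% names(config$strata_depths_m)) {
    abort(sprintf("unknown stratum '%s'", stratum))
  }
  with_seed(seed, {
    depth <- config$strata_depths_m[[stratum]]
    prow <- config$ports[config$ports$port == port, ]
    lat0 <- prow$lat + runif(1, -0.05, 0.05)
    dist <- offshore_km_for_depth(config, depth)
    lon0 <- lon_at_offshore(config, dist, lat0)

    step_km <- config$tow_speed_kn * KNOT_KMH / 60
    # heading along-shore (due north) with small per-minute wobble
    n_margin <- 5L
    n_pts <- config$tow_minutes + 1L + 2L * n_margin
    heading <- pi / 2 + rnorm(n_pts - 1, 0, 0.08)  # radians from east axis
    dx <- step_km * cos(heading)
    dy <- step_km * sin(heading)
    kx <- EARTH_RADIUS_KM * pi / 180 * cos(lat0 * pi / 180)
    ky <- EARTH_RADIUS_KM * pi / 180
    lon <- lon0 + c(0, cumsum(dx)) / kx
    lat <- lat0 + c(0, cumsum(dy)) / ky
    t_start <- lubridate::ymd_hms(
      paste(date, sprintf("%02d:00:00", start_hour)), tz = "UTC") -
      n_margin * 60
    times <- t_start + 60 * (seq_len(n_pts) - 1)
    track <- tibble::tibble(lon = lon, lat = lat, time = times)

    tow0 <- times[n_margin + 1]
    tow1 <- times[n_margin + 1 + config$tow_minutes]
    ob_times <- seq(tow0, tow1, by = 15 * 60)
    ob_idx <- match(ob_times, times)
    onboard <- tibble::tibble(haul_id = haul_id, lon = lon[ob_idx],
                              lat = lat[ob_idx], time = ob_times)

    # catch
    dyn <- config$dynamics
    wcol <- c(shelf = "w_shelf", upper_slope = "w_upper",
              lower_slope = "w_lower")[[stratum]]
    inds <- purrr::pmap(list(dyn$code, dyn[[wcol]], dyn$meanlog_len,
                             dyn$sdlog_len, dyn$discard_rate),
      function(code, w, ml, sl, drate) {
        n <- rpois(1, w * config$n_per_haul)
        if (n == 0) return(NULL)
        sp_reg <- config$species[config$species$code == code, ]
        len <- rlnorm_trunc(n, ml, sl, sp_reg$length_min_cm,
                            sp_reg$length_max_cm)
        # under-MCRS individuals are mostly (not always) discarded
        p_disc <- rep(drate, n)
        if (!is.na(sp_reg$mcrs_cm)) p_disc[len < sp_reg$mcrs_cm] <- 0.9
        discarded <- runif(n) < p_disc
        lab <- runif(n) < config$lab_fraction | discarded
        w_true <- length_to_weight(len, sp_reg$a, sp_reg$b) *
          rlnorm(n, 0, config$weight_noise_sd)
        tibble::tibble(
          species_code = code, length_cm = len,
          weight_true_g = w_true,
          weight_g = dplyr::if_else(lab, w_true, NA_real_),
          measured_in = dplyr::if_else(lab, "laboratory", "field"),
          category = dplyr::if_else(discarded, "discarded", "landed")
        )
      })
    inds <- dplyr::bind_rows(inds)

    samples <- list()
    individuals <- list()
    for (cat in c("landed", "discarded")) {
      sub <- inds[inds$category == cat, ]
      if (nrow(sub) == 0) next
      sid <- paste0(haul_id, "_", substr(cat, 1, 1))
      sub_w <- sum(sub$weight_true_g) / 1000
      sp_true <- if (cat == "landed") runif(1, 1, 4) else 1
      dp_true <- if (cat == "discarded") runif(1, 1, 2.5) else 1
      samples[[cat]] <- tibble::tibble(
        sample_id = sid, haul_id = haul_id, category = cat,
        subsample_weight_kg = sub_w,
        fraction_weight_kg = sub_w * sp_true,
        sp = sp_true, dp = dp_true
      )
      individuals[[cat]] <- dplyr::mutate(
        dplyr::select(sub, -"weight_true_g", -"category"), sample_id = sid)
    }
    # debris and litter: weighed items, never length-measured
    for (cat in c("natural_debris", "marine_litter")) {
      n_items <- rpois(1, 2)
      if (n_items == 0) next
      sid <- paste0(haul_id, "_", substr(cat, 1, 2))
      w_items <- rlnorm(n_items, log(500), 0.8)
      samples[[cat]] <- tibble::tibble(
        sample_id = sid, haul_id = haul_id, category = cat,
        subsample_weight_kg = sum(w_items) / 1000,
        fraction_weight_kg = sum(w_items) / 1000,
        sp = 1, dp = 1
      )
      individuals[[cat]] <- tibble::tibble(
        species_code = if (cat == "marine_litter") "LIT-PLASTIC"
                       else "DEB-STONE",
        length_cm = NA_real_, weight_g = w_items,
        measured_in = "field", sample_id = sid
      )
    }

    haul <- tibble::tibble(
      haul_id = haul_id, vessel_id = vessel_id, date = as.Date(date),
      port = port, area = prow$area, season = season_of(date),
      depth_stratum_m = depth, gear_width_m = config$gear_width_m
    )
    list(
      haul = haul, track = dplyr::mutate(track, haul_id = haul_id),
      onboard = onboard,
      samples = dplyr::bind_rows(samples),
      individuals = dplyr::bind_rows(individuals),
      gpx = write_gpx_text(track),
      truth = list(stratum = stratum,
                   planned_distance_km = config$tow_minutes * step_km)
    )
  })
}

#' Simulate one fleet day of VMS pings and landings
#'
#' Each vessel steams offshore, trawls along-shore at fishing speed inside the
#' permitted depth band, and steams home, reporting a VMS ping every
#' `vms_interval_h` hours. The true activity of each reported ping is kept in
#' `fishing_true`. Landings are the vessel-day totals of a per-species
#' simulated catch, priced at the configured ex-vessel prices, so landed kg
#' equal simulated catch kg by construction.
#'
#' @param config a [sim_config()].
#' @param date the fleet day.
#' @param seed seed for this day.
#' @return list with `pings` (reported VMS pings with `fishing_true`) and
#'   `landings`.
#' @export
simulate_fleet_day <- function(config, date, seed) {
  with_seed(seed, {
    all_pings <- list()
    all_landings <- list()
    for (v in seq_len(config$n_vessels)) {
      vessel <- sprintf("VES%02d", v)
      prow <- config$ports[home_port_index(v, nrow(config$ports)), ]
      fish_depth <- runif(1, config$depth_range_m[1] + 50,
                          min(700, config$depth_range_m[2] - 100))
      dist <- offshore_km_for_depth(config, fish_depth)
      lat0 <- prow$lat + runif(1, -0.05, 0.05)
      fish_speed <- runif(1, 2.5, 4.0)
      t0 <- lubridate::ymd_hms(paste(date, "04:00:00"), tz = "UTC")
      hours <- seq(0, 12, by = config$vms_interval_h)
      n <- length(hours)
      status <- c("steam", rep("fish", n - 2), "steam")
      # along-shore fishing path at constant offshore distance; consecutive
      # fishing pings spaced by speed * interval so recomputed speeds match
      spacing_km <- fish_speed * KNOT_KMH * config$vms_interval_h
      ky <- EARTH_RADIUS_KM * pi / 180
      lat <- lat0 + cumsum(c(0, rep(spacing_km, n - 1))) / ky *
        ifelse(status == "fish", 1, 0.3)
      lon <- ifelse(status == "fish",
                    lon_at_offshore(config, dist, lat0),
                    lon_at_offshore(config, 1.0, lat0))
      speed <- ifelse(status == "fish", fish_speed, runif(n, 8, 10))
      all_pings[[v]] <- tibble::tibble(
        vessel_id = vessel, time = t0 + hours * 3600,
        lon = lon, lat = lat, speed_kn = speed,
        course_deg = 0, origin = "reported",
        fishing_true = status == "fish"
      )
      dyn <- config$dynamics
      catch_kg <- rlnorm(nrow(dyn), log(40), 0.6) *
        (dyn$w_shelf + dyn$w_upper + dyn$w_lower) / 2
      keep <- catch_kg > 1
      all_landings[[v]] <- tibble::tibble(
        date = as.Date(date), vessel_id = vessel, port = prow$port,
        species_code = dyn$code[keep],
        weight_kg = catch_kg[keep],
        revenue_eur = catch_kg[keep] * dyn$price_eur_kg[keep]
      )
    }
    list(pings = dplyr::bind_rows(all_pings),
         landings = dplyr::bind_rows(all_landings))
  })
}

#' Generate a complete synthetic survey bundle
#'
#' Runs [simulate_haul()] for every vessel-day-stratum and
#' [simulate_fleet_day()] for every day, then pushes the simulated GPX text
#' through the real ingestion path ([parse_gpx()], [cut_haul_track()],
#' [swept_distance()]) so haul geometry is computed exactly as for field data.
#' The result is a consistent dataset that passes [check_completeness()] with
#' no issues when `defect_rate = 0`.
#'
#' @param config a [sim_config()].
#' @return a `trawl_survey` list: `species`, `ports`, `hauls` (with swept
#'   geometry), `tracks` (raw GPS), `cut_tracks`, `onboard`, `samples`,
#'   `individuals`, `vms`, `landings`, `gpx` (named GPX texts), `truth`.
#' @export
generate_survey <- function(config = sim_config()) {
  dates <- config$start_date + (seq_len(config$n_days) - 1) *
    config$day_spacing_days
  strata <- names(config$strata_depths_m)[seq_len(config$hauls_per_trip)]
  hauls <- list(); tracks <- list(); onboard <- list()
  samples <- list(); individuals <- list(); gpx <- list()
  idx <- 0L
  for (d in seq_along(dates)) {
    for (v in seq_len(config$n_vessels)) {
      vessel <- sprintf("VES%02d", v)
      port <- config$ports$port[home_port_index(v, nrow(config$ports))]
      for (s in seq_along(strata)) {
        idx <- idx + 1L
        hid <- sprintf("H%03d", idx)
        sim <- simulate_haul(
          config, strata[s], seed = derive_seed(config$seed, "haul", idx),
          haul_id = hid, vessel_id = vessel, date = dates[d], port = port,
          start_hour = 6 + s * 2)
        hauls[[idx]] <- sim$haul
        tracks[[idx]] <- sim$track
        onboard[[idx]] <- sim$onboard
        samples[[idx]] <- sim$samples
        individuals[[idx]] <- sim$individuals
        gpx[[hid]] <- sim$gpx
      }
    }
  }
  hauls <- dplyr::bind_rows(hauls)
  tracks <- dplyr::bind_rows(tracks)
  onboard <- dplyr::bind_rows(onboard)
  samples <- dplyr::bind_rows(samples)
  individuals <- dplyr::bind_rows(individuals)
  individuals$individual_id <- sprintf("I%05d", seq_len(nrow(individuals)))

  geom <- compute_haul_geometry(hauls, tracks, onboard)

  fleet <- purrr::map(seq_along(dates), function(d) {
    simulate_fleet_day(config, dates[d],
                       seed = derive_seed(config$seed, "fleet", d))
  })
  vms <- dplyr::bind_rows(purrr::map(fleet, "pings"))
  landings <- dplyr::bind_rows(purrr::map(fleet, "landings"))

  survey <- list(
    species = config$species,
    ports = config$ports,
    hauls = add_time_labels(geom$hauls),
    tracks = tracks,
    cut_tracks = geom$cut_tracks,
    onboard = onboard,
    samples = samples,
    individuals = individuals,
    vms = vms,
    landings = landings,
    gpx = gpx,
    truth = list(config = config)
  )
  class(survey) <- "trawl_survey"
  if (config$defect_rate > 0) {
    survey <- inject_length_defects(
      survey, n = config$defect_rate,
      seed = derive_seed(config$seed, "defects"))
  }
  survey
}

#' @export
print.trawl_survey <- function(x, ...) {
  cat(sprintf(
    paste0("Synthetic trawl survey: %d hauls, %d samples, %d individuals,\n",
           "  %d VMS pings, %d landing records, %d species\n"),
    nrow(x$hauls), nrow(x$samples), nrow(x$individuals), nrow(x$vms),
    nrow(x$landings), nrow(x$species)))
  invisible(x)
}

#' Inject out-of-range length defects into a survey
#'
#' Replaces `n` randomly chosen length-measured individuals' lengths with
#' values above their species' usual range, recording which rows were
#' corrupted in `truth$defect_ids`. Used to verify that the QC range check
#' finds exactly the injected defects.
#'
#' @param survey a `trawl_survey`.
#' @param n number of defects to inject.
#' @param seed RNG seed.
#' @return the modified survey.
#' @export
inject_length_defects <- function(survey, n, seed = 1L) {
  with_seed(seed, {
    eligible <- which(!is.na(survey$individuals$length_cm))
    n <- min(n, length(eligible))
    pick <- sample(eligible, n)
    reg <- survey$species
    for (i in pick) {
      sp <- survey$individuals$species_code[i]
      lmax <- reg$length_max_cm[reg$code == sp]
      survey$individuals$length_cm[i] <- lmax * runif(1, 1.5, 3)
      # keep the weight consistent with having been mistyped, not re-weighed
    }
    survey$truth$defect_ids <- survey$individuals$individual_id[pick]
    survey
  })
}
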