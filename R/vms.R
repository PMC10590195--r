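# VMS pipeline: clean pings, code trips, densify to a 10-min mesh, classify
# fishing activity with speed and depth filters, compute fishing time, fuse
# daily landings by equal allocation over fishing positions, and rasterize
# effort / landings / revenue-per-unit-effort grids.

KNOT_KMH <- 1.852

empty_pings <- function() {
  tibble::tibble(vessel_id = character(), time = as.POSIXct(character()),
                 lon = numeric(), lat = numeric(), speed_kn = numeric(),
                 course_deg = numeric(), origin = character())
}

#' Clean VMS pings
#'
#' Collapses exact (vessel, timestamp) duplicates to their first occurrence
#' and removes pings falling inside the supplied land polygon(s). Input order
#' is preserved; removal counts are reported via a message.
#'
#' @param pings tibble with at least `vessel_id`, `time`, `lon`, `lat`.
#' @param land_polygons optional polygon boundary: a two-column matrix or data
#'   frame of (lon, lat) vertices, `NA` rows separating multiple rings.
#' @return the cleaned pings tibble.
#' @export
clean_pings <- function(pings, land_polygons = NULL) {
  stopifnot_cols(pings, c("vessel_id", "time", "lon", "lat"), "pings")
  if (nrow(pings) == 0) return(pings)
  dup <- duplicated(pings[, c("vessel_id", "time")])
  out <- pings[!dup, ]
  n_land <- 0L
  if (!is.null(land_polygons) && nrow(out) > 0) {
    bnd <- as.matrix(land_polygons)[, 1:2, drop = FALSE]
    on_land <- mgcv::in.out(bnd, cbind(out$lon, out$lat))
    n_land <- sum(on_land)
    out <- out[!on_land, ]
  }
  inform(sprintf("clean_pings: removed %d duplicate(s), %d ping(s) on land",
                 sum(dup), n_land))
  out
}

#' Assign trip codes to pings
#'
#' A fishing trip is one vessel-day (the fleet lands its catch daily), so the
#' trip code is the vessel id plus the local calendar date of the ping.
#'
#' @param pings pings tibble.
#' @param tz timezone defining the local calendar date; default
#'   `"Europe/Madrid"`.
#' @return pings with `trip_date` (Date) and `trip_code` columns.
#' @export
assign_trip_codes <- function(pings, tz = "Europe/Madrid") {
  stopifnot_cols(pings, c("vessel_id", "time"), "pings")
  pings |>
    dplyr::mutate(
      trip_date = as.Date(lubridate::with_tz(.data$time, tz)),
      trip_code = paste(.data$vessel_id, format(.data$trip_date), sep = "_")
    )
}

# Interpolate one time-sorted trip onto the 10-min mesh.
interpolate_trip <- function(trip, interval_min) {
  step <- interval_min * 60
  t_num <- as.numeric(trip$time)
  t0 <- ceiling(min(t_num) / step) * step
  t1 <- floor(max(t_num) / step) * step
  mesh <- if (t0 > t1) numeric(0) else seq(t0, t1, by = step)
  mesh <- setdiff(mesh, t_num)
  if (length(mesh) > 0) {
    new <- tibble::tibble(
      vessel_id = trip$vessel_id[1],
      time = as.POSIXct(mesh, origin = "1970-01-01",
                        tz = attr(trip$time, "tzone") %||% "UTC"),
      lon = stats::approx(t_num, trip$lon, xout = mesh)$y,
      lat = stats::approx(t_num, trip$lat, xout = mesh)$y,
      speed_kn = NA_real_,
      course_deg = NA_real_,
      origin = "interpolated"
    )
    for (extra in setdiff(names(trip), names(new))) {
      new[[extra]] <- trip[[extra]][1]
    }
    out <- dplyr::arrange(dplyr::bind_rows(trip, new), .data$time)
  } else {
    out <- trip
  }
  # Speed over the densified mesh for interpolated points (km over the
  # preceding segment divided by its duration, in knots).
  need <- which(out$origin == "interpolated" & is.na(out$speed_kn))
  if (length(need) > 0 && nrow(out) >= 2) {
    seg_km <- c(NA_real_, haversine_km(out$lon, out$lat))
    seg_h <- c(NA_real_, diff(as.numeric(out$time)) / 3600)
    sp <- seg_km / seg_h / KNOT_KMH
    # first point of a trip has no preceding segment: use the following one
    sp[1] <- sp[2]
    out$speed_kn[need] <- sp[need]
  }
  out
}

#' Densify trip tracks to a 10-minute mesh
#'
#' Within each trip, adds linearly interpolated positions at every timestamp
#' that is a whole multiple of `interval_min` minutes inside the trip's time
#' window. Reported pings are retained untouched; added pings carry
#' `origin = "interpolated"` and a speed recomputed from the densified mesh
#' (segment distance over segment duration). A trip already on the mesh gains
#' no points, so the operation is idempotent.
#'
#' @param pings pings tibble with `trip_code` (see [assign_trip_codes()]).
#' @param interval_min mesh resolution in minutes; default 10.
#' @return densified pings tibble, ordered by trip and time.
#' @export
interpolate_pings <- function(pings, interval_min = 10) {
  stopifnot_cols(pings, c("vessel_id", "time", "lon", "lat", "trip_code"),
                 "pings")
  if (!"origin" %in% names(pings)) pings$origin <- "reported"
  if (!"speed_kn" %in% names(pings)) pings$speed_kn <- NA_real_
  if (!"course_deg" %in% names(pings)) pings$course_deg <- NA_real_
  trips <- split(pings, pings$trip_code)
  out <- purrr::map(trips, function(trip) {
    trip <- dplyr::arrange(trip, .data$time)
    if (nrow(trip) < 2) {
      warn(sprintf("trip %s has a single ping; nothing to interpolate",
                   trip$trip_code[1]))
      return(trip)
    }
    interpolate_trip(trip, interval_min)
  })
  dplyr::bind_rows(out)
}

#' Classify fishing activity of pings
#'
#' A ping is fishing when its speed lies within the trawling speed range and
#' the seabed depth at its position lies within the permitted trawling depth
#' range; the speed filter excludes steaming and inactivity, the depth filter
#' removes erroneous positions outside the fishing grounds. Pings where the
#' bathymetry is unavailable are marked not fishing and counted in a message.
#'
#' @param pings pings tibble.
#' @param speed_range numeric length-2, knots; default `c(1, 4.5)` (a
#'   conventional bottom-trawling range, not a published value).
#' @param depth_range numeric length-2, metres; default `c(50, 1000)`, the
#'   depths where bottom trawling is permitted in the study area.
#' @param bathymetry function `(lon, lat) -> depth in metres (>= 0)`,
#'   vectorized; e.g. [shelf_bathymetry()].
#' @return pings with a logical `is_fishing` column.
#' @export
classify_fishing <- function(pings, speed_range = c(1, 4.5),
                             depth_range = c(50, 1000), bathymetry) {
  stopifnot_cols(pings, c("lon", "lat", "speed_kn"), "pings")
  if (speed_range[1] >= speed_range[2]) abort("speed_range min must be < max")
  depth <- bathymetry(pings$lon, pings$lat)
  miss <- !is.finite(depth)
  if (any(miss)) {
    inform(sprintf(
      "classify_fishing: %d ping(s) without bathymetry marked not fishing",
      sum(miss)))
  }
  pings$is_fishing <- !miss & !is.na(pings$speed_kn) &
    pings$speed_kn >= speed_range[1] & pings$speed_kn <= speed_range[2] &
    depth >= depth_range[1] & depth <= depth_range[2]
  pings
}

#' Fishing time of a trip
#'
#' Each classified fishing ping on the 10-min mesh represents `interval_min`
#' minutes of trawling; the trip's fishing time is their total in hours. A
#' result above the 12-h daily fishing limit raises a warning (never a
#' truncation).
#'
#' @param pings classified pings of one trip.
#' @param interval_min minutes represented by one ping; default 10.
#' @return fishing time in hours.
#' @export
fishing_time <- function(pings, interval_min = 10) {
  stopifnot_cols(pings, "is_fishing", "pings")
  h <- sum(pings$is_fishing, na.rm = TRUE) * interval_min / 60
  if (h > 12) {
    warn(sprintf("fishing time %.2f h exceeds the 12 h daily limit", h))
  }
  h
}

#' Allocate daily landings over fishing positions
#'
#' Landings are reported per trip (vessel and day); each species' weight and
#' revenue are distributed equally among the trip's fishing pings. Trips with
#' landings but no fishing ping cannot be mapped: their landings are returned
#' in the `unallocated` attribute and excluded.
#'
#' @param pings classified pings with `trip_date` and `is_fishing`.
#' @param landings tibble `date`, `vessel_id`, `port`, `species_code`,
#'   `weight_kg`, `revenue_eur`.
#' @return tibble of per-ping allocations (`vessel_id`, `time`, `lon`, `lat`,
#'   `trip_code`, `species_code`, `weight_kg`, `revenue_eur`), with attribute
#'   `unallocated` holding the landings rows that could not be placed.
#' @export
allocate_landings <- function(pings, landings) {
  stopifnot_cols(pings, c("vessel_id", "time", "lon", "lat", "trip_date",
                          "is_fishing"), "pings")
  stopifnot_cols(landings, c("date", "vessel_id", "species_code", "weight_kg",
                             "revenue_eur"), "landings")
  fishing <- dplyr::filter(pings, .data$is_fishing)
  n_fish <- fishing |>
    dplyr::count(.data$vessel_id, .data$trip_date, name = "n_fishing")
  landings <- dplyr::mutate(landings, date = as.Date(.data$date))
  joined <- landings |>
    dplyr::left_join(n_fish,
                     by = c(vessel_id = "vessel_id", date = "trip_date"))
  unallocated <- joined |>
    dplyr::filter(is.na(.data$n_fishing) | .data$n_fishing == 0) |>
    dplyr::select(-"n_fishing")
  if (nrow(unallocated) > 0) {
    warn(sprintf(
      "%d landing record(s) on trips without fishing pings left unallocated",
      nrow(unallocated)))
  }
  per_ping <- joined |>
    dplyr::filter(!is.na(.data$n_fishing), .data$n_fishing > 0) |>
    dplyr::mutate(weight_kg = .data$weight_kg / .data$n_fishing,
                  revenue_eur = .data$revenue_eur / .data$n_fishing)
  alloc <- fishing |>
    dplyr::select("vessel_id", "time", "lon", "lat", "trip_code",
                  "trip_date") |>
    dplyr::inner_join(
      dplyr::select(per_ping, "vessel_id", date = "date", "species_code",
                    "weight_kg", "revenue_eur"),
      by = c("vessel_id", trip_date = "date"),
      relationship = "many-to-many")
  attr(alloc, "unallocated") <- unallocated
  alloc
}

#' Rasterize fishing effort, landings and revenue
#'
#' Projects fishing pings onto a local km grid and accumulates, per square
#' cell: effort (trawling hours per km²), allocated landings (kg per km²) and
#' revenue per unit effort (€ per hour per km², defined only where the cell
#' has effort). The projection is a local equirectangular tangent plane
#' centred on `origin` (default: the centroid of the fishing pings).
#'
#' @param pings classified pings (`is_fishing` set).
#' @param allocations output of [allocate_landings()] (may be `NULL` for an
#'   effort-only grid).
#' @param cell_km square cell side in km; default 1.
#' @param origin optional `c(lon, lat)` of the grid origin.
#' @param interval_min minutes represented by one ping.
#' @return an `effort_grid`: tibble `cell_x`, `cell_y`, `lon`, `lat` (cell
#'   centres), `effort_h_km2`, `landings_kg_km2`, `revenue_eur`,
#'   `rpue_eur_h_km2`, with attributes `cell_km` and `origin`.
#' @export
rasterize_effort <- function(pings, allocations = NULL, cell_km = 1,
                             origin = NULL, interval_min = 10) {
  if (cell_km <= 0) abort("cell_km must be > 0")
  fishing <- dplyr::filter(pings, .data$is_fishing)
  if (is.null(origin)) {
    origin <- if (nrow(fishing) > 0) {
      c(mean(fishing$lon), mean(fishing$lat))
    } else {
      c(0, 0)
    }
  }
  cell_area <- cell_km^2
  grid_cells <- function(lon, lat) {
    p <- project_local_km(lon, lat, origin[1], origin[2])
    list(cx = floor(p$x / cell_km), cy = floor(p$y / cell_km))
  }
  if (nrow(fishing) > 0) {
    gc <- grid_cells(fishing$lon, fishing$lat)
    eff <- tibble::tibble(cell_x = gc$cx, cell_y = gc$cy) |>
      dplyr::count(.data$cell_x, .data$cell_y, name = "n_pings") |>
      dplyr::mutate(effort_h_km2 = .data$n_pings * interval_min / 60 /
                      cell_area)
  } else {
    eff <- tibble::tibble(cell_x = integer(), cell_y = integer(),
                          n_pings = integer(), effort_h_km2 = numeric())
  }
  if (!is.null(allocations) && nrow(allocations) > 0) {
    ga <- grid_cells(allocations$lon, allocations$lat)
    lnd <- allocations |>
      dplyr::mutate(cell_x = ga$cx, cell_y = ga$cy) |>
      dplyr::group_by(.data$cell_x, .data$cell_y) |>
      dplyr::summarise(landings_kg_km2 = sum(.data$weight_kg) / cell_area,
                       revenue_eur = sum(.data$revenue_eur),
                       .groups = "drop")
  } else {
    lnd <- tibble::tibble(cell_x = integer(), cell_y = integer(),
                          landings_kg_km2 = numeric(),
                          revenue_eur = numeric())
  }
  grid <- dplyr::full_join(eff, lnd, by = c("cell_x", "cell_y")) |>
    dplyr::mutate(
      dplyr::across(c("n_pings", "effort_h_km2", "landings_kg_km2",
                      "revenue_eur"),
                    ~ tidyr::replace_na(.x, 0)),
      rpue_eur_h_km2 = dplyr::if_else(
        .data$effort_h_km2 > 0,
        .data$revenue_eur / (.data$effort_h_km2 * cell_area * cell_area),
        NA_real_),
      lon = origin[1] + (.data$cell_x + 0.5) * cell_km /
        (EARTH_RADIUS_KM * cos(origin[2] * pi / 180) * pi / 180),
      lat = origin[2] + (.data$cell_y + 0.5) * cell_km /
        (EARTH_RADIUS_KM * pi / 180)
    ) |>
    dplyr::arrange(.data$cell_x, .data$cell_y)
  structure(grid, cell_km = cell_km, origin = origin,
            class = c("effort_grid", class(grid)))
}

#' Plot an effort grid layer
#'
#' @param object an `effort_grid` from [rasterize_effort()].
#' @param layer which layer to map; one of `"effort_h_km2"`,
#'   `"landings_kg_km2"`, `"rpue_eur_h_km2"`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.effort_grid <- function(object, layer = "effort_h_km2", ...) {
  cell <- attr(object, "cell_km")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$cell_x * cell,
                               y = .data$cell_y * cell,
                               fill = .data[[layer]])) +
    ggplot2::geom_tile(width = cell, height = cell) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "East (km)", y = "North (km)", fill = layer)
}

#' Write an effort grid as CSV and GeoJSON cell polygons
#'
#' @param grid an `effort_grid`.
#' @param path_csv,path_geojson output paths; either may be `NULL`.
#' @return the grid, invisibly.
#' @export
write_effort_grid <- function(grid, path_csv = NULL, path_geojson = NULL) {
  if (!is.null(path_csv)) {
    long <- grid |>
      tibble::as_tibble() |>
      dplyr::select("cell_x", "cell_y", "effort_h_km2", "landings_kg_km2",
                    "rpue_eur_h_km2") |>
      tidyr::pivot_longer(-c("cell_x", "cell_y"),
                          names_to = "layer", values_to = "value") |>
      dplyr::mutate(value = signif6(.data$value))
    readr::write_csv(long, path_csv)
  }
  if (!is.null(path_geojson)) {
    cell <- attr(grid, "cell_km")
    origin <- attr(grid, "origin")
    kx <- EARTH_RADIUS_KM * cos(origin[2] * pi / 180) * pi / 180
    ky <- EARTH_RADIUS_KM * pi / 180
    features <- purrr::map(seq_len(nrow(grid)), function(i) {
      x0 <- grid$cell_x[i] * cell
      y0 <- grid$cell_y[i] * cell
      corners <- list(c(x0, y0), c(x0 + cell, y0), c(x0 + cell, y0 + cell),
                      c(x0, y0 + cell), c(x0, y0))
      ring <- lapply(corners, function(c2) {
        c(signif6(origin[1] + c2[1] / kx), signif6(origin[2] + c2[2] / ky))
      })
      list(
        type = "Feature",
        geometry = list(type = "Polygon", coordinates = list(ring)),
        properties = list(
          cell_x = grid$cell_x[i], cell_y = grid$cell_y[i],
          effort_h_km2 = signif6(grid$effort_h_km2[i]),
          landings_kg_km2 = signif6(grid$landings_kg_km2[i]),
          rpue_eur_h_km2 = if (is.na(grid$rpue_eur_h_km2[i])) NULL else
            signif6(grid$rpue_eur_h_km2[i])
        )
      )
    })
    write_geojson(list(type = "FeatureCollection", features = features),
                  path_geojson)
  }
  invisible(grid)
}
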