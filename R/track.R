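# Haul geometry: cutting the raw GPS track to the fishing haul using the
# onboard position window, and computing swept distance and swept area.

#' Cut a GPS track to the haul window
#'
#' The fishing haul is delimited by the manually collected onboard positions:
#' the subtrack whose timestamps lie within `[first onboard fix, last onboard
#' fix]` (inclusive on both ends) is retained. Only onboard timestamps are
#' used; onboard coordinates serve for visual validation elsewhere.
#'
#' @param track a track tibble (`lon`, `lat`, `time`), time-ordered.
#' @param onboard a tibble of onboard fixes with at least a `time` column and
#'   two or more rows.
#' @return the cut track tibble.
#' @export
cut_haul_track <- function(track, onboard) {
  stopifnot_cols(track, c("lon", "lat", "time"), "track")
  stopifnot_cols(onboard, "time", "onboard positions")
  if (nrow(onboard) < 2) abort("need at least 2 onboard positions")
  t0 <- min(onboard$time)
  t1 <- max(onboard$time)
  if (t1 < t0) abort("onboard window ends before it starts")
  out <- dplyr::filter(track, .data$time >= t0, .data$time <= t1)
  if (nrow(out) == 0) {
    abort("onboard window does not overlap the GPS track: empty haul")
  }
  out
}

#' Swept distance of a track
#'
#' Sum of great-circle (haversine, mean Earth radius 6371 km) distances over
#' consecutive trackpoints. A single-point track has distance 0.
#'
#' @param track a track tibble (`lon`, `lat`, `time`).
#' @return distance in km.
#' @export
#' @examples
#' trk <- tibble::tibble(lon = c(0, 0.1), lat = c(0, 0),
#'                       time = as.POSIXct(c(0, 60), origin = "1970-01-01"))
#' swept_distance(trk) # ~11.12 km
swept_distance <- function(track) {
  stopifnot_cols(track, c("lon", "lat"), "track")
  if (nrow(track) < 2) return(0)
  sum(haversine_km(track$lon, track$lat))
}

#' Swept area of a haul
#'
#' Area covered by the gear: swept distance times gear width,
#' `SD (km) * GW (m) / 1000`, in km².
#'
#' @param sd_km swept distance in km, >= 0.
#' @param gw_m gear (net) width in metres, > 0.
#' @return area in km².
#' @export
#' @examples
#' swept_area(2, 50) # 0.1 km^2
swept_area <- function(sd_km, gw_m) {
  if (any(!is.finite(gw_m) | gw_m <= 0)) abort("gear width must be > 0")
  if (any(!is.finite(sd_km) | sd_km < 0)) abort("swept distance must be >= 0")
  sd_km * gw_m / 1000
}

#' Compute haul geometry for a whole survey
#'
#' For every haul: cuts the raw track to the onboard window, computes swept
#' distance and swept area, and returns the hauls table augmented with
#' `swept_distance_km` and `swept_area_km2`. Gaps longer than `gap_warn_min`
#' minutes between consecutive GPS points raise a warning.
#'
#' @param hauls hauls tibble with `haul_id` and `gear_width_m`.
#' @param tracks long tibble of raw GPS points: `haul_id`, `lon`, `lat`,
#'   `time`.
#' @param onboard long tibble of onboard fixes: `haul_id`, `time` (and
#'   usually `lon`, `lat`).
#' @param gap_warn_min gap threshold (minutes) that triggers a warning.
#' @return list with `hauls` (augmented tibble) and `cut_tracks` (long tibble
#'   of the cut trackpoints).
#' @export
compute_haul_geometry <- function(hauls, tracks, onboard, gap_warn_min = 10) {
  stopifnot_cols(hauls, c("haul_id", "gear_width_m"), "hauls")
  stopifnot_cols(tracks, c("haul_id", "lon", "lat", "time"), "tracks")
  stopifnot_cols(onboard, c("haul_id", "time"), "onboard")
  per_haul <- purrr::map(hauls$haul_id, function(h) {
    trk <- dplyr::arrange(dplyr::filter(tracks, .data$haul_id == h),
                          .data$time)
    ob <- dplyr::filter(onboard, .data$haul_id == h)
    if (nrow(trk) == 0) abort(sprintf("haul %s has no GPS track", h))
    if (nrow(ob) < 2) abort(sprintf("haul %s has < 2 onboard positions", h))
    gaps <- diff(as.numeric(trk$time)) / 60
    if (length(gaps) > 0 && any(gaps > gap_warn_min)) {
      warn(sprintf("haul %s: GPS gap of %.1f min exceeds %g min",
                   h, max(gaps), gap_warn_min))
    }
    cut <- cut_haul_track(trk[, c("lon", "lat", "time")], ob)
    cut$haul_id <- h
    cut
  })
  cut_tracks <- dplyr::bind_rows(per_haul)
  geom <- cut_tracks |>
    dplyr::group_by(.data$haul_id) |>
    dplyr::summarise(
      swept_distance_km = if (dplyr::n() < 2) 0 else
        sum(haversine_km(.data$lon, .data$lat)),
      .groups = "drop"
    )
  hauls <- hauls |>
    dplyr::select(-dplyr::any_of(c("swept_distance_km", "swept_area_km2"))) |>
    dplyr::left_join(geom, by = "haul_id") |>
    dplyr::mutate(swept_area_km2 = swept_area(.data$swept_distance_km,
                                              .data$gear_width_m))
  list(hauls = hauls, cut_tracks = cut_tracks)
}
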