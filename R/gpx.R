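# GPX track ingestion. Haul tracks arrive as GPX 1.1 files with one
# trackpoint per minute; every point must carry a timestamp since the haul is
# delimited in time by the onboard fixes.

#' Parse a GPX document into a track tibble
#'
#' Reads all `trkpt` elements of a GPX 1.1 document, concatenating multiple
#' track segments in document order. Every trackpoint must carry a `<time>`
#' child; a missing timestamp is an error naming the offending point.
#'
#' @param x GPX content: a file path or a single string of GPX XML.
#' @return a tibble with columns `lon`, `lat` (WGS84 decimal degrees) and
#'   `time` (POSIXct, UTC), ordered by time, plus attribute `source = "gpx"`.
#' @export
#' @seealso [read_gpx()] for the path-only wrapper.
parse_gpx <- function(x) {
  doc <- tryCatch(xml2::read_xml(x),
                  error = function(e) abort(paste0("malformed GPX: ",
                                                   conditionMessage(e))))
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trk/trkseg/trkpt")
  if (length(pts) == 0) abort("GPX document contains no trackpoints")
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  tstr <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
  missing_t <- which(is.na(tstr) | tstr == "")
  if (length(missing_t) > 0) {
    abort(sprintf("trackpoint %d has no <time> element", missing_t[1]))
  }
  time <- lubridate::ymd_hms(tstr, tz = "UTC", quiet = TRUE)
  if (anyNA(time)) {
    abort(sprintf("trackpoint %d has an unparseable <time>",
                  which(is.na(time))[1]))
  }
  if (any(abs(lat) > 90, na.rm = TRUE) || any(abs(lon) > 180, na.rm = TRUE)) {
    abort("trackpoint coordinates outside WGS84 bounds")
  }
  trk <- tibble::tibble(lon = lon, lat = lat, time = time)
  trk <- dplyr::arrange(trk, .data$time)
  if (any(duplicated(trk$time))) {
    warn("GPX track has duplicated timestamps; keeping all points")
  }
  attr(trk, "source") <- "gpx"
  trk
}

#' @rdname parse_gpx
#' @param path path to a `.gpx` file.
#' @export
read_gpx <- function(path) {
  if (!file.exists(path)) abort(sprintf("GPX file not found: %s", path))
  parse_gpx(path)
}

#' Serialize a track as a GPX 1.1 document
#'
#' Inverse of [parse_gpx()]; used by the synthetic survey generator so the
#' ingestion path is exercised on real GPX text.
#'
#' @param track a tibble with `lon`, `lat`, `time`.
#' @param creator creator attribute string.
#' @return a single string of GPX XML.
#' @export
write_gpx_text <- function(track, creator = "trawlmetrics") {
  stopifnot_cols(track, c("lon", "lat", "time"), "track")
  pts <- sprintf(
    '      <trkpt lat="%.6f" lon="%.6f"><time>%s</time></trkpt>',
    track$lat, track$lon,
    format(lubridate::with_tz(track$time, "UTC"), "%Y-%m-%dT%H:%M:%SZ")
  )
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<gpx version="1.1" creator="', creator,
    '" xmlns="http://www.topografix.com/GPX/1/1">\n',
    "  <trk>\n    <trkseg>\n",
    paste(pts, collapse = "\n"),
    "\n    </trkseg>\n  </trk>\n</gpx>\n"
  )
}

#' Convert a track to a GeoJSON LineString feature
#'
#' @param track a tibble with `lon`, `lat`, `time`.
#' @param properties named list of extra feature properties.
#' @return a list representing a GeoJSON `Feature` (serialize with
#'   [jsonlite::toJSON()] or [write_geojson()]).
#' @export
track_to_geojson <- function(track, properties = list()) {
  stopifnot_cols(track, c("lon", "lat", "time"), "track")
  coords <- lapply(seq_len(nrow(track)), function(i) {
    c(signif6(track$lon[i]), signif6(track$lat[i]))
  })
  ts <- format(lubridate::with_tz(track$time, "UTC"), "%Y-%m-%dT%H:%M:%SZ")
  list(
    type = "Feature",
    geometry = list(type = "LineString", coordinates = coords),
    properties = c(list(timestamps = ts), properties)
  )
}

#' Write a GeoJSON object to a file
#'
#' @param x a GeoJSON-shaped list (e.g. from [track_to_geojson()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}
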