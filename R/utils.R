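# Shared internal helpers: geodesy, seasons, seed derivation, formatting.

# Mean Earth radius (km) used for all great-circle distances.
EARTH_RADIUS_KM <- 6371.0

# Great-circle distances (km) between consecutive rows of a lon/lat matrix.
haversine_km <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(numeric(0))
  p <- cbind(lon, lat)
  geosphere::distHaversine(p[-n, , drop = FALSE], p[-1, , drop = FALSE],
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Meteorological season of a date
#'
#' Seasons follow meteorological quarters: March-May is spring, June-August
#' summer, September-November autumn, December-February winter.
#'
#' @param date a `Date` vector (or something coercible with [as.Date()]).
#' @return character vector with values `"spring"`, `"summer"`, `"autumn"`,
#'   `"winter"`.
#' @export
#' @examples
#' season_of(as.Date(c("2021-04-15", "2021-12-31")))
season_of <- function(date) {
  m <- lubridate::month(as.Date(date))
  dplyr::case_when(
    m %in% 3:5 ~ "spring",
    m %in% 6:8 ~ "summer",
    m %in% 9:11 ~ "autumn",
    TRUE ~ "winter"
  )
}

# Deterministic child seed < 2^31 derived from a master seed, a stream label
# and an index, so each entity type draws from its own stream.
derive_seed <- function(master, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  s <- (as.double(master) * 48271 + h * 16807 + as.double(index) * 69621) %%
    2147483629
  as.integer(s) + 1L
}

# Local equirectangular (tangent-plane) projection: degrees -> km relative to
# an origin. Adequate at the <= 200 km extent of coastal effort grids.
project_local_km <- function(lon, lat, origin_lon, origin_lat) {
  kx <- EARTH_RADIUS_KM * cos(origin_lat * pi / 180) * pi / 180
  ky <- EARTH_RADIUS_KM * pi / 180
  list(x = (lon - origin_lon) * kx, y = (lat - origin_lat) * ky)
}

# Fixed significant-digit formatting for reproducible export artifacts.
signif6 <- function(x) signif(x, 6)

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
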