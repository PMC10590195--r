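# Survey bundle I/O: the on-disk layout mirrors what the monitoring program
# collects — one GPX file per haul plus CSV tables — so the ingestion path
# (GPX parsing, haul cutting, swept-area computation) is exercised when a
# survey is read back.

#' Write a survey bundle to a directory
#'
#' Writes `species.csv`, `ports.csv`, `hauls.csv`, `onboard.csv`,
#' `samples.csv`, `individuals.csv`, `vms.csv`, `landings.csv`, one GPX file
#' per haul under `gpx/`, and a `manifest.json` listing every file.
#'
#' @param survey a `trawl_survey` bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(file.path(dir, "gpx"), showWarnings = FALSE, recursive = TRUE)
  reg <- survey$species
  names(reg)[names(reg) == "code"] <- "code"
  readr::write_csv(reg, file.path(dir, "species.csv"), na = "")
  readr::write_csv(survey$ports, file.path(dir, "ports.csv"))
  hauls_out <- dplyr::select(
    survey$hauls, -dplyr::any_of(c("swept_distance_km", "swept_area_km2")))
  readr::write_csv(hauls_out, file.path(dir, "hauls.csv"))
  readr::write_csv(survey$onboard, file.path(dir, "onboard.csv"))
  readr::write_csv(survey$samples, file.path(dir, "samples.csv"))
  readr::write_csv(survey$individuals, file.path(dir, "individuals.csv"),
                   na = "")
  readr::write_csv(dplyr::select(survey$vms, -dplyr::any_of("fishing_true")),
                   file.path(dir, "vms.csv"))
  readr::write_csv(survey$landings, file.path(dir, "landings.csv"))
  gpx_files <- character(0)
  if (!is.null(survey$gpx)) {
    for (h in names(survey$gpx)) {
      p <- file.path(dir, "gpx", paste0(h, ".gpx"))
      writeLines(survey$gpx[[h]], p)
      gpx_files <- c(gpx_files, file.path("gpx", paste0(h, ".gpx")))
    }
  }
  jsonlite::write_json(
    list(tables = c("species.csv", "ports.csv", "hauls.csv", "onboard.csv",
                    "samples.csv", "individuals.csv", "vms.csv",
                    "landings.csv"),
         gpx = gpx_files,
         n_hauls = nrow(survey$hauls)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a survey bundle from a directory
#'
#' Reads the CSV tables and GPX files written by [write_survey()] (or
#' assembled by hand in the same layout) and recomputes haul geometry from
#' the raw tracks and onboard fixes.
#'
#' @param dir directory holding the survey files.
#' @return a `trawl_survey` bundle.
#' @export
read_survey <- function(dir) {
  rd <- function(f, ...) readr::read_csv(file.path(dir, f),
                                         show_col_types = FALSE, ...)
  species <- validate_species_registry(rd("species.csv"))
  hauls <- rd("hauls.csv")
  onboard <- rd("onboard.csv")
  samples <- rd("samples.csv")
  individuals <- rd("individuals.csv")
  vms_path <- file.path(dir, "vms.csv")
  vms <- if (file.exists(vms_path)) rd("vms.csv") else NULL
  landings_path <- file.path(dir, "landings.csv")
  landings <- if (file.exists(landings_path)) rd("landings.csv") else NULL
  ports_path <- file.path(dir, "ports.csv")
  ports <- if (file.exists(ports_path)) rd("ports.csv") else NULL

  gpx_paths <- list.files(file.path(dir, "gpx"), pattern = "\\.gpx$",
                          full.names = TRUE)
  tracks <- purrr::map(gpx_paths, function(p) {
    trk <- read_gpx(p)
    trk$haul_id <- sub("\\.gpx$", "", basename(p))
    trk
  })
  tracks <- dplyr::bind_rows(tracks)
  geom <- compute_haul_geometry(hauls, tracks, onboard)
  survey <- list(
    species = species, ports = ports, hauls = add_time_labels(geom$hauls),
    tracks = tracks, cut_tracks = geom$cut_tracks, onboard = onboard,
    samples = samples, individuals = individuals, vms = vms,
    landings = landings, gpx = NULL, truth = NULL
  )
  class(survey) <- "trawl_survey"
  survey
}

#' Write standardized metrics as tidy CSV
#'
#' @param metrics output of [standardize_abundance()] or
#'   [standardize_biomass()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  readr::write_csv(metrics, path)
  invisible(path)
}
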