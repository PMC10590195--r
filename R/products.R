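# Exportable data products: length-frequency series, 4-level catch
# composition trees and per-haul geolocation documents, emitted as static
# JSON / GeoJSON / CSV artifacts with fixed 6-significant-digit formatting so
# rebuilding from the same tables is byte-identical.

#' Length-frequency series per species
#'
#' Aggregated abundance at length (individuals/km²) per species, averaged
#' over the hauls of the requested grouping (default: the whole survey — all
#' areas and years).
#'
#' @param survey a survey bundle.
#' @param species character vector of species codes (default: all registered
#'   species present in the data).
#' @param by optional haul grouping columns passed to
#'   [aggregate_abundance()]; `NULL` averages over everything.
#' @param abundance optional precomputed [standardize_abundance()] table.
#' @param ... passed to [standardize_abundance()].
#' @return tibble `species_code`, group columns (if any), `length_class`,
#'   `abundance_n_km2`, sorted by class.
#' @export
build_length_frequency <- function(survey, species = NULL, by = NULL,
                                   abundance = NULL, ...) {
  if (is.null(abundance)) abundance <- standardize_abundance(survey, ...)
  present <- unique(abundance$species_code)
  if (is.null(species)) {
    species <- intersect(survey$species$code, present)
  } else {
    unknown <- setdiff(species, survey$species$code)
    if (length(unknown) > 0) {
      abort(sprintf("unknown species in filter: %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  agg <- aggregate_abundance(
    dplyr::filter(abundance, .data$species_code %in% species),
    survey$hauls, survey$samples, by = by)
  agg |>
    dplyr::rename(abundance_n_km2 = "value") |>
    dplyr::arrange(.data$species_code, .data$length_class)
}

#' Plot length-frequency series
#'
#' @param lf output of [build_length_frequency()].
#' @return a ggplot with one line per species.
#' @export
plot_length_frequency <- function(lf) {
  ggplot2::ggplot(lf, ggplot2::aes(x = .data$length_class,
                                   y = .data$abundance_n_km2,
                                   colour = .data$species_code)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Length class (cm)",
                  y = expression(Individuals / km^2), colour = "Species")
}

#' Hierarchical catch composition tree
#'
#' Builds the 4-level composition hierarchy: `area -> port -> category ->
#' species` (mode `"port"`) or `year -> season -> category -> species` (mode
#' `"season"`). Leaves carry the aggregated biomass (kg/km², averaged over
#' the hauls of the port or year-season group); every internal node's value
#' is the sum of its children, up to the root.
#'
#' @param survey a survey bundle.
#' @param mode `"port"` or `"season"`.
#' @param species optional species filter applied to the leaves before
#'   summation.
#' @param biomass optional precomputed [standardize_biomass()] table.
#' @return a `composition_node` list (`label`, `level`, `value`, `children`);
#'   flatten with [composition_leaves()], write with
#'   [write_catch_composition()].
#' @export
build_catch_composition <- function(survey, mode = c("port", "season"),
                                    species = NULL, biomass = NULL) {
  mode <- match.arg(mode)
  if (is.null(biomass)) biomass <- standardize_biomass(survey)
  hauls <- add_time_labels(survey$hauls)
  if (mode == "port") {
    lv <- c("area", "port")
    if (!all(lv %in% names(hauls))) abort("hauls lack area/port labels")
  } else {
    lv <- c("year", "season")
  }
  agg <- aggregate_biomass(biomass, hauls, survey$samples, by = lv[2])
  lab_map <- dplyr::distinct(hauls, .data[[lv[1]]], .data[[lv[2]]])
  agg <- dplyr::left_join(agg, lab_map, by = lv[2])
  if (!is.null(species)) {
    unknown <- setdiff(
      species, c(survey$species$code, unique(agg$species_code)))
    if (length(unknown) > 0) {
      abort(sprintf("unknown species in filter: %s",
                    paste(unknown, collapse = ", ")))
    }
    agg <- dplyr::filter(agg, .data$species_code %in% species)
  }
  leaves <- agg |>
    dplyr::transmute(
      l1 = as.character(.data[[lv[1]]]), l2 = as.character(.data[[lv[2]]]),
      l3 = .data$category, l4 = .data$species_code,
      value = signif6(.data$value))
  node <- function(label, level, children) {
    list(label = label, level = level,
         value = sum(purrr::map_dbl(children, "value")),
         children = children)
  }
  build <- function(df, depth) {
    if (depth == 4) {
      return(purrr::map(seq_len(nrow(df)), function(i) {
        list(label = df$l4[i], level = "species", value = df$value[i],
             children = NULL)
      }))
    }
    col <- paste0("l", depth)
    lev_names <- c("1" = if (mode == "port") "area" else "year",
                   "2" = if (mode == "port") "port" else "season",
                   "3" = "category")
    parts <- split(df, df[[col]])
    purrr::map(parts, function(d) {
      node(d[[col]][1], lev_names[[as.character(depth)]],
           build(d, depth + 1))
    }) |> unname()
  }
  root <- node("total", "root",
               build(dplyr::arrange(leaves, .data$l1, .data$l2, .data$l3,
                                    .data$l4), 1))
  structure(root, class = "composition_node", mode = mode)
}

#' Flatten a composition tree to its leaves
#'
#' @param tree a `composition_node` from [build_catch_composition()].
#' @return tibble `level1`, `level2`, `category`, `species_code`,
#'   `biomass_kg_km2` — the downloadable form of a composition pie chart.
#' @export
composition_leaves <- function(tree) {
  rows <- list()
  for (n1 in tree$children) {
    for (n2 in n1$children) {
      for (n3 in n2$children) {
        for (n4 in n3$children) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            level1 = n1$label, level2 = n2$label, category = n3$label,
            species_code = n4$label, biomass_kg_km2 = n4$value)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a composition tree as JSON and its leaves as CSV
#'
#' @param tree a `composition_node`.
#' @param path_json,path_csv output paths; either may be `NULL`.
#' @return the tree, invisibly.
#' @export
write_catch_composition <- function(tree, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(unclass(tree), path_json, auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(path_csv)) readr::write_csv(composition_leaves(tree), path_csv)
  invisible(tree)
}

#' @export
print.composition_node <- function(x, ...) {
  cat(sprintf("Catch composition tree (%s mode): root %.4g kg/km2, %d leaves\n",
              attr(x, "mode"), x$value, nrow(composition_leaves(x))))
  invisible(x)
}

#' Per-haul geolocation document
#'
#' GeoJSON Feature for one haul: the cut track as a LineString and, as
#' properties, the haul's metadata (date, port, area, season, depth, swept
#' area, duration) and its catch composition aggregated per category and
#' species (kg/km², the sum of the haul's per-sample biomass).
#'
#' @param survey a survey bundle (with `cut_tracks`).
#' @param haul_id haul identifier.
#' @param biomass optional precomputed [standardize_biomass()] table.
#' @return a GeoJSON-shaped list (write with [write_geojson()]).
#' @export
build_haul_geolocation <- function(survey, haul_id, biomass = NULL) {
  haul <- dplyr::filter(survey$hauls, .data$haul_id == !!haul_id)
  if (nrow(haul) == 0) abort(sprintf("unknown haul '%s'", haul_id))
  trk <- dplyr::filter(survey$cut_tracks, .data$haul_id == !!haul_id)
  if (nrow(trk) == 0) abort(sprintf("haul '%s' has no cut track", haul_id))
  if (is.null(biomass)) biomass <- standardize_biomass(survey)
  comp <- biomass |>
    dplyr::filter(.data$haul_id == !!haul_id) |>
    dplyr::group_by(.data$category, .data$species_code) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop")
  comp_list <- purrr::map(split(comp, comp$category), function(d) {
    setNames(as.list(signif6(d$value)), d$species_code)
  })
  duration_min <- as.numeric(difftime(max(trk$time), min(trk$time),
                                      units = "mins"))
  track_to_geojson(
    trk[, c("lon", "lat", "time")],
    properties = list(
      haul_id = haul_id,
      date = format(haul$date),
      port = haul$port,
      area = haul$area,
      season = haul$season,
      depth_m = haul$depth_stratum_m,
      gear_width_m = haul$gear_width_m,
      swept_distance_km = signif6(haul$swept_distance_km),
      swept_area_km2 = signif6(haul$swept_area_km2),
      duration_min = duration_min,
      composition_kg_km2 = comp_list
    )
  )
}

#' Export all data products of a survey
#'
#' Writes the length-frequency JSON, the port and season composition trees
#' (JSON + CSV) and one geolocation GeoJSON per haul into `dir`.
#'
#' @param survey a survey bundle.
#' @param dir output directory (created if needed).
#' @return named list of written file paths, invisibly.
#' @export
export_products <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  abundance <- standardize_abundance(survey)
  biomass <- standardize_biomass(survey)
  lf <- build_length_frequency(survey, abundance = abundance)
  lf_path <- file.path(dir, "length_frequency.json")
  lf_out <- purrr::map(split(lf, lf$species_code), function(d) {
    list(length_class = d$length_class,
         abundance_n_km2 = signif6(d$abundance_n_km2))
  })
  jsonlite::write_json(lf_out, lf_path, auto_unbox = FALSE, digits = NA)
  paths <- list(length_frequency = lf_path)
  for (mode in c("port", "season")) {
    tree <- build_catch_composition(survey, mode = mode, biomass = biomass)
    pj <- file.path(dir, sprintf("composition_%s.json", mode))
    pc <- file.path(dir, sprintf("composition_%s.csv", mode))
    write_catch_composition(tree, pj, pc)
    paths[[paste0("composition_", mode)]] <- c(pj, pc)
  }
  geo_dir <- file.path(dir, "hauls")
  dir.create(geo_dir, showWarnings = FALSE)
  for (h in survey$hauls$haul_id) {
    write_geojson(build_haul_geolocation(survey, h, biomass = biomass),
                  file.path(geo_dir, paste0(h, ".geojson")))
  }
  paths$haul_geolocation <- geo_dir
  invisible(paths)
}
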