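# Swept-area standardization.
#
# Catch is standardized to densities over the area swept by the gear:
#   abundance (individuals / km^2), per species x, length class y, sample z:
#       A_xyz = F_xyz * SP_z * DP_z / (SD * GW)
#   biomass (kg / km^2), per species x, category k, sample z:
#       B_xkz = sum_i w_i * SP_z * DP_z / (SD * GW)
# where F is the measured count, SP the subsample raising factor, DP the
# discard raising factor (1 outside the discarded category), SD the swept
# distance (km) and GW the gear width (km). w_i is the measured weight of
# individual i when it was weighed in the laboratory, otherwise a*L^b from
# the species' length-weight relationship (applied only to field-measured
# individuals).

# Default length-class widths (cm) per taxon group: crustaceans are measured
# in carapace length and resolved at 0.5 cm, everything else at 1 cm.
DEFAULT_BIN_WIDTHS <- c(fish = 1, cephalopod = 1, crustacean = 0.5, other = 1)

#' Assign individuals to length classes
#'
#' Bins individual lengths into half-open classes `[m*w, (m+1)*w)` and counts
#' individuals per (species, length class, sample). The class is labelled by
#' its lower bound. The width `w` is taken per taxon group from
#' `bin_widths` via the registry, or forced globally with `bin_width`.
#'
#' @param individuals tibble with `species_code`, `length_cm`, `sample_id`.
#' @param registry species registry (needed unless `bin_width` is given).
#' @param bin_width single width (cm) overriding the per-group defaults.
#' @param bin_widths named vector of widths per group; default 1 cm for fish
#'   and cephalopods, 0.5 cm for crustaceans.
#' @return tibble `species_code`, `length_class`, `sample_id`, `count`.
#' @export
#' @examples
#' ind <- tibble::tibble(species_code = "HKE", length_cm = c(2.1, 2.9, 3),
#'                       sample_id = "s1")
#' bin_lengths(ind, bin_width = 1)
bin_lengths <- function(individuals, registry = NULL, bin_width = NULL,
                        bin_widths = DEFAULT_BIN_WIDTHS) {
  stopifnot_cols(individuals, c("species_code", "length_cm", "sample_id"),
                 "individuals")
  # debris/litter items carry weights but no length; they have no length class
  individuals <- dplyr::filter(individuals, !is.na(.data$length_cm))
  if (nrow(individuals) == 0) {
    return(tibble::tibble(species_code = character(), length_class = numeric(),
                          sample_id = character(), count = integer()))
  }
  if (!is.null(bin_width)) {
    if (!is.numeric(bin_width) || bin_width <= 0) {
      abort("bin_width must be a positive number")
    }
    w <- rep(bin_width, nrow(individuals))
  } else {
    if (is.null(registry)) abort("supply a registry or an explicit bin_width")
    if (any(bin_widths <= 0)) abort("bin widths must be positive")
    grp <- registry$group[match(individuals$species_code, registry$code)]
    grp[is.na(grp) | !grp %in% names(bin_widths)] <- "other"
    w <- unname(bin_widths[grp])
  }
  individuals |>
    dplyr::mutate(length_class = floor(.data$length_cm / w) * w) |>
    dplyr::count(.data$species_code, .data$length_class, .data$sample_id,
                 name = "count") |>
    dplyr::arrange(.data$species_code, .data$sample_id, .data$length_class)
}

#' Swept-area abundance density
#'
#' Standardizes a measured count to individuals per km² swept:
#' `F * SP * DP / (SD * GW)`.
#'
#' @param count measured individuals `F` (>= 0).
#' @param sp subsample raising factor (>= 1).
#' @param dp discard raising factor (>= 1; 1 outside the discarded fraction).
#' @param sd_km swept distance (km), > 0.
#' @param gw_km gear width (km), > 0.
#' @return individuals per km².
#' @export
#' @examples
#' abundance_density(10, sp = 2, dp = 1, sd_km = 2, gw_km = 0.05) # 200
abundance_density <- function(count, sp, dp, sd_km, gw_km) {
  if (any(sd_km <= 0) || any(gw_km <= 0)) {
    abort("degenerate haul: swept distance and gear width must be > 0")
  }
  if (any(count < 0)) abort("count must be >= 0")
  if (any(sp < 1) || any(dp < 1)) {
    abort("raising factors SP and DP must be >= 1")
  }
  count * sp * dp / (sd_km * gw_km)
}

#' Standardize abundance by length class for a survey
#'
#' Applies [bin_lengths()] and [abundance_density()] across all samples of a
#' survey bundle.
#'
#' @param survey a survey bundle (list with `individuals`, `samples`, `hauls`,
#'   `species`), e.g. from [generate_survey()] or [read_survey()].
#' @param ... passed to [bin_lengths()] (`bin_width`, `bin_widths`).
#' @return tibble `species_code`, `length_class`, `sample_id`, `haul_id`,
#'   `category`, `count`, `value` (individuals/km²), `units`.
#' @export
standardize_abundance <- function(survey, ...) {
  stopifnot_cols(survey$samples,
                 c("sample_id", "haul_id", "category", "sp", "dp"), "samples")
  stopifnot_cols(survey$hauls,
                 c("haul_id", "swept_distance_km", "gear_width_m"), "hauls")
  counts <- bin_lengths(survey$individuals, registry = survey$species, ...)
  counts |>
    dplyr::inner_join(
      dplyr::select(survey$samples, "sample_id", "haul_id", "category",
                    "sp", "dp"),
      by = "sample_id") |>
    dplyr::inner_join(
      dplyr::select(survey$hauls, "haul_id", "swept_distance_km",
                    "gear_width_m"),
      by = "haul_id") |>
    dplyr::mutate(
      value = abundance_density(.data$count, .data$sp, .data$dp,
                                .data$swept_distance_km,
                                .data$gear_width_m / 1000),
      units = "individuals/km2"
    ) |>
    dplyr::select("species_code", "length_class", "sample_id", "haul_id",
                  "category", "count", "value", "units")
}

#' Swept-area biomass density of one sample's individuals
#'
#' Sums individual weights — measured weight for laboratory individuals,
#' `a * L^b` (grams) for field individuals measured only in length — raises by
#' SP and DP, converts to kg and divides by the swept area.
#'
#' @param individuals tibble with `length_cm`, `weight_g` (NA when not
#'   weighed) and `measured_in` (`"field"` or `"laboratory"`).
#' @param a,b length-weight parameters used for unweighed individuals; may be
#'   `NA` when every individual carries a measured weight.
#' @param sp,dp raising factors (>= 1).
#' @param sd_km,gw_km swept distance and gear width (km).
#' @return kg per km².
#' @export
biomass_density <- function(individuals, a, b, sp, dp, sd_km, gw_km) {
  if (sd_km <= 0 || gw_km <= 0) {
    abort("degenerate haul: swept area must be > 0")
  }
  if (nrow(individuals) == 0) return(0)
  w <- individuals$weight_g
  need_lw <- is.na(w)
  if (any(need_lw)) {
    if (is.na(a) || is.na(b)) {
      abort("length-weight parameters missing for unweighed individuals")
    }
    w[need_lw] <- length_to_weight(individuals$length_cm[need_lw], a, b)
  }
  sum(w) / 1000 * sp * dp / (sd_km * gw_km)
}

#' Standardize biomass by catch category for a survey
#'
#' Applies [biomass_density()] per (species, sample). Weights measured in the
#' laboratory are used as-is; field individuals are converted with the
#' registry's length-weight relationship. Debris and litter items always carry
#' measured weights and are never length-converted.
#'
#' @param survey a survey bundle (see [standardize_abundance()]).
#' @return tibble `species_code`, `category`, `sample_id`, `haul_id`, `value`
#'   (kg/km²), `units`.
#' @export
standardize_biomass <- function(survey) {
  ind <- survey$individuals
  stopifnot_cols(ind, c("species_code", "length_cm", "weight_g", "sample_id"),
                 "individuals")
  reg <- survey$species
  need <- unique(ind$species_code[is.na(ind$weight_g)])
  missing_par <- setdiff(need, reg$code)
  if (length(missing_par) > 0) {
    abort(sprintf("no length-weight parameters for species: %s",
                  paste(missing_par, collapse = ", ")))
  }
  joined <- ind |>
    dplyr::left_join(dplyr::select(reg, species_code = "code", "a", "b"),
                     by = "species_code") |>
    dplyr::inner_join(
      dplyr::select(survey$samples, "sample_id", "haul_id", "category",
                    "sp", "dp"),
      by = "sample_id") |>
    dplyr::inner_join(
      dplyr::select(survey$hauls, "haul_id", "swept_distance_km",
                    "gear_width_m"),
      by = "haul_id")
  w_g <- joined$weight_g
  need_lw <- is.na(w_g)
  w_g[need_lw] <- length_to_weight(joined$length_cm[need_lw],
                                   joined$a[need_lw], joined$b[need_lw])
  joined$w_g <- w_g
  joined |>
    dplyr::group_by(.data$species_code, .data$category, .data$sample_id,
                    .data$haul_id) |>
    dplyr::summarise(
      value = sum(.data$w_g) / 1000 * .data$sp[1] * .data$dp[1] /
        (.data$swept_distance_km[1] * .data$gear_width_m[1] / 1000),
      .groups = "drop"
    ) |>
    dplyr::mutate(units = "kg/km2")
}

# Shared engine for the aggregation of per-sample densities over hauls:
# for each group of hauls (port, area, year-season, or the whole survey),
# per value key: (1/N) * sum over the group's NS samples, where N counts all
# hauls in the group (a haul without the species still counts in N).
aggregate_density <- function(values, hauls, samples = NULL, by = NULL,
                              keys) {
  hauls <- add_time_labels(hauls)
  bad <- setdiff(by, names(hauls))
  if (length(bad) > 0) {
    abort(sprintf("unknown haul grouping column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (!is.null(by) && any(purrr::map_lgl(by, ~ anyNA(hauls[[.x]])))) {
    abort("haul has a missing group label (port/area/season)")
  }
  grp_tbl <- hauls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n_hauls = dplyr::n(), .groups = "drop")
  if (!is.null(samples)) {
    ns_tbl <- samples |>
      dplyr::left_join(dplyr::select(hauls, "haul_id",
                                     dplyr::all_of(by)), by = "haul_id") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(n_samples = dplyr::n_distinct(.data$sample_id),
                       .groups = "drop")
  } else {
    ns_tbl <- values |>
      dplyr::left_join(dplyr::select(hauls, "haul_id",
                                     dplyr::all_of(by)), by = "haul_id") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(n_samples = dplyr::n_distinct(.data$sample_id),
                       .groups = "drop")
  }
  sums <- values |>
    dplyr::left_join(dplyr::select(hauls, "haul_id", dplyr::all_of(by)),
                     by = "haul_id") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, keys)))) |>
    dplyr::summarise(.sum = sum(.data$value), .groups = "drop")
  join_grp <- function(x, y) {
    if (length(by) == 0) dplyr::cross_join(x, y) else
      dplyr::left_join(x, y, by = by)
  }
  out <- sums |>
    join_grp(grp_tbl) |>
    join_grp(ns_tbl) |>
    dplyr::mutate(value = .data$.sum / .data$n_hauls) |>
    dplyr::select(dplyr::all_of(c(by, keys)), "n_hauls", "n_samples", "value")
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(by, keys))))
}

#' Aggregate standardized abundance over hauls
#'
#' For each group of hauls and each (species, length class):
#' `(1/N) * sum over the group's samples of the per-sample abundance`, where
#' `N` is the number of hauls in the group. A haul where the species is
#' absent contributes nothing to the sum but still counts in `N`, so the
#' result is an average over effort.
#'
#' @param abundance output of [standardize_abundance()].
#' @param hauls hauls tibble (used for group labels and `N`).
#' @param samples optional samples tibble; when given, `n_samples` (`NS`)
#'   counts all samples in the group's hauls, not only those where the species
#'   occurs.
#' @param by character vector of haul columns defining the groups (`"port"`,
#'   `"area"`, `c("year", "season")`, ...); `NULL` aggregates the whole
#'   survey.
#' @return tibble with the group columns, `species_code`, `length_class`,
#'   `n_hauls`, `n_samples`, `value` (individuals/km²).
#' @export
aggregate_abundance <- function(abundance, hauls, samples = NULL, by = NULL) {
  aggregate_density(abundance, hauls, samples, by,
                    keys = c("species_code", "length_class"))
}

#' Aggregate standardized biomass over hauls
#'
#' Same averaging as [aggregate_abundance()] applied to per-sample biomass,
#' keyed by (species, category). Groups are typically ports (`by = "port"`)
#' or year-seasons (`by = c("year", "season")`).
#'
#' @inheritParams aggregate_abundance
#' @param biomass output of [standardize_biomass()].
#' @return tibble with the group columns, `species_code`, `category`,
#'   `n_hauls`, `n_samples`, `value` (kg/km²).
#' @export
aggregate_biomass <- function(biomass, hauls, samples = NULL, by = NULL) {
  aggregate_density(biomass, hauls, samples, by,
                    keys = c("species_code", "category"))
}

# Ensure hauls carry year and season labels derived from the date.
add_time_labels <- function(hauls) {
  if (!"year" %in% names(hauls) && "date" %in% names(hauls)) {
    hauls$year <- lubridate::year(as.Date(hauls$date))
  }
  if (!"season" %in% names(hauls) && "date" %in% names(hauls)) {
    hauls$season <- season_of(hauls$date)
  }
  hauls
}
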