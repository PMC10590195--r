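# Quality control. Mirrors the survey's human-in-the-loop validation
# workflow: parametrized range checks on lengths, MCRS flags on landed
# individuals, log-log residual outliers against the fitted length-weight
# relationship, and end-of-season completeness checks. Checks never mutate
# the data; every finding is returned as an issue row.

qc_issue <- function(severity, rule_id, table, row_id, message) {
  tibble::tibble(severity = severity, rule_id = rule_id, table = table,
                 row_id = as.character(row_id), message = message)
}

qc_empty <- function() {
  tibble::tibble(severity = character(), rule_id = character(),
                 table = character(), row_id = character(),
                 message = character())
}

#' Validate individual lengths against the species registry
#'
#' Emits a `length_range` warning for every individual whose length falls
#' outside the species' usual `[length_min_cm, length_max_cm]` range, a
#' `below_mcrs` warning for landed individuals under the species' minimum
#' conservation reference size, and an `unknown_species` error for individuals
#' of species absent from the registry. Range and MCRS violations are
#' warnings, not errors: extreme values may be true observations that the
#' operator confirms visually.
#'
#' @param individuals tibble with `species_code`, `length_cm` and (for the
#'   MCRS check) a `category` column or a joinable `sample_id`.
#' @param registry species registry tibble.
#' @param samples optional samples tibble supplying `category` per
#'   `sample_id` when `individuals` lacks a `category` column.
#' @return an issues tibble (`severity`, `rule_id`, `table`, `row_id`,
#'   `message`); empty when everything passes.
#' @export
validate_lengths <- function(individuals, registry, samples = NULL) {
  stopifnot_cols(individuals, c("species_code", "length_cm"), "individuals")
  ind <- tibble::as_tibble(individuals)
  if (!"row_id" %in% names(ind)) {
    ind$row_id <- if ("individual_id" %in% names(ind)) {
      as.character(ind$individual_id)
    } else {
      as.character(seq_len(nrow(ind)))
    }
  }
  # debris/litter items are weighed, never length-measured: out of scope here
  ind <- dplyr::filter(ind, !is.na(.data$length_cm))
  if (nrow(ind) == 0) return(qc_empty())
  if (!"category" %in% names(ind) && !is.null(samples) &&
      all(c("sample_id", "category") %in% c(names(ind), names(samples)))) {
    ind <- dplyr::left_join(
      ind, dplyr::select(samples, "sample_id", "category"), by = "sample_id")
  }
  reg <- dplyr::select(registry, species_code = "code", "length_min_cm",
                       "length_max_cm", dplyr::any_of("mcrs_cm"))
  j <- dplyr::left_join(ind, reg, by = "species_code")

  issues <- list()
  unk <- is.na(j$length_min_cm)
  if (any(unk)) {
    issues <- c(issues, list(qc_issue(
      "error", "unknown_species", "individuals", j$row_id[unk],
      sprintf("species '%s' is not in the registry", j$species_code[unk])
    )))
  }
  out <- !unk & (j$length_cm < j$length_min_cm | j$length_cm > j$length_max_cm)
  if (any(out)) {
    issues <- c(issues, list(qc_issue(
      "warning", "length_range", "individuals", j$row_id[out],
      sprintf("%s length %.2f cm outside usual range [%g, %g] cm",
              j$species_code[out], j$length_cm[out],
              j$length_min_cm[out], j$length_max_cm[out])
    )))
  }
  if ("mcrs_cm" %in% names(j) && "category" %in% names(j)) {
    und <- !unk & !is.na(j$mcrs_cm) & !is.na(j$category) &
      j$category == "landed" & j$length_cm < j$mcrs_cm
    if (any(und)) {
      issues <- c(issues, list(qc_issue(
        "warning", "below_mcrs", "individuals", j$row_id[und],
        sprintf("landed %s of %.2f cm is below the MCRS of %g cm",
                j$species_code[und], j$length_cm[und], j$mcrs_cm[und])
      )))
    }
  }
  if (length(issues) == 0) qc_empty() else dplyr::bind_rows(issues)
}

#' Flag length-weight outliers
#'
#' Flags weighed individuals whose log-weight residual from the fitted
#' log-log length-weight line exceeds `k` residual standard deviations —
#' the numeric counterpart of spotting stray points on the length-weight
#' scatter plot during data entry.
#'
#' @param individuals tibble with `length_cm` and `weight_g`.
#' @param fit an [lw_fit][fit_length_weight] for the species.
#' @param k residual-sd multiplier (> 0); default 3.
#' @return issues tibble with one `lw_outlier` warning per flagged individual.
#' @export
flag_lw_outliers <- function(individuals, fit, k = 3) {
  if (!inherits(fit, "lw_fit")) abort("fit must be an lw_fit object")
  if (!is.numeric(k) || k <= 0) abort("k must be > 0")
  ind <- tibble::as_tibble(individuals)
  if (!"row_id" %in% names(ind)) ind$row_id <- as.character(seq_len(nrow(ind)))
  weighed <- is.finite(ind$weight_g) & ind$weight_g > 0 &
    is.finite(ind$length_cm) & ind$length_cm > 0
  if (!any(weighed)) {
    inform("flag_lw_outliers: no weighed individuals to check")
    return(qc_empty())
  }
  d <- ind[weighed, ]
  resid <- log(d$weight_g) - (log(fit$a) + fit$b * log(d$length_cm))
  flag <- abs(resid) > k * fit$residual_sd_loglog
  if (!any(flag)) return(qc_empty())
  qc_issue(
    "warning", "lw_outlier", "individuals", d$row_id[flag],
    sprintf("weight %.1f g deviates %.1f sd from the length-weight fit at %.1f cm",
            d$weight_g[flag], abs(resid[flag]) / fit$residual_sd_loglog,
            d$length_cm[flag])
  )
}

#' End-of-season completeness check of a survey bundle
#'
#' Cross-table referential and consistency checks run before a season's data
#' are accepted: every haul has a GPS track and at least two onboard
#' positions; every sample references an existing haul and has
#' `subsample_weight_kg <= fraction_weight_kg`; every individual references an
#' existing sample; every haul has a positive swept area.
#'
#' @param survey a survey bundle (list with `hauls`, `tracks`, `onboard`,
#'   `samples`, `individuals`).
#' @return issues tibble; empty for a fully consistent dataset.
#' @export
check_completeness <- function(survey) {
  issues <- list()
  hauls <- survey$hauls
  no_track <- !hauls$haul_id %in% unique(survey$tracks$haul_id)
  if (any(no_track)) {
    issues <- c(issues, list(qc_issue(
      "error", "haul_without_track", "hauls", hauls$haul_id[no_track],
      sprintf("haul %s has no GPS track", hauls$haul_id[no_track]))))
  }
  ob_counts <- table(survey$onboard$haul_id)
  n_ob <- as.integer(ob_counts[hauls$haul_id])
  n_ob[is.na(n_ob)] <- 0L
  no_ob <- n_ob < 2
  if (any(no_ob)) {
    issues <- c(issues, list(qc_issue(
      "error", "haul_without_onboard", "hauls", hauls$haul_id[no_ob],
      sprintf("haul %s has %d onboard position(s); at least 2 required",
              hauls$haul_id[no_ob], n_ob[no_ob]))))
  }
  if ("swept_area_km2" %in% names(hauls)) {
    bad_area <- !is.finite(hauls$swept_area_km2) | hauls$swept_area_km2 <= 0
    if (any(bad_area)) {
      issues <- c(issues, list(qc_issue(
        "error", "nonpositive_swept_area", "hauls", hauls$haul_id[bad_area],
        sprintf("haul %s has swept area <= 0", hauls$haul_id[bad_area]))))
    }
  }
  smp <- survey$samples
  orphan_s <- !smp$haul_id %in% hauls$haul_id
  if (any(orphan_s)) {
    issues <- c(issues, list(qc_issue(
      "error", "sample_missing_haul", "samples", smp$sample_id[orphan_s],
      sprintf("sample %s references unknown haul %s",
              smp$sample_id[orphan_s], smp$haul_id[orphan_s]))))
  }
  bad_w <- smp$subsample_weight_kg > smp$fraction_weight_kg
  if (any(bad_w)) {
    issues <- c(issues, list(qc_issue(
      "error", "subsample_exceeds_fraction", "samples", smp$sample_id[bad_w],
      sprintf("sample %s: subsample %.2f kg exceeds fraction %.2f kg",
              smp$sample_id[bad_w], smp$subsample_weight_kg[bad_w],
              smp$fraction_weight_kg[bad_w]))))
  }
  ind <- survey$individuals
  orphan_i <- !ind$sample_id %in% smp$sample_id
  if (any(orphan_i)) {
    rid <- if ("individual_id" %in% names(ind)) {
      ind$individual_id[orphan_i]
    } else {
      which(orphan_i)
    }
    issues <- c(issues, list(qc_issue(
      "error", "individual_missing_sample", "individuals", rid,
      sprintf("individual references unknown sample %s",
              ind$sample_id[orphan_i]))))
  }
  if (length(issues) == 0) qc_empty() else dplyr::bind_rows(issues)
}

#' Run the full QC suite on a survey bundle
#'
#' Combines [check_completeness()], [validate_lengths()] and, per species with
#' at least three weighed individuals, [flag_lw_outliers()] against a
#' length-weight fit of that species' weighed individuals.
#'
#' @param survey a survey bundle.
#' @param k outlier threshold in residual standard deviations.
#' @return issues tibble sorted by severity then rule.
#' @export
qc_survey <- function(survey, k = 3) {
  issues <- dplyr::bind_rows(
    check_completeness(survey),
    validate_lengths(survey$individuals, survey$species, survey$samples)
  )
  weighed <- dplyr::filter(survey$individuals,
                           is.finite(.data$weight_g), .data$weight_g > 0)
  by_sp <- split(weighed, weighed$species_code)
  for (d in by_sp) {
    if (nrow(d) >= 3 && length(unique(d$length_cm)) >= 2) {
      fit <- fit_length_weight(d, species_code = d$species_code[1])
      issues <- dplyr::bind_rows(issues, flag_lw_outliers(d, fit, k = k))
    }
  }
  dplyr::arrange(issues, dplyr::desc(.data$severity == "error"),
                 .data$rule_id, .data$row_id)
}

#' Write a QC report
#'
#' Writes the issues tibble as CSV and as structured JSON (grouped counts per
#' rule plus the full issue list).
#'
#' @param issues issues tibble from the QC functions.
#' @param path_csv,path_json output paths; either may be `NULL` to skip.
#' @return the issues tibble, invisibly.
#' @export
write_qc_report <- function(issues, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) readr::write_csv(issues, path_csv)
  if (!is.null(path_json)) {
    summary <- issues |>
      dplyr::count(.data$severity, .data$rule_id, name = "n")
    jsonlite::write_json(
      list(n_issues = nrow(issues),
           n_errors = sum(issues$severity == "error"),
           by_rule = summary, issues = issues),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(issues)
}
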