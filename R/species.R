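# Species registry and length-weight conversion.
#
# The registry carries, per species, the allometric coefficients (a, b) of the
# length-weight relationship W = a * L^b (L in cm, W in grams), the usual
# length range used by the QC range check, and the minimum conservation
# reference size (MCRS) where one is defined.

#' Read a species registry from CSV
#'
#' The registry CSV must have columns `code`, `scientific_name`, `a`, `b`,
#' `length_min_cm`, `length_max_cm`, `mcrs_cm`, `group`. `a` is calibrated for
#' weights in grams and lengths in cm; `group` is one of `"fish"`,
#' `"crustacean"`, `"cephalopod"`, `"other"`.
#'
#' @param path path to the CSV file.
#' @return a tibble, validated with [validate_species_registry()].
#' @export
read_species_registry <- function(path) {
  reg <- readr::read_csv(
    path,
    col_types = readr::cols(
      code = readr::col_character(),
      scientific_name = readr::col_character(),
      a = readr::col_double(),
      b = readr::col_double(),
      length_min_cm = readr::col_double(),
      length_max_cm = readr::col_double(),
      mcrs_cm = readr::col_double(),
      group = readr::col_character()
    )
  )
  validate_species_registry(reg)
}

#' Validate a species registry
#'
#' Checks the registry invariants: positive `a` and `b`, unique codes,
#' `length_min_cm < length_max_cm`, and MCRS (when present) within
#' `[0, length_max_cm]`.
#'
#' @param registry a data frame with the registry columns (see
#'   [read_species_registry()]).
#' @return the registry as a tibble, invisibly unchanged, or an error.
#' @export
validate_species_registry <- function(registry) {
  registry <- tibble::as_tibble(registry)
  stopifnot_cols(registry, c("code", "a", "b", "length_min_cm",
                             "length_max_cm", "group"), "species registry")
  if (anyDuplicated(registry$code)) {
    abort("species registry has duplicated codes")
  }
  if (any(registry$a <= 0) || any(registry$b <= 0)) {
    abort("length-weight parameters a and b must be > 0 for every species")
  }
  if (any(registry$length_min_cm >= registry$length_max_cm)) {
    abort("length_min_cm must be < length_max_cm for every species")
  }
  if ("mcrs_cm" %in% names(registry)) {
    bad <- !is.na(registry$mcrs_cm) &
      (registry$mcrs_cm < 0 | registry$mcrs_cm > registry$length_max_cm)
    if (any(bad)) {
      abort(sprintf("MCRS outside [0, length_max_cm] for: %s",
                    paste(registry$code[bad], collapse = ", ")))
    }
  }
  registry
}

#' Convert length to weight with an allometric relationship
#'
#' Evaluates `W = a * L^b`, the standard fisheries length-weight relationship.
#' With `a` calibrated for grams and cm (the registry convention), the result
#' is in grams.
#'
#' @param length_cm numeric vector of lengths (cm), all > 0.
#' @param a,b allometric coefficient and exponent; scalars or vectors recycled
#'   against `length_cm`.
#' @return numeric vector of weights in the units of the `a` calibration.
#' @export
#' @examples
#' length_to_weight(10, a = 0.01, b = 3) # 10 g
length_to_weight <- function(length_cm, a, b) {
  if (length(length_cm) > 0 && any(!is.finite(length_cm) | length_cm <= 0)) {
    abort("length_cm must be positive and finite")
  }
  if (any(a <= 0) || any(b <= 0)) abort("a and b must be > 0")
  a * length_cm^b
}

#' Subsample raising factor
#'
#' The raising factor SP scales counts or weights observed in a measured
#' subsample up to the full sorted fraction: `SP = fraction_weight /
#' subsample_weight >= 1`. SP is 1 when the whole fraction was measured.
#'
#' @param subsample_weight_kg weight of the measured subsample (kg), > 0.
#' @param fraction_weight_kg weight of the whole sorted fraction (kg), >= the
#'   subsample weight.
#' @return numeric raising factor(s) >= 1.
#' @export
#' @examples
#' raising_factor(2, 8) # 4
raising_factor <- function(subsample_weight_kg, fraction_weight_kg) {
  if (any(!is.finite(subsample_weight_kg) | subsample_weight_kg <= 0) ||
      any(!is.finite(fraction_weight_kg) | fraction_weight_kg <= 0)) {
    abort("subsample and fraction weights must be positive")
  }
  if (any(subsample_weight_kg > fraction_weight_kg)) {
    abort("subsample_weight_kg exceeds fraction_weight_kg")
  }
  fraction_weight_kg / subsample_weight_kg
}

#' Fit a length-weight relationship
#'
#' Ordinary least squares on the log-log form `log(W) = log(a) + b * log(L)`,
#' the standard way allometric length-weight parameters are estimated from
#' laboratory individuals whose weight was measured directly. The fitted
#' relationship is then used to convert field individuals, measured only in
#' length, to weight.
#'
#' @param data a data frame of measured individuals.
#' @param length,weight column names (unquoted) holding length (cm) and weight
#'   (g); defaults `length_cm`, `weight_g`.
#' @param species_code optional species label stored in the result.
#' @return an object of class `lw_fit` with elements `a`, `b`, `r_squared`,
#'   `n_points`, `residual_sd_loglog`, `species_code` and the underlying `lm`
#'   fit. Supports [tidy()], [glance()], [predict()][predict.lw_fit] and
#'   [autoplot()][autoplot.lw_fit].
#' @export
#' @examples
#' d <- data.frame(length_cm = 5:24, weight_g = 0.005 * (5:24)^3.1)
#' fit <- fit_length_weight(d)
#' glance(fit)
fit_length_weight <- function(data, length = length_cm, weight = weight_g,
                              species_code = NA_character_) {
  len <- dplyr::pull(data, {{ length }})
  wt <- dplyr::pull(data, {{ weight }})
  keep <- is.finite(len) & is.finite(wt) & len > 0 & wt > 0
  len <- len[keep]
  wt <- wt[keep]
  if (base::length(len) < 3) {
    abort("fit_length_weight needs at least 3 positive length-weight pairs")
  }
  if (base::length(unique(len)) < 2) {
    abort("fit_length_weight needs at least 2 distinct lengths")
  }
  fit <- lm(log(wt) ~ log(len))
  res <- list(
    species_code = species_code,
    a = unname(exp(coef(fit)[1])),
    b = unname(coef(fit)[2]),
    r_squared = summary(fit)$r.squared,
    n_points = base::length(len),
    residual_sd_loglog = stats::sigma(fit),
    model = fit,
    data = tibble::tibble(length_cm = len, weight_g = wt)
  )
  structure(res, class = "lw_fit")
}

#' @export
print.lw_fit <- function(x, ...) {
  cat(sprintf(
    "Length-weight fit%s: W = %.6g * L^%.4f  (n = %d, R^2 = %.4f)\n",
    if (is.na(x$species_code)) "" else paste0(" [", x$species_code, "]"),
    x$a, x$b, x$n_points, x$r_squared
  ))
  invisible(x)
}

#' @describeIn fit_length_weight predicted weight (g) at new lengths (cm).
#' @param object,newdata,... an `lw_fit`, a vector of lengths (cm), ignored.
#' @export
predict.lw_fit <- function(object, newdata, ...) {
  length_to_weight(newdata, object$a, object$b)
}

#' Tidy a length-weight fit
#'
#' @param x an `lw_fit` object.
#' @param ... ignored.
#' @return one row per parameter (`a`, `b`) with estimate and standard error
#'   on the log-log scale mapped back where meaningful.
#' @export
tidy.lw_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b),
    std_error_loglog = unname(s[, "Std. Error"]),
    p_value = unname(s[, "Pr(>|t|)"])
  )
}

#' Glance at a length-weight fit
#'
#' @param x an `lw_fit` object.
#' @param ... ignored.
#' @return one-row tibble with `a`, `b`, `r_squared`, `n_points`,
#'   `residual_sd_loglog`.
#' @export
glance.lw_fit <- function(x, ...) {
  tibble::tibble(
    species_code = x$species_code,
    a = x$a, b = x$b, r_squared = x$r_squared,
    n_points = x$n_points, residual_sd_loglog = x$residual_sd_loglog
  )
}

#' Plot a length-weight fit
#'
#' Scatter of the measured individuals with the fitted allometric curve,
#' on log-log axes where the fit is linear.
#'
#' @param object an `lw_fit`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.lw_fit <- function(object, ...) {
  grid <- tibble::tibble(
    length_cm = seq(min(object$data$length_cm), max(object$data$length_cm),
                    length.out = 200)
  )
  grid$weight_g <- predict(object, grid$length_cm)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$length_cm, y = .data$weight_g)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Length (cm)", y = "Weight (g)",
      title = sprintf("W = %.4g L^%.3f (R² = %.3f)",
                      object$a, object$b, object$r_squared)
    )
}
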