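#' Fit the quadratic daytime temperature trend
#'
#' Operative and body temperatures in shallow, sun-exposed water rise
#' through the day in a curvilinear fashion: steeply through the morning,
#' flattening toward late afternoon. This is captured by ordinary least
#' squares on
#' \deqn{T = \beta_0 + \beta_1 t + \beta_2 t^2 + \beta_3 \,[species] + \epsilon,}
#' with `t` in raw decimal clock hours (not centered) and an optional
#' additive species offset for the second species level. This is the
#' fixed-effects skeleton of the fuller mixed-model treatment of such
#' repeated-measures series; with random individual effects omitted, the
#' standard errors here understate between-individual uncertainty (see the
#' package vignette).
#'
#' @param hour Numeric decimal clock hours (>= 4 distinct values).
#' @param value Numeric temperatures, degC.
#' @param species Optional factor/character of species labels; when
#'   supplied both levels must be present.
#' @param response Label stored with the model (e.g. `"Te"` or `"Tb"`).
#' @return An object of class `trend_model`: `coefficients` (named
#'   `intercept`, `linear`, `quadratic` and optionally `species_offset`),
#'   `se`, `peak_hour` (`-linear / (2 quadratic)`, `NA` when the quadratic
#'   term is 0), `species_levels`, `hour_range`, `response`, `n`.
#' @export
fit_quadratic_trend <- function(hour, value, species = NULL,
                                response = "Te") {
  hour <- as.numeric(hour)
  value <- as.numeric(value)
  .at_assert(length(hour) == length(value), "design",
             "hour and value must have equal length")
  .at_assert(length(unique(hour)) >= 4L, "design",
             "need >= 4 distinct hours to identify a quadratic trend, got %d",
             length(unique(hour)))
  if (!is.null(species)) {
    species <- factor(species)
    .at_assert(nlevels(species) == 2L, "design",
               "species term requires exactly 2 species levels, got %d",
               nlevels(species))
    fit <- stats::lm(value ~ hour + I(hour^2) + species)
  } else {
    fit <- stats::lm(value ~ hour + I(hour^2))
  }
  if (fit$rank < length(stats::coef(fit)) || anyNA(stats::coef(fit)))
    .at_stop("design", "rank-deficient design: coefficients not identifiable")
  cf <- stats::coef(fit)
  # summary.lm warns on noiseless (exact) data; the SEs are still well defined
  se <- suppressWarnings(summary(fit)$coefficients[, "Std. Error"])
  names(cf) <- names(se) <-
    c("intercept", "linear", "quadratic",
      if (!is.null(species)) "species_offset")
  structure(list(coefficients = cf, se = se,
                 peak_hour = if (cf[["quadratic"]] != 0)
                   -cf[["linear"]] / (2 * cf[["quadratic"]]) else NA_real_,
                 species_levels = if (is.null(species)) NULL else levels(species),
                 hour_range = range(hour), response = response,
                 n = length(value)),
            class = "trend_model")
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf("Quadratic daytime trend (%s, n = %d):\n", x$response, x$n))
  for (nm in names(x$coefficients))
    cat(sprintf("  %-14s %9.4f +/- %.4f\n", nm, x$coefficients[[nm]],
                x$se[[nm]]))
  if (is.finite(x$peak_hour))
    cat(sprintf("  peak hour      %9.2f\n", x$peak_hour))
  invisible(x)
}

#' Predict from a fitted daytime trend
#'
#' Evaluates `intercept + linear*hour + quadratic*hour^2`, plus the species
#' offset when predicting for the second species level. Hours outside the
#' fitted span are allowed but flagged with a warning, since a quadratic
#' extrapolates poorly.
#'
#' @param model A `trend_model` from [fit_quadratic_trend()].
#' @param hour Numeric decimal clock hour(s).
#' @param species Optional species label(s); required to be known levels
#'   when the model includes a species term.
#' @return Numeric predicted temperature(s), degC.
#' @export
predict_trend <- function(model, hour, species = NULL) {
  stopifnot(inherits(model, "trend_model"))
  hour <- as.numeric(hour)
  cf <- model$coefficients
  if (any(hour < model$hour_range[1L] | hour > model$hour_range[2L]))
    warning(sprintf("extrapolating outside the fitted span [%g, %g]",
                    model$hour_range[1L], model$hour_range[2L]))
  pred <- cf[["intercept"]] + cf[["linear"]] * hour +
    cf[["quadratic"]] * hour^2
  if (!is.null(model$species_levels)) {
    .at_assert(!is.null(species), "label",
               "model includes a species term; supply species")
    species <- as.character(species)
    unknown <- setdiff(unique(species), model$species_levels)
    if (length(unknown) > 0L)
      .at_stop("label", "unknown species label(s): %s",
               paste(unknown, collapse = ", "))
    pred <- pred + cf[["species_offset"]] *
      as.numeric(species == model$species_levels[2L])
  } else if (!is.null(species)) {
    # species supplied but model has no species term: offset is zero
    pred <- pred
  }
  unname(pred)
}
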