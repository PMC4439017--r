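#' Thermal-gradient configuration
#'
#' Describes the horizontal thermal gradient used in preference trials: an
#' ordered set of compartment temperatures. The default is the 12-step
#' 8-30 degC gradient in 2 degC steps with a 0.5 degC holding tolerance.
#'
#' @param compartment_temps Ordered numeric compartment temperatures, degC.
#' @param tolerance_C Holding tolerance of each compartment, degC (> 0).
#' @return An object of class `gradient_config`.
#' @export
gradient_config <- function(compartment_temps = seq(8, 30, by = 2),
                            tolerance_C = 0.5) {
  .at_assert(length(compartment_temps) >= 2L &&
               all(diff(compartment_temps) > 0 | diff(compartment_temps) < 0) &&
               length(unique(sign(diff(compartment_temps)))) == 1L,
             "parameter", "compartment temperatures must be strictly monotone")
  .at_assert(is.numeric(tolerance_C) && tolerance_C > 0,
             "parameter", "tolerance must be > 0")
  structure(list(compartment_temps = as.numeric(compartment_temps),
                 tolerance_C = tolerance_C),
            class = "gradient_config")
}

#' Load thermal-gradient trial records
#'
#' Reads per-individual gradient occupancy records: which compartment each
#' animal occupied at (nominally) 10-min intervals, with flags for being in
#' the water and active.
#'
#' @param path CSV with columns `individual_id`, `species`, `timestamp`,
#'   `compartment` (0-based index into the gradient), `in_water`, `active`
#'   (logical or 0/1). Lines starting with `#` are ignored.
#' @return A `data.frame` with typed columns.
#' @export
load_gradient_records <- function(path) {
  df <- .at_read_csv(path, "gradient")
  .at_assert(nrow(df) > 0L, "empty_input", "gradient file has no data rows: %s", path)
  .at_check_columns(df, c("individual_id", "species", "timestamp", "compartment",
                          "in_water", "active"), "gradient file")
  data.frame(individual_id = as.character(df$individual_id),
             species = as.character(df$species),
             timestamp = .at_parse_time(df$timestamp),
             compartment = as.integer(df$compartment),
             in_water = as.logical(df$in_water),
             active = as.logical(df$active),
             stringsAsFactors = FALSE)
}

#' Assign body temperatures from gradient compartments
#'
#' Body temperature of a small ectotherm equilibrates quickly with the
#' surrounding water, so T_b is taken as the nominal water temperature of
#' the occupied compartment (not the +/- tolerance band).
#'
#' @param records Gradient records (see [load_gradient_records()]); must
#'   contain a 0-based `compartment` column.
#' @param config A [gradient_config()].
#' @return `records` with an added numeric `tb_C` column.
#' @export
assign_tb_from_compartment <- function(records, config = gradient_config()) {
  stopifnot(inherits(config, "gradient_config"))
  .at_check_columns(records, "compartment", "gradient records")
  idx <- records$compartment
  k <- length(config$compartment_temps)
  bad <- which(is.na(idx) | idx < 0L | idx >= k)
  if (length(bad) > 0L)
    .at_stop("index", "compartment index out of range [0, %d] in row(s): %s",
             k - 1L, paste(utils::head(bad, 10L), collapse = ", "))
  records$tb_C <- config$compartment_temps[idx + 1L]
  records
}

#' Exclude chronically inactive individuals
#'
#' Animals that were inactive or out of the water for more than the
#' threshold fraction of their records yield no usable preference data and
#' are excluded. The rule is a strict inequality: an individual exactly at
#' the threshold is retained.
#'
#' @param records Gradient records with logical `in_water` and `active`
#'   columns.
#' @param threshold Exclusion threshold on the inactive-or-out-of-water
#'   fraction, in (0, 1]. Default 0.90.
#' @return A list with `retained` (character ids), `excluded` (a
#'   `data.frame` of excluded ids with their inactive fractions) and
#'   `fractions` (per-individual inactive fraction, named).
#' @export
filter_inactive <- function(records, threshold = 0.90) {
  .at_assert(is.numeric(threshold) && length(threshold) == 1L &&
               threshold > 0 && threshold <= 1,
             "parameter", "threshold must lie in (0, 1]")
  .at_check_columns(records, c("individual_id", "in_water", "active"),
                    "gradient records")
  inactive <- !records$active | !records$in_water
  frac <- tapply(inactive, records$individual_id, mean)
  excluded <- names(frac)[frac > threshold]
  list(retained = setdiff(names(frac), excluded),
       excluded = data.frame(individual_id = excluded,
                             inactive_fraction = as.numeric(frac[excluded]),
                             stringsAsFactors = FALSE),
       fractions = frac)
}

#' Estimate a preferred-temperature range from gradient body temperatures
#'
#' The preferred range is bounded by percentiles of the individual's
#' selected-temperature distribution: by default the 10th and 90th, the
#' interval the animal is taken to target when thermoregulating without
#' constraint. Percentiles use linear interpolation between order
#' statistics (rank position (n-1)p/100), i.e. `stats::quantile(type = 7)`.
#'
#' @param tb_samples Numeric body temperatures, degC.
#' @param p_low,p_high Lower/upper percentile boundaries (defaults 10, 90).
#' @param min_n Minimum sample size (default 10).
#' @param individual_id,species Optional labels carried into the result.
#' @return An object of class `tp_estimate`: list with `lower_C`,
#'   `upper_C`, `mean_C`, `n_obs`, plus any labels.
#' @export
estimate_tp_range <- function(tb_samples, p_low = 10, p_high = 90,
                              min_n = 10, individual_id = NA_character_,
                              species = NA_character_) {
  tb_samples <- tb_samples[is.finite(tb_samples)]
  .at_assert(length(tb_samples) >= min_n, "sample_size",
             "need at least %d observations, got %d", min_n, length(tb_samples))
  .at_assert(p_low <= p_high && p_low >= 0 && p_high <= 100,
             "parameter", "percentiles must satisfy 0 <= p_low <= p_high <= 100")
  q <- stats::quantile(tb_samples, probs = c(p_low, p_high) / 100,
                       type = 7, names = FALSE)
  structure(list(individual_id = individual_id, species = species,
                 lower_C = q[1L], upper_C = q[2L],
                 mean_C = mean(tb_samples), n_obs = length(tb_samples)),
            class = "tp_estimate")
}

#' @export
print.tp_estimate <- function(x, ...) {
  cat(sprintf("Tp estimate%s: [%.2f, %.2f] degC, mean %.2f (n = %d)\n",
              if (is.na(x$individual_id)) "" else paste0(" for ", x$individual_id),
              x$lower_C, x$upper_C, x$mean_C, x$n_obs))
  invisible(x)
}

#' Per-individual preferred-temperature table from gradient records
#'
#' Convenience wrapper: assigns T_b from compartments, applies the
#' inactivity filter, restricts to in-water active records, and estimates
#' one preferred range per retained individual.
#'
#' @inheritParams assign_tb_from_compartment
#' @inheritParams filter_inactive
#' @inheritParams estimate_tp_range
#' @return A list with `estimates` (a `data.frame`, one row per retained
#'   individual: `individual_id`, `species`, `lower_C`, `upper_C`,
#'   `mean_C`, `n_obs`) and `exclusions` (the filter report).
#' @export
estimate_tp_table <- function(records, config = gradient_config(),
                              threshold = 0.90, p_low = 10, p_high = 90,
                              min_n = 10) {
  records <- assign_tb_from_compartment(records, config)
  filt <- filter_inactive(records, threshold)
  usable <- records[records$individual_id %in% filt$retained &
                      records$in_water & records$active, , drop = FALSE]
  est <- lapply(split(usable, usable$individual_id), function(d) {
    e <- estimate_tp_range(d$tb_C, p_low, p_high, min_n,
                           individual_id = d$individual_id[1L],
                           species = d$species[1L])
    data.frame(individual_id = e$individual_id, species = e$species,
               lower_C = e$lower_C, upper_C = e$upper_C, mean_C = e$mean_C,
               n_obs = e$n_obs, stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, est)
  rownames(est) <- NULL
  list(estimates = est, exclusions = filt$excluded)
}

#' Species-level preferred-temperature summary
#'
#' Mean of the per-individual mean selected temperatures for one species,
#' with a non-parametric percentile bootstrap confidence interval across
#' individuals. With a single individual the mean is returned and the CI is
#' flagged unavailable.
#'
#' @param estimates The `estimates` data.frame from [estimate_tp_table()].
#' @param species Species label to summarize.
#' @param n_boot,level,seed Passed to [bootstrap_ci()].
#' @return A list: `species`, `mean_C`, `ci_lower`, `ci_upper`,
#'   `n_individuals`, `ci_available`.
#' @export
summarize_species_tp <- function(estimates, species, n_boot = 9999,
                                 level = 0.95, seed = NULL) {
  .at_assert(species %in% estimates$species, "label",
             "unknown species label '%s'", species)
  m <- estimates$mean_C[estimates$species == species]
  if (length(m) < 2L) {
    return(list(species = species, mean_C = mean(m), ci_lower = NA_real_,
                ci_upper = NA_real_, n_individuals = length(m),
                ci_available = FALSE))
  }
  ci <- bootstrap_ci(m, n_boot = n_boot, level = level, seed = seed)
  list(species = species, mean_C = ci$point, ci_lower = ci$lower,
       ci_upper = ci$upper, n_individuals = length(m), ci_available = TRUE)
}

#' Pool individual boundaries into species-level preferred ranges
#'
#' The species-level range applied to all conspecifics is the mean of the
#' individual lower boundaries to the mean of the individual upper
#' boundaries.
#'
#' @param estimates The `estimates` data.frame from [estimate_tp_table()].
#' @return Named list of [tp_range()] objects, one per species.
#' @export
species_tp_ranges <- function(estimates) {
  sp <- split(estimates, estimates$species)
  lapply(sp, function(d) tp_range(mean(d$lower_C), mean(d$upper_C)))
}
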