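#' Configuration for a simulated thermoregulation study
#'
#' Bundles the environmental and behavioral parameters of one simulated
#' species group. Defaults emulate a mid-June shallow-tank study: a 45-cm
#' water column logged every 5 cm and 30 min, a quadratic daytime surface
#' warming trend, linear vertical stratification (surface warmer), and
#' hourly daytime observations between 10:00 and 17:00.
#'
#' @param n_individuals Number of agents (default 30).
#' @param behavior `"thermoregulator"` (active depth selection toward the
#'   preferred range) or `"conformer"` (temperature-independent depth
#'   use). A conformer is exactly a thermoregulator with `effort = 0`.
#' @param tp_range Preferred range used by the agents ([tp_range()]).
#' @param effort Probability per hour that a thermoregulator actively
#'   selects the best depth rather than a uniformly random one, in [0, 1]
#'   (default 0.85).
#' @param species Species label stamped on the records.
#' @param depth_max_cm,depth_step_cm Water-column geometry (defaults 45, 5).
#' @param hours Observation clock hours (default `10:17`).
#' @param date Study date (default `"2014-06-10"`).
#' @param surface_trend Quadratic surface-temperature coefficients
#'   `c(intercept, linear, quadratic)` in degC against decimal hour;
#'   the default rises from about 17.6 degC at 10:00 to a plateau near
#'   24.8 degC around 17:00.
#' @param stratification_C_per_cm Linear vertical gradient, degC per cm,
#'   surface warmer (default 0.08, i.e. 3.6 degC over 45 cm).
#' @param noise_sd_C SD of Gaussian measurement/microhabitat noise added
#'   to every grid cell, degC (default 0.3).
#' @param seed RNG seed (mandatory; default 1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 30,
                       behavior = c("thermoregulator", "conformer"),
                       tp_range = aquatherm::tp_range(15.9, 19.9),
                       effort = 0.85,
                       species = NULL,
                       depth_max_cm = 45, depth_step_cm = 5,
                       hours = 10:17, date = "2014-06-10",
                       surface_trend = c(intercept = -17.076,
                                         linear = 4.912,
                                         quadratic = -0.144),
                       stratification_C_per_cm = 0.08,
                       noise_sd_C = 0.3, seed = 1) {
  behavior <- match.arg(behavior)
  .at_assert(depth_max_cm %% depth_step_cm == 0, "config",
             "depth step must divide the maximum depth")
  .at_assert(effort >= 0 && effort <= 1, "config", "effort must be in [0, 1]")
  .at_assert(noise_sd_C >= 0, "config", "noise sd must be >= 0")
  .at_assert(is.numeric(seed) && length(seed) == 1L, "config",
             "a scalar seed is required")
  stopifnot(inherits(tp_range, "tp_range"))
  if (is.null(species)) species <- behavior
  structure(list(n_individuals = as.integer(n_individuals),
                 behavior = behavior, tp_range = tp_range,
                 effort = effort, species = species,
                 depth_max_cm = depth_max_cm, depth_step_cm = depth_step_cm,
                 hours = as.numeric(hours), date = as.Date(date),
                 surface_trend = unname(surface_trend),
                 stratification_C_per_cm = stratification_C_per_cm,
                 noise_sd_C = noise_sd_C, seed = as.integer(seed)),
            class = "sim_config")
}

.at_sim_depths <- function(config) seq(0, config$depth_max_cm,
                                       by = config$depth_step_cm)

.at_sim_times <- function(config) {
  start <- (min(config$hours) - 1) * 3600
  end <- (max(config$hours) + 1) * 3600
  as.POSIXct(as.character(config$date), tz = "UTC") + seq(start, end, by = 1800)
}

.at_surface_temp <- function(config, hour_dec) {
  b <- config$surface_trend
  b[1L] + b[2L] * hour_dec + b[3L] * hour_dec^2
}

#' Simulate a stratified operative-temperature profile
#'
#' Builds a depth x time grid on 30-min timestamps spanning the configured
#' observation hours (padded one hour either side):
#' `Te(depth, t) = surface_trend(t) - stratification * depth + N(0, noise_sd)`.
#'
#' @param config A [sim_config()].
#' @param tank_id Tank identifier for the profile.
#' @param seed RNG seed; defaults to `config$seed`. Pass `NULL` to draw
#'   from the current RNG stream (used when composing several tanks in one
#'   reproducible study).
#' @return A `te_profile`.
#' @export
simulate_te_profile <- function(config, tank_id = "logger1",
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  depths <- .at_sim_depths(config)
  times <- .at_sim_times(config)
  hour_dec <- (as.numeric(times) -
                 as.numeric(as.POSIXct(as.character(config$date), tz = "UTC"))) / 3600
  surface <- .at_surface_temp(config, hour_dec)
  grid <- outer(-config$stratification_C_per_cm * depths, surface, `+`)
  if (config$noise_sd_C > 0)
    grid <- grid + matrix(stats::rnorm(length(grid), 0, config$noise_sd_C),
                          nrow = nrow(grid))
  dimnames(grid) <- list(depth = depths, NULL)
  structure(list(tank_id = tank_id, depths = depths, times = times,
                 grid = grid),
            class = "te_profile")
}

# Workhorse: simulate hourly depth choices for a set of agents against one
# profile. p_regulate is the per-hour probability of active selection.
.at_sim_positions <- function(profile, config, ids, tank_id) {
  depths <- profile$depths
  p_reg <- if (config$behavior == "thermoregulator") config$effort else 0
  rows <- list()
  for (h in config$hours) {
    inst <- .at_instant(config$date, h)
    temps <- .at_column_temps(profile, inst)
    devs <- deviation_from_range(temps, config$tp_range)
    best <- max(depths[devs <= min(devs) + 1e-12])  # ties -> deepest
    u <- stats::runif(length(ids))
    pick <- depths[sample.int(length(depths), length(ids), replace = TRUE)]
    depth <- ifelse(u < p_reg, best, pick)
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = ids, species = config$species, tank_id = tank_id,
      date = as.character(config$date), hour = h, depth_cm = depth,
      tb_C = temps[match(depth, depths)], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$individual_id, out$hour), ]
}

# Analytic expectation of E (mean-of-deviations convention) under the
# behavioral rule, given the realized temperature field.
.at_expected_e <- function(profile, config) {
  p_reg <- if (config$behavior == "thermoregulator") config$effort else 0
  per_hour <- vapply(config$hours, function(h) {
    temps <- .at_column_temps(profile, .at_instant(config$date, h))
    devs <- deviation_from_range(temps, config$tp_range)
    de_mod <- mean(devs)
    db_best <- min(devs)
    p_reg * (de_mod - db_best)
  }, numeric(1))
  mean(per_hour)
}

#' Simulate hourly agent positions in a water column
#'
#' At each observation hour every agent either actively selects the grid
#' depth whose temperature deviates least from its preferred range (ties
#' broken toward the deepest such depth, matching the tendency of aquatic
#' thermoregulators to retreat downward) — with probability `effort` — or
#' occupies a uniformly random grid depth. A conformer always does the
#' latter. Body temperature is the water temperature at the occupied depth.
#'
#' @param profile A `te_profile` covering the configured hours.
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`; `NULL` draws from the
#'   current stream.
#' @return A list: `observations` (a `data.frame` with one row per
#'   individual-hour: `individual_id`, `species`, `tank_id`, `date`,
#'   `hour`, `depth_cm`, `tb_C`) and `truth` (behavior, effort, the range
#'   used, and `expected_E`, the analytic expectation of the
#'   mean-of-deviations effectiveness under the behavioral rule).
#' @export
simulate_agent_positions <- function(profile, config, seed = config$seed) {
  stopifnot(inherits(profile, "te_profile"), inherits(config, "sim_config"))
  .at_assert(length(profile$depths) > 0L, "config", "empty depth grid")
  span_ok <- all(.at_instant(config$date, config$hours) >= min(profile$times)) &&
    all(.at_instant(config$date, config$hours) <= max(profile$times))
  .at_assert(span_ok, "config", "profile does not cover the configured hours")
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("%s_%02d", config$species, seq_len(config$n_individuals))
  obs <- .at_sim_positions(profile, config, ids, profile$tank_id)
  truth <- list(behavior = stats::setNames(rep(config$behavior,
                                               config$n_individuals), ids),
                effort = config$effort,
                tp_range = c(lower_C = config$tp_range$lower_C,
                             upper_C = config$tp_range$upper_C),
                expected_E = .at_expected_e(profile, config))
  list(observations = obs, truth = truth)
}

# Gradient-trial generator: one center per individual around the middle of
# the species range, records discretized to the nearest compartment.
.at_sim_gradient <- function(config, n_individuals, n_motionless,
                             gradient = gradient_config(),
                             between_sd = 0.8) {
  temps <- gradient$compartment_temps
  step <- temps[2L] - temps[1L]
  center <- (config$tp_range$lower_C + config$tp_range$upper_C) / 2
  # P10-P90 width of a normal is 2 * 1.2816 * sd
  within_sd <- (config$tp_range$upper_C - config$tp_range$lower_C) / 2.5631
  times <- .at_instant(config$date, 10) + seq(0, 7 * 3600, by = 600)
  rows <- list()
  for (i in seq_len(n_individuals)) {
    id <- sprintf("%s_tp%02d", config$species, i)
    mu <- stats::rnorm(1, center, between_sd)
    tb <- stats::rnorm(length(times), mu, within_sd)
    comp <- pmin(pmax(round((tb - temps[1L]) / step), 0L),
                 length(temps) - 1L)
    motionless <- i <= n_motionless
    p_active <- if (motionless) 0.04 else 0.95
    rows[[i]] <- data.frame(
      individual_id = id, species = config$species,
      timestamp = format(times, "%Y-%m-%dT%H:%M:%S"),
      compartment = as.integer(comp),
      in_water = stats::runif(length(times)) < 0.98,
      active = stats::runif(length(times)) < p_active,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.at_write_csv_seed <- function(df, path, seed) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Generate a complete two-species synthetic study
#'
#' Produces everything the analysis pipeline consumes, with known ground
#' truth: depth-stratified logger readings for a subset of logger-equipped
#' tanks (two marginal and one middle tank of a 14-tank array, each tank
#' inheriting the profile of its nearest logger), hourly behavioral
#' observations for two species with different behavioral rules and
#' preferred ranges, and thermal-gradient trial records (including fully
#' motionless individuals that the inactivity filter should discard).
#'
#' The default design pairs an active thermoregulator species holding a
#' cool preferred range (30 individuals) against a thermoconformer with a
#' warmer, wider range (26 individuals), so that the regulator faces a
#' thermally poor habitat (positive expected E) and the conformer stays
#' near thermoconformity (expected E of zero under the mean-of-deviations
#' convention).
#'
#' @param config_a,config_b [sim_config()] for the two species; their
#'   environmental settings (column geometry, hours, date, trend,
#'   stratification) must match.
#' @param dir Optional output directory; when given, writes
#'   `loggers.csv`, `observations.csv`, `gradient_trials.csv` and
#'   `truth.json` (CSVs carry the seed in a `#` header line).
#' @param n_tanks Number of tanks in the array (default 14).
#' @param logger_tanks Indices of the logger-equipped tanks (default
#'   `c(1, 7, 14)`).
#' @param inter_tank_sd_C SD of the between-tank thermal perturbation,
#'   degC (default 0.1 for the tank offset and again for cell-level
#'   noise), keeping tanks within the <= 1 degC consistency envelope.
#' @param gradient_n,gradient_motionless Per-species gradient-trial sample
#'   size (default 15) and number of fully motionless individuals
#'   (defaults 3 and 1 for species a and b).
#' @return (Invisibly) a list: `readings` (logger rows), `observations`,
#'   `gradient`, `profiles` (named list of `te_profile`), `tank_map`,
#'   `truth`, and `files` (paths, when `dir` was given).
#' @export
generate_study <- function(config_a = sim_config(),
                           config_b = sim_config(
                             n_individuals = 26, behavior = "conformer",
                             tp_range = tp_range(19.2, 24.2),
                             species = "conformer", seed = 1),
                           dir = NULL, n_tanks = 14,
                           logger_tanks = c(1, 7, 14),
                           inter_tank_sd_C = 0.1,
                           gradient_n = 15,
                           gradient_motionless = c(3, 1)) {
  stopifnot(inherits(config_a, "sim_config"), inherits(config_b, "sim_config"))
  same_env <- identical(.at_sim_depths(config_a), .at_sim_depths(config_b)) &&
    identical(config_a$hours, config_b$hours) &&
    identical(config_a$date, config_b$date) &&
    identical(config_a$surface_trend, config_b$surface_trend) &&
    identical(config_a$stratification_C_per_cm,
              config_b$stratification_C_per_cm)
  .at_assert(same_env, "config",
             "the two configurations disagree on the shared environment")
  set.seed(config_a$seed)

  tanks <- sprintf("tank%02d", seq_len(n_tanks))
  loggers <- tanks[logger_tanks]
  nearest <- vapply(seq_len(n_tanks), function(i)
    tanks[logger_tanks[which.min(abs(logger_tanks - i))]], character(1))
  tank_map <- stats::setNames(nearest, tanks)

  # shared thermal field plus small per-tank perturbations
  base <- simulate_te_profile(config_a, tank_id = loggers[1L], seed = NULL)
  profiles <- stats::setNames(lapply(loggers, function(tk) {
    p <- base
    p$tank_id <- tk
    p$grid <- p$grid + stats::rnorm(1, 0, inter_tank_sd_C) +
      matrix(stats::rnorm(length(p$grid), 0, inter_tank_sd_C),
             nrow = nrow(p$grid))
    p
  }), loggers)

  readings <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(tank_id = p$tank_id,
               depth_cm = rep(p$depths, times = length(p$times)),
               timestamp = format(rep(p$times, each = length(p$depths)),
                                  "%Y-%m-%dT%H:%M:%S"),
               temp_C = as.vector(p$grid), stringsAsFactors = FALSE)
  }))
  rownames(readings) <- NULL

  # spread individuals across the array; each experiences its mapped logger
  sim_species <- function(config, id_offset_tanks) {
    ids <- sprintf("%s_%02d", config$species, seq_len(config$n_individuals))
    tank_of <- tanks[((seq_along(ids) - 1L + id_offset_tanks) %% n_tanks) + 1L]
    obs <- do.call(rbind, lapply(split(seq_along(ids), tank_map[tank_of]), function(ix) {
      .at_sim_positions(profiles[[tank_map[tank_of[ix[1L]]]]], config,
                        ids[ix], tank_of[ix[1L]])
    }))
    obs$tank_id <- tank_of[match(obs$individual_id, ids)]
    obs
  }
  obs_a <- sim_species(config_a, 0L)
  obs_b <- sim_species(config_b, 7L)
  observations <- rbind(obs_a, obs_b)
  rownames(observations) <- NULL

  grad <- rbind(
    .at_sim_gradient(config_a, gradient_n, gradient_motionless[1L]),
    .at_sim_gradient(config_b, gradient_n, gradient_motionless[2L]))

  truth <- list(
    seed = config_a$seed,
    species = stats::setNames(
      list(list(behavior = config_a$behavior, effort = config_a$effort,
                n_individuals = config_a$n_individuals,
                tp_range = c(config_a$tp_range$lower_C,
                             config_a$tp_range$upper_C),
                expected_E = .at_expected_e(profiles[[1L]], config_a)),
           list(behavior = config_b$behavior, effort = config_b$effort,
                n_individuals = config_b$n_individuals,
                tp_range = c(config_b$tp_range$lower_C,
                             config_b$tp_range$upper_C),
                expected_E = .at_expected_e(profiles[[1L]], config_b))),
      c(config_a$species, config_b$species)),
    tank_map = as.list(tank_map))

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(loggers = file.path(dir, "loggers.csv"),
                  observations = file.path(dir, "observations.csv"),
                  gradient = file.path(dir, "gradient_trials.csv"),
                  truth = file.path(dir, "truth.json"))
    .at_write_csv_seed(readings, files$loggers, config_a$seed)
    obs_out <- observations[, c("individual_id", "species", "tank_id",
                                "date", "hour", "depth_cm")]
    .at_write_csv_seed(obs_out, files$observations, config_a$seed)
    .at_write_csv_seed(grad, files$gradient, config_a$seed)
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(readings = readings, observations = observations,
                 gradient = grad, profiles = profiles, tank_map = tank_map,
                 truth = truth, files = files))
}
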