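# End-to-end orchestration: gradient trials -> Tp ranges -> Te profiles ->
# index table -> summaries, tests, trend fits.

.at_default_config <- function() {
  list(paths = list(loggers = NULL, observations = NULL, gradient = NULL),
       tank_map = NULL,
       tp_ranges = NULL,          # named list lower/upper; overrides gradient
       p_low = 10, p_high = 90, min_n = 10, inactivity_threshold = 0.90,
       convention = "deviation_of_mean", variant = "difference",
       per_individual_first = FALSE,
       n_perm = 9999, n_boot = 9999, level = 0.95,
       seed = 42, out_dir = NULL)
}

#' Assemble a pipeline run configuration
#'
#' Merges user settings over the documented defaults. `config` may be a
#' named list or the path to a YAML file with the same structure.
#'
#' @param config Named list or YAML path; `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(config = NULL) {
  base <- .at_default_config()
  if (is.character(config) && length(config) == 1L) {
    .at_assert(file.exists(config), "io", "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.null(config)) {
    .at_assert(is.list(config), "config", "config must be a list or YAML path")
    for (nm in names(config)) {
      if (nm %in% c("paths") && is.list(config[[nm]])) {
        base$paths[names(config$paths)] <- config$paths
      } else {
        base[[nm]] <- config[[nm]]
      }
    }
  }
  structure(base, class = "run_config")
}

# Run one pipeline stage, re-raising any error with the stage name attached.
.at_stage <- function(name, log_env, expr) {
  log_env$log <- c(log_env$log, sprintf("[stage %s] start", name))
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("in stage '%s': %s", name, conditionMessage(e)),
      class = c("aquatherm_stage_error", class(e))))
  })
}

.at_log <- function(log_env, fmt, ...) {
  log_env$log <- c(log_env$log, sprintf(fmt, ...))
}

#' Run the full thermoregulation analysis pipeline
#'
#' Orchestrates every analysis stage on one study's inputs: loads and
#' filters gradient-trial records and estimates species preferred ranges
#' (unless ranges are supplied directly), builds operative-temperature
#' profiles from logger readings and checks inter-tank consistency,
#' assembles the hourly index table (d_e, d_b, E), summarizes indices per
#' species with bootstrap CIs, runs permutation tests for the species
#' effect on d_e, d_b and E plus the hour and hour x species terms,
#' decomposes E variance by individual identity, and fits the quadratic
#' daytime trends of T_e and T_b.
#'
#' @param config A [run_config()], a named list of overrides, or a YAML
#'   path. Required entries: `paths$loggers` and `paths$observations`;
#'   either `paths$gradient` or `tp_ranges`.
#' @return A list of results: `tp_table`, `tp_exclusions`,
#'   `species_ranges`, `consistency`, `index_table`, `summary`, `tests`
#'   (a `data.frame`), `variance_E`, `trend_te`, `trend_tb`, `log` and the
#'   echoed `config`. When `config$out_dir` is set, tables, the log and
#'   the configuration are also written there as CSV/JSON/text.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  set.seed(cfg$seed)
  lg <- new.env()
  lg$log <- c(sprintf("aquatherm %s | seed %d | convention %s | variant %s",
                      as.character(utils::packageVersion("aquatherm")),
                      cfg$seed, cfg$convention, cfg$variant))

  # --- preferred ranges -----------------------------------------------
  tp_table <- NULL; tp_excl <- NULL
  if (!is.null(cfg$tp_ranges)) {
    ranges <- lapply(cfg$tp_ranges, function(r)
      tp_range(as.numeric(r[[1L]]), as.numeric(r[[2L]])))
    .at_log(lg, "[stage tpref] using %d supplied species range(s)",
            length(ranges))
  } else {
    .at_assert(!is.null(cfg$paths$gradient), "config",
               "need either paths$gradient or tp_ranges")
    grad <- .at_stage("tpref", lg, load_gradient_records(cfg$paths$gradient))
    tp <- .at_stage("tpref", lg, estimate_tp_table(
      grad, threshold = cfg$inactivity_threshold,
      p_low = cfg$p_low, p_high = cfg$p_high, min_n = cfg$min_n))
    tp_table <- tp$estimates
    tp_excl <- tp$exclusions
    ranges <- species_tp_ranges(tp_table)
    .at_log(lg, "[stage tpref] %d record(s) in, %d individual(s) retained, %d excluded (>%d%% inactive)",
            nrow(grad), nrow(tp_table), nrow(tp_excl),
            round(100 * cfg$inactivity_threshold))
  }

  # --- thermal environment --------------------------------------------
  .at_assert(!is.null(cfg$paths$loggers), "config", "paths$loggers is required")
  readings <- .at_stage("profiles", lg, load_te_readings(cfg$paths$loggers))
  tanks <- unique(readings$tank_id)
  profiles <- .at_stage("profiles", lg, stats::setNames(
    lapply(tanks, function(tk) build_profile(readings, tk)), tanks))
  consistency <- if (length(profiles) >= 2L)
    check_inter_tank_consistency(profiles) else NULL
  .at_log(lg, "[stage profiles] %d reading(s) -> %d profile(s); max inter-tank diff %s degC",
          nrow(readings), length(profiles),
          if (is.null(consistency)) "NA" else
            sprintf("%.2f%s", consistency$max_diff_C,
                    if (consistency$flag) " (FLAG >1)" else ""))

  # --- index table -----------------------------------------------------
  .at_assert(!is.null(cfg$paths$observations), "config",
             "paths$observations is required")
  obs <- .at_stage("indices", lg, {
    .at_assert(file.exists(cfg$paths$observations), "io",
               "observation file not found: %s", cfg$paths$observations)
    .at_read_csv(cfg$paths$observations, "observations")
  })
  tank_map <- if (is.null(cfg$tank_map)) NULL else
    unlist(cfg$tank_map)
  idx <- .at_stage("indices", lg, build_index_table(
    obs, profiles, ranges, convention = cfg$convention,
    variant = cfg$variant, tank_map = tank_map))
  .at_log(lg, "[stage indices] %d observation(s) in, %d index record(s) out",
          nrow(obs), nrow(idx))

  # --- summaries and inference ----------------------------------------
  summary_tab <- .at_stage("summary", lg, summarize_indices(
    idx, per_individual_first = cfg$per_individual_first,
    n_boot = cfg$n_boot, level = cfg$level))
  tests <- .at_stage("inference", lg, {
    one <- function(metric) {
      t <- permutation_anova(idx[[metric]], idx$species,
                             ids = idx$individual_id, n_perm = cfg$n_perm)
      data.frame(term = "species", response = metric,
                 pseudo_F = t$observed, df1 = t$df[1L], df2 = t$df[2L],
                 p_value = t$p_value, n_perm = t$n_perm_used,
                 stringsAsFactors = FALSE)
    }
    main <- do.call(rbind, lapply(c("de_C", "db_C", "e_diff_C"), one))
    fac <- factorial_permutation(idx$e_diff_C, idx$species,
                                 factor(idx$hour), n_perm = cfg$n_perm)
    fac_rows <- do.call(rbind, Map(function(t, nm) data.frame(
      term = nm, response = "e_diff_C", pseudo_F = t$observed,
      df1 = t$df[1L], df2 = t$df[2L], p_value = t$p_value,
      n_perm = t$n_perm_used, stringsAsFactors = FALSE),
      fac, c("species (record-level)", "hour", "hour x species")))
    rbind(main, fac_rows)
  })
  variance_E <- .at_stage("inference", lg,
                          variance_explained(idx$e_diff_C, idx$individual_id))
  .at_log(lg, "[stage inference] species effect on E: pseudo-F = %.3f, P = %.4g; individual identity explains %.1f%% of E variance",
          tests$pseudo_F[tests$term == "species" & tests$response == "e_diff_C"],
          tests$p_value[tests$term == "species" & tests$response == "e_diff_C"],
          variance_E$pct_between_individuals)

  # --- daily trends ----------------------------------------------------
  trend_te <- .at_stage("trend", lg, fit_quadratic_trend(
    idx$hour, idx$mean_Te, idx$species, response = "Te"))
  trend_tb <- .at_stage("trend", lg, fit_quadratic_trend(
    idx$hour, idx$tb_C, idx$species, response = "Tb"))
  .at_log(lg, "[stage trend] Te quadratic %.4f, Tb quadratic %.4f",
          trend_te$coefficients[["quadratic"]],
          trend_tb$coefficients[["quadratic"]])

  out <- list(tp_table = tp_table, tp_exclusions = tp_excl,
              species_ranges = ranges, consistency = consistency,
              index_table = idx, summary = summary_tab, tests = tests,
              variance_E = variance_E, trend_te = trend_te,
              trend_tb = trend_tb, log = lg$log, config = cfg)

  if (!is.null(cfg$out_dir)) {
    d <- cfg$out_dir
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    if (!is.null(tp_table))
      utils::write.csv(tp_table, file.path(d, "tp_table.csv"),
                       row.names = FALSE)
    utils::write.csv(idx, file.path(d, "index_table.csv"), row.names = FALSE)
    utils::write.csv(summary_tab, file.path(d, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(tests, file.path(d, "tests.csv"), row.names = FALSE)
    writeLines(lg$log, file.path(d, "log.txt"))
    jsonlite::write_json(
      list(seed = cfg$seed, convention = cfg$convention,
           variant = cfg$variant, p_low = cfg$p_low, p_high = cfg$p_high,
           n_perm = cfg$n_perm, n_boot = cfg$n_boot),
      file.path(d, "run_config.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
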