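#' Preferred-temperature range
#'
#' A closed interval of body temperatures an animal targets when
#' thermoregulating, bounded by percentile boundaries of its
#' gradient-selected temperatures (typically the 10th and 90th).
#'
#' @param lower_C,upper_C Boundaries in degC, `lower_C <= upper_C`.
#' @return An object of class `tp_range`.
#' @export
tp_range <- function(lower_C, upper_C) {
  .at_assert(is.finite(lower_C) && is.finite(upper_C), "range",
             "range boundaries must be finite")
  .at_assert(lower_C <= upper_C, "range",
             "inverted range: lower (%g) > upper (%g)", lower_C, upper_C)
  structure(list(lower_C = as.numeric(lower_C), upper_C = as.numeric(upper_C)),
            class = "tp_range")
}

#' @export
print.tp_range <- function(x, ...) {
  cat(sprintf("Tp range [%.2f, %.2f] degC\n", x$lower_C, x$upper_C))
  invisible(x)
}

#' Deviation of a temperature from a preferred range
#'
#' The non-negative distance of `temp` from the range: 0 inside the range,
#' `lower - temp` below it, `temp - upper` above it. This single primitive
#' underlies both the thermal-quality index d_e (applied to operative
#' temperature) and the accuracy index d_b (applied to body temperature).
#'
#' @param temp Numeric temperature(s), degC.
#' @param range A [tp_range()].
#' @return Non-negative numeric deviation(s), degC.
#' @export
#' @examples
#' r <- tp_range(18, 20)
#' deviation_from_range(c(15, 19, 21), r)  # 3, 0, 1
deviation_from_range <- function(temp, range) {
  stopifnot(inherits(range, "tp_range"))
  .at_assert(all(is.finite(temp)), "domain", "temperatures must be finite")
  pmax(range$lower_C - temp, temp - range$upper_C, 0)
}

#' Thermal quality of habitat (d_e) per hour
#'
#' d_e measures how far the thermal environment sits from the animal's
#' preferred range; 0 means the habitat offers preferred temperatures,
#' larger values a thermally worse habitat. Two conventions are supported:
#' \describe{
#'   \item{`deviation_of_mean`}{(default) deviation of the across-depth
#'     mean operative temperature from the range — the deviation of mean
#'     T_e.}
#'   \item{`mean_of_deviations`}{mean over depths of the deviation of each
#'     available operative temperature — the classical
#'     average-over-available-T_e form. Under this convention an animal
#'     occupying uniformly random depths has expected d_b equal to d_e,
#'     making it the natural null for thermoconformity.}
#' }
#'
#' @param profile A `te_profile`.
#' @param range A [tp_range()].
#' @param hours Clock hours at which to evaluate.
#' @param convention `"deviation_of_mean"` or `"mean_of_deviations"`.
#' @return `data.frame` with columns `hour`, `de_C`, `mean_Te`.
#' @export
compute_de <- function(profile, range, hours,
                       convention = c("deviation_of_mean", "mean_of_deviations")) {
  convention <- match.arg(convention)
  stopifnot(inherits(profile, "te_profile"))
  dates <- .at_profile_dates(profile)
  rows <- lapply(hours, function(h) {
    per_date <- lapply(dates, function(d) {
      inst <- .at_instant(d, h)
      if (inst < min(profile$times) - 1e-6 || inst > max(profile$times) + 1e-6)
        return(NULL)
      temps <- .at_column_temps(profile, inst)
      de <- switch(convention,
                   deviation_of_mean = deviation_from_range(mean(temps), range),
                   mean_of_deviations = mean(deviation_from_range(temps, range)))
      c(de, mean(temps))
    })
    per_date <- per_date[!vapply(per_date, is.null, logical(1))]
    if (length(per_date) == 0L)
      .at_stop("out_of_range", "hour %g is outside the profile span", h)
    m <- do.call(rbind, per_date)
    data.frame(hour = h, de_C = mean(m[, 1]), mean_Te = mean(m[, 2]))
  })
  do.call(rbind, rows)
}

#' Accuracy of thermoregulation (d_b)
#'
#' The deviation of body temperature from the preferred range, computed in
#' the same way as d_e but on T_b: 0 when the animal holds a preferred
#' temperature, larger values the further its body temperature strays.
#'
#' @param tb_C Numeric body temperature(s), degC; `NA` is an error.
#' @param range A [tp_range()].
#' @return Non-negative numeric d_b value(s), degC.
#' @export
compute_db <- function(tb_C, range) {
  .at_assert(!anyNA(tb_C), "missing_data", "body temperature is missing")
  deviation_from_range(tb_C, range)
}

#' Effectiveness of thermoregulation (E)
#'
#' The default difference form is `E = d_e - d_b`: values around zero
#' indicate thermoconformity, positive values active thermoregulation, and
#' negative values active avoidance of the preferred range. The ratio form
#' `E = d_b / d_e` is the historical formulation and is provided as
#' printed; note that other authors define the ratio-based index as
#' `1 - d_b/d_e`, so ratio values are not comparable across studies without
#' checking the convention. The ratio is flagged undefined (`NA`) when
#' `d_e = 0`.
#'
#' @param de_C,db_C Non-negative index values, degC.
#' @param variant `"difference"` (default) or `"ratio"`.
#' @return Numeric E value(s); `NA` where the ratio is undefined.
#' @export
#' @examples
#' compute_effectiveness(2.8, 1.5)  # 1.3
compute_effectiveness <- function(de_C, db_C,
                                  variant = c("difference", "ratio")) {
  variant <- match.arg(variant)
  .at_assert(all(de_C >= 0, na.rm = TRUE) && all(db_C >= 0, na.rm = TRUE),
             "domain", "d_e and d_b must be non-negative")
  if (variant == "difference") return(de_C - db_C)
  out <- ifelse(de_C == 0, NA_real_, db_C / de_C)
  out
}

#' Build the per-individual-hour index table
#'
#' Joins behavioral observations (individual, tank, date, hour, depth) with
#' operative-temperature profiles and species preferred ranges, assigns
#' T_b from the occupied depth via [te_at()], and computes d_e, d_b and E
#' for every individual-hour.
#'
#' @param observations `data.frame` with columns `individual_id`,
#'   `species`, `tank_id`, `date`, `hour`, `depth_cm`.
#' @param profiles Named list of `te_profile` objects, keyed by tank id.
#' @param ranges Named list of [tp_range()] objects, keyed by species.
#' @param convention Passed to [compute_de()].
#' @param variant Passed to [compute_effectiveness()].
#' @param tank_map Optional named character vector mapping observation
#'   tanks to logger-equipped tanks whose profile they inherit (tanks
#'   already in `profiles` need no entry).
#' @return `data.frame`: one row per observation with `tb_C`, `mean_Te`,
#'   `de_C`, `db_C`, `e_diff_C` and `e_ratio` appended. `e_diff_C` equals
#'   `de_C - db_C` exactly for every row.
#' @export
build_index_table <- function(observations, profiles, ranges,
                              convention = c("deviation_of_mean",
                                             "mean_of_deviations"),
                              variant = c("difference", "ratio"),
                              tank_map = NULL) {
  convention <- match.arg(convention)
  variant <- match.arg(variant)
  .at_check_columns(observations,
                    c("individual_id", "species", "tank_id", "date", "hour",
                      "depth_cm"), "observations")

  obs_tanks <- unique(observations$tank_id)
  resolve <- function(tk) if (!is.null(tank_map) && tk %in% names(tank_map))
    tank_map[[tk]] else tk
  profile_for <- vapply(obs_tanks, resolve, character(1))
  missing_tanks <- obs_tanks[!profile_for %in% names(profiles)]
  if (length(missing_tanks) > 0L)
    .at_stop("join", "no profile for tank(s): %s",
             paste(unique(missing_tanks), collapse = ", "))
  missing_sp <- setdiff(unique(observations$species), names(ranges))
  if (length(missing_sp) > 0L)
    .at_stop("join", "no preferred range for species: %s",
             paste(missing_sp, collapse = ", "))

  obs <- observations
  obs$.profile <- profile_for[match(obs$tank_id, obs_tanks)]
  obs$.instant <- .at_instant(obs$date, obs$hour)

  # de and mean_Te are shared by all animals in the same (profile, instant)
  env_key <- paste(obs$.profile, format(obs$.instant, "%Y-%m-%dT%H:%M"))
  env <- lapply(split(seq_len(nrow(obs)), env_key), function(ix) {
    p <- profiles[[obs$.profile[ix[1L]]]]
    inst <- obs$.instant[ix[1L]]
    temps <- .at_column_temps(p, inst)
    list(ix = ix, temps = temps, mean_Te = mean(temps))
  })

  out <- obs[, c("individual_id", "species", "tank_id", "date", "hour",
                 "depth_cm")]
  out$tb_C <- NA_real_
  out$mean_Te <- NA_real_
  out$de_C <- NA_real_
  for (e in env) {
    ix <- e$ix
    p <- profiles[[obs$.profile[ix[1L]]]]
    out$tb_C[ix] <- te_at(p, obs$depth_cm[ix],
                          rep(obs$.instant[ix[1L]], length(ix)))
    out$mean_Te[ix] <- e$mean_Te
    for (sp in unique(out$species[ix])) {
      jx <- ix[out$species[ix] == sp]
      r <- ranges[[sp]]
      out$de_C[jx] <- switch(convention,
        deviation_of_mean = deviation_from_range(e$mean_Te, r),
        mean_of_deviations = mean(deviation_from_range(e$temps, r)))
    }
  }
  out$db_C <- vapply(seq_len(nrow(out)), function(i)
    compute_db(out$tb_C[i], ranges[[out$species[i]]]), numeric(1))
  out$e_diff_C <- out$de_C - out$db_C
  out$e_ratio <- compute_effectiveness(out$de_C, out$db_C, "ratio")
  attr(out, "convention") <- convention
  attr(out, "variant") <- variant
  rownames(out) <- NULL
  out
}

#' Summarize thermoregulatory indices by group
#'
#' Group-wise means of operative temperature, body temperature, d_e, d_b
#' and E with non-parametric percentile bootstrap confidence intervals. By
#' default the mean is the grand mean over individual-hour records and the
#' bootstrap resamples records; with `per_individual_first = TRUE` records
#' are first averaged within individuals and the bootstrap resamples
#' individuals (a cluster bootstrap respecting repeated measures).
#'
#' @param records Index table from [build_index_table()].
#' @param group_by Grouping column (default `"species"`).
#' @param per_individual_first Average within individuals before the group
#'   mean (default `FALSE`).
#' @param n_boot,level,seed Bootstrap settings (see [bootstrap_ci()]).
#' @return Long `data.frame`: one row per group x metric with `mean`,
#'   `ci_lower`, `ci_upper`, `n_records`, `n_individuals`.
#' @export
summarize_indices <- function(records, group_by = "species",
                              per_individual_first = FALSE,
                              n_boot = 9999, level = 0.95, seed = NULL) {
  .at_check_columns(records, c(group_by, "individual_id", "mean_Te", "tb_C",
                               "de_C", "db_C", "e_diff_C"), "index records")
  metrics <- c(mean_Te = "mean_Te", tb_C = "tb_C", de_C = "de_C",
               db_C = "db_C", e_diff_C = "e_diff_C")
  groups <- split(records, records[[group_by]])
  .at_assert(all(vapply(groups, nrow, integer(1)) >= 1L), "label",
             "empty group in '%s'", group_by)
  rows <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    for (m in names(metrics)) {
      vals <- if (per_individual_first)
        as.numeric(tapply(d[[m]], d$individual_id, mean)) else d[[m]]
      if (length(vals) >= 2L) {
        ci <- bootstrap_ci(vals, n_boot = n_boot, level = level, seed = seed)
        lo <- ci$lower; hi <- ci$upper
      } else {
        lo <- NA_real_; hi <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, mean = mean(vals), ci_lower = lo, ci_upper = hi,
        n_records = nrow(d),
        n_individuals = length(unique(d$individual_id)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[1L] <- group_by
  out
}
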