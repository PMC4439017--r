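#' Load water-column datalogger readings
#'
#' Reads a CSV of depth-stratified temperature records, one row per
#' (tank, depth, timestamp). Depths are centimetres below the surface
#' (0 = surface, positive downward), matching the 5-cm bottom marks of the
#' experimental tanks. Timestamps are ISO-8601 and on a 30-min grid on
#' standard input, though neither is enforced here.
#'
#' @param path Path to a CSV with columns `tank_id`, `depth_cm`,
#'   `timestamp`, `temp_C`. Lines starting with `#` are ignored.
#' @return A `data.frame` with columns `tank_id` (character), `depth_cm`
#'   (numeric), `timestamp` (POSIXct, UTC) and `temp_C` (numeric), one row
#'   per reading.
#' @details Rows whose timestamp or temperature fail to parse are dropped
#'   with a warning naming the offending row numbers. Duplicate
#'   (tank, depth, timestamp) keys are an error because they make the grid
#'   ambiguous.
#' @seealso [build_profile()] to assemble readings into a complete grid.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write.csv(data.frame(tank_id = "T1", depth_cm = c(0, 5),
#'                      timestamp = "2014-06-10T10:00:00",
#'                      temp_C = c(21.5, 21.0)),
#'           path, row.names = FALSE)
#' load_te_readings(path)
load_te_readings <- function(path) {
  df <- .at_read_csv(path, "logger")
  .at_assert(nrow(df) > 0L, "empty_input", "logger file has no data rows: %s", path)
  .at_check_columns(df, c("tank_id", "depth_cm", "timestamp", "temp_C"), "logger file")

  ts <- .at_parse_time(df$timestamp)
  temp <- suppressWarnings(as.numeric(df$temp_C))
  depth <- suppressWarnings(as.numeric(df$depth_cm))
  bad <- which(is.na(ts) | !is.finite(temp) | !is.finite(depth))
  if (length(bad) > 0L) {
    warning(sprintf("dropped %d unparseable logger row(s): %s",
                    length(bad), paste(utils::head(bad, 10L), collapse = ", ")))
    keep <- setdiff(seq_len(nrow(df)), bad)
    df <- df[keep, , drop = FALSE]
    ts <- ts[keep]; temp <- temp[keep]; depth <- depth[keep]
  }
  .at_assert(nrow(df) > 0L, "empty_input", "no parseable logger rows in %s", path)

  out <- data.frame(tank_id = as.character(df$tank_id), depth_cm = depth,
                    timestamp = ts, temp_C = temp, stringsAsFactors = FALSE)
  key <- paste(out$tank_id, out$depth_cm, format(out$timestamp, "%Y-%m-%dT%H:%M:%S"))
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    .at_stop("duplicate", "duplicated (tank, depth, timestamp) key(s): %s",
             paste(utils::head(dups, 5L), collapse = "; "))
  }
  out
}

#' Build an operative-temperature profile for one tank
#'
#' Assembles logger readings for a single tank into a complete depth-by-time
#' temperature grid (a `te_profile`). The vertically stratified profile is
#' the null distribution of body temperatures a non-thermoregulating animal
#' would attain, so downstream indices require every cell to be filled.
#'
#' @param readings A `data.frame` as returned by [load_te_readings()].
#' @param tank_id Tank identifier to extract.
#' @return An object of class `te_profile`: a list with `tank_id`, `depths`
#'   (increasing cm grid), `times` (increasing POSIXct) and `grid`
#'   (depth x time temperature matrix, degrees C).
#' @details The time grid is reconstructed from the minimum to the maximum
#'   observed timestamp at the modal spacing. A single interior missing
#'   timestep at a depth is filled by linear interpolation in time at that
#'   depth; a missing boundary cell takes the nearest observed value. Two
#'   or more consecutive missing timesteps at a depth are an error, because
#'   interpolating across them would invent unobserved thermal structure.
#' @export
build_profile <- function(readings, tank_id) {
  .at_check_columns(readings, c("tank_id", "depth_cm", "timestamp", "temp_C"),
                    "readings")
  sel <- readings[readings$tank_id == tank_id, , drop = FALSE]
  .at_assert(nrow(sel) > 0L, "empty_input", "no readings for tank '%s'", tank_id)

  depths <- sort(unique(sel$depth_cm))
  tnum <- as.numeric(sel$timestamp)
  tobs <- sort(unique(tnum))
  if (length(tobs) > 1L) {
    steps <- diff(tobs)
    step <- as.numeric(names(sort(table(steps), decreasing = TRUE))[1L])
    times_num <- seq(tobs[1L], tobs[length(tobs)], by = step)
  } else {
    times_num <- tobs
  }
  grid <- matrix(NA_real_, nrow = length(depths), ncol = length(times_num),
                 dimnames = list(depth = depths, NULL))
  di <- match(sel$depth_cm, depths)
  ti <- match(round(tnum, 3), round(times_num, 3))
  .at_assert(!anyNA(ti), "grid",
             "tank '%s' has timestamps off the reconstructed time grid", tank_id)
  grid[cbind(di, ti)] <- sel$temp_C

  for (i in seq_along(depths)) {
    row <- grid[i, ]
    if (!anyNA(row)) next
    runs <- rle(is.na(row))
    interior <- which(runs$values)
    # interior runs of >= 2 NA (boundary runs are filled by nearest value,
    # but still capped at 1 missing step)
    if (any(runs$lengths[runs$values] > 1L)) {
      pos <- cumsum(runs$lengths)
      bad <- pos[which(runs$values & runs$lengths > 1L)[1L]]
      .at_stop("gap", ">1 consecutive missing timestep for tank '%s' at depth %g cm (around %s)",
               tank_id, depths[i],
               format(as.POSIXct(times_num[bad], tz = "UTC", origin = "1970-01-01")))
    }
    ok <- which(!is.na(row))
    grid[i, ] <- stats::approx(times_num[ok], row[ok], xout = times_num,
                               method = "linear", rule = 2)$y
  }

  structure(list(tank_id = tank_id, depths = depths,
                 times = as.POSIXct(times_num, tz = "UTC", origin = "1970-01-01"),
                 grid = grid),
            class = "te_profile")
}

#' @export
print.te_profile <- function(x, ...) {
  cat(sprintf("Operative-temperature profile, tank '%s'\n", x$tank_id))
  cat(sprintf("  depths: %g-%g cm (%d levels)\n",
              min(x$depths), max(x$depths), length(x$depths)))
  cat(sprintf("  times:  %s to %s (%d instants)\n",
              format(min(x$times)), format(max(x$times)), length(x$times)))
  cat(sprintf("  temp:   %.1f to %.1f degC\n", min(x$grid), max(x$grid)))
  invisible(x)
}

#' Interpolate operative temperature at arbitrary depth and time
#'
#' Bilinear interpolation on the profile grid: linear in depth at the two
#' bracketing times, then linear in time. Exact grid points are returned
#' unchanged, so the profile is reproduced identically on its own lattice.
#'
#' @param profile A `te_profile`.
#' @param depth_cm Depth(s) in cm; recycled against `time`.
#' @param time POSIXct instant(s) within the profile span.
#' @return Numeric vector of temperatures, degrees C.
#' @export
te_at <- function(profile, depth_cm, time) {
  stopifnot(inherits(profile, "te_profile"))
  n <- max(length(depth_cm), length(time))
  depth_cm <- rep_len(depth_cm, n)
  tnum <- rep_len(as.numeric(time), n)
  dgrid <- profile$depths
  tgrid <- as.numeric(profile$times)

  if (any(depth_cm < dgrid[1L] - 1e-9 | depth_cm > dgrid[length(dgrid)] + 1e-9))
    .at_stop("out_of_range", "depth outside profile span [%g, %g] cm",
             dgrid[1L], dgrid[length(dgrid)])
  if (any(tnum < tgrid[1L] - 1e-6 | tnum > tgrid[length(tgrid)] + 1e-6))
    .at_stop("out_of_range", "time outside profile span %s to %s",
             format(profile$times[1L]), format(profile$times[length(tgrid)]))

  di <- pmin(pmax(findInterval(depth_cm, dgrid), 1L), length(dgrid) - 1L)
  ti <- pmin(pmax(findInterval(tnum, tgrid), 1L), max(length(tgrid) - 1L, 1L))
  if (length(dgrid) == 1L) di <- rep_len(1L, n)

  wd <- if (length(dgrid) == 1L) rep_len(0, n) else
    (depth_cm - dgrid[di]) / (dgrid[di + 1L] - dgrid[di])
  wt <- if (length(tgrid) == 1L) rep_len(0, n) else
    (tnum - tgrid[ti]) / (tgrid[ti + 1L] - tgrid[ti])
  wd <- pmin(pmax(wd, 0), 1)
  wt <- pmin(pmax(wt, 0), 1)

  g <- profile$grid
  i2 <- if (length(dgrid) == 1L) di else di + 1L
  j2 <- if (length(tgrid) == 1L) ti else ti + 1L
  v1 <- (1 - wd) * g[cbind(di, ti)] + wd * g[cbind(i2, ti)]   # at bracketing time 1
  v2 <- (1 - wd) * g[cbind(di, j2)] + wd * g[cbind(i2, j2)]   # at bracketing time 2
  (1 - wt) * v1 + wt * v2
}

# All depth-grid temperatures at one instant (internal).
.at_column_temps <- function(profile, instant) {
  te_at(profile, profile$depths, rep(as.numeric(instant), length(profile$depths)))
}

# Dates (UTC) covered by a profile.
.at_profile_dates <- function(profile) {
  unique(as.Date(profile$times, tz = "UTC"))
}

#' Hourly water-column summaries
#'
#' For each requested clock hour, evaluates the profile at every depth of
#' its grid (via [te_at()], i.e. interpolating the 30-min logger series to
#' the exact hour) and reports the across-depth mean, minimum and maximum.
#' The column mean at an hour is the environmental side of the hourly
#' thermal-quality index d_e.
#'
#' @param profile A `te_profile`.
#' @param hours Numeric clock hours (e.g. `10:17`). May be empty.
#' @return A `data.frame` with columns `hour`, `mean_Te`, `min_Te`,
#'   `max_Te`. When the profile spans several dates the statistics are
#'   averaged across dates at each hour.
#' @export
hourly_column_stats <- function(profile, hours) {
  stopifnot(inherits(profile, "te_profile"))
  if (length(hours) == 0L)
    return(data.frame(hour = numeric(0), mean_Te = numeric(0),
                      min_Te = numeric(0), max_Te = numeric(0)))
  dates <- .at_profile_dates(profile)
  out <- lapply(hours, function(h) {
    per_date <- lapply(dates, function(d) {
      inst <- .at_instant(d, h)
      if (inst < min(profile$times) - 1e-6 || inst > max(profile$times) + 1e-6)
        return(NULL)
      temps <- .at_column_temps(profile, inst)
      c(mean(temps), min(temps), max(temps))
    })
    per_date <- per_date[!vapply(per_date, is.null, logical(1))]
    if (length(per_date) == 0L)
      .at_stop("out_of_range", "hour %g is outside the profile span", h)
    m <- do.call(rbind, per_date)
    data.frame(hour = h, mean_Te = mean(m[, 1]), min_Te = mean(m[, 2]),
               max_Te = mean(m[, 3]))
  })
  do.call(rbind, out)
}

#' Check inter-tank thermal consistency
#'
#' With several logger-equipped tanks on identical grids, computes for every
#' depth-time cell the spread (max minus min) of temperatures across tanks
#' and reports the largest spread. Spreads at or below 1 degree C indicate
#' that the logger tanks map the thermal conditions of the whole array well
#' enough that unlogged tanks can inherit a neighbour's profile.
#'
#' @param profiles A list of two or more `te_profile` objects on identical
#'   depth and time grids.
#' @param tolerance_C Spread above which the consistency flag is raised
#'   (default 1.0).
#' @return A list with `max_diff_C` (largest across-tank spread over all
#'   cells), `flag` (`TRUE` when `max_diff_C > tolerance_C`) and
#'   `tolerance_C`.
#' @export
check_inter_tank_consistency <- function(profiles, tolerance_C = 1.0) {
  .at_assert(length(profiles) >= 2L, "design",
             "need at least 2 profiles, got %d", length(profiles))
  ref <- profiles[[1L]]
  for (p in profiles[-1L]) {
    same <- identical(p$depths, ref$depths) &&
      isTRUE(all.equal(as.numeric(p$times), as.numeric(ref$times)))
    if (!same)
      .at_stop("grid_mismatch", "profiles are not on identical depth/time grids")
  }
  arr <- vapply(profiles, function(p) p$grid, ref$grid)
  spread <- apply(arr, c(1, 2), function(v) max(v) - min(v))
  max_diff <- max(spread)
  list(max_diff_C = max_diff, flag = max_diff > tolerance_C,
       tolerance_C = tolerance_C)
}
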