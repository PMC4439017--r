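# Independent oracles and fixture builders used across the suite.

# Brute-force linear-interpolation percentile: sort, take rank (n-1)p/100,
# interpolate between the bracketing order statistics.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p / 100
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo + 1] + (h - lo) * (s[hi + 1] - s[lo + 1])
}

# Classical one-way F-ratio via the standard linear-model route.
oracle_f <- function(y, g) {
  unname(anova(stats::lm(y ~ factor(g)))[1, "F value"])
}

# Exhaustive two-group permutation p-value: enumerate every assignment of
# the observed values to the two group sizes and count F >= observed.
oracle_perm_p_exhaustive <- function(y, g) {
  g <- factor(g)
  stopifnot(nlevels(g) == 2)
  n1 <- sum(g == levels(g)[1])
  obs <- oracle_f(y, g)
  picks <- utils::combn(length(y), n1)
  fs <- apply(picks, 2, function(ix) {
    lab <- rep(levels(g)[2], length(y))
    lab[ix] <- levels(g)[1]
    oracle_f(y, lab)
  })
  mean(fs >= obs - 1e-9)
}

# Build a te_profile from an explicit depth x time temperature matrix by
# round-tripping through the logger CSV reader and grid builder, so the
# fixture exercises the real plumbing.
make_profile <- function(grid, depths = NULL, hours_span = c(9, 18),
                         date = "2014-06-10", tank = "T1",
                         drop_cells = NULL) {
  if (is.null(depths)) depths <- (seq_len(nrow(grid)) - 1) * 5
  times <- as.POSIXct(date, tz = "UTC") +
    seq(hours_span[1] * 3600, hours_span[2] * 3600, by = 1800)
  stopifnot(ncol(grid) == length(times))
  df <- data.frame(tank_id = tank,
                   depth_cm = rep(depths, times = length(times)),
                   timestamp = format(rep(times, each = length(depths)),
                                      "%Y-%m-%dT%H:%M:%S"),
                   temp_C = as.vector(grid))
  if (!is.null(drop_cells)) df <- df[-drop_cells, ]
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  build_profile(load_te_readings(path), tank)
}

# Constant-in-time profile whose column temperatures at every instant are
# `column` (one value per depth).
make_static_profile <- function(column, ...) {
  make_profile(matrix(column, nrow = length(column), ncol = 19), ...)
}
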