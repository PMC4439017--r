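test_that("logger CSV loading counts rows and rejects malformed input", {
  # 9 depths x 48 half-hours
  times <- as.POSIXct("2014-06-10", tz = "UTC") + seq(0, by = 1800, length.out = 48)
  df <- expand.grid(depth_cm = seq(5, 45, by = 5), t = seq_along(times))
  df <- data.frame(tank_id = "T1", depth_cm = df$depth_cm,
                   timestamp = format(times[df$t], "%Y-%m-%dT%H:%M:%S"),
                   temp_C = 20)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_equal(nrow(load_te_readings(path)), 432L)

  # missing temp_C column
  path2 <- tempfile(fileext = ".csv")
  write.csv(df[, c("tank_id", "depth_cm", "timestamp")], path2,
            row.names = FALSE)
  expect_error(load_te_readings(path2), class = "aquatherm_format",
               regexp = "temp_C")

  # empty file
  path3 <- tempfile(fileext = ".csv")
  write.csv(df[0, ], path3, row.names = FALSE)
  expect_error(load_te_readings(path3), class = "aquatherm_empty_input")

  # duplicated keys
  path4 <- tempfile(fileext = ".csv")
  write.csv(rbind(df, df[1, ]), path4, row.names = FALSE)
  expect_error(load_te_readings(path4), class = "aquatherm_duplicate")
})

test_that("profile construction fills single gaps and rejects longer ones", {
  grid <- matrix(rep(seq(18, 19.8, length.out = 19), each = 3), nrow = 3)
  # complete grid survives round-trip unchanged
  p <- make_profile(grid, depths = c(0, 5, 10))
  expect_equal(unname(p$grid), grid)
  expect_equal(p$depths, c(0, 5, 10))

  # one interior missing cell between 18.0 and 19.0 -> 18.5
  g2 <- matrix(18, nrow = 2, ncol = 19)
  g2[1, 5] <- 18.0; g2[1, 7] <- 19.0
  # drop cell (depth row 1, time 6): row index in long layout
  drop <- (6 - 1) * 2 + 1
  p2 <- make_profile(g2, depths = c(0, 5), drop_cells = drop)
  expect_equal(unname(p2$grid[1, 6]), 18.5)

  # two consecutive missing cells at one depth -> gap error
  drops <- c((6 - 1) * 2 + 1, (7 - 1) * 2 + 1)
  expect_error(make_profile(g2, depths = c(0, 5), drop_cells = drops),
               class = "aquatherm_gap")
})

test_that("te_at reproduces the lattice and interpolates bilinearly", {
  depths <- c(0, 5, 10, 15, 20)
  grid <- outer(depths, 1:19, function(d, j) 20 + 0.1 * d + 0.05 * j)
  grid[5, 7] <- 21.5
  p <- make_profile(grid, depths = depths)

  # lattice identity, including an arbitrary overwritten cell
  expect_equal(te_at(p, 20, p$times[7]), 21.5)
  for (ij in list(c(1, 1), c(3, 10), c(5, 19)))
    expect_equal(te_at(p, depths[ij[1]], p$times[ij[2]]),
                 unname(grid[ij[1], ij[2]]))

  # midpoint between depths holding 20.0 and 22.0 at a grid time -> 21.0
  g2 <- matrix(c(20, 22), nrow = 2, ncol = 19)
  p2 <- make_profile(g2, depths = c(0, 10))
  expect_equal(te_at(p2, 5, p2$times[3]), 21.0)

  # time midway between grid instants holding 20.0 and 21.0 -> 20.5
  g3 <- matrix(20, nrow = 2, ncol = 19)
  g3[, 8] <- 20; g3[, 9] <- 21
  p3 <- make_profile(g3, depths = c(0, 5))
  tmid <- p3$times[8] + 900
  expect_equal(te_at(p3, 0, tmid), 20.5)

  # out-of-span queries error
  expect_error(te_at(p, 25, p$times[1]), class = "aquatherm_out_of_range")
  expect_error(te_at(p, 0, p$times[1] - 3600),
               class = "aquatherm_out_of_range")
})

test_that("interpolated values stay within the bracketing grid values", {
  set.seed(42)
  grid <- matrix(rnorm(10 * 19, 20, 3), nrow = 10)
  p <- make_profile(grid)
  tnum <- as.numeric(p$times)
  for (i in 1:200) {
    d <- runif(1, 0, 45)
    tt <- runif(1, tnum[1], tnum[19])
    di <- findInterval(d, p$depths, all.inside = TRUE)
    ti <- findInterval(tt, tnum, all.inside = TRUE)
    cell <- grid[di:(di + 1), ti:(ti + 1)]
    v <- te_at(p, d, as.POSIXct(tt, tz = "UTC", origin = "1970-01-01"))
    expect_gte(v, min(cell) - 1e-9)
    expect_lte(v, max(cell) + 1e-9)
  }
})

test_that("hourly column statistics summarize the depth grid at each hour", {
  # constant 20 degC column
  p <- make_static_profile(rep(20, 5))
  s <- hourly_column_stats(p, 10:17)
  expect_equal(s$mean_Te, rep(20, 8))
  expect_equal(s$min_Te, rep(20, 8))
  expect_equal(s$max_Te, rep(20, 8))

  # linear 18..26 over 9 depths: mean 22, min 18, max 26
  p2 <- make_static_profile(seq(26, 18, length.out = 9))
  s2 <- hourly_column_stats(p2, 12)
  expect_equal(s2$mean_Te, 22)
  expect_equal(s2$min_Te, 18)
  expect_equal(s2$max_Te, 26)

  # empty hour list: empty result, no error
  expect_equal(nrow(hourly_column_stats(p, numeric(0))), 0L)
  # hour outside span errors
  expect_error(hourly_column_stats(p, 3), class = "aquatherm_out_of_range")
})

test_that("hourly means are invariant under input row reordering", {
  set.seed(7)
  times <- as.POSIXct("2014-06-10", tz = "UTC") + seq(9, 18, by = 0.5) * 3600
  df <- expand.grid(depth_cm = seq(0, 45, 5), t = seq_along(times))
  df <- data.frame(tank_id = "T1", depth_cm = df$depth_cm,
                   timestamp = format(times[df$t], "%Y-%m-%dT%H:%M:%S"),
                   temp_C = round(rnorm(nrow(df), 21, 2), 2))
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write.csv(df, p1, row.names = FALSE)
  write.csv(df[sample(nrow(df)), ], p2, row.names = FALSE)
  s1 <- hourly_column_stats(build_profile(load_te_readings(p1), "T1"), 10:17)
  s2 <- hourly_column_stats(build_profile(load_te_readings(p2), "T1"), 10:17)
  expect_equal(s1, s2)
})

test_that("inter-tank consistency reports the worst across-tank spread", {
  base <- matrix(20, nrow = 3, ncol = 19)
  pa <- make_profile(base, depths = c(0, 5, 10), tank = "A")
  pb <- make_profile(base, depths = c(0, 5, 10), tank = "B")
  r <- check_inter_tank_consistency(list(pa, pb))
  expect_equal(r$max_diff_C, 0)
  expect_false(r$flag)

  g2 <- base; g2[2, 4] <- 21.5
  pc <- make_profile(g2, depths = c(0, 5, 10), tank = "C")
  r2 <- check_inter_tank_consistency(list(pa, pc))
  expect_equal(r2$max_diff_C, 1.5)
  expect_true(r2$flag)

  # three tanks with one cell at 20.0 / 20.4 / 21.0: spread 1.0, no flag
  g3 <- base; g3[1, 1] <- 20.4
  g4 <- base; g4[1, 1] <- 21.0
  pd <- make_profile(g3, depths = c(0, 5, 10), tank = "D")
  pe <- make_profile(g4, depths = c(0, 5, 10), tank = "E")
  r3 <- check_inter_tank_consistency(list(pa, pd, pe))
  expect_equal(r3$max_diff_C, 1.0)
  expect_false(r3$flag)

  # mismatched grids
  pf <- make_profile(base[1:2, ], depths = c(0, 5), tank = "G")
  expect_error(check_inter_tank_consistency(list(pa, pf)),
               class = "aquatherm_grid_mismatch")
})
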