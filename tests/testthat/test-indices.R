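test_that("deviation from the preferred range is zero inside, distance outside", {
  r <- tp_range(18, 20)
  expect_equal(deviation_from_range(19.0, r), 0.0)
  expect_equal(deviation_from_range(21.0, r), 1.0)
  expect_equal(deviation_from_range(15.0, r), 3.0)
  expect_equal(deviation_from_range(c(18, 20), r), c(0, 0))  # boundaries inside
  expect_error(tp_range(20, 18), class = "aquatherm_range")
})

test_that("d_e follows its convention on a hand-computed column", {
  r <- tp_range(18, 20)
  # constant 22 degC column: 2.0 under either convention
  p <- make_static_profile(rep(22, 5))
  expect_equal(compute_de(p, r, 12, "deviation_of_mean")$de_C, 2)
  expect_equal(compute_de(p, r, 12, "mean_of_deviations")$de_C, 2)

  # column {18, 20, 22}: deviation of mean (20) = 0; mean of deviations = 2/3
  p2 <- make_static_profile(c(22, 20, 18))
  expect_equal(compute_de(p2, r, c(10, 14), "deviation_of_mean")$de_C, c(0, 0))
  expect_equal(compute_de(p2, r, 10, "mean_of_deviations")$de_C, 2 / 3)

  # column entirely inside the range: 0
  p3 <- make_static_profile(c(18.5, 19, 19.5))
  expect_equal(compute_de(p3, r, 11, "deviation_of_mean")$de_C, 0)
  expect_equal(compute_de(p3, r, 11, "mean_of_deviations")$de_C, 0)

  expect_error(compute_de(p, r, 12, "bogus"))
})

test_that("d_b is the body-temperature deviation with a missing-data guard", {
  r <- tp_range(18, 20)
  expect_equal(compute_db(19.0, r), 0)
  expect_equal(compute_db(22.8, r), 2.8)
  expect_equal(compute_db(14.0, r), 4.0)
  expect_error(compute_db(NA_real_, r), class = "aquatherm_missing_data")
})

test_that("effectiveness combines d_e and d_b in both variants", {
  expect_equal(compute_effectiveness(2.8, 1.5, "difference"), 1.3)
  expect_equal(compute_effectiveness(1.7, 1.7, "difference"), 0)
  expect_true(is.na(compute_effectiveness(0, 0, "ratio")))
  expect_equal(compute_effectiveness(2, 1, "ratio"), 0.5)
  expect_error(compute_effectiveness(-1, 0.5), class = "aquatherm_domain")
})

make_small_study <- function(column = c(23, 21, 19), n_ind = 2,
                             hours = c(12, 13), species = "sp",
                             depths_used = 0) {
  p <- make_static_profile(column)
  obs <- expand.grid(individual_id = sprintf("%s%02d", species, seq_len(n_ind)),
                     hour = hours, stringsAsFactors = FALSE)
  obs$species <- species
  obs$tank_id <- "T1"
  obs$date <- "2014-06-10"
  obs$depth_cm <- rep_len(depths_used, nrow(obs))
  list(profile = p, obs = obs)
}

test_that("the index table matches a spreadsheet-style hand calculation", {
  # two individuals, two hours, static column {23, 21, 19} at depths 0/5/10
  st <- make_small_study()
  st$obs$depth_cm <- c(0, 10, 10, 0)  # ind1: 23 then 19; ind2: 19 then 23
  r <- tp_range(18, 20)
  idx <- build_index_table(st$obs, list(T1 = st$profile), list(sp = r))
  # mean Te = 21 -> de = 1 everywhere; db = 3 at depth 0 (Tb 23), 0 at 10 (Tb 19)
  expect_equal(idx$de_C, rep(1, 4))
  expect_equal(idx$db_C, c(3, 0, 0, 3))
  expect_equal(idx$e_diff_C, c(-2, 1, 1, -2))
  expect_equal(idx$e_ratio, c(3, 0, 0, 3))
  expect_equal(idx$tb_C, c(23, 19, 19, 23))
  expect_equal(idx$mean_Te, rep(21, 4))
})

test_that("index-table counting, identities and join errors hold", {
  st <- make_small_study(n_ind = 30, hours = 10:17)
  r <- tp_range(18, 20)
  idx <- build_index_table(st$obs, list(T1 = st$profile), list(sp = r))
  expect_equal(nrow(idx), 240L)
  expect_equal(idx$e_diff_C, idx$de_C - idx$db_C)
  expect_true(all(idx$de_C >= 0 & idx$db_C >= 0))

  # agent always inside an all-inside-range column: everything zero
  st2 <- make_small_study(column = c(19.5, 19, 18.5))
  idx2 <- build_index_table(st2$obs, list(T1 = st2$profile), list(sp = r))
  expect_equal(idx2$de_C, rep(0, nrow(idx2)))
  expect_equal(idx2$db_C, rep(0, nrow(idx2)))
  expect_equal(idx2$e_diff_C, rep(0, nrow(idx2)))

  expect_error(build_index_table(st$obs, list(T9 = st$profile), list(sp = r)),
               class = "aquatherm_join", regexp = "T1")
  expect_error(build_index_table(st$obs, list(T1 = st$profile),
                                 list(other = r)),
               class = "aquatherm_join", regexp = "sp")

  # a tank map redirects unlogged tanks to a logger profile
  st$obs$tank_id <- "T5"
  idx3 <- build_index_table(st$obs, list(T1 = st$profile), list(sp = r),
                            tank_map = c(T5 = "T1"))
  expect_equal(idx3$de_C, idx$de_C)
})

test_that("widening the preferred range never increases d_e or d_b", {
  set.seed(21)
  st <- make_small_study(column = rnorm(10, 21, 2), n_ind = 5, hours = 10:17)
  st$obs$depth_cm <- sample(seq(0, 45, 5), nrow(st$obs), replace = TRUE)
  widths <- list(tp_range(19, 20), tp_range(18, 21), tp_range(17, 22),
                 tp_range(15, 24))
  prev_de <- Inf; prev_db <- Inf
  for (r in widths) {
    idx <- build_index_table(st$obs, list(T1 = st$profile), list(sp = r))
    expect_lte(mean(idx$de_C), prev_de + 1e-12)
    expect_lte(mean(idx$db_C), prev_db + 1e-12)
    expect_true(all(idx$de_C >= 0 & idx$db_C >= 0))
    prev_de <- mean(idx$de_C); prev_db <- mean(idx$db_C)
  }
})

test_that("group summaries obey the linearity of the mean", {
  st <- make_small_study(n_ind = 6, hours = 10:17)
  set.seed(9)
  st$obs$depth_cm <- sample(c(0, 5, 10), nrow(st$obs), replace = TRUE)
  idx <- build_index_table(st$obs, list(T1 = st$profile),
                           list(sp = tp_range(18, 20)))
  s <- summarize_indices(idx, n_boot = 199, seed = 1)
  m <- function(metric) s$mean[s$metric == metric]
  expect_equal(m("e_diff_C"), m("de_C") - m("db_C"))

  # identical records: means are the raw values
  idc <- idx; idc$de_C <- 2; idc$db_C <- 1; idc$e_diff_C <- 1
  s2 <- summarize_indices(idc, n_boot = 199, seed = 1)
  expect_equal(s2$mean[s2$metric == "de_C"], 2)
  expect_equal(s2$mean[s2$metric == "db_C"], 1)
  expect_equal(s2$mean[s2$metric == "e_diff_C"], 1)
})

test_that("a cooler range worsens habitat quality relative to a warmer one", {
  # same thermal field, two species differing only in range coverage
  st <- make_small_study(column = c(23, 22, 21), n_ind = 4, hours = 10:17)
  obs2 <- st$obs; obs2$species <- "warm"
  obs2$individual_id <- sub("sp", "warm", obs2$individual_id)
  obs <- rbind(st$obs, obs2)
  ranges <- list(sp = tp_range(16, 18), warm = tp_range(21, 23))
  idx <- build_index_table(obs, list(T1 = st$profile), ranges)
  de <- tapply(idx$de_C, idx$species, mean)
  expect_gt(de[["sp"]], de[["warm"]])
})
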