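test_that("simulated profiles follow trend, stratification and seed", {
  # no noise, no stratification: every depth equals the surface trend
  cfg <- sim_config(noise_sd_C = 0, stratification_C_per_cm = 0, seed = 1)
  p <- simulate_te_profile(cfg)
  hour_dec <- (as.numeric(p$times) - as.numeric(p$times[1])) / 3600 + 9
  surf <- -17.076 + 4.912 * hour_dec - 0.144 * hour_dec^2
  for (i in seq_along(p$depths))
    expect_equal(unname(p$grid[i, ]), surf, tolerance = 1e-10)

  # stratification 0.08 degC/cm: surface minus bottom = 3.6 at every time
  cfg2 <- sim_config(noise_sd_C = 0, stratification_C_per_cm = 0.08, seed = 1)
  p2 <- simulate_te_profile(cfg2)
  expect_equal(unname(p2$grid[1, ] - p2$grid[nrow(p2$grid), ]),
               rep(3.6, ncol(p2$grid)))

  # seeded determinism
  cfg3 <- sim_config(seed = 99)
  expect_identical(simulate_te_profile(cfg3)$grid,
                   simulate_te_profile(cfg3)$grid)
})

test_that("a full-effort thermoregulator achieves d_b = 0 when the range is reachable", {
  # noise-free column straddles the range at every daytime hour
  cfg <- sim_config(n_individuals = 10, effort = 1, noise_sd_C = 0,
                    tp_range = tp_range(15, 25), seed = 2)
  p <- simulate_te_profile(cfg)
  sim <- simulate_agent_positions(p, cfg)
  r <- tp_range(15, 25)
  db <- deviation_from_range(sim$observations$tb_C, r)
  expect_equal(db, rep(0, nrow(sim$observations)))
  expect_equal(nrow(sim$observations), 80L)
})

test_that("ties in best depth break toward the deepest depth", {
  # uniform column: every depth ties; effort-1 regulator must sit deepest
  cfg <- sim_config(n_individuals = 5, effort = 1, noise_sd_C = 0,
                    stratification_C_per_cm = 0,
                    tp_range = tp_range(0, 50), seed = 3)
  p <- simulate_te_profile(cfg)
  sim <- simulate_agent_positions(p, cfg)
  expect_true(all(sim$observations$depth_cm == 45))
})

test_that("effort zero is exactly a conformer", {
  reg0 <- sim_config(n_individuals = 8, behavior = "thermoregulator",
                     effort = 0, species = "s", seed = 5)
  conf <- sim_config(n_individuals = 8, behavior = "conformer",
                     effort = 0.85, species = "s", seed = 5)
  p <- simulate_te_profile(reg0)
  o1 <- simulate_agent_positions(p, reg0, seed = 11)$observations
  o2 <- simulate_agent_positions(p, conf, seed = 11)$observations
  expect_identical(o1$depth_cm, o2$depth_cm)
  expect_identical(o1$tb_C, o2$tb_C)
})

test_that("conformers have expected E near zero under mean-of-deviations", {
  cfg <- sim_config(n_individuals = 30, behavior = "conformer",
                    tp_range = tp_range(19.2, 24.2), seed = 6)
  p <- simulate_te_profile(cfg)
  sim <- simulate_agent_positions(p, cfg)
  expect_equal(sim$truth$expected_E, 0)
  idx <- build_index_table(sim$observations, list(logger1 = p),
                           list(conformer = tp_range(19.2, 24.2)),
                           convention = "mean_of_deviations")
  expect_lt(abs(mean(idx$e_diff_C)), 0.2)
})

test_that("pipeline-estimated accuracy approaches the truth as effort grows", {
  r <- tp_range(15, 25)   # reachable at some depth at every hour
  db_at <- function(eff, seed) {
    cfg <- sim_config(n_individuals = 20, effort = eff, noise_sd_C = 0.1,
                      tp_range = r, seed = seed)
    p <- simulate_te_profile(cfg)
    sim <- simulate_agent_positions(p, cfg)
    idx <- build_index_table(sim$observations, list(logger1 = p),
                             list(thermoregulator = r),
                             convention = "mean_of_deviations")
    c(db = mean(idx$db_C), gap = abs(mean(idx$e_diff_C) - mean(idx$de_C)))
  }
  lo <- db_at(0.3, 7); hi <- db_at(1, 8)
  expect_lt(hi[["db"]], lo[["db"]])
  expect_lt(hi[["db"]], 0.05)          # d_b -> 0 at full effort
  expect_lt(hi[["gap"]], 0.05)         # mean E -> mean d_e
})

test_that("a generated study has the right shape and ground truth", {
  st <- generate_study()
  expect_equal(nrow(st$observations), (30 + 26) * 8)
  expect_equal(length(st$profiles), 3L)
  expect_setequal(unique(st$observations$species),
                  c("thermoregulator", "conformer"))
  expect_equal(st$truth$species$conformer$expected_E, 0)
  expect_gt(st$truth$species$thermoregulator$expected_E, 0)
  # every observation tank resolves to a logger profile
  expect_true(all(st$tank_map[st$observations$tank_id] %in%
                    names(st$profiles)))
  # logger tanks stay within the 1-degC consistency envelope
  cc <- check_inter_tank_consistency(st$profiles)
  expect_false(cc$flag)

  # mismatched environments are rejected
  bad <- sim_config(depth_max_cm = 40, seed = 1)
  expect_error(generate_study(config_b = bad), class = "aquatherm_config")
})

test_that("written study files round-trip losslessly through the loaders", {
  dir <- tempfile("study")
  st <- generate_study(dir = dir)
  readings <- load_te_readings(file.path(dir, "loggers.csv"))
  expect_equal(nrow(readings), nrow(st$readings))
  for (tk in names(st$profiles)) {
    p <- build_profile(readings, tk)
    expect_equal(p$grid, st$profiles[[tk]]$grid, tolerance = 1e-12)
  }
  grad <- load_gradient_records(file.path(dir, "gradient_trials.csv"))
  expect_equal(nrow(grad), nrow(st$gradient))
  obs <- read.csv(file.path(dir, "observations.csv"), comment.char = "#")
  expect_equal(nrow(obs), nrow(st$observations))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 1L)
  # seed is stamped in the CSV headers
  first <- readLines(file.path(dir, "loggers.csv"), n = 1)
  expect_match(first, "^# seed: 1$")
})

test_that("regulator and conformer species separate as designed", {
  st <- generate_study()
  ranges <- lapply(st$truth$species, function(s)
    tp_range(s$tp_range[1], s$tp_range[2]))
  idx <- build_index_table(st$observations, st$profiles, ranges,
                           tank_map = st$tank_map)
  e <- tapply(idx$e_diff_C, idx$species, mean)
  expect_gt(e[["thermoregulator"]], 0.3)
  expect_lt(abs(e[["conformer"]]), 0.5)
})
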