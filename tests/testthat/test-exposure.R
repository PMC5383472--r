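test_that("SEL accumulation is an energy sum with the usual dB identities", {
  expect_equal(accumulate_sel(NA, 180, 1), 180)
  expect_equal(accumulate_sel(180, 180, 1), 180 + 10 * log10(2))
  # N equal 1-s exposures at L give L + 10 log10 N
  sel <- NA_real_
  for (i in 1:100) sel <- accumulate_sel(sel, 180, 1)
  expect_equal(sel, 200)
  expect_equal(accumulate_sel(NA, 150, 0), NA_real_)  # still unexposed
  expect_error(accumulate_sel(180, 180, -1), "non-negative")
})

test_that("incremental accumulation equals the brute-force end-of-run energy sum", {
  set.seed(21)
  rl <- runif(500, 120, 200)
  secs <- runif(500, 0, 10)
  inc <- NA_real_
  for (i in seq_along(rl)) inc <- accumulate_sel(inc, rl[i], secs[i])
  brute <- 10 * log10(sum(10^(rl / 10) * secs))
  expect_equal(inc, brute, tolerance = 1e-9)
})

test_that("a stationary agent matches the closed-form SEL", {
  # 10 km, SL 240, 15 log R, 10% duty, 1 h: 180 + 10 log10(360), plus the
  # (near-zero) M-weighting at 1 kHz
  sim <- run_simulation(stationary_config(duration_h = 1))
  w <- m_weighting(1, "pinniped-in-water")
  expect_equal(sim$final$sel_db, 180 + 10 * log10(360) + w,
               tolerance = 1e-3)
  # 10x the duration adds exactly 10 dB (energy linearity)
  sim10 <- run_simulation(stationary_config(duration_h = 10))
  expect_equal(sim10$final$sel_db - sim$final$sel_db, 10,
               tolerance = 1e-9)
})

test_that("the duty-fraction convention makes SEL independent of the time step", {
  s60 <- run_simulation(stationary_config(duration_h = 2, dt_s = 60))
  s30 <- run_simulation(stationary_config(duration_h = 2, dt_s = 30))
  expect_lt(abs(s60$final$sel_db - s30$final$sel_db), 1e-6)
})

test_that("A- and M-weighted runs of one trajectory differ by the weighting offset", {
  gs <- gray_seal()
  env <- small_env(radius_km = 40, cell_km = 10)
  base <- scenario_config(gs, env, n_agents = 50, duration_h = 2,
                          scheme = "M", seed = 31)
  simM <- run_simulation(base)
  simA <- run_simulation(scenario_config(
    gs, env, n_agents = 50, duration_h = 2, scheme = "A", seed = 31))
  offset <- simM$weighting_db - simA$weighting_db
  expect_equal(offset, 71 + m_weighting(1, "pinniped-in-water"))
  expect_equal(simM$final$sel_db - simA$final$sel_db,
               rep(offset, 50), tolerance = 1e-9)
})

test_that("cumulative SEL is nondecreasing for every agent", {
  gs <- gray_seal()
  env <- small_env(radius_km = 40, cell_km = 10)
  sim <- run_simulation(scenario_config(
    gs, env, n_agents = 60, duration_h = 24, seed = 41,
    record_hours = c(1, 3, 6, 12, 18, 24)))
  snaps <- sim$snapshots[order(sim$snapshots$agent, sim$snapshots$t_h), ]
  drops <- tapply(snaps$sel_db, snaps$agent, function(s) min(diff(s)))
  expect_true(all(drops >= 0))
})

test_that("simulations are reproducible given the seed", {
  gs <- gray_seal()
  env <- small_env(radius_km = 30, cell_km = 10)
  cfg <- scenario_config(gs, env, n_agents = 40, duration_h = 2, seed = 99)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$snapshots, s2$snapshots)
  s3 <- run_simulation(scenario_config(gs, env, n_agents = 40,
                                       duration_h = 2, seed = 100))
  expect_false(identical(s1$final$sel_db, s3$final$sel_db))
})

test_that("mean SEL curve reports dB-domain means and order-statistic bands", {
  # identical stationary agents: zero-width band equal to the mean
  sim <- run_simulation(stationary_config(n_agents = 25, duration_h = 1))
  curve <- mean_sel_curve(sim)
  expect_equal(curve$lower_db, curve$upper_db, tolerance = 1e-3)
  expect_equal(curve$mean_sel_db, curve$lower_db, tolerance = 1e-3)

  gs <- gray_seal()
  env <- small_env(radius_km = 40, cell_km = 10)
  sim2 <- run_simulation(scenario_config(gs, env, n_agents = 200,
                                         duration_h = 2, seed = 5))
  curve2 <- mean_sel_curve(sim2)
  final <- sim2$final$sel_db
  expect_equal(curve2$lower_db[nrow(curve2)],
               quantile(final, 0.025, type = 1, names = FALSE))
  expect_equal(curve2$upper_db[nrow(curve2)],
               quantile(final, 0.975, type = 1, names = FALSE))
  expect_true(all(curve2$mean_sel_db >= curve2$lower_db &
                    curve2$mean_sel_db <= curve2$upper_db))
  # the band needs at least 20 agents
  tiny <- run_simulation(scenario_config(gs, env, n_agents = 5,
                                         duration_h = 1, seed = 5))
  expect_true(all(is.na(mean_sel_curve(tiny)$lower_db)))
  expect_error(mean_sel_curve(tibble::tibble()), "no exposure histories")
})

test_that("tidy, glance, autoplot and history export work on a simulation", {
  sim <- run_simulation(stationary_config(n_agents = 30, duration_h = 1))
  td <- tidy(sim)
  expect_true(all(c("agent", "t_h", "rl_db", "sel_db") %in% names(td)))
  gl <- glance(sim)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_agents, 30)
  expect_s3_class(ggplot2::autoplot(sim, threshold_db = 203), "ggplot")
  path <- withr::local_tempfile(fileext = ".csv")
  write_histories(sim, path)
  expect_equal(nrow(readr::read_csv(path, show_col_types = FALSE)),
               nrow(sim$snapshots))
})

test_that("scenario configs validate their inputs", {
  gs <- gray_seal()
  env <- small_env(radius_km = 20, cell_km = 5)
  expect_error(scenario_config(gs, env, n_agents = 0), "at least 1")
  expect_error(scenario_config(gs, env, duration_h = -1), "positive")
  expect_error(scenario_config(gs, env, boundary_km = 500),
               "does not reach")
  expect_error(scenario_config(gs, env,
                               source = sound_source(pulsed = TRUE)),
               "out of scope")
  no_aud <- species_profile("x", "pinniped-in-water", 1, 2, 100, 300, 60,
                            audiogram = NULL)
  expect_error(scenario_config(no_aud, env, scheme = "A"),
               "requires a species audiogram")
})
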