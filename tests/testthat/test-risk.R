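test_that("exceedance fraction has its boundary and monotonicity properties", {
  gs <- gray_seal()
  env <- small_env(radius_km = 40, cell_km = 10)
  sim <- run_simulation(scenario_config(gs, env, n_agents = 100,
                                        duration_h = 12, seed = 51,
                                        record_hours = c(1, 6, 12)))
  expect_equal(fraction_exceeding(sim, -Inf), 100)
  expect_equal(fraction_exceeding(sim, Inf), 0)
  med <- stats::median(sim$final$sel_db)
  expect_equal(fraction_exceeding(sim, med), 50)  # closed threshold, even n
  # nondecreasing in time (SEL accumulates), nonincreasing in threshold
  thr <- med
  over_time <- vapply(c(1, 6, 12),
                      function(h) fraction_exceeding(sim, thr, h),
                      numeric(1))
  expect_true(all(diff(over_time) >= 0))
  over_thr <- vapply(c(180, 190, 200, 210),
                     function(t) fraction_exceeding(sim, t, 12),
                     numeric(1))
  expect_true(all(diff(over_thr) <= 0))
  expect_error(fraction_exceeding(sim, 200, 24), "beyond the simulated")
  expect_error(fraction_exceeding(sim, 200, 3), "no snapshot")
})

test_that("stationary-agent exceedance matches the analytic disc computation", {
  # stationary agents on a uniform disc: SEL_1h(r) = 220.56 - 15 log10 r (+W),
  # so P(SEL >= thr) = (r*/R)^2 with r* from inverting the closed form
  gs <- gray_seal()
  env <- small_env(radius_km = 100, cell_km = 5)
  n <- 2000
  sim <- run_simulation(scenario_config(
    gs, env, n_agents = n, duration_h = 1, speed_ms = 0,
    responsive = FALSE, seed = 61, record_hours = 1))
  w <- m_weighting(1, "pinniped-in-water")
  thr <- 200
  r_star <- 10^((240 - 15 * 3 + 10 * log10(360) + w - thr) / 15)
  p <- (r_star / 100)^2
  se <- sqrt(p * (1 - p) / n)
  observed <- fraction_exceeding(sim, thr, 1) / 100
  expect_lt(abs(observed - p), 3 * se)
})

test_that("expected TTS count scales the dose-response mean to abundance", {
  gs <- gray_seal()
  env <- small_env(radius_km = 40, cell_km = 10)
  sim <- run_simulation(scenario_config(gs, env, n_agents = 50,
                                        duration_h = 6, seed = 71))
  curve <- tts_curve()
  brute <- sum(dose_response(sim$final$sel_db, curve)) / 50 * 300
  expect_equal(expected_tts_count(sim, curve, 300), brute)
  # all SELs at the midpoint -> abundance / 2
  mid <- curve$midpoint_db
  sim_mid <- sim
  sim_mid$final$sel_db <- rep(mid, 50)
  expect_equal(expected_tts_count(sim_mid, curve, 300), 150)
  # far below the midpoint -> ~0
  sim_low <- sim
  sim_low$final$sel_db <- rep(100, 50)
  expect_lt(expected_tts_count(sim_low, curve, 300), 1e-4)
  expect_error(expected_tts_count(sim, curve, -1), "non-negative")
})

test_that("any-effect probability composes per-agent probabilities independently", {
  gs <- gray_seal()
  env <- small_env(radius_km = 40, cell_km = 10)
  sim <- run_simulation(scenario_config(gs, env, n_agents = 30,
                                        duration_h = 2, seed = 81))
  curve <- dose_response_curve(200, 4)
  p <- dose_response(sim$final$sel_db, curve)
  expect_equal(any_effect_probability(sim, curve), 1 - prod(1 - p))
})

test_that("risk maps aggregate exceedance by starting cell", {
  gs <- gray_seal()
  # one occupied cell: the map is nonzero only there
  env1 <- small_env(radius_km = 40, cell_km = 10)
  one <- env1$density
  keep <- which.max(one$density * (abs(one$x_km - 25) < 5) *
                      (abs(one$y_km) < 5))
  dens1 <- density_grid(one$x_km, one$y_km,
                        ifelse(seq_len(nrow(one)) == keep, 1, 0),
                        cell_km = 10)
  sim1 <- run_simulation(scenario_config(
    gs, list(density = dens1, bathymetry = env1$bathymetry),
    n_agents = 40, duration_h = 1, seed = 91))
  map1 <- risk_map(sim1, dens1, -Inf)
  expect_equal(map1$risk[map1$cell == keep], 1)
  expect_true(all(is.na(map1$risk[map1$cell != keep])))

  # abundance-weighted map mean equals the overall fraction
  env <- small_env(radius_km = 30, cell_km = 10)
  sim <- run_simulation(scenario_config(gs, env, n_agents = 300,
                                        duration_h = 2, seed = 92))
  thr <- stats::median(sim$final$sel_db)
  map <- risk_map(sim, env$density, thr)
  overall <- fraction_exceeding(sim, thr) / 100
  weighted <- sum(map$risk * map$n_agents, na.rm = TRUE) /
    sum(map$n_agents)
  expect_equal(weighted, overall)
  expect_true(all(map$risk >= 0 & map$risk <= 1, na.rm = TRUE))
  expect_s3_class(ggplot2::autoplot(map), "ggplot")
})

test_that("uncertainty propagation yields order-statistic CIs that widen with CV", {
  gs <- gray_seal()
  mk_env <- function(cv) {
    e <- disc_scenario(radius_km = 30, cell_km = 10, cv = cv)
    e
  }
  base <- function(cv, seed) {
    scenario_config(gs, mk_env(cv), n_agents = 120, duration_h = 2,
                    seed = seed)
  }
  rs <- risk_with_uncertainty(base(0.5, 7), n_realizations = 8,
                              threshold_db = 195)
  expect_s3_class(rs, "risk_summary")
  draws <- rs$realizations$pct_exceeding
  expect_equal(rs$pct_exceeding_ci,
               quantile(draws, c(0.025, 0.975), type = 1, names = FALSE))
  expect_true(rs$pct_exceeding_ci[1] <= rs$pct_exceeding_ci[2])
  td <- tidy(rs)
  expect_true(all(td$conf_low <= td$conf_high))
  expect_equal(nrow(glance(rs)), 1)

  # expected-count CI widens with density CV (same seeds, paired)
  rs0 <- risk_with_uncertainty(base(0, 7), n_realizations = 8,
                               threshold_db = 195)
  width <- function(x) diff(x$expected_count_ci)
  expect_gt(width(rs), width(rs0))
  expect_error(risk_with_uncertainty(base(0, 7), n_realizations = 1),
               "at least 2")
})
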