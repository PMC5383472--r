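test_that("M-weighting is a normalized band-pass: <= 0, 0 at the band center, steep roll-off", {
  groups <- functional_groups()
  for (g in groups$group) {
    row <- groups[groups$group == g, ]
    f_star <- sqrt(row$f_low_khz * row$f_high_khz)
    expect_equal(m_weighting(f_star, g), 0, tolerance = 1e-9)
    f_grid <- 10^seq(log10(row$f_low_khz / 100),
                     log10(row$f_high_khz * 100), length.out = 500)
    w <- m_weighting(f_grid, g)
    expect_true(all(w <= 1e-9))
    # band-pass limit: far below the band the weighting is strongly negative
    expect_lt(m_weighting(row$f_low_khz / 100, g), -40)
  }
})

test_that("M-weighting is effectively zero at 1 kHz for both example groups", {
  expect_equal(m_weighting(1, "pinniped-in-water"), 0, tolerance = 1)
  expect_equal(m_weighting(1, "high-frequency cetacean"), 0, tolerance = 1)
  expect_error(m_weighting(1, "bats"), "unknown functional hearing group")
  expect_error(m_weighting(-1, "pinniped-in-water"), "positive")
})

test_that("A-weighting is minus the audiogram, interpolated on log-frequency", {
  gs <- gray_seal()
  expect_equal(a_weighting(1, gs$audiogram), -71)
  expect_equal(a_weighting(1, harbor_porpoise()$audiogram), -80)
  # exact at every audiogram node, including a zero-threshold node
  aud <- audiogram(c(0.5, 1, 2), c(10, 0, 5))
  expect_equal(a_weighting(aud$frequency_khz, aud), -aud$threshold_db)
  # log-frequency linearity between nodes
  mid <- sqrt(0.5 * 1)
  expect_equal(hearing_threshold(aud, mid), 5)
  expect_error(a_weighting(0.1, aud), "outside the audiogram domain")
})

test_that("PTS thresholds follow the group criterion (M) and the 95-dB hearing rule (A)", {
  gs <- gray_seal()
  hp <- harbor_porpoise()
  expect_equal(pts_threshold(gs, "M"), 203)
  expect_equal(pts_threshold(hp, "M"), 215)
  expect_equal(pts_threshold(gs, "A", frequency_khz = 1), 166)
  expect_equal(pts_threshold(hp, "A", frequency_khz = 1), 175)
  # A-scheme identity: threshold - 95 is the interpolated audiogram
  f <- c(0.5, 0.7, 1, 3)
  expect_equal(pts_threshold(gs, "A", f) - 95,
               hearing_threshold(gs$audiogram, f))
  no_aud <- species_profile("test", "pinniped-in-water", 1, 2, 100, 300,
                            60, audiogram = NULL)
  expect_error(pts_threshold(no_aud, "A", 1), "no audiogram")
  expect_equal(tts_threshold(gs), 183)
  expect_equal(tts_threshold(hp), 195)
})

test_that("dose-response is a bounded monotone logistic hitting the TTS anchor", {
  curve <- tts_curve()
  p195 <- dose_response(195, curve)
  expect_gte(p195, 0.18)
  expect_lte(p195, 0.19)
  expect_equal(dose_response(curve$midpoint_db, curve), 0.5)
  expect_lt(dose_response(100, curve), 1e-6)
  grid <- seq(100, 300, length.out = 1000)
  p <- dose_response(grid, curve)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(dose_response(NA, curve), 0)  # unexposed agents
})

test_that("species table loading validates profiles and rejects malformed input", {
  profiles <- example_species()
  expect_length(profiles, 2)
  expect_named(profiles, c("gray seal", "harbor porpoise"))
  expect_s3_class(profiles[["gray seal"]], "species_profile")
  expect_identical(profiles[["gray seal"]]$functional_group,
                   "pinniped-in-water")
  expect_identical(profiles[["harbor porpoise"]]$functional_group,
                   "high-frequency cetacean")

  dir <- withr::local_tempdir()
  aud <- data.frame(frequency_khz = c(1, 0.5), threshold_db = c(71, 77))
  readr::write_csv(aud, file.path(dir, "aud.csv"))
  row <- data.frame(
    species = "x", functional_group = "pinniped-in-water",
    typical_speed_ms = 1, max_speed_ms = 2, max_dive_depth_m = 100,
    dive_duration_s = 300, surface_time_s = 60, responds_to_noise = TRUE,
    aversion_sd_default = 1, heading_sd = 1, audiogram_file = "aud.csv")
  readr::write_csv(row, file.path(dir, "sp.csv"))
  expect_error(read_species_table(file.path(dir, "sp.csv")),
               "strictly increasing")  # unsorted audiogram

  readr::write_csv(audiogram(c(0.5, 1), c(77, 71)),
                   file.path(dir, "aud.csv"))
  row$typical_speed_ms <- -1
  readr::write_csv(row, file.path(dir, "sp.csv"))
  expect_error(read_species_table(file.path(dir, "sp.csv")), "positive")

  row$typical_speed_ms <- 1
  row$functional_group <- "kraken"
  readr::write_csv(row, file.path(dir, "sp.csv"))
  expect_error(read_species_table(file.path(dir, "sp.csv")),
               "unknown functional hearing group")

  row$functional_group <- NULL
  readr::write_csv(row, file.path(dir, "sp.csv"))
  expect_error(read_species_table(file.path(dir, "sp.csv")),
               "missing columns")
})

test_that("audiogram constructor enforces its invariants", {
  expect_error(audiogram(1, 70), "at least two")
  expect_error(audiogram(c(1, 1), c(70, 70)), "strictly increasing")
  expect_error(audiogram(c(1, 2), c(70, Inf)), "finite")
  expect_error(audiogram(c(-1, 2), c(70, 60)), "positive")
})
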