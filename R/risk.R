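# Convert exposure histories into risk outputs: exceedance fractions,
# expected threshold-shift counts, Monte-Carlo confidence intervals, and
# gridded risk maps.

#' Percentage of agents exceeding a threshold
#'
#' `100 * #(agents with SEL(at_hours) >= threshold) / n`.  Exceedance is
#' closed (`>=`): ties at the threshold count as an effect, which is the
#' conservative convention.  Unexposed agents (`NA` SEL) count as below
#' threshold.
#'
#' @param sim A `sel_simulation`.
#' @param threshold_db Weighted cumulative SEL threshold in dB re 1
#'   uPa2/s.
#' @param at_hours Recorded time (h) at which to evaluate; defaults to the
#'   final time.  Times beyond the simulated duration are an error.
#' @return Percentage in `[0, 100]`.
#' @export
fraction_exceeding <- function(sim, threshold_db, at_hours = NULL) {
  stopifnot(inherits(sim, "sel_simulation"))
  if (is.null(at_hours)) at_hours <- sim$config$duration_h
  if (at_hours > sim$config$duration_h) {
    abort("`at_hours` is beyond the simulated duration")
  }
  recorded <- unique(sim$snapshots$t_h)
  hit <- recorded[abs(recorded - at_hours) < 1e-8]
  if (length(hit) != 1L) {
    abort(paste0("no snapshot recorded at ", at_hours,
                 " h; recorded times: ",
                 paste(signif(recorded, 4), collapse = ", ")))
  }
  sel <- sim$snapshots$sel_db[sim$snapshots$t_h == hit]
  100 * mean(!is.na(sel) & sel >= threshold_db)
}

#' Expected number of animals experiencing an effect
#'
#' Scales the dose-response probability averaged over agents up to the
#' population abundance: `abundance * mean_i P(SEL_i)` with final
#' per-agent SELs.
#'
#' @param sim A `sel_simulation`.
#' @param curve A [dose_response_curve()]; default the packaged
#'   [tts_curve()].
#' @param abundance Number of animals the simulated agents represent
#'   (`>= 0`), e.g. [abundance()] of the density grid.
#' @return Expected number of affected animals.
#' @export
expected_tts_count <- function(sim, curve = tts_curve(), abundance) {
  stopifnot(inherits(sim, "sel_simulation"))
  if (abundance < 0) abort("`abundance` must be non-negative")
  abundance * mean(dose_response(sim$final$sel_db, curve))
}

#' Probability that any agent experiences the effect
#'
#' `1 - prod(1 - p_i)` with per-agent probabilities from a dose-response
#' curve, treating agents as independent.
#'
#' @inheritParams expected_tts_count
#' @return Probability in `[0, 1]`.
#' @export
any_effect_probability <- function(sim, curve) {
  stopifnot(inherits(sim, "sel_simulation"))
  p <- dose_response(sim$final$sel_db, curve)
  1 - exp(sum(log1p(-pmin(p, 1 - 1e-16))))
}

#' Risk summary with density-uncertainty confidence intervals
#'
#' Repeats the simulation `n_realizations` times, each time resampling
#' the density surface from its cell CVs ([resample_density()]) and
#' reseeding agents with a fresh seed, and reports the 2.5/97.5
#' percentiles of each output across realizations as its confidence
#' interval.  The point estimates come from a baseline run on the input
#' grid.  Only density and seeding stochasticity are resampled; movement
#' and hearing parameters are held fixed (an extension hook, not a
#' limitation of the interval machinery).
#'
#' @param config A [scenario_config()].
#' @param n_realizations Number of Monte-Carlo realizations (`>= 2`).
#' @param threshold_db PTS threshold; default from the config's scheme via
#'   [pts_threshold()].
#' @param curve Dose-response curve for the expected-count output.
#' @return A list of class `risk_summary` with the point estimates, their
#'   CIs, and the per-realization outputs.
#' @export
risk_with_uncertainty <- function(config, n_realizations = 25,
                                  threshold_db = NULL,
                                  curve = tts_curve()) {
  stopifnot(inherits(config, "scenario_config"))
  if (n_realizations < 2) abort("`n_realizations` must be at least 2")
  if (is.null(threshold_db)) {
    threshold_db <- pts_threshold(config$species, config$scheme,
                                  config$source$frequency_khz)
  }
  base <- run_simulation(config)
  one <- function(i) {
    set.seed((config$seed + 7919L * i) %% 2147483647L)
    grid_i <- resample_density(config$environment$density)
    cfg_i <- modify_config(
      config,
      environment = list(density = grid_i,
                         bathymetry = config$environment$bathymetry),
      seed = (config$seed + 104729L * i) %% 2147483647L)
    sim_i <- run_simulation(cfg_i)
    tibble(
      realization = i,
      pct_exceeding = fraction_exceeding(sim_i, threshold_db),
      expected_count = expected_tts_count(sim_i, curve,
                                          abundance(grid_i)),
      any_pts_probability = any_effect_probability(
        sim_i, dose_response_curve(threshold_db, curve$scale_db)))
  }
  draws <- purrr::map_dfr(seq_len(n_realizations), one)
  ci <- function(v) quantile(v, c(0.025, 0.975), type = 1, names = FALSE)
  structure(list(
    species = config$species$species,
    scheme = config$scheme,
    threshold_db = threshold_db,
    n_realizations = n_realizations,
    pct_exceeding = fraction_exceeding(base, threshold_db),
    pct_exceeding_ci = ci(draws$pct_exceeding),
    expected_count = expected_tts_count(
      base, curve, abundance(config$environment$density)),
    expected_count_ci = ci(draws$expected_count),
    any_pts_probability = any_effect_probability(
      base, dose_response_curve(threshold_db, curve$scale_db)),
    any_pts_probability_ci = ci(draws$any_pts_probability),
    realizations = draws
  ), class = "risk_summary")
}

#' @export
print.risk_summary <- function(x, ...) {
  cat(sprintf("<risk_summary> %s, %s-weighting, threshold %.1f dB\n",
              x$species, x$scheme, x$threshold_db))
  cat(sprintf("  %% exceeding PTS: %.2f%% (95%% CI %.2f-%.2f)\n",
              x$pct_exceeding, x$pct_exceeding_ci[1],
              x$pct_exceeding_ci[2]))
  cat(sprintf("  expected TTS count: %.1f (95%% CI %.1f-%.1f)\n",
              x$expected_count, x$expected_count_ci[1],
              x$expected_count_ci[2]))
  cat(sprintf("  P(any agent PTS): %.3f (95%% CI %.3f-%.3f)\n",
              x$any_pts_probability, x$any_pts_probability_ci[1],
              x$any_pts_probability_ci[2]))
  invisible(x)
}

#' @export
tidy.risk_summary <- function(x, ...) {
  tibble(
    statistic = c("pct_exceeding", "expected_count",
                  "any_pts_probability"),
    estimate = c(x$pct_exceeding, x$expected_count,
                 x$any_pts_probability),
    conf_low = c(x$pct_exceeding_ci[1], x$expected_count_ci[1],
                 x$any_pts_probability_ci[1]),
    conf_high = c(x$pct_exceeding_ci[2], x$expected_count_ci[2],
                  x$any_pts_probability_ci[2])
  )
}

#' @export
glance.risk_summary <- function(x, ...) {
  tibble(species = x$species, scheme = x$scheme,
         threshold_db = x$threshold_db,
         n_realizations = x$n_realizations,
         pct_exceeding = x$pct_exceeding,
         expected_count = x$expected_count,
         any_pts_probability = x$any_pts_probability)
}

#' Gridded exceedance risk map
#'
#' Per starting cell of the density grid: the fraction of that cell's
#' agents whose final SEL meets the threshold.  Cells that seeded no
#' agents are `NA` (missing, not zero).  Areas of high and low risk are
#' read at the resolution of the input density data.
#'
#' @param sim A `sel_simulation`.
#' @param grid The [density_grid()] the simulation was seeded from.
#' @param threshold_db Weighted cumulative SEL threshold (dB re 1 uPa2/s).
#' @return A tibble of class `risk_map`: the grid cells with an added
#'   `risk` column (fraction in `[0, 1]` or `NA`) and `n_agents`.
#' @export
risk_map <- function(sim, grid, threshold_db) {
  stopifnot(inherits(sim, "sel_simulation"),
            inherits(grid, "density_grid"))
  if (max(sim$final$cell) > nrow(grid)) {
    abort("agent starting cells do not match the supplied grid")
  }
  per_cell <- sim$final |>
    dplyr::group_by(cell = .data$cell) |>
    dplyr::summarise(
      risk = mean(!is.na(.data$sel_db) & .data$sel_db >= threshold_db),
      n_agents = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(as_tibble(grid), per_cell, by = "cell")
  out$n_agents[is.na(out$n_agents)] <- 0L
  attr(out, "cell_km") <- attr(grid, "cell_km")
  attr(out, "threshold_db") <- threshold_db
  class(out) <- c("risk_map", class(out))
  out
}

#' Plot a risk map
#'
#' @param object A [risk_map()].
#' @param ... Unused.
#' @return A ggplot tile map of per-cell exceedance risk.
#' @export
autoplot.risk_map <- function(object, ...) {
  ggplot(object, aes(x = .data$x_km, y = .data$y_km,
                     fill = .data$risk)) +
    geom_tile() +
    coord_equal() +
    scale_fill_viridis_c(na.value = "grey90", limits = c(0, 1)) +
    labs(x = "x (km)", y = "y (km)", fill = "P(exceed)",
         title = sprintf("Exceedance risk at %.0f dB re 1 µPa²/s",
                         attr(object, "threshold_db")))
}
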