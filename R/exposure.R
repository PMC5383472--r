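# The simulation engine: advance all agents through time, query received
# levels, apply the auditory weighting, and accumulate per-agent SEL.

#' Assemble a scenario configuration
#'
#' Bundles everything one simulation run needs: the source and propagation
#' model, the species profile, the weighting scheme, the environment
#' (density + bathymetry), agent count, duration, time step, responsive
#' movement settings, optional hard boundary, and the RNG seed.
#'
#' @param species A [species_profile()].
#' @param environment A list with elements `density` ([density_grid()])
#'   and `bathymetry` ([bathymetry_grid()]), e.g. from [disc_scenario()].
#' @param source A [sound_source()].
#' @param propagation A [propagation_model()].
#' @param scheme Weighting scheme, `"M"` (functional group) or `"A"`
#'   (audiogram).
#' @param n_agents Number of agents (`>= 1`).
#' @param duration_h Scenario duration in hours (> 0).
#' @param dt_s Time step in seconds (> 0; default 60, which resolves the
#'   dive cycle while keeping multi-day runs fast).
#' @param aversion_sd Wrapped-normal heading SD (radians) for responsive
#'   movement.  `NULL` uses the species default when the species responds
#'   to noise, and natural (non-responsive) movement otherwise.
#' @param responsive Logical; force responsive movement on/off.  Default
#'   follows the species' `responds_to_noise` flag.
#' @param boundary_km Optional hard reflecting boundary radius (km), e.g.
#'   a site-fidelity surrogate.  Must be positive and the environment grid
#'   must reach it.
#' @param speed_ms Optional swim-speed override in m/s (`>= 0`; 0 gives
#'   stationary agents, useful for closed-form checks).  Default: the
#'   species' typical swim speed.
#' @param record_hours Times (h) at which per-agent snapshots are stored.
#'   Default: the standard duration grid `{1, 6, 12, 24, 48, 96, 168,
#'   240}` clipped to the duration, plus the final time.  The running SEL
#'   accumulator is exact regardless of the snapshot grid.
#' @param field Optional [precompute_field()] library; by default received
#'   levels are evaluated with the closed-form [received_level()].
#' @param seed Integer RNG seed; identical seed + config gives identical
#'   output, and sharing a seed across the arms of a comparison pairs
#'   their agents to reduce Monte-Carlo variance in dB differences.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(species, environment, source = sound_source(),
                            propagation = propagation_model(),
                            scheme = c("M", "A"), n_agents = 10000,
                            duration_h = 240, dt_s = 60,
                            aversion_sd = NULL, responsive = NULL,
                            boundary_km = NULL, speed_ms = NULL,
                            record_hours = NULL, field = NULL, seed = 1) {
  stopifnot(inherits(species, "species_profile"),
            inherits(source, "sound_source"),
            inherits(propagation, "propagation_model"),
            inherits(environment$density, "density_grid"),
            inherits(environment$bathymetry, "bathymetry_grid"))
  scheme <- match.arg(scheme)
  if (source$pulsed) {
    abort("pulsed-sound criteria are out of scope; use a nonpulsed source")
  }
  if (n_agents < 1) abort("`n_agents` must be at least 1")
  if (duration_h <= 0) abort("`duration_h` must be positive")
  if (dt_s <= 0) abort("`dt_s` must be positive")
  if (scheme == "A" && is.null(species$audiogram)) {
    abort("A-weighting requires a species audiogram")
  }
  if (is.null(responsive)) responsive <- species$responds_to_noise
  if (is.null(aversion_sd) && responsive) {
    aversion_sd <- species$aversion_sd_default
  }
  if (responsive && (!is.finite(aversion_sd) || aversion_sd < 0)) {
    abort("`aversion_sd` must be non-negative")
  }
  if (!is.null(boundary_km)) {
    if (boundary_km <= 0) abort("`boundary_km` must be positive")
    extent <- max(abs(c(environment$density$x_km, environment$density$y_km)))
    if (boundary_km > extent + attr(environment$density, "cell_km")) {
      abort("environment grid does not reach the hard boundary radius")
    }
  }
  if (is.null(speed_ms)) speed_ms <- species$typical_speed_ms
  if (!is.finite(speed_ms) || speed_ms < 0) {
    abort("`speed_ms` must be non-negative")
  }
  if (is.null(record_hours)) {
    record_hours <- unique(c(
      c(1, 6, 12, 24, 48, 96, 168, 240)[
        c(1, 6, 12, 24, 48, 96, 168, 240) <= duration_h], duration_h))
  }
  record_hours <- sort(unique(record_hours))
  if (any(record_hours <= 0) || any(record_hours > duration_h)) {
    abort("`record_hours` must lie in (0, duration_h]")
  }
  structure(list(
    species = species, environment = environment, source = source,
    propagation = propagation, scheme = scheme, n_agents = n_agents,
    duration_h = duration_h, dt_s = dt_s, aversion_sd = aversion_sd,
    responsive = responsive, boundary_km = boundary_km,
    speed_ms = speed_ms, record_hours = record_hours, field = field,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  species: %s; weighting: %s\n", x$species$species, x$scheme))
  cat(sprintf("  source: %.0f dB @ %.3g kHz, duty %.0f%%; spreading %g log R\n",
              x$source$level_db, x$source$frequency_khz,
              100 * x$source$duty_cycle, x$propagation$spreading_db))
  cat(sprintf("  %d agents, %g h at dt = %g s; movement: %s (sd %s), speed %.2f m/s\n",
              x$n_agents, x$duration_h, x$dt_s,
              if (x$responsive) "responsive" else "natural",
              if (x$responsive) format(x$aversion_sd) else
                format(x$species$heading_sd), x$speed_ms))
  cat(sprintf("  boundary: %s; seed %d\n",
              if (is.null(x$boundary_km)) "none" else
                paste0(x$boundary_km, " km"), x$seed))
  invisible(x)
}

# internal: tweak fields of a config, re-validating
modify_config <- function(config, ...) {
  dots <- list(...)
  args <- config
  class(args) <- NULL
  args[names(dots)] <- dots
  # aversion/responsive must be re-derived only when explicitly changed
  if (!"aversion_sd" %in% names(dots)) args$aversion_sd <- config$aversion_sd
  do.call(scenario_config, args)
}

#' Accumulate sound exposure on the energy scale
#'
#' SEL accumulation is an energy sum: `seconds` of exposure at a (1-second
#' equivalent) weighted received level `level_db` adds
#' `10^(level_db / 10) * seconds` to the linear exposure, and
#' `new = 10 log10(10^(prev / 10) + 10^(level_db / 10) * seconds)`.
#' `NA` is the "no exposure yet" sentinel (avoids -Inf dB arithmetic):
#' accumulating onto `NA` returns the new contribution alone, and zero
#' seconds onto `NA` stays `NA`.
#'
#' @param prev_db Previous cumulative SEL in dB re 1 uPa2/s, or `NA` for
#'   no exposure yet.
#' @param level_db Weighted received level in dB.
#' @param seconds Active exposure seconds (`>= 0`).
#' @return Updated cumulative SEL in dB re 1 uPa2/s.
#' @export
#' @examples
#' accumulate_sel(NA, 180, 1)     # 180 dB
#' accumulate_sel(180, 180, 1)    # +10 log10(2) = 183.0103 dB
accumulate_sel <- function(prev_db, level_db, seconds) {
  if (any(seconds < 0)) abort("exposure seconds must be non-negative")
  prev_e <- ifelse(is.na(prev_db), 0, 10^(prev_db / 10))
  e <- prev_e + 10^(level_db / 10) * seconds
  ifelse(e > 0, 10 * log10(e), NA_real_)
}

#' Run an exposure simulation
#'
#' Seeds `n_agents` from the density surface, then for every time step:
#' moves all agents (directed random walk with wrapped-normal headings,
#' reflecting boundary and land constraints), queries the received level
#' at each agent's position, applies the frequency weighting for the
#' scenario's single-tone source, and adds `duty_cycle * dt` seconds of
#' exposure energy to each agent's running SEL accumulator.  Per-agent
#' snapshots (position, depth, received level, cumulative SEL) are stored
#' on the `record_hours` grid; the accumulator itself is exact.
#'
#' Reproducible given the config seed.
#'
#' @param config A [scenario_config()].
#' @return An object of class `sel_simulation`: a list with `config`, the
#'   scalar `weighting_db` applied at the source frequency, `snapshots`
#'   (tibble: `agent`, `t_h`, `x_km`, `y_km`, `depth_m`, `rl_db`,
#'   `sel_db`) and `final` (tibble: `agent`, `cell`, `x0_km`, `y0_km`,
#'   `sel_db`).
#' @seealso [mean_sel_curve()], [fraction_exceeding()], [tidy.sel_simulation()]
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  sp <- config$species
  src <- config$source
  prop <- config$propagation
  n <- config$n_agents
  dt <- config$dt_s
  bathy <- index_bathymetry(config$environment$bathymetry)

  w_db <- switch(config$scheme,
    M = m_weighting(src$frequency_khz, sp$functional_group),
    A = a_weighting(src$frequency_khz, sp$audiogram))

  pos <- sample_positions(config$environment$density, n,
                          bathymetry = bathy,
                          boundary_km = config$boundary_km)
  x <- pos$x_km
  y <- pos$y_km
  heading <- runif(n, -pi, pi)
  cycle_s <- sp$dive_duration_s + sp$surface_time_s
  phase <- runif(n, 0, cycle_s)

  heading_sd <- if (config$responsive) config$aversion_sd else sp$heading_sd
  land_possible <- any(config$environment$bathymetry$depth_m <= 0)
  bathy_arg <- if (land_possible) bathy else NULL

  n_steps <- as.integer(round(config$duration_h * 3600 / dt))
  rec_steps <- as.integer(round(config$record_hours * 3600 / dt))
  rec_steps <- pmin(pmax(rec_steps, 1L), n_steps)
  active_s <- src$duty_cycle * dt

  energy <- numeric(n)  # linear exposure; 0 = "no exposure yet" sentinel
  snaps <- vector("list", length(rec_steps))
  rec_i <- 1L

  for (s in seq_len(n_steps)) {
    st <- step_agents(x, y, heading, config$speed_ms, dt, heading_sd,
                      responsive = config$responsive,
                      source_x_km = src$x_km, source_y_km = src$y_km,
                      boundary_km = config$boundary_km,
                      bathymetry = bathy_arg)
    x <- st$x_km
    y <- st$y_km
    heading <- st$heading
    rl <- if (is.null(config$field)) {
      received_level(src, prop, x, y)
    } else {
      field_level(config$field, x, y)
    }
    energy <- energy + 10^((rl + w_db) / 10) * active_s
    if (rec_i <= length(rec_steps) && s == rec_steps[rec_i]) {
      t_s <- s * dt
      snaps[[rec_i]] <- tibble(
        agent = seq_len(n), t_h = t_s / 3600, x_km = x, y_km = y,
        depth_m = dive_depth(t_s, phase, sp, depth_at(bathy, x, y)),
        rl_db = rl,
        sel_db = ifelse(energy > 0, 10 * log10(energy), NA_real_))
      rec_i <- rec_i + 1L
    }
  }

  final_sel <- ifelse(energy > 0, 10 * log10(energy), NA_real_)
  structure(list(
    config = config,
    weighting_db = w_db,
    snapshots = dplyr::bind_rows(snaps),
    final = tibble(agent = seq_len(n), cell = pos$cell,
                   x0_km = pos$x_km, y0_km = pos$y_km,
                   sel_db = final_sel)
  ), class = "sel_simulation")
}

#' @export
print.sel_simulation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sel_simulation> %s, %s-weighted, %d agents over %g h\n",
              cfg$species$species, cfg$scheme, cfg$n_agents,
              cfg$duration_h))
  m <- mean(x$final$sel_db, na.rm = TRUE)
  cat(sprintf("  final SEL: mean %.1f dB re 1 uPa2/s (weighting %.2f dB)\n",
              m, x$weighting_db))
  invisible(x)
}

#' Mean SEL curve with a central 95% band
#'
#' Per recorded time point: the mean of the per-agent cumulative SELs
#' (averaged on the dB scale, the convention used for population exposure
#' curves) and the empirical 2.5/97.5 percentiles (order statistics, so
#' the band is the central 95% of simulated animals, a prediction band,
#' not a standard error).  The band requires at least 20 agents and is
#' `NA` otherwise.
#'
#' @param sim A `sel_simulation` (or its `snapshots` tibble).
#' @param times Optional subset of recorded times (h).
#' @return A tibble with `t_h`, `mean_sel_db`, `lower_db`, `upper_db`,
#'   `n_agents`.
#' @export
mean_sel_curve <- function(sim, times = NULL) {
  snaps <- if (inherits(sim, "sel_simulation")) sim$snapshots else sim
  if (!is.data.frame(snaps) || nrow(snaps) == 0) {
    abort("no exposure histories to summarize")
  }
  if (!is.null(times)) {
    snaps <- dplyr::filter(snaps, .data$t_h %in% times)
    if (nrow(snaps) == 0) abort("requested times are not in the snapshots")
  }
  snaps |>
    dplyr::group_by(.data$t_h) |>
    dplyr::summarise(
      mean_sel_db = mean(.data$sel_db),
      lower_db = if (dplyr::n() >= 20)
        quantile(.data$sel_db, 0.025, type = 1, names = FALSE)
      else NA_real_,
      upper_db = if (dplyr::n() >= 20)
        quantile(.data$sel_db, 0.975, type = 1, names = FALSE)
      else NA_real_,
      n_agents = dplyr::n(),
      .groups = "drop")
}

#' Tidy an exposure simulation
#'
#' @param x A `sel_simulation`.
#' @param ... Unused.
#' @return The per-agent snapshot tibble (`agent`, `t_h`, `x_km`, `y_km`,
#'   `depth_m`, `rl_db`, `sel_db`).
#' @export
tidy.sel_simulation <- function(x, ...) {
  x$snapshots
}

#' One-row summary of an exposure simulation
#'
#' @param x A `sel_simulation`.
#' @param ... Unused.
#' @return A tibble with the scenario's headline numbers: agent count,
#'   duration, weighting, mean final SEL and the central 95% band.
#' @export
glance.sel_simulation <- function(x, ...) {
  curve <- mean_sel_curve(x)
  last <- curve[which.max(curve$t_h), ]
  tibble(
    species = x$config$species$species,
    scheme = x$config$scheme,
    n_agents = x$config$n_agents,
    duration_h = x$config$duration_h,
    weighting_db = x$weighting_db,
    mean_sel_db = last$mean_sel_db,
    lower_db = last$lower_db,
    upper_db = last$upper_db
  )
}

#' Plot the mean SEL curve of a simulation
#'
#' Mean cumulative SEL against time with the central-95% prediction band,
#' on a log-scaled time axis.
#'
#' @param object A `sel_simulation`.
#' @param threshold_db Optional horizontal reference (e.g. a PTS
#'   threshold).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sel_simulation <- function(object, threshold_db = NULL, ...) {
  curve <- mean_sel_curve(object)
  p <- ggplot(curve, aes(x = .data$t_h, y = .data$mean_sel_db)) +
    geom_ribbon(aes(ymin = .data$lower_db, ymax = .data$upper_db),
                fill = "grey70", alpha = 0.6) +
    geom_line() +
    scale_x_log10() +
    labs(x = "Exposure duration (h)",
         y = "Cumulative SEL (dB re 1 µPa²/s)",
         title = sprintf("%s, %s-weighting",
                         object$config$species$species,
                         object$config$scheme))
  if (!is.null(threshold_db)) {
    p <- p + geom_hline(yintercept = threshold_db, linetype = "dashed")
  }
  p
}

#' Export exposure histories as delimited text
#'
#' @param sim A `sel_simulation`.
#' @param path CSV output path (`agent`, `t_h`, `rl_db`, `sel_db`).
#' @return `path`, invisibly.
#' @export
write_histories <- function(sim, path) {
  stopifnot(inherits(sim, "sel_simulation"))
  readr::write_csv(
    sim$snapshots[, c("agent", "t_h", "rl_db", "sel_db")], path)
  invisible(path)
}
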