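# The three standard experiment sets (weighting comparison, aversion
# sweep, constrained movement), plus deterministic fixture generation.
#
# All comparisons share seeds across their arms (paired-seed design) so
# that dB differences between arms carry far less Monte-Carlo noise than
# the arm means themselves.

default_duration_grid <- function(duration_h) {
  grid <- c(1, 6, 12, 24, 48, 96, 168, 240)
  unique(c(grid[grid <= duration_h], duration_h))
}

#' Weighting-scheme comparison
#'
#' For each species and each weighting scheme (A and M), runs the scenario
#' and tabulates the percentage of agents whose weighted cumulative SEL
#' meets the scheme's PTS threshold at each duration, together with the
#' mean-SEL curves.  Arms share the config seed, so the A- and M-weighted
#' runs of a species follow identical trajectories and differ only in the
#' weighting applied.
#'
#' @param config A [scenario_config()] template (its species/scheme are
#'   overridden per arm).
#' @param species A list of [species_profile()] objects (default: the
#'   packaged gray seal and harbor porpoise).
#' @param durations_h Durations (h) at which exceedance is tabulated;
#'   default the standard grid up to the config duration.
#' @return A list of class `weighting_comparison` with `table` (species x
#'   scheme x duration exceedance percentages) and `curves` (mean SEL with
#'   95% band per arm).
#' @export
run_weighting_comparison <- function(config, species = example_species(),
                                     durations_h = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (inherits(species, "species_profile")) species <- list(species)
  if (is.null(durations_h)) {
    durations_h <- default_duration_grid(config$duration_h)
  }
  arms <- tidyr::expand_grid(
    species_name = purrr::map_chr(species, "species"),
    scheme = c("A", "M"))
  run_arm <- function(species_name, scheme) {
    sp <- species[[match(species_name,
                         purrr::map_chr(species, "species"))]]
    cfg <- modify_config(config, species = sp, scheme = scheme,
                         record_hours = durations_h)
    sim <- run_simulation(cfg)
    thr <- pts_threshold(sp, scheme, config$source$frequency_khz)
    table <- tibble(
      species = species_name, scheme = scheme, pts_threshold_db = thr,
      duration_h = durations_h,
      pct_exceeding = purrr::map_dbl(
        durations_h, ~ fraction_exceeding(sim, thr, .x)))
    curves <- mean_sel_curve(sim) |>
      dplyr::mutate(species = species_name, scheme = scheme,
                    .before = 1)
    list(table = table, curves = curves)
  }
  res <- purrr::pmap(arms, run_arm)
  structure(list(
    table = purrr::map_dfr(res, "table"),
    curves = purrr::map_dfr(res, "curves"),
    frequency_khz = config$source$frequency_khz
  ), class = "weighting_comparison")
}

#' @export
print.weighting_comparison <- function(x, ...) {
  cat("<weighting_comparison> % of agents exceeding PTS by duration\n")
  wide <- tidyr::pivot_wider(x$table,
                             names_from = "duration_h",
                             values_from = "pct_exceeding")
  print(wide, n = nrow(wide))
  invisible(x)
}

#' @export
tidy.weighting_comparison <- function(x, ...) x$table

#' @export
autoplot.weighting_comparison <- function(object, ...) {
  ggplot(object$curves,
         aes(x = .data$t_h, y = .data$mean_sel_db,
             colour = .data$scheme, fill = .data$scheme)) +
    geom_ribbon(aes(ymin = .data$lower_db, ymax = .data$upper_db),
                alpha = 0.25, colour = NA) +
    geom_line() +
    facet_wrap(~ species) +
    scale_x_log10() +
    labs(x = "Exposure duration (h)",
         y = "Mean cumulative SEL (dB re 1 µPa²/s)",
         colour = "Weighting", fill = "Weighting")
}

#' Aversion-strength sweep
#'
#' Runs the scenario once per responsive-movement heading SD (all arms
#' paired on the config seed) and reports the mean-SEL curves plus the
#' difference between the most directionless arm (largest SD) and the most
#' directed arm (smallest SD) at selected times.
#'
#' @param config A [scenario_config()] template.
#' @param sds Wrapped-normal heading SDs (radians) to sweep; the standard
#'   set spans directionless movement (10) to directed fleeing (0.05).
#' @param at_hours Times (h) for the difference table.
#' @return A list of class `aversion_sweep` with `curves` and
#'   `differences` (`t_h`, `diff_db` = mean SEL(max SD) - mean SEL(min
#'   SD)).
#' @export
run_aversion_sweep <- function(config, sds = c(10, 1, 0.5, 0.1, 0.05),
                               at_hours = c(24, 240)) {
  stopifnot(inherits(config, "scenario_config"))
  if (length(sds) == 0 || any(sds <= 0)) {
    abort("`sds` must be a non-empty vector of positive heading SDs")
  }
  at_hours <- at_hours[at_hours <= config$duration_h]
  curves <- purrr::map_dfr(sds, function(sd) {
    cfg <- modify_config(config, aversion_sd = sd, responsive = TRUE)
    mean_sel_curve(run_simulation(cfg)) |>
      dplyr::mutate(aversion_sd = sd, .before = 1)
  })
  loose <- dplyr::filter(curves, .data$aversion_sd == max(sds))
  tight <- dplyr::filter(curves, .data$aversion_sd == min(sds))
  differences <- dplyr::inner_join(
    dplyr::select(loose, "t_h", loose_db = "mean_sel_db"),
    dplyr::select(tight, "t_h", tight_db = "mean_sel_db"),
    by = "t_h") |>
    dplyr::filter(.data$t_h %in% at_hours) |>
    dplyr::mutate(diff_db = .data$loose_db - .data$tight_db)
  structure(list(curves = curves, differences = differences,
                 sds = sort(sds, decreasing = TRUE)),
            class = "aversion_sweep")
}

#' @export
print.aversion_sweep <- function(x, ...) {
  cat("<aversion_sweep> heading SDs:", paste(x$sds, collapse = ", "),
      "\n")
  cat("mean SEL difference, directionless minus directed:\n")
  print(x$differences)
  invisible(x)
}

#' @export
tidy.aversion_sweep <- function(x, ...) x$curves

#' @export
autoplot.aversion_sweep <- function(object, ...) {
  ggplot(object$curves,
         aes(x = .data$t_h, y = .data$mean_sel_db,
             colour = factor(.data$aversion_sd))) +
    geom_line() +
    scale_x_log10() +
    labs(x = "Exposure duration (h)",
         y = "Mean cumulative SEL (dB re 1 µPa²/s)",
         colour = "Heading SD (rad)")
}

#' Constrained- versus unconstrained-movement comparison
#'
#' For each (boundary radius, heading SD) pair, runs a constrained arm
#' (hard reflecting boundary; seeding restricted to the boundary) and a
#' matched unconstrained arm with the same seed, and reports both curves
#' and the constrained-minus-unconstrained mean-SEL differences.
#'
#' @param config A [scenario_config()] template (its `boundary_km` and
#'   `aversion_sd` are overridden per arm).
#' @param boundaries_km Hard boundary radii (km), one per comparison.
#' @param sds Responsive heading SDs (radians), matched to
#'   `boundaries_km`.
#' @param at_hours Times (h) for the difference table.
#' @return A list of class `constrained_comparison` with `curves` and
#'   `differences`.
#' @export
run_constrained_movement <- function(config, boundaries_km = c(100, 75),
                                     sds = c(10, 0.5),
                                     at_hours = c(24, 240)) {
  stopifnot(inherits(config, "scenario_config"),
            length(boundaries_km) == length(sds))
  if (any(boundaries_km <= 0)) abort("boundary radii must be positive")
  at_hours <- at_hours[at_hours <= config$duration_h]
  one <- function(boundary_km, sd) {
    con <- modify_config(config, boundary_km = boundary_km,
                         aversion_sd = sd, responsive = TRUE)
    unc <- modify_config(config, boundary_km = NULL, aversion_sd = sd,
                         responsive = TRUE)
    curves <- dplyr::bind_rows(
      mean_sel_curve(run_simulation(con)) |>
        dplyr::mutate(arm = "constrained"),
      mean_sel_curve(run_simulation(unc)) |>
        dplyr::mutate(arm = "unconstrained")) |>
      dplyr::mutate(boundary_km = boundary_km, aversion_sd = sd,
                    .before = 1)
    curves
  }
  curves <- purrr::map2_dfr(boundaries_km, sds, one)
  differences <- curves |>
    dplyr::select("boundary_km", "aversion_sd", "t_h", "arm",
                  "mean_sel_db") |>
    tidyr::pivot_wider(names_from = "arm",
                       values_from = "mean_sel_db") |>
    dplyr::filter(.data$t_h %in% at_hours) |>
    dplyr::mutate(diff_db = .data$constrained - .data$unconstrained)
  structure(list(curves = curves, differences = differences),
            class = "constrained_comparison")
}

#' @export
print.constrained_comparison <- function(x, ...) {
  cat("<constrained_comparison> constrained minus unconstrained mean SEL:\n")
  print(x$differences)
  invisible(x)
}

#' @export
tidy.constrained_comparison <- function(x, ...) x$curves

#' @export
autoplot.constrained_comparison <- function(object, ...) {
  ggplot(object$curves,
         aes(x = .data$t_h, y = .data$mean_sel_db,
             colour = .data$arm)) +
    geom_line() +
    facet_wrap(~ boundary_km + aversion_sd, labeller = label_both) +
    scale_x_log10() +
    labs(x = "Exposure duration (h)",
         y = "Mean cumulative SEL (dB re 1 µPa²/s)", colour = NULL)
}

#' Write the packaged fixtures and default experiment configs
#'
#' Writes the species table (with its audiograms and the functional-group
#' table), the uniform-density disc and flat 50-m bathymetry grids, and
#' the three default experiment configuration files (YAML) to a
#' directory.  Deterministic: running twice produces byte-identical
#' files.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
generate_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fixtures <- c("species_synthetic.csv",
                "audiogram_gray_seal_synthetic.csv",
                "audiogram_harbor_porpoise_synthetic.csv",
                "m_weighting_groups.csv")
  for (f in fixtures) {
    file.copy(selrisk_file(f), file.path(dir, f), overwrite = TRUE)
  }
  env <- disc_scenario()
  write_grid(env$density, file.path(dir, "density_disc.csv"))
  write_grid(env$bathymetry, file.path(dir, "bathymetry_flat.csv"))
  base <- list(
    source = list(level_db = 240, frequency_khz = 1, duty_cycle = 0.1),
    propagation = list(spreading_db = 15, reference_m = 1,
                       absorption_db_km = 0),
    environment = list(density = "density_disc.csv",
                       bathymetry = "bathymetry_flat.csv",
                       cell_km = 5),
    n_agents = 10000, duration_h = 240, dt_s = 60, seed = 1)
  configs <- list(
    weighting = c(base, list(
      experiment = "weighting_comparison",
      species = c("gray seal", "harbor porpoise"),
      schemes = c("A", "M"))),
    aversion = c(base, list(
      experiment = "aversion_sweep", species = "gray seal",
      scheme = "M", sds = c(10, 1, 0.5, 0.1, 0.05))),
    constrained = c(base, list(
      experiment = "constrained_movement", species = "gray seal",
      scheme = "M", boundaries_km = c(100, 75), sds = c(10, 0.5))))
  for (nm in names(configs)) {
    yaml::write_yaml(configs[[nm]],
                     file.path(dir, paste0("config_", nm, ".yaml")))
  }
  invisible(file.path(dir, c(fixtures, "density_disc.csv",
                             "bathymetry_flat.csv",
                             paste0("config_", names(configs), ".yaml"))))
}
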