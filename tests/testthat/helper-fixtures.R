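# Shared fixtures, built in code.

gray_seal <- function() example_species("gray seal")
harbor_porpoise <- function() example_species("harbor porpoise")

# flat 50-m disc environment at reduced resolution for fast tests
small_env <- function(radius_km = 100, cell_km = 10) {
  disc_scenario(radius_km = radius_km, depth_m = 50, cell_km = cell_km)
}

# a single ~point cell so an agent sits at a known range from the source
point_env <- function(x_km = 10, y_km = 0, depth_m = 50) {
  list(density = density_grid(x_km, y_km, 1, cv = 0, cell_km = 0.001),
       bathymetry = bathymetry_grid(x_km, y_km, depth_m, cell_km = 0.001))
}

# stationary-agent config used by the closed-form oracles
stationary_config <- function(range_km = 10, duration_h = 1, dt_s = 60,
                              scheme = "M", n_agents = 1, seed = 1, ...) {
  scenario_config(gray_seal(), point_env(range_km), scheme = scheme,
                  n_agents = n_agents, duration_h = duration_h,
                  dt_s = dt_s, speed_ms = 0, responsive = FALSE,
                  seed = seed, ...)
}

# circular mean resultant length
resultant_length <- function(theta) {
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}
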