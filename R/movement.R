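# Horizontal directed-random-walk movement with wrapped-normal headings,
# optional aversive directionality, a triangular dive cycle, and
# boundary / land constraints.

#' Wrap angles to [-pi, pi)
#'
#' @param angle Angles in radians.
#' @return Equivalent angles in `[-pi, pi)`.
#' @export
wrap_angle <- function(angle) {
  needs <- angle < -pi | angle >= pi  # leave in-range values untouched
  angle[needs] <- ((angle[needs] + pi) %% (2 * pi)) - pi
  angle
}

#' Draw wrapped-normal headings
#'
#' Samples headings from a wrapped normal distribution with the given mean
#' direction and standard deviation, wrapped to `[-pi, pi)`.  `sd = 0`
#' returns the mean exactly (continual movement in the same direction);
#' large `sd` (e.g. 10) is effectively a uniform circular distribution
#' (mean resultant length `exp(-sd^2 / 2)`).
#'
#' @param n Number of draws.
#' @param mean Mean direction(s) in radians.
#' @param sd Standard deviation in radians (`>= 0`).
#' @return Headings in `[-pi, pi)`.
#' @export
#' @examples
#' draw_headings(5, mean = 0, sd = 0)      # all exactly 0
#' h <- draw_headings(1e4, 0, 0.5)         # resultant length ~ exp(-0.125)
draw_headings <- function(n, mean, sd) {
  if (any(sd < 0)) abort("heading SD must be non-negative")
  wrap_angle(rnorm(n, mean = mean, sd = sd))
}

#' Reflect positions at a hard circular boundary
#'
#' Specular reflection of the radial component: a proposed position at
#' range `r > boundary` is returned at range `2 * boundary - r` on the same
#' bearing; headings are reflected about the local tangent.  Legal
#' proposals are unchanged.  For step lengths shorter than the boundary
#' radius the result is always inside the boundary.
#'
#' @param x_km,y_km Proposed positions in km (relative to the boundary
#'   center at the origin).
#' @param heading Headings in radians (reflected for offending positions).
#' @param boundary_km Hard boundary radius in km.
#' @return A list with elements `x_km`, `y_km`, `heading`.
#' @export
reflect_boundary <- function(x_km, y_km, heading, boundary_km) {
  r <- sqrt(x_km^2 + y_km^2)
  out <- r > boundary_km
  if (any(out)) {
    bearing <- atan2(y_km[out], x_km[out])
    r_new <- 2 * boundary_km - r[out]
    x_km[out] <- r_new * cos(bearing)
    y_km[out] <- r_new * sin(bearing)
    heading[out] <- wrap_angle(2 * bearing - heading[out] + pi)
  }
  list(x_km = x_km, y_km = y_km, heading = heading)
}

#' Advance agents one movement step
#'
#' Each agent draws a new heading from a wrapped normal whose mean is the
#' bearing pointing directly away from the source (responsive / aversive
#' movement, recomputed every step) or its previous heading (natural
#' correlated random walk), then moves `speed * dt` along it.  Proposals
#' beyond the hard boundary are reflected ([reflect_boundary()]); proposals
#' onto land trigger up to `max_retries` heading re-draws and finally a
#' reversed heading with no displacement.
#'
#' @param x_km,y_km,heading Current agent states (vectors of equal
#'   length).
#' @param speed_ms Swim speed in m/s (scalar or per-agent, `>= 0`).
#' @param dt_s Time step in s (> 0).
#' @param heading_sd Wrapped-normal heading SD in radians.
#' @param responsive Logical; if `TRUE` the heading mean is the
#'   away-from-source bearing, otherwise the previous heading.
#' @param source_x_km,source_y_km Source position (km).
#' @param boundary_km Optional hard boundary radius (km).
#' @param bathymetry Optional [bathymetry_grid()]; proposals onto land
#'   (depth `<= 0`) are rejected.
#' @param max_retries Heading re-draws before forcing a reversed heading.
#' @return A list with updated `x_km`, `y_km`, `heading`.
#' @export
step_agents <- function(x_km, y_km, heading, speed_ms, dt_s, heading_sd,
                        responsive = FALSE, source_x_km = 0,
                        source_y_km = 0, boundary_km = NULL,
                        bathymetry = NULL, max_retries = 8L) {
  if (dt_s <= 0) abort("`dt_s` must be positive")
  n <- length(x_km)
  mean_heading <- if (responsive) {
    atan2(y_km - source_y_km, x_km - source_x_km)
  } else {
    heading
  }
  new_heading <- draw_headings(n, mean_heading, heading_sd)
  step_km <- rep_len(speed_ms * dt_s / 1000, n)
  xp <- x_km + step_km * cos(new_heading)
  yp <- y_km + step_km * sin(new_heading)
  if (!is.null(bathymetry)) {
    bad <- depth_at(bathymetry, xp, yp) <= 0
    tries <- 0L
    while (any(bad) && tries < max_retries) {
      idx <- which(bad)
      new_heading[idx] <- draw_headings(length(idx), mean_heading[idx],
                                        heading_sd)
      xp[idx] <- x_km[idx] + step_km[idx] * cos(new_heading[idx])
      yp[idx] <- y_km[idx] + step_km[idx] * sin(new_heading[idx])
      bad[idx] <- depth_at(bathymetry, xp[idx], yp[idx]) <= 0
      tries <- tries + 1L
    }
    if (any(bad)) {  # stuck: stay put, reverse heading
      idx <- which(bad)
      xp[idx] <- x_km[idx]
      yp[idx] <- y_km[idx]
      new_heading[idx] <- wrap_angle(new_heading[idx] + pi)
    }
  }
  if (!is.null(boundary_km)) {
    refl <- reflect_boundary(xp, yp, new_heading, boundary_km)
    xp <- refl$x_km
    yp <- refl$y_km
    new_heading <- refl$heading
  }
  list(x_km = xp, y_km = yp, heading = new_heading)
}

#' Depth in the dive cycle
#'
#' A triangular dive cycle: the agent descends linearly to its target
#' depth and ascends back over one dive duration, then spends the surface
#' interval at depth 0.  The target depth is the lesser of the species'
#' maximum dive depth and the local seafloor depth, so agents never dive
#' below the seafloor.  Since the sound field is depth-independent, diving
#' affects realism (and any depth-resolved extensions) but not the
#' accumulated SEL.
#'
#' @param t_s Elapsed time in s.
#' @param phase_s Per-agent phase offset in s (randomized at seeding so
#'   the population's dive cycles are unsynchronized).
#' @param profile A [species_profile()].
#' @param seafloor_m Local seafloor depth in m.
#' @return Depths in m, in `[0, min(max dive depth, seafloor)]`.
#' @export
dive_depth <- function(t_s, phase_s, profile, seafloor_m) {
  stopifnot(inherits(profile, "species_profile"))
  cycle <- profile$dive_duration_s + profile$surface_time_s
  tau <- (t_s + phase_s) %% cycle
  target <- pmin(profile$max_dive_depth_m, pmax(seafloor_m, 0))
  in_dive <- tau < profile$dive_duration_s
  frac <- tau / profile$dive_duration_s
  ifelse(in_dive, target * (1 - abs(1 - 2 * frac)), 0)
}
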