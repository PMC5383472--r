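# Source specification, duty-cycle scheduling, geometric-spreading
# propagation, and a precomputed received-level field with bilinear
# interpolation.

#' Specify a sound source
#'
#' @param level_db Source level SL in dB re 1 uPa2/s at the reference
#'   range (1 m).
#' @param frequency_khz Emission frequency in kHz (> 0); the scenarios are
#'   single-tone.
#' @param duty_cycle Fraction of time the source is actively emitting, in
#'   `[0, 1]`.
#' @param x_km,y_km Source position in km (the scenario convention puts the
#'   source at the origin).
#' @param pulsed Logical; pulsed sources use different effect criteria and
#'   are out of scope, so `TRUE` is rejected by [scenario_config()].
#' @return A list of class `sound_source`.
#' @export
#' @examples
#' sound_source(level_db = 240, frequency_khz = 1, duty_cycle = 0.1)
sound_source <- function(level_db = 240, frequency_khz = 1,
                         duty_cycle = 0.1, x_km = 0, y_km = 0,
                         pulsed = FALSE) {
  if (!is.finite(level_db)) abort("`level_db` must be finite")
  if (!is.finite(frequency_khz) || frequency_khz <= 0) {
    abort("`frequency_khz` must be positive")
  }
  if (!is.finite(duty_cycle) || duty_cycle < 0 || duty_cycle > 1) {
    abort("`duty_cycle` must lie in [0, 1]")
  }
  structure(list(level_db = level_db, frequency_khz = frequency_khz,
                 duty_cycle = duty_cycle, x_km = x_km, y_km = y_km,
                 pulsed = isTRUE(pulsed)),
            class = "sound_source")
}

#' @export
print.sound_source <- function(x, ...) {
  cat(sprintf(
    "<sound_source> %.0f dB re 1 uPa2/s @ 1 m, %.3g kHz, duty %.0f%%, at (%.1f, %.1f) km\n",
    x$level_db, x$frequency_khz, 100 * x$duty_cycle, x$x_km, x$y_km))
  invisible(x)
}

#' Specify a geometric-spreading propagation model
#'
#' Transmission loss of `k` dB per decade of range (`k = 10` cylindrical,
#' `15` intermediate, `20` spherical spreading) plus optional linear
#' absorption.
#'
#' @param spreading_db Spreading coefficient `k` in dB per decade of range
#'   (> 0).
#' @param reference_m Reference range in m (> 0) at which the received
#'   level equals the source level; ranges below it are clamped.
#' @param absorption_db_km Absorption in dB/km (`>= 0`; default 0, matching
#'   a bare `15 log R` model).
#' @return A list of class `propagation_model`.
#' @export
propagation_model <- function(spreading_db = 15, reference_m = 1,
                              absorption_db_km = 0) {
  if (!is.finite(spreading_db) || spreading_db <= 0) {
    abort("`spreading_db` must be positive")
  }
  if (!is.finite(reference_m) || reference_m <= 0) {
    abort("`reference_m` must be positive")
  }
  if (!is.finite(absorption_db_km) || absorption_db_km < 0) {
    abort("`absorption_db_km` must be non-negative")
  }
  structure(list(spreading_db = spreading_db, reference_m = reference_m,
                 absorption_db_km = absorption_db_km),
            class = "propagation_model")
}

#' @export
print.propagation_model <- function(x, ...) {
  cat(sprintf("<propagation_model> %g log10(R) spreading, ref %g m, absorption %g dB/km\n",
              x$spreading_db, x$reference_m, x$absorption_db_km))
  invisible(x)
}

#' Received level at positions
#'
#' `RL = SL - k log10(max(r, r_ref) / r_ref) - alpha * r_km`, with the
#' range `r` taken from horizontal distance only (the sound field is
#' depth-independent).  Ranges below the reference range are clamped, so
#' `RL <= SL` everywhere.
#'
#' @param source A [sound_source()].
#' @param model A [propagation_model()].
#' @param x_km,y_km Receiver positions in km.
#' @return Received levels in dB (same reference as the source level).
#' @export
#' @examples
#' received_level(sound_source(240), propagation_model(15), 10, 0)  # 180 dB
received_level <- function(source, model, x_km, y_km) {
  stopifnot(inherits(source, "sound_source"),
            inherits(model, "propagation_model"))
  r_km <- sqrt((x_km - source$x_km)^2 + (y_km - source$y_km)^2)
  r_m <- pmax(r_km * 1000, model$reference_m)
  source$level_db - model$spreading_db * log10(r_m / model$reference_m) -
    model$absorption_db_km * r_m / 1000
}

#' Active emission seconds in a time interval
#'
#' The duty cycle is realized as a deterministic energy fraction: over
#' `[t0, t1]` the source is active for `(t1 - t0) * duty_cycle` seconds.
#' For time steps much longer than a ping period this carries identical
#' cumulative energy to an explicit ping schedule, and it makes the
#' accumulated SEL independent of the step size.
#'
#' @param t0_s,t1_s Interval endpoints in seconds, `t1_s >= t0_s`.
#' @param source A [sound_source()].
#' @return Active seconds.
#' @export
active_exposure_seconds <- function(t0_s, t1_s, source) {
  stopifnot(inherits(source, "sound_source"))
  if (any(t1_s < t0_s)) abort("negative exposure interval")
  (t1_s - t0_s) * source$duty_cycle
}

#' Precompute a received-level field
#'
#' Evaluates [received_level()] on a regular grid, producing a field
#' library that can be queried with [field_level()] (bilinear
#' interpolation).  Mirrors the practice of pre-calculating sound fields
#' once per scenario and letting agents look levels up.
#'
#' @param source A [sound_source()].
#' @param model A [propagation_model()].
#' @param x_km,y_km Grid node coordinates (each a sorted vector).
#' @return A list of class `field_library` with `x_km`, `y_km`, `rl_db`
#'   (matrix) and the source/model provenance.
#' @export
precompute_field <- function(source, model, x_km, y_km) {
  if (length(x_km) < 2 || length(y_km) < 2) {
    abort("a field library needs at least a 2 x 2 grid")
  }
  if (any(diff(x_km) <= 0) || any(diff(y_km) <= 0)) {
    abort("grid node coordinates must be strictly increasing")
  }
  rl <- outer(x_km, y_km, function(x, y) received_level(source, model, x, y))
  structure(list(x_km = as.numeric(x_km), y_km = as.numeric(y_km),
                 rl_db = rl, source = source, model = model),
            class = "field_library")
}

#' @export
print.field_library <- function(x, ...) {
  cat(sprintf("<field_library> %d x %d nodes over [%g, %g] x [%g, %g] km\n",
              length(x$x_km), length(x$y_km), min(x$x_km), max(x$x_km),
              min(x$y_km), max(x$y_km)))
  invisible(x)
}

#' Query a field library
#'
#' Bilinear interpolation of the precomputed received levels.  Queries
#' outside the grid extent are an error (the library must cover the
#' simulation domain).
#'
#' @param field A [precompute_field()] result.
#' @param x_km,y_km Query positions in km.
#' @return Received levels in dB.
#' @export
field_level <- function(field, x_km, y_km) {
  stopifnot(inherits(field, "field_library"))
  xs <- field$x_km
  ys <- field$y_km
  if (any(x_km < xs[1] | x_km > xs[length(xs)] |
          y_km < ys[1] | y_km > ys[length(ys)])) {
    abort("query position outside the field library extent")
  }
  i <- pmin(findInterval(x_km, xs), length(xs) - 1L)
  j <- pmin(findInterval(y_km, ys), length(ys) - 1L)
  tx <- (x_km - xs[i]) / (xs[i + 1L] - xs[i])
  ty <- (y_km - ys[j]) / (ys[j + 1L] - ys[j])
  z00 <- field$rl_db[cbind(i, j)]
  z10 <- field$rl_db[cbind(i + 1L, j)]
  z01 <- field$rl_db[cbind(i, j + 1L)]
  z11 <- field$rl_db[cbind(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}

#' Export / import a field library as gridded text
#'
#' @param field A field library.
#' @param path CSV path (`x_km`, `y_km`, `rl_db`, one row per node).
#' @return `path` invisibly, or the re-read `field_library`.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "field_library"))
  grid <- tidyr::expand_grid(y_km = field$y_km, x_km = field$x_km)
  grid$rl_db <- as.vector(field$rl_db[cbind(
    match(grid$x_km, field$x_km), match(grid$y_km, field$y_km))])
  readr::write_csv(grid[, c("x_km", "y_km", "rl_db")], path)
  invisible(path)
}

#' @rdname write_field
#' @param source,model Provenance to attach on import.
#' @export
read_field <- function(path, source, model) {
  dat <- readr::read_csv(path, col_types = readr::cols(.default = "d"))
  xs <- sort(unique(dat$x_km))
  ys <- sort(unique(dat$y_km))
  rl <- matrix(NA_real_, length(xs), length(ys))
  rl[cbind(match(dat$x_km, xs), match(dat$y_km, ys))] <- dat$rl_db
  structure(list(x_km = xs, y_km = ys, rl_db = rl,
                 source = source, model = model),
            class = "field_library")
}
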