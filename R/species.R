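# Species parameters, audiograms, auditory weighting functions and
# threshold-shift effect criteria.

#' Construct an audiogram
#'
#' An audiogram records a species' hearing threshold `H(f)` (dB re 1 uPa)
#' against frequency.  Thresholds between tabulated points are interpolated
#' linearly in `log10(frequency)`; no extrapolation is performed outside the
#' tabulated domain.
#'
#' @param frequency_khz Numeric vector of frequencies in kHz, strictly
#'   increasing, at least two points.
#' @param threshold_db Hearing thresholds in dB re 1 uPa at those
#'   frequencies; all finite.
#' @return A tibble of class `audiogram` with columns `frequency_khz` and
#'   `threshold_db`.
#' @seealso [hearing_threshold()], [a_weighting()], [read_audiogram()]
#' @export
#' @examples
#' aud <- audiogram(c(0.5, 1, 2, 4), c(77, 71, 66, 62))
#' hearing_threshold(aud, 1)
audiogram <- function(frequency_khz, threshold_db) {
  if (length(frequency_khz) < 2L) {
    abort("an audiogram needs at least two (frequency, threshold) points")
  }
  if (length(frequency_khz) != length(threshold_db)) {
    abort("`frequency_khz` and `threshold_db` must have the same length")
  }
  if (any(!is.finite(frequency_khz)) || any(frequency_khz <= 0)) {
    abort("audiogram frequencies must be finite and positive")
  }
  if (any(diff(frequency_khz) <= 0)) {
    abort("audiogram frequencies must be strictly increasing")
  }
  if (any(!is.finite(threshold_db))) {
    abort("audiogram thresholds must be finite")
  }
  out <- tibble(frequency_khz = as.numeric(frequency_khz),
                threshold_db = as.numeric(threshold_db))
  class(out) <- c("audiogram", class(out))
  out
}

#' Read an audiogram from a two-column delimited file
#'
#' @param path Path to a CSV file with columns `frequency_khz` and
#'   `threshold_db`.
#' @return An [audiogram()].
#' @export
read_audiogram <- function(path) {
  dat <- readr::read_csv(path, col_types = readr::cols(
    frequency_khz = readr::col_double(),
    threshold_db = readr::col_double()
  ))
  audiogram(dat$frequency_khz, dat$threshold_db)
}

#' Hearing threshold at a frequency
#'
#' Evaluates `H(f)` by linear interpolation in `log10(f)` between audiogram
#' points.  Frequencies outside the tabulated domain are an error: hearing
#' sensitivity falls off too steeply at the ends of the hearing range for
#' extrapolation to be defensible.
#'
#' @param audiogram An [audiogram()].
#' @param frequency_khz Frequencies (kHz) at which to evaluate, all within
#'   the audiogram's tabulated domain.
#' @return Hearing thresholds in dB re 1 uPa.
#' @export
hearing_threshold <- function(audiogram, frequency_khz) {
  stopifnot(inherits(audiogram, "audiogram"))
  f <- as.numeric(frequency_khz)
  rng <- range(audiogram$frequency_khz)
  if (any(!is.finite(f)) || any(f < rng[1]) || any(f > rng[2])) {
    abort(sprintf(
      "frequency outside the audiogram domain [%g, %g] kHz", rng[1], rng[2]))
  }
  approx(log10(audiogram$frequency_khz), audiogram$threshold_db,
         xout = log10(f), ties = "ordered")$y
}

#' Functional hearing groups and M-weighting band edges
#'
#' The five marine-mammal functional hearing groups with their band-pass
#' edges (kHz) and the recommended cumulative-SEL thresholds for permanent
#' and temporary threshold shift (PTS/TTS) under nonpulsed sound, as a
#' packaged fixture table.  In-air pinniped criteria use a different
#' pressure reference and are out of scope (thresholds `NA`).
#'
#' @return A tibble with columns `group`, `f_low_khz`, `f_high_khz`,
#'   `pts_nonpulse_db`, `tts_nonpulse_db`.
#' @export
functional_groups <- function() {
  if (is.null(the$groups)) {
    the$groups <- readr::read_csv(
      selrisk_file("m_weighting_groups.csv"),
      col_types = readr::cols(
        group = readr::col_character(),
        f_low_khz = readr::col_double(),
        f_high_khz = readr::col_double(),
        pts_nonpulse_db = readr::col_double(),
        tts_nonpulse_db = readr::col_double()
      ))
  }
  the$groups
}

lookup_group <- function(group) {
  groups <- functional_groups()
  row <- groups[groups$group == group, ]
  if (nrow(row) != 1L) {
    abort(paste0("unknown functional hearing group: '", group,
                 "' (expected one of ",
                 paste0("'", groups$group, "'", collapse = ", "), ")"))
  }
  row
}

#' M-weighting for a functional hearing group
#'
#' Band-pass frequency weighting
#' `W_M(f) = K + 20 log10(f_high^2 f^2 / ((f^2 + f_low^2) (f^2 + f_high^2)))`
#' with band edges `(f_low, f_high)` per functional group and `K` chosen in
#' closed form so that the maximum over frequency is exactly 0 dB (attained
#' at `f = sqrt(f_low * f_high)`).  The weighting is ~0 inside the group's
#' passband and rolls off at 12 dB/octave outside.
#'
#' @param frequency_khz Frequencies in kHz (> 0).
#' @param group Functional group name, one of the rows of
#'   [functional_groups()].
#' @return Weights in dB, all `<= 0`.
#' @export
#' @examples
#' m_weighting(1, "pinniped-in-water")  # ~0 dB in the passband
m_weighting <- function(frequency_khz, group) {
  f <- as.numeric(frequency_khz)
  if (any(!is.finite(f)) || any(f <= 0)) {
    abort("frequencies must be finite and positive")
  }
  row <- lookup_group(group)
  fl <- row$f_low_khz
  fh <- row$f_high_khz
  # max of the unnormalized form is 40*log10(fh / (fl + fh))
  k <- -40 * log10(fh / (fl + fh))
  k + 20 * log10(fh^2 * f^2 / ((f^2 + fl^2) * (f^2 + fh^2)))
}

#' Audiogram-derived (A) weighting
#'
#' Discounts a received level by the species' hearing threshold:
#' `W_A(f) = -H(f)`, so that an A-weighted level is the sensation level on
#' the SEL scale.  This is this field's audiogram weighting, unrelated to
#' the IEC sound-level-meter A-curve.
#'
#' @inheritParams hearing_threshold
#' @return Weights in dB.
#' @export
a_weighting <- function(frequency_khz, audiogram) {
  -hearing_threshold(audiogram, frequency_khz)
}

#' Construct a species profile
#'
#' Movement and dive parameters, functional hearing group, audiogram, and
#' responsive-movement defaults for a single species.
#'
#' @param species Species name.
#' @param functional_group Functional hearing group name (see
#'   [functional_groups()]).
#' @param typical_speed_ms,max_speed_ms Typical and maximum swim speed in
#'   m/s; `0 < typical <= max`.
#' @param max_dive_depth_m Maximum dive depth in m (> 0).
#' @param dive_duration_s Typical dive duration in s (> 0).
#' @param surface_time_s Typical inter-dive surface interval in s (> 0).
#' @param responds_to_noise Logical; does the species show responsive
#'   (aversive) movement when exposed?
#' @param aversion_sd_default Default wrapped-normal heading SD (radians)
#'   used for responsive movement when a scenario does not override it.
#' @param heading_sd Heading SD (radians) of the natural (non-responsive)
#'   correlated random walk.
#' @param audiogram An [audiogram()], or `NULL` if only M-weighting will be
#'   used.
#' @return A list of class `species_profile`.
#' @export
species_profile <- function(species, functional_group,
                            typical_speed_ms, max_speed_ms,
                            max_dive_depth_m, dive_duration_s,
                            surface_time_s, responds_to_noise = TRUE,
                            aversion_sd_default = 1,
                            heading_sd = 1,
                            audiogram = NULL) {
  lookup_group(functional_group)  # errors on unknown group
  if (!is.finite(typical_speed_ms) || typical_speed_ms <= 0 ||
      !is.finite(max_speed_ms) || max_speed_ms <= 0) {
    abort("swim speeds must be finite and positive")
  }
  if (typical_speed_ms > max_speed_ms) {
    abort("typical swim speed must not exceed maximum swim speed")
  }
  if (max_dive_depth_m <= 0 || dive_duration_s <= 0 || surface_time_s <= 0) {
    abort("dive depth, dive duration and surface time must be positive")
  }
  if (!is.null(audiogram)) stopifnot(inherits(audiogram, "audiogram"))
  structure(list(
    species = species,
    functional_group = functional_group,
    typical_speed_ms = typical_speed_ms,
    max_speed_ms = max_speed_ms,
    max_dive_depth_m = max_dive_depth_m,
    dive_duration_s = dive_duration_s,
    surface_time_s = surface_time_s,
    responds_to_noise = isTRUE(responds_to_noise),
    aversion_sd_default = aversion_sd_default,
    heading_sd = heading_sd,
    audiogram = audiogram
  ), class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat("<species_profile> ", x$species, " (", x$functional_group, ")\n",
      sep = "")
  cat(sprintf("  swim %.1f m/s (max %.1f); dive to %.0f m, %ds down / %ds at surface\n",
              x$typical_speed_ms, x$max_speed_ms, x$max_dive_depth_m,
              x$dive_duration_s, x$surface_time_s))
  cat(sprintf("  responds to noise: %s; audiogram: %s\n",
              x$responds_to_noise,
              if (is.null(x$audiogram)) "none" else
                paste0(nrow(x$audiogram), " points")))
  invisible(x)
}

#' Read a species parameter table
#'
#' One row per species.  Required columns: `species`, `functional_group`,
#' `typical_speed_ms`, `max_speed_ms`, `max_dive_depth_m`,
#' `dive_duration_s`, `surface_time_s`, `responds_to_noise`,
#' `aversion_sd_default`, `heading_sd`, `audiogram_file` (path relative to
#' the table's directory, or empty for no audiogram).  Missing fields are
#' rejected; no cross-species inference is attempted.
#'
#' @param path Path to the CSV table.
#' @return A named list of [species_profile()] objects.
#' @export
read_species_table <- function(path) {
  dat <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  required <- c("species", "functional_group", "typical_speed_ms",
                "max_speed_ms", "max_dive_depth_m", "dive_duration_s",
                "surface_time_s", "responds_to_noise",
                "aversion_sd_default", "heading_sd", "audiogram_file")
  missing <- setdiff(required, names(dat))
  if (length(missing) > 0) {
    abort(paste0("species table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (anyNA(dat[required[required != "audiogram_file"]])) {
    abort("species table contains missing values")
  }
  dir <- dirname(path)
  profiles <- purrr::pmap(dat, function(species, functional_group,
                                        typical_speed_ms, max_speed_ms,
                                        max_dive_depth_m, dive_duration_s,
                                        surface_time_s, responds_to_noise,
                                        aversion_sd_default, heading_sd,
                                        audiogram_file, ...) {
    aud <- NULL
    if (!is.na(audiogram_file) && nzchar(audiogram_file)) {
      aud <- read_audiogram(file.path(dir, audiogram_file))
    }
    species_profile(
      species = species,
      functional_group = functional_group,
      typical_speed_ms = as.numeric(typical_speed_ms),
      max_speed_ms = as.numeric(max_speed_ms),
      max_dive_depth_m = as.numeric(max_dive_depth_m),
      dive_duration_s = as.numeric(dive_duration_s),
      surface_time_s = as.numeric(surface_time_s),
      responds_to_noise = as.logical(responds_to_noise),
      aversion_sd_default = as.numeric(aversion_sd_default),
      heading_sd = as.numeric(heading_sd),
      audiogram = aud
    )
  })
  setNames(profiles, dat$species)
}

#' Packaged example species
#'
#' Profiles for gray seal (*Halichoerus grypus*, pinniped-in-water) and
#' harbor porpoise (*Phocoena phocoena*, high-frequency cetacean).  The
#' movement parameters are literature-realistic values and the audiograms
#' are synthetic literature-shaped curves anchored so that the hearing
#' threshold at 1 kHz is 71 dB (gray seal) and 80 dB (harbor porpoise);
#' they are fixtures for the idealized scenarios, not measured curves.
#'
#' @param species Optional species name(s) to select; default both.
#' @return A named list of [species_profile()] objects (or a single
#'   profile when one name is requested).
#' @export
#' @examples
#' gs <- example_species("gray seal")
#' pts_threshold(gs, "A", frequency_khz = 1)
example_species <- function(species = NULL) {
  if (is.null(the$species)) {
    the$species <- read_species_table(selrisk_file("species_synthetic.csv"))
  }
  out <- the$species
  if (!is.null(species)) {
    missing <- setdiff(species, names(out))
    if (length(missing) > 0) {
      abort(paste0("no packaged profile for: ",
                   paste(missing, collapse = ", ")))
    }
    out <- out[species]
    if (length(out) == 1L) out <- out[[1L]]
  }
  out
}

#' PTS threshold for a species under a weighting scheme
#'
#' Under the M scheme the threshold is the functional group's recommended
#' cumulative-SEL criterion for nonpulsed sound (e.g. 203 dB re 1 uPa2/s
#' for pinnipeds in water, 215 dB for high-frequency cetaceans).  Under the
#' A scheme the threshold is "audiogram appropriate": 95 dB above the
#' species' hearing threshold at the exposure frequency,
#' `H(f) + 95 dB re 1 uPa2/s`.
#'
#' @param species A [species_profile()].
#' @param scheme `"M"` or `"A"`.
#' @param frequency_khz Exposure frequency in kHz; required for scheme
#'   `"A"`.
#' @return Threshold in dB re 1 uPa2/s (weighted cumulative SEL).
#' @export
pts_threshold <- function(species, scheme = c("M", "A"),
                          frequency_khz = NULL) {
  stopifnot(inherits(species, "species_profile"))
  scheme <- match.arg(scheme)
  if (scheme == "M") {
    thr <- lookup_group(species$functional_group)$pts_nonpulse_db
    if (is.na(thr)) {
      abort(paste0("no nonpulsed PTS criterion for group '",
                   species$functional_group, "'"))
    }
    return(thr)
  }
  if (is.null(species$audiogram)) {
    abort(paste0("species '", species$species,
                 "' has no audiogram; A-scheme threshold unavailable"))
  }
  if (is.null(frequency_khz)) {
    abort("`frequency_khz` is required for the A scheme")
  }
  hearing_threshold(species$audiogram, frequency_khz) + 95
}

#' TTS threshold for a species under the M scheme
#'
#' The functional group's recommended cumulative-SEL criterion for TTS
#' onset under nonpulsed sound.
#'
#' @inheritParams pts_threshold
#' @return Threshold in dB re 1 uPa2/s.
#' @export
tts_threshold <- function(species) {
  stopifnot(inherits(species, "species_profile"))
  thr <- lookup_group(species$functional_group)$tts_nonpulse_db
  if (is.na(thr)) {
    abort(paste0("no nonpulsed TTS criterion for group '",
                 species$functional_group, "'"))
  }
  thr
}

#' Logistic dose-response curve
#'
#' `P(SEL) = 1 / (1 + exp(-(SEL - midpoint) / scale))`: the probability of
#' an effect (e.g. TTS onset) as a monotone nondecreasing function of
#' cumulative weighted SEL, with `P -> 0` far below the midpoint and
#' `P -> 1` far above.
#'
#' @param midpoint_db SEL (dB re 1 uPa2/s) at which the probability is 0.5.
#' @param scale_db Logistic scale (dB, > 0); smaller is steeper.
#' @return A list of class `dose_response_curve`.
#' @seealso [dose_response()], [tts_curve()]
#' @export
dose_response_curve <- function(midpoint_db, scale_db) {
  if (!is.finite(midpoint_db) || !is.finite(scale_db) || scale_db <= 0) {
    abort("`midpoint_db` must be finite and `scale_db` positive")
  }
  structure(list(midpoint_db = midpoint_db, scale_db = scale_db),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("<dose_response_curve> midpoint %.2f dB, scale %.2f dB\n",
              x$midpoint_db, x$scale_db))
  invisible(x)
}

#' Evaluate a dose-response curve
#'
#' @param sel_db Cumulative weighted SEL in dB re 1 uPa2/s; `NA` (the
#'   no-exposure sentinel) maps to probability 0.
#' @param curve A [dose_response_curve()].
#' @return Probabilities in `[0, 1]`.
#' @export
dose_response <- function(sel_db, curve) {
  stopifnot(inherits(curve, "dose_response_curve"))
  p <- plogis(sel_db, location = curve$midpoint_db, scale = curve$scale_db)
  p[is.na(sel_db)] <- 0
  p
}

#' Packaged TTS dose-response curve
#'
#' Logistic curve calibrated so that a cumulative SEL of 195 dB re
#' 1 uPa2/s - the level at which statistically significant TTS begins in
#' the experimental literature - maps to a probability of 0.185 (within
#' the reported 0.18-0.19 band).  The slope (scale 4 dB) is a documented
#' free choice; only the 195-dB anchor is empirically pinned.
#'
#' @return A [dose_response_curve()] with midpoint ~200.93 dB, scale 4 dB.
#' @export
#' @examples
#' dose_response(195, tts_curve())
tts_curve <- function() {
  scale <- 4
  midpoint <- 195 + scale * log((1 - 0.185) / 0.185)
  dose_response_curve(midpoint, scale)
}
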