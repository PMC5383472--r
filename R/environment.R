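# Density-weighted agent seeding, density uncertainty resampling,
# bathymetry / boundary geometry, and the idealized scenario fixture.
#
# Coordinates are local planar x,y in km with the sound source at the
# origin; real-world grids should be pre-projected.

#' Construct a density grid
#'
#' A regular grid of animal density (animals/km2) with a per-cell
#' coefficient of variation (CV) describing the uncertainty of the density
#' estimate.  The grid seeds agents ([sample_positions()]) and drives
#' uncertainty resampling ([resample_density()]).
#'
#' @param x_km,y_km Cell-center coordinates in km (regular spacing).
#' @param density Animal density in animals/km2, `>= 0`, at least one
#'   positive cell.
#' @param cv Per-cell coefficient of variation, `>= 0` (scalar or
#'   per-cell).
#' @param cell_km Cell edge length in km.
#' @return A tibble of class `density_grid` with columns `x_km`, `y_km`,
#'   `density`, `cv` and attribute `cell_km`.
#' @export
density_grid <- function(x_km, y_km, density, cv = 0, cell_km) {
  n <- length(x_km)
  stopifnot(length(y_km) == n, length(density) == n)
  cv <- rep_len(cv, n)
  if (any(!is.finite(density)) || any(density < 0)) {
    abort("densities must be finite and non-negative")
  }
  if (all(density == 0)) {
    abort("density grid must contain at least one cell with positive density")
  }
  if (any(!is.finite(cv)) || any(cv < 0)) {
    abort("cell CVs must be finite and non-negative")
  }
  if (!is.finite(cell_km) || cell_km <= 0) {
    abort("`cell_km` must be positive")
  }
  out <- tibble(cell = seq_len(n), x_km = as.numeric(x_km),
                y_km = as.numeric(y_km), density = as.numeric(density),
                cv = as.numeric(cv))
  attr(out, "cell_km") <- cell_km
  class(out) <- c("density_grid", class(out))
  out
}

#' Construct a bathymetry grid
#'
#' Seafloor depth in m (positive down) on a regular grid; land is encoded
#' as depth `<= 0`.  Lookups outside the grid extent return the nearest
#' edge cell (open water continues beyond the mapped area).
#'
#' @param x_km,y_km Cell-center coordinates in km (regular spacing).
#' @param depth_m Seafloor depth in m; `<= 0` marks land.
#' @param cell_km Cell edge length in km.
#' @return A tibble of class `bathymetry_grid` with attribute `cell_km`.
#' @export
bathymetry_grid <- function(x_km, y_km, depth_m, cell_km) {
  n <- length(x_km)
  stopifnot(length(y_km) == n, length(depth_m) == n)
  if (any(!is.finite(depth_m))) abort("depths must be finite")
  if (!is.finite(cell_km) || cell_km <= 0) abort("`cell_km` must be positive")
  out <- tibble(x_km = as.numeric(x_km), y_km = as.numeric(y_km),
                depth_m = as.numeric(depth_m))
  attr(out, "cell_km") <- cell_km
  class(out) <- c("bathymetry_grid", class(out))
  out
}

# internal: nearest-neighbour lookup structure for a regular grid
grid_index <- function(grid, value_col) {
  xs <- sort(unique(grid$x_km))
  ys <- sort(unique(grid$y_km))
  mat <- matrix(NA_real_, nrow = length(xs), ncol = length(ys))
  i <- match(grid$x_km, xs)
  j <- match(grid$y_km, ys)
  mat[cbind(i, j)] <- grid[[value_col]]
  if (anyNA(mat)) abort("grid is not a complete regular lattice")
  list(xs = xs, ys = ys, mat = mat)
}

nearest_axis_index <- function(centers, coords) {
  if (length(centers) == 1L) return(rep(1L, length(coords)))
  pmin(pmax(round(approx(centers, seq_along(centers), xout = coords,
                         rule = 2, ties = "ordered")$y), 1L),
       length(centers))
}

lookup_nearest <- function(idx, x_km, y_km) {
  # index of the nearest cell center, clamped to the grid extent
  i <- nearest_axis_index(idx$xs, x_km)
  j <- nearest_axis_index(idx$ys, y_km)
  idx$mat[cbind(i, j)]
}

#' Seafloor depth at positions
#'
#' Nearest-cell lookup on a [bathymetry_grid()]; positions beyond the grid
#' extent take the nearest edge value.
#'
#' @param bathymetry A [bathymetry_grid()].
#' @param x_km,y_km Positions in km.
#' @return Depths in m (positive down; `<= 0` is land).
#' @export
depth_at <- function(bathymetry, x_km, y_km) {
  stopifnot(inherits(bathymetry, "bathymetry_grid"))
  idx <- attr(bathymetry, "index")
  if (is.null(idx)) idx <- grid_index(bathymetry, "depth_m")
  lookup_nearest(idx, x_km, y_km)
}

# internal: attach the lookup index once (used by the simulation engine)
index_bathymetry <- function(bathymetry) {
  attr(bathymetry, "index") <- grid_index(bathymetry, "depth_m")
  bathymetry
}

#' Total abundance implied by a density grid
#'
#' @param grid A [density_grid()].
#' @return Expected number of animals, `sum(density * cell area)`.
#' @export
abundance <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  sum(grid$density) * attr(grid, "cell_km")^2
}

#' Seed agent positions from a density grid
#'
#' Cells are chosen with probability proportional to `density * area`;
#' positions are uniform within the chosen cell.  An optional hard boundary
#' and bathymetry restrict seeding: cells whose center lies beyond the
#' boundary radius or on land get zero weight, and any within-cell jitter
#' that crosses the boundary is reflected radially back inside (a
#' sub-cell-scale correction that keeps the seeded positions strictly
#' legal).
#'
#' @param grid A [density_grid()].
#' @param n Number of agents (`>= 1`).
#' @param bathymetry Optional [bathymetry_grid()]; cells on land are
#'   excluded.
#' @param boundary_km Optional hard boundary radius (km) around the origin.
#' @return A tibble with columns `agent`, `cell`, `x_km`, `y_km`.
#' @export
sample_positions <- function(grid, n, bathymetry = NULL,
                             boundary_km = NULL) {
  stopifnot(inherits(grid, "density_grid"))
  if (n < 1) abort("`n` must be at least 1")
  cell_km <- attr(grid, "cell_km")
  w <- grid$density * cell_km^2
  if (!is.null(boundary_km)) {
    w[sqrt(grid$x_km^2 + grid$y_km^2) > boundary_km] <- 0
  }
  if (!is.null(bathymetry)) {
    w[depth_at(bathymetry, grid$x_km, grid$y_km) <= 0] <- 0
  }
  if (all(w == 0)) {
    abort("no cell has positive density inside the boundary and off land")
  }
  pick <- sample.int(nrow(grid), n, replace = TRUE, prob = w)
  x <- grid$x_km[pick] + (runif(n) - 0.5) * cell_km
  y <- grid$y_km[pick] + (runif(n) - 0.5) * cell_km
  if (!is.null(boundary_km)) {
    r <- sqrt(x^2 + y^2)
    out <- r > boundary_km
    if (any(out)) {
      scale <- (2 * boundary_km - r[out]) / r[out]
      x[out] <- x[out] * scale
      y[out] <- y[out] * scale
    }
  }
  if (!is.null(bathymetry)) {
    on_land <- depth_at(bathymetry, x, y) <= 0
    if (any(on_land)) {  # fall back to the (water) cell center
      x[on_land] <- grid$x_km[pick[on_land]]
      y[on_land] <- grid$y_km[pick[on_land]]
    }
  }
  tibble(agent = seq_len(n), cell = pick, x_km = x, y_km = y)
}

#' Resample a density grid according to its cell CVs
#'
#' Each cell density is drawn from a mean-preserving lognormal with mean
#' equal to the input density and coefficient of variation equal to the
#' cell CV (`sdlog^2 = log(1 + cv^2)`, `meanlog = log(D) - sdlog^2 / 2`);
#' cells with `cv = 0` or zero density are unchanged.  Cells are resampled
#' independently.  Used by [risk_with_uncertainty()] to propagate density
#' uncertainty into confidence intervals.
#'
#' @param grid A [density_grid()].
#' @return A new [density_grid()] realization.
#' @export
resample_density <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  d <- grid$density
  live <- d > 0 & grid$cv > 0
  if (any(live)) {
    sdlog <- sqrt(log1p(grid$cv[live]^2))
    meanlog <- log(d[live]) - sdlog^2 / 2
    d[live] <- rlnorm(sum(live), meanlog, sdlog)
  }
  out <- grid
  out$density <- d
  out
}

#' Idealized uniform-disc scenario fixture
#'
#' The package's reference environment: a uniform-density disc of animals
#' centered on the sound source over a flat seabed.  Cells whose center
#' lies within `radius_km` of the origin carry `density_per_km2`; all other
#' cells are empty.  Bathymetry is a constant `depth_m` everywhere.
#' Deterministic given its arguments.
#'
#' @param radius_km Disc radius in km (> 0).
#' @param depth_m Uniform water depth in m (> 0).
#' @param cell_km Grid cell size in km.
#' @param density_per_km2 Animal density inside the disc (animals/km2).
#' @param cv Density CV applied to the occupied cells.
#' @return A list with elements `density` ([density_grid()]) and
#'   `bathymetry` ([bathymetry_grid()]).
#' @export
#' @examples
#' env <- disc_scenario(radius_km = 100, depth_m = 50)
#' abundance(env$density)
disc_scenario <- function(radius_km = 100, depth_m = 50, cell_km = 5,
                          density_per_km2 = 0.05, cv = 0.3) {
  if (radius_km <= 0 || depth_m <= 0 || cell_km <= 0 ||
      density_per_km2 <= 0) {
    abort("disc radius, depth, cell size and density must be positive")
  }
  half <- ceiling(radius_km / cell_km)
  centers <- seq(-half, half) * cell_km
  cells <- tidyr::expand_grid(x_km = centers, y_km = centers)
  r <- sqrt(cells$x_km^2 + cells$y_km^2)
  dens <- ifelse(r <= radius_km, density_per_km2, 0)
  list(
    density = density_grid(cells$x_km, cells$y_km, dens, cv = cv,
                           cell_km = cell_km),
    bathymetry = bathymetry_grid(cells$x_km, cells$y_km,
                                 rep(depth_m, nrow(cells)),
                                 cell_km = cell_km)
  )
}

#' Write / read gridded delimited text
#'
#' Grids are exchanged as three-column CSV (`x_km`, `y_km`, value...),
#' one row per cell.
#'
#' @param grid A [density_grid()] or [bathymetry_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  dat <- as_tibble(grid)
  dat$cell <- NULL
  readr::write_csv(dat, path)
  invisible(path)
}

#' @rdname write_grid
#' @param cell_km Cell size of the stored grid (km).
#' @export
read_density_grid <- function(path, cell_km) {
  dat <- readr::read_csv(path, col_types = readr::cols(.default = "d"))
  density_grid(dat$x_km, dat$y_km, dat$density, cv = dat$cv,
               cell_km = cell_km)
}

#' @rdname write_grid
#' @export
read_bathymetry_grid <- function(path, cell_km) {
  dat <- readr::read_csv(path, col_types = readr::cols(.default = "d"))
  bathymetry_grid(dat$x_km, dat$y_km, dat$depth_m, cell_km = cell_km)
}
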