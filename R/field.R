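#' Geometry of one air-cored solenoid
#'
#' The coil axis is Z ("perpendicular to the seeded cells"); the winding is
#' modelled as `turns` circular loops uniformly spaced over the axial span
#' `[z_inner, z_inner + length]` (multiplied by `sense`).
#'
#' @param radius Coil radius, m.
#' @param length Winding length, m.
#' @param turns Number of turns.
#' @param z_inner Axial position of the inner (gap-side) end, m.
#' @param sense Winding sense, `+1` or `-1`.
#' @return A `solenoid_spec` list.
#' @export
solenoid_spec <- function(radius = 0.05, length = 0.05, turns = 699,
                          z_inner = 0.015, sense = 1) {
  stopifnot(radius > 0, length > 0)
  if (turns < 1) abort("a solenoid needs at least 1 turn")
  structure(list(radius = radius, length = length, turns = as.integer(turns),
                 z_inner = z_inner, sense = sign(sense)),
            class = "solenoid_spec")
}

#' Default calibrated bioreactor: a coaxial solenoid pair in series
#'
#' Two identical coils facing each other across a 30 mm gap, mirror-symmetric
#' about the culture midplane `z = 0`. The radius (50 mm, comparable to the
#' coil separation, which flattens the radial profile over the culture
#' region to ~1%) and the turn count (699 per coil) are calibrations, not
#' measurements: the turns are solved so that the 0.319 A peak current
#' produces ~2.83 mT at the center, the field magnitude implied by the
#' published peak energy density of ~3.18 J/m^3.
#'
#' @param radius,length,turns,gap Coil geometry; `gap` is the distance
#'   between the two inner coil ends, m.
#' @return List of two [solenoid_spec()]s (`top`, `bottom`).
#' @export
default_bioreactor <- function(radius = 0.05, length = 0.05, turns = 699,
                               gap = 0.03) {
  top <- solenoid_spec(radius, length, turns, z_inner = gap / 2, sense = 1)
  bottom <- solenoid_spec(radius, length, turns, z_inner = -gap / 2 - length,
                          sense = 1)
  list(top = top, bottom = bottom)
}

#' Trapezoidal current pulse of the field generator
#'
#' Piecewise-linear pulse: linear rise, plateau, linear fall, repeated at
#' `frequency`. The published ramp is 0 to 319 mA in 1.36 ms at 75 Hz; the
#' fall is assumed symmetric and the plateau fills half the 13.33 ms period.
#'
#' @param I_peak Peak current, A.
#' @param rise,fall Ramp durations, s.
#' @param frequency Repetition frequency, Hz.
#' @param plateau Plateau duration, s; default `1/(2 frequency) - rise`.
#' @return A `current_waveform` list with fields plus `dIdt_max` (A/s).
#' @export
current_waveform <- function(I_peak = 0.319, rise = 1.36e-3, fall = 1.36e-3,
                             frequency = 75, plateau = NULL) {
  plateau <- plateau %||% max(1 / (2 * frequency) - rise, 0)
  stopifnot(I_peak >= 0, rise > 0, fall > 0, plateau >= 0)
  if (rise + plateau + fall > 1 / frequency)
    abort("pulse (rise + plateau + fall) does not fit in one period")
  structure(list(I_peak = I_peak, rise = rise, plateau = plateau, fall = fall,
                 frequency = frequency, dIdt_max = I_peak / rise),
            class = "current_waveform")
}

#' Instantaneous current of a trapezoidal pulse train
#'
#' @param wf A [current_waveform()].
#' @param t Times, s.
#' @return Current in A at each time.
#' @export
current_at <- function(wf, t) {
  u <- t %% (1 / wf$frequency)
  I <- numeric(length(u))
  r <- wf$rise; p <- wf$plateau; f <- wf$fall
  i1 <- u < r
  i2 <- u >= r & u < r + p
  i3 <- u >= r + p & u < r + p + f
  I[i1] <- wf$I_peak * u[i1] / r
  I[i2] <- wf$I_peak
  I[i3] <- wf$I_peak * (1 - (u[i3] - r - p) / f)
  I
}

#' Magnetic field of a circular current loop (closed form)
#'
#' Field of a loop of radius `R` centered on the Z axis at `z_loop`, at field
#' points given in Cartesian coordinates, via the standard complete-elliptic
#' integral expressions for the radial and axial components. On axis this
#' reduces to `mu0 I R^2 / (2 (R^2 + z^2)^(3/2))`.
#'
#' @param R Loop radius, m.
#' @param I Current, A.
#' @param z_loop Axial position of the loop, m.
#' @param x,y,z Field-point coordinates, m (vectors of equal length or
#'   length 1).
#' @return Tibble with `Bx`, `By`, `Bz` in tesla.
#' @export
loop_field <- function(R, I, z_loop, x, y, z) {
  pts <- vctrs_recycle(x, y, z)
  x <- pts[[1]]; y <- pts[[2]]; z <- pts[[3]]
  rho <- sqrt(x^2 + y^2)
  zz <- z - z_loop
  if (any(abs(rho - R) < 1e-6 & abs(zz) < 1e-6))
    abort("singular point: field requested within 1e-6 m of the wire")
  Brho_z <- loop_field_cyl(R, I, rho, zz)
  cosphi <- ifelse(rho > 0, x / rho, 0)
  sinphi <- ifelse(rho > 0, y / rho, 0)
  tibble(Bx = Brho_z$Brho * cosphi, By = Brho_z$Brho * sinphi,
         Bz = Brho_z$Bz)
}

# Loop field in cylindrical components (rho >= 0, z relative to the loop
# plane), vectorized. k^2 = 4 R rho / ((R + rho)^2 + z^2).
loop_field_cyl <- function(R, I, rho, z) {
  n <- length(rho)
  Brho <- Bz <- numeric(n)
  on_axis <- rho < 1e-12
  if (any(on_axis)) {
    Bz[on_axis] <- mu0 * I * R^2 / (2 * (R^2 + z[on_axis]^2)^1.5)
  }
  if (any(!on_axis)) {
    r <- rho[!on_axis]; zz <- z[!on_axis]
    Q <- (R + r)^2 + zz^2
    m <- 4 * R * r / Q
    ek <- pracma::ellipke(m)
    K <- ek$k; E <- ek$e
    pref <- mu0 * I / (2 * pi * sqrt(Q))
    den <- (R - r)^2 + zz^2
    Bz[!on_axis] <- pref * (K + E * (R^2 - r^2 - zz^2) / den)
    Brho[!on_axis] <- pref * (zz / r) * (-K + E * (R^2 + r^2 + zz^2) / den)
  }
  list(Brho = Brho, Bz = Bz)
}

vctrs_recycle <- function(...) {
  vs <- list(...)
  n <- max(lengths(vs))
  lapply(vs, function(v) if (length(v) == n) v else rep(v, length.out = n))
}

#' Magnetic field of a finite solenoid
#'
#' Superposition of `turns` loops uniformly spaced along the winding length.
#'
#' @param spec A [solenoid_spec()].
#' @param I Current, A.
#' @inheritParams loop_field
#' @return Tibble with `Bx`, `By`, `Bz` in tesla.
#' @export
solenoid_field <- function(spec, I, x, y, z) {
  stopifnot(inherits(spec, "solenoid_spec"))
  pts <- vctrs_recycle(x, y, z)
  x <- pts[[1]]; y <- pts[[2]]; z <- pts[[3]]
  # one loop at the axial center of each turn (midpoint rule: converges to
  # the uniform current sheet as O((L/turns)^2))
  dz <- spec$length / spec$turns
  zs <- spec$z_inner + dz * (seq_len(spec$turns) - 0.5)
  rho <- sqrt(x^2 + y^2)
  Brho <- Bz <- numeric(length(x))
  for (zl in zs) {
    f <- loop_field_cyl(spec$radius, I * spec$sense, rho, z - zl)
    Brho <- Brho + f$Brho
    Bz <- Bz + f$Bz
  }
  cosphi <- ifelse(rho > 0, x / rho, 0)
  sinphi <- ifelse(rho > 0, y / rho, 0)
  tibble(Bx = Brho * cosphi, By = Brho * sinphi, Bz = Bz)
}

#' Field map of the solenoid pair at the culture plane
#'
#' Profiles of the vertical component `B_Z` (and the transverse components)
#' along the X and Y lines through the center of the culture plane.
#'
#' @param pair List of two [solenoid_spec()]s (see [default_bioreactor()]).
#' @param I Current, A.
#' @param z_plane Culture-plane height, m (midplane by default).
#' @param coords Sample coordinates along each line, m.
#' @return Tibble with `axis` (`"X"`/`"Y"`), `coord_m`, `Bz_mT`, `Bx_mT`,
#'   `By_mT`.
#' @export
pair_field_map <- function(pair, I = 0.319, z_plane = 0,
                           coords = seq(-0.04, 0.04, length.out = 81)) {
  line <- function(axis) {
    x <- if (axis == "X") coords else 0
    y <- if (axis == "Y") coords else 0
    f1 <- solenoid_field(pair[[1]], I, x, y, z_plane)
    f2 <- solenoid_field(pair[[2]], I, x, y, z_plane)
    tibble(axis = axis, coord_m = coords,
           Bz_mT = (f1$Bz + f2$Bz) * 1e3,
           Bx_mT = (f1$Bx + f2$Bx) * 1e3,
           By_mT = (f1$By + f2$By) * 1e3)
  }
  dplyr::bind_rows(line("X"), line("Y"))
}

#' Field homogeneity over the central culture region
#'
#' Maximum relative deviation of `B_Z` from its center value over the
#' quasihomogeneity region.
#'
#' @param map Field map from [pair_field_map()].
#' @param region_halfwidth Half-width of the region, m; default covers the
#'   central 30% of the sampled span.
#' @return Maximum of `|Bz - Bz(0)| / |Bz(0)|` over the region (one number).
#' @export
homogeneity <- function(map, region_halfwidth = NULL) {
  span <- max(map$coord_m) - min(map$coord_m)
  region_halfwidth <- region_halfwidth %||% (0.3 * span / 2)
  inside <- abs(map$coord_m) <= region_halfwidth
  if (!any(inside)) abort("empty homogeneity region")
  b0 <- map$Bz_mT[which.min(abs(map$coord_m))][1]
  max(abs(map$Bz_mT[inside] - b0) / abs(b0))
}

#' Magnetic energy density
#'
#' `u = |B|^2 / (2 mu0)`.
#'
#' @param B Field magnitude in tesla.
#' @return Energy density in J/m^3.
#' @export
energy_density <- function(B) B^2 / (2 * mu0)

#' Azimuthal electric field induced by a ramping axial field
#'
#' For a spatially uniform axial field over a dish of radius at least `r`,
#' Faraday's law gives `E = (r / 2) |dB/dt|` azimuthally at radius `r`.
#'
#' @param r Radius, m.
#' @param dBdt Field ramp rate, T/s.
#' @return Electric field in V/m (linear in `r`).
#' @export
induced_e_field <- function(r, dBdt) r / 2 * abs(dBdt)

#' One-stop dosimetry report of the default (or a given) bioreactor
#'
#' @param pair Solenoid pair (default [default_bioreactor()]).
#' @param wf Current waveform (default [current_waveform()]).
#' @param dish_radius Culture-dish radius for the induced-field figure, m
#'   (17.5 mm: the edge of a 35 mm dish).
#' @return One-row tibble: `B_center_mT`, `homogeneity_pct` (over the
#'   central 30% region), `u_J_m3`, `dBdt_T_s`, `E_edge_mV_m`.
#' @export
field_report <- function(pair = default_bioreactor(), wf = current_waveform(),
                         dish_radius = 0.0175) {
  map <- pair_field_map(pair, I = wf$I_peak)
  b0 <- map$Bz_mT[map$axis == "X"][which.min(abs(map$coord_m[map$axis == "X"]))]
  dBdt <- b0 * 1e-3 / wf$rise
  tibble(
    B_center_mT = b0,
    homogeneity_pct = 100 * homogeneity(map),
    u_J_m3 = energy_density(b0 * 1e-3),
    dBdt_T_s = dBdt,
    E_edge_mV_m = 1e3 * induced_e_field(dish_radius, dBdt)
  )
}
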