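#' Micropolar fluid parameters
#'
#' The mild-stenosis reduction of the Eringen micropolar balance laws leaves
#' exactly two material groups: the coupling number `N = kappa/(mu + kappa)`
#' (strength of the coupling between microrotation and bulk shear,
#' `0 <= N < 1`) and the micropolar parameter
#' `m^2 = r0^2 (2 mu + kappa) kappa / (gamma_m (mu + kappa))` (`m > 0`),
#' which sets the thickness `~1/m` of the microrotation boundary layers.
#' `N -> 0` recovers a Newtonian fluid; large `m` confines micropolar effects
#' to thin wall layers.
#'
#' @param N Coupling number, `0 <= N < 1`.
#' @param m Micropolar parameter, `> 0`.
#' @return An object of class `"fluid_params"`.
#' @examples
#' fluid_params(N = 0.75, m = 50)
#' @export
fluid_params <- function(N = 0.75, m = 50) {
  stopifnot(is.numeric(N), length(N) == 1L, is.finite(N),
            is.numeric(m), length(m) == 1L, is.finite(m))
  if (N < 0 || N >= 1) stop("coupling number `N` must satisfy 0 <= N < 1")
  if (m <= 0) stop("micropolar parameter `m` must be > 0")
  structure(list(N = N, m = m), class = "fluid_params")
}

#' @export
print.fluid_params <- function(x, ...) {
  cat(sprintf("Micropolar fluid: coupling number N = %g, parameter m = %g\n",
              x$N, x$m))
  invisible(x)
}

## Exponentially scaled modified-Bessel basis at radius r for a station with
## outer wall h and inner wall rc.  I-terms carry exp(m (r - h)) <= 1 and
## K-terms exp(m (rc - r)) <= 1, so every matrix entry stays O(1): unscaled
## I1(m r) overflows double precision once m r exceeds ~700 and loses digits
## well before that.
scaled_basis <- function(r, h, rc, m) {
  list(I0 = besselI(m * r, 0, expon.scaled = TRUE),
       I1 = besselI(m * r, 1, expon.scaled = TRUE),
       K0 = besselK(m * r, 0, expon.scaled = TRUE),
       K1 = besselK(m * r, 1, expon.scaled = TRUE),
       fI = exp(m * (r - h)),
       fK = exp(m * (rc - r)))
}

#' Solve the micropolar annulus boundary-value problem at one station
#'
#' At a fixed axial station the annular gap `[rc, h]` carries the reduced
#' axial-momentum and angular-momentum balances, whose general solution is
#' \deqn{\nu_\theta = c_2 I_1(mr) + c_3 K_1(mr)
#'       - \frac{1-N}{2-N}\Big(\frac{c_1}{r} + \frac{r}{2}\Big)
#'         \frac{\partial p}{\partial z},}
#' \deqn{v_z = \frac{N}{m}\big(-c_2 I_0(mr) + c_3 K_0(mr)\big)
#'       + \frac{2(1-N)}{2-N}\Big(c_1 \ln r + \frac{r^2}{4}\Big)
#'         \frac{\partial p}{\partial z} + c_4,}
#' subject to `v_z(rc) = 0`, `v_z(h) = u`, and vanishing microrotation at
#' both walls.  (The sign of the pressure-gradient group in `v_z` follows
#' from integrating the momentum balance; with the opposite sign the pair
#' fails both governing equations.)
#'
#' The problem is linear in the pressure gradient `dpdz` and the wall slip
#' `u`, so the solver computes the two unit sub-problems
#' (`dpdz = 1, u = 0`) and (`dpdz = 0, u = 1`) once; any station quantity at
#' given `(dpdz, u)` is their superposition.  The first constant is stored in
#' the combined form `c1 * dpdz` (the form in which it enters every
#' expression), which keeps the unit-slip sub-problem nondegenerate.  `c2`
#' and `c3` are stored exponentially rescaled (`c2 e^{mh}`, `c3 e^{-m rc}`)
#' so that all downstream expressions combine only like-scaled,
#' overflow-free products.
#'
#' The station also carries the closed-form flux coefficients `A`, `B` with
#' `Q = A * dpdz + B * u` (see [flux_coefficients()]).
#'
#' @param h Outer (arterial wall) radius at the station.
#' @param rc Inner (catheter) radius, `0 < rc < h`.
#' @param fluid A [fluid_params()] object.
#' @param max_condition Refuse to return a solution when the boundary
#'   matrix's condition estimate exceeds this (near-closed annulus).
#' @return An object of class `"station_solution"`: list with `h`, `rc`,
#'   `fluid`, unit-sub-problem constants `cp` and `cu` (each
#'   `(c1*dpdz, c2 e^{mh}, c3 e^{-m rc}, c4)`), flux coefficients `A`, `B`,
#'   and the condition estimate `condition`.
#' @examples
#' st <- solve_station(0.9, 0.1, fluid_params(0.75, 50))
#' axial_velocity(0.5, st, dpdz = -1, u = 0.01)
#' @export
solve_station <- function(h, rc, fluid, max_condition = 1e12) {
  stopifnot(is.numeric(h), is.numeric(rc), length(h) == 1L, length(rc) == 1L,
            inherits(fluid, "fluid_params"))
  if (!(rc > 0 && rc < h))
    stop("station requires 0 < rc < h")
  N <- fluid$N; m <- fluid$m
  k <- (1 - N) / (2 - N)
  bc <- scaled_basis(rc, h, rc, m)
  bh <- scaled_basis(h,  h, rc, m)
  ## rows: nu(rc) = 0, nu(h) = 0, vz(rc) = 0, vz(h) = u
  ## unknowns: (c1*dpdz, c2 e^{mh}, c3 e^{-m rc}, c4)
  M <- rbind(
    c(-k / rc,          bc$I1 * bc$fI,        bc$K1 * bc$fK,        0),
    c(-k / h,           bh$I1 * bh$fI,        bh$K1 * bh$fK,        0),
    c(2 * k * log(rc), -(N / m) * bc$I0 * bc$fI, (N / m) * bc$K0 * bc$fK, 1),
    c(2 * k * log(h),  -(N / m) * bh$I0 * bh$fI, (N / m) * bh$K0 * bh$fK, 1))
  cond <- kappa(M, exact = FALSE)
  if (!is.finite(cond) || cond > max_condition)
    stop(sprintf(paste0("ill-conditioned boundary matrix (condition ",
                        "estimate %.3g > %.3g); annulus too thin"),
                 cond, max_condition))
  rhs <- cbind(p = c(k * rc / 2, k * h / 2, -2 * k * rc^2 / 4, -2 * k * h^2 / 4),
               u = c(0, 0, 0, 1))
  x <- solve(M, rhs)
  st <- structure(
    list(h = h, rc = rc, fluid = fluid,
         cp = x[, "p"], cu = x[, "u"], condition = cond),
    class = "station_solution")
  st$A <- station_flux(st, st$cp, dpdz = 1)
  st$B <- station_flux(st, st$cu, dpdz = 0)
  st
}

#' @export
print.station_solution <- function(x, ...) {
  cat(sprintf("Station: annulus [%g, %g], N = %g, m = %g\n",
              x$rc, x$h, x$fluid$N, x$fluid$m))
  cat(sprintf("  flux coefficients  A = %.6g (per unit dp/dz),  B = %.6g (per unit slip)\n",
              x$A, x$B))
  cat(sprintf("  boundary matrix condition estimate %.3g\n", x$condition))
  invisible(x)
}

## combined constants at given (dpdz, u) by superposition
station_constants <- function(station, dpdz, u)
  station$cp * dpdz + station$cu * u

#' Integration constants at a station
#'
#' Convenience wrapper: solves the station and returns the four integration
#' constants for given pressure gradient and slip, by superposition of the
#' unit sub-problems.  The first constant is the combined `c1 * dpdz` (well
#' defined for any `dpdz`, including 0); `c2`, `c3` are exponentially
#' rescaled as described in [solve_station()].
#'
#' @inheritParams solve_station
#' @param dpdz Axial pressure gradient.
#' @param u Wall slip velocity.
#' @return Named numeric vector `c(c1p, c2s, c3s, c4)`.
#' @export
solve_constants <- function(h, rc, fluid, dpdz = 1, u = 0) {
  st <- solve_station(h, rc, fluid)
  cc <- station_constants(st, dpdz, u)
  names(cc) <- c("c1p", "c2s", "c3s", "c4")
  cc
}

#' Axial velocity profile at a station
#'
#' Evaluates `v_z(r)` for the station solution at the given pressure
#' gradient and slip.  Satisfies `v_z(rc) = 0` and `v_z(h) = u`.
#'
#' @param r Radius (vectorized), within `[rc, h]`.
#' @param station A [solve_station()] object.
#' @param dpdz Axial pressure gradient.
#' @param u Wall slip velocity.
#' @return Numeric vector of axial velocities.
#' @export
axial_velocity <- function(r, station, dpdz, u) {
  check_radius(r, station)
  cc <- station_constants(station, dpdz, u)
  N <- station$fluid$N; m <- station$fluid$m
  k <- (1 - N) / (2 - N)
  b <- scaled_basis(r, station$h, station$rc, m)
  (N / m) * (-cc[2L] * b$I0 * b$fI + cc[3L] * b$K0 * b$fK) +
    2 * k * (cc[1L] * log(r) + r^2 / 4 * dpdz) + cc[4L]
}

#' Microrotation profile at a station
#'
#' Evaluates the microrotation component `nu_theta(r)`; vanishes at both
#' walls by construction of the boundary conditions.
#'
#' @inheritParams axial_velocity
#' @return Numeric vector of microrotation values.
#' @export
microrotation <- function(r, station, dpdz, u) {
  check_radius(r, station)
  cc <- station_constants(station, dpdz, u)
  N <- station$fluid$N; m <- station$fluid$m
  k <- (1 - N) / (2 - N)
  b <- scaled_basis(r, station$h, station$rc, m)
  cc[2L] * b$I1 * b$fI + cc[3L] * b$K1 * b$fK -
    k * (cc[1L] / r + r / 2 * dpdz)
}

## analytic d v_z / d r anywhere in the gap (I0' = I1, K0' = -K1)
velocity_gradient <- function(r, station, dpdz, u) {
  cc <- station_constants(station, dpdz, u)
  N <- station$fluid$N; m <- station$fluid$m
  k <- (1 - N) / (2 - N)
  b <- scaled_basis(r, station$h, station$rc, m)
  -N * (cc[2L] * b$I1 * b$fI + cc[3L] * b$K1 * b$fK) +
    2 * k * (cc[1L] / r + r / 2 * dpdz)
}

#' Wall velocity gradient
#'
#' Analytic radial derivative of the axial velocity, evaluated at the
#' arterial wall `r = h`; the quantity from which wall shear stress is
#' formed.
#'
#' @inheritParams axial_velocity
#' @return The scalar `d v_z / d r` at `r = h`.
#' @export
wall_velocity_gradient <- function(station, dpdz, u)
  unname(velocity_gradient(station$h, station, dpdz, u))

#' Closed-form flux coefficients of a station
#'
#' The volumetric flux through the annulus, `Q = int 2 r v_z dr` over
#' `[rc, h]`, is linear in the pressure gradient and the slip:
#' `Q = A * dpdz + B * u`.  `A` and `B` are evaluated in closed form from the
#' termwise antiderivatives `int r I0(mr) dr = (r/m) I1(mr)`,
#' `int r K0(mr) dr = -(r/m) K1(mr)` and
#' `int 2 r ln r dr = r^2 ln r - r^2/2`, combined in the same exponential
#' scaling as the constants so no overflow occurs.
#'
#' @inheritParams solve_station
#' @return List with elements `A` (flux per unit pressure gradient) and `B`
#'   (flux per unit slip).
#' @examples
#' flux_coefficients(0.9, 0.1, fluid_params(0.75, 50))
#' @export
flux_coefficients <- function(h, rc, fluid) {
  st <- solve_station(h, rc, fluid)
  list(A = st$A, B = st$B)
}

## closed-form Q for one set of combined constants at pressure gradient dpdz
station_flux <- function(station, cc, dpdz) {
  N <- station$fluid$N; m <- station$fluid$m
  k <- (1 - N) / (2 - N)
  h <- station$h; rc <- station$rc
  bc <- scaled_basis(rc, h, rc, m)
  bh <- scaled_basis(h,  h, rc, m)
  TI <- -(2 * N / m^2) * cc[2L] * (h * bh$I1 * bh$fI - rc * bc$I1 * bc$fI)
  TK <-  (2 * N / m^2) * cc[3L] * (rc * bc$K1 * bc$fK - h * bh$K1 * bh$fK)
  Tlog <- 2 * k * (cc[1L] * ((h^2 * log(h) - h^2 / 2) -
                             (rc^2 * log(rc) - rc^2 / 2)) +
                   dpdz * (h^4 - rc^4) / 8)
  unname(TI + TK + Tlog + cc[4L] * (h^2 - rc^2))
}

check_radius <- function(r, station) {
  if (any(r < station$rc - 1e-12) || any(r > station$h + 1e-12))
    stop("radius outside the annulus [rc, h]")
  invisible(TRUE)
}
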