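#' Newtonian annulus velocity (closed-form reference)
#'
#' Classical annular Poiseuille solution of
#' `(1/r) d/dr (r dv/dr) = dpdz` with `v(rc) = 0` and `v(h) = u`:
#' `v = (dpdz/4) r^2 + C1 ln r + C2`.  This is the `N -> 0` limit of the
#' micropolar station solution and serves as an independent reference in the
#' tests and in [self_check()].
#'
#' @param r Radius (vectorized), within `[rc, h]`.
#' @param h Outer radius.
#' @param rc Inner radius, `0 < rc < h`.
#' @param dpdz Pressure gradient.
#' @param u Slip velocity at the outer wall.
#' @return Numeric vector of velocities.
#' @export
newtonian_velocity <- function(r, h, rc, dpdz, u = 0) {
  stopifnot(rc > 0, rc < h)
  ## two boundary conditions fix C1, C2
  C1 <- (u - dpdz / 4 * (h^2 - rc^2)) / log(h / rc)
  C2 <- -dpdz / 4 * rc^2 - C1 * log(rc)
  dpdz / 4 * r^2 + C1 * log(r) + C2
}

#' Newtonian annulus flux (closed form)
#'
#' Flux `Q = int 2 r v dr` of [newtonian_velocity()], by termwise
#' antiderivatives.
#'
#' @inheritParams newtonian_velocity
#' @return The scalar flux.
#' @export
newtonian_flux <- function(h, rc, dpdz, u = 0) {
  C1 <- (u - dpdz / 4 * (h^2 - rc^2)) / log(h / rc)
  C2 <- -dpdz / 4 * rc^2 - C1 * log(rc)
  dpdz / 8 * (h^4 - rc^4) +
    C1 * ((h^2 * log(h) - h^2 / 2) - (rc^2 * log(rc) - rc^2 / 2)) +
    C2 * (h^2 - rc^2)
}

#' Flux by adaptive quadrature (oracle)
#'
#' Integrates `2 r v(r)` over the annulus with tight tolerance; the
#' brute-force counterpart of the closed-form flux coefficients.
#'
#' @param velocity A function of `r` returning the axial velocity
#'   (vectorized).
#' @param rc,h Annulus radii.
#' @param abs_tol Absolute quadrature tolerance.
#' @return The scalar flux.
#' @export
quadrature_flux <- function(velocity, rc, h, abs_tol = 1e-10) {
  q <- tryCatch(
    stats::integrate(function(r) 2 * r * velocity(r), rc, h,
                     abs.tol = abs_tol, rel.tol = abs_tol,
                     subdivisions = 400L),
    error = function(e) stop("flux quadrature oracle failed: ",
                             conditionMessage(e), call. = FALSE))
  q$value
}

#' Stenosis extrema by derivative sign-scan (oracle)
#'
#' Brute-force counterpart of [stenosis_extrema()]: walks `dh/dz` across the
#' stenotic segment on a fine grid, records sign changes, and refines each
#' bracketed root by bisection to ~1e-10.  Slow by design; used to
#' cross-check the cubic-root path.
#'
#' @param geom A [geometry_params()] object with `eps > 0`.
#' @param step Scan step (must be <= 1e-5 so no pair of extrema is missed).
#' @return Numeric vector of extremum locations `(zL, zC, zR)`.
#' @export
extrema_scan <- function(geom, step = 1e-6) {
  stopifnot(inherits(geom, "geometry_params"), step <= 1e-5)
  if (geom$eps <= 0) stop("no stenosis: `eps` must be > 0")
  ## slope of the stenotic branch on the closed segment (the wall's
  ## one-sided derivative at the segment ends belongs to the taper, not to
  ## the constriction whose stationary points are sought)
  slope <- function(z) geom$zeta -
    (3 * geom$eps / 2) * stenosis_shape_d1(z - geom$gamma)
  z <- seq(geom$gamma, geom$gamma + 1, by = step)
  s <- sign(slope(z))
  exact <- z[s == 0 & z > geom$gamma & z < geom$gamma + 1]
  flip <- which(s[-1L] * s[-length(s)] < 0)
  roots <- vapply(flip, function(i) {
    lo <- z[i]; hi <- z[i + 1L]
    flo <- slope(lo)
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      fm <- slope(mid)
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1L))
  roots <- sort(c(roots, exact))
  if (length(roots) != 3L)
    stop(sprintf("degenerate geometry: scan found %d sign changes, expected 3",
                 length(roots)))
  roots
}

#' Numerical self-check of the solver identities
#'
#' Runs the package's oracle identities end to end: boundary residuals of a
#' reference station, closed-form flux versus adaptive quadrature, the
#' Newtonian limit at vanishing coupling number, extrema versus the
#' derivative sign-scan, and nontapered wall-shear symmetry.  Numerical
#' regressions in the scaled Bessel assembly are silent without this, so the
#' CLI exposes it as a subcommand.
#'
#' @param verbose Print the table.
#' @return (Invisibly) a data.frame with columns `check`, `value`, `tol`,
#'   `pass`; attribute `ok` is `TRUE` when all rows pass.
#' @examples
#' sc <- self_check(verbose = FALSE)
#' attr(sc, "ok")
#' @export
self_check <- function(verbose = TRUE) {
  fl <- fluid_params(0.75, 50)
  st <- solve_station(0.9, 0.1, fl)
  dpdz <- -1; u <- 0.01
  rows <- list()
  add <- function(check, value, tol)
    rows[[length(rows) + 1L]] <<- data.frame(check = check, value = value,
                                             tol = tol, pass = value < tol)
  add("boundary residual max",
      max(abs(c(axial_velocity(0.1, st, dpdz, u),
                axial_velocity(0.9, st, dpdz, u) - u,
                microrotation(0.1, st, dpdz, u),
                microrotation(0.9, st, dpdz, u)))), 1e-10)
  qn <- quadrature_flux(function(r) axial_velocity(r, st, dpdz, u), 0.1, 0.9)
  add("flux closed form vs quadrature (rel)",
      abs((st$A * dpdz + st$B * u - qn) / qn), 1e-8)
  stn <- solve_station(0.9, 0.1, fluid_params(1e-6, 50))
  r <- seq(0.1, 0.9, length.out = 41L)
  add("Newtonian limit max-abs (N = 1e-6)",
      max(abs(axial_velocity(r, stn, dpdz, u) -
              newtonian_velocity(r, 0.9, 0.1, dpdz, u))), 1e-4)
  geom <- geometry_params(eps = 0.1, rc = 0.1, zeta = 0)
  ex <- stenosis_extrema(geom)
  add("extrema vs sign-scan",
      max(abs(c(ex$zL, ex$zC, ex$zR) - extrema_scan(geom, step = 1e-5))),
      1e-6)
  flow <- flow_conditions(1, 0.01)
  add("nontapered wall-shear symmetry",
      abs(wall_shear_stress_at(ex$zL, geom, fl, flow) -
          wall_shear_stress_at(ex$zR, geom, fl, flow)), 1e-9)
  out <- do.call(rbind, rows)
  attr(out, "ok") <- all(out$pass)
  if (verbose) {
    print(out, row.names = FALSE)
    cat(if (all(out$pass)) "All self-checks passed.\n"
        else "SELF-CHECK FAILURE\n")
  }
  invisible(out)
}
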