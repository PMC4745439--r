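#' Geometry of a catheterized tapered artery with an overlapping stenosis
#'
#' Bundles and validates the nondimensional parameters that define the annular
#' flow domain at every axial station.  Lengths are scaled by the unconstricted
#' arterial radius `r0`, axial positions by the stenosis length `L1`, so the
#' artery spans `z` in `[0, 1/Gamma]` and the stenotic segment occupies
#' `[gamma, gamma + 1]`.
#'
#' The taper may be given either as the taper angle `phi` (radians; the taper
#' parameter is `zeta = tan(phi)`) or directly as `zeta`; supplying both is an
#' error.  `phi < 0` is a converging artery, `phi > 0` diverging, `phi = 0`
#' nontapered.
#'
#' @param eps Stenosis height parameter (fraction of `r0`, >= 0).  The actual
#'   depth of the constriction at the two humps is about `1.26 * eps` and
#'   `0.75 * eps` at the central saddle; see [stenosis_extrema()].
#' @param gamma Axial position where the stenosis begins (`L0/L1`).
#' @param Gamma Stenosis length as a fraction of the artery length (`L1/L`),
#'   in `(0, 1]`.
#' @param rc Catheter radius (fraction of `r0`); must leave the annulus open,
#'   `rc < min h(z)`.
#' @param phi Taper angle in radians, or `NULL` if `zeta` is given.
#' @param zeta Taper parameter `tan(phi)`, or `NULL` if `phi` is given.  When
#'   both are `NULL` the artery is nontapered (`zeta = 0`).
#' @return An object of class `"geometry_params"`: a list with elements
#'   `zeta`, `phi` (`NA` when the taper was given as `zeta`), `eps`, `gamma`,
#'   `Gamma`, `rc`.
#' @examples
#' geom <- geometry_params(eps = 0.1, rc = 0.1)
#' artery_radius(1, geom)
#' @seealso [artery_radius()], [stenosis_extrema()]
#' @export
geometry_params <- function(eps = 0.1, gamma = 0.5, Gamma = 0.5, rc = 0.1,
                            phi = NULL, zeta = NULL) {
  if (!is.null(phi) && !is.null(zeta))
    stop("supply either `phi` or `zeta`, not both (overdetermined taper)")
  if (is.null(zeta)) zeta <- if (is.null(phi)) 0 else tan(phi)
  for (nm in c("eps", "gamma", "Gamma", "rc", "zeta"))
    if (!is.numeric(get(nm)) || length(get(nm)) != 1L || !is.finite(get(nm)))
      stop("`", nm, "` must be a finite numeric scalar")
  if (eps < 0) stop("`eps` must be >= 0")
  if (Gamma <= 0 || Gamma > 1) stop("`Gamma` must lie in (0, 1]")
  if (gamma < 0) stop("`gamma` must be >= 0")
  if (gamma + 1 > 1 / Gamma + 1e-12)
    stop("stenosis [gamma, gamma + 1] must lie inside the artery [0, 1/Gamma]")
  if (rc <= 0) stop("`rc` must be > 0")
  geom <- structure(
    list(zeta = zeta, phi = if (is.null(phi)) NA_real_ else phi,
         eps = eps, gamma = gamma, Gamma = Gamma, rc = rc),
    class = "geometry_params")
  hmin <- min_radius(geom)
  if (rc >= hmin)
    stop(sprintf("catheter radius rc = %g closes the annulus (min h = %g)",
                 rc, hmin))
  geom
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("Artery geometry (nondimensional)\n")
  cat(sprintf("  taper        zeta = %g%s\n", x$zeta,
              if (is.na(x$phi)) "" else sprintf(" (phi = %g rad)", x$phi)))
  cat(sprintf("  stenosis     eps = %g on [%g, %g]\n", x$eps, x$gamma,
              x$gamma + 1))
  cat(sprintf("  artery span  [0, %g]   catheter rc = %g\n", 1 / x$Gamma, x$rc))
  invisible(x)
}

## quartic shape factor of the overlapping stenosis, u = z - gamma in [0, 1];
## vanishes at u = 0 and u = 1 (11 - 47 + 72 - 36 = 0), so h is continuous.
stenosis_shape <- function(u) 11 * u - 47 * u^2 + 72 * u^3 - 36 * u^4

stenosis_shape_d1 <- function(u) 11 - 94 * u + 216 * u^2 - 144 * u^3

#' Annular radius of the arterial wall
#'
#' Evaluates the nondimensional wall profile
#' `h(z) = 1 + zeta*z - (3 eps / 2) * (11u - 47u^2 + 72u^3 - 36u^4)` with
#' `u = z - gamma` inside the stenotic segment, and `h(z) = 1 + zeta*z`
#' elsewhere.  The quartic bracket vanishes at both ends of the segment, so
#' the profile is continuous.
#'
#' @param z Axial position(s) in `[0, 1/Gamma]` (units of the stenosis
#'   length).
#' @param geom A [geometry_params()] object.
#' @param check When `TRUE` (default) error if `z` leaves the artery or the
#'   annulus closes (`h <= rc`).
#' @return Numeric vector of annular radii `h(z)`.
#' @examples
#' geom <- geometry_params(eps = 0.1, rc = 0.1)
#' artery_radius(c(0.2, 1), geom)   # 1 outside the stenosis, 0.925 at the saddle
#' @export
artery_radius <- function(z, geom, check = TRUE) {
  stopifnot(inherits(geom, "geometry_params"))
  if (check && (any(z < -1e-12) || any(z > 1 / geom$Gamma + 1e-12)))
    stop("`z` outside the artery [0, 1/Gamma]")
  h <- 1 + geom$zeta * z
  inside <- z > geom$gamma & z < geom$gamma + 1
  u <- z[inside] - geom$gamma
  h[inside] <- h[inside] - (3 * geom$eps / 2) * stenosis_shape(u)
  if (check && any(h <= geom$rc))
    stop(sprintf("annulus closed: h(z) <= rc at z = %g",
                 z[which(h <= geom$rc)[1L]]))
  h
}

## dh/dz, used by the extrema search, the scan oracle and Newton polishing
artery_radius_d1 <- function(z, geom) {
  d <- rep(geom$zeta, length(z))
  inside <- z > geom$gamma & z < geom$gamma + 1
  u <- z[inside] - geom$gamma
  d[inside] <- d[inside] - (3 * geom$eps / 2) * stenosis_shape_d1(u)
  d
}

## smallest annular radius over the artery: candidates are the stenosis
## extrema (when they exist), the segment ends and the artery ends
min_radius <- function(geom) {
  cand <- c(0, geom$gamma, geom$gamma + 1, 1 / geom$Gamma)
  if (geom$eps > 0) {
    u <- extremum_roots(geom$zeta, geom$eps)
    cand <- c(cand, geom$gamma + u)
  }
  min(artery_radius(cand, geom, check = FALSE))
}

## real roots in (0,1) of 144u^3 - 216u^2 + 94u - 11 + 2 zeta/(3 eps) = 0,
## polished by Newton iteration on dh/dz (up to 3 roots, ascending)
extremum_roots <- function(zeta, eps, tol = 1e-9) {
  stopifnot(eps > 0)
  rt <- polyroot(c(-11 + 2 * zeta / (3 * eps), 94, -216, 144))
  u <- Re(rt[abs(Im(rt)) < 1e-8])
  u <- sort(u[u > tol & u < 1 - tol])
  ## Newton on g(u) = zeta - (3 eps/2) S'(u); g'(u) = -(3 eps/2) S''(u)
  for (i in seq_along(u)) {
    for (iter in 1:50) {
      g  <- zeta - (3 * eps / 2) * stenosis_shape_d1(u[i])
      gp <- -(3 * eps / 2) * (-94 + 432 * u[i] - 432 * u[i]^2)
      step <- g / gp
      u[i] <- u[i] - step
      if (abs(step) < 1e-13) break
    }
  }
  u
}

#' Locations and radii of the stenosis extrema
#'
#' The overlapping stenosis has two depth maxima (`zL`, `zR`) separated by a
#' central saddle (`zC`).  They are the stationary points of `h(z)`, i.e. the
#' roots in `(0, 1)` of the cubic
#' `144 u^3 - 216 u^2 + 94 u - 11 + 2 zeta / (3 eps) = 0`, `u = z - gamma`.
#' Roots are found from the cubic (companion-matrix solve via [polyroot()])
#' and polished to ~1e-12 by Newton iteration on `dh/dz`.
#'
#' For a nontapered artery the cubic factors through `u = 1/2`, so
#' `zL + zR = 2 zC` and the two humps have equal radii.  A taper too steep
#' for the stated `eps` (fewer than three real roots in `(0,1)`) is a
#' degenerate geometry and raises an error, as does `eps = 0` (no stenosis,
#' the cubic's constant term is singular).
#'
#' @param geom A [geometry_params()] object with `eps > 0`.
#' @return An object of class `"extrema_report"`: list with `zL`, `zC`, `zR`
#'   and the annular radii `hL`, `hC`, `hR` there.
#' @examples
#' ex <- stenosis_extrema(geometry_params(eps = 0.1, rc = 0.1))
#' c(ex$zL, ex$zC, ex$zR)   # 0.6882 1.0000 1.3118
#' @export
stenosis_extrema <- function(geom) {
  stopifnot(inherits(geom, "geometry_params"))
  if (geom$eps <= 0)
    stop("no stenosis: `eps` must be > 0 to locate extrema")
  u <- extremum_roots(geom$zeta, geom$eps)
  if (length(u) != 3L)
    stop(sprintf(paste0("degenerate geometry: %d extrema in (0,1) instead ",
                        "of 3 (taper too steep for eps = %g)"),
                 length(u), geom$eps))
  z <- geom$gamma + u
  h <- artery_radius(z, geom)
  structure(list(zL = z[1L], zC = z[2L], zR = z[3L],
                 hL = h[1L], hC = h[2L], hR = h[3L]),
            class = "extrema_report")
}

#' @export
print.extrema_report <- function(x, ...) {
  cat("Stenosis extrema (z, h):\n")
  cat(sprintf("  zL = %.4f  h = %.4f\n", x$zL, x$hL))
  cat(sprintf("  zC = %.4f  h = %.4f\n", x$zC, x$hC))
  cat(sprintf("  zR = %.4f  h = %.4f\n", x$zR, x$hR))
  invisible(x)
}

#' @export
as.data.frame.extrema_report <- function(x, ...) {
  data.frame(location = c("zL", "zC", "zR"),
             z = c(x$zL, x$zC, x$zR),
             h = c(x$hL, x$hC, x$hR))
}

#' Tabulate the wall profile
#'
#' Evaluates `h(z)` on a regular grid over the artery, e.g. for export or
#' plotting.
#'
#' @param geom A [geometry_params()] object.
#' @param n Number of grid points (>= 2).
#' @return A data.frame with columns `z` and `h`.
#' @export
wall_profile <- function(geom, n = 201L) {
  stopifnot(inherits(geom, "geometry_params"), n >= 2)
  z <- seq(0, 1 / geom$Gamma, length.out = n)
  data.frame(z = z, h = artery_radius(z, geom))
}
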