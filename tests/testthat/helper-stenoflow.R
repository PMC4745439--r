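## shared fixtures: all generated in code, fixed seeds

base_geom <- function(...) geometry_params(eps = 0.1, rc = 0.1, zeta = 0, ...)
base_fluid <- function() fluid_params(N = 0.75, m = 50)
base_flow <- function() flow_conditions(Q = 1, u = 0.01)

## random admissible stations (annulus + fluid + forcing)
random_stations <- function(n, seed = 42L) {
  set.seed(seed)
  data.frame(
    h = runif(n, 0.6, 1.1),
    rc = runif(n, 0.02, 0.35),
    N = runif(n, 0.05, 0.9),
    m = exp(runif(n, log(2), log(300))),
    dpdz = runif(n, -5, 5),
    u = runif(n, 0, 0.05))
}

## centered finite difference
fd <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
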