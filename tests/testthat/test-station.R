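test_that("boundary conditions hold at random admissible stations", {
  cases <- random_stations(20, seed = 101L)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    st <- solve_station(cs$h, cs$rc, fluid_params(cs$N, cs$m))
    res <- c(axial_velocity(cs$rc, st, cs$dpdz, cs$u),
             axial_velocity(cs$h, st, cs$dpdz, cs$u) - cs$u,
             microrotation(cs$rc, st, cs$dpdz, cs$u),
             microrotation(cs$h, st, cs$dpdz, cs$u))
    expect_lt(max(abs(res)), 1e-10)
  }
})

test_that("homogeneous forcing gives the zero solution", {
  st <- solve_station(0.9, 0.1, base_fluid())
  r <- seq(0.1, 0.9, length.out = 7)
  expect_equal(axial_velocity(r, st, 0, 0), rep(0, 7), tolerance = 1e-14)
  expect_equal(microrotation(r, st, 0, 0), rep(0, 7), tolerance = 1e-14)
  expect_equal(unname(solve_constants(0.9, 0.1, base_fluid(), 0, 0)),
               rep(0, 4), tolerance = 1e-14)
})

test_that("solution is the superposition of the unit sub-problems", {
  st <- solve_station(0.85, 0.15, fluid_params(0.6, 30))
  r <- seq(0.2, 0.8, length.out = 9)
  for (case in list(c(-2.5, 0.02), c(0.7, 0), c(0, 1))) {
    dpdz <- case[1L]; u <- case[2L]
    v <- dpdz * axial_velocity(r, st, 1, 0) + u * axial_velocity(r, st, 0, 1)
    expect_equal(axial_velocity(r, st, dpdz, u), v, tolerance = 1e-12)
    w <- dpdz * microrotation(r, st, 1, 0) + u * microrotation(r, st, 0, 1)
    expect_equal(microrotation(r, st, dpdz, u), w, tolerance = 1e-12)
  }
})

test_that("closed-form flux coefficients match adaptive quadrature", {
  cases <- random_stations(12, seed = 202L)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    fl <- fluid_params(cs$N, cs$m)
    st <- solve_station(cs$h, cs$rc, fl)
    qA <- quadrature_flux(function(r) axial_velocity(r, st, 1, 0),
                          cs$rc, cs$h)
    qB <- quadrature_flux(function(r) axial_velocity(r, st, 0, 1),
                          cs$rc, cs$h)
    expect_equal(st$A, qA, tolerance = 1e-8)
    expect_equal(st$B, qB, tolerance = 1e-8)
    ## and the affine flux identity for the combined forcing
    q <- quadrature_flux(function(r) axial_velocity(r, st, cs$dpdz, cs$u),
                         cs$rc, cs$h)
    expect_equal(st$A * cs$dpdz + st$B * cs$u, q, tolerance = 1e-7)
  }
})

test_that("vanishing coupling number recovers the Newtonian annulus", {
  st <- solve_station(0.9, 0.1, fluid_params(1e-6, 50))
  r <- seq(0.1, 0.9, length.out = 81)
  for (case in list(c(-1, 0), c(-1, 0.01), c(2, 0.02))) {
    vn <- newtonian_velocity(r, 0.9, 0.1, case[1L], case[2L])
    expect_lt(max(abs(axial_velocity(r, st, case[1L], case[2L]) - vn)), 1e-4)
  }
  nf <- flux_coefficients(0.9, 0.1, fluid_params(1e-6, 50))
  expect_equal(nf$A, newtonian_flux(0.9, 0.1, 1, 0), tolerance = 1e-3)
  expect_equal(nf$B, newtonian_flux(0.9, 0.1, 0, 1), tolerance = 1e-3)
})

test_that("microrotation tends to half the vorticity as coupling vanishes", {
  ## away from the m-boundary layers, 2 nu_theta ~ -dv_z/dr
  st <- solve_station(0.9, 0.1, fluid_params(1e-6, 80))
  for (r in c(0.35, 0.5, 0.65)) {
    dv <- fd(function(q) axial_velocity(q, st, -1, 0), r)
    expect_equal(microrotation(r, st, -1, 0), -dv / 2, tolerance = 1e-3)
  }
})

test_that("wall velocity gradient matches a finite-difference derivative", {
  cases <- random_stations(8, seed = 303L)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    st <- solve_station(cs$h, cs$rc, fluid_params(cs$N, cs$m))
    g <- wall_velocity_gradient(st, cs$dpdz, cs$u)
    ## one-sided stencil folded inward (the wall is the domain edge)
    h1 <- 1e-6
    gfd <- (3 * axial_velocity(cs$h, st, cs$dpdz, cs$u) -
            4 * axial_velocity(cs$h - h1, st, cs$dpdz, cs$u) +
            axial_velocity(cs$h - 2 * h1, st, cs$dpdz, cs$u)) / (2 * h1)
    expect_equal(g, gfd, tolerance = 1e-5)
  }
  st <- solve_station(0.9, 0.1, base_fluid())
  expect_identical(wall_velocity_gradient(st, 0, 0), 0)
})

test_that("flux coefficients are continuous in the wall radius", {
  fl <- base_fluid()
  for (h in c(0.7, 0.9, 1.05)) {
    A0 <- flux_coefficients(h, 0.1, fl)$A
    A1 <- flux_coefficients(h + 1e-8, 0.1, fl)$A
    expect_lt(abs(A1 - A0) / abs(A0), 1e-5)
  }
})

test_that("exponential scaling keeps large-m stations finite and accurate", {
  ## unscaled I1(m h) here is ~1e310 and would overflow
  st <- solve_station(0.9, 0.1, fluid_params(0.75, 800))
  expect_true(all(is.finite(c(st$cp, st$cu, st$A, st$B))))
  res <- c(axial_velocity(0.1, st, -1, 0.01),
           axial_velocity(0.9, st, -1, 0.01) - 0.01,
           microrotation(0.1, st, -1, 0.01),
           microrotation(0.9, st, -1, 0.01))
  expect_lt(max(abs(res)), 1e-9)
})

test_that("near-closed annulus is refused with a conditioning error", {
  expect_error(solve_station(0.9, 0.9 - 1e-11, base_fluid()),
               "ill-conditioned")
  expect_error(solve_station(0.5, 0.6, base_fluid()), "0 < rc < h")
})

test_that("radii outside the annulus are rejected", {
  st <- solve_station(0.9, 0.1, base_fluid())
  expect_error(axial_velocity(0.05, st, -1, 0), "outside the annulus")
  expect_error(microrotation(0.95, st, -1, 0), "outside the annulus")
})

test_that("fluid parameter validation enforces the admissible ranges", {
  expect_error(fluid_params(N = 1), "0 <= N < 1")
  expect_error(fluid_params(N = -0.1), "0 <= N < 1")
  expect_error(fluid_params(m = 0), "m")
  expect_silent(fluid_params(N = 0, m = 1e-3))
})
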