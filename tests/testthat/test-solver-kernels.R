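test_that("mixture properties interpolate linearly between the phases", {
  ph <- phase_pair()
  expect_equal(mixture_properties(1, ph),
               list(density = 997, viscosity = 1e-3))
  expect_equal(mixture_properties(0, ph),
               list(density = 1.2, viscosity = 1.8e-5))
  half <- mixture_properties(0.5, ph)
  expect_equal(half$density, (997 + 1.2) / 2)
  expect_equal(half$viscosity, (1e-3 + 1.8e-5) / 2)
  expect_error(mixture_properties(1.1, ph), "clip_tol")
  # bounded for arbitrary fields
  r <- matrix(runif(64), 8, 8)
  mp <- mixture_properties(r, ph)
  expect_true(all(mp$density >= 1.2 & mp$density <= 997))
})

test_that("curvature is zero for flat interfaces and uniform fields", {
  nx <- 64; ny <- 32; dx <- 1e-3; dy <- 1e-3
  r <- matrix(0, nx, ny); r[, 1:16] <- 1
  k <- interface_curvature(r, dx, dy)
  expect_lt(max(abs(k$kappa)), 1e-9)
  # uniform fields: no interface anywhere
  expect_identical(max(abs(interface_curvature(matrix(1, nx, ny),
                                               dx, dy)$kappa)), 0)
  expect_identical(max(abs(interface_curvature(matrix(0, nx, ny),
                                               dx, dy)$kappa)), 0)
})

test_that("curvature of a circular disk approximates 1/R", {
  n <- 256; L <- 0.04; dx <- L / n; R <- 0.01
  # area fractions: exact 0/1 away from the interface, subsampled within
  # a two-cell band (the solver maintains comparable geometric fractions)
  sub <- 64
  off <- ((1:sub) - 0.5) / sub
  r <- matrix(0, n, n)
  for (i in 1:n) {
    x0 <- (i - 0.5) * dx
    for (j in 1:n) {
      d <- sqrt((x0 - L / 2)^2 + ((j - 0.5) * dx - L / 2)^2)
      if (abs(d - R) < 2 * dx) {
        xx <- (i - 1 + off) * dx; yy <- (j - 1 + off) * dx
        r[i, j] <- mean(outer(xx, yy, function(x, y)
          (x - L / 2)^2 + (y - L / 2)^2 < R^2))
      } else r[i, j] <- as.numeric(d < R)
    }
  }
  k <- interface_curvature(r, dx, dx)
  iface <- r > 0.4 & r < 0.6
  kap <- k$kappa[iface]
  expect_gt(length(kap), 20)
  expect_lt(max(abs(abs(kap) - 1 / R)) / (1 / R), 0.10)
})

test_that("CSF force vanishes without surface tension or interface", {
  nx <- 32; ny <- 32
  r <- matrix(0, nx, ny); r[, 1:16] <- 1
  k <- interface_curvature(r, 1e-3, 1e-3)
  f0 <- csf_force(r, k$kappa, 0, 1e-3, 1e-3)
  expect_identical(max(abs(f0$fx)), 0)
  expect_identical(max(abs(f0$fy)), 0)
  # flat interface: kappa = 0 so the net vertical force vanishes
  f <- csf_force(r, k$kappa, 0.072, 1e-3, 1e-3)
  expect_lt(abs(sum(f$fy)), 1e-10)
})

test_that("phase advection is exact for zero velocity", {
  set.seed(7)
  r <- matrix(runif(32 * 16), 32, 16)
  out <- advect_phase_fraction(r, matrix(0, 33, 16), matrix(0, 32, 17),
                               1e-3, 1e-3, 1e-4)
  expect_identical(out$r, r)
  expect_identical(out$clipped, 0)
})

test_that("uniform translation conserves volume and moves the centroid", {
  nx <- 64; ny <- 32; dx <- 1 / nx; dy <- 1 / ny
  r <- matrix(0, nx, ny); r[20:30, 10:20] <- 1
  u <- matrix(0.8, nx + 1, ny); v <- matrix(0, nx, ny + 1)
  dt <- 0.4 * dx / 0.8
  nsteps <- 40
  rr <- r
  for (s in seq_len(nsteps)) {
    out <- advect_phase_fraction(rr, u, v, dx, dy, dt, periodic_x = TRUE,
                                 x_first = s %% 2 == 0)
    expect_lt(abs(sum(out$r) - sum(r)) / sum(r), 1e-10)
    rr <- out$r
  }
  shift_cells <- 0.8 * dt * nsteps / dx
  cx0 <- sum(r * row(r)) / sum(r)
  cx1 <- sum(rr * row(rr)) / sum(rr)
  expect_lt(abs((cx1 - cx0) - shift_cells), 1)
})

test_that("a disk survives a full solid-body rotation", {
  nx <- 128; dx <- 1 / nx
  xc <- (1:nx - 0.5) * dx
  r0 <- outer(xc, xc, function(x, y)
    as.numeric((x - 0.5)^2 + (y - 0.65)^2 < 0.15^2))
  om <- pi
  u <- -om * outer(rep(1, nx + 1), xc - 0.5)
  v <- om * outer(xc - 0.5, rep(1, nx + 1))
  dt0 <- 0.4 * dx / max(abs(u), abs(v))
  nsteps <- ceiling(2 / dt0); dt <- 2 / nsteps
  rr <- r0
  for (s in seq_len(nsteps)) {
    rr <- advect_phase_fraction(rr, u, v, dx, dx, dt,
                                x_first = s %% 2 == 0)$r
  }
  expect_lt(abs(sum(rr) - sum(r0)) / sum(r0), 1e-3)
  expect_gt(sum(pmin(rr, r0)) / sum(r0), 0.95)
})

test_that("advection rejects CFL-violating steps with a diagnostic", {
  r <- matrix(0.5, 16, 16)
  u <- matrix(2, 17, 16); v <- matrix(0, 16, 17)
  expect_error(advect_phase_fraction(r, u, v, 1e-3, 1e-3, 1e-3),
               "CFL violation")
})

test_that("stable timestep combines CFL, capillary and viscous limits", {
  proto <- agitation_protocol(0.02, 0)
  num <- numerics_config(cfl = 0.3, capillary_safety = 1)
  # capillary limit with both phases at 997 (the closed-form check)
  ph_heavy <- phase_pair(fluid_phase(997, 1e-3), fluid_phase(997, 1e-3),
                         0.072)
  expect_equal(stable_dt(0, 1e-3, 1e-3, ph_heavy, proto, num),
               sqrt(997 * (1e-3)^3 / (2 * pi * 0.072)), tolerance = 1e-12)
  expect_equal(stable_dt(0, 1e-3, 1e-3, ph_heavy, proto, num), 1.4846e-3,
               tolerance = 1e-4)
  # CFL limit dominates at high speed
  ph <- phase_pair()
  expect_equal(stable_dt(0.45, 1e-3, 1e-3, phase_pair(surface_tension = 0),
                         proto, num), 0.3 * 1e-3 / 0.45, tolerance = 1e-12)
  expect_equal(0.3 * 1e-3 / 0.45, 6.67e-4, tolerance = 1e-3)
  # monotone: faster flow, more tension, finer grid all shrink dt
  base <- stable_dt(0.1, 1e-3, 1e-3, ph, proto, num)
  expect_lte(stable_dt(0.2, 1e-3, 1e-3, ph, proto, num), base)
  expect_lte(stable_dt(0.1, 5e-4, 5e-4, ph, proto, num), base)
  expect_lte(stable_dt(0.1, 1e-3, 1e-3,
                       phase_pair(surface_tension = 0.144), proto, num),
             base)
  # quiescent field with active forcing: forcing velocity scale bounds dt
  p40 <- agitation_protocol(0.02, 40)
  expect_lte(stable_dt(0, 1e-3, 1e-3, phase_pair(surface_tension = 0),
                       p40, num), 0.3 * 1e-3 / (0.02 * p40$omega) + 1e-15)
})
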