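make_state <- function(nx = 8, ny = 8, geo = container_geometry()) {
  st <- initial_state(geo, grid = grid_spec(nx, ny))
  st
}

test_that("volume-averaged velocity matches trivial cases and the oracle", {
  st <- make_state()
  expect_identical(volume_avg_velocity(st), 0)
  # uniform velocity in the whole domain: liquid-weighted mean is U
  st$u[] <- 0.25
  expect_equal(volume_avg_velocity(st), 0.25, tolerance = 1e-14)
  # random fields: equal to the naive cell loop to 1e-12
  set.seed(42)
  for (k in 1:3) {
    st$u <- matrix(rnorm(9 * 8, sd = 0.1), 9, 8)
    st$v <- matrix(rnorm(8 * 9, sd = 0.1), 8, 9)
    st$r <- matrix(runif(64), 8, 8)
    expect_equal(volume_avg_velocity(st), naive_vol_avg_velocity(st),
                 tolerance = 1e-12)
  }
  st$r[] <- 0
  expect_error(volume_avg_velocity(st), "no liquid")
})

test_that("wall shear stress is exact for a Couette profile", {
  geo <- container_geometry(fill_volume = 0.12 * 0.08 * 0.0299)
  st <- make_state(16, 16, geo)          # nearly full of liquid
  gam <- 100
  dy <- st$dy
  yc <- (1:16 - 0.5) * dy
  for (j in 1:16) st$u[, j] <- gam * yc[j]
  w <- wall_shear_stress(st)
  bottom <- w$faces[w$faces$wall == "bottom", ]
  expect_equal(unique(round(bottom$tau, 12)), 1e-3 * gam,
               tolerance = 1e-12)       # tau = mu gamma = 0.1 Pa exactly
  expect_equal(pa_to_dyne_cm2(0.21), 2.1)
})

test_that("still fluid has zero wall shear stress everywhere", {
  w <- wall_shear_stress(make_state())
  expect_identical(w$wall_avg_wss, 0)
  expect_identical(w$max_wss, 0)
})

test_that("WSS aggregates match the naive loop and scale with viscosity", {
  set.seed(11)
  st <- make_state()
  st$u <- matrix(rnorm(9 * 8, sd = 0.2), 9, 8)
  st$v <- matrix(rnorm(8 * 9, sd = 0.2), 8, 9)
  st$r <- matrix(runif(64), 8, 8)
  w <- wall_shear_stress(st)
  o <- naive_wall_wss(st)
  expect_equal(w$wall_avg_wss, o$avg, tolerance = 1e-12)
  expect_equal(w$max_wss, o$max, tolerance = 1e-12)
  # tau = mu * rate: frozen kinematics, doubled liquid viscosity
  st2 <- st
  st2$phases <- phase_pair(fluid_phase(997, 2e-3),
                           fluid_phase(1.2, 3.6e-5), 0.072)
  w2 <- wall_shear_stress(st2)
  expect_equal(w2$wall_avg_wss, 2 * w$wall_avg_wss, tolerance = 1e-12)
})

test_that("interface geometry recovers flat and tilted planes", {
  geo <- container_geometry()
  st <- initial_state(geo, grid = grid_spec(64, 32))
  ig <- interface_geometry(st)
  expect_equal(ig$interface_length, geo$W1, tolerance = 1e-9)
  expect_equal(ig$interface_area, geo$W1 * geo$L1, tolerance = 1e-9)
  expect_equal(ig$v_interface, 0)

  # tilted plane: length = W1 / cos(theta) within 1% on a fine grid
  theta <- atan(0.08)                    # gentle tilt staying in-domain
  st2 <- initial_state(geo, grid = grid_spec(128, 128),
                       elevation = function(x)
                         geo$H2 + (x - geo$W1 / 2) * tan(theta))
  ig2 <- interface_geometry(st2)
  expect_equal(ig2$interface_length, geo$W1 / cos(theta),
               tolerance = 0.01)

  # uniform velocity: interface-averaged speed equals it
  st$u[] <- 0.123
  expect_equal(interface_geometry(st)$v_interface, 0.123,
               tolerance = 1e-10)

  # no 0.5 crossing: flagged
  st$r[] <- 1
  expect_true(interface_geometry(st)$flagged)
})

test_that("interface length is bounded below by the coexistence width", {
  run <- cached_small_run()
  d <- run$diagnostics
  expect_true(all(d$interface_length >= run$geometry$W1 * 0.99))
})

test_that("cycle windows discard the start-up cycle", {
  proto <- agitation_protocol(0.02, 20, 5L)
  tt <- seq(0, 15, 0.01)
  series <- tibble::tibble(t = tt, cycle = pmin(floor(tt / 3) + 1, 5))
  w <- cycle_windows(series, proto)
  expect_equal(nrow(w$windows), 5)
  expect_equal(w$windows$t_start, c(0, 3, 6, 9, 12))
  expect_identical(w$steady_cycles, 2:5)
  expect_error(cycle_windows(series[series$t < 5, ], proto), "two full")
  w0 <- cycle_windows(series, agitation_protocol(0.02, 0))
  expect_equal(nrow(w0$windows), 1)
})

test_that("steady summaries match hand-computed means and variances", {
  proto <- agitation_protocol(0.02, 20, 3L)
  tt <- seq(0, 9, 0.05)
  cyc <- pmin(floor(tt / 3) + 1L, 3L)
  # constant series: mean = c, variance = 0
  s1 <- tibble::tibble(t = tt, cycle = cyc, vol_avg_speed = 0.2,
                       wall_avg_wss = 0.1, max_liquid_speed = 0.2,
                       max_wss = 0.1, interface_area = 0.01,
                       v_interface = 0.2)
  w <- cycle_windows(s1, proto)
  sm <- summarize_cycles(s1, w, 20)
  expect_equal(sm$mean_speed, 0.2)
  expect_equal(sm$var_speed, 0)
  expect_gte(sm$peak_speed, sm$mean_speed)
  # per-cycle means {1, 3}: mean 2, sample variance 2
  s2 <- s1
  s2$vol_avg_speed <- ifelse(s2$cycle == 2, 1, 3)
  sm2 <- summarize_cycles(s2, w, 20)
  expect_equal(sm2$mean_speed, 2, tolerance = 0.01)
  expect_equal(sm2$var_speed, 2, tolerance = 1e-12)
})

test_that("peak speed occurs near maximum displacement of the cycle", {
  run <- cached_small_run()
  d <- run$diagnostics
  steady <- d[d$cycle == 2, ]
  tpk <- steady$t_over_T[which.max(steady$max_liquid_speed)]
  # velocity maxima cluster near t/T = 0.5 and 0.9 (extremes of the
  # container displacement); allow the neighborhood of either
  expect_true(min(abs(tpk - 0.5), abs(tpk - 0.9), abs(tpk - 1)) < 0.25)
})
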