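# Short solver runs probing the dynamical contracts on small grids; the
# full-scale study-condition properties live in test-acceptance.R.

test_that("a quiescent liquid stays in discrete hydrostatic equilibrium", {
  geo <- container_geometry()
  run <- run_simulation(geo, protocol = agitation_protocol(0.02, 0),
                        grid = grid_spec(48, 16),
                        static_shortcut = FALSE, duration = 1)
  st <- run$final_state
  expect_lt(max(abs(st$u), abs(st$v)), 1e-8)
  # pressure profile matches the face-density hydrostatic integral to 0.1%
  rho <- mixture_properties(st$r, st$phases)$density
  dy <- st$dy
  for (i in c(1, 24, 48)) {
    pe <- numeric(16)
    pe[16] <- rho[i, 16] * 9.81 * dy / 2
    for (j in 15:1) pe[j] <- pe[j + 1] + 9.81 * dy * (rho[i, j] +
                                                        rho[i, j + 1]) / 2
    expect_lt(max(abs(st$p[i, ] - pe)) / max(pe), 1e-3)
  }
})

test_that("unagitated runs short-circuit to the static solution", {
  run <- run_simulation(protocol = agitation_protocol(0.02, 0))
  d <- run$diagnostics
  expect_true(all(d$vol_avg_speed == 0))
  expect_true(all(d$max_wss == 0))
  expect_equal(unique(d$interface_length), run$geometry$W1)
  expect_match(run$log, "static")
})

test_that("a short forced run conserves volume, boundedness and periodicity", {
  run <- cached_small_run()        # 20 rpm, 2 cycles, 48x16
  d <- run$diagnostics
  expect_true(all(run$final_state$r >= 0 & run$final_state$r <= 1))
  drift <- abs(d$liquid_volume - d$liquid_volume[1]) / d$liquid_volume[1]
  expect_lt(max(drift), 5e-3)
  expect_lt(sum(d$clipped), 1e-8)
  expect_lt(max(d$div_max[-1]) * max(d$dt), 1e-6)
  expect_true(all(diff(d$t) > 0))
  # interface stays sharp: mixed band no wider than ~3 cells
  band <- d$mixed_cells * (run$geometry$W1 / run$grid$nx) *
    (run$geometry$H_total / run$grid$ny) / d$interface_length
  expect_lt(mean(band[-1]), 3 * run$geometry$H_total / run$grid$ny)
})

test_that("snapshots land at the requested normalized cycle times", {
  run <- cached_small_run()
  tt <- vapply(run$snapshots, `[[`, numeric(1), "t")
  expect_length(tt, 10)                      # 5 per cycle x 2 cycles
  Tc <- run$protocol$T_cycle
  frac <- sort(unique(round((tt / Tc) %% 1, 6)))
  expect_equal(frac, c(0.1, 0.3, 0.5, 0.7, 0.9), tolerance = 1e-5)
})

test_that("reruns with identical configuration are bit-identical", {
  proto <- agitation_protocol(0.02, 20, 1L)
  r1 <- run_simulation(protocol = proto, grid = grid_spec(24, 8),
                       snapshot_norm_times = NULL)
  r2 <- run_simulation(protocol = proto, grid = grid_spec(24, 8),
                       snapshot_norm_times = NULL)
  expect_identical(r1$diagnostics, r2$diagnostics)
  expect_identical(r1$final_state$r, r2$final_state$r)
})

test_that("piso_step advances a state and stays solenoidal", {
  st <- initial_state(container_geometry(), grid = grid_spec(24, 8))
  proto <- agitation_protocol(0.02, 40)
  st2 <- piso_step(st, proto, t_end = 0.05)
  expect_gt(st2$t, st$t)
  expect_true(all(is.finite(st2$u)), all(is.finite(st2$p)))
  expect_gt(max(abs(st2$u)), 0)          # forcing set the fluid in motion
  d <- attr(st2, "diagnostics")
  expect_true(is.data.frame(d))
  expect_lt(max(d$div_max), 1e-2)
  # volume unchanged through the substeps
  expect_lt(abs(sum(st2$r) - sum(st$r)) / sum(st$r), 1e-6)
})

test_that("pressure jump across a static drop approaches sigma/R", {
  # 2D cylindrical drop, no gravity: Young-Laplace dp = sigma / R
  n <- 64; L <- 0.04; R <- 0.01
  geo <- container_geometry(W1 = L, L1 = L, H_total = L,
                            fill_volume = 0.9 * pi * R^2 * L)
  st <- initial_state(geo, grid = grid_spec(n, n), gravity = 0)
  xc <- (1:n - 0.5) * (L / n)
  st$r <- outer(xc, xc, function(x, y) {
    d <- sqrt((x - L / 2)^2 + (y - L / 2)^2)
    pmin(pmax((R - d) / (L / n) + 0.5, 0), 1)
  })
  st$p <- matrix(0, n, n)
  proto <- agitation_protocol(0, 0)
  out <- pcslosh:::.vof_run_cpp(st$r, st$u, st$v, st$p, st$dx, st$dy,
                                997, 1e-3, 1.2, 1.8e-5, 0.072, 0,
                                0, 0, 0, 0.02,
                                0.3, 0.9, 2, 1e-8, 5000, 1e-3, 1,
                                numeric(0))
  expect_identical(out$status, "ok")
  d <- sqrt(outer((xc - L / 2)^2, (xc - L / 2)^2, `+`))
  p_in <- mean(out$p[d < 0.5 * R])
  p_out <- mean(out$p[d > 1.5 * R])
  expect_equal(p_in - p_out, 0.072 / R, tolerance = 0.15)
})
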