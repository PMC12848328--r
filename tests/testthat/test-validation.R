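uniform_field <- function(u, v = 0) function(t, x, y)
  cbind(rep(u, length(x)), rep(v, length(x)))

test_that("bead tracks are reproducible and exact for simple fields", {
  geo <- container_geometry()
  t1 <- generate_tracks(uniform_field(0), geo, n_beads = 5, n_frames = 20,
                        noise_px = 0, seed = 42)
  t2 <- generate_tracks(uniform_field(0), geo, n_beads = 5, n_frames = 20,
                        noise_px = 0, seed = 42)
  expect_identical(t1, t2)
  # zero field, zero noise: constant tracks
  for (b in split(t1, t1$bead)) {
    expect_lt(diff(range(b$x_px)), 1e-12)
    expect_lt(diff(range(b$y_px)), 1e-12)
  }
  # uniform field: displacement per frame = U / fps exactly
  U <- 0.01; fps <- 30
  t3 <- generate_tracks(uniform_field(U), geo, n_beads = 3, n_frames = 10,
                        fps = fps, noise_px = 0, seed = 1)
  mpp <- attr(t3, "meters_per_pixel")
  for (b in split(t3, t3$bead)) {
    expect_equal(unique(round(diff(b$x_px) * mpp, 12)), U / fps,
                 tolerance = 1e-9)
  }
  # different seeds differ
  t4 <- generate_tracks(uniform_field(0), geo, n_beads = 5, n_frames = 20,
                        noise_px = 1, seed = 7)
  t5 <- generate_tracks(uniform_field(0), geo, n_beads = 5, n_frames = 20,
                        noise_px = 1, seed = 8)
  expect_false(identical(t4$x_px, t5$x_px))
})

test_that("track velocities convert to cm/s with correct statistics", {
  geo <- container_geometry()
  U <- 0.01                               # 1 cm/s
  tr <- generate_tracks(uniform_field(U), geo, n_beads = 10, n_frames = 50,
                        noise_px = 0, seed = 2)
  vs <- tracks_to_velocity(tr)
  expect_equal(nrow(vs), 49)              # n_frames - 1
  expect_equal(unique(round(vs$mean_speed, 10)), 1, tolerance = 1e-8)
  # static tracks give zeros
  tr0 <- generate_tracks(uniform_field(0), geo, n_beads = 4, n_frames = 10,
                         noise_px = 0, seed = 3)
  expect_true(all(tracks_to_velocity(tr0)$mean_speed == 0))
})

test_that("noise-only speeds match the 2D folded-Gaussian expectation", {
  # frame-to-frame displacement of a static bead is a 2D Gaussian with
  # per-component sd sqrt(2) sigma_px; its norm has mean sd sqrt(pi/2)
  geo <- container_geometry()
  sig <- 1.5; fps <- 30
  tr <- generate_tracks(uniform_field(0), geo, n_beads = 40,
                        n_frames = 400, fps = fps, noise_px = sig,
                        seed = 10)
  vs <- tracks_to_velocity(tr)
  mpp <- attr(tr, "meters_per_pixel")
  expected <- sqrt(2) * sig * sqrt(pi / 2) * mpp * fps * 100  # cm/s
  expect_equal(mean(vs$mean_speed), expected, tolerance = 0.02)
})

test_that("a known uniform field is recovered within the 95% CI", {
  geo <- container_geometry()
  U <- 0.02                                # 2 cm/s
  tr <- generate_tracks(uniform_field(U / sqrt(2), U / sqrt(2)), geo,
                        n_beads = 20, n_frames = 600, noise_px = 0.5,
                        seed = 4)
  vs <- tracks_to_velocity(tr)
  # noise adds a positive bias to speeds; subtract its closed form
  mpp <- attr(tr, "meters_per_pixel")
  bias <- sqrt(2) * 0.5 * sqrt(pi / 2) * mpp * 30 * 100
  grand <- mean(vs$mean_speed)
  ci <- mean(vs$ci95, na.rm = TRUE)
  expect_lt(abs(sqrt(grand^2 - bias^2) - U * 100), 2 * ci + 0.05 * U * 100)
})

test_that("simulated series correlates with tracks drawn from itself", {
  run <- cached_dense_run()
  field <- field_from_run(run)
  geo <- run$geometry
  # self-comparison with zero noise
  tr0 <- generate_tracks(field, geo, n_beads = 25, n_frames = 180,
                         fps = 30, noise_px = 0, seed = 6)
  vs0 <- tracks_to_velocity(tr0)
  r0 <- compare_sim_exp(run$diagnostics, vs0)
  expect_gt(r0$r, 0.8)
  # moderate tracking noise still correlates (slow 20 rpm flow carries a
  # small signal-to-noise ratio; a lower frame rate reduces the noise
  # speed floor proportionally)
  tr1 <- generate_tracks(field, geo, n_beads = 40, n_frames = 60,
                         fps = 10, noise_px = 1, seed = 6)
  r1 <- compare_sim_exp(run$diagnostics, tracks_to_velocity(tr1))
  expect_gt(r1$r, 0.5)
  # control: time-reversed simulated series correlates worse
  rev_sim <- run$diagnostics
  rev_sim$vol_avg_speed <- rev(rev_sim$vol_avg_speed)
  rrev <- compare_sim_exp(rev_sim, vs0)
  expect_lt(abs(rrev$r), abs(r0$r))
  # non-overlapping time ranges error
  late <- vs0; late$time <- late$time + 1e4
  expect_error(compare_sim_exp(run$diagnostics, late), "overlap")
})

test_that("TrackMate-style CSV export round-trips", {
  tr <- generate_tracks(uniform_field(0.01), container_geometry(),
                        n_beads = 3, n_frames = 5, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_tracks_csv(tr, f)
  df <- read.csv(f)
  expect_named(df, c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y"))
  expect_equal(nrow(df), nrow(tr))
})

test_that("bulk metrics converge across four progressively refined grids", {
  # vigorous (40 rpm) conditions, shortened window: the finest pair of
  # meshes agrees in cycle-mean volume-averaged speed within 5%
  tab <- mesh_independence(container_geometry(), phase_pair(),
                           agitation_protocol(0.02, 40, 3L),
                           list(grid_spec(32, 12), grid_spec(48, 16),
                                grid_spec(64, 24), grid_spec(96, 32)))
  expect_true(all(tab$status == "ok"))
  expect_lt(tab$delta_speed[4], 0.05)
  expect_true(attr(tab, "converged"))
})

test_that("mesh independence table reports deltas and trivial cases", {
  geo <- container_geometry()
  # static case: all velocity metrics are zero at any resolution
  tab0 <- mesh_independence(geo, phase_pair(), agitation_protocol(0.02, 0),
                            list(grid_spec(16, 8), grid_spec(24, 8)))
  expect_true(all(tab0$mean_speed == 0))
  expect_true(all(tab0$status == "ok"))
  # identical resolutions twice: delta exactly zero
  proto <- agitation_protocol(0.02, 20, 2L)
  tab1 <- mesh_independence(geo, phase_pair(), proto,
                            list(grid_spec(24, 8), grid_spec(24, 8)))
  expect_equal(tab1$delta_speed[2], 0)
  expect_error(mesh_independence(geo, phase_pair(), proto,
                                 list(grid_spec(16, 8))), "two resolutions")
})
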