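#' Velocity-field interpolator from a completed run
#'
#' Builds a function `f(t, x, y) -> c(u, v)` (m/s) by bilinear
#' interpolation in space over the run's snapshots and linear interpolation
#' in time between them, for advecting tracer beads through simulated flow.
#'
#' @param run `pc_run` with at least two snapshots
#' @return interpolating function
#' @export
field_from_run <- function(run) {
  if (length(run$snapshots) < 2)
    stop("run has fewer than two snapshots", call. = FALSE)
  times <- vapply(run$snapshots, `[[`, numeric(1), "t")
  dx <- run$geometry$W1 / run$grid$nx
  dy <- run$geometry$H_total / run$grid$ny
  fields <- lapply(run$snapshots, function(s)
    list(uc = cell_centered_u(s$u), vc = cell_centered_v(s$v)))
  nx <- run$grid$nx; ny <- run$grid$ny

  interp2 <- function(M, x, y) {
    # bilinear on cell centers, clamped at walls
    fx <- clamp(x / dx - 0.5, 0, nx - 1)
    fy <- clamp(y / dy - 0.5, 0, ny - 1)
    i0 <- pmin(floor(fx), nx - 2); j0 <- pmin(floor(fy), ny - 2)
    tx <- fx - i0; ty <- fy - j0
    (1 - tx) * (1 - ty) * M[cbind(i0 + 1, j0 + 1)] +
      tx * (1 - ty) * M[cbind(i0 + 2, j0 + 1)] +
      (1 - tx) * ty * M[cbind(i0 + 1, j0 + 2)] +
      tx * ty * M[cbind(i0 + 2, j0 + 2)]
  }
  function(t, x, y) {
    t <- clamp(t, times[1], times[length(times)])
    k <- findInterval(t, times, rightmost.closed = TRUE)
    k <- clamp(k, 1, length(times) - 1)
    w <- (t - times[k]) / (times[k + 1] - times[k])
    u <- (1 - w) * interp2(fields[[k]]$uc, x, y) +
      w * interp2(fields[[k + 1]]$uc, x, y)
    v <- (1 - w) * interp2(fields[[k]]$vc, x, y) +
      w * interp2(fields[[k + 1]]$vc, x, y)
    cbind(u, v)
  }
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate synthetic bead tracks through a velocity field
#'
#' Emulates the particle-tracking validation experiment: tracer beads
#' seeded uniformly in the liquid region are advected by the velocity field
#' (explicit midpoint integration at the frame rate) and their recorded
#' pixel positions carry i.i.d. Gaussian localization noise of `noise_px`
#' pixels, mimicking spot-detection error.  Fully reproducible for a given
#' seed.  Beads leaving the domain have their tracks truncated.
#'
#' @param field function `(t, x, y) -> cbind(u, v)` in m/s (e.g.
#'   [field_from_run()] or an analytic field)
#' @param geometry `pc_geometry` (seeding region and pixel calibration)
#' @param n_beads number of beads (>= 1; default 20)
#' @param n_frames frames to record (default 600)
#' @param fps frame rate (1/s)
#' @param noise_px Gaussian localization noise, pixels (default 1)
#' @param meters_per_pixel calibration; default W1 spanning 480 px
#' @param seed RNG seed (required for reproducibility)
#' @return `pc_tracks`: tibble (bead, frame, x_px, y_px) with attributes
#'   `fps`, `meters_per_pixel`, `seed`, `truncated`
#' @export
generate_tracks <- function(field, geometry = container_geometry(),
                            n_beads = 20L, n_frames = 600L, fps = 30,
                            noise_px = 1, meters_per_pixel = NULL,
                            seed = 1L) {
  stopifnot(n_beads >= 1, n_frames >= 2, fps > 0, noise_px >= 0)
  if (is.null(meters_per_pixel)) meters_per_pixel <- geometry$W1 / 480
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  # seed uniformly inside the liquid layer, away from walls
  x <- runif(n_beads, 0.05 * geometry$W1, 0.95 * geometry$W1)
  y <- runif(n_beads, 0.1 * geometry$H2, 0.9 * geometry$H2)
  alive <- rep(TRUE, n_beads)
  dtf <- 1 / fps
  rows_x <- matrix(NA_real_, n_frames, n_beads)
  rows_y <- matrix(NA_real_, n_frames, n_beads)
  truncated <- integer(0)
  for (f in seq_len(n_frames)) {
    rows_x[f, alive] <- x[alive] / meters_per_pixel +
      rnorm(sum(alive), 0, noise_px)
    rows_y[f, alive] <- y[alive] / meters_per_pixel +
      rnorm(sum(alive), 0, noise_px)
    if (f == n_frames) break
    t_now <- (f - 1) * dtf
    if (any(alive)) {
      v1 <- field(t_now, x[alive], y[alive])
      xm <- x[alive] + 0.5 * dtf * v1[, 1]
      ym <- y[alive] + 0.5 * dtf * v1[, 2]
      v2 <- field(t_now + 0.5 * dtf, xm, ym)
      x[alive] <- x[alive] + dtf * v2[, 1]
      y[alive] <- y[alive] + dtf * v2[, 2]
      out <- alive & (x < 0 | x > geometry$W1 | y < 0 |
                        y > geometry$H_total)
      if (any(out)) {
        truncated <- union(truncated, which(out))
        alive[out] <- FALSE
      }
    }
  }
  long <- do.call(rbind, lapply(seq_len(n_beads), function(b) {
    keep <- !is.na(rows_x[, b])
    tibble::tibble(bead = b, frame = which(keep) - 1L,
                   x_px = rows_x[keep, b], y_px = rows_y[keep, b])
  }))
  structure(long, class = c("pc_tracks", class(long)),
            fps = fps, meters_per_pixel = meters_per_pixel, seed = seed,
            truncated = truncated)
}

#' Frame-to-frame bead speeds as a mean +/- CI series
#'
#' Per bead, the instantaneous speed between consecutive frames is
#' `|dposition| * meters_per_pixel * fps`, converted to cm/s; the series
#' reports the across-bead mean and 95% confidence half-width per frame
#' interval.  Single-frame tracks are excluded.
#'
#' @param tracks `pc_tracks`
#' @return tibble (time, mean_speed, ci95, n_beads) in cm/s
#' @export
tracks_to_velocity <- function(tracks) {
  fps <- attr(tracks, "fps")
  mpp <- attr(tracks, "meters_per_pixel")
  sp <- lapply(split(tracks, tracks$bead), function(tb) {
    if (nrow(tb) < 2) return(NULL)
    dxp <- diff(tb$x_px); dyp <- diff(tb$y_px)
    tibble::tibble(frame = tb$frame[-1],
                   speed = sqrt(dxp^2 + dyp^2) * mpp * fps * 100)  # cm/s
  })
  sp <- do.call(rbind, sp)
  if (is.null(sp)) stop("no track has two or more frames", call. = FALSE)
  agg <- lapply(split(sp$speed, sp$frame), function(v) {
    n <- length(v)
    half <- if (n > 1) qt(0.975, n - 1) * sd(v) / sqrt(n) else NA_real_
    c(mean(v), half, n)
  })
  fr <- as.integer(names(agg))
  m <- do.call(rbind, agg)
  tibble::tibble(time = fr / fps, mean_speed = m[, 1], ci95 = m[, 2],
                 n_beads = as.integer(m[, 3]))
}

#' Correlate a simulated velocity series with a bead-track series
#'
#' Resamples the simulated liquid-volume-averaged speed (m/s, converted to
#' cm/s) onto the bead-series time base by linear interpolation and
#' computes the Pearson correlation.
#'
#' @param sim diagnostics tibble of a run (`t`, `vol_avg_speed`)
#' @param exp velocity series from [tracks_to_velocity()] (cm/s)
#' @return list with `r` and `p`
#' @export
compare_sim_exp <- function(sim, exp) {
  t0 <- max(min(sim$t), min(exp$time))
  t1 <- min(max(sim$t), max(exp$time))
  if (t1 <= t0) stop("non-overlapping time ranges", call. = FALSE)
  keep <- exp$time >= t0 & exp$time <= t1
  tt <- exp$time[keep]
  sim_i <- approx(sim$t, sim$vol_avg_speed * 100, xout = tt)$y
  pearson(sim_i, exp$mean_speed[keep])
}

#' Mesh-independence study
#'
#' Runs the same protocol at progressively refined grids and tabulates the
#' steady-cycle bulk metrics with successive relative differences; the
#' study is flagged converged when the finest pair differs by < 5% in the
#' cycle-mean volume-averaged speed.
#'
#' @param geometry `pc_geometry`
#' @param phases `pc_phases`
#' @param protocol `pc_protocol`
#' @param resolutions list of `pc_grid`, coarse to fine (>= 2)
#' @param numerics `pc_numerics`
#' @param gravity gravitational acceleration (m/s^2)
#' @return tibble: one row per resolution with metrics, deltas, and a
#'   `converged` attribute; solver failures leave a partial table
#' @export
mesh_independence <- function(geometry, phases, protocol, resolutions,
                              numerics = numerics_config(),
                              gravity = 9.81) {
  if (length(resolutions) < 2)
    stop("need at least two resolutions", call. = FALSE)
  rows <- list()
  for (gr in resolutions) {
    res <- tryCatch({
      run <- run_simulation(geometry, phases, protocol, gr, numerics,
                            gravity, snapshot_norm_times = NULL)
      s <- summarize_run(run)
      tibble::tibble(nx = gr$nx, ny = gr$ny, cells = gr$nx * gr$ny,
                     mean_speed = s$mean_speed, mean_wss = s$mean_wss,
                     mean_interface_length = s$mean_area / geometry$L1,
                     status = "ok")
    }, pc_solver_error = function(e) {
      tibble::tibble(nx = gr$nx, ny = gr$ny, cells = gr$nx * gr$ny,
                     mean_speed = NA_real_, mean_wss = NA_real_,
                     mean_interface_length = NA_real_,
                     status = conditionMessage(e))
    })
    rows[[length(rows) + 1]] <- res
  }
  tab <- do.call(rbind, rows)
  rel_delta <- function(v) c(NA, abs(diff(v)) / abs(v[-length(v)]))
  tab$delta_speed <- rel_delta(tab$mean_speed)
  tab$delta_wss <- rel_delta(tab$mean_wss)
  tab$delta_interface <- rel_delta(tab$mean_interface_length)
  fin <- utils::tail(tab$delta_speed, 1)
  attr(tab, "converged") <- isTRUE(is.finite(fin) && fin < 0.05)
  tab
}

#' Export bead tracks in a TrackMate-like CSV schema
#'
#' Columns TRACK_ID, FRAME, POSITION_X, POSITION_Y (pixels).
#' @param tracks `pc_tracks`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- data.frame(TRACK_ID = tracks$bead, FRAME = tracks$frame,
                   POSITION_X = tracks$x_px, POSITION_Y = tracks$y_px)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
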