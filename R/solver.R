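#' Mixture density and viscosity fields
#'
#' Phase-fraction weighted averages: `rho = r rho_l + (1 - r) rho_g` and the
#' same form for viscosity, so both are bounded by the two phase values.
#'
#' @param r phase-fraction field (liquid = 1, gas = 0), any numeric array
#' @param phases `pc_phases`
#' @param clip_tol excursions of `r` beyond \[0,1\] larger than this raise an
#'   error
#' @return list of `density` and `viscosity` fields shaped like `r`
#' @export
mixture_properties <- function(r, phases, clip_tol = 1e-8) {
  if (any(r < -clip_tol | r > 1 + clip_tol))
    stop("phase fraction outside [0, 1] beyond clip_tol", call. = FALSE)
  r <- pmin(pmax(r, 0), 1)
  list(density = r * phases$liquid$density +
         (1 - r) * phases$gas$density,
       viscosity = r * phases$liquid$dynamic_viscosity +
         (1 - r) * phases$gas$dynamic_viscosity)
}

#' Interface normal and curvature of a phase-fraction field
#'
#' The fraction field is convolved with a small smoothing kernel (two passes
#' of a 3x3 binomial kernel, effective radius ~2 cells) before differencing;
#' face normals `n = grad(r_s)/|grad(r_s)|` are divergence-differenced to
#' `kappa = -div(n)`.  Cells whose raw fraction gradient is negligible are
#' assigned zero curvature by contract.
#'
#' @param r phase-fraction matrix (nx x ny)
#' @param dx,dy cell sizes (m)
#' @param smooth_passes smoothing kernel passes
#' @return list with `kappa` (1/m) and `grad_mag` (|grad r|, 1/m) matrices
#' @export
interface_curvature <- function(r, dx, dy, smooth_passes = 2L) {
  .curvature_cpp(r, dx, dy, as.integer(smooth_passes))
}

#' Continuum-surface-force volumetric surface-tension force
#'
#' Brackbill CSF form `F_s = sigma kappa grad(r)`: a volumetric force
#' concentrated on interface cells.  Returned at cell centers with central
#' gradients (the solver itself applies the equivalent face-based form).
#'
#' @param r phase-fraction matrix
#' @param kappa curvature matrix from [interface_curvature()]
#' @param sigma surface tension (N/m)
#' @param dx,dy cell sizes (m)
#' @return list of force density components `fx`, `fy` (N/m^3)
#' @export
csf_force <- function(r, kappa, sigma, dx, dy) {
  nx <- nrow(r); ny <- ncol(r)
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  gx[2:(nx - 1), ] <- (r[3:nx, ] - r[1:(nx - 2), ]) / (2 * dx)
  gy[, 2:(ny - 1)] <- (r[, 3:ny] - r[, 1:(ny - 2)]) / (2 * dy)
  list(fx = sigma * kappa * gx, fy = sigma * kappa * gy)
}

#' Advect the phase fraction through one timestep
#'
#' Dimensionally split geometric (PLIC) advection with Youngs normals and a
#' per-cell dilation correction; conserves liquid volume to round-off for a
#' discretely divergence-free velocity and keeps the fraction bounded for
#' CFL <= 0.5.  A CFL violation raises an error (step rejected).
#'
#' @param r phase-fraction matrix (nx x ny)
#' @param u face velocity, (nx+1) x ny (m/s)
#' @param v face velocity, nx x (ny+1) (m/s)
#' @param dx,dy cell sizes (m)
#' @param dt timestep (s)
#' @param periodic_x,periodic_y periodic wrap (test harness; production runs
#'   are wall-bounded)
#' @param x_first sweep order (alternated by the solver between steps)
#' @return list with updated `r` and the `clipped` mass fraction
#' @export
advect_phase_fraction <- function(r, u, v, dx, dy, dt,
                                  periodic_x = FALSE, periodic_y = FALSE,
                                  x_first = TRUE) {
  .advect_vof_cpp(r, u, v, dx, dy, dt, periodic_x, periodic_y, x_first)
}

#' Stability-limited timestep
#'
#' `dt = capillary_safety * min(CFL, capillary, viscous)` with
#' * CFL limit `cfl * min(dx, dy) / U` where `U = max(max|u|, a w)` (the
#'   forcing velocity scale guards against unbounded dt from a quiescent
#'   field),
#' * capillary limit `sqrt(rho_mean min(dx,dy)^3 / (2 pi sigma))` with
#'   `rho_mean` the mean of the two phase densities,
#' * explicit viscous limit `0.25 min(dx,dy)^2 min(rho/mu)` over the phases.
#'
#' @param max_speed current maximum face speed (m/s)
#' @param dx,dy cell sizes (m)
#' @param phases `pc_phases`
#' @param protocol `pc_protocol`
#' @param numerics `pc_numerics`
#' @return dt (s), strictly positive
#' @export
stable_dt <- function(max_speed, dx, dy, phases, protocol,
                      numerics = numerics_config()) {
  h <- min(dx, dy)
  U <- max(max_speed, protocol$amplitude * protocol$omega)
  dt_cfl <- if (U > 0) numerics$cfl * h / U else Inf
  sigma <- phases$surface_tension
  rho_mean <- 0.5 * (phases$liquid$density + phases$gas$density)
  dt_cap <- if (sigma > 0) sqrt(rho_mean * h^3 / (2 * pi * sigma)) else Inf
  dt_visc <- 0.25 * h^2 * min(
    phases$liquid$density / phases$liquid$dynamic_viscosity,
    phases$gas$density / phases$gas$dynamic_viscosity)
  dt <- numerics$capillary_safety * min(dt_cfl, dt_cap, dt_visc)
  stopifnot(dt > 0)
  dt
}

#' Initial solver state: liquid at rest with a flat (or perturbed) interface
#'
#' Fills the container to height `H2` with exact per-cell area fractions and
#' sets the discretely hydrostatic pressure consistent with the face-density
#' gravity discretization, so a quiescent configuration is an exact discrete
#' equilibrium.
#'
#' @param geometry `pc_geometry`
#' @param phases `pc_phases`
#' @param grid `pc_grid`
#' @param gravity gravitational acceleration (m/s^2)
#' @param elevation optional function of x (m) returning local liquid height
#'   (m); default is the flat fill height `H2`
#' @return `pc_state` list with matrices `r`, `u`, `v`, `p`, time `t`, and
#'   grid metadata
#' @export
initial_state <- function(geometry, phases = phase_pair(),
                          grid = grid_spec(), gravity = 9.81,
                          elevation = NULL) {
  nx <- grid$nx; ny <- grid$ny
  sp <- grid_spacing(grid, geometry)
  dx <- sp$dx; dy <- sp$dy
  xc <- (seq_len(nx) - 0.5) * dx
  h <- if (is.null(elevation)) rep(geometry$H2, nx) else elevation(xc)
  if (any(h < 0 | h > geometry$H_total))
    stop("elevation outside the container", call. = FALSE)
  r <- matrix(0, nx, ny)
  for (i in seq_len(nx)) {
    jf <- floor(h[i] / dy)
    fr <- h[i] / dy - jf
    if (jf > 0) r[i, seq_len(min(jf, ny))] <- 1
    if (jf < ny && fr > 0) r[i, jf + 1] <- fr
  }
  rho <- mixture_properties(r, phases)$density
  p <- matrix(0, nx, ny)
  p[, ny] <- rho[, ny] * gravity * dy / 2
  if (ny > 1) for (j in (ny - 1):1)
    p[, j] <- p[, j + 1] + gravity * dy * 0.5 * (rho[, j] + rho[, j + 1])
  structure(list(t = 0, r = r, u = matrix(0, nx + 1, ny),
                 v = matrix(0, nx, ny + 1), p = p,
                 dx = dx, dy = dy, geometry = geometry, phases = phases),
            class = "pc_state")
}

#' Advance a state through one or more PISO timesteps
#'
#' Explicit momentum predictor (limited second-order upwind advection,
#' explicit deviatoric viscous stresses, gravity, the container-frame
#' agitation force and the CSF surface-tension force) followed by
#' `n_correctors` pressure-correction projections; then geometric VOF
#' advection of the phase fraction by the corrected solenoidal velocity.
#'
#' @param state `pc_state`
#' @param protocol `pc_protocol`
#' @param numerics `pc_numerics`
#' @param gravity gravitational acceleration (m/s^2)
#' @param t_end target time (s); the solver substeps adaptively to reach it
#' @return updated `pc_state` with a `diagnostics` attribute (tibble)
#' @export
piso_step <- function(state, protocol, numerics = numerics_config(),
                      gravity = 9.81, t_end = NULL) {
  phases <- state$phases
  if (is.null(t_end)) {
    umax <- max(abs(state$u), abs(state$v))
    t_end <- state$t + stable_dt(umax, state$dx, state$dy, phases, protocol,
                                 numerics)
  }
  out <- .vof_run_cpp(state$r, state$u, state$v, state$p,
                      state$dx, state$dy,
                      phases$liquid$density, phases$liquid$dynamic_viscosity,
                      phases$gas$density, phases$gas$dynamic_viscosity,
                      phases$surface_tension, gravity,
                      protocol$amplitude, protocol$omega,
                      state$t, t_end,
                      numerics$cfl, numerics$capillary_safety,
                      numerics$n_correctors, numerics$poisson_tol,
                      numerics$max_poisson_iter,
                      dt_max(protocol), 1L, numeric(0))
  check_solver_status(out)
  new_state <- state
  new_state$t <- t_end
  new_state$r <- out$r; new_state$u <- out$u
  new_state$v <- out$v; new_state$p <- out$p
  attr(new_state, "diagnostics") <- diag_to_tibble(out$diagnostics, protocol)
  new_state
}

dt_max <- function(protocol) {
  if (protocol$frequency > 0) protocol$T_cycle / 100 else 5e-3
}

check_solver_status <- function(out) {
  if (!identical(out$status, "ok")) {
    cond <- structure(
      class = c("pc_solver_error", "error", "condition"),
      list(message = sprintf(
             "solver aborted: %s (steps = %d, last pressure residual = %g)",
             out$status, out$n_steps, out$last_residual),
           call = sys.call(-1), partial = out))
    stop(cond)
  }
  invisible(out)
}

diag_to_tibble <- function(D, protocol) {
  d <- tibble::as_tibble(as.data.frame(D))
  Tc <- protocol$T_cycle
  if (is.finite(Tc)) {
    d$cycle <- pmin(floor(d$t / Tc) + 1L, ceiling(max(d$t) / Tc))
    d$t_over_T <- d$t / Tc - (d$cycle - 1L)
  } else {
    d$cycle <- 1L
    d$t_over_T <- 0
  }
  d
}

#' Run the full two-phase agitation simulation
#'
#' Integrates `n_cycles` oscillation periods from a quiescent flat-interface
#' hydrostatic initial condition, collecting per-step diagnostics and field
#' snapshots at the requested normalized times `t/T` of each cycle.
#'
#' For `frequency = 0` the protocol is unagitated storage: by default the
#' run short-circuits to the static solution (zero velocity, flat interface,
#' hydrostatic pressure) with an analytic diagnostics series; set
#' `static_shortcut = FALSE` to integrate the quiescent state explicitly
#' over `duration` seconds (used e.g. to verify hydrostatic equilibrium).
#'
#' @param geometry `pc_geometry`
#' @param phases `pc_phases`
#' @param protocol `pc_protocol`
#' @param grid `pc_grid`
#' @param numerics `pc_numerics`
#' @param gravity gravitational acceleration (m/s^2)
#' @param snapshot_norm_times normalized times `t/T` within each cycle at
#'   which to store field snapshots (set `NULL` for none)
#' @param static_shortcut short-circuit unagitated runs to the static solve
#' @param duration run length (s) used when `frequency = 0` and
#'   `static_shortcut = FALSE`
#' @param elevation optional initial interface elevation function (see
#'   [initial_state()])
#' @return `pc_run`: list with `diagnostics` (tibble), `snapshots`,
#'   `final_state`, `protocol`, `geometry`, `grid`, `log`
#' @export
run_simulation <- function(geometry = container_geometry(),
                           phases = phase_pair(),
                           protocol = agitation_protocol(),
                           grid = grid_spec(),
                           numerics = numerics_config(),
                           gravity = 9.81,
                           snapshot_norm_times = c(0.1, 0.3, 0.5, 0.7, 0.9),
                           static_shortcut = TRUE,
                           duration = 5,
                           elevation = NULL) {
  state <- initial_state(geometry, phases, grid, gravity, elevation)

  if (protocol$frequency == 0 && static_shortcut && is.null(elevation)) {
    tt <- seq(0, duration, by = duration / 50)
    d <- tibble::tibble(
      t = tt, dt = c(0, diff(tt)), vol_avg_speed = 0, max_liquid_speed = 0,
      wall_avg_wss = 0, max_wss = 0,
      interface_length = geometry$W1,
      interface_area = geometry$W1 * geometry$L1,
      v_interface = 0,
      liquid_volume = geometry$fill_volume / geometry$L1,
      div_max = 0, cg_iters = 0, clipped = 0,
      mixed_cells = sum(state$r > 0.01 & state$r < 0.99),
      n_segments = NA_real_, centroid_x = geometry$W1 / 2,
      cycle = 1L, t_over_T = 0)
    return(structure(list(diagnostics = d, snapshots = list(),
                          final_state = state, protocol = protocol,
                          geometry = geometry, grid = grid,
                          log = "static shortcut (frequency = 0)"),
                     class = "pc_run"))
  }

  t_end <- if (protocol$frequency > 0)
    protocol$n_cycles * protocol$T_cycle else duration
  snap_times <- numeric(0)
  if (!is.null(snapshot_norm_times) && protocol$frequency > 0) {
    snap_times <- as.vector(outer(snapshot_norm_times,
                                  seq_len(protocol$n_cycles) - 1, `+`)) *
      protocol$T_cycle
    snap_times <- sort(snap_times[snap_times <= t_end])
  }
  out <- .vof_run_cpp(state$r, state$u, state$v, state$p,
                      state$dx, state$dy,
                      phases$liquid$density, phases$liquid$dynamic_viscosity,
                      phases$gas$density, phases$gas$dynamic_viscosity,
                      phases$surface_tension, gravity,
                      protocol$amplitude, protocol$omega,
                      0, t_end,
                      numerics$cfl, numerics$capillary_safety,
                      numerics$n_correctors, numerics$poisson_tol,
                      numerics$max_poisson_iter,
                      dt_max(protocol), 1L, snap_times)
  check_solver_status(out)
  d <- diag_to_tibble(out$diagnostics, protocol)
  d$interface_area <- d$interface_length * geometry$L1

  final <- state
  final$t <- t_end
  final$r <- out$r; final$u <- out$u; final$v <- out$v; final$p <- out$p

  snaps <- lapply(out$snapshots, function(s) {
    s$t_over_T <- if (protocol$frequency > 0)
      (s$t / protocol$T_cycle) %% 1 else 0
    s
  })
  vol0 <- d$liquid_volume[1]
  logtxt <- sprintf(
    paste0("steps=%d  dt range [%.3g, %.3g] s  mean Poisson iters=%.1f  ",
           "max divergence=%.3g 1/s  volume drift=%.3g  clipped total=%.3g"),
    out$n_steps, min(d$dt[-1]), max(d$dt), mean(d$cg_iters),
    max(d$div_max), (utils::tail(d$liquid_volume, 1) - vol0) / vol0,
    sum(d$clipped))
  structure(list(diagnostics = d, snapshots = snaps, final_state = final,
                 protocol = protocol, geometry = geometry, grid = grid,
                 log = logtxt),
            class = "pc_run")
}

#' @export
print.pc_run <- function(x, ...) {
  cat(sprintf("<pc_run> %g rpm, %d cycles, grid %dx%d\n",
              x$protocol$frequency, x$protocol$n_cycles,
              x$grid$nx, x$grid$ny))
  cat(" ", x$log, "\n")
  invisible(x)
}
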