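#' Liquid-volume-averaged speed of a solver state
#'
#' Phase-fraction-weighted mean of the cell-centered speed magnitude,
#' `sum(r |u|) / sum(r)`: the gas-phase velocity is physically irrelevant to
#' the stored concentrate, so averaging is liquid-weighted by default; set
#' `liquid_weighted = FALSE` for a whole-domain average.
#'
#' @param state `pc_state`
#' @param liquid_weighted weight by the liquid fraction (default) or not
#' @return mean speed (m/s)
#' @export
volume_avg_velocity <- function(state, liquid_weighted = TRUE) {
  uc <- cell_centered_u(state$u)
  vc <- cell_centered_v(state$v)
  sp <- sqrt(uc^2 + vc^2)
  if (liquid_weighted) {
    w <- sum(state$r)
    if (w <= 0) stop("no liquid in the domain", call. = FALSE)
    sum(state$r * sp) / w
  } else mean(sp)
}

cell_centered_u <- function(u) {
  nx <- nrow(u) - 1
  0.5 * (u[seq_len(nx), , drop = FALSE] + u[seq_len(nx) + 1, , drop = FALSE])
}

cell_centered_v <- function(v) {
  ny <- ncol(v) - 1
  0.5 * (v[, seq_len(ny), drop = FALSE] + v[, seq_len(ny) + 1, drop = FALSE])
}

#' Wall shear stress on the wetted container walls
#'
#' One-sided evaluation at the no-slip bottom and side walls:
#' `tau = mu |u_t| / (h/2)` using the tangential velocity at the first cell
#' center (exact for a linear profile).  Aggregates are taken over wetted
#' faces only (adjacent cell liquid fraction > 0.5) and the average is
#' face-length weighted.
#'
#' @param state `pc_state`
#' @return list with `faces` (tibble: wall, index, position, tau, wetted),
#'   `wall_avg_wss`, `max_wss` (Pa)
#' @export
wall_shear_stress <- function(state) {
  r <- state$r; nx <- nrow(r); ny <- ncol(r)
  dx <- state$dx; dy <- state$dy
  mu <- mixture_properties(r, state$phases)$viscosity
  uc <- cell_centered_u(state$u)
  vc <- cell_centered_v(state$v)

  faces <- list()
  # bottom wall: tangential = u at first interior cell center
  faces$bottom <- tibble::tibble(
    wall = "bottom", index = seq_len(nx), position = (seq_len(nx) - 0.5) * dx,
    length = dx, tau = mu[, 1] * abs(uc[, 1]) / (dy / 2),
    wetted = r[, 1] > 0.5)
  faces$left <- tibble::tibble(
    wall = "left", index = seq_len(ny), position = (seq_len(ny) - 0.5) * dy,
    length = dy, tau = mu[1, ] * abs(vc[1, ]) / (dx / 2),
    wetted = r[1, ] > 0.5)
  faces$right <- tibble::tibble(
    wall = "right", index = seq_len(ny), position = (seq_len(ny) - 0.5) * dy,
    length = dy, tau = mu[nx, ] * abs(vc[nx, ]) / (dx / 2),
    wetted = r[nx, ] > 0.5)
  fc <- do.call(rbind, faces)
  wet <- fc[fc$wetted, ]
  list(faces = fc,
       wall_avg_wss = if (nrow(wet)) sum(wet$tau * wet$length) /
         sum(wet$length) else 0,
       max_wss = if (nrow(wet)) max(wet$tau) else 0)
}

#' Convert wall shear stress between Pa and dyne/cm^2
#'
#' 1 Pa = 10 dyne/cm^2.
#' @param tau_pa stress in Pa
#' @return stress in dyne/cm^2
#' @export
pa_to_dyne_cm2 <- function(tau_pa) 10 * tau_pa

#' Gas-liquid interface geometry and interface-averaged speed
#'
#' Extracts the phase-fraction 0.5 level set of the cell-centered field by
#' marching squares (the field is padded to the walls with zero-gradient
#' ghost nodes so a flat interface spans the full width `W1`), returning the
#' contour length, the interfacial area `A = length * L1`, and the
#' contour-length-weighted mean speed magnitude along the interface.
#'
#' @param state `pc_state`
#' @return list with `interface_length` (m), `interface_area` (m^2),
#'   `v_interface` (m/s; `NA` and `flagged = TRUE` when no 0.5 crossing
#'   exists)
#' @export
interface_geometry <- function(state) {
  uc <- cell_centered_u(state$u)
  vc <- cell_centered_v(state$v)
  res <- .interface_geometry_cpp(state$r, uc, vc, state$dx, state$dy)
  list(interface_length = res$length,
       interface_area = res$length * state$geometry$L1,
       v_interface = res$v_interface,
       flagged = res$n_segments == 0)
}

#' Split a diagnostics series into oscillation-cycle windows
#'
#' Windows are `[kT, (k+1)T)`; the steady set discards cycle 1, which holds
#' the start-up transient.  Unagitated series (infinite period) form a
#' single window.
#'
#' @param series diagnostics tibble from [run_simulation()]
#' @param protocol `pc_protocol`
#' @return list with `windows` (tibble: cycle, t_start, t_end) and
#'   `steady_cycles` (integer vector)
#' @export
cycle_windows <- function(series, protocol) {
  if (!is.finite(protocol$T_cycle)) {
    return(list(windows = tibble::tibble(cycle = 1L, t_start = min(series$t),
                                         t_end = max(series$t)),
                steady_cycles = 1L))
  }
  span <- max(series$t) - min(series$t)
  if (span < 2 * protocol$T_cycle - 1e-9)
    stop("series must span at least two full periods", call. = FALSE)
  n <- floor(span / protocol$T_cycle + 1e-9)
  windows <- tibble::tibble(cycle = seq_len(n),
                            t_start = (seq_len(n) - 1) * protocol$T_cycle,
                            t_end = seq_len(n) * protocol$T_cycle)
  list(windows = windows, steady_cycles = seq.int(2L, n))
}

#' Steady-window summary of one agitated run
#'
#' Means, peaks, and across-cycle sample variances (ddof = 1 over the
#' per-cycle means) of the diagnostics over the steady cycles.  Peak speed
#' is the maximum local liquid-phase speed; peak WSS the maximum wetted-wall
#' shear stress.
#'
#' @param series diagnostics tibble
#' @param windows result of [cycle_windows()]
#' @param rpm agitation frequency label for the row
#' @return one-row tibble (`pc_cycle_summary`)
#' @export
summarize_cycles <- function(series, windows, rpm) {
  steady <- series[series$cycle %in% windows$steady_cycles, ]
  if (!nrow(steady)) steady <- series
  per_cycle <- function(col, f) {
    vapply(split(steady[[col]], steady$cycle), f, numeric(1))
  }
  cm_speed <- per_cycle("vol_avg_speed", mean)
  cm_wss <- per_cycle("wall_avg_wss", mean)
  cm_area <- per_cycle("interface_area", mean)
  cm_vi <- per_cycle("v_interface", mean)
  svar <- function(x) if (length(x) > 1) stats::var(x) else 0
  tibble::tibble(
    rpm = rpm,
    mean_speed = mean(steady$vol_avg_speed),
    mean_wss = mean(steady$wall_avg_wss),
    peak_speed = max(steady$max_liquid_speed),
    peak_wss = max(steady$max_wss),
    mean_area = mean(steady$interface_area),
    mean_v_interface = mean(steady$v_interface),
    var_speed = svar(cm_speed), var_wss = svar(cm_wss),
    var_area = svar(cm_area), var_v_interface = svar(cm_vi),
    n_steady_cycles = length(unique(steady$cycle)))
}

#' Summarize a completed run over its steady cycles
#'
#' Convenience wrapper: [cycle_windows()] + [summarize_cycles()] on a
#' `pc_run`.  For an unagitated run the single window covers the whole
#' series and all metrics are static.
#'
#' @param run `pc_run`
#' @return one-row tibble
#' @export
summarize_run <- function(run) {
  d <- run$diagnostics
  if (!"interface_area" %in% names(d))
    d$interface_area <- d$interface_length * run$geometry$L1
  w <- cycle_windows(d, run$protocol)
  summarize_cycles(d, w, run$protocol$frequency)
}
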