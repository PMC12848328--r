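#' Container geometry for the storage-bag slice
#'
#' Describes the rigid rectangular storage container: `W1` is the interior
#' extent along the agitation direction, `L1` the transverse depth (used as
#' extrusion depth for all per-area and per-volume quantities of the 2D
#' slice), and `H_total` the interior height.  The liquid height
#' `H2 = fill_volume / (W1 * L1)` and gas headspace `H1 = H_total - H2` are
#' derived.
#'
#' @param W1 interior length along the agitation direction (m)
#' @param L1 transverse interior depth (m)
#' @param H_total interior height (m)
#' @param fill_volume liquid fill volume (m^3)
#' @return An object of class `pc_geometry` with fields `W1`, `L1`,
#'   `H_total`, `fill_volume`, and derived `H2`, `H1`.
#' @examples
#' geo <- container_geometry()          # default 65 mL neonatal-scale bag
#' geo$H2 + geo$H1 == geo$H_total
#' @export
container_geometry <- function(W1 = 0.12, L1 = 0.08, H_total = 0.03,
                               fill_volume = 65e-6) {
  stopifnot(is.numeric(W1), is.numeric(L1), is.numeric(H_total),
            is.numeric(fill_volume))
  if (W1 <= 0 || L1 <= 0 || H_total <= 0 || fill_volume <= 0)
    stop("all geometry dimensions must be strictly positive", call. = FALSE)
  if (fill_volume >= W1 * L1 * H_total)
    stop("fill_volume must be smaller than the container interior volume",
         call. = FALSE)
  H2 <- fill_volume / (W1 * L1)
  structure(list(W1 = W1, L1 = L1, H_total = H_total,
                 fill_volume = fill_volume,
                 H2 = H2, H1 = H_total - H2),
            class = "pc_geometry")
}

#' @export
print.pc_geometry <- function(x, ...) {
  cat(sprintf("<pc_geometry> W1 = %g m, L1 = %g m, H_total = %g m\n",
              x$W1, x$L1, x$H_total))
  cat(sprintf("  fill = %g mL  ->  H2 = %.3g mm liquid, H1 = %.3g mm gas\n",
              x$fill_volume * 1e6, x$H2 * 1e3, x$H1 * 1e3))
  invisible(x)
}

#' A single fluid phase
#'
#' @param density mass density (kg/m^3)
#' @param dynamic_viscosity dynamic viscosity (Pa s)
#' @return `pc_fluid` object.
#' @export
fluid_phase <- function(density, dynamic_viscosity) {
  if (density <= 0 || dynamic_viscosity <= 0)
    stop("density and viscosity must be strictly positive", call. = FALSE)
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "pc_fluid")
}

#' Liquid/gas phase pair with surface tension
#'
#' Defaults are water (997 kg/m^3, 1 cP) against air (1.2 kg/m^3, 0.018 cP)
#' with a clean water-air surface tension of 0.072 N/m at ~22 degC.
#'
#' @param liquid,gas `pc_fluid` objects
#' @param surface_tension interfacial tension (N/m), >= 0
#' @return `pc_phases` object.
#' @export
phase_pair <- function(liquid = fluid_phase(997, 1e-3),
                       gas = fluid_phase(1.2, 1.8e-5),
                       surface_tension = 0.072) {
  stopifnot(inherits(liquid, "pc_fluid"), inherits(gas, "pc_fluid"))
  if (surface_tension < 0)
    stop("surface_tension must be >= 0", call. = FALSE)
  structure(list(liquid = liquid, gas = gas,
                 surface_tension = surface_tension),
            class = "pc_phases")
}

#' Sinusoidal agitation protocol
#'
#' Horizontal sinusoidal displacement of half-range `amplitude` at
#' `frequency` rpm; in the container-fixed frame this enters the momentum
#' equation as the body acceleration `-a w^2 sin(w t)` along x, with angular
#' frequency `w = 2 pi frequency / 60`.  `frequency = 0` denotes unagitated
#' storage.
#'
#' @param amplitude horizontal displacement half-range (m)
#' @param frequency agitation rate (rpm), >= 0
#' @param n_cycles number of oscillation cycles to simulate (>= 1)
#' @return `pc_protocol` with derived `omega` (rad/s) and `T_cycle` (s;
#'   `Inf` when frequency is 0).
#' @export
agitation_protocol <- function(amplitude = 0.02, frequency = 20,
                               n_cycles = 5L) {
  if (amplitude < 0 || frequency < 0)
    stop("amplitude and frequency must be >= 0", call. = FALSE)
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  omega <- 2 * pi * frequency / 60
  structure(list(amplitude = amplitude, frequency = frequency,
                 n_cycles = n_cycles, omega = omega,
                 T_cycle = if (frequency > 0) 60 / frequency else Inf),
            class = "pc_protocol")
}

#' Uniform grid specification for the 2D slice
#'
#' @param nx,ny cell counts along `W1` and `H_total` (each >= 8)
#' @return `pc_grid` object; `dx`/`dy` are derived once a geometry is bound
#'   via [grid_spacing()].
#' @export
grid_spec <- function(nx = 96L, ny = 32L) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 8L || ny < 8L) stop("nx and ny must each be >= 8", call. = FALSE)
  structure(list(nx = nx, ny = ny), class = "pc_grid")
}

#' @rdname grid_spec
#' @param grid a `pc_grid`
#' @param geometry a `pc_geometry`
#' @export
grid_spacing <- function(grid, geometry) {
  list(dx = geometry$W1 / grid$nx, dy = geometry$H_total / grid$ny)
}

#' Container-frame body acceleration of sinusoidal agitation
#'
#' `acc_x(t) = -a w^2 sin(w t)`: the non-inertial body force per unit mass
#' seen in the frame fixed to a container whose position is `a sin(w t)`.
#' Total function: zero amplitude or frequency give identically zero.
#'
#' @param protocol a `pc_protocol`
#' @param t time (s), vectorized
#' @return acceleration along x (m/s^2)
#' @examples
#' p <- agitation_protocol(0.02, 60)
#' body_acceleration(p, 0)                      # 0
#' body_acceleration(p, pi / 2 / p$omega)       # -a w^2
#' @export
body_acceleration <- function(protocol, t) {
  stopifnot(inherits(protocol, "pc_protocol"), all(t >= 0))
  -protocol$amplitude * protocol$omega^2 * sin(protocol$omega * t)
}

#' Reynolds number of the liquid layer
#'
#' Uses the liquid depth `H2` as characteristic length (thin-film sloshing
#' convention; override via `length_scale`).  Flows with `Re < 2300` are
#' flagged laminar.
#'
#' @param geometry `pc_geometry`
#' @param liquid `pc_fluid`
#' @param U characteristic speed (m/s), >= 0
#' @param length_scale characteristic length (m); defaults to `H2`
#' @return list with `Re` and logical `laminar`
#' @export
reynolds_number <- function(geometry, liquid, U,
                            length_scale = geometry$H2) {
  stopifnot(U >= 0, length_scale > 0)
  Re <- liquid$density * U * length_scale / liquid$dynamic_viscosity
  list(Re = Re, laminar = Re < 2300)
}

#' Stokes number of a suspended particle
#'
#' `St = rho_p d_p^2 / (18 mu T)` for a particle of density `rho_p` and
#' diameter `d_p` in a carrier fluid of viscosity `mu` with flow timescale
#' `T`.  `St << 1` means particles follow the carrier fluid, which justifies
#' treating the platelet suspension as a single homogeneous liquid.
#' Defaults are literature-typical platelet values.
#'
#' @param rho_p particle density (kg/m^3)
#' @param d_p particle diameter (m)
#' @param mu carrier dynamic viscosity (Pa s)
#' @param T_flow flow timescale (s)
#' @return dimensionless Stokes number
#' @export
stokes_number <- function(rho_p = 1060, d_p = 2e-6, mu = 1e-3, T_flow = 1) {
  if (any(c(rho_p, d_p, mu, T_flow) <= 0))
    stop("all Stokes-number inputs must be strictly positive", call. = FALSE)
  rho_p * d_p^2 / (18 * mu * T_flow)
}

#' Oxygen-permeable bag material
#'
#' @param name unique material label
#' @param otr oxygen transmission rate (cm^3 STP / m^2 / 24 h), >= 0
#' @return `pc_material` object
#' @export
bag_material <- function(name, otr) {
  if (otr < 0) stop("otr must be >= 0", call. = FALSE)
  structure(list(name = name, otr = otr), class = "pc_material")
}

#' Default bag materials: polyolefin and TOTM-plasticized PVC
#'
#' Oxygen transmission rates ~2000 and ~690 cm^3/m^2/24 h respectively.
#' @return named list of `pc_material`
#' @export
default_bag_materials <- function() {
  list(PO = bag_material("PO", 2000),
       `PVC-TOTM` = bag_material("PVC-TOTM", 690))
}
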