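#' Numerical parameters of the solver
#'
#' @param cfl Courant number target (0 < cfl <= 0.5; the bounded VOF scheme
#'   requires <= 0.5)
#' @param capillary_safety multiplicative safety factor on the stability
#'   timestep (0 < x <= 1)
#' @param n_correctors PISO pressure-correction passes (>= 2)
#' @param poisson_tol relative residual tolerance of the pressure solve
#'   (<= 1e-6)
#' @param max_poisson_iter iteration cap of the conjugate-gradient solve
#' @param clip_tol permitted out-of-bounds excursion of the phase fraction
#'   before clipping is considered an invariant violation
#' @param rng_seed reserved; the solver itself is deterministic
#' @return `pc_numerics` object
#' @export
numerics_config <- function(cfl = 0.3, capillary_safety = 0.9,
                            n_correctors = 2L, poisson_tol = 1e-8,
                            max_poisson_iter = 5000L, clip_tol = 1e-8,
                            rng_seed = NULL) {
  if (cfl <= 0 || cfl > 0.5) stop("cfl must lie in (0, 0.5]", call. = FALSE)
  if (capillary_safety <= 0 || capillary_safety > 1)
    stop("capillary_safety must lie in (0, 1]", call. = FALSE)
  n_correctors <- as.integer(n_correctors)
  if (n_correctors < 2L) stop("n_correctors must be >= 2", call. = FALSE)
  if (poisson_tol > 1e-6) stop("poisson_tol must be <= 1e-6", call. = FALSE)
  structure(list(cfl = cfl, capillary_safety = capillary_safety,
                 n_correctors = n_correctors, poisson_tol = poisson_tol,
                 max_poisson_iter = as.integer(max_poisson_iter),
                 clip_tol = clip_tol, rng_seed = rng_seed),
            class = "pc_numerics")
}

#' Assemble a full storage-simulation configuration
#'
#' Bundles geometry, fluids, agitation, numerics and bag materials; this is
#' the object the pipeline functions consume and what [read_config()]
#' produces from YAML.
#'
#' @param geometry `pc_geometry`
#' @param phases `pc_phases`
#' @param protocol `pc_protocol`
#' @param grid `pc_grid`
#' @param numerics `pc_numerics`
#' @param bag_materials named list of `pc_material`
#' @param gravity gravitational acceleration (m/s^2)
#' @param diffusivity liquid-phase oxygen diffusivity (m^2/s)
#' @param c_sat dissolved O2 concentration at the OTR reference partial
#'   pressure (mol/m^3)
#' @return `pc_config` object
#' @export
storage_config <- function(geometry = container_geometry(),
                           phases = phase_pair(),
                           protocol = agitation_protocol(),
                           grid = grid_spec(),
                           numerics = numerics_config(),
                           bag_materials = default_bag_materials(),
                           gravity = 9.81,
                           diffusivity = 2.42e-9,
                           c_sat = 1.38) {
  structure(list(geometry = geometry, phases = phases, protocol = protocol,
                 grid = grid, numerics = numerics,
                 bag_materials = bag_materials, gravity = gravity,
                 diffusivity = diffusivity, c_sat = c_sat),
            class = "pc_config")
}

known_config_keys <- list(
  geometry = c("W1", "L1", "H_total", "fill_volume"),
  fluids = c("liquid_density", "liquid_viscosity", "gas_density",
             "gas_viscosity", "surface_tension"),
  agitation = c("amplitude", "frequency", "n_cycles"),
  numerics = c("nx", "ny", "cfl", "capillary_safety", "n_correctors",
               "poisson_tol", "max_poisson_iter", "clip_tol", "rng_seed"),
  bag_materials = NULL,      # free-form name: otr map
  constants = c("gravity", "diffusivity", "c_sat")
)

#' Read a YAML configuration file
#'
#' Sections: `geometry`, `fluids`, `agitation`, `numerics`, `bag_materials`,
#' `constants`.  Every field of the corresponding constructors is
#' addressable; unknown sections or keys raise an error rather than being
#' silently ignored.
#'
#' @param path YAML file path
#' @return `pc_config`
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(known_config_keys))
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(raw)) {
    keys <- known_config_keys[[sec]]
    if (is.null(keys)) next
    badk <- setdiff(names(raw[[sec]]), keys)
    if (length(badk))
      stop("unknown key(s) in section '", sec, "': ",
           paste(badk, collapse = ", "), call. = FALSE)
  }
  g <- raw$geometry %||% list()
  geometry <- do.call(container_geometry, g)
  f <- raw$fluids %||% list()
  phases <- phase_pair(
    liquid = fluid_phase(f$liquid_density %||% 997,
                         f$liquid_viscosity %||% 1e-3),
    gas = fluid_phase(f$gas_density %||% 1.2, f$gas_viscosity %||% 1.8e-5),
    surface_tension = f$surface_tension %||% 0.072)
  a <- raw$agitation %||% list()
  protocol <- agitation_protocol(a$amplitude %||% 0.02,
                                 a$frequency %||% 20,
                                 a$n_cycles %||% 5L)
  n <- raw$numerics %||% list()
  grid <- grid_spec(n$nx %||% 96L, n$ny %||% 32L)
  numerics <- do.call(numerics_config,
                      n[setdiff(names(n), c("nx", "ny"))])
  mats <- raw$bag_materials
  bag_materials <- if (is.null(mats)) default_bag_materials() else {
    out <- lapply(names(mats), function(nm) bag_material(nm, mats[[nm]]))
    stats::setNames(out, names(mats))
  }
  cst <- raw$constants %||% list()
  storage_config(geometry = geometry, phases = phases, protocol = protocol,
                 grid = grid, numerics = numerics,
                 bag_materials = bag_materials,
                 gravity = cst$gravity %||% 9.81,
                 diffusivity = cst$diffusivity %||% 2.42e-9,
                 c_sat = cst$c_sat %||% 1.38)
}

#' Stable content hash of a configuration
#'
#' Canonicalizes by recursively sorting names, then hashes the JSON
#' serialization, so the hash is invariant under key reordering.
#'
#' @param config `pc_config` (or any list)
#' @return character md5 hash
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, canon)
      if (!is.null(names(x)) && any(nzchar(names(x))))
        x <- x[order(names(x))]
    }
    x
  }
  plain <- rapply(unclass(config), identity, how = "replace")
  js <- jsonlite::toJSON(canon(plain), auto_unbox = TRUE, digits = NA,
                         null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
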