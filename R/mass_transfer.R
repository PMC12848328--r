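#' Interface contact time of Higbie penetration theory
#'
#' `t_C = W1 / V_interface`: the residence time of a liquid element at the
#' gas-liquid interface, taken as the container width along the agitation
#' direction divided by the interface-averaged speed.  A quiescent interface
#' (`v_interface = 0`) gives an infinite contact time.
#'
#' @param W1 container width along the agitation direction (m)
#' @param v_interface interface-averaged speed (m/s), >= 0
#' @return contact time (s); `Inf` for a quiescent interface
#' @export
contact_time <- function(W1, v_interface) {
  if (W1 <= 0) stop("W1 must be > 0", call. = FALSE)
  if (any(v_interface < 0))
    stop("v_interface must be >= 0", call. = FALSE)
  ifelse(v_interface > 0, W1 / v_interface, Inf)
}

#' Higbie penetration-theory liquid-side mass-transfer coefficient
#'
#' `K_L = 2 sqrt(D / (pi t_C))`: the time-average of the unsteady
#' penetration flux over one interface renewal of duration `t_C`.
#' `K_L -> 0` as `t_C -> Inf` (stagnant interface).
#'
#' @param D liquid-phase diffusivity (m^2/s)
#' @param t_C contact time (s), > 0 or `Inf`
#' @return K_L (m/s)
#' @export
higbie_kl <- function(D, t_C) {
  if (D <= 0) stop("D must be > 0", call. = FALSE)
  if (any(t_C <= 0)) stop("t_C must be > 0", call. = FALSE)
  ifelse(is.finite(t_C), 2 * sqrt(D / (pi * t_C)), 0)
}

#' Bag-side mass-transfer coefficient from an oxygen transmission rate
#'
#' Converts a film OTR (cm^3 STP / m^2 / 24 h, measured under a 1 atm pure
#' oxygen partial-pressure difference) to a liquid-concentration-based
#' transfer coefficient: the molar flux `J = OTR * 1e-6 / (0.022414 * 86400)`
#' mol/(m^2 s) divided by the dissolved-oxygen saturation `c_sat` at the
#' same reference partial pressure.  The ratio of `K_bag` between materials
#' is independent of this driving-force convention.
#'
#' @param material `pc_material`
#' @param c_sat dissolved O2 concentration at 1 atm O2 (mol/m^3); default
#'   1.38 (Henry's law, ~22 degC water)
#' @param molar_volume molar volume at STP (m^3/mol)
#' @return K_bag (m/s)
#' @export
kbag_from_otr <- function(material, c_sat = 1.38,
                          molar_volume = 22.414e-3) {
  if (c_sat <= 0) stop("c_sat must be > 0", call. = FALSE)
  flux <- material$otr * 1e-6 / (molar_volume * 86400)  # mol / m^2 / s
  flux / c_sat
}

#' Total mass-transfer coefficient by resistances in series
#'
#' `1/K_total = 1/K_bag + 1/K_L` (`R_total = R_bag + R_L`); with no bag
#' (open-top container) `K_total = K_L`.  A zero coefficient on either side
#' gives zero total transfer.
#'
#' @param K_L liquid-side coefficient (m/s), >= 0
#' @param K_bag bag-side coefficient (m/s) or `NULL` for an open container
#' @return list with `K_total` and resistances `R_L`, `R_bag`, `R_total`
#'   (s/m; `Inf` where the coefficient is 0)
#' @export
total_mass_transfer <- function(K_L, K_bag = NULL) {
  if (K_L < 0) stop("K_L must be >= 0", call. = FALSE)
  R_L <- if (K_L > 0) 1 / K_L else Inf
  if (is.null(K_bag)) {
    return(list(K_total = K_L, R_L = R_L, R_bag = 0, R_total = R_L))
  }
  if (K_bag < 0) stop("K_bag must be >= 0", call. = FALSE)
  R_bag <- if (K_bag > 0) 1 / K_bag else Inf
  R_total <- R_L + R_bag
  K_total <- if (is.finite(R_total)) 1 / R_total else 0
  list(K_total = K_total, R_L = R_L, R_bag = R_bag, R_total = R_total)
}

#' Per-rpm, per-material mass-transfer table
#'
#' For each agitation frequency: contact time from the steady-mean
#' interface speed, Higbie `K_L`, steady-mean interfacial area `A`, and for
#' each bag material (plus the open-top "None" row) the series-resistance
#' `K_total` and the volumetric product `K_total * A`.  The unagitated row
#' uses the quiescent-interface limit `K_L = 0` exactly.
#'
#' @param summaries tibble of per-rpm cycle summaries
#'   ([summarize_run()] rows; must contain `rpm`, `mean_v_interface`,
#'   `mean_area`)
#' @param geometry `pc_geometry`
#' @param materials list of `pc_material` (default [default_bag_materials()])
#' @param D liquid diffusivity (m^2/s)
#' @param c_sat dissolved O2 saturation used for `K_bag` (mol/m^3)
#' @return tibble with one row per (rpm, material)
#' @export
mass_transfer_table <- function(summaries, geometry,
                                materials = default_bag_materials(),
                                D = 2.42e-9, c_sat = 1.38) {
  expected <- c(0, 20, 40, 60)
  if (!all(expected %in% summaries$rpm))
    warning("missing rpm levels: ",
            paste(setdiff(expected, summaries$rpm), collapse = ", "),
            "; building a partial table", call. = FALSE)
  rows <- list()
  for (k in seq_len(nrow(summaries))) {
    s <- summaries[k, ]
    vi <- if (s$rpm == 0) 0 else s$mean_v_interface
    tC <- contact_time(geometry$W1, vi)
    KL <- higbie_kl(D, tC)
    for (mat in c(list(NULL), materials)) {
      Kb <- if (is.null(mat)) NULL else kbag_from_otr(mat, c_sat)
      tot <- total_mass_transfer(KL, Kb)
      rows[[length(rows) + 1]] <- tibble::tibble(
        rpm = s$rpm, t_C = tC, K_L = KL, A = s$mean_area,
        material = if (is.null(mat)) "None" else mat$name,
        K_bag = if (is.null(mat)) NA_real_ else Kb,
        K_total = tot$K_total, K_total_A = tot$K_total * s$mean_area,
        R_L = tot$R_L, R_bag = tot$R_bag, R_total = tot$R_total)
    }
  }
  do.call(rbind, rows)
}
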