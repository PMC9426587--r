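# Cross-membrane O2 transport for a cylindrical trichome, following a
# radial series-resistance (Fick) scheme: cytoplasm | cell membrane (diffusivity
# epsilon * d_O2) | (mixed layer, segregated variant) | diffusive boundary
# layer | far field.

# dimensionless radial log-resistances of the shells
o2_resistances <- function(p) {
  if (any(unlist(p[c("R", "L_g", "L_b", "L_m", "L", "V")]) <= 0)) {
    stop("degenerate O2 diffusion geometry: all lengths must be positive")
  }
  r0 <- p$R
  r1 <- p$R + p$L_g
  list(
    membrane = (1 / p$epsilon) * log(r1 / r0),
    boundary_unified = log((r1 + p$L_b) / r1),
    boundary_mixed = log((r1 + p$L_m + p$L_b) / (r1 + p$L_m))
  )
}

# conductance (s^-1, per unit cytoplasm volume) for a total log-resistance rho
o2_conductance <- function(p, rho) {
  (2 * pi * p$d_O2 * p$L / p$V) / rho
}

#' Cross-membrane O2 exchange, unified trichome
#'
#' Net diffusive O2 flux (per unit cytoplasm volume) between the cytoplasm and
#' the far field through the cell membrane and the diffusive boundary layer in
#' series:
#' `T_O2 = -(2 pi d_O2 L / V) * \{(1/eps) ln(R/(R+L_g)) -
#'  ln((R+L_g+L_b)/(R+L_g))\}^-1 * (O2_far - O2_in)`.
#' Positive values are influx (gain of intracellular O2).
#'
#' @param O2_in intracellular O2, mol m-3.
#' @param params fixed parameters.
#' @return flux, mol O2 m-3 s-1.
#' @export
o2_exchange_unified <- function(O2_in, params) {
  stopifnot(all(O2_in >= 0))
  rho <- o2_resistances(params)
  g <- o2_conductance(params, rho$membrane + rho$boundary_unified)
  g * (params$O2_far - O2_in)
}

#' Per-compartment O2 exchange, segregated trichome
#'
#' Resistor-network exchange for the diazocyte/photosynthetic-cell variant:
#' each cell type communicates through its membrane with a common well-mixed
#' layer enveloping the trichome, which in turn communicates with the far
#' field through the boundary layer. The mixed layer is quasi-steady (no
#' storage), so its concentration is the conductance-weighted mean
#' `O2_mixed = (g_c (f_D O2_D + (1-f_D) O2_P) + g_env O2_far) / (g_c + g_env)`,
#' with membrane areas partitioned by the cell-count fractions `f_D` and
#' `1 - f_D`. With that closure, the volume-weighted sum of cell fluxes equals
#' the net trichome-environment flux exactly.
#'
#' @param O2_D,O2_P diazocyte and photosynthetic-cell O2, mol m-3.
#' @param params fixed parameters.
#' @return list with per-own-volume fluxes `flux_D`, `flux_P` (positive =
#'   gain), the net environment flux `flux_env` (per total cell volume), and
#'   the mixed-layer concentration `O2_mixed`.
#' @export
o2_exchange_segregated <- function(O2_D, O2_P, params) {
  stopifnot(all(O2_D >= 0), all(O2_P >= 0))
  rho <- o2_resistances(params)
  g_c <- o2_conductance(params, rho$membrane)
  g_env <- o2_conductance(params, rho$boundary_mixed)
  fD <- params$f_D
  O2_mixed <- (g_c * (fD * O2_D + (1 - fD) * O2_P) + g_env * params$O2_far) /
    (g_c + g_env)
  list(
    flux_D = g_c * (O2_mixed - O2_D),
    flux_P = g_c * (O2_mixed - O2_P),
    flux_env = g_env * (params$O2_far - O2_mixed),
    O2_mixed = O2_mixed
  )
}
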