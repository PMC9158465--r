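#' Surface area of a spherical cell
#'
#' Area of a sphere expressed in terms of its volume,
#' `A = (36 pi)^(1/3) V^(2/3)`. Volumes are in L (= dm^3), so the area is
#' in dm^2.
#'
#' @param V_total total cell volume, L.
#' @return Surface area, dm^2.
#' @export
surface_area <- function(V_total) {
  if (any(V_total <= 0)) stop("V_total must be positive")
  (36 * pi)^(1 / 3) * V_total^(2 / 3)
}

#' Zero-turgor volume of the elastic wall law
#'
#' The volume `V0` at which turgor vanishes, placed so that the elastic law
#' evaluated at the initial volume returns exactly the resting turgor `P_0`:
#' `V0 = V(0) * exp(-P_0 / epsilon)`.
#'
#' @param params a [biophys_params()] record.
#' @return Zero-turgor volume, L.
#' @export
zero_turgor_volume <- function(params) {
  params$V_total0 * exp(-params$P_0 / params$epsilon)
}

#' Turgor pressure as a function of total cell volume
#'
#' Elastic wall law: `P = epsilon * ln(V / V0)` for `V >= V0`, and 0 below
#' the zero-turgor volume (a flaccid wall exerts no pressure). Turgor
#' increases with volume, which is what gates the mechanosensitive channel
#' during swelling.
#'
#' @param V_total total cell volume, L (vectorised).
#' @param derived a [biophys_derived()] record.
#' @param params a [biophys_params()] record.
#' @return Turgor pressure, MPa (non-negative).
#' @export
turgor_pressure <- function(V_total, derived, params) {
  if (any(V_total <= 0)) stop("V_total must be positive")
  pmax(0, params$epsilon * log(V_total / derived$V_zero))
}

#' Initial internal osmolarity from osmotic balance at rest
#'
#' At the pre-stimulus steady state the turgor exactly balances the osmotic
#' pressure difference, giving
#' `Osm_i(0) = c_e(0) + P_0 / (c_PC * R * T)`.
#'
#' @param params a [biophys_params()] record.
#' @return Initial internal osmolarity, umol/L.
#' @export
initial_internal_osmolarity <- function(params) {
  params$c_n_e0 + params$P_0 / (params$c_PC * params$R * params$T)
}

#' Internal osmolarity at a given osmotic volume
#'
#' Non-permeable solutes are diluted/concentrated by the water volume while
#' internal glycerol is held constant:
#' `Osm_i = Gly_i + c_n_i * V_os(0) / V_os`.
#'
#' @param V_os osmotic (water) volume, L (vectorised).
#' @param derived a [biophys_derived()] record.
#' @param params a [biophys_params()] record.
#' @return Internal osmolarity, umol/L.
#' @export
internal_osmolarity <- function(V_os, derived, params) {
  if (any(V_os <= 0)) stop("V_os must be positive")
  params$Gly_i + derived$c_n_i * derived$V_os0 / V_os
}

#' External osmolarity under the dilution stimulus
#'
#' Constant at `c_e(0)` before the shock; from `t_off` it relaxes
#' exponentially (time constant `t_m`) toward `c_e(0) / d`. Extracellular
#' glycerol is held at its initial value, so it contributes no net term.
#'
#' @param t time, s (vectorised).
#' @param params a [biophys_params()] record.
#' @param protocol a [stimulus_protocol()] record.
#' @return External osmolarity, umol/L.
#' @export
external_osmolarity <- function(t, params, protocol) {
  dilution_course(t, params$c_n_e0, protocol)
}

# shared exponential dilution course for osmolarity and external calcium
dilution_course <- function(t, x0, protocol) {
  x_inf <- x0 / protocol$d
  ifelse(t < protocol$t_off,
         x0,
         (x0 - x_inf) * exp((protocol$t_off - t) / protocol$t_m) + x_inf)
}

#' Rate of change of the osmotic volume
#'
#' Water flux driven by the imbalance between turgor and the van't Hoff
#' osmotic pressure difference:
#' `dV_os/dt = -L_p * A(V) * (P(V) + c_PC R T (Osm_e - Osm_i))`.
#' Zero at the constructed resting state; positive (swelling) immediately
#' after a sufficiently large hypotonic dilution.
#'
#' @param V_os osmotic volume, L.
#' @param t time, s.
#' @param params a [biophys_params()] record.
#' @param derived a [biophys_derived()] record.
#' @param protocol a [stimulus_protocol()] record.
#' @return Volume rate, L/s.
#' @export
osmotic_volume_rate <- function(V_os, t, params, derived, protocol) {
  if (any(V_os <= 0)) stop("V_os must be positive")
  V_total <- params$V_b + V_os
  P <- turgor_pressure(V_total, derived, params)
  osm_gap <- external_osmolarity(t, params, protocol) -
    internal_osmolarity(V_os, derived, params)
  -params$L_p * surface_area(V_total) *
    (P + params$c_PC * params$R * params$T * osm_gap)
}
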