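#' Opening probability of the mechanosensitive channel
#'
#' Boltzmann gating as a function of turgor pressure:
#' `P_open = 1 - 1 / (1 + exp((P - P_MS) / g_MS))`, i.e. a logistic curve
#' with half-activation at `P_MS` and slope `g_MS`. The exponent is clipped
#' to avoid overflow; the value saturates to 0 or 1 in the tails.
#'
#' @param P turgor pressure, MPa (vectorised).
#' @param params a [kinetic_params()] record (uses `P_MS`, `g_MS`).
#' @return Opening probability in (0, 1).
#' @export
open_probability <- function(P, params) {
  z <- (P - params$P_MS) / params$g_MS
  z <- pmin(pmax(z, -700), 700)
  1 - 1 / (1 + exp(z))
}

#' Extracellular calcium under the dilution stimulus
#'
#' The extracellular pool is a reservoir: cellular uptake is negligible and
#' the concentration follows the same exponential dilution course as the
#' external osmolarity, from `Ca_ex0` toward `Ca_ex0 / d`.
#'
#' @param t time, s (vectorised).
#' @param params a [kinetic_params()] record (uses `Ca_ex0` as fallback).
#' @param protocol a [stimulus_protocol()] record; its `Ca_ex0` takes
#'   precedence when set.
#' @return Extracellular calcium, nM.
#' @export
extracellular_calcium <- function(t, params, protocol) {
  ca0 <- protocol$Ca_ex0 %||% params$Ca_ex0
  dilution_course(t, ca0, protocol)
}

#' Michaelis-Menten transport flux
#'
#' `v_max * s / (k_m + s)`; used by the Pmr1, Vcx1 and Pmc1 transporters
#' (and by the disabled unidentified influx acting on external calcium).
#' Returns 0 by convention when `k_m + s == 0`.
#'
#' @param v_max maximal rate, nM/s.
#' @param k_m Michaelis constant, nM.
#' @param s substrate concentration, nM (vectorised).
#' @return Flux, nM/s.
#' @export
michaelis_flux <- function(v_max, k_m, s) {
  denom <- k_m + s
  ifelse(denom == 0, 0, v_max * s / denom)
}

#' Gradient-driven channel flux
#'
#' Passive flux down the transmembrane concentration gradient,
#' `gate * rate * (ca_ex - ca_cyt)`. The Cch1/Mid1 channel uses `gate = 1`;
#' the mechanosensitive channel uses its Boltzmann opening probability.
#'
#' @param rate rate parameter, 1/s.
#' @param ca_ex extracellular calcium, nM.
#' @param ca_cyt cytosolic calcium, nM.
#' @param gate gating factor in `[0, 1]` (default 1).
#' @return Signed flux, nM/s (negative when the gradient is outward).
#' @export
gradient_flux <- function(rate, ca_ex, ca_cyt, gate = 1) {
  gate * rate * (ca_ex - ca_cyt)
}

#' Multiplicative feedback-inhibition factor
#'
#' `1 / (1 + k_I * modifier)`, applied to an uninhibited flux. The
#' mechanosensitive channel is inhibited by calcium-bound calmodulin; Vcx1
#' by calmodulin-bound calcineurin.
#'
#' @param k_I inhibition constant, nM^-1.
#' @param modifier inhibitor concentration, nM.
#' @return Scale factor in (0, 1].
#' @export
inhibition_factor <- function(k_I, modifier) {
  1 / (1 + k_I * modifier)
}

#' Rate of calcium-bound calmodulin
#'
#' Mass-action binding of three calcium ions with high cooperativity:
#' `dCaMb/dt = km_plus * (CaM_t - CaMb) * ca^3 - km_minus * CaMb`.
#'
#' @param ca_cyt cytosolic calcium, nM.
#' @param camb calcium-bound calmodulin, nM.
#' @param params a [kinetic_params()] record.
#' @return Rate, nM/s.
#' @export
calmodulin_rate <- function(ca_cyt, camb, params) {
  params$km_plus * (params$CaM_t - camb) * ca_cyt^3 -
    params$km_minus * camb
}

#' Rate of calmodulin-bound (activated) calcineurin
#'
#' `dCaNb/dt = kn_plus * (CaN_t - CaNb) * CaMb - kn_minus * CaNb`.
#'
#' @param camb calcium-bound calmodulin, nM.
#' @param canb calmodulin-bound calcineurin, nM.
#' @param params a [kinetic_params()] record.
#' @return Rate, nM/s.
#' @export
calcineurin_rate <- function(camb, canb, params) {
  params$kn_plus * (params$CaN_t - canb) * camb - params$kn_minus * canb
}

#' Quasi-steady activated calcineurin at a given bound-calmodulin level
#'
#' With an unbinding rate of order 10^3 1/s, activated calcineurin relaxes
#' on millisecond timescales and tracks `CaN_t * camb / (camb + kn_minus /
#' kn_plus)`; used to initialise trajectories and in resting-state solves.
#'
#' @param camb calcium-bound calmodulin, nM.
#' @param params a [kinetic_params()] record.
#' @return Quasi-steady CaNb, nM.
#' @export
quasi_steady_canb <- function(camb, params) {
  if (params$kn_plus == 0) return(0 * camb)
  params$CaN_t * camb / (camb + params$kn_minus / params$kn_plus)
}

#' Cytosolic calcium balance and per-transporter flux breakdown
#'
#' Evaluates every calcium flux at one state and time: influx through the
#' Cch1/Mid1 channel and the mechanosensitive channel (gated by turgor and
#' inhibited by bound calmodulin), efflux through Pmr1, Vcx1 (inhibited by
#' activated calcineurin) and Pmc1, plus the disabled unidentified influx.
#' The calcium rate is the signed sum
#' `j_IN + j_Cch1 + j_MS - j_Pmr1 - j_Vcx1 - j_Pmc1`. Calmodulin binding
#' does not consume calcium in the default balance; `buffered = TRUE`
#' subtracts the stoichiometric term `3 * dCaMb/dt` for exploration.
#'
#' @param state named list or vector with `Ca_cyt`, `CaMb`, `CaNb` (nM).
#' @param t time, s.
#' @param P turgor pressure, MPa.
#' @param params a [kinetic_params()] record.
#' @param protocol a [stimulus_protocol()] record.
#' @param buffered subtract calcium consumed by calmodulin binding?
#' @return A list with `rate` (nM/s) and `fluxes`, a named list carrying
#'   `j_IN`, `j_Cch1`, `j_MS`, `j_Pmc1`, `j_Vcx1`, `j_Pmr1`, `P_open`, the
#'   uninhibited `j_MS0`, `j_Vcx10`, `j_Cch10`, and `ca_ex`.
#' @export
calcium_rate <- function(state, t, P, params, protocol, buffered = FALSE) {
  ca <- state[["Ca_cyt"]]
  camb <- state[["CaMb"]]
  canb <- state[["CaNb"]]
  ca_ex <- extracellular_calcium(t, params, protocol)
  p_open <- open_probability(P, params)

  j_in <- michaelis_flux(params$v_IN, params$k_IN, ca_ex)
  j_cch1_0 <- gradient_flux(params$k_Cch1, ca_ex, ca)
  j_cch1 <- j_cch1_0 * inhibition_factor(params$kI_Cch1, canb)
  j_ms_0 <- gradient_flux(params$k_MS, ca_ex, ca, gate = p_open)
  j_ms <- j_ms_0 * inhibition_factor(params$kI_MS, camb)
  j_pmr1 <- michaelis_flux(params$v_Pmr1, params$k_Pmr1, ca)
  j_vcx1_0 <- michaelis_flux(params$v_Vcx1, params$k_Vcx1, ca)
  j_vcx1 <- j_vcx1_0 * inhibition_factor(params$kI_Vcx1, canb)
  j_pmc1 <- michaelis_flux(params$v_Pmc1, params$k_Pmc1, ca)

  rate <- j_in + j_cch1 + j_ms - j_pmr1 - j_vcx1 - j_pmc1
  if (buffered) rate <- rate - 3 * calmodulin_rate(ca, camb, params)
  list(rate = rate,
       fluxes = list(j_IN = j_in, j_Cch1 = j_cch1, j_MS = j_ms,
                     j_Pmc1 = j_pmc1, j_Vcx1 = j_vcx1, j_Pmr1 = j_pmr1,
                     P_open = p_open, j_MS0 = j_ms_0, j_Vcx10 = j_vcx1_0,
                     j_Cch10 = j_cch1_0, ca_ex = ca_ex))
}

#' Right-hand side of the coupled volume/calcium ODE system
#'
#' State ordering is `c(V_os, Ca_cyt, CaMb, CaNb)`. Turgor is computed from
#' the instantaneous total volume and feeds the mechanosensitive gate.
#' Bound-protein states are clamped into `[0, total]` for evaluation; a
#' clamp is reported through the `clamped` attribute of the result.
#' Deterministic and free of side effects, in the form expected by
#' [deSolve::lsoda()].
#'
#' @param t time, s.
#' @param y numeric state vector `c(V_os, Ca_cyt, CaMb, CaNb)`.
#' @param parms list with `params` ([kinetic_params()]), `biophys`
#'   ([biophys_params()]), `derived` ([biophys_derived()]), `protocol`
#'   ([stimulus_protocol()]) and optional logical `buffered`.
#' @return A list whose first element is the derivative vector
#'   `c(dV_os, dCa_cyt, dCaMb, dCaNb)`.
#' @export
system_rhs <- function(t, y, parms) {
  kp <- parms$params
  camb <- min(max(y[3], 0), kp$CaM_t)
  canb <- min(max(y[4], 0), kp$CaN_t)
  clamped <- (camb != y[3]) || (canb != y[4])
  ca <- max(y[2], 0)

  dV <- osmotic_volume_rate(y[1], t, parms$biophys, parms$derived,
                            parms$protocol)
  P <- turgor_pressure(parms$biophys$V_b + y[1], parms$derived,
                       parms$biophys)
  cr <- calcium_rate(list(Ca_cyt = ca, CaMb = camb, CaNb = canb),
                     t, P, kp, parms$protocol,
                     buffered = isTRUE(parms$buffered))
  dy <- c(dV,
          cr$rate,
          calmodulin_rate(ca, camb, kp),
          calcineurin_rate(camb, canb, kp))
  out <- list(dy)
  attr(out, "clamped") <- clamped
  out
}
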