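# Shared fixtures and an independent scalar oracle for the model equations.

default_kp <- kinetic_params()
default_bp <- biophys_params()
default_proto <- stimulus_protocol()
default_derived <- biophys_derived(default_bp)

# Literal term-by-term transcription of the model equations, written as
# plain scalar arithmetic with no calls into the package's flux helpers.
# Used as the oracle for calcium_rate()/system_rhs() equivalence.
oracle_rhs <- function(t, y, kp, bp, dv, proto, buffered = FALSE) {
  V_os <- y[1]
  ca <- max(y[2], 0)
  camb <- min(max(y[3], 0), kp$CaM_t)
  canb <- min(max(y[4], 0), kp$CaN_t)

  # volume: dV_os/dt = -Lp A (P + cPC R T (Osm_e - Osm_i))
  V <- bp$V_b + V_os
  A <- (36 * pi)^(1 / 3) * V^(2 / 3)
  P <- if (V >= dv$V_zero) bp$epsilon * log(V / dv$V_zero) else 0
  osm_e <- if (t < proto$t_off) bp$c_n_e0 else
    (bp$c_n_e0 - bp$c_n_e0 / proto$d) *
      exp((proto$t_off - t) / proto$t_m) + bp$c_n_e0 / proto$d
  osm_i <- bp$Gly_i + dv$c_n_i * dv$V_os0 / V_os
  dV <- -bp$L_p * A * (P + bp$c_PC * bp$R * bp$T * (osm_e - osm_i))

  # calcium balance
  ca_ex <- if (t < proto$t_off) proto$Ca_ex0 else
    (proto$Ca_ex0 - proto$Ca_ex0 / proto$d) *
      exp((proto$t_off - t) / proto$t_m) + proto$Ca_ex0 / proto$d
  p_open <- 1 - 1 / (1 + exp((P - kp$P_MS) / kp$g_MS))
  j_in <- kp$v_IN * ca_ex / (kp$k_IN + ca_ex)
  j_pmr1 <- kp$v_Pmr1 * ca / (kp$k_Pmr1 + ca)
  j_vcx1_0 <- kp$v_Vcx1 * ca / (kp$k_Vcx1 + ca)
  j_pmc1 <- kp$v_Pmc1 * ca / (kp$k_Pmc1 + ca)
  j_ms_0 <- p_open * kp$k_MS * (ca_ex - ca)
  j_cch1_0 <- kp$k_Cch1 * (ca_ex - ca)
  j_cch1 <- j_cch1_0 / (1 + kp$kI_Cch1 * canb)
  j_ms <- j_ms_0 / (1 + kp$kI_MS * camb)
  j_vcx1 <- j_vcx1_0 / (1 + kp$kI_Vcx1 * canb)
  dcamb <- kp$km_plus * (kp$CaM_t - camb) * ca^3 - kp$km_minus * camb
  dca <- j_in + j_cch1 + j_ms - j_pmr1 - j_vcx1 - j_pmc1
  if (buffered) dca <- dca - 3 * dcamb
  dcanb <- kp$kn_plus * (kp$CaN_t - canb) * camb - kp$kn_minus * canb
  c(dV, dca, dcamb, dcanb)
}

# random admissible state for property tests
random_state <- function(kp, dv) {
  c(V_os = dv$V_os0 * stats::runif(1, 0.8, 1.2),
    Ca_cyt = stats::runif(1, 0, 30000),
    CaMb = stats::runif(1, 0, kp$CaM_t),
    CaNb = stats::runif(1, 0, kp$CaN_t))
}

# quick fit-grade solver for tests that do not probe accuracy itself
fast_settings <- function(dt = 0.5) {
  solver_settings(rtol = 1e-6, atol = c(1e-18, 1e-3, 1e-6, 1e-6), dt = dt)
}
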