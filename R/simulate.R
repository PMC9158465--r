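#' Integrator settings for the stiff HTS simulation
#'
#' The calcineurin unbinding rate (10^3 1/s) makes the system stiff; lsoda
#' switches automatically between stiff and non-stiff methods. Absolute
#' tolerances are per state variable: the osmotic volume lives near 3e-14 L
#' and bound-protein feedback responds to sub-nanomolar changes, so each
#' state gets a tolerance well below its own scale.
#'
#' @param rtol relative tolerance.
#' @param atol absolute tolerances for `c(V_os, Ca_cyt, CaMb, CaNb)`.
#' @param dt output grid spacing, s.
#' @param hmax maximum internal step, s.
#' @param compiled use the compiled right-hand side (default); `FALSE`
#'   integrates the plain-R [system_rhs()], which is slower but is the
#'   reference implementation.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(rtol = 1e-8,
                            atol = c(1e-20, 1e-4, 1e-8, 1e-8),
                            dt = 0.1,
                            hmax = NULL,
                            compiled = TRUE) {
  stopifnot(rtol > 0, all(atol > 0), dt > 0)
  structure(list(rtol = rtol, atol = atol, dt = dt, hmax = hmax,
                 compiled = isTRUE(compiled)),
            class = "solver_settings")
}

# pack parameter records into the slot order of src/rhs.c
pack_parms <- function(params, biophys, derived, protocol,
                       buffered = FALSE) {
  c(biophys$V_b, biophys$L_p, biophys$c_PC * biophys$R * biophys$T,
    biophys$Gly_i, derived$c_n_i, derived$V_os0, derived$V_zero,
    biophys$epsilon,
    protocol$d, protocol$t_off, protocol$t_m, biophys$c_n_e0,
    protocol$Ca_ex0 %||% params$Ca_ex0,
    params$v_Vcx1, params$k_Vcx1, params$v_Pmc1, params$k_Pmc1,
    params$v_Pmr1, params$k_Pmr1, params$k_MS, params$k_Cch1,
    params$P_MS, params$g_MS, params$km_plus, params$km_minus,
    params$kn_plus, params$kn_minus, params$CaM_t, params$CaN_t,
    params$kI_MS, params$kI_Vcx1, params$kI_Cch1,
    params$v_IN, params$k_IN, as.numeric(buffered))
}

# residual of the cytosolic calcium balance at pre-stimulus turgor,
# with CaMb frozen and CaNb at its quasi-steady value (inlined for speed;
# calcium_rate() is the reference form and tests hold them equal)
resting_residual <- function(ca, camb0, params, biophys, protocol) {
  canb <- quasi_steady_canb(camb0, params)
  ca_ex <- protocol$Ca_ex0 %||% params$Ca_ex0
  p_open <- open_probability(biophys$P_0, params)
  michaelis_flux(params$v_IN, params$k_IN, ca_ex) +
    params$k_Cch1 * (ca_ex - ca) / (1 + params$kI_Cch1 * canb) +
    p_open * params$k_MS * (ca_ex - ca) / (1 + params$kI_MS * camb0) -
    michaelis_flux(params$v_Pmr1, params$k_Pmr1, ca) -
    michaelis_flux(params$v_Vcx1, params$k_Vcx1, ca) /
      (1 + params$kI_Vcx1 * canb) -
    michaelis_flux(params$v_Pmc1, params$k_Pmc1, ca)
}

#' Resting cytosolic calcium at a given bound-calmodulin level
#'
#' Solves the calcium balance for its pre-stimulus stationary point by
#' bisection, with turgor at `P_0`, bound calmodulin frozen at `camb0`
#' (its kinetics are quasi-static on the experimental horizon) and
#' activated calcineurin at its quasi-steady value. The residual is
#' strictly decreasing in calcium, so the root is unique.
#'
#' @param params a [kinetic_params()] record.
#' @param camb0 resting calcium-bound calmodulin, nM.
#' @param biophys a [biophys_params()] record.
#' @param protocol a [stimulus_protocol()] record (supplies `Ca_ex0`).
#' @return Resting cytosolic calcium, nM.
#' @export
resting_baseline <- function(params, camb0 = 0,
                             biophys = biophys_params(),
                             protocol = stimulus_protocol()) {
  stopifnot(camb0 >= 0, camb0 <= params$CaM_t)
  ca_ex <- protocol$Ca_ex0 %||% params$Ca_ex0
  f <- function(ca) resting_residual(ca, camb0, params, biophys, protocol)
  if (f(0) <= 0) return(0)          # no net influx at zero calcium
  upper <- ca_ex
  if (f(upper) > 0) {
    stop("no stationary point below extracellular calcium; residual at ",
         upper, " nM is ", signif(f(upper), 4), " nM/s")
  }
  stats::uniroot(f, c(0, upper), tol = 1e-8)$root
}

#' Calibrate resting bound calmodulin to a target baseline
#'
#' Finds `camb0` such that [resting_baseline()] equals `target_baseline`.
#' Higher bound calmodulin inhibits the mechanosensitive leak more strongly
#' and lowers the baseline, so the map is monotone and the solve is a
#' bisection. When the mechanosensitive rate is zero the baseline does not
#' depend on `camb0` and the parameter is non-identifiable; an error says
#' so unless the target is already met, in which case 0 is returned.
#'
#' @param params a [kinetic_params()] record.
#' @param target_baseline resting cytosolic calcium to reproduce, nM.
#' @param biophys a [biophys_params()] record.
#' @param protocol a [stimulus_protocol()] record.
#' @param tol fixed-point convergence tolerance on `camb0`, nM.
#' @param clamp if `TRUE`, an unreachable target returns the achievable
#'   extreme (`0` or `CaM_t`) instead of erroring; used inside fitting
#'   objectives so infeasible candidates keep a finite, informative loss.
#' @return Resting calcium-bound calmodulin, nM.
#' @export
calibrate_resting_calmodulin <- function(params, target_baseline,
                                         biophys = biophys_params(),
                                         protocol = stimulus_protocol(),
                                         tol = 1e-9, clamp = FALSE) {
  ca_ex <- protocol$Ca_ex0 %||% params$Ca_ex0
  p_open <- open_probability(biophys$P_0, params)
  ms_gradient <- p_open * params$k_MS * (ca_ex - target_baseline)
  if (params$k_MS == 0 || params$kI_MS == 0 || ms_gradient <= 0) {
    hi <- resting_baseline(params, 0, biophys, protocol)
    if (abs(hi - target_baseline) <= max(1e-6, 1e-3 * target_baseline)) {
      return(0)
    }
    if (clamp) return(0)
    stop("resting bound calmodulin is non-identifiable ",
         "(mechanosensitive leak inert); achievable baseline is ",
         signif(hi, 6), " nM")
  }
  # at the target baseline the MS leak must supply the efflux not met by
  # the other influxes; inverting the inhibition factor gives camb0, with
  # the weak CaNb -> Vcx1 coupling resolved by fixed-point iteration
  other_in <- michaelis_flux(params$v_IN, params$k_IN, ca_ex)
  efflux_fixed <-
    michaelis_flux(params$v_Pmr1, params$k_Pmr1, target_baseline) +
    michaelis_flux(params$v_Pmc1, params$k_Pmc1, target_baseline)
  vcx0 <- michaelis_flux(params$v_Vcx1, params$k_Vcx1, target_baseline)
  cch0 <- params$k_Cch1 * (ca_ex - target_baseline)
  camb <- 0
  for (i in 1:200) {
    canb <- quasi_steady_canb(camb, params)
    needed <- efflux_fixed +
      vcx0 / (1 + params$kI_Vcx1 * canb) -
      cch0 / (1 + params$kI_Cch1 * canb) - other_in
    if (needed <= 0) {
      # baseline below reach even with the MS leak fully inhibited
      if (clamp) return(params$CaM_t)
      stop("target baseline ", target_baseline,
           " nM below the achievable range (mechanosensitive leak ",
           "cannot be negative)")
    }
    camb_new <- (ms_gradient / needed - 1) / params$kI_MS
    # forgive round-off at the boundaries of the achievable range
    if (camb_new < 0 && ms_gradient / needed > 1 - 1e-9) camb_new <- 0
    if (camb_new > params$CaM_t &&
        camb_new < params$CaM_t * (1 + 1e-9)) camb_new <- params$CaM_t
    if (camb_new < 0) {
      if (clamp) return(0)
      stop("target baseline ", target_baseline,
           " nM above the achievable range; uninhibited baseline is ",
           signif(resting_baseline(params, 0, biophys, protocol), 6),
           " nM")
    }
    if (camb_new > params$CaM_t) {
      if (clamp) return(params$CaM_t)
      stop("target baseline ", target_baseline,
           " nM below the achievable range; fully inhibited baseline is ",
           signif(resting_baseline(params, params$CaM_t, biophys,
                                   protocol), 6), " nM")
    }
    if (abs(camb_new - camb) <= tol * (1 + camb)) return(camb_new)
    camb <- camb_new
  }
  stop("calibration fixed point did not converge")
}

# resolve a strain's resting bound calmodulin (numeric or calibrated)
resolve_resting_camb <- function(strain, params, biophys, protocol) {
  rc <- strain$resting_camb
  if (is.numeric(rc)) return(rc)
  if (identical(rc, "calibrate")) {
    return(calibrate_resting_calmodulin(params, strain$target_baseline,
                                        biophys, protocol))
  }
  stop("resting_camb must be numeric or \"calibrate\"")
}

#' Simulate the hypotonic-shock response of one strain
#'
#' Builds the strain's parameter record, calibrates (or accepts) the
#' resting state, and integrates the coupled volume/calcium system with
#' lsoda over `[0, t_end]`. The integration is split at the stimulus onset
#' `t_off`, where the forcing is continuous but not smooth. The returned
#' trace carries the state series plus derived series (turgor, opening
#' probability, per-transporter fluxes, external calcium).
#'
#' @param strain a [strain_config()] record.
#' @param params base [kinetic_params()] (wild-type defaults if omitted).
#' @param biophys a [biophys_params()] record.
#' @param protocol a [stimulus_protocol()] record.
#' @param settings a [solver_settings()] record.
#' @param buffered subtract calmodulin-bound calcium from the balance?
#' @return A `ca_trace`: a data frame with columns `time_s`, `V_os_L`,
#'   `ca_cyt_nM`, `camb_nM`, `canb_nM`, `turgor_MPa`, `p_open`, `ca_ex_nM`,
#'   `j_cch1`, `j_ms`, `j_pmc1`, `j_vcx1`, `j_pmr1`, `j_in` and attributes
#'   `strain`, `protocol`, `params`, `biophys`, `resting_camb`.
#' @export
simulate_strain <- function(strain = strain_config(),
                            params = kinetic_params(),
                            biophys = biophys_params(),
                            protocol = stimulus_protocol(),
                            settings = solver_settings(),
                            buffered = FALSE) {
  sp <- strain_parameters(strain, params)
  derived <- biophys_derived(biophys)
  camb0 <- resolve_resting_camb(strain, sp, biophys, protocol)
  ca0 <- resting_baseline(sp, camb0, biophys, protocol)
  y0 <- c(V_os = derived$V_os0, Ca_cyt = ca0, CaMb = camb0,
          CaNb = quasi_steady_canb(camb0, sp))
  parms <- list(params = sp, biophys = biophys, derived = derived,
                protocol = protocol, buffered = buffered)

  grid <- seq(0, protocol$t_end, by = settings$dt)
  if (grid[length(grid)] < protocol$t_end) grid <- c(grid, protocol$t_end)
  pieces <- list()
  breaks <- unique(c(0, protocol$t_off, protocol$t_end))
  breaks <- breaks[breaks >= 0 & breaks <= protocol$t_end]
  y <- y0
  for (i in seq_len(length(breaks) - 1)) {
    tt <- grid[grid >= breaks[i] & grid <= breaks[i + 1]]
    tt <- unique(c(breaks[i], tt, breaks[i + 1]))
    sol <- if (settings$compiled) {
      deSolve::lsoda(y, tt, func = "calshock_derivs",
                     parms = pack_parms(sp, biophys, derived, protocol,
                                        buffered),
                     dllname = "calshock", initfunc = "calshock_initmod",
                     rtol = settings$rtol, atol = settings$atol,
                     hmax = settings$hmax %||% Inf, maxsteps = 50000)
    } else {
      deSolve::lsoda(y, tt, system_rhs, parms,
                     rtol = settings$rtol, atol = settings$atol,
                     hmax = settings$hmax %||% Inf, maxsteps = 50000)
    }
    if (attr(sol, "istate")[1] < 0) {
      stop("integration failed for strain '", strain$name,
           "' near t = ", sol[nrow(sol), 1], " s")
    }
    y <- sol[nrow(sol), -1]
    keep <- sol[, 1] %in% tt & !duplicated(sol[, 1])
    pieces[[i]] <- sol[keep, , drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  out <- out[!duplicated(out[, 1]), , drop = FALSE]
  out <- out[out[, 1] %in% grid, , drop = FALSE]

  tr <- data.frame(time_s = out[, 1], V_os_L = out[, 2],
                   ca_cyt_nM = out[, 3], camb_nM = out[, 4],
                   canb_nM = out[, 5])
  tr <- cbind(tr, derived_series(tr, sp, biophys, derived, protocol))
  structure(tr, class = c("ca_trace", "data.frame"),
            strain = strain$name, protocol = protocol, params = sp,
            biophys = biophys, resting_camb = camb0)
}

# vectorised derived quantities along a state series
derived_series <- function(tr, params, biophys, derived, protocol) {
  P <- turgor_pressure(biophys$V_b + tr$V_os_L, derived, biophys)
  p_open <- open_probability(P, params)
  ca_ex <- extracellular_calcium(tr$time_s, params, protocol)
  ca <- tr$ca_cyt_nM
  inhib_ms <- inhibition_factor(params$kI_MS, tr$camb_nM)
  inhib_vcx <- inhibition_factor(params$kI_Vcx1, tr$canb_nM)
  inhib_cch <- inhibition_factor(params$kI_Cch1, tr$canb_nM)
  data.frame(
    turgor_MPa = P,
    p_open = p_open,
    ca_ex_nM = ca_ex,
    j_cch1 = gradient_flux(params$k_Cch1, ca_ex, ca) * inhib_cch,
    j_ms = gradient_flux(params$k_MS, ca_ex, ca, gate = p_open) * inhib_ms,
    j_pmc1 = michaelis_flux(params$v_Pmc1, params$k_Pmc1, ca),
    j_vcx1 = michaelis_flux(params$v_Vcx1, params$k_Vcx1, ca) * inhib_vcx,
    j_pmr1 = michaelis_flux(params$v_Pmr1, params$k_Pmr1, ca),
    j_in = michaelis_flux(params$v_IN, params$k_IN, ca_ex)
  )
}

#' Baseline, peak and time-to-peak of a calcium trace
#'
#' Baseline is the mean cytosolic calcium before the stimulus onset; peak
#' is the maximum from onset to the end of the window; time-to-peak is
#' measured from the onset.
#'
#' @param trace a `ca_trace` (or any data frame with `time_s` and
#'   `ca_cyt_nM`).
#' @param protocol a [stimulus_protocol()] record; defaults to the trace's
#'   own protocol attribute.
#' @return A list with `baseline`, `peak` (nM) and `time_to_peak` (s).
#' @export
trace_metrics <- function(trace, protocol = attr(trace, "protocol")) {
  stopifnot(!is.null(protocol))
  pre <- trace$time_s < protocol$t_off
  post <- trace$time_s >= protocol$t_off
  if (!any(pre)) stop("trace has no pre-stimulus samples")
  if (!any(post)) stop("trace has no post-stimulus samples")
  ca_post <- trace$ca_cyt_nM[post]
  i <- which.max(ca_post)
  list(baseline = mean(trace$ca_cyt_nM[pre]),
       peak = ca_post[i],
       time_to_peak = trace$time_s[post][i] - protocol$t_off)
}

#' Scan the mixing time and tabulate peak response metrics
#'
#' Re-simulates the same strain for every mixing time on the grid (the
#' resting state does not depend on the mixing time, so the calibration is
#' done once) and tabulates peak and time-to-peak. The row index of the
#' maximal peak is reported as an attribute; ties break toward the smaller
#' mixing time.
#'
#' @param t_m_grid mixing times to scan, s.
#' @param strain a [strain_config()] record.
#' @param params,biophys,protocol,settings as in [simulate_strain()].
#' @return A data frame `(t_m, baseline, peak, time_to_peak)` with
#'   attribute `t_m_opt`, the mixing time of the maximal peak.
#' @export
mixing_time_scan <- function(t_m_grid = 1:40,
                             strain = strain_config(),
                             params = kinetic_params(),
                             biophys = biophys_params(),
                             protocol = stimulus_protocol(),
                             settings = solver_settings()) {
  stopifnot(length(t_m_grid) >= 1, all(t_m_grid > 0))
  sp <- strain_parameters(strain, params)
  camb0 <- resolve_resting_camb(strain, sp, biophys, protocol)
  fixed <- strain
  fixed$resting_camb <- camb0     # calibrate once, reuse across the grid
  rows <- lapply(t_m_grid, function(tm) {
    proto <- stimulus_protocol(d = protocol$d, t_off = protocol$t_off,
                               t_m = tm, Ca_ex0 = protocol$Ca_ex0,
                               t_end = protocol$t_end)
    tr <- tryCatch(
      simulate_strain(fixed, params, biophys, proto, settings),
      error = function(e) stop("mixing-time scan failed at t_m = ", tm,
                               " s: ", conditionMessage(e))
    )
    m <- trace_metrics(tr, proto)
    data.frame(t_m = tm, baseline = m$baseline, peak = m$peak,
               time_to_peak = m$time_to_peak)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$t_m), ]
  rownames(tab) <- NULL
  attr(tab, "t_m_opt") <- tab$t_m[which.max(tab$peak)]
  tab
}

#' Flux decomposition and inhibition diagnostics along a trace
#'
#' Recomputes the per-transporter fluxes from the state series, adds the
#' uninhibited mechanosensitive and Vcx1 fluxes for comparison with their
#' inhibited counterparts, and the signed flux sum (which reproduces the
#' calcium derivative pointwise).
#'
#' @param trace a `ca_trace` from [simulate_strain()].
#' @return A data frame with `time_s`, the inhibited fluxes, `j_ms0`,
#'   `j_vcx10`, `p_open` and `net_flux` (nM/s).
#' @export
flux_decomposition <- function(trace) {
  params <- attr(trace, "params")
  stopifnot(!is.null(params))
  j_ms0 <- gradient_flux(params$k_MS, trace$ca_ex_nM, trace$ca_cyt_nM,
                         gate = trace$p_open)
  j_vcx10 <- michaelis_flux(params$v_Vcx1, params$k_Vcx1, trace$ca_cyt_nM)
  net <- trace$j_in + trace$j_cch1 + trace$j_ms -
    trace$j_pmr1 - trace$j_vcx1 - trace$j_pmc1
  data.frame(time_s = trace$time_s,
             j_cch1 = trace$j_cch1, j_ms = trace$j_ms,
             j_pmc1 = trace$j_pmc1, j_vcx1 = trace$j_vcx1,
             j_pmr1 = trace$j_pmr1, j_in = trace$j_in,
             j_ms0 = j_ms0, j_vcx10 = j_vcx10,
             p_open = trace$p_open, net_flux = net)
}

#' Write a calcium trace to CSV (with a YAML metadata sidecar)
#'
#' @param trace a `ca_trace`.
#' @param path CSV output path; the sidecar goes to `paste0(path, ".meta.yaml")`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(strain = attr(trace, "strain") %||% "unknown",
               protocol = unclass(attr(trace, "protocol")),
               resting_camb = attr(trace, "resting_camb"))
  if (!is.null(attr(trace, "params"))) {
    meta$params <- unclass(attr(trace, "params"))
  }
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 15)
  invisible(path)
}
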