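#' Biophysical parameters of the walled-cell volume/turgor model
#'
#' Constructs the parameter record for the physical half of the model: cell
#' volumes, hydraulic conductivity, resting turgor, osmolarities and the
#' volumetric elastic modulus of the wall. Defaults describe a yeast cell
#' grown in rich (YPD-like) medium at 30 degrees C.
#'
#' Canonical units are s, L (= dm^3), MPa and umol/L. The conversion factor
#' `c_PC` turns a van't Hoff concentration term (in M) into MPa, so the
#' osmotic pressure of a concentration difference `dc` (umol/L) is
#' `c_PC * R * T * dc` MPa.
#'
#' @param V_b osmotically inactive (solid) volume, L.
#' @param V_total0 initial total cell volume V(0), L.
#' @param L_p hydraulic conductivity of the membrane, dm MPa^-1 s^-1.
#' @param P_0 initial (resting) turgor pressure, MPa.
#' @param c_PC concentration-to-pressure conversion factor (dimensionless).
#' @param R gas constant, J mol^-1 K^-1.
#' @param T temperature, K.
#' @param c_n_e0 initial extracellular osmolarity, umol/L.
#' @param Gly_i intracellular glycerol concentration, umol/L (held constant
#'   on the short horizon modeled here).
#' @param epsilon volumetric elastic modulus of the cell wall, MPa.
#' @param sigma reflection coefficient; glycerol is the only permeable
#'   solute considered and sigma is fixed at 1.
#' @param V_ex extracellular volume, L; treated as an infinite reservoir and
#'   playing no dynamical role.
#' @return An object of class `biophys_params` (a named list).
#' @export
biophys_params <- function(V_b = 20.5e-15,
                           V_total0 = 50e-15,
                           L_p = 1.3e-7,
                           P_0 = 0.61,
                           c_PC = 1e-9,
                           R = 8.314,
                           T = 303.15,
                           c_n_e0 = 260000,
                           Gly_i = 180000,
                           epsilon = 14.3,
                           sigma = 1,
                           V_ex = 1000 * V_total0) {
  p <- list(V_b = V_b, V_total0 = V_total0, V_ex = V_ex, L_p = L_p,
            P_0 = P_0, c_PC = c_PC, R = R, T = T, c_n_e0 = c_n_e0,
            Gly_i = Gly_i, epsilon = epsilon, sigma = sigma)
  stopifnot(V_b > 0, V_total0 > 0, V_b < V_total0, V_ex > 0,
            L_p >= 0, P_0 >= 0, epsilon > 0, sigma == 1,
            c_PC * R * T > 0, c_n_e0 > 0, Gly_i >= 0)
  structure(p, class = "biophys_params")
}

#' Quantities derived from the biophysical parameters
#'
#' Computes the initial osmotic volume, the initial internal osmolarity
#' implied by osmotic balance at the resting turgor, the non-permeable
#' internal solute concentration, the initial extracellular glycerol, and
#' the zero-turgor volume used by the elastic turgor law.
#'
#' @param params a [biophys_params()] record.
#' @return An object of class `biophys_derived` with fields `V_os0`,
#'   `Osm_i0`, `c_n_i`, `Gly_e0`, `V_zero`.
#' @export
biophys_derived <- function(params) {
  stopifnot(inherits(params, "biophys_params"))
  V_os0 <- params$V_total0 - params$V_b
  Osm_i0 <- initial_internal_osmolarity(params)
  c_n_i <- Osm_i0 - params$Gly_i
  stopifnot(V_os0 > 0, c_n_i > 0)
  structure(list(V_os0 = V_os0,
                 Osm_i0 = Osm_i0,
                 c_n_i = c_n_i,
                 Gly_e0 = params$Gly_i / 1000,
                 V_zero = zero_turgor_volume(params)),
            class = "biophys_derived")
}

#' Hypotonic dilution stimulus protocol
#'
#' The shock is applied at `t_off` by (conceptually) adding `d - 1` volumes
#' of distilled water to one volume of medium; the external osmolarity and
#' external calcium relax exponentially, with time constant `t_m`, from
#' their initial values to `initial/d`.
#'
#' @param d dilution factor (>= 1). Adding four volumes of water to one of
#'   medium gives d = 5.
#' @param t_off stimulus onset time, s.
#' @param t_m mixing time (exponential time constant of the dilution), s.
#' @param Ca_ex0 initial extracellular calcium, nM.
#' @param t_end simulation horizon, s.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(d = 5, t_off = 30, t_m = 9.1,
                              Ca_ex0 = 29500, t_end = 160) {
  stopifnot(d >= 1, t_m > 0, t_off >= 0, t_off < t_end, Ca_ex0 >= 0)
  structure(list(d = d, t_off = t_off, t_m = t_m,
                 Ca_ex0 = Ca_ex0, t_end = t_end),
            class = "stimulus_protocol")
}

#' Kinetic parameters of the calcium signaling model (wild-type defaults)
#'
#' Rate constants, affinities, gating parameters, calmodulin/calcineurin
#' binding constants and feedback-inhibition constants of the biochemical
#' half of the model. Defaults are the fitted wild-type values.
#'
#' The calmodulin unbinding rate is tied to the binding rate
#' (`km_minus = km_plus * 9000`) unless `km_minus` is supplied explicitly.
#' The `v_IN`/`k_IN` influx and the calcineurin feedback on the Cch1 channel
#' (`kI_Cch1`) belong to the pre-simplification model and default to zero
#' (disabled); setting them non-zero reconstructs the fuller model.
#'
#' @param Ca_cyt0 initial cytosolic calcium, nM.
#' @param Ca_ex0 initial extracellular calcium, nM.
#' @param v_Vcx1,v_Pmc1,v_Pmr1 maximal transport rates, nM/s.
#' @param k_Vcx1,k_Pmc1,k_Pmr1 Michaelis constants, nM.
#' @param k_MS,k_Cch1 channel rate parameters, 1/s.
#' @param P_MS turgor pressure of half-maximal mechanosensitive-channel
#'   opening, MPa.
#' @param g_MS gating slope, MPa.
#' @param km_plus calmodulin binding rate, nM^-4 s^-1.
#' @param km_minus calmodulin unbinding rate, 1/s; default `km_plus * 9000`.
#' @param kn_plus calcineurin binding rate, nM^-2 s^-1 (as tabulated).
#' @param kn_minus calcineurin unbinding rate, 1/s.
#' @param CaM_t total calmodulin, nM.
#' @param CaN_t total calcineurin, nM.
#' @param kI_MS,kI_Vcx1,kI_Cch1 feedback inhibition constants, nM^-1.
#' @param v_IN,k_IN disabled unidentified-influx parameters (nM/s, nM).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(Ca_cyt0 = 100,
                           Ca_ex0 = 29500,
                           v_Vcx1 = 2820420,
                           v_Pmc1 = 280870,
                           v_Pmr1 = 813,
                           k_Vcx1 = 100000,
                           k_Pmc1 = 4300,
                           k_Pmr1 = 70,
                           k_MS = 132184,
                           k_Cch1 = 0.37,
                           P_MS = 0.76,
                           g_MS = 0.039,
                           km_plus = 1.8e-14,
                           km_minus = NULL,
                           kn_plus = 0.1,
                           kn_minus = 1000,
                           CaM_t = 2600,
                           CaN_t = 310,
                           kI_MS = 26395,
                           kI_Vcx1 = 9348540,
                           kI_Cch1 = 0,
                           v_IN = 0,
                           k_IN = 1) {
  if (is.null(km_minus)) km_minus <- km_plus * 9000
  p <- list(Ca_cyt0 = Ca_cyt0, Ca_ex0 = Ca_ex0,
            v_Vcx1 = v_Vcx1, v_Pmc1 = v_Pmc1, v_Pmr1 = v_Pmr1,
            k_Vcx1 = k_Vcx1, k_Pmc1 = k_Pmc1, k_Pmr1 = k_Pmr1,
            k_MS = k_MS, k_Cch1 = k_Cch1, P_MS = P_MS, g_MS = g_MS,
            km_plus = km_plus, km_minus = km_minus,
            kn_plus = kn_plus, kn_minus = kn_minus,
            CaM_t = CaM_t, CaN_t = CaN_t,
            kI_MS = kI_MS, kI_Vcx1 = kI_Vcx1, kI_Cch1 = kI_Cch1,
            v_IN = v_IN, k_IN = k_IN)
  rates <- unlist(p)
  stopifnot(all(rates >= 0), g_MS > 0)
  structure(p, class = "kinetic_params")
}

#' Apply a sparse set of overrides to a kinetic parameter record
#'
#' @param params a [kinetic_params()] record.
#' @param overrides named list of replacement values; names must be existing
#'   kinetic parameter fields.
#' @return A `kinetic_params` record with the overrides applied. Overriding
#'   `km_plus` retunes `km_minus` to `km_plus * 9000` unless `km_minus` is
#'   itself overridden.
#' @export
patch_params <- function(params, overrides) {
  stopifnot(inherits(params, "kinetic_params"))
  if (length(overrides) == 0) return(params)
  bad <- setdiff(names(overrides), names(params))
  if (length(bad) > 0) {
    stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "))
  }
  if ("km_plus" %in% names(overrides) && !"km_minus" %in% names(overrides)) {
    overrides$km_minus <- overrides$km_plus * 9000
  }
  params[names(overrides)] <- overrides
  structure(params, class = "kinetic_params")
}

#' Write model parameters to a YAML configuration file
#'
#' One section per parameter record (`biophysics`, `kinetics`, `protocol`);
#' sparse strain overrides can be carried in a `strain_overrides` section.
#'
#' @param path output file path.
#' @param biophys a [biophys_params()] record (optional).
#' @param kinetics a [kinetic_params()] record (optional).
#' @param protocol a [stimulus_protocol()] record (optional).
#' @param strain_overrides optional named list of sparse overrides.
#' @return `path`, invisibly.
#' @export
write_config <- function(path, biophys = NULL, kinetics = NULL,
                         protocol = NULL, strain_overrides = NULL) {
  cfg <- list()
  if (!is.null(biophys)) cfg$biophysics <- unclass(biophys)
  if (!is.null(kinetics)) cfg$kinetics <- unclass(kinetics)
  if (!is.null(protocol)) cfg$protocol <- unclass(protocol)
  if (!is.null(strain_overrides)) cfg$strain_overrides <- strain_overrides
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read model parameters from a YAML configuration file
#'
#' Sections missing from the file fall back to package defaults.
#'
#' @param path a file written by [write_config()] (or hand-authored with the
#'   same sections).
#' @return A list with elements `biophys`, `kinetics`, `protocol` and
#'   `strain_overrides` (the last may be `NULL`).
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  list(
    biophys  = do.call(biophys_params, as.list(cfg$biophysics %||% list())),
    kinetics = do.call(kinetic_params, as.list(cfg$kinetics %||% list())),
    protocol = do.call(stimulus_protocol, as.list(cfg$protocol %||% list())),
    strain_overrides = cfg$strain_overrides
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
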