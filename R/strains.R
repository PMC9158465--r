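#' Strain configuration for in-silico knockouts
#'
#' A deletion mutant is simulated by overriding the kinetic parameters tied
#' to the deleted gene product. The named strains carry the fitted
#' overrides:
#' \describe{
#'   \item{wild-type}{no overrides.}
#'   \item{cnb1}{no functional calcineurin (`CaN_t = 0`) and reduced Pmc1
#'     expression (`v_Pmc1 = 41079`), since Pmc1 transcription depends on
#'     calcineurin.}
#'   \item{cch1}{no Cch1/Mid1 channel (`k_Cch1 = 0`) with the same basal
#'     Pmc1 expression (`v_Pmc1 = 41079`).}
#'   \item{flc2}{loss of the inhibitory Flc2 subunit, modeled as an
#'     increased mechanosensitive-channel rate (`k_MS = 238519`).}
#'   \item{custom}{overrides supplied by the caller.}
#' }
#'
#' @param name strain name: `"wild-type"`, `"cnb1"`, `"cch1"`, `"flc2"` or
#'   `"custom"` (the Greek-delta spellings `"cnb1D"` etc. are accepted).
#' @param overrides named list of extra kinetic-parameter overrides
#'   (required for `"custom"`, merged on top of the named-strain ones
#'   otherwise).
#' @param resting_camb resting calcium-bound calmodulin (nM), or the string
#'   `"calibrate"` to solve for the value that reproduces
#'   `target_baseline`.
#' @param target_baseline resting cytosolic calcium (nM) used when
#'   `resting_camb = "calibrate"`.
#' @return An object of class `strain_config`.
#' @export
strain_config <- function(name = "wild-type", overrides = list(),
                          resting_camb = "calibrate",
                          target_baseline = 215) {
  key <- tolower(gsub("[^a-z0-9-]", "", tolower(name)))
  key <- sub("(d|delta)$", "", key)
  named <- list(
    "wild-type" = list(),
    "wildtype"  = list(),
    "wt"        = list(),
    "cnb1"      = list(CaN_t = 0, v_Pmc1 = 41079),
    "cch1"      = list(k_Cch1 = 0, v_Pmc1 = 41079),
    "flc2"      = list(k_MS = 238519)
  )
  if (key %in% names(named)) {
    base_over <- named[[key]]
  } else if (key == "custom") {
    if (length(overrides) == 0) {
      stop("strain 'custom' requires explicit overrides")
    }
    base_over <- list()
  } else {
    stop("unknown strain name: ", name)
  }
  base_over[names(overrides)] <- overrides
  structure(list(name = name, overrides = base_over,
                 resting_camb = resting_camb,
                 target_baseline = target_baseline),
            class = "strain_config")
}

#' Kinetic parameters for a strain
#'
#' Applies the strain's sparse overrides to a base (wild-type) parameter
#' record.
#'
#' @param strain a [strain_config()] record.
#' @param base a [kinetic_params()] record (wild-type defaults if omitted).
#' @return A patched `kinetic_params` record.
#' @export
strain_parameters <- function(strain, base = kinetic_params()) {
  stopifnot(inherits(strain, "strain_config"))
  patch_params(base, strain$overrides)
}
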