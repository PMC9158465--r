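#' Design of a synthetic calcium-trace dataset
#'
#' Describes a set of experimental conditions (strain, stimulus protocol,
#' generating parameter overrides, replicates, sampling interval) plus a
#' noise model, emulating aequorin-style cytosolic calcium recordings: a
#' pre-stimulus baseline of order 100-250 nM and a transient peak within a
#' couple of minutes of the shock, with replicate-to-replicate noise.
#'
#' Noise model per sample: `y = clean * (1 + mult_sd * e1) + add_sd * e2`
#' with `e1`, `e2` i.i.d. standard normal, clamped at 0. Per-replicate
#' seeds derive deterministically from the master seed.
#'
#' @param conditions list of conditions; each a list with `label`, `strain`
#'   (a [strain_config()]), `protocol` (a [stimulus_protocol()]), optional
#'   `overrides` (generating kinetic overrides) and optional `camb0`.
#' @param n_replicates replicates per condition (>= 1).
#' @param sampling_interval sampling interval, s.
#' @param add_sd additive Gaussian noise sd, nM.
#' @param mult_sd multiplicative Gaussian noise sd (fraction).
#' @param master_seed master RNG seed.
#' @param params,biophys base parameter records for the clean simulations.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(conditions,
                             n_replicates = 3,
                             sampling_interval = 1,
                             add_sd = 10,
                             mult_sd = 0.02,
                             master_seed = 1L,
                             params = kinetic_params(),
                             biophys = biophys_params()) {
  stopifnot(length(conditions) >= 1, n_replicates >= 1,
            sampling_interval > 0, add_sd >= 0, mult_sd >= 0)
  labels <- vapply(conditions, function(cc) cc$label %||% "", "")
  if (any(labels == "")) stop("every condition needs a label")
  if (anyDuplicated(labels)) {
    stop("duplicate condition labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(list(conditions = conditions, n_replicates = n_replicates,
                 sampling_interval = sampling_interval, add_sd = add_sd,
                 mult_sd = mult_sd, master_seed = as.integer(master_seed),
                 params = params, biophys = biophys),
            class = "synthetic_design")
}

# deterministic per-(condition, replicate) seed below 2^31
derive_seed <- function(master_seed, i_cond, i_rep) {
  as.integer((as.numeric(master_seed) * 2654435761 +
                i_cond * 97561 + i_rep * 1013) %% 2147483647)
}

# clean sampled trajectory for one condition
clean_condition_trace <- function(condition, design) {
  strain <- condition$strain %||% strain_config()
  if (!is.null(condition$camb0)) strain$resting_camb <- condition$camb0
  params <- patch_params(design$params, condition$overrides %||% list())
  proto <- condition$protocol %||% stimulus_protocol()
  settings <- solver_settings(dt = design$sampling_interval)
  simulate_strain(strain, params, design$biophys, proto, settings)
}

#' Generate one noisy synthetic calcium trace
#'
#' Simulates the clean trajectory for the condition, samples it on the
#' design grid and applies the design's noise model. The RNG seed is
#' recorded on the result; the same seed reproduces the trace exactly.
#'
#' @param condition one element of a design's `conditions`.
#' @param design the [synthetic_design()] the condition belongs to.
#' @param seed integer seed for the noise draws.
#' @param clean optionally, a precomputed clean trace for the condition
#'   (avoids re-simulation across replicates).
#' @return A data frame `time_s`, `ca_cyt_nM`, `ca_ex_nM` with attributes
#'   `seed`, `label`, `strain`, `protocol`, `clean_ca` (the noise-free
#'   samples).
#' @export
synth_trace <- function(condition, design, seed, clean = NULL) {
  if (is.null(clean)) clean <- clean_condition_trace(condition, design)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- nrow(clean)
  y <- clean$ca_cyt_nM * (1 + design$mult_sd * stats::rnorm(n)) +
    design$add_sd * stats::rnorm(n)
  y <- pmax(y, 0)
  structure(data.frame(time_s = clean$time_s, ca_cyt_nM = y,
                       ca_ex_nM = clean$ca_ex_nM),
            seed = as.integer(seed),
            label = condition$label,
            strain = attr(clean, "strain"),
            protocol = attr(clean, "protocol"),
            clean_ca = clean$ca_cyt_nM)
}

#' Generate a full synthetic dataset (and optionally write it out)
#'
#' Simulates every condition once, then draws `n_replicates` noisy traces
#' per condition with seeds derived from the master seed. With `write =
#' TRUE`, writes one CSV per trace plus a YAML manifest recording the
#' generating parameters — the ground truth for recovery experiments.
#' Regenerating from the same design reproduces the files byte-identically.
#'
#' @param design a [synthetic_design()].
#' @param dir output directory (created if needed) when `write = TRUE`.
#' @param write write CSVs and a manifest?
#' @return A list with `experiments` (one per condition x replicate, each
#'   carrying `trace`, `strain`, `protocol`, `label`, `replicate`, `seed`),
#'   `manifest` (list) and, when written, `files`.
#' @export
synth_dataset <- function(design, dir = NULL, write = !is.null(dir)) {
  experiments <- list()
  manifest <- list(master_seed = design$master_seed,
                   sampling_interval = design$sampling_interval,
                   add_sd = design$add_sd, mult_sd = design$mult_sd,
                   conditions = list())
  files <- character(0)
  if (write) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(design$conditions)) {
    cond <- design$conditions[[i]]
    clean <- clean_condition_trace(cond, design)
    manifest$conditions[[cond$label]] <- list(
      strain = (cond$strain %||% strain_config())$name,
      overrides = cond$overrides %||% list(),
      camb0 = attr(clean, "resting_camb"),
      protocol = unclass(attr(clean, "protocol")),
      seeds = integer(0))
    for (r in seq_len(design$n_replicates)) {
      seed <- derive_seed(design$master_seed, i, r)
      manifest$conditions[[cond$label]]$seeds <-
        c(manifest$conditions[[cond$label]]$seeds, seed)
      tr <- synth_trace(cond, design, seed, clean = clean)
      experiments[[length(experiments) + 1]] <- list(
        trace = as.data.frame(tr),
        strain = cond$strain %||% strain_config(),
        protocol = attr(tr, "protocol"),
        label = cond$label, replicate = r, seed = seed)
      if (write) {
        path <- file.path(dir, sprintf("%s_rep%d.csv", cond$label, r))
        utils::write.csv(as.data.frame(tr), path, row.names = FALSE)
        files <- c(files, path)
      }
    }
  }
  if (write) {
    mpath <- file.path(dir, "manifest.yaml")
    yaml::write_yaml(manifest, mpath, precision = 15)
    files <- c(files, mpath)
  }
  out <- list(experiments = experiments, manifest = manifest)
  if (write) out$files <- files
  out
}

#' Read calcium trace CSVs back into a dataset
#'
#' Validates the header, monotone time and non-negative concentrations;
#' attaches metadata from a per-directory manifest when present, otherwise
#' loads with a warning and marks the strain unknown.
#'
#' @param paths CSV file paths.
#' @return A list of experiments in the same shape as
#'   [synth_dataset()]`$experiments`.
#' @export
read_traces <- function(paths) {
  lapply(paths, function(p) {
    if (!file.exists(p)) stop("no such file: ", p)
    df <- utils::read.csv(p)
    need <- c("time_s", "ca_cyt_nM")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("malformed header in ", p, ": missing ",
           paste(miss, collapse = ", "))
    }
    if (is.unsorted(df$time_s, strictly = TRUE)) {
      stop("non-monotone time column in ", p)
    }
    bad <- which(df$ca_cyt_nM < 0)
    if (length(bad)) {
      stop("negative concentration in ", p, " at line ", bad[1] + 1)
    }
    mpath <- file.path(dirname(p), "manifest.yaml")
    strain_name <- "unknown"
    protocol <- stimulus_protocol()
    label <- sub("\\.csv$", "", basename(p))
    if (file.exists(mpath)) {
      man <- yaml::read_yaml(mpath)
      cond_label <- sub("_rep[0-9]+$", "", label)
      cond <- man$conditions[[cond_label]]
      if (!is.null(cond)) {
        strain_name <- cond$strain
        protocol <- do.call(stimulus_protocol, cond$protocol)
      }
    } else {
      warning("no manifest next to ", p, "; strain marked unknown")
    }
    strain <- tryCatch(strain_config(strain_name),
                       error = function(e) strain_config("wild-type"))
    list(trace = df, strain = strain, protocol = protocol,
         label = label, replicate = NA, seed = NA)
  })
}
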