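#' Define a parameter-estimation problem over calcium traces
#'
#' Free parameters are declared with bounds and a scope: `"shared"`
#' parameters take one value across all experiments (reaction constants
#' must agree between conditions), while `"per-experiment"` parameters take
#' one value per experiment (bound-protein initial levels and
#' expression-proxy rates such as `v_Pmc1` or `k_MS` may differ between
#' strains and conditions). The special free-parameter name `camb0` is the
#' resting calcium-bound calmodulin of an experiment.
#'
#' Parameters whose search range spans three or more decades are searched
#' on a log10 scale.
#'
#' @param dataset a list of experiments, each a list with elements `trace`
#'   (data frame with `time_s` and `ca_cyt_nM`), `strain` (a
#'   [strain_config()]), `protocol` (a [stimulus_protocol()]) and optional
#'   `weight`.
#' @param free data frame with columns `name`, `lower`, `upper`, `scope`.
#' @param params base [kinetic_params()] holding every fixed value.
#' @param biophys a [biophys_params()] record.
#' @param settings [solver_settings()] used inside the objective (a looser
#'   default than the reporting solver keeps fitting affordable).
#' @param baseline_weight weight of an optional steady-state residual
#'   penalising the mismatch between the model resting state and the mean
#'   pre-stimulus observation (0 disables it).
#' @return An object of class `estimation_problem`.
#' @export
estimation_problem <- function(dataset, free,
                               params = kinetic_params(),
                               biophys = biophys_params(),
                               settings = solver_settings(rtol = 1e-6,
                                 atol = c(1e-18, 1e-3, 1e-6, 1e-6),
                                 dt = 1),
                               baseline_weight = 0) {
  if (length(dataset) == 0) stop("dataset is empty")
  stopifnot(is.data.frame(free),
            all(c("name", "lower", "upper", "scope") %in% names(free)))
  if (anyDuplicated(free$name)) {
    stop("parameter named in more than one scope: ",
         paste(free$name[duplicated(free$name)], collapse = ", "))
  }
  stopifnot(all(is.finite(free$lower)), all(is.finite(free$upper)),
            all(free$lower < free$upper),
            all(free$scope %in% c("shared", "per-experiment")))
  known <- c(names(params), "camb0")
  bad <- setdiff(free$name, known)
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "))
  per_ok <- c("camb0", "v_Pmc1", "k_MS")
  per <- free$name[free$scope == "per-experiment"]
  if (!all(per %in% per_ok)) {
    stop("per-experiment scope is restricted to ",
         paste(per_ok, collapse = ", "))
  }
  free$log_scale <- free$lower > 0 & (free$upper / free$lower >= 1e3)
  structure(list(dataset = dataset, free = free, params = params,
                 biophys = biophys, settings = settings,
                 baseline_weight = baseline_weight),
            class = "estimation_problem")
}

# slot layout of the packed parameter vector: shared first, then
# per-experiment blocks in dataset order
theta_layout <- function(problem) {
  free <- problem$free
  n_exp <- length(problem$dataset)
  shared <- free[free$scope == "shared", , drop = FALSE]
  per <- free[free$scope == "per-experiment", , drop = FALSE]
  slots <- list()
  for (i in seq_len(nrow(shared))) {
    slots[[length(slots) + 1]] <- list(name = shared$name[i], exp = NA,
                                       lower = shared$lower[i],
                                       upper = shared$upper[i],
                                       log_scale = shared$log_scale[i])
  }
  for (i in seq_len(nrow(per))) {
    for (e in seq_len(n_exp)) {
      slots[[length(slots) + 1]] <- list(name = per$name[i], exp = e,
                                         lower = per$lower[i],
                                         upper = per$upper[i],
                                         log_scale = per$log_scale[i])
    }
  }
  slots
}

#' Bounds of the packed parameter vector of a problem
#'
#' @param problem an [estimation_problem()].
#' @return A list with `lower`, `upper`, `names` (slot labels) and
#'   `log_scale` flags, in packing order (shared slots first, then one slot
#'   per experiment for each per-experiment parameter).
#' @export
theta_bounds <- function(problem) {
  slots <- theta_layout(problem)
  list(lower = vapply(slots, `[[`, 0, "lower"),
       upper = vapply(slots, `[[`, 0, "upper"),
       names = vapply(slots, function(s) {
         if (is.na(s$exp)) s$name else paste0(s$name, "[", s$exp, "]")
       }, ""),
       log_scale = vapply(slots, `[[`, TRUE, "log_scale"))
}

# expand a packed theta into per-experiment (params, camb0) records
expand_theta <- function(theta, problem) {
  slots <- theta_layout(problem)
  if (length(theta) != length(slots)) {
    stop("theta has length ", length(theta), ", expected ", length(slots))
  }
  n_exp <- length(problem$dataset)
  out <- vector("list", n_exp)
  for (e in seq_len(n_exp)) {
    strain <- problem$dataset[[e]]$strain
    sp <- strain_parameters(strain, problem$params)
    camb0 <- if (is.numeric(strain$resting_camb)) strain$resting_camb else NA
    out[[e]] <- list(params = sp, camb0 = camb0)
  }
  for (k in seq_along(slots)) {
    s <- slots[[k]]
    val <- theta[k]
    targets <- if (is.na(s$exp)) seq_len(n_exp) else s$exp
    for (e in targets) {
      if (s$name == "camb0") {
        out[[e]]$camb0 <- val
      } else {
        out[[e]]$params <- patch_params(out[[e]]$params,
                                        stats::setNames(list(val), s$name))
      }
    }
  }
  out
}

#' Weighted sum-of-squares objective for an estimation problem
#'
#' Expands the packed vector, simulates every experiment from its resting
#' state, interpolates the simulated calcium onto the observed time points
#' and accumulates the weighted squared residuals (plus an optional
#' steady-state term). If `camb0` is not a free or preset value it is
#' calibrated so the model baseline matches the mean pre-stimulus
#' observation. Solver failures yield `Inf` (with a message), never an
#' error.
#'
#' @param theta packed parameter vector (see [theta_bounds()]).
#' @param problem an [estimation_problem()].
#' @return The loss, nM^2.
#' @export
sse_objective <- function(theta, problem) {
  expanded <- tryCatch(expand_theta(theta, problem), error = function(e) e)
  if (inherits(expanded, "error")) stop(expanded)
  total <- 0
  for (e in seq_along(problem$dataset)) {
    exp_e <- problem$dataset[[e]]
    px <- expanded[[e]]
    obs <- exp_e$trace
    w <- exp_e$weight %||% 1
    loss_e <- tryCatch({
      camb0 <- px$camb0
      if (is.na(camb0)) {
        target <- mean(obs$ca_cyt_nM[obs$time_s < exp_e$protocol$t_off])
        camb0 <- calibrate_resting_calmodulin(px$params, target,
                                              problem$biophys,
                                              exp_e$protocol,
                                              clamp = TRUE)
      }
      # params are already fully patched; the strain carries only the rest
      strain <- structure(list(name = "custom", overrides = list(),
                               resting_camb = camb0, target_baseline = NA),
                          class = "strain_config")
      tr <- simulate_strain(strain, px$params, problem$biophys,
                            exp_e$protocol, problem$settings)
      sim <- stats::approx(tr$time_s, tr$ca_cyt_nM, xout = obs$time_s,
                           rule = 2)$y
      loss <- sum(w * (sim - obs$ca_cyt_nM)^2)
      if (problem$baseline_weight > 0) {
        target <- mean(obs$ca_cyt_nM[obs$time_s < exp_e$protocol$t_off])
        base <- resting_baseline(px$params, camb0, problem$biophys,
                                 exp_e$protocol)
        loss <- loss + problem$baseline_weight * (base - target)^2
      }
      loss
    }, error = function(err) {
      message("objective: experiment ", e, " failed (",
              conditionMessage(err), "); returning Inf")
      Inf
    })
    total <- total + loss_e
  }
  total
}

#' Swarm settings for the particle-swarm optimizer
#'
#' Constriction-style defaults: inertia 0.729 with cognitive and social
#' coefficients 1.494. Velocities are clamped to a fraction of the search
#' range; positions are clipped to the bounds with the offending velocity
#' component zeroed (absorbing boundary).
#'
#' @param n_particles swarm size (>= 2).
#' @param n_iter iteration budget.
#' @param inertia inertia weight.
#' @param cognitive,social acceleration coefficients.
#' @param v_clamp velocity clamp as a fraction of the range per dimension.
#' @param seed RNG seed recorded in results.
#' @param ftol stop early once the best loss falls at or below this value.
#' @param patience stop early after this many iterations without relative
#'   improvement better than 1e-10 (`Inf` disables).
#' @return An object of class `swarm_settings`.
#' @export
swarm_settings <- function(n_particles = 40, n_iter = 300,
                           inertia = 0.729, cognitive = 1.494,
                           social = 1.494, v_clamp = 0.5,
                           seed = 1L, ftol = -Inf, patience = Inf) {
  stopifnot(n_particles >= 2, n_iter >= 0, cognitive > 0, social > 0,
            v_clamp > 0, v_clamp <= 1)
  structure(list(n_particles = n_particles, n_iter = n_iter,
                 inertia = inertia, cognitive = cognitive, social = social,
                 v_clamp = v_clamp, seed = as.integer(seed), ftol = ftol,
                 patience = patience),
            class = "swarm_settings")
}

#' Global-best particle swarm optimization
#'
#' Minimises `objective` over a box. Each particle keeps its personal best;
#' the swarm shares one global best. Velocity update is inertia plus
#' cognitive and social attraction with uniform random weights; positions
#' are clipped to the bounds (absorbing). Dimensions flagged `log_scale`
#' are searched in log10 space. Fully reproducible from the seed; the
#' best-loss history is monotone non-increasing.
#'
#' @param objective function of a numeric vector returning a scalar loss.
#' @param lower,upper bounds (finite, `lower < upper`).
#' @param settings a [swarm_settings()] record.
#' @param log_scale logical vector: search these dimensions in log10 space
#'   (requires positive bounds).
#' @return A `fit_result` list: `par` (best vector, original scale),
#'   `value` (best loss), `history` (best loss per iteration, element 1 =
#'   initial swarm), `n_evaluations`, `settings`, and `swarm` (final
#'   particle positions, original scale).
#' @export
pso_optimize <- function(objective, lower, upper,
                         settings = swarm_settings(),
                         log_scale = rep(FALSE, length(lower))) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(lower < upper),
            length(log_scale) == d,
            all(!log_scale | lower > 0))
  to_internal <- function(x) ifelse(log_scale, log10(x), x)
  to_external <- function(x) ifelse(log_scale, 10^x, x)
  lo <- to_internal(lower)
  hi <- to_internal(upper)
  rng <- hi - lo
  vmax <- settings$v_clamp * rng

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(settings$seed)

  n <- settings$n_particles
  pos <- matrix(stats::runif(n * d), n, d)
  pos <- sweep(sweep(pos, 2, rng, "*"), 2, lo, "+")
  vel <- matrix(stats::runif(n * d, -1, 1), n, d)
  vel <- sweep(vel, 2, vmax, "*")

  eval_pos <- function(x) objective(to_external(x))
  f <- apply(pos, 1, eval_pos)
  pbest <- pos
  pbest_f <- f
  g <- which.min(f)
  gbest <- pos[g, ]
  gbest_f <- f[g]
  history <- gbest_f
  n_eval <- n
  stagnant <- 0

  for (it in seq_len(settings$n_iter)) {
    if (gbest_f <= settings$ftol) break
    r1 <- matrix(stats::runif(n * d), n, d)
    r2 <- matrix(stats::runif(n * d), n, d)
    vel <- settings$inertia * vel +
      settings$cognitive * r1 * (pbest - pos) +
      settings$social * r2 * sweep(-pos, 2, gbest, "+")
    vel <- pmin(pmax(vel, matrix(-vmax, n, d, byrow = TRUE)),
                matrix(vmax, n, d, byrow = TRUE))
    pos <- pos + vel
    below <- sweep(pos, 2, lo, "<")
    above <- sweep(pos, 2, hi, ">")
    vel[below | above] <- 0
    pos <- pmin(pmax(pos, matrix(lo, n, d, byrow = TRUE)),
                matrix(hi, n, d, byrow = TRUE))
    f <- apply(pos, 1, eval_pos)
    n_eval <- n_eval + n
    improved <- f < pbest_f
    pbest[improved, ] <- pos[improved, , drop = FALSE]
    pbest_f[improved] <- f[improved]
    g <- which.min(pbest_f)
    prev <- gbest_f
    if (pbest_f[g] < gbest_f) {
      gbest <- pbest[g, ]
      gbest_f <- pbest_f[g]
    }
    history <- c(history, gbest_f)
    rel_gain <- if (is.finite(prev) && prev != 0)
      (prev - gbest_f) / abs(prev) else as.numeric(prev > gbest_f)
    stagnant <- if (rel_gain > 1e-10) 0 else stagnant + 1
    if (stagnant >= settings$patience) break
  }
  structure(list(par = to_external(gbest), value = gbest_f,
                 history = history, n_evaluations = n_eval,
                 settings = settings,
                 swarm = t(apply(pos, 1, to_external))),
            class = "fit_result")
}

#' Fit an estimation problem with particle-swarm optimization
#'
#' Wires [sse_objective()] into [pso_optimize()] with the problem's slot
#' layout (shared parameters occupy one slot; per-experiment parameters one
#' slot per experiment) and reports the best vector in named form.
#'
#' @param problem an [estimation_problem()].
#' @param settings a [swarm_settings()] record.
#' @return A `fit_result` augmented with `par_named` (named best vector)
#'   and `residual_loss` (loss recomputed from the best vector).
#' @export
fit_traces <- function(problem, settings = swarm_settings()) {
  b <- theta_bounds(problem)
  if ("camb0" %in% problem$free$name && problem$params$k_MS == 0 &&
      !"k_MS" %in% problem$free$name) {
    stop("camb0 is non-identifiable when the mechanosensitive rate is 0")
  }
  res <- pso_optimize(function(th) sse_objective(th, problem),
                      b$lower, b$upper, settings, b$log_scale)
  res$par_named <- stats::setNames(res$par, b$names)
  res$residual_loss <- sse_objective(res$par, problem)
  res
}

#' Parameter-recovery experiment on synthetic data
#'
#' Generates a synthetic dataset with known parameters, fits the declared
#' free parameters, and reports per-parameter relative error plus whether
#' each true value lies within the final swarm spread.
#'
#' @param design a [synthetic_design()].
#' @param free free-parameter table as in [estimation_problem()].
#' @param truth named vector of generating values for the free parameters.
#' @param settings a [swarm_settings()] record.
#' @param params,biophys base records for the problem's fixed values.
#' @param solver [solver_settings()] for the objective's simulations.
#' @return A list with `fit` (the `fit_result`), `truth`, `estimate`,
#'   `relative_error` and `within_swarm` (per free slot).
#' @export
recovery_experiment <- function(design, free, truth,
                                settings = swarm_settings(),
                                params = kinetic_params(),
                                biophys = biophys_params(),
                                solver = NULL) {
  ds <- synth_dataset(design, write = FALSE)
  dataset <- ds$experiments
  args <- list(dataset = dataset, free = free, params = params,
               biophys = biophys)
  if (!is.null(solver)) args$settings <- solver
  problem <- do.call(estimation_problem, args)
  if (nrow(free) == 0) {
    return(list(fit = NULL, truth = truth, estimate = truth,
                relative_error = stats::setNames(numeric(0), character(0)),
                within_swarm = logical(0)))
  }
  fit <- fit_traces(problem, settings)
  b <- theta_bounds(problem)
  base <- sub("\\[.*\\]$", "", b$names)
  tru <- truth[base]
  rel <- abs(fit$par - tru) / abs(tru)
  within <- vapply(seq_along(b$names), function(k) {
    rng <- range(fit$swarm[, k])
    tru[k] >= rng[1] && tru[k] <= rng[2]
  }, TRUE)
  list(fit = fit,
       truth = stats::setNames(as.numeric(tru), b$names),
       estimate = fit$par_named,
       relative_error = stats::setNames(as.numeric(rel), b$names),
       within_swarm = stats::setNames(within, b$names))
}
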