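# Harmonic boost potential (threshold + force constant selection, energy and
# force modification) and the staged Langevin protocol built on the compiled
# BAOAB integrator.

#' Summary statistics of the potential energy
#'
#' @param v numeric vector of potential-energy samples (kcal/mol), or pass
#'   the individual fields via the named arguments
#' @param v_max,v_min,v_avg,sigma_v,n_samples explicit fields
#' @return object of class `potential_stats`
#' @export
potential_stats <- function(v = NULL, v_max = NULL, v_min = NULL, v_avg = NULL,
                            sigma_v = NULL, n_samples = NULL) {
  if (!is.null(v)) {
    stopifnot(length(v) >= 2, all(is.finite(v)))
    v_max <- max(v); v_min <- min(v); v_avg <- mean(v)
    sigma_v <- stats::sd(v) * sqrt((length(v) - 1) / length(v))
    n_samples <- length(v)
  }
  stopifnot(n_samples >= 2, sigma_v >= 0,
            v_min <= v_avg, v_avg <= v_max)
  structure(list(v_max = v_max, v_min = v_min, v_avg = v_avg,
                 sigma_v = sigma_v, n_samples = as.integer(n_samples)),
            class = "potential_stats")
}

#' Boost parameters (threshold energy and harmonic force constant)
#'
#' Normally produced by [compute_boost_params()]; the constructor only
#' validates the invariants `k0 in (0, 1]` and `k >= 0`.
#'
#' @param mode `"lower_bound"` (E = Vmax) or `"upper_bound"` (E = Vmin + 1/k)
#' @param sigma_0 user limit on the boost standard deviation (kcal/mol)
#' @param E threshold energy (kcal/mol)
#' @param k harmonic force constant ((kcal/mol)^-1)
#' @param k0 dimensionless force constant
#' @export
boost_params <- function(mode, sigma_0, E, k, k0) {
  mode <- match.arg(mode, c("lower_bound", "upper_bound"))
  stopifnot(sigma_0 > 0, k >= 0, k0 > 0, k0 <= 1)
  structure(list(mode = mode, sigma_0 = sigma_0, E = E, k = k, k0 = k0),
            class = "boost_params")
}

#' @export
print.boost_params <- function(x, ...) {
  cat(sprintf("boost_params [%s]: E = %.4f kcal/mol, k = %.6g (kcal/mol)^-1, k0 = %.4f\n",
              x$mode, x$E, x$k, x$k0))
  invisible(x)
}

#' Harmonic boost energy
#'
#' \eqn{\Delta V = 0} for \eqn{V \ge E} and
#' \eqn{\Delta V = k (E - V)^2 / 2} for \eqn{V < E}; the modified potential
#' is \eqn{V^* = V + \Delta V}.
#'
#' @param V potential energy (kcal/mol), vectorised
#' @param params a [boost_params()]
#' @return boost energy (kcal/mol), same length as `V`
#' @export
boost_energy <- function(V, params) {
  stopifnot(inherits(params, "boost_params"))
  ifelse(V >= params$E, 0, 0.5 * params$k * (params$E - V)^2)
}

#' Force scaling factor on the boosted surface
#'
#' The gradient of \eqn{V^* = V + k(E-V)^2/2} is \eqn{(1 - k(E - V))}
#' times the unbiased gradient on \eqn{V < E}, and unchanged above the
#' threshold.  A negative scale signals a threshold violating
#' \eqn{E \le V_{min} + 1/k} and is an error.
#'
#' @inheritParams boost_energy
#' @return dimensionless scale in `[0, 1]`, same length as `V`
#' @export
boost_force_scale <- function(V, params) {
  stopifnot(inherits(params, "boost_params"))
  s <- ifelse(V >= params$E, 1, 1 - params$k * (params$E - V))
  if (any(s < -1e-12)) {
    stop("negative force scale: threshold E exceeds Vmin + 1/k for V = ",
         format(V[which(s < -1e-12)[1]]))
  }
  pmax(s, 0)
}

#' Compute boost parameters from potential-energy statistics
#'
#' Lower-bound mode sets the threshold at the observed maximum,
#' `E = Vmax`, with
#' \deqn{k_0 = \min(1, \frac{\sigma_0}{\sigma_V}\,\frac{V_{max}-V_{min}}{V_{max}-V_{avg}})}
#' Upper-bound mode sets `E = Vmin + 1/k` with
#' \deqn{k_0 = (1 - \sigma_0/\sigma_V)\,\frac{V_{max}-V_{min}}{V_{avg}-V_{min}}}
#' clamped to `(0, 1]`; it is infeasible when `sigma_0 >= sigma_v`.
#' In both modes `k = k0 / (Vmax - Vmin)` and the returned threshold
#' satisfies `Vmax <= E <= Vmin + 1/k`.
#'
#' @param stats a [potential_stats()]
#' @param sigma_0 upper limit on the boost standard deviation (kcal/mol);
#'   capping it keeps the boost distribution near-Gaussian so cumulant
#'   reweighting stays accurate
#' @param mode `"lower_bound"` or `"upper_bound"`
#' @return a [boost_params()]
#' @export
compute_boost_params <- function(stats, sigma_0,
                                 mode = c("lower_bound", "upper_bound")) {
  stopifnot(inherits(stats, "potential_stats"), sigma_0 > 0)
  mode <- match.arg(mode)
  if (stats$sigma_v <= 0) {
    stop("degenerate statistics: sigma_v = 0 (constant potential energy)")
  }
  span <- stats$v_max - stats$v_min
  if (span <= 0) stop("degenerate statistics: Vmax == Vmin")
  if (mode == "lower_bound") {
    k0 <- min(1.0, (sigma_0 / stats$sigma_v) * span / (stats$v_max - stats$v_avg))
    k <- k0 / span
    E <- stats$v_max
  } else {
    if (sigma_0 >= stats$sigma_v) {
      stop("upper_bound mode infeasible: sigma_0 >= sigma_v gives k0 <= 0")
    }
    k0 <- (1.0 - sigma_0 / stats$sigma_v) * span / (stats$v_avg - stats$v_min)
    if (k0 <= 0) stop("upper_bound mode infeasible: k0 <= 0")
    k0 <- min(1.0, k0)
    k <- k0 / span
    E <- stats$v_min + 1 / k
  }
  boost_params(mode, sigma_0, E, k, k0)
}

#' Langevin simulation configuration
#'
#' @param n_steps total number of integration steps
#' @param timestep integration timestep (ps)
#' @param temperature thermostat temperature (K)
#' @param friction Langevin collision frequency (ps^-1)
#' @param seed RNG seed
#' @param stride store every `stride`-th step
#' @param stages either fractions `c(cmd, equil, prod)` summing to 1 for the
#'   staged boosted protocol, or a list with explicit step counts
#'   `list(cmd =, equil =, prod =)` (overrides `n_steps`)
#' @param refresh boost-parameter refresh interval (steps) during boosted
#'   equilibration
#' @param burnin steps discarded from the start of the
#'   statistics-collection stage (relaxation from the initial structure;
#'   keeps the transient out of Vmax/Vmin)
#' @export
langevin_config <- function(n_steps, timestep = 0.002, temperature = 300,
                            friction = 2.0, seed = 1, stride = 10,
                            stages = c(0.2, 0.2, 0.6), refresh = 500,
                            burnin = 2000) {
  stopifnot(temperature > 0, timestep > 0, friction >= 0, stride >= 1,
            refresh >= 1, burnin >= 0)
  if (is.list(stages)) {
    stopifnot(all(c("cmd", "equil", "prod") %in% names(stages)))
    n_steps <- stages$cmd + stages$equil + stages$prod
  } else {
    stopifnot(length(stages) == 3, abs(sum(stages) - 1) < 1e-9,
              n_steps >= 1)
  }
  structure(list(n_steps = as.integer(n_steps), timestep = timestep,
                 temperature = temperature, friction = friction,
                 seed = as.integer(seed), stride = as.integer(stride),
                 stages = stages, refresh = as.integer(refresh),
                 burnin = as.integer(burnin)),
            class = "langevin_config")
}

stage_steps <- function(config) {
  if (is.list(config$stages)) {
    with(config$stages, c(cmd = cmd, equil = equil, prod = prod))
  } else {
    n <- config$n_steps
    cmd <- round(config$stages[1] * n)
    equil <- round(config$stages[2] * n)
    c(cmd = cmd, equil = equil, prod = n - cmd - equil)
  }
}

.segment <- function(system, x, v, config, boost_on, E, k, stats_acc, stride,
                     n_steps) {
  langevin_segment_cpp(system$kind_code, system$params, x, v, system$masses,
                       config$timestep, config$temperature, config$friction,
                       as.integer(n_steps), as.integer(stride), boost_on, E, k,
                       stats_acc$vmax, stats_acc$vmin, stats_acc$mean,
                       stats_acc$m2, stats_acc$n)
}

.stats_from_acc <- function(acc) {
  potential_stats(v_max = acc$vmax, v_min = acc$vmin, v_avg = acc$mean,
                  sigma_v = sqrt(max(acc$m2, 0) / acc$n),
                  n_samples = acc$n)
}

#' Run (optionally boosted) Langevin dynamics on a toy system
#'
#' BAOAB-discretised Langevin integration.  With `boost = NULL` the run is a
#' single unbiased segment.  With `boost = "lower_bound"` or
#' `"upper_bound"` the staged protocol is used: (i) an unbiased
#' statistics-collection stage, (ii) a boosted equilibration stage during
#' which the threshold and force constant are refreshed every
#' `config$refresh` steps from the running statistics, (iii) a production
#' stage with frozen parameters.  A fixed [boost_params()] object applies
#' that boost to the whole run without staging.
#'
#' @param system a `toy_system` (see [toy_potential()], [make_switch_chain()])
#' @param config a [langevin_config()]
#' @param boost `NULL`, a mode string, or a [boost_params()]
#' @param sigma_0 boost-width limit (kcal/mol) used in adaptive modes
#' @param x0 optional initial coordinates (defaults to `system$x0`)
#' @return object of class `gamd_run`: production-frame `positions`
#'   (matrix, one row per stored frame), `times` (ps), `records`
#'   (step/V/dV/E/k table), final `stats`, frozen `params` (or NULL), and
#'   the equilibration/collection histories
#' @export
run_langevin <- function(system, config, boost = NULL, sigma_0 = 6.0,
                         x0 = NULL) {
  stopifnot(inherits(system, "toy_system"), inherits(config, "langevin_config"))
  set.seed(config$seed)
  x <- if (is.null(x0)) system$x0 else x0
  stopifnot(length(x) == system$n_dof)
  v <- stats::rnorm(system$n_dof) *
    sqrt(KB_KCAL * config$temperature * KCAL_TO_AMU_A2_PS2 / system$masses)
  acc <- list(vmax = -Inf, vmin = Inf, mean = 0, m2 = 0, n = 0)
  dt <- config$timestep
  kBT <- KB_KCAL * config$temperature

  finish <- function(seg, params, step0, extra = list()) {
    records <- data.frame(step = step0 + seg$steps, V = seg$V, dV = seg$dV,
                          E = if (is.null(params)) Inf else params$E,
                          k = if (is.null(params)) 0 else params$k)
    if (any(abs(records$dV) > 50 * kBT)) {
      warning("boost energy exceeded 50 kT; timestep may be unstable",
              call. = FALSE)
    }
    out <- c(list(positions = seg$frames,
                  times = (step0 + seg$steps) * dt,
                  records = records,
                  stats = .stats_from_acc(list(vmax = seg$vmax, vmin = seg$vmin,
                                               mean = seg$mean, m2 = seg$m2,
                                               n = seg$nstat)),
                  params = params, config = config, system = system),
             extra)
    class(out) <- "gamd_run"
    out
  }

  if (is.null(boost)) {
    seg <- .segment(system, x, v, config, FALSE, Inf, 0, acc, config$stride,
                    config$n_steps)
    return(finish(seg, NULL, 0L))
  }
  if (inherits(boost, "boost_params")) {
    seg <- .segment(system, x, v, config, TRUE, boost$E, boost$k, acc,
                    config$stride, config$n_steps)
    return(finish(seg, boost, 0L))
  }
  mode <- match.arg(boost, c("lower_bound", "upper_bound"))
  st <- stage_steps(config)

  # (i) unbiased statistics collection; a burn-in prefix relaxes the
  # initial structure and is excluded from the running statistics
  burn <- min(config$burnin, floor(st[["cmd"]] / 2))
  if (burn > 0) {
    seg0 <- .segment(system, x, v, config, FALSE, Inf, 0, acc, 0L, burn)
    x <- seg0$x; v <- seg0$v
  }
  seg1 <- .segment(system, x, v, config, FALSE, Inf, 0, acc, config$stride,
                   st["cmd"] - burn)
  acc <- list(vmax = seg1$vmax, vmin = seg1$vmin, mean = seg1$mean,
              m2 = seg1$m2, n = seg1$nstat)
  x <- seg1$x; v <- seg1$v

  # (ii) boosted equilibration, parameters refreshed every `refresh` steps
  done <- 0L
  equil_frames <- list()
  while (done < st["equil"]) {
    chunk <- min(config$refresh, st["equil"] - done)
    params <- compute_boost_params(.stats_from_acc(acc), sigma_0, mode)
    seg <- .segment(system, x, v, config, TRUE, params$E, params$k, acc,
                    config$stride, chunk)
    acc <- list(vmax = seg$vmax, vmin = seg$vmin, mean = seg$mean,
                m2 = seg$m2, n = seg$nstat)
    x <- seg$x; v <- seg$v
    equil_frames[[length(equil_frames) + 1L]] <- seg$frames
    done <- done + chunk
  }

  # (iii) production with frozen parameters
  params <- compute_boost_params(.stats_from_acc(acc), sigma_0, mode)
  seg3 <- .segment(system, x, v, config, TRUE, params$E, params$k, acc,
                   config$stride, st["prod"])
  finish(seg3, params, st[["cmd"]] + st[["equil"]],
         extra = list(collection = seg1$frames,
                      equilibration = do.call(rbind, equil_frames)))
}

#' @export
print.gamd_run <- function(x, ...) {
  cat(sprintf("gamd_run: %d stored production frames, %d dof%s\n",
              nrow(x$positions), ncol(x$positions),
              if (is.null(x$params)) " (unbiased)" else
                sprintf(" (boosted, E = %.3f, k0 = %.3f)",
                        x$params$E, x$params$k0)))
  invisible(x)
}

#' Convert a run's stored frames to a trajectory
#' @param run a `gamd_run`
#' @param topology the matching [topology()]
#' @export
run_trajectory <- function(run, topology) {
  trajectory(topology, run$positions, time = run$times,
             frame_stride = run$config$timestep * run$config$stride)
}

#' Count well-to-well transitions of a 1D coordinate with hysteresis
#'
#' A transition is counted each time the coordinate, having last been at or
#' beyond one threshold, reaches the other.  Hysteresis suppresses the
#' barrier-top recrossing noise of a naive sign-change count.
#'
#' @param x coordinate series
#' @param lo,hi hysteresis thresholds (`lo < hi`)
#' @export
count_well_transitions <- function(x, lo = -1, hi = 1) {
  stopifnot(lo < hi)
  state <- 0L  # -1 low well, +1 high well, 0 undecided
  n <- 0L
  for (xi in x) {
    s <- if (xi <= lo) -1L else if (xi >= hi) 1L else 0L
    if (s != 0L) {
      if (state != 0L && s != state) n <- n + 1L
      state <- s
    }
  }
  n
}

#' Anharmonicity of a boost-energy sample
#'
#' Entropy gap \eqn{\gamma = S_{gauss}(\hat\sigma) - \hat S} between the
#' differential entropy of a Gaussian with the sample's standard deviation
#' and a histogram estimate of the sample's differential entropy.  Near 0
#' for Gaussian boosts; large when the boost distribution is multimodal or
#' heavy-tailed, in which case cumulant reweighting is unreliable.
#'
#' @param delta_v boost-energy samples (>= 100 values)
#' @param bins number of histogram bins for the entropy estimate
#' @return non-negative gamma; `Inf` (with a warning) for a degenerate
#'   zero-variance sample
#' @export
anharmonicity <- function(delta_v, bins = 100) {
  if (length(delta_v) < 100) {
    stop("at least 100 samples are required to estimate anharmonicity")
  }
  s <- stats::sd(delta_v)
  if (!is.finite(s) || s < 1e-12) {
    warning("constant boost energy: anharmonicity undefined, returning Inf")
    return(Inf)
  }
  s_gauss <- 0.5 * log(2 * pi * exp(1) * s^2)
  h <- graphics::hist(delta_v, breaks = bins, plot = FALSE)
  w <- diff(h$breaks)
  p <- h$counts / sum(h$counts)
  nz <- p > 0
  s_emp <- -sum(p[nz] * log(p[nz] / w[nz]))
  max(s_gauss - s_emp, 0)
}
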