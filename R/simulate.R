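#' Simulate a model with the continuous (ODE) backend
#'
#' Integrates the model's drift with an adaptive explicit Runge-Kutta
#' solver (Dormand-Prince 4(5) via \pkg{deSolve}, `rtol = 1e-8`,
#' `atol = 1e-10`) and reports the solution on the fixed `dt` output grid.
#' The tolerances over-resolve these dynamics so that `dt` acts purely as
#' an output grid, not an accuracy knob.
#'
#' @param spec A [model_spec()].
#' @param params Full parameter set from [resolve_parameters()], or a named
#'   vector/list of overrides applied to the model defaults.
#' @return A [trajectory()] on the grid `tstart, tstart + dt, ...,`
#'   capped at `tfinal`.
#' @examples
#' traj <- simulate_ode(make_basic_bacteria_model())
#' peak(traj, "B")
#' @export
simulate_ode <- function(spec, params = NULL) {
  pars <- as_full_params(spec, params)
  times <- time_grid(pars)
  y0 <- pars[spec$variables]
  plist <- as.list(pars)
  rhs <- function(t, y, p) list(spec$drift_fn(y, p))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = plist,
                      method = "ode45", rtol = 1e-8, atol = 1e-10)
  m <- unclass(sol)
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- which(!stats::complete.cases(m) | rowSums(!is.finite(m)) > 0)[1L]
    stop("ODE solver failed near t = ", format(times[min(bad, length(times))]),
         " (non-finite state)")
  }
  series <- m[, spec$variables, drop = FALSE]
  # adaptive solvers can undershoot 0 by roundoff; clamp within tolerance
  series[series < 0 & series > -1e-9] <- 0
  trajectory(times = m[, "time"], series = series,
             meta = list(backend = "ode", model = spec$id, pars = pars))
}

#' Simulate a model with the discrete-time (forward Euler) backend
#'
#' Applies the difference-equation counterpart of the model,
#' `x(t + dt) = x(t) + dt * drift(x(t))`, with the output `dt` as the
#' update step. Any component driven below zero is clamped to zero and a
#' warning reports the first step at which this happened.
#'
#' @inheritParams simulate_ode
#' @return A [trajectory()] on the `dt` grid.
#' @export
simulate_discrete <- function(spec, params = NULL) {
  pars <- as_full_params(spec, params)
  times <- time_grid(pars)
  plist <- as.list(pars)
  nv <- length(spec$variables)
  out <- matrix(NA_real_, nrow = length(times), ncol = nv,
                dimnames = list(NULL, spec$variables))
  x <- pars[spec$variables]
  out[1L, ] <- x
  dt <- pars[["dt"]]
  first_clamp <- NA_integer_
  for (i in seq_len(length(times) - 1L)) {
    x <- x + dt * spec$drift_fn(x, plist)
    if (any(!is.finite(x)))
      stop("discrete update produced non-finite state at step ", i,
           " (t = ", format(times[i + 1L]), ")")
    if (any(x < 0)) {
      if (is.na(first_clamp)) first_clamp <- i
      x[x < 0] <- 0
    }
    out[i + 1L, ] <- x
  }
  if (!is.na(first_clamp))
    warning("negative state clamped to 0, first at step ", first_clamp)
  trajectory(times = times, series = out,
             meta = list(backend = "discrete", model = spec$id, pars = pars))
}

#' Simulate a model with the stochastic (Gillespie SSA) backend
#'
#' Runs the exact stochastic simulation algorithm (direct method) over the
#' model's event decomposition: waiting times are exponential with rate
#' equal to the total propensity and events are chosen proportionally to
#' their propensities. The jump process is sampled onto the `dt` output
#' grid by carrying the last event's state forward. If the total propensity
#' reaches zero the process is absorbed and the remaining grid is filled
#' with the absorbing state. Identical `seed` and parameters give an
#' identical trajectory; the caller's RNG state is left untouched.
#'
#' When every event carries a structured kinetics description (a
#' mass-action rate constant, state-variable exponents, and an optional
#' saturation factor — true for both bundled models), the event loop runs
#' in compiled code; otherwise a plain-R loop evaluates the propensity
#' closures directly. Both paths draw the same RNG sequence (two uniforms
#' per event) and so produce identical trajectories for a given seed.
#'
#' @inheritParams simulate_ode
#' @param seed Integer RNG seed.
#' @param method `"auto"` (compiled kernel when available), `"compiled"`,
#'   or `"reference"` (the plain-R loop).
#' @return A [trajectory()] on the `dt` grid; series are nonnegative
#'   integers.
#' @examples
#' traj <- simulate_stochastic(make_basic_bacteria_model(), seed = 1)
#' @export
simulate_stochastic <- function(spec, params = NULL, seed = 123L,
                                method = c("auto", "compiled", "reference")) {
  method <- match.arg(method)
  pars <- as_full_params(spec, params)
  y0 <- pars[spec$variables]
  if (any(y0 != round(y0))) {
    warning("initial conditions rounded to integers for the stochastic backend")
    pars[spec$variables] <- round(y0)
  }
  times <- time_grid(pars)
  plist <- as.list(pars)
  nv <- length(spec$variables)
  change <- event_change_matrix(spec)
  pfn <- spec$propensity_fn
  out <- matrix(NA_real_, nrow = length(times), ncol = nv,
                dimnames = list(NULL, spec$variables))

  kin <- lapply(spec$events, `[[`, "kinetics")
  has_kinetics <- !any(vapply(kin, is.null, logical(1L)))
  if (method == "compiled" && !has_kinetics)
    stop("compiled SSA needs structured kinetics on every event")
  use_compiled <- has_kinetics && method != "reference"

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  if (use_compiled) {
    ne <- length(kin)
    powers <- matrix(0L, nrow = ne, ncol = nv,
                     dimnames = list(NULL, spec$variables))
    sat_var <- rep(-1L, ne)
    sat_const <- rep(0, ne)
    rate <- numeric(ne)
    for (j in seq_len(ne)) {
      rate[j] <- kin[[j]]$rate(plist)
      powers[j, names(kin[[j]]$powers)] <- kin[[j]]$powers
      if (!is.null(kin[[j]]$sat)) {
        sat_var[j] <- match(kin[[j]]$sat$var, spec$variables) - 1L
        sat_const[j] <- kin[[j]]$sat$const(plist)
      }
    }
    out[] <- ssa_mass_action(change, rate, powers, sat_var, sat_const,
                             pars[spec$variables], times)
  } else {
    x <- pars[spec$variables]
    t_now <- pars[["tstart"]]
    gi <- 1L  # next grid index to fill
    ngrid <- length(times)
    repeat {
      a <- pfn(x, plist)
      a0 <- sum(a)
      if (a0 <= 0) {  # absorbed: fill remaining grid with current state
        while (gi <= ngrid) { out[gi, ] <- x; gi <- gi + 1L }
        break
      }
      u <- stats::runif(2L)
      t_next <- t_now - log(u[1L]) / a0
      while (gi <= ngrid && times[gi] <= t_next) {  # state holds until t_next
        out[gi, ] <- x
        gi <- gi + 1L
      }
      if (gi > ngrid) break
      j <- findInterval(u[2L] * a0, cumsum(a)) + 1L
      x <- x + change[j, ]
      t_now <- t_next
    }
  }
  trajectory(times = times, series = out,
             meta = list(backend = "stochastic", model = spec$id,
                         pars = pars, seed = as.integer(seed)))
}

#' Run a model through a backend selected by id
#'
#' @inheritParams simulate_ode
#' @param backend One of `"ode"`, `"discrete"`, `"stochastic"`.
#' @param seed Integer seed, used by the stochastic backend only.
#' @return A [trajectory()].
#' @export
simulate_model <- function(spec, params = NULL,
                           backend = c("ode", "discrete", "stochastic"),
                           seed = 123L) {
  backend <- match.arg(backend)
  switch(backend,
         ode = simulate_ode(spec, params),
         discrete = simulate_discrete(spec, params),
         stochastic = simulate_stochastic(spec, params, seed = seed))
}

# Accept either a full resolved parameter vector or a set of overrides.
as_full_params <- function(spec, params) {
  if (is.null(params)) return(resolve_parameters(spec))
  params <- unlist(params)
  if (setequal(names(params), names(spec$parameters))) {
    validate_parameters(params[names(spec$parameters)])
    return(params[names(spec$parameters)])
  }
  resolve_parameters(spec, params)
}
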