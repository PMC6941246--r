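# Independent reference computations used by the test-suite and the
# acceptance checks. None of these call the simulation engines they verify.

#' Closed-form logistic growth
#'
#' Analytic solution of dB/dt = g*B*(1 - B/Bmax): the bacterial equation of
#' the basic model with immune killing and natural death switched off
#' (k = 0, dB = 0, I = 0).
#'
#' @param B0 Initial abundance (>= 0).
#' @param g Growth rate (>= 0).
#' @param Bmax Carrying capacity (> 0).
#' @param t Time (vectorised).
#' @return `Bmax / (1 + (Bmax/B0 - 1) * exp(-g*t))`, or 0 when `B0 = 0`.
#' @export
logistic_closed_form <- function(B0, g, Bmax, t) {
  stopifnot(B0 >= 0, Bmax > 0, g >= 0)
  if (B0 == 0) return(rep(0, length(t)))
  Bmax / (1 + (Bmax / B0 - 1) * exp(-g * t))
}

#' Interior equilibrium of the basic bacteria model
#'
#' Setting both drifts to zero with B, I > 0 gives `B* = dI/r` from the
#' immune equation and, substituting into the bacterial equation,
#' `I* = (g*(1 - B*/Bmax) - dB)/k`. The equilibrium is infeasible when
#' `r = 0` or `k = 0` (no interior solution) or when `I* < 0`.
#'
#' @param pars Parameter set containing `g`, `Bmax`, `dB`, `k`, `r`, `dI`.
#' @return List with `feasible` (logical) and, when feasible, `B` and `I`.
#' @examples
#' interior_equilibrium_basic(make_basic_bacteria_model()$parameters)
#' @export
interior_equilibrium_basic <- function(pars) {
  pars <- as.list(pars)
  if (pars$r == 0 || pars$k == 0)
    return(list(feasible = FALSE, B = NA_real_, I = NA_real_))
  B_star <- pars$dI / pars$r
  I_star <- (pars$g * (1 - B_star / pars$Bmax) - pars$dB) / pars$k
  if (I_star < 0)
    return(list(feasible = FALSE, B = B_star, I = I_star))
  list(feasible = TRUE, B = B_star, I = I_star)
}

#' Fixed-step classical RK4 reference integration
#'
#' Independent check on [simulate_ode()]: classical 4th-order Runge-Kutta
#' with a fine fixed step `dt_fine`, reported on the model's coarse output
#' grid. The fine step must divide the dynamics much more finely than the
#' output grid (`dt_fine <= dt/10`).
#'
#' @param spec A [model_spec()].
#' @param params Parameter overrides or full set.
#' @param dt_fine Fixed integration step.
#' @return A [trajectory()] on the `dt` output grid.
#' @export
rk4_fine_reference <- function(spec, params = NULL, dt_fine = 1e-3) {
  pars <- as_full_params(spec, params)
  if (dt_fine > pars[["dt"]] / 10)
    stop("dt_fine must be at most dt/10")
  grid <- time_grid(pars)
  plist <- as.list(pars)
  f <- spec$drift_fn
  out <- matrix(NA_real_, nrow = length(grid), ncol = length(spec$variables),
                dimnames = list(NULL, spec$variables))
  x <- pars[spec$variables]
  out[1L, ] <- x
  for (i in seq_len(length(grid) - 1L)) {
    # integrate one output interval with substeps of size <= dt_fine
    span <- grid[i + 1L] - grid[i]
    nsub <- max(1L, ceiling(span / dt_fine))
    h <- span / nsub
    for (s in seq_len(nsub)) {
      k1 <- f(x, plist)
      k2 <- f(x + h / 2 * k1, plist)
      k3 <- f(x + h / 2 * k2, plist)
      k4 <- f(x + h * k3, plist)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(x)))
        stop("RK4 reference produced non-finite state near t = ",
             format(grid[i]))
    }
    out[i + 1L, ] <- x
  }
  trajectory(times = grid, series = out,
             meta = list(backend = "rk4_reference", model = spec$id,
                         pars = pars))
}

#' Empirical convergence order of the discrete backend
#'
#' Runs the forward-Euler and ODE backends at each step size, measures the
#' grid-averaged absolute deviation between them, and returns the empirical
#' orders `log2(err(dt)/err(dt/2))` for successive halvings. The
#' grid-averaged (L1) norm is used because the default dynamics contain a
#' near-singular immune spike at which the max-norm error is pre-asymptotic
#' at practical step sizes; the mean error exhibits the scheme's first
#' order.
#'
#' @param spec A [model_spec()].
#' @param dts Decreasing sequence of step sizes, each half the previous.
#' @param params Optional parameter overrides applied at every step size.
#' @return List with `dts`, `errors` (one per dt), and `orders` (one per
#'   successive pair).
#' @export
euler_convergence_order <- function(spec, dts = c(0.05, 0.025, 0.0125),
                                    params = NULL) {
  stopifnot(length(dts) >= 2L, all(diff(dts) < 0))
  errors <- vapply(dts, function(dtv) {
    ov <- c(as.list(params), list(dt = dtv))
    ode <- simulate_ode(spec, ov)
    eul <- suppressWarnings(simulate_discrete(spec, ov))
    mean(abs(eul$series - ode$series))
  }, numeric(1L))
  orders <- log2(errors[-length(errors)] / errors[-1L])
  list(dts = dts, errors = errors, orders = orders)
}
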