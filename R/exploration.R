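#' Peak (maximum) of a variable over a trajectory
#'
#' The headline outcome metric: the maximum of the variable's series over
#' the reported output grid.
#'
#' @param traj A [trajectory()].
#' @param variable Variable name.
#' @return A single number.
#' @export
peak <- function(traj, variable) {
  max(get_series(traj, variable))
}

#' Final reported value of a variable
#'
#' Companion metric to [peak()] for steady-state checks: the last value on
#' the output grid.
#'
#' @inheritParams peak
#' @return A single number.
#' @export
final_value <- function(traj, variable) {
  s <- get_series(traj, variable)
  s[length(s)]
}

metric_registry <- list(peak = peak, final_value = final_value)

#' Logarithmic parameter grid
#'
#' `n` values `10^e` with exponents equally spaced from `lo_exponent` to
#' `hi_exponent` inclusive — the conventional grid for sweeping rate
#' parameters spanning orders of magnitude.
#'
#' @param lo_exponent,hi_exponent Decadic exponents of the first and last
#'   grid value (`lo_exponent <= hi_exponent`).
#' @param n Number of grid points (`n >= 1`).
#' @return Numeric vector of length `n`, strictly increasing for `n > 1`.
#' @examples
#' log_grid(-5, -2, 20)  # the r grid of the peak-load sweep
#' @export
log_grid <- function(lo_exponent, hi_exponent, n) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a positive count (empty grid requested)")
  if (lo_exponent > hi_exponent)
    stop("lo_exponent must not exceed hi_exponent")
  10^seq(lo_exponent, hi_exponent, length.out = n)
}

#' Sweep one parameter over a grid and record an outcome metric
#'
#' For each grid value, runs one simulation with that value substituted
#' into the base parameter set (all other inputs fixed) and records the
#' chosen metric of the chosen variable. This automates the
#' run-loop-record-plot workflow for questions like "how does peak
#' bacterial load change with the immune activation rate?".
#'
#' @param spec A [model_spec()].
#' @param base Base parameter set (overrides or full set; defaults used if
#'   `NULL`).
#' @param parameter Name of the parameter to sweep.
#' @param values Strictly increasing numeric grid of parameter values,
#'   e.g. from [log_grid()].
#' @param metric `"peak"` or `"final_value"`.
#' @param variable Variable the metric is taken over.
#' @param backend Backend id passed to [simulate_model()].
#' @param seeds For the stochastic backend, one seed per grid point
#'   (reproducibility: each grid value gets its own fixed stream).
#' @return An object of class `sweep_result`: list with `parameter`,
#'   `values`, `metric`, `variable`, `outcomes`, `meta`.
#' @examples
#' sw <- sweep_parameter(make_basic_bacteria_model(), parameter = "r",
#'                       values = log_grid(-5, -2, 5),
#'                       metric = "peak", variable = "B")
#' as.data.frame(sw)
#' @export
sweep_parameter <- function(spec, base = NULL, parameter, values,
                            metric = c("peak", "final_value"), variable,
                            backend = c("ode", "discrete", "stochastic"),
                            seeds = NULL) {
  metric <- match.arg(metric)
  backend <- match.arg(backend)
  if (!parameter %in% names(spec$parameters))
    stop("unknown parameter '", parameter, "' for model '", spec$id, "'")
  if (!variable %in% spec$variables)
    stop("unknown variable '", variable, "' for model '", spec$id, "'")
  if (length(values) < 1L) stop("empty grid: at least one value required")
  if (length(values) > 1L && any(diff(values) <= 0))
    stop("grid values must be strictly increasing")
  if (backend == "stochastic") {
    if (is.null(seeds)) seeds <- seq_along(values)
    if (length(seeds) != length(values))
      stop("need exactly one seed per grid point (",
           length(values), " values, ", length(seeds), " seeds)")
  }
  base_pars <- as_full_params(spec, base)
  metric_fn <- metric_registry[[metric]]
  outcomes <- vapply(seq_along(values), function(i) {
    pars <- base_pars
    pars[[parameter]] <- values[i]
    traj <- tryCatch(
      simulate_model(spec, pars, backend = backend,
                     seed = if (backend == "stochastic") seeds[i] else 123L),
      error = function(e) stop("sweep failed at ", parameter, " = ",
                               format(values[i]), ": ", conditionMessage(e),
                               call. = FALSE))
    metric_fn(traj, variable)
  }, numeric(1L))
  structure(
    list(parameter = parameter, values = values, metric = metric,
         variable = variable, outcomes = outcomes,
         meta = list(backend = backend, model = spec$id, base = base_pars,
                     seeds = if (backend == "stochastic") seeds)),
    class = "sweep_result")
}

#' @export
as.data.frame.sweep_result <- function(x, ...) {
  df <- data.frame(x$values, x$outcomes)
  names(df) <- c(x$parameter, paste0(x$metric, "_", x$variable))
  df
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Sweep of ", x$parameter, " (", length(x$values), " values, ",
      x$meta$backend, " backend, model ", x$meta$model, ")\n", sep = "")
  cat("Outcome: ", x$metric, " of ", x$variable, "\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' Plot a sweep result
#'
#' Log-log scatter of outcome against parameter value, the conventional
#' presentation for order-of-magnitude sweeps.
#'
#' @param x A `sweep_result`.
#' @param log Axis log spec, default `"xy"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sweep_result <- function(x, log = "xy", ...) {
  graphics::plot(x$values, x$outcomes, log = log,
                 xlab = x$parameter,
                 ylab = paste(x$metric, "of", x$variable), ...)
  invisible(x)
}
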