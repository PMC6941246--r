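#' Trajectory: simulation output container
#'
#' Holds the output time grid and one series per model variable, plus
#' metadata on how the run was produced.
#'
#' @param times Strictly increasing numeric vector starting at `tstart`.
#' @param series Numeric matrix, one column per variable (named), with
#'   `length(times)` rows.
#' @param meta List with at least `backend`, `model`, and `pars`; `seed`
#'   when stochastic.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, series, meta = list()) {
  series <- as.matrix(series)
  stopifnot(is.numeric(times), nrow(series) == length(times),
            !is.null(colnames(series)))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(times = times, series = series, meta = meta),
            class = "trajectory")
}

#' Time grid used by the fixed-step and output samplers
#'
#' The grid is `tstart, tstart + dt, ...`; its final point is exactly
#' `tfinal` when `(tfinal - tstart)/dt` is integral (up to floating-point
#' slack), otherwise the grid stops at the last multiple not exceeding
#' `tfinal`.
#'
#' @param pars Parameter set containing `tstart`, `tfinal`, `dt`.
#' @return Numeric vector of output times.
#' @export
time_grid <- function(pars) {
  nsteps <- floor((pars[["tfinal"]] - pars[["tstart"]]) / pars[["dt"]] + 1e-9)
  pars[["tstart"]] + pars[["dt"]] * (0:nsteps)
}

#' Extract one variable's series from a trajectory
#'
#' @param traj A [trajectory()].
#' @param variable Variable name.
#' @return Numeric vector of the same length as `traj$times`.
#' @export
get_series <- function(traj, variable) {
  stopifnot(inherits(traj, "trajectory"))
  if (!variable %in% colnames(traj$series))
    stop("unknown variable '", variable, "'; trajectory has: ",
         paste(colnames(traj$series), collapse = ", "))
  traj$series[, variable]
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, x$series, check.names = FALSE)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory (", x$meta$backend %||% "?", " backend, model ",
      x$meta$model %||% "?", ")\n", sep = "")
  cat(length(x$times), "time points in [", x$times[1L], ",",
      x$times[length(x$times)], "], variables:",
      paste(colnames(x$series), collapse = ", "), "\n")
  rng <- apply(x$series, 2L, range)
  for (v in colnames(x$series))
    cat("  ", v, ": range [", format(rng[1L, v]), ", ",
        format(rng[2L, v]), "]\n", sep = "")
  invisible(x)
}

#' Plot a trajectory's time series
#'
#' One line per variable on a common (optionally log) ordinate axis.
#'
#' @param x A [trajectory()].
#' @param log Axis log spec as in [graphics::plot()], e.g. `"y"`.
#' @param ... Further arguments passed to [graphics::matplot()].
#' @export
plot.trajectory <- function(x, log = "", ...) {
  s <- x$series
  if (grepl("y", log)) s[s <= 0] <- NA  # log axis cannot show zeros
  graphics::matplot(x$times, s, type = "l", lty = 1,
                    col = seq_len(ncol(s)) + 1L,
                    xlab = "time", ylab = "abundance", log = log, ...)
  graphics::legend("topright", legend = colnames(s), lty = 1,
                   col = seq_len(ncol(s)) + 1L, bty = "n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
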