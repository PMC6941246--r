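# CSV and config I/O. Trajectories are written at full double precision
# (%.17g) so that read(write(x)) reproduces every value exactly as
# formatted and identical runs produce byte-identical files.

#' Write a trajectory to CSV
#'
#' Header is `time` followed by the variable names in model order; values
#' are written at full double precision (17 significant digits), so a
#' round-trip through [read_trajectory_csv()] preserves every value.
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  if (ncol(traj$series) < 1L)
    stop("trajectory has no variables; at least one is required")
  header <- paste(c("time", colnames(traj$series)), collapse = ",")
  m <- cbind(traj$times, traj$series)
  rows <- apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' Inverse of [write_trajectory_csv()]. The first column must be `time`;
#' remaining columns become the variable series.
#'
#' @param path CSV file path.
#' @return A [trajectory()] (meta records only the source path).
#' @export
read_trajectory_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("malformed trajectory CSV '", path, "': need a header and data")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (header[1L] != "time" || length(header) < 2L)
    stop("malformed trajectory CSV '", path,
         "' at line 1: header must be time,<variables>")
  ncols <- length(header)
  vals <- lapply(2:length(lines), function(i) {
    fields <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    if (length(fields) != ncols)
      stop("malformed trajectory CSV '", path, "' at line ", i, ": expected ",
           ncols, " fields, found ", length(fields))
    v <- suppressWarnings(as.numeric(fields))
    if (anyNA(v))
      stop("malformed trajectory CSV '", path, "' at line ", i,
           ": non-numeric value")
    v
  })
  m <- do.call(rbind, vals)
  colnames(m) <- header
  trajectory(times = m[, "time"],
             series = m[, -1L, drop = FALSE],
             meta = list(source = path))
}

#' Write a sweep result to CSV
#'
#' Two data columns (parameter value, outcome) preceded by `#`-prefixed
#' metadata header lines recording the model, backend, metric, and
#' variable.
#'
#' @param sweep A `sweep_result` from [sweep_parameter()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  meta <- c(
    paste0("# model: ", sweep$meta$model),
    paste0("# backend: ", sweep$meta$backend),
    paste0("# metric: ", sweep$metric, " of ", sweep$variable))
  header <- paste(c(sweep$parameter,
                    paste0(sweep$metric, "_", sweep$variable)),
                  collapse = ",")
  rows <- sprintf("%.17g,%.17g", sweep$values, sweep$outcomes)
  writeLines(c(meta, header, rows), path)
  invisible(path)
}

#' Read a run configuration file
#'
#' Accepts YAML or JSON (chosen by file extension, falling back to YAML).
#' Recognised keys: `model`, `backend`, `seed`, `overrides` (name-value
#' map), `sweep` (block with `parameter`, `lo`, `hi`, `n`, `metric`,
#' `variable`), `out`, `plot`, `quiet`.
#'
#' @param path Config file path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg)) stop("config file must contain a mapping of settings")
  known <- c("model", "backend", "seed", "overrides", "sweep", "out",
             "plot", "quiet")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config field ", paste(unknown, collapse = ", "))
  cfg
}

# INFO-level logging to stderr, suppressed by quiet = TRUE.
log_info <- function(quiet, ...) {
  if (!isTRUE(quiet)) message("INFO: ", ...)
}
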