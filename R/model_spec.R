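#' Declarative compartmental model specification
#'
#' A `model_spec` bundles everything the simulation backends need to run a
#' small compartmental model: the ordered variable names, the parameter
#' defaults (initial conditions, rate constants, and time settings share one
#' flat namespace, mirroring the simulator call signatures), the
#' deterministic drift as a list of signed rate terms per variable, and a
#' stochastic event decomposition (state-change vectors plus propensity
#' functions) whose signed sum reproduces the drift.
#'
#' Rate terms and propensities are stored as evaluable functions of
#' `(state, pars)` together with a human-readable string form used by
#' [describe_model()]. `drift_fn` and `propensity_fn` are combined fast
#' evaluators; when not supplied they are assembled from the term lists.
#'
#' @param id Short string identifier, e.g. `"basicbacteria"`.
#' @param variables Character vector of variable names, in order.
#' @param parameters Named numeric vector of parameter defaults. Must
#'   include the time settings `tstart`, `tfinal`, `dt` and one initial
#'   condition named after each variable.
#' @param drift_terms Named list (one element per variable) of lists of
#'   terms; each term is `list(label = <string>, fn = function(state, pars))`
#'   returning a signed rate.
#' @param events List of stochastic events; each is
#'   `list(name = <string>, change = <named integer vector>,
#'   label = <string>, fn = function(state, pars))` with `fn` returning a
#'   nonnegative propensity.
#' @param drift_fn Optional `function(state, pars)` returning the full drift
#'   vector (one element per variable); defaults to summing `drift_terms`.
#' @param propensity_fn Optional `function(state, pars)` returning all event
#'   propensities at once; defaults to evaluating `events` one by one.
#'
#' @return An object of class `model_spec`.
#' @seealso [make_basic_bacteria_model()], [make_saturated_immunity_model()]
#' @export
model_spec <- function(id, variables, parameters, drift_terms, events,
                       drift_fn = NULL, propensity_fn = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(variables), length(variables) >= 1L,
            is.numeric(parameters), !is.null(names(parameters)))
  if (!all(variables %in% names(parameters)))
    stop("every variable needs an initial-condition default named after it")
  if (!all(c("tstart", "tfinal", "dt") %in% names(parameters)))
    stop("parameters must include tstart, tfinal and dt")
  if (!setequal(names(drift_terms), variables))
    stop("drift_terms must have exactly one entry per variable")
  drift_terms <- drift_terms[variables]
  for (ev in events) {
    if (!all(names(ev$change) %in% variables))
      stop("event '", ev$name, "' changes an undeclared variable")
  }
  if (is.null(drift_fn)) {
    drift_fn <- function(state, pars) {
      vapply(drift_terms, function(terms) {
        sum(vapply(terms, function(tm) tm$fn(state, pars), numeric(1L)))
      }, numeric(1L))
    }
  }
  if (is.null(propensity_fn)) {
    propensity_fn <- function(state, pars) {
      vapply(events, function(ev) ev$fn(state, pars), numeric(1L))
    }
  }
  structure(
    list(id = id, variables = variables, parameters = parameters,
         drift_terms = drift_terms, events = events,
         drift_fn = drift_fn, propensity_fn = propensity_fn),
    class = "model_spec")
}

#' Evaluate the deterministic drift of a model
#'
#' @param spec A [model_spec()].
#' @param state Named numeric vector of variable values.
#' @param pars Named list or vector of parameter values.
#' @return Named numeric vector: d(state)/dt, one element per variable.
#' @export
eval_drift <- function(spec, state, pars) {
  d <- spec$drift_fn(state, as.list(pars))
  names(d) <- spec$variables
  d
}

#' Evaluate all event propensities of a model
#'
#' @inheritParams eval_drift
#' @return Numeric vector of nonnegative rates, one per event, named by
#'   event name.
#' @export
eval_propensities <- function(spec, state, pars) {
  a <- spec$propensity_fn(state, as.list(pars))
  names(a) <- vapply(spec$events, `[[`, character(1L), "name")
  a
}

#' State-change (stoichiometry) matrix of a model's events
#'
#' @param spec A [model_spec()].
#' @return Integer matrix with one row per event and one column per
#'   variable; entry (i, j) is the increment of variable j when event i
#'   fires.
#' @export
event_change_matrix <- function(spec) {
  m <- matrix(0L, nrow = length(spec$events), ncol = length(spec$variables),
              dimnames = list(vapply(spec$events, `[[`, character(1L), "name"),
                              spec$variables))
  for (i in seq_along(spec$events)) {
    ch <- spec$events[[i]]$change
    m[i, names(ch)] <- as.integer(ch)
  }
  m
}

#' Human-readable description of a model
#'
#' Prints the model's variables, parameter defaults, drift equations (as the
#' signed sum of their rate-term strings), and the stochastic event
#' decomposition.
#'
#' @param spec A [model_spec()] or a registered model id string.
#' @return Invisibly, the character vector of lines printed.
#' @export
describe_model <- function(spec) {
  if (is.character(spec)) spec <- get_app(spec)$spec
  stopifnot(inherits(spec, "model_spec"))
  lines <- c(
    paste0("Model: ", spec$id),
    paste0("Variables: ", paste(spec$variables, collapse = ", ")),
    "Drift equations:")
  for (v in spec$variables) {
    labs <- vapply(spec$drift_terms[[v]], `[[`, character(1L), "label")
    rhs <- paste(labs, collapse = " ")
    rhs <- sub("^\\+ ", "", rhs)
    lines <- c(lines, paste0("  d", v, "/dt = ", rhs))
  }
  lines <- c(lines, "Stochastic events (change | propensity):")
  cm <- event_change_matrix(spec)
  for (i in seq_along(spec$events)) {
    ev <- spec$events[[i]]
    chg <- paste(sprintf("%+d %s", cm[i, cm[i, ] != 0L],
                         colnames(cm)[cm[i, ] != 0L]), collapse = ", ")
    lines <- c(lines, paste0("  ", ev$name, ": ", chg, " | ", ev$label))
  }
  lines <- c(lines, "Defaults:",
             paste0("  ", paste(names(spec$parameters),
                                vapply(spec$parameters, format, character(1L)),
                                sep = " = ", collapse = ", ")))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.model_spec <- function(x, ...) {
  describe_model(x)
  invisible(x)
}
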