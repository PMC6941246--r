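#' Basic bacteria-immune response model
#'
#' A two-compartment predator-prey-type model of an acute bacterial
#' infection. Bacteria `B` grow logistically with rate `g` up to carrying
#' capacity `Bmax`, die naturally at rate `dB`, and are killed by the immune
#' response at rate `k*I`. The immune response `I` is activated
#' proportionally to the product of bacteria and current response
#' (mass-action term `r*B*I`) and decays at rate `dI`:
#'
#' \deqn{dB/dt = g B (1 - B/Bmax) - d_B B - k B I}
#' \deqn{dI/dt = r B I - d_I I}
#'
#' Units are arbitrary: abundances for `B` and `I`, and a time unit fixed
#' implicitly by the rate parameters. Defaults give an acute infection that
#' peaks and is cleared within the 30-unit simulation window:
#' `B = 10, I = 1, g = 1, Bmax = 1e5, dB = 0.1, k = 1e-6, r = 0.001,
#' dI = 1, tstart = 0, tfinal = 30, dt = 0.05`.
#'
#' For the stochastic backend the logistic term is decomposed into a birth
#' event at rate `g*B` and a density-dependent death event at rate
#' `g*B^2/Bmax`, so all propensities stay nonnegative even when `B > Bmax`;
#' the six events are B birth, B density-dependent death, B natural death,
#' B killed by I, I activation, and I decay.
#'
#' @return A [model_spec()] with id `"basicbacteria"`.
#' @examples
#' spec <- make_basic_bacteria_model()
#' eval_drift(spec, c(B = 10, I = 1), spec$parameters)
#' @export
make_basic_bacteria_model <- function() {
  pars <- c(B = 10, I = 1, g = 1, Bmax = 1e5, dB = 0.1, k = 1e-6,
            r = 0.001, dI = 1, tstart = 0, tfinal = 30, dt = 0.05)
  drift_terms <- list(
    B = list(
      list(label = "+ g*B*(1 - B/Bmax)",
           fn = function(x, p) p$g * x[["B"]] * (1 - x[["B"]] / p$Bmax)),
      list(label = "- dB*B", fn = function(x, p) -p$dB * x[["B"]]),
      list(label = "- k*B*I", fn = function(x, p) -p$k * x[["B"]] * x[["I"]])),
    I = list(
      list(label = "+ r*B*I", fn = function(x, p) p$r * x[["B"]] * x[["I"]]),
      list(label = "- dI*I", fn = function(x, p) -p$dI * x[["I"]])))
  events <- list(
    list(name = "B_birth", change = c(B = 1L), label = "g*B",
         fn = function(x, p) p$g * x[["B"]],
         kinetics = list(rate = function(p) p$g, powers = c(B = 1L))),
    list(name = "B_density_death", change = c(B = -1L), label = "g*B^2/Bmax",
         fn = function(x, p) p$g * x[["B"]]^2 / p$Bmax,
         kinetics = list(rate = function(p) p$g / p$Bmax, powers = c(B = 2L))),
    list(name = "B_death", change = c(B = -1L), label = "dB*B",
         fn = function(x, p) p$dB * x[["B"]],
         kinetics = list(rate = function(p) p$dB, powers = c(B = 1L))),
    list(name = "B_killed", change = c(B = -1L), label = "k*B*I",
         fn = function(x, p) p$k * x[["B"]] * x[["I"]],
         kinetics = list(rate = function(p) p$k, powers = c(B = 1L, I = 1L))),
    list(name = "I_activation", change = c(I = 1L), label = "r*B*I",
         fn = function(x, p) p$r * x[["B"]] * x[["I"]],
         kinetics = list(rate = function(p) p$r, powers = c(B = 1L, I = 1L))),
    list(name = "I_decay", change = c(I = -1L), label = "dI*I",
         fn = function(x, p) p$dI * x[["I"]],
         kinetics = list(rate = function(p) p$dI, powers = c(I = 1L))))
  model_spec(
    id = "basicbacteria", variables = c("B", "I"), parameters = pars,
    drift_terms = drift_terms, events = events,
    drift_fn = function(x, p) {
      B <- x[[1L]]; I <- x[[2L]]
      c(p$g * B * (1 - B / p$Bmax) - p$dB * B - p$k * B * I,
        p$r * B * I - p$dI * I)
    },
    propensity_fn = function(x, p) {
      B <- x[[1L]]; I <- x[[2L]]
      c(p$g * B, p$g * B * B / p$Bmax, p$dB * B, p$k * B * I,
        p$r * B * I, p$dI * I)
    })
}

#' Bacteria model with saturating immune activation
#'
#' Identical to [make_basic_bacteria_model()] except that immune activation
#' saturates at high bacterial load: the mass-action term `r*B*I` is
#' replaced by `r*B*I/(s + B)`. For `B` well below the saturation constant
#' `s` the response grows at a per-capita rate proportional to `B` (about
#' `r*B/s`); for `B` well above `s` it grows at the fixed maximum per-capita
#' rate `r`, independent of bacterial load.
#'
#' \deqn{dI/dt = r B I / (s + B) - d_I I}
#'
#' Defaults change to `r = 1e3` and `s = 1e3` (with the saturating form,
#' `r` is a per-time maximum rate rather than a per-abundance-per-time
#' constant, so a much larger value is needed to trigger the response); all
#' other defaults match the basic model.
#'
#' @return A [model_spec()] with id `"basicbacteria_saturated"`.
#' @examples
#' spec <- make_saturated_immunity_model()
#' eval_drift(spec, c(B = 1e3, I = 1), spec$parameters)
#' @export
make_saturated_immunity_model <- function() {
  base <- make_basic_bacteria_model()
  pars <- c(base$parameters[setdiff(names(base$parameters), c("r"))],
            r = 1e3, s = 1e3)
  # keep the printed signature order: ..., r, dI, tstart, tfinal, dt, s
  pars <- pars[c("B", "I", "g", "Bmax", "dB", "k", "r", "dI",
                 "tstart", "tfinal", "dt", "s")]
  drift_terms <- base$drift_terms
  drift_terms$I[[1L]] <- list(
    label = "+ r*B*I/(s + B)",
    fn = function(x, p) p$r * x[["B"]] * x[["I"]] / (p$s + x[["B"]]))
  events <- base$events
  i_act <- which(vapply(events, `[[`, character(1L), "name") == "I_activation")
  events[[i_act]] <- list(
    name = "I_activation", change = c(I = 1L), label = "r*B*I/(s + B)",
    fn = function(x, p) p$r * x[["B"]] * x[["I"]] / (p$s + x[["B"]]),
    kinetics = list(rate = function(p) p$r, powers = c(B = 1L, I = 1L),
                    sat = list(var = "B", const = function(p) p$s)))
  model_spec(
    id = "basicbacteria_saturated", variables = c("B", "I"),
    parameters = pars, drift_terms = drift_terms, events = events,
    drift_fn = function(x, p) {
      B <- x[[1L]]; I <- x[[2L]]
      c(p$g * B * (1 - B / p$Bmax) - p$dB * B - p$k * B * I,
        p$r * B * I / (p$s + B) - p$dI * I)
    },
    propensity_fn = function(x, p) {
      B <- x[[1L]]; I <- x[[2L]]
      c(p$g * B, p$g * B * B / p$Bmax, p$dB * B, p$k * B * I,
        p$r * B * I / (p$s + B), p$dI * I)
    })
}

#' Resolve a model's parameter set with user overrides
#'
#' Starts from the model's printed defaults and applies the supplied
#' overrides. Initial conditions, rate constants, and time settings live in
#' one flat namespace named exactly as in the simulator signatures (`B`,
#' `I`, `g`, `Bmax`, `dB`, `k`, `r`, `dI`, `tstart`, `tfinal`, `dt`, and
#' `s` for the saturated model).
#'
#' @param spec A [model_spec()].
#' @param overrides Named numeric vector or list of values to replace
#'   defaults; may be empty.
#' @return Named numeric vector: the full validated parameter set.
#' @examples
#' resolve_parameters(make_basic_bacteria_model(), c(g = 0.5, r = 0.002))
#' @export
resolve_parameters <- function(spec, overrides = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  pars <- spec$parameters
  if (length(overrides)) {
    overrides <- unlist(overrides)
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be named")
    unknown <- setdiff(names(overrides), names(pars))
    if (length(unknown))
      stop("unknown parameter ", paste(unknown, collapse = ", "),
           " for model '", spec$id, "'")
    pars[names(overrides)] <- as.numeric(overrides)
  }
  validate_parameters(pars)
  pars
}

validate_parameters <- function(pars) {
  bad <- names(pars)[!is.finite(pars) | pars < 0]
  # tstart may be any finite value >= 0 per the nonnegativity contract
  if (length(bad))
    stop("parameter ", paste(bad, collapse = ", "),
         " must be finite and nonnegative")
  if ("Bmax" %in% names(pars) && pars[["Bmax"]] <= 0)
    stop("parameter Bmax must be > 0")
  if (pars[["dt"]] <= 0) stop("parameter dt must be > 0")
  if (pars[["tfinal"]] <= pars[["tstart"]])
    stop("parameter tfinal must be greater than tstart")
  invisible(pars)
}
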