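# Shared fixtures: random nonnegative states and parameter draws used by
# the property-style tests. Draw ranges keep the dynamics bounded so the
# fixed-step backends stay finite over short horizons.

basic <- make_basic_bacteria_model()
saturated <- make_saturated_immunity_model()

random_state <- function() {
  c(B = stats::runif(1, 0, 2e5), I = stats::runif(1, 0, 1e6))
}

random_params <- function(spec) {
  ov <- c(B = stats::runif(1, 0, 1000), I = stats::runif(1, 0, 100),
          g = stats::runif(1, 0, 2), Bmax = stats::runif(1, 1e3, 1e6),
          dB = stats::runif(1, 0, 1), k = 10^stats::runif(1, -8, -5),
          r = 10^stats::runif(1, -5, -2), dI = stats::runif(1, 0, 2),
          tfinal = stats::runif(1, 1, 5))
  if ("s" %in% names(spec$parameters))
    ov <- c(ov, s = 10^stats::runif(1, -1, 4))
  resolve_parameters(spec, ov)
}
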