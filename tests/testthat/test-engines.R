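test_that("ODE backend reports the fixed output grid", {
  traj <- simulate_ode(basic)
  expect_length(traj$times, 601)
  expect_equal(traj$times[1], 0)
  expect_equal(traj$times[601], 30)
  expect_equal(diff(traj$times), rep(0.05, 600))
  expect_identical(colnames(traj$series), c("B", "I"))
  # grid stops at the last multiple of dt below tfinal when not integral
  traj2 <- simulate_ode(basic, c(tfinal = 1.07, dt = 0.25))
  expect_equal(traj2$times, c(0, 0.25, 0.5, 0.75, 1))
})

test_that("ODE backend with B0 = 0 decouples: B stays 0, I decays exponentially", {
  traj <- simulate_ode(basic, c(B = 0))
  expect_true(all(traj$series[, "B"] == 0))
  expect_equal(traj$series[, "I"], exp(-traj$times),
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("ODE backend matches the closed-form logistic limit", {
  traj <- simulate_ode(basic, c(k = 0, dB = 0, I = 0))
  ref <- logistic_closed_form(10, 1, 1e5, traj$times)
  expect_lt(max(abs(traj$series[, "B"] - ref) / ref), 1e-6)
})

test_that("discrete backend performs the forward-Euler hand-checked first step", {
  traj <- suppressWarnings(simulate_discrete(basic))
  expect_equal(unname(traj$series[2, "B"]), 10.4499495, tolerance = 1e-12)
  expect_equal(unname(traj$series[2, "I"]), 0.9505, tolerance = 1e-12)
})

test_that("discrete backend is exactly zero from the absorbing origin", {
  traj <- simulate_discrete(basic, c(B = 0, I = 0))
  expect_true(all(traj$series == 0))
})

test_that("discrete-to-ODE deviation halves with the step (first order)", {
  co <- euler_convergence_order(basic)
  factors <- co$errors[-3] / co$errors[-1]
  expect_true(all(factors >= 1.5 & factors <= 2.5))
})

test_that("discrete backend clamps negative states with a warning and errors on overflow", {
  expect_warning(simulate_discrete(basic), "clamped.*step")
  expect_error(suppressWarnings(simulate_discrete(basic, c(g = 1e200))),
               "non-finite state at step")
})

test_that("stochastic backend propensities and absorbing state behave as specified", {
  a <- eval_propensities(basic, c(B = 10, I = 1), basic$parameters)
  expect_equal(unname(a), c(10, 1e-3, 1, 1e-5, 0.01, 1), tolerance = 1e-12)
  traj <- simulate_stochastic(basic, c(B = 0, I = 0), seed = 99)
  expect_true(all(traj$series == 0))
  expect_length(traj$times, 601)
})

test_that("stochastic backend is reproducible and leaves the caller's RNG alone", {
  a <- simulate_stochastic(basic, c(tfinal = 5), seed = 11)
  b <- simulate_stochastic(basic, c(tfinal = 5), seed = 11)
  expect_identical(a$series, b$series)
  d <- simulate_stochastic(basic, c(tfinal = 5), seed = 12)
  expect_false(identical(a$series, d$series))

  set.seed(123); u1 <- runif(5)
  set.seed(123); invisible(simulate_stochastic(basic, c(tfinal = 1), seed = 5))
  u2 <- runif(5)
  expect_identical(u1, u2)
})

test_that("compiled and plain-R stochastic paths draw identical trajectories", {
  a <- simulate_stochastic(basic, c(tfinal = 5), seed = 7, method = "compiled")
  b <- simulate_stochastic(basic, c(tfinal = 5), seed = 7, method = "reference")
  expect_identical(a$series, b$series)
  ov <- c(B = 50, I = 5, r = 1.2, s = 20, tfinal = 2)
  a2 <- simulate_stochastic(saturated, ov, seed = 5, method = "compiled")
  b2 <- simulate_stochastic(saturated, ov, seed = 5, method = "reference")
  expect_identical(a2$series, b2$series)
})

test_that("stochastic backend rounds non-integer initial conditions with a warning", {
  expect_warning(traj <- simulate_stochastic(basic, c(B = 10.4, tfinal = 1),
                                             seed = 3),
                 "rounded")
  expect_equal(unname(traj$series[1, "B"]), 10)
})

test_that("all backends stay nonnegative under random nonnegative parameters", {
  set.seed(7)
  for (i in 1:20) {
    spec <- if (i %% 2 == 0) basic else saturated
    pars <- random_params(spec)
    pars[["dt"]] <- 0.05
    o <- simulate_ode(spec, pars)
    expect_true(all(o$series >= -1e-9))
    d <- suppressWarnings(simulate_discrete(spec, pars))
    expect_true(all(d$series >= 0))
  }
  for (i in 1:5) {
    pars <- random_params(basic)
    pars[c("B", "I")] <- round(pars[c("B", "I")])
    pars[["tfinal"]] <- 2
    s <- simulate_stochastic(basic, pars, seed = i)
    expect_true(all(s$series >= 0))
    expect_true(all(s$series == floor(s$series)))
  }
})

test_that("deterministic backends are bit-reproducible across runs", {
  expect_identical(simulate_ode(basic)$series, simulate_ode(basic)$series)
  expect_identical(suppressWarnings(simulate_discrete(basic))$series,
                   suppressWarnings(simulate_discrete(basic))$series)
})

test_that("simulate_model dispatches on backend id", {
  expect_identical(simulate_model(basic, backend = "ode")$meta$backend, "ode")
  expect_identical(
    simulate_model(basic, c(tfinal = 1), backend = "stochastic",
                   seed = 2)$series,
    simulate_stochastic(basic, c(tfinal = 1), seed = 2)$series)
  expect_error(simulate_model(basic, backend = "nope"))
})
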