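make_traj <- function(vals, var = "B") {
  trajectory(times = seq(0, by = 1, length.out = length(vals)),
             series = matrix(vals, ncol = 1, dimnames = list(NULL, var)))
}

test_that("peak and final_value reduce small series correctly", {
  tr <- make_traj(c(1, 5, 3))
  expect_equal(peak(tr, "B"), 5)
  expect_equal(final_value(tr, "B"), 3)
  const <- make_traj(rep(4.2, 7))
  expect_equal(peak(const, "B"), 4.2)
  expect_equal(final_value(const, "B"), 4.2)
  expect_error(peak(tr, "I"), "unknown variable")
  expect_error(final_value(tr, "Z"), "unknown variable")
})

test_that("peak of monotone logistic growth is the closed-form value at tfinal", {
  traj <- simulate_ode(basic, c(k = 0, dB = 0, I = 0))
  expected <- logistic_closed_form(10, 1, 1e5, 30)
  expect_equal(peak(traj, "B"), expected, tolerance = 1e-6)
})

test_that("final value at long horizon recovers the interior equilibrium", {
  traj <- simulate_ode(basic, c(tfinal = 3000))
  eq <- interior_equilibrium_basic(basic$parameters)
  expect_true(eq$feasible)
  expect_equal(final_value(traj, "B"), eq$B, tolerance = 0.01)
  expect_equal(final_value(traj, "I"), eq$I, tolerance = 0.01)
})

test_that("log_grid spans the decade endpoints inclusively", {
  g1 <- log_grid(-5, -2, 20)
  expect_length(g1, 20)
  expect_equal(g1[1], 1e-5)
  expect_equal(g1[20], 1e-2)
  expect_true(all(diff(g1) > 0))
  g2 <- log_grid(-3, 3, 20)
  expect_equal(c(g2[1], g2[20]), c(1e-3, 1e3))
  expect_equal(log_grid(0, 0, 1), 1)
  expect_error(log_grid(-5, -2, 0), "empty grid|positive count")
  expect_error(log_grid(2, -2, 5), "exceed")
})

test_that("peak-load sweep over r declines, matching the immune-control picture", {
  sw <- sweep_parameter(basic, parameter = "r", values = log_grid(-5, -2, 20),
                        metric = "peak", variable = "B", backend = "ode")
  expect_length(sw$outcomes, 20)
  expect_true(all(diff(sw$outcomes) <= 0))
  expect_gt(sw$outcomes[1], sw$outcomes[20])
  # each outcome equals an independently recomputed single run
  for (i in c(1, 10, 20)) {
    tr <- simulate_ode(basic, c(r = sw$values[i]))
    expect_equal(sw$outcomes[i], peak(tr, "B"), tolerance = 1e-12)
  }
})

test_that("a single-value sweep reduces to one simulation", {
  sw <- sweep_parameter(basic, parameter = "r", values = 0.001,
                        metric = "peak", variable = "B", backend = "ode")
  expect_length(sw$outcomes, 1)
  expect_equal(sw$outcomes, peak(simulate_ode(basic), "B"))
})

test_that("sweeps are pure: identical inputs give identical outcomes", {
  vals <- log_grid(-4, -3, 4)
  s1 <- sweep_parameter(basic, parameter = "r", values = vals,
                        metric = "final_value", variable = "I")
  s2 <- sweep_parameter(basic, parameter = "r", values = vals,
                        metric = "final_value", variable = "I")
  expect_identical(s1$outcomes, s2$outcomes)
  st1 <- sweep_parameter(basic, base = c(tfinal = 2), parameter = "g",
                         values = c(0.5, 1, 1.5), metric = "peak",
                         variable = "B", backend = "stochastic",
                         seeds = c(4, 5, 6))
  st2 <- sweep_parameter(basic, base = c(tfinal = 2), parameter = "g",
                         values = c(0.5, 1, 1.5), metric = "peak",
                         variable = "B", backend = "stochastic",
                         seeds = c(4, 5, 6))
  expect_identical(st1$outcomes, st2$outcomes)
})

test_that("saturation sweep declines and the large-s limit pins the immune peak at I0", {
  sw <- sweep_parameter(saturated, parameter = "s",
                        values = log_grid(-3, 3, 20),
                        metric = "peak", variable = "I", backend = "ode")
  expect_length(sw$outcomes, 20)
  expect_gt(sw$outcomes[1], sw$outcomes[20])
  expect_true(all(diff(sw$outcomes) <= 0))
  tr <- simulate_ode(saturated, c(s = 1e12))
  expect_equal(peak(tr, "I"), 1, tolerance = 1e-3)
})

test_that("sweep validates its inputs", {
  expect_error(sweep_parameter(basic, parameter = "zz", values = 1,
                               metric = "peak", variable = "B"),
               "unknown parameter")
  expect_error(sweep_parameter(basic, parameter = "r", values = 1,
                               metric = "peak", variable = "Z"),
               "unknown variable")
  expect_error(sweep_parameter(basic, parameter = "r", values = numeric(0),
                               metric = "peak", variable = "B"),
               "empty grid")
  expect_error(sweep_parameter(basic, parameter = "r", values = c(2, 1),
                               metric = "peak", variable = "B"),
               "strictly increasing")
  expect_error(sweep_parameter(basic, parameter = "r", values = c(1e-4, 1e-3),
                               metric = "peak", variable = "B",
                               backend = "stochastic", seeds = 1L),
               "one seed per grid point")
  expect_error(sweep_parameter(basic, parameter = "tfinal",
                               values = c(-2, -1), metric = "peak",
                               variable = "B"),
               "sweep failed at tfinal = -2")
})
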