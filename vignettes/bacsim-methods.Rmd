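---
title: "Models, backends and numerical choices in bacsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, backends and numerical choices in bacsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacsim)
```

## The scientific problem

`bacsim` simulates the within-host dynamics of an acute bacterial
infection: a pathogen population $B$ growing towards a resource limit while
an immune response $I$ is recruited against it. The structure is that of a
predator–prey system — bacteria are the prey, immune effectors the
predator — and the questions it is built to answer are of the
"what controls the peak?" kind: how the maximum bacterial load depends on
the immune activation rate, or how the maximum immune response depends on
how quickly activation saturates.

## Models and parameters

### Basic bacteria model

$$\frac{dB}{dt} = g B\left(1 - \frac{B}{B_{max}}\right) - d_B B - k B I,
\qquad \frac{dI}{dt} = r B I - d_I I$$

| symbol | meaning | units | default |
|---|---|---|---|
| $B_0$, $I_0$ | initial bacteria / immune level | abundance | 10, 1 |
| $g$ | bacterial growth rate | 1/time | 1 |
| $B_{max}$ | carrying capacity | abundance | $10^5$ |
| $d_B$ | bacterial death rate | 1/time | 0.1 |
| $k$ | immune kill rate constant | 1/(abundance·time) | $10^{-6}$ |
| $r$ | immune activation rate | 1/(abundance·time) | $10^{-3}$ |
| $d_I$ | immune decay rate | 1/time | 1 |
| $t_{start}$, $t_{final}$, $dt$ | time window and output step | time | 0, 30, 0.05 |

Abundances are in arbitrary units and the time unit is whatever the rate
parameters are expressed in; the package checks only nonnegativity (plus
$B_{max} > 0$, $dt > 0$, $t_{final} > t_{start}$), not dimensional
consistency.

With the defaults the model produces an acute infection: $B$ grows nearly
logistically to $\approx 1.7\times 10^4$, the $rBI$ term then amplifies
$I$ explosively (peak $\approx 1.6\times 10^7$ near $t \approx 9$), $B$
crashes by four orders of magnitude, and the system spirals towards the
interior equilibrium
$B^* = d_I/r = 1000$,
$I^* = (g(1 - B^*/B_{max}) - d_B)/k = 890000$.
That near-singular spike matters for the numerical choices below.

### Saturating immune activation

The variant model replaces $rBI$ with $rBI/(s+B)$: activation is
proportional to bacterial load only below the saturation constant $s$ and
approaches the fixed per-capita rate $r$ above it (a Michaelis–Menten-type
form). Its defaults change to $r = 10^3$ and $s = 10^3$. Note that the
role, units, and magnitude of $r$ change between the two models — in the
basic model it is a per-abundance-per-time constant ($10^{-3}$), in the
saturated model a per-time maximum rate ($10^3$). The package documents
this and keeps the two defaults independent rather than attempting any
reconciliation; they are different parameters that happen to share a
letter.

### Declarative specification and the event decomposition

A `model_spec` stores, per variable, a list of signed rate terms (each an
evaluable function plus a display string) and, separately, a list of
stochastic events with integer state-change vectors and propensity
functions. The invariant connecting them — for every variable, the signed
sum of propensities times state changes equals the drift — is enforced by
property tests over random nonnegative states, not by construction, so a
user adding a model gets an immediate, checkable contract.

The logistic term is split into birth $gB$ and density-dependent death
$gB^2/B_{max}$ so that every propensity is nonnegative for any nonnegative
state, including $B > B_{max}$ (where the net logistic rate is negative).
Initial conditions, rate constants and time settings share one flat
namespace named exactly as the simulator signatures (`B`, `I`, `g`, ...),
so overriding an initial condition is no different from overriding a rate.

## Simulation backends

All three backends share the signature `(spec, params[, seed])` and return
a `trajectory` on the output grid $t_{start}, t_{start}+dt, \dots$, capped
at $t_{final}$ (the final point is exactly $t_{final}$ when
$(t_{final}-t_{start})/dt$ is integral; otherwise the grid stops at the
last multiple below it).

**ODE.** Adaptive explicit Runge–Kutta (Dormand–Prince 4(5) via
`deSolve`), `rtol = 1e-8`, `atol = 1e-10`. These tolerances over-resolve
the dynamics by design: $dt$ is purely an output grid, and halving it does
not change the reported solution beyond interpolation. Values driven a
hair below zero by interpolation round-off are clamped within a $10^{-9}$
tolerance. The solver is cross-checked against an independently
implemented fixed-step classical RK4 reference (`rk4_fine_reference`) and
against closed forms (logistic growth, exponential decay).

**Discrete.** Forward Euler, $x(t+dt) = x(t) + dt\,f(x(t))$, with the
output $dt$ as the update step — the standard difference-equation
counterpart of the ODE. Euler can overshoot into negative abundances; the
backend clamps to zero and warns with the first affected step index.
Clamping is deterministic and keeps the run teachable rather than letting
it blow up silently; with the default $dt = 0.05$ the default basic run
does clamp once during the bacterial crash, which is part of why the
discrete and continuous backends visibly disagree there.

**Stochastic.** Exact Gillespie direct method over the event
decomposition: exponential waiting times at the total propensity, event
choice proportional to propensities, two uniform draws per event. The jump
process is sampled onto the $dt$ grid by last-value-carried-forward; if
the total propensity hits zero the remaining grid is filled with the
absorbing state. Exactness (rather than tau-leaping) keeps the backend
consistent with the event-decomposition contract at the cost of speed;
tau-leaping would be the natural extension for heavier workloads.

Because the default dynamics generate $\sim 10^7$ individual events per
replicate in large-population settings, the event loop runs in compiled
code whenever every event carries a structured kinetics form — a rate
constant times at most two state-variable factors, with an optional
saturation divisor $1/(s + x_v)$ — which covers both bundled models. A
plain-R loop over the propensity closures remains as the generic fallback
and as an independent check: both paths consume the identical RNG stream,
and the test suite asserts they produce bit-identical trajectories for a
fixed seed. `set.seed(seed)` is applied inside the simulator and the
caller's RNG state is restored afterwards.

## Outcome metrics and sweeps

Two metrics are deliberately the whole metric set: `peak` (the maximum of
a variable over the reported grid — the headline outcome for acute
infection dynamics) and `final_value` (the last reported value, used for
equilibrium checks). `sweep_parameter` substitutes each value of a
one-dimensional grid — typically `log_grid(lo, hi, n)`, $n$ values of
$10^e$ with equally spaced exponents — into an otherwise fixed parameter
set, runs one simulation per value, and records the metric. Stochastic
sweeps require exactly one seed per grid point, which keeps them
reproducible and embarrassingly parallel by contract; replicate-averaged
sweeps are left as an extension.

Note that `peak` is taken over the output grid, not the continuous
solution; with the default $dt$ the difference is negligible because the
solver over-resolves the dynamics.

## Numerical and testing choices

**Convergence diagnostic.** `euler_convergence_order` measures the
deviation between the Euler and ODE backends at a sequence of halved step
sizes and reports $\log_2$ error ratios. The error norm is the
grid-averaged absolute (L1) deviation rather than the maximum. The reason
is the immune spike: near $t \approx 9$ the default solution has
e-folding times comparable to $dt$ itself, Euler's local relative error
there is of order one, and the max-norm is dominated by that single
feature — its ratios only approach first order for $dt \lesssim 0.0125$.
The grid-averaged error is already in the asymptotic regime at
$dt = 0.05$ and cleanly exhibits the scheme's order ($\approx 0.96$ and
$1.00$ across $dt \in \{0.05, 0.025, 0.0125\}$ on the default model).

**Stochastic–deterministic agreement.** The large-population check
(100 replicates at $B_0 = 1000$, $I_0 = 100$ over $t \in [0,5]$) compares
replicate means of $B$ with the ODE solution at $t = 1, 2, 5$ within
three Monte-Carlo standard errors. Two caveats are worth recording. The
comparison is exact only in the infinite-population limit: after the
bacterial crash ($t = 5$) the mean of the jump process sits slightly
above the deterministic solution because crash timing varies between
replicates and the average of shifted crashes is not the crash of the
average. At 100 replicates this bias is comparable to the Monte-Carlo
error (observed $|z| \approx 0.5$–$2.5$ depending on the seed set), so
the three-standard-error band holds, but it would eventually fail for a
much larger replicate count — a property of the system, not a defect of
the simulator. Problem sizes here (100 replicates, horizon 5) keep the
check to a couple of minutes on one core.

**Oracles.** Every reference computation used to validate an engine is
implemented without calling that engine: the logistic closed form and the
interior equilibrium are hand-derived formulas; the RK4 reference is a
separate fixed-step integrator. Dual-oracle tests (closed form vs RK4 at
$dt = 10^{-4}$, agreement to $10^{-8}$ relative) guard against a shared
mistake.

**Degenerate inputs.** The origin is absorbing in both models and all
backends preserve it exactly. $B_0 = 0$ decouples the system
($I(t) = I_0 e^{-d_I t}$), which is tested against the ODE backend.
Non-integer initial conditions are rounded (with a warning) by the
stochastic backend only.

## What the bundled experiments show

The two sweeps mirror the package's intended workflow. Sweeping $r$ over
`log_grid(-5, -2, 20)` with the `peak` of $B$: a weakly activated immune
response lets bacteria approach carrying capacity ($\approx 9\times
10^4$), a strongly activated one caps the peak near $1.6\times 10^3$, and
the curve is monotone non-increasing across the grid. Sweeping $s$ over
`log_grid(-3, 3, 20)` with the `peak` of $I$: more saturation (larger
$s$) weakens activation, and as $s \to \infty$ the immune growth term
vanishes entirely, so the peak of $I$ collapses to $I_0$ (verified at
$s = 10^{12}$ to $10^{-3}$ absolute).

## Limitations

The toolkit is a teaching- and exploration-grade simulator, not a fitting
framework: there is no likelihood machinery, no parameter estimation, and
no uncertainty quantification beyond seeded replication. The deterministic
backends are non-stiff explicit methods; parameter regions that make the
system stiff (very large $r$ with the basic model, say) are handled by
the adaptive solver slowing down, not by a stiff method. The compiled
stochastic kernel supports products of at most two state variables with a
single saturation divisor; more exotic rate laws fall back to the plain-R
loop, which is orders of magnitude slower. Sweeps are one-parameter only,
by design.
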