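# bacsim

Scriptable simulation of within-host bacteria–immune response dynamics.

`bacsim` is aimed at people studying (or teaching) the population dynamics
of an acute bacterial infection inside a single host: how fast the pathogen
grows, how strongly the immune response is triggered, and what controls the
peak bacterial load. It packages two small compartmental models behind one
declarative model description and three interchangeable simulation
backends, so the same model can be run as a continuous ODE, as a
discrete-time difference equation, or as an exact stochastic jump process,
and swept over parameter grids without writing simulation code.

## The models

Both models track a bacterial load $B$ and an immune response level $I$
(arbitrary abundance units; the time unit is fixed implicitly by the rate
parameters).

**basicbacteria** — logistic growth, mass-action immune activation:

$$\frac{dB}{dt} = g B \left(1 - \frac{B}{B_{max}}\right) - d_B B - k B I,
\qquad
\frac{dI}{dt} = r B I - d_I I$$

with defaults $B_0 = 10$, $I_0 = 1$, $g = 1$, $B_{max} = 10^5$,
$d_B = 0.1$, $k = 10^{-6}$, $r = 10^{-3}$, $d_I = 1$ over $t \in [0, 30]$
with output step $dt = 0.05$.

**basicbacteria_saturated** — immune activation saturates at high load:
the growth term $rBI$ becomes $rBI/(s + B)$, so activation is proportional
to $B$ while $B \ll s$ and approaches the fixed maximum per-capita rate
$r$ when $B \gg s$. Defaults change to $r = 10^3$, $s = 10^3$.

For the stochastic backend each model is decomposed into six events
(bacterial birth $gB$, density-dependent death $gB^2/B_{max}$, natural
death $d_B B$, killing by the immune response $kBI$, immune activation,
immune decay) whose signed sum reproduces the drift exactly; the event
loop is an exact Gillespie direct-method simulation with a compiled hot
path.

## Worked example

```r
library(bacsim)

spec <- make_basic_bacteria_model()
traj <- simulate_ode(spec)          # defaults as printed above
peak(traj, "B")                     # 17037.93
peak(traj, "I")                     # 16266988
final_value(traj, "B")              # 4619.288
```

With the default parameters the infection is acute: bacteria grow almost
unchecked to a peak load of about $1.7 \times 10^4$, which triggers a
massive immune expansion (peak $I \approx 1.6 \times 10^7$) that crashes
the bacterial population; by $t = 30$ the system is spiralling towards its
interior equilibrium $(B^\*, I^\*) = (d_I/r,\; (g(1 - B^\*/B_{max}) -
d_B)/k) = (1000,\; 890000)$.

How does the peak load depend on the immune activation rate?

```r
sw <- sweep_parameter(spec, parameter = "r",
                      values = log_grid(-5, -2, 20),
                      metric = "peak", variable = "B")
head(as.data.frame(sw), 3)
#              r   peak_B
# 1 1.000000e-05 90000.00
# 2 1.438450e-05 90000.00
# 3 2.069138e-05 89999.34
plot(sw)    # log-log scatter: peak load falls from ~9e4 to ~1.6e3
```

A weakly activated response ($r = 10^{-5}$) lets bacteria reach the
vicinity of the carrying capacity; at $r = 10^{-2}$ the response caps the
peak near $1.6 \times 10^3$ — a monotone decline across the grid.

The same runs are available from a shell:

```sh
Rscript inst/cli/bacsim list
Rscript inst/cli/bacsim run --model basicbacteria --set g=0.5,r=0.002 \
    --out run.csv --plot run.png
Rscript inst/cli/bacsim sweep --model basicbacteria_saturated --param s \
    --lo -3 --hi 3 --n 20 --metric peak --variable I --out sweep.csv
```

Settings can also live in a YAML or JSON config file
(`--config run.yaml`); flags override file values, which override model
defaults.

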