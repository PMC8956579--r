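# embedstable

Design and analysis of multistable gene-regulatory network models built by
**embedding bistable subsystems**, with the GATA1–GATA2–PU.1 fate-decision
module of haematopoiesis as the worked system.

## Who this is for

Systems biologists and modellers who need mathematical models with three or
more stable steady states using realistic (non-cooperative, Hill coefficient
1) regulation, and who want the full workflow around such models: equilibrium
and stability analysis, random-parameter screening, likelihood-free parameter
fitting, and stochastic single-cell simulation.

## The core idea

Take a bistable two-gene subsystem for "gene Z versus everything else", where
"everything else" is an auxiliary node U:

```
dz/dt = a1 z / ((1 + b1 z)(1 + b2 u)) − k1 z
du/dt = c1 u / ((1 + d1 u)(1 + d2 z)) − k2 u
```

and a second bistable subsystem for two genes X and Y of the same
Shea–Ackers double-negative-feedback form.  Declaring `u = x + y` and
substituting it away couples the two: every repression that acted *on* u's
production (here `1/(1 + d2 z)`) is inherited by each production term of x
and y, and u's own equation is dropped.  The embedded three-gene system

```
dx/dt = α1 x / ((1 + β1 x)(1 + β2 y)(1 + d2 z)) − k3 x
dy/dt = γ1 y / ((1 + σ1 y)(1 + σ2 x)(1 + d2 z)) − k4 y
dz/dt = a1 z / ((1 + b1 z)(1 + b2 (x + y))) − k1 z
```

is tristable when the subsystems are bistable and simple transversality
inequalities hold (all checked in closed form by the package).  A modified
model adds basal production constants and a weak positive regulation from
GATA2 to GATA1 (with suitable fitted parameters this family supports a
fourth, low-expression stable state; see the vignette for what the packaged
parameter set does and does not reproduce); a time-windowed GATA-switching
rate `k*(t)` with transfer efficiency `ψ` drives transitions between
states, and an Itô SDE version (semi-implicit Euler) reproduces
heterogeneous single-cell fate outcomes.

## Worked example

```r
library(embedstable)

# the classic bistable toggle switch (a = 0.2, b = 4, hill = 3)
eq <- find_equilibria(toggle_params(), box = cbind(c(0, 0), c(6, 6)))
eq
#> Equilibrium set: 3 point(s)
#>   (1.35211, 1.35211)  residual=4.86e-11  saddle
#>   (0.255822, 4.13413)  residual=0.00e+00  stable
#>   (4.13413, 0.255822)  residual=0.00e+00  stable

# embed a second toggle through u = x + y: tristability emerges
sys <- embed(toggle_subsystem(vars = c("z", "u"), aux = "u"),
             toggle_subsystem(vars = c("x", "y")),
             list(u = c(x = 1, y = 1)))
find_equilibria(sys, box = cbind(rep(0, 3), rep(6, 3)))
#> Equilibrium set: 5 point(s)
#>   (0.283026, 0.283026, 3.5859)  residual=1.21e-11  stable
#>   (0.494979, 0.494979, 2.23027)  residual=3.97e-13  saddle
#>   (4.07336, 0.257438, 0.248646)  residual=4.44e-16  stable
#>   (1.32625, 1.32625, 0.403436)  residual=8.33e-17  saddle
#>   (0.257438, 4.07336, 0.248646)  residual=4.44e-16  stable
```

The two stable toggle states (A/B in the phase plane) plus the saddle
between them, and after embedding the three stable states (one per gene
high) with the two connecting saddles.

Screen for bistable parameter sets, fit a model to time-course data by ABC
rejection, and simulate stochastic fate decisions:

```r
scr <- screen_bistability(10000, seed = 1)       # case1/case2/case3 catalogue
data <- synth_target(example_xy_params(), seed = 1)
post <- abc_rejection(data, abc_config(n_draws = 5e4, quantile = 0.001))
ens  <- run_ensemble(1000, sde_config(init = c(0.001, 0.001, 7.9)),
                     example_quad_params())   # start in the GATA2-high state
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/embedstable.R", package = "embedstable"))')
Rscript "$CLI" equilibria --model tristable_toggle --out runs/eq
Rscript "$CLI" sweep --n 500 --k0 0.1,0.4,0.8 --psi 0.0002,0.001 --out runs/sweep
```

Subcommands: `equilibria`, `search`, `perturb`, `abc`, `simulate`, `sweep`,
`fixtures`.  Every run writes delimited tables plus a JSON manifest (config
echo, seed, package version).

## Package layout

- `R/model_core.R` — the vector fields (toggle, two-node, GATA-switching,
  embedded tristable, quad-stable) with typed, validated parameter sets
- `R/embedding.R` — the embedding transform on structural term descriptors
- `R/equilibria.R`, `R/theorems.R` — multistart Newton equilibrium finding,
  Jacobian classification, and the closed-form existence/stability conditions
- `R/bistability.R` — random-parameter screening and perturbation robustness
- `R/abc.R` — ABC rejection fitting with the summed-absolute-deviation
  distance; synthetic data generation
- `R/sde.R` — Itô SDE simulation (semi-implicit Euler, compiled core),
  endpoint classification, ensemble sweeps
- `vignettes/embedding-multistability.Rmd` — the methods notes: model
  assumptions, parameter choices, numerical decisions, limitations
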