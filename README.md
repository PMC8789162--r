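# dynOED

Robust D-optimal design of dynamic gas-exchange experiments for
estimating respiration and fermentation kinetics of stored fruit.

## The problem

Controlled-atmosphere storage of fruit depends on six kinetic parameters
— maximal respiration rate V<sub>m,O2</sub>, its O2 half-saturation
K<sub>m,O2</sub>, the CO2 inhibition constant K<sub>mn,CO2</sub>
(handled as its inverse), the respiration quotient r<sub>q</sub>,
the maximal fermentation rate V<sub>m,f,CO2</sub> and its O2 inhibition
constant K<sub>m,f,O2</sub> — that must be estimated from experiments in
which fruit respires inside a jar while O2 and CO2 partial pressures are
recorded.  A *dynamic* experiment steers the inlet gas composition and
flow rate through a piecewise-constant schedule u(t) and can extract far
more information from a single jar than a battery of constant-condition
runs.

`dynOED` picks that schedule.  It integrates the jar mass balances
together with the forward sensitivity equations ∂x/∂θ, assembles the
Fisher information matrix

F<sub>mn</sub> = Σ<sub>k,i</sub> w<sub>ki</sub> s<sub>kim</sub> s<sub>kin</sub>,
  w = 1/v + σ⁴/(2v²),  v = σ²y + 0.01,

(the second weight term carries the information in the signal-dependent
noise variance), and maximizes a scalar of det F over the control
schedule:

* **locally optimal design**: det F at one parameter guess θ*;
* **robust (pseudo-Bayesian) design**: the average of det F over a
  Markov-chain of prior draws — insensitive to the guess;
* **sigma-point design**: the unscented-transform average over 13
  deterministic points, a cheaper summary of the same prior.

The package also contains the estimation side (heteroscedastic Gaussian
likelihood, ML fitting with sensitivity-based gradients, adaptive MCMC
posterior sampling) and a synthetic posterior-chain generator so the
whole pipeline runs self-contained.

## A worked example

```r
library(dynOED)

params <- params_from_vector(reference_chain_mean()[param_names()])
jar    <- jar_setup()                       # 5 dm3 jar, 4 kg pears, 293.15 K
grid   <- experiment_grid(te = 24, N = 96)  # 24 h, one sample per 15 min

chain   <- make_synthetic_chain(R = 6000, seed = 1)   # 4 chains x 1500
thinned <- burn_and_thin(chain, burn = 500, thin = 40) # 100 draws

local_res <- optimize_design(
  design_problem(jar, grid, objective = "local", params = params,
                 M = 12, n_starts = 4, seed = 2))
robust_res <- optimize_design(
  design_problem(jar, grid, objective = "robust", chain = thinned,
                 M = 12, n_starts = 1, seed = 3),
  extra_starts = list(local_res$profile))

robust_criterion(robust_res$profile, chain, jar, grid)
#> [1] 1.211760e+20
robust_criterion(local_res$profile, chain, jar, grid)
#> [1] 8.585498e+19
```

The robust design outperforms the locally optimal one by ~40% in
expected det F over the prior.  The per-draw difference distribution
shows why:

```r
cmpr <- compare_designs(local_res$profile, robust_res$profile, chain,
                        jar, grid)
c(mean = cmpr$mean, skewness = cmpr$skewness)
#>         mean     skewness
#> 3.532098e+19 8.668002e+00
```

The strong right skew means the two designs perform similarly for most
prior draws, but the robust design wins big on the subpopulation with a
low CO2 inhibition constant — exactly the parameter region a single
local guess misses.  Precision at the optimized design
(`precision_summary()`) confirms the three inhibition constants remain
the hardest parameters (coefficients of variation ≈ 17%, 71% and 43%,
versus 5–14% for the rates and respiration quotient).

A command-line wrapper ships in `exec/dynoed` with subcommands
`simulate`, `fit`, `sample-posterior`, `design`, `evaluate`, `compare`
and `make-chain`; see `?oed_cli`.

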