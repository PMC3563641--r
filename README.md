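# discrimod

Robust optimal experimental design for discriminating rival kinetic models.

## The problem

Systems biologists routinely face several ODE models of the same biochemical
process that all fit the available measurements equally well. Rather than
guessing, one can *design* the next experiment — initial concentrations,
measurement time points, perturbations, input profiles — so that the rival
models' predicted responses separate as much as possible; if the separation
exceeds the measurement noise, the wrong hypothesis can be rejected.
`discrimod` is for modellers who want to compute such designs, including
*robust* ones that keep their discriminating power even at the least
favorable parameter values inside given confidence boxes.

## The method

For responses η¹, η² of the two models, the package maximizes a
Kullback–Leibler-based criterion

    J(ξ, θ₁, θ₂) = Σⱼ wⱼ(ξ) Σᵢ KL( N(η¹ᵢⱼ, σ₁²) ‖ N(η²ᵢⱼ, σ₂²) ),

which in the homoscedastic case reduces to the scaled sum of squared response
differences Σ wⱼ (η¹ − η²)² / (2σ²). The weights wⱼ are smooth (tanh)
Heaviside steps that disable measurements spaced below a minimum interval or
coinciding with perturbations, keeping J differentiable. The robust design
problem is the max-min program

    max_{ξ ∈ Ξ}  min_{θ₁ ∈ Θ₁, θ₂ ∈ Θ₂}  J(ξ, θ₁, θ₂),

solved by outer approximation: alternately re-estimate worst-case parameters
at the current design (multistart local minimization inside the boxes) and
re-optimize the design against the growing finite set of worst-case pairs
(epigraph reformulation), until the robustification gap
Δₖ = |J_design − J_worst| falls below a tolerance. A homotopy ramp can
introduce new worst-case constraints gradually to stabilize convergence.

The package ships a model registry (simple Michaelis–Menten enzyme, a
slow-transition hysteretic enzyme, a five-state chemostat benchmark network
with two rival variants), an event-aware ODE simulator with sensitivities,
box-constrained least-squares fitting, synthetic data generation under
additive and relative noise, a replicated-design lack-of-fit test, a
residual-variance F-ratio test, and KL-divergence robustness histograms.

## Worked example

Robustify a design on a closed-form saddle, J(ξ, θ) = (ξ − θ)² + ξ with
ξ, θ ∈ [0, 1], whose max-min optimum is ξ* = 1 with J* = 1:

```r
library(discrimod)
sp <- saddle_problem(xi0 = 0.2)
st <- robust_design(sp$modelA, sp$modelB, sp$space, sp$boxes,
                    sp$paramsA, sp$paramsB, sp$init_design, sp$cfg,
                    eps_stop = 1e-3, max_iter = 10, n_starts = 3, seed = 2)
print(st)
#> Robust design (outer approximation)
#>   iterations: 2, stopped: TRUE (converged)
#>   final J_design = 1, J_worst = 1, gap = 0 (eps_stop 0.001)
#>   constraint set size |P| = 2
st$design$x0[["x"]]
#> [1] 1
```

The loop found the saddle in two outer iterations: phase one pushed the
worst-case θ to the current design point, phase two pushed the design to the
upper bound, and the gap between the design-phase objective and the
re-estimated worst case closed to ~1e-8.

A kinetic example — recover the hysteretic enzyme's dominant rate constants
from five noisy synthetic datasets (26 points, 10 time units apart, additive
noise at 1% of the signal range, all ten parameters refit from a ±20%
perturbed start):

```r
r <- recovery_experiment(seed = 0)
round(r$estimates[c("k6", "k10")], 4)
#>     k6    k10
#> 5.8781 3.4729
```

The generating values are 6.0 and 4.0. The active-branch constants are only
partially identifiable from substrate and product data (the unobserved
active-enzyme amplitude absorbs part of them), so single-run estimates
scatter by a few percent to ~15% across noise seeds; the methods vignette
(`vignettes/robust-discrimination-design.Rmd`) quantifies this.

## Configuration-driven runs

Every pipeline stage (`simulate`, `fit`, `evaluate`, `worstcase`, `design`,
`robust`, `histogram`, `loftest`) can be driven from a YAML run
configuration via `run()`, or from a shell through the thin CLI wrapper:

```sh
Rscript inst/cli/discrimod.R robust --config run.yaml --out results/
```

Results are written as JSON with provenance (seed, config hash, package
version), time series and histograms as tab-separated text, and designs both
as lossless JSON and as human-readable bracketed matrix dumps.
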