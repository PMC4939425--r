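# nrlangevin

Nonreversible Langevin samplers and asymptotic-variance reduction.

## The problem

Computing an expectation π(f) = ∫ f dπ under a Gibbs target
π(x) ∝ exp(−βV(x)) by the time average π_T(f) = T⁻¹∫₀ᵀ f(X_t) dt of an
ergodic diffusion is the workhorse of molecular simulation and Bayesian
computation. The accuracy of π_T(f) is governed by the asymptotic
variance σ²_f in the central limit theorem
√T (π_T(f) − π(f)) ⇒ N(0, σ²_f). Adding a drift αγ(x) that is
divergence-free with respect to π,

    dX_t = (∇log π(X_t) + α γ(X_t)) dt + √2 dW_t,   ∇·(γπ) = 0,

keeps π stationary, breaks detailed balance, and — for a well-chosen γ —
can reduce σ²_f by orders of magnitude: the fast deterministic flow
averages f along level sets of V, leaving only the slow diffusive motion
across level sets to contribute variance.

The package is for method developers and computational scientists who
want to construct such perturbations, simulate the resulting dynamics,
and quantify the variance reduction — exactly where the theory permits,
and by Monte Carlo where it does not.

## What it provides

* **Targets** — standard/anisotropic Gaussians, a warped (banana-shaped)
  Gaussian, a periodic potential on the torus, and a dimer in a WCA
  solvent with its reaction coordinate; all with analytic gradients and
  finite-difference validation (`check_gradient()`).
* **Divergence-free drifts** — constant antisymmetric matrix
  (γ = J∇log π), smoothed/bounded (γ = J∇V·ψ(V)), and skew matrix-field
  constructions, with a numerical `divergence_check()`; optimal-J
  recipes for linear (`optimal_linear_J()`) and quadratic observables
  (`pairing_J()`), and the dimer's block-circulant / corner-rotation
  matrices (`dimer_J()`).
* **Samplers** — Euler–Maruyama, MALA (reversible or with nonreversible
  proposal), and a Strang splitting (MALA half-steps around an RK4
  integration of the deterministic flow), with seeded reproducibility,
  blow-up flags and gradient-evaluation accounting.
* **Estimators** — ensemble and batch-means estimators of σ²_f, CLT
  confidence intervals, MSE with divergence bookkeeping; broom-style
  `tidy()`/`glance()` methods.
* **Exact theory for Gaussian targets** — for the nonreversible
  Ornstein–Uhlenbeck process dX = −(I + αJ)X dt + √2 dW with quadratic
  observables x·Mx + l·x − Tr M: the exact Poisson solution via a
  Lyapunov solve (`solve_poisson()`), the asymptotic variance
  σ² = 4 Tr(CMᵀ) + 2 l·A⁻¹l (`asymptotic_variance()`), its
  rotation-integral half-convention variant (`rotation_form_variance()`),
  kernel projections, large-strength limits and the rearrangement lower
  bound.
* **Experiment drivers** — `alpha_sweep()`, `mh_comparison()`,
  `mse_sweep()` (fixed gradient-evaluation budgets across schemes) and
  `dimer_experiment()`, all returning tibbles with `autoplot()` methods,
  plus a thin CLI at `inst/scripts/nrlangevin-cli.R`.

## Worked example

The planar-rotation model: standard 2-D Gaussian target, rotational
perturbation J, observable f(x) = 2x₁² (so M = diag(2, 0)). The exact
asymptotic variance is 4(1 + 1/(1+α²)).

```r
library(nrlangevin)
J <- rbind(c(0, -1), c(1, 0))
tidy(ou_model(J, alpha = 0, M = diag(c(2, 0))), alphas = c(0, 1, 3, 10))
#> # A tibble: 4 × 4
#>   alpha sigma2 sigma2_rotation_form linear_term
#>   <dbl>  <dbl>                <dbl>       <dbl>
#> 1     0   8                    4              0
#> 2     1   6                    3              0
#> 3     3   4.4                  2.2            0
#> 4    10   4.04                 2.02           0
```

`sigma2` is the Green–Kubo-consistent asymptotic variance: 8 for the
reversible dynamics, decaying towards 4 — the irreducible contribution
of the radial (kernel) component of the observable, which no rotation
can average out. `sigma2_rotation_form` is the half-normalised
convention described in the methods vignette; `linear_term` is zero
because l = 0.

A Monte-Carlo ensemble from the unadjusted sampler arbitrates the closed
form (100 replicas of T = 100 at Δt = 0.005):

```r
g   <- make_gaussian(2)
obs <- make_observable_quadratic(diag(c(2, 0)), k = 0, name = "2x1sq",
                                 known_mean = 2)
alpha_sweep(g, J, obs, alphas = c(0, 3), dt = 0.005, n_steps = 20000,
            n_replicas = 100, master_seed = 2024)
#> # A tibble: 2 × 8
#>   alpha estimate sigma2 sigma2_se ci_low ci_high n_replicas diverged_fraction
#>   <dbl>    <dbl>  <dbl>     <dbl>  <dbl>   <dbl>      <int>             <dbl>
#> 1     0     2.00  10.1      1.44    1.93    2.06        100                 0
#> 2     3     2.01   4.36     0.620   1.97    2.05        100                 0
```

Both estimates of π(f) bracket the true value 2, and the variance
estimates 10.1 and 4.36 agree with the exact values 8 and 4.4 within
three standard errors of the ensemble estimator — the α = 3 run needs
less than half the simulation time of the reversible one for the same
accuracy.

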