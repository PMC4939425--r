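---
title: "Nonreversible Langevin samplers: model, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonreversible Langevin samplers: model, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrlangevin)
```

## The model

To estimate an expectation $\pi(f) = \int f \,d\pi$ under a Gibbs target
$\pi(x) \propto e^{-\beta V(x)}$, one simulates an ergodic diffusion and
takes the time average $\pi_T(f) = T^{-1}\int_0^T f(X_t)\,dt$. The standard
choice is the reversible overdamped Langevin dynamics
$dX_t = \nabla \log \pi(X_t)\,dt + \sqrt{2}\,dW_t$. This package implements
its nonreversible perturbation

$$dX_t = \big(\nabla \log \pi(X_t) + \alpha\,\gamma(X_t)\big)\,dt
  + \sqrt{2}\,dW_t,$$

where $\gamma$ is divergence-free with respect to the target,
$\nabla\cdot(\gamma\pi) = 0$, so that $\pi$ remains stationary for every
strength $\alpha$ while detailed balance is broken. The quantity of
interest is the asymptotic variance $\sigma_f^2(\alpha)$ in the central
limit theorem $\sqrt{T}(\pi_T(f) - \pi(f)) \Rightarrow N(0, \sigma_f^2)$:
a well-chosen $\gamma$ can reduce it dramatically, because the fast
deterministic flow $\alpha\gamma$ averages the observable along level sets
of the potential, leaving only the (slow, reversible) motion across level
sets to contribute variance.

Three families of divergence-free fields are provided:

* `constant_J_drift()`: $\gamma = J\nabla\log\pi$ for an antisymmetric
  matrix $J$;
* `smoothed_drift()`: $\gamma = J\nabla V\,\psi(V)$, bounded when $\psi$
  is compactly supported, and conserving $V$ along its flow;
* `matrix_field_drift()`: $\gamma = -J(x)\nabla V(x) + \nabla\cdot J(x)$
  for a skew-symmetric matrix function.

`divergence_check()` validates any field numerically by central
differences of $|\nabla\cdot(\gamma\pi)|/\pi$.

## Exact theory for linear drifts

When $\pi = N(0, I)$ the perturbed dynamics is the nonreversible
Ornstein–Uhlenbeck process $dX_t = -(I + \alpha J)X_t\,dt + \sqrt2\,dW_t$,
whose stationary law is $N(0, I)$ for every $\alpha$ and $J$. For the
centred quadratic observable $f(x) = x\cdot Mx + l\cdot x - \mathrm{Tr}M$
the Poisson equation $-\mathcal{L}\phi = f - \pi(f)$ has the exact
quadratic solution $\phi = x\cdot Cx + D\cdot x - \mathrm{Tr}C$ with

$$A C + C A^\top = M, \qquad A D = l, \qquad A = I - \alpha J,$$

solved in `solve_poisson()` by a dense Kronecker-product Lyapunov solve
(`solve_lyapunov()`; dimensions in scope are at most a few tens, so the
$d^2 \times d^2$ linear solve is exact and instantaneous). Tracing the
Lyapunov equation gives $\mathrm{Tr}\,C = \mathrm{Tr}\,M / 2$, which the
tests assert. The asymptotic variance follows as

$$\sigma^2_f(\alpha) = 4\,\mathrm{Tr}(CM^\top) + 2\,l\cdot A^{-1}l
 = 2\langle \phi, f - \pi(f)\rangle_\pi ,$$

implemented in `asymptotic_variance()`.

### The two normalisation conventions

Reference values for this model family circulate under two conventions
that differ by a factor of two in the quadratic contribution.
The Green–Kubo route fixes the normalisation unambiguously: for the 1-D
process with $f = x^2 - 1$, the stationary autocovariance is
$2e^{-2t}$, so $\sigma^2 = 2\int_0^\infty 2e^{-2t}dt = 2$; and for the
planar-rotation model ($J$ a rotation generator, $M = \mathrm{diag}(2,0)$)
a direct polar-coordinates calculation gives
$\sigma^2_f(\alpha) = 4(1 + 1/(1+\alpha^2))$. `asymptotic_variance()`
reproduces both, and Monte-Carlo ensembles from the samplers converge to
it — the decisive arbiter.

The alternative convention evaluates

$$2\int_0^\infty e^{-2s}\,\mathrm{Tr}\!\left[e^{\alpha Js} M
  e^{-\alpha Js} M^\top\right] ds + 2\,l\cdot(I + \alpha^2 J^\top
  J)^{-1}l,$$

whose quadratic part at $\alpha = 0$ is $\|M\|_F^2$ — half the Green–Kubo
value (the linear parts coincide). Several widely quoted reference
numbers for the two-block example below (30, 25, 20) follow this
convention, so the package exposes it as a separate, clearly named
operation `rotation_form_variance()` rather than silently rescaling one
into the other; a regression test locks the factor-two relation on random
models.

### Optimal perturbations, limits and bounds

For a linear observable $f = l\cdot x$ the variance is
$2\,l\cdot(I+\alpha^2 J^\top J)^{-1}l$ (`linear_term()`); it decays to
$2|l_{\mathcal N}|^2$, where $l_{\mathcal N}$ is the projection of $l$
onto $\mathrm{Ker}\,J$ (`nullspace_projection()`, kernel detected by SVD
with a $10^{-10}$ relative threshold). `optimal_linear_J()` builds the
unit-Frobenius rank-two matrix $(\tilde l\otimes\omega -
\omega\otimes\tilde l)/\sqrt2$ that empties the kernel component,
yielding $4|l|^2/(2+\alpha^2)$. The default $\omega$ is chosen
deterministically (Gram–Schmidt of a fixed basis vector against $l$) so
that results never depend on RNG state.

For quadratic observables `pairing_J()` implements the eigen-pairing
construction: sort the eigenvalues of $M$ ascending and rotate the $k$-th
smallest towards the $k$-th largest. The limiting variance under this
rotation is $\tfrac12\sum_k(\lambda_{i_k}+\lambda_{j_k})^2$ (in the
rotation-form convention), minimised by the smallest-with-largest
pairing, and bounded below by the rearrangement bound
$\lambda^{\downarrow}\cdot\lambda^{\uparrow} + 2|l_{\mathcal N}|^2$
(`variance_lower_bound()`), tight only for $M = mI$. Design choices made
here, where the construction is genuinely open:

* **odd dimension** — the middle eigenvector is left unpaired (zero
  row/column), receiving no perturbation;
* **eigenvector sign ambiguity** — each eigenvector's first nonzero
  component is made positive, so the matrix is deterministic;
* **normalisation** — the raw pairing sum is the default; unit Frobenius
  norm is available via `normalize = TRUE` (a strength rescaling makes
  the two equivalent in the large-$\alpha$ limit).

`large_alpha_limit()` evaluates the limiting variance numerically at
$\alpha = 10^6$, verified against $10^7$ (warning if the two disagree
beyond tolerance), plus the exact kernel term — chosen over a symbolic
commutant decomposition for robustness on arbitrary inputs.

## Sampling engines

* `euler_maruyama()` — the unadjusted discretisation
  $X^{(n+1)} = X^{(n)} + \Delta t[\nabla\log\pi + \alpha\gamma](X^{(n)})
  + \sqrt{2\Delta t}\,\xi_n$. One gradient evaluation per step.
* `mala()` — the same proposal (with covariance $2\Delta t I$, consistent
  with the $\sqrt2$ diffusion; a variance-$\Delta t$ convention also
  appears in the literature and differs only by a stepsize relabelling),
  corrected by a Metropolis–Hastings step so the reversible chain is
  exactly $\pi$-invariant at any stepsize. The acceptance ratio is
  $\pi(\tilde X)q(\tilde X \to X)/[\pi(X)q(X \to \tilde X)]$. Passing a
  perturbation field gives the nonreversible-proposal variant, which is
  used to demonstrate that Metropolisation negates the variance gain.
  One fresh gradient per step (the current state's gradient is cached).
* `splitting()` — the Strang composition
  $\Phi_{r,\Delta t/2}\circ\Phi_{n,\Delta t}\circ\Phi_{r,\Delta t/2}$: a
  reversible MALA substep of half a step, the deterministic flow of
  $\alpha\gamma$ integrated by classical RK4 (`rk4_flow()`), and a second
  MALA substep. At $\alpha = 0$ it reduces exactly to MALA on the same
  RNG stream. Cost is accounted as six gradient evaluations per step
  (two proposals plus four RK4 stages, after reusing two evaluations);
  the experiment drivers use these per-step costs (1/1/6) to equalise
  gradient budgets across schemes.

Divergence handling: a step whose state is non-finite or whose norm
exceeds `blowup_norm` ($10^8$ by default) truncates the recorded series
and sets a flag — never an error — so sweeps can report blow-up
fractions. The energy-based test ($|V|$ beyond the threshold, or $V$ not
evaluable) runs every 64 steps, since it costs a potential evaluation and
an energy explosion drags the state norm or the next gradient with it
within a few steps. Torus coordinates are wrapped into $[0, L)$ after
every step, and all torus distances use the minimum-image convention.
Seeded runs are bit-reproducible; replica ensembles derive child seeds
deterministically from one master seed.

### Sign and $\beta$ conventions

The constant-matrix field is defined as $\gamma = J\nabla\log\pi =
-\beta J\nabla V$. A literature variant writes the assembled drift as
$-(\beta I + \alpha J)\nabla V$; `constant_J_drift(..., beta_free =
TRUE)` reproduces it exactly (the two differ only by rescaling $\alpha$
by $\beta$, and all variance results depend on $J$ only through
$J^\top J$ and conjugation, so flipping the sign of $J$ changes
nothing). The built-in targets store $\beta$ and fold it into
`log_density` and `grad_log_density`.

## Built-in targets and what the generator does (and does not) emulate

* `make_gaussian(d)` — standard normal; the exactly solvable reference.
* `make_warped_gaussian(b)` — $V = x_1^2/100 + (x_2 + bx_1^2 - 100b)^2$,
  $b = 0.05$ by default: mass concentrated along a parabolic ridge, the
  canonical case where reversible samplers crawl and the level-set flow
  pays off. The $x_1$ marginal has variance 50, so its relaxation time is
  about 50 time units — desk-scale runs resolve variance *orderings*
  but not the full-scale reduction factor (about 80 at $T = 10^5$),
  which is out of reach of any test-suite budget.
* `make_periodic(beta)` — $V = \sin(2\pi x_1)\cos(2\pi x_2)$ on the unit
  torus, default $\beta = 10$ (temperature $0.1$): a strongly metastable
  landscape.
* `make_dimer(params)` — $N$ particles in a periodic 2-D box; particles
  1–2 bound by the double well $V_S(r) = h[1 - (r - r_0 - w)^2/w^2]^2$
  (minima at the compact separation $r_0$ and stretched $r_0 + 2w$,
  barrier $h$), all other pairs purely repulsive WCA
  (Lennard-Jones truncated and shifted at $r_0 = 2^{1/6}\sigma$).
  The observable is the reaction coordinate
  $\xi = (|q_1 - q_2| - r_0)/(2w)$. The parameter $w$ must be strictly
  positive — $w = 0$, which appears in some parameter listings, makes
  both $V_S$ and $\xi$ singular — and defaults to $0.5$. The box length
  is not fixed by the reference setting; the default $L = 5\sigma$ gives
  a moderate planar density for the default $N = 16$. Overlapping
  particles raise a domain error instead of returning infinite energy,
  so samplers can flag divergence deterministically.

The synthetic-data layer is exactly these process simulators: what the
tests exercise is data generated by the very dynamics the theory
describes. Passing tests therefore validate the estimators and the
closed-form theory against each other, not the behaviour of these
methods on real molecular systems, where potentials are rougher, $d$ is
far larger and gradients are expensive.

## Estimators

`ergodic_average()` is the post-burn-in mean. Two asymptotic-variance
estimators are provided, and only these two:

* `ensemble_sigma2()` — $T \times$ sample variance of $\pi_T(f)$ across
  independent replicas; unbiased as $T \to \infty$, with a
  normal-theory uncertainty $\sigma^2\sqrt{2/(R-1)}$ reported for the
  variance estimate itself.
* `batch_means_sigma2()` — $T_b \times$ sample variance of contiguous
  batch means from a single trajectory. The batch count defaults to 30;
  batches are equal-length and contiguous, and a trailing remainder is
  discarded (the classical construction fixes no tie-break, so one had
  to be chosen).

Confidence intervals use the normal quantile (the central limit theorem
is the justification), not Student-t. `mse()` excludes diverged replicas
and reports their fraction; the relative variant divides by $\pi(f)^2$
and refuses a zero reference.

## Desk-scale experiment sizes

The experiment drivers default to nothing; every size is explicit at the
call site. The test-suite and reference-script sizes were chosen once,
as the smallest ensembles whose 3-standard-error bands still separate
the effects being demonstrated: ensembles of 100–150 replicas of
$T = 100$–$150$ time units at $\Delta t = 0.005$–$0.02$ for the Gaussian
arbitration and Green–Kubo checks; 30-replica sweeps for qualitative
orderings; and a 16-particle dimer only in short smoke runs, with $N = 4$
used for gradient verification. Full-scale reference settings
($T = 10^5$, $10^3$ replicas, $10^{10}$ steps) remain expressible
through the same interfaces.

Reference means for MSE studies must come from analytic values or
adaptive quadrature — never from self-simulation; `mse_sweep()` takes
the reference as an argument for exactly this reason.

## Known limitations

* Pure-R integrators: roughly $10^5$ steps per second per chain. The
  package targets method study at desk scale, not production molecular
  simulation.
* No spectral/initial-sequence variance estimators, no adaptive
  stepsizes, no higher-order weak schemes beyond the Strang splitting,
  and no search over the space of admissible fields beyond the printed
  constructive recipes — these are out of scope by design.
* The operator-theoretic spectral machinery behind the large-$\alpha$
  classification is represented only through the closed-form Gaussian
  and planar worked cases, not as general operator computations.
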