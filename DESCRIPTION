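Package: nrlangevin
Title: Nonreversible Langevin Samplers and Asymptotic Variance Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for sampling from Gibbs-type target densities with
    overdamped Langevin dynamics perturbed by a divergence-free
    (nonreversible) drift, and for quantifying the resulting reduction in
    the asymptotic variance of time-average estimators. Provides built-in
    targets (Gaussian, warped Gaussian, periodic potential, dimer in a
    repulsive solvent), constructors for divergence-free perturbation
    fields from antisymmetric matrices, Euler-Maruyama, MALA and
    Strang-splitting integrators with gradient-evaluation accounting and
    blow-up detection, ensemble and batch-means estimators of the
    asymptotic variance, and exact Poisson-equation/Lyapunov computations
    of the asymptotic variance for Ornstein-Uhlenbeck (linear-drift)
    processes with linear and quadratic observables, including optimal
    antisymmetric perturbations and large-strength limits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    utils,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
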