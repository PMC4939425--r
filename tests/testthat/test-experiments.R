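obs_2x1sq <- make_observable_quadratic(diag(c(2, 0)), k = 0, name = "2x1sq",
                                       known_mean = 2)

test_that("alpha sweep tracks the closed-form variance of the rotation model", {
  g <- make_gaussian(2)
  sw <- alpha_sweep(g, J_rot, obs_2x1sq, alphas = c(0, 3), dt = 0.01,
                    n_steps = 10000, n_replicas = 60, master_seed = 71)
  expect_s3_class(sw, "tbl_df")
  expect_equal(nrow(sw), 2L)
  for (i in 1:2) {
    expect_lt(abs(sw$sigma2[i] - sigma2_closed_form(sw$alpha[i])),
              3 * sw$sigma2_se[i])
    # pooled estimate near pi(f) = 2, allowing the O(dt(1+alpha^2)) EM
    # stationary-covariance inflation on top of the CI half-width
    bias <- 2 / (1 - 0.01 * (1 + sw$alpha[i]^2) / 2) - 2
    expect_lt(abs(sw$estimate[i] - 2),
              (sw$ci_high[i] - sw$estimate[i]) + 2 * bias + 0.05)
  }
  expect_true(all(sw$diverged_fraction == 0))
  expect_error(
    alpha_sweep(g, J_rot, obs_2x1sq, alphas = 0, dt = 0.01, n_steps = 100,
                n_replicas = 1, master_seed = 1),
    ">= 2")
  expect_error(
    alpha_sweep(g, J_rot, obs_2x1sq, alphas = numeric(0), dt = 0.01,
                n_steps = 100, n_replicas = 4, master_seed = 1),
    "non-empty")
})

test_that("experiment tables are bit-reproducible from the master seed", {
  g <- make_gaussian(2)
  a <- alpha_sweep(g, J_rot, obs_2x1sq, alphas = c(0, 2), dt = 0.02,
                   n_steps = 1500, n_replicas = 8, master_seed = 5)
  b <- alpha_sweep(g, J_rot, obs_2x1sq, alphas = c(0, 2), dt = 0.02,
                   n_steps = 1500, n_replicas = 8, master_seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- alpha_sweep(g, J_rot, obs_2x1sq, alphas = c(0, 2), dt = 0.02,
                   n_steps = 1500, n_replicas = 8, master_seed = 6)
  expect_false(identical(a$estimate, c$estimate))
})

test_that("Metropolising the nonreversible proposal negates its benefit", {
  g <- make_gaussian(2)
  tb <- mh_comparison(g, J_rot, obs_2x1sq, alphas = c(0, 8), dt = 0.01,
                      n_steps = 10000, n_replicas = 50, master_seed = 81,
                      burn_in = 200)
  mh <- dplyr::filter(tb, scheme == "mh-nonrev")
  em <- dplyr::filter(tb, scheme == "em")
  # enforcing detailed balance makes the variance INCREASE with the
  # strength (rejected long proposals), the opposite of the unadjusted
  # sampler whose exact variance falls from 8 to about 4
  expect_gt(mh$sigma2[mh$alpha == 8], mh$sigma2[mh$alpha == 0])
  # proposals further from the current state are rejected more often
  expect_lt(mh$acceptance_rate[mh$alpha == 8],
            mh$acceptance_rate[mh$alpha == 0] - 0.2)
  # Metropolisation removes the EM discretisation bias at alpha = 8
  expect_lt(abs(mh$bias[mh$alpha == 8]), abs(em$bias[em$alpha == 8]))
  # at alpha = 0 the nonreversible-proposal chain IS reversible MALA:
  # identical replica seeds give identical estimates
  expect_equal(mh$estimate[mh$alpha == 0], em$estimate[em$alpha == 0],
               tolerance = 0.2)
})

test_that("MSE sweep equalises gradient budgets and shows the bias-variance tradeoff", {
  g <- make_gaussian(1)
  fx2 <- make_observable("x2", function(x) x^2, known_mean = 1)
  tb <- mse_sweep(g, matrix(0, 1, 1), fx2, reference = 1, alphas = 0,
                  dts = c(0.005, 0.05, 0.4), budget = 2e4, n_replicas = 30,
                  master_seed = 91, schemes = c("em", "mala"),
                  relative = FALSE)
  # budget accounting: em and mala run budget/1 steps each
  expect_true(all(tb$n_steps == 2e4))
  em <- dplyr::filter(tb, scheme == "em")$mse
  # U shape: middle timestep beats both the variance-dominated small-dt end
  # and the bias-dominated large-dt end
  expect_lt(em[2], em[1])
  expect_lt(em[2], em[3])
  # MALA has no discretisation bias: its large-dt MSE stays at sampling level
  ml <- dplyr::filter(tb, scheme == "mala")$mse
  expect_lt(ml[3], em[3])
  expect_true(all(tb$diverged_fraction == 0))

  # splitting cells get budget / 6 steps
  tb6 <- mse_sweep(make_gaussian(2), J_rot, obs_2x1sq, reference = 2,
                   alphas = 2, dts = 0.05, budget = 1.2e4, n_replicas = 2,
                   master_seed = 92, schemes = "splitting",
                   relative = FALSE)
  expect_equal(tb6$n_steps, 2000L)
})

test_that("diverged cells are reported, not dropped", {
  w <- make_warped_gaussian(0.05)
  f2 <- make_observable("norm2", function(x) sum(x^2))
  tb <- mse_sweep(w, J_rot, f2, reference = 29.53, alphas = 40,
                  dts = 0.25, budget = 2000, n_replicas = 4,
                  master_seed = 93, schemes = "em", relative = TRUE)
  expect_equal(tb$diverged_fraction, 1)
  expect_true(is.na(tb$mse))
})

test_that("dimer experiment estimates the reaction coordinate by batch means", {
  p <- dimer_params(n_particles = 4, box_length = 4.5)
  res <- dimer_experiment(p, kind = "block_circulant", alpha = 2,
                          dt = 2e-4, n_steps = 6000, seed = 17,
                          burn_in = 500, n_batches = 10)
  expect_s3_class(res$variance, "variance_estimate")
  expect_false(res$run$diverged)
  expect_true(is.finite(res$variance$estimate))
  expect_gte(res$variance$sigma2, 0)
  expect_equal(res$variance$method, "batch_means")

  # corner perturbation leaves the solvent drift untouched
  t4 <- make_dimer(p)
  f2 <- constant_J_drift(dimer_J(4, "corner_rotation"), t4, beta_free = TRUE)
  set.seed(1)
  q <- dimer_grid_configuration(p) + runif(8, -0.05, 0.05)
  gam <- f2$gamma(q)
  expect_equal(gam[5:8], rep(0, 4))
  expect_true(any(gam[1:4] != 0))
})

test_that("block and corner perturbations agree on the dimer observable", {
  p <- dimer_params(n_particles = 4, box_length = 4.5)
  run_one <- function(kind) {
    dimer_experiment(p, kind = kind, alpha = 4, dt = 2e-4, n_steps = 30000,
                     seed = 19, burn_in = 2000, n_batches = 15)$variance
  }
  v1 <- run_one("block_circulant")
  v2 <- run_one("corner_rotation")
  # both target the same stationary distribution: estimates agree within
  # joint CLT intervals
  joint <- sqrt((v1$ci_high - v1$estimate)^2 + (v2$ci_high - v2$estimate)^2)
  expect_lt(abs(v1$estimate - v2$estimate), 3 * joint)
})

test_that("XYZ round trip preserves configurations and tags", {
  p <- dimer_params(n_particles = 5, box_length = 6)
  q <- dimer_grid_configuration(p)
  path <- tempfile(fileext = ".xyz")
  write_xyz(q, p, path)
  back <- read_xyz(path)
  expect_equal(back$q, q, tolerance = 1e-9)
  expect_equal(back$tags, c("D", "D", "S", "S", "S"))
  unlink(path)
})

test_that("autoplot builds ggplot objects for sweeps and runs", {
  g <- make_gaussian(2)
  sw <- alpha_sweep(g, J_rot, obs_2x1sq, alphas = c(0, 2), dt = 0.05,
                    n_steps = 500, n_replicas = 4, master_seed = 3)
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
  cfg <- sampler_config(dt = 0.05, n_steps = 200, x0 = c(0, 0), seed = 2)
  run <- mala(g, cfg, obs_2x1sq)
  expect_s3_class(ggplot2::autoplot(run), "ggplot")
})
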