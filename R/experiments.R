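utils::globalVariables(c("alpha", "sigma2", "ci_low", "ci_high", "dt",
                         "scheme", "estimate"))

# Deterministic child seeds for replica ensembles: one master seed feeds a
# seeded draw of distinct sub-2^31 integers, so every table cell is
# bit-reproducible from `master_seed` alone.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

run_scheme <- function(scheme, target, field, cfg, observable) {
  switch(scheme,
         em = euler_maruyama(target, field, cfg, observable),
         mala = mala(target, cfg, observable),
         `mh-nonrev` = mala(target, cfg, observable, field = field),
         splitting = splitting(target, field, cfg, observable),
         stop("unknown scheme: ", scheme))
}

replica_averages <- function(scheme, target, field, observable, alpha, dt,
                             n_steps, seeds, x0, burn_in = 0) {
  vapply(seeds, function(s) {
    cfg <- sampler_config(dt = dt, n_steps = n_steps, alpha = alpha,
                          x0 = x0, seed = s, burn_in = burn_in)
    run <- run_scheme(scheme, target, field, cfg, observable)
    if (run$diverged || nrow(run$series) <= burn_in) return(NA_real_)
    ergodic_average(run$series[, 1], dt, burn_in)
  }, numeric(1))
}

#' Sweep the perturbation strength and estimate the asymptotic variance
#'
#' For each strength in `alphas`, runs `n_replicas` independently seeded
#' replicas of the chosen scheme, forms the time-average estimate of the
#' observable in each, and summarises with the ensemble estimator of
#' \eqn{\sigma_f^2} and its confidence interval.
#'
#' @param target a [target_density()].
#' @param J antisymmetric matrix defining the perturbation
#'   (via [constant_J_drift()]).
#' @param observable an observable.
#' @param alphas numeric vector of perturbation strengths.
#' @param dt timestep.
#' @param n_steps steps per replica.
#' @param n_replicas independent replicas per strength (`>= 2`).
#' @param master_seed master seed; replica seeds are derived
#'   deterministically from it.
#' @param scheme `"em"`, `"mala"`, `"mh-nonrev"` or `"splitting"`.
#' @param x0 initial point (default origin).
#' @param burn_in recorded samples dropped before averaging.
#' @param beta_free use the bare-potential drift convention
#'   (see [constant_J_drift()]).
#' @param level confidence level.
#' @return A tibble (class `"nr_sweep"`) with one row per strength:
#'   `alpha`, `estimate`, `sigma2`, `sigma2_se`, `ci_low`, `ci_high`,
#'   `n_replicas`, `diverged_fraction`.
#' @export
alpha_sweep <- function(target, J, observable, alphas, dt, n_steps,
                        n_replicas, master_seed, scheme = "em",
                        x0 = numeric(target$dim), burn_in = 0,
                        beta_free = FALSE, level = 0.95) {
  if (n_replicas < 2) stop("`n_replicas` must be >= 2 for the ensemble estimator")
  if (length(alphas) == 0) stop("`alphas` must be non-empty")
  field <- constant_J_drift(J, target, beta_free = beta_free)
  seeds <- matrix(derive_seeds(master_seed, n_replicas * length(alphas)),
                  ncol = length(alphas))
  Teff <- (n_steps - burn_in) * dt
  out <- purrr::imap_dfr(as.numeric(alphas), function(a, i) {
    est <- replica_averages(scheme, target, field, observable, a, dt,
                            n_steps, seeds[, i], x0, burn_in)
    ok <- is.finite(est)
    if (sum(ok) < 2) {
      return(tibble::tibble(alpha = a, estimate = NA_real_,
                            sigma2 = NA_real_, sigma2_se = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            n_replicas = sum(ok),
                            diverged_fraction = mean(!ok)))
    }
    ve <- ensemble_sigma2(est[ok], Teff, level)
    tibble::tibble(alpha = a, estimate = ve$estimate, sigma2 = ve$sigma2,
                   sigma2_se = ve$sigma2_se, ci_low = ve$ci_low,
                   ci_high = ve$ci_high, n_replicas = ve$n,
                   diverged_fraction = mean(!ok))
  })
  class(out) <- c("nr_sweep", class(out))
  attr(out, "sweep_var") <- "alpha"
  out
}

#' Compare the unadjusted nonreversible sampler with its Metropolised version
#'
#' Paired strength sweep of the unadjusted Euler-Maruyama scheme against
#' the Metropolis-Hastings chain that uses the same nonreversible proposal.
#' Metropolisation enforces detailed balance, so the variance reduction of
#' the nonreversible drift is expected to be negated (and the acceptance
#' rate to fall with the strength), while the unadjusted chain keeps it at
#' the price of a discretisation bias.
#'
#' @inheritParams alpha_sweep
#' @return A tibble with one row per (scheme, alpha): columns of
#'   [alpha_sweep()] plus `scheme`, `acceptance_rate` and `bias`
#'   (estimate minus the observable's `known_mean`, when available).
#' @export
mh_comparison <- function(target, J, observable, alphas, dt, n_steps,
                          n_replicas, master_seed,
                          x0 = numeric(target$dim), burn_in = 0,
                          beta_free = FALSE, level = 0.95) {
  field <- constant_J_drift(J, target, beta_free = beta_free)
  seeds <- matrix(derive_seeds(master_seed, n_replicas * length(alphas)),
                  ncol = length(alphas))
  Teff <- (n_steps - burn_in) * dt
  ref <- observable$known_mean
  out <- purrr::map_dfr(c("em", "mh-nonrev"), function(sch) {
    purrr::imap_dfr(as.numeric(alphas), function(a, i) {
      acc <- 0; nsd <- 0
      est <- vapply(seeds[, i], function(s) {
        cfg <- sampler_config(dt = dt, n_steps = n_steps, alpha = a,
                              x0 = x0, seed = s, burn_in = burn_in)
        run <- run_scheme(sch, target, field, cfg, observable)
        if (!is.na(run$n_accepted)) {
          acc <<- acc + run$n_accepted; nsd <<- nsd + run$n_steps
        }
        if (run$diverged || nrow(run$series) <= burn_in) return(NA_real_)
        ergodic_average(run$series[, 1], dt, burn_in)
      }, numeric(1))
      ok <- is.finite(est)
      ve <- if (sum(ok) >= 2) ensemble_sigma2(est[ok], Teff, level) else NULL
      tibble::tibble(
        scheme = sch, alpha = a,
        estimate = if (is.null(ve)) NA_real_ else ve$estimate,
        sigma2 = if (is.null(ve)) NA_real_ else ve$sigma2,
        ci_low = if (is.null(ve)) NA_real_ else ve$ci_low,
        ci_high = if (is.null(ve)) NA_real_ else ve$ci_high,
        acceptance_rate = if (nsd > 0) acc / nsd else NA_real_,
        bias = if (!is.null(ref) && !is.null(ve)) ve$estimate - ref else NA_real_,
        n_replicas = sum(ok), diverged_fraction = mean(!ok))
    })
  })
  class(out) <- c("nr_sweep", class(out))
  attr(out, "sweep_var") <- "alpha"
  out
}

#' Timestep sweep of the mean squared error under a fixed gradient budget
#'
#' For each (scheme, alpha, dt) cell the number of steps is set to
#' `budget / grad_evals_per_step(scheme)` so every cell spends the same
#' number of gradient evaluations; `n_replicas` replicas then yield the
#' (relative) mean squared error of the time average against `reference`.
#' Diverged replicas are excluded and their fraction reported — a cell
#' where all replicas blow up keeps `mse = NA`.
#'
#' @inheritParams alpha_sweep
#' @param dts numeric vector of timesteps.
#' @param budget total gradient evaluations per replica.
#' @param reference the true value of \eqn{\pi(f)}; supply an analytic or
#'   quadrature value, never a self-simulated one.
#' @param schemes character vector of schemes to compare.
#' @param relative report the relative MSE \eqn{(\mathrm{Err}/\pi(f))^2}.
#' @return A tibble with one row per (scheme, alpha, dt).
#' @export
mse_sweep <- function(target, J, observable, reference, alphas, dts, budget,
                      n_replicas, master_seed, schemes = c("em", "mala"),
                      x0 = numeric(target$dim), burn_in = 0,
                      relative = TRUE, beta_free = FALSE) {
  if (relative && reference == 0) stop("relative MSE needs nonzero reference")
  field <- constant_J_drift(J, target, beta_free = beta_free)
  cells <- expand.grid(scheme = schemes, alpha = as.numeric(alphas),
                       dt = as.numeric(dts), stringsAsFactors = FALSE)
  seeds <- matrix(derive_seeds(master_seed, n_replicas * nrow(cells)),
                  ncol = nrow(cells))
  out <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    sch <- cells$scheme[i]; a <- cells$alpha[i]; h <- cells$dt[i]
    n_steps <- max(2L, as.integer(budget %/% grad_evals_per_step(sch)))
    est <- replica_averages(sch, target, field, observable, a, h,
                            n_steps, seeds[, i], x0, burn_in)
    r <- mse(est, reference, relative)
    tibble::tibble(scheme = sch, alpha = a, dt = h, n_steps = n_steps,
                   mse = r$mse, n_replicas = r$n_replicas,
                   diverged_fraction = r$diverged_fraction)
  })
  class(out) <- c("nr_sweep", class(out))
  attr(out, "sweep_var") <- "dt"
  out
}

#' Dimer reaction-coordinate experiment
#'
#' Single-trajectory estimation of the mean reaction coordinate
#' \eqn{E_\pi\,\xi(q)} of the dimer-in-solvent model under a nonreversible
#' perturbation, with the asymptotic variance estimated by batch means.
#'
#' @param params a [dimer_params()].
#' @param kind which antisymmetric matrix to use (see [dimer_J()]).
#' @param alpha perturbation strength.
#' @param dt timestep.
#' @param n_steps number of steps.
#' @param seed RNG seed.
#' @param burn_in recorded samples dropped before estimation.
#' @param n_batches batch count for the variance estimator.
#' @param record_stride recording stride.
#' @param x0 initial configuration; the default places the particles on a
#'   regular grid in the box with the dimer at its compact distance.
#' @param snapshot_path optional path; when given, the final configuration
#'   is written there in XYZ format.
#' @return A list with `variance` (a `"variance_estimate"` whose `estimate`
#'   is the time average of the reaction coordinate) and the full `run`.
#' @export
dimer_experiment <- function(params, kind = "block_circulant", alpha = 0,
                             dt = 1e-4, n_steps = 1e4, seed = 1,
                             burn_in = 0, n_batches = 30, record_stride = 1,
                             x0 = NULL, snapshot_path = NULL) {
  target <- make_dimer(params)
  J <- dimer_J(params$n_particles, kind)
  field <- constant_J_drift(J, target, beta_free = TRUE)
  if (is.null(x0)) x0 <- dimer_grid_configuration(params)
  xi <- make_observable("xi", function(q) reaction_coordinate(q, params))
  cfg <- sampler_config(dt = dt, n_steps = n_steps, alpha = alpha, x0 = x0,
                        seed = seed, burn_in = burn_in,
                        record_stride = record_stride)
  run <- euler_maruyama(target, field, cfg, xi)
  if (run$diverged) {
    warning("dimer trajectory diverged at step ", run$diverged_at)
  }
  ve <- batch_means_sigma2(run$series[, 1], dt * record_stride,
                           n_batches = n_batches, burn_in = burn_in)
  if (!is.null(snapshot_path)) {
    write_xyz(run$final_state, params, snapshot_path)
  }
  list(variance = ve, run = run)
}

#' Regular-grid starting configuration for the dimer model
#'
#' Particles on a square lattice filling the box; particles 1 and 2
#' (the dimer) are then placed at the compact separation `r0`.
#'
#' @param params a [dimer_params()].
#' @return A configuration vector of length `2N`.
#' @export
dimer_grid_configuration <- function(params) {
  N <- params$n_particles; L <- params$box_length
  side <- ceiling(sqrt(N))
  sp <- L / side
  idx <- seq_len(N) - 1L
  xy <- cbind((idx %% side + 0.5) * sp, (idx %/% side + 0.5) * sp)
  xy[2, ] <- xy[1, ] + c(params$r0, 0)   # compact dimer
  as.vector(t(xy)) %% L
}

#' Write a dimer configuration in XYZ format
#'
#' Plain-text XYZ: an atom count line, a comment line, then one
#' `tag x y z` line per particle (z = 0 for this planar model). Dimer
#' particles are tagged `D`, solvent particles `S`.
#'
#' @param q configuration vector of length `2N`.
#' @param params a [dimer_params()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(q, params, path) {
  N <- params$n_particles
  stopifnot(length(q) == 2 * N)
  xy <- matrix(q, ncol = 2, byrow = TRUE)
  tags <- c("D", "D", rep("S", N - 2))
  lines <- c(
    as.character(N),
    sprintf("dimer model: N=%d L=%g", N, params$box_length),
    sprintf("%s %.10f %.10f 0.0", tags, xy[, 1], xy[, 2])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a dimer configuration from an XYZ file
#'
#' @param path file written by [write_xyz()] (or any XYZ file with
#'   one particle per line after the two header lines).
#' @return A list with the configuration vector `q` and the particle `tags`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  body <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  tags <- vapply(body, `[[`, character(1), 1)
  xy <- t(vapply(body, function(p) as.numeric(p[2:3]), numeric(2)))
  list(q = as.vector(t(xy)), tags = tags)
}

#' Plot a strength or timestep sweep
#'
#' @param object a sweep tibble from [alpha_sweep()], [mh_comparison()] or
#'   [mse_sweep()].
#' @param ... unused.
#' @return A ggplot object: the estimated variance (or MSE) against the
#'   swept variable, with confidence ribbons where available, on a log-y
#'   scale.
#' @export
autoplot.nr_sweep <- function(object, ...) {
  xvar <- attr(object, "sweep_var") %||% "alpha"
  yvar <- if ("mse" %in% names(object)) "mse" else "sigma2"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]],
                                            y = .data[[yvar]]))
  if ("scheme" %in% names(object)) {
    p <- p + ggplot2::aes(colour = .data[["scheme"]])
  }
  p <- p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = xvar,
                  y = if (yvar == "mse") "mean squared error"
                      else expression(hat(sigma)[f]^2))
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trace plot of a sampler run
#'
#' @param object a `"sampler_run"`.
#' @param ... unused.
#' @return A ggplot of each recorded observable against time.
#' @export
autoplot.sampler_run <- function(object, ...) {
  s <- object$series
  df <- tibble::tibble(
    time = rep(seq_len(nrow(s)) * object$dt * object$record_stride,
               ncol(s)),
    observable = rep(colnames(s), each = nrow(s)),
    value = as.vector(s)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data[["time"]],
                                   y = .data[["value"]])) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap("observable", scales = "free_y") +
    ggplot2::labs(x = "time", y = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
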