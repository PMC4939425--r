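#' Sampler configuration
#'
#' Settings shared by all time-discrete sampling engines.
#'
#' @param dt timestep (`> 0`).
#' @param n_steps number of steps (`>= 1`).
#' @param alpha strength of the nonreversible perturbation (default 0).
#' @param x0 initial point.
#' @param seed optional RNG seed; seeded runs are bit-reproducible.
#' @param burn_in recorded samples discarded by downstream estimators
#'   (`>= 0`, `< n_steps`); kept with the run for provenance.
#' @param record_stride record the observables every this many steps.
#' @param blowup_norm divergence threshold on the state norm; non-finite
#'   states always count as divergence.
#' @param noise logical test hook: `FALSE` suppresses the Brownian increment
#'   so single deterministic Euler steps can be checked exactly.
#' @return An object of class `"sampler_config"`.
#' @export
sampler_config <- function(dt, n_steps, alpha = 0, x0, seed = NULL,
                           burn_in = 0, record_stride = 1,
                           blowup_norm = 1e8, noise = TRUE) {
  if (dt <= 0) stop("`dt` must be positive")
  if (n_steps < 1) stop("`n_steps` must be >= 1")
  if (burn_in < 0 || burn_in >= n_steps) stop("need 0 <= burn_in < n_steps")
  if (record_stride < 1) stop("`record_stride` must be >= 1")
  if (!all(is.finite(x0))) stop("`x0` must be finite")
  structure(
    list(dt = dt, n_steps = as.integer(n_steps), alpha = alpha, x0 = x0,
         seed = seed, burn_in = as.integer(burn_in),
         record_stride = as.integer(record_stride),
         blowup_norm = blowup_norm, noise = isTRUE(noise)),
    class = "sampler_config"
  )
}

as_observable_list <- function(observables) {
  if (inherits(observables, "observable")) observables <- list(observables)
  stopifnot(all(vapply(observables, inherits, logical(1), "observable")))
  nm <- vapply(observables, `[[`, character(1), "name")
  stats::setNames(observables, nm)
}

wrap_state <- function(x, target) {
  if (target$domain == "torus") x %% target$period else x
}

new_sampler_run <- function(series, cfg, scheme, n_accepted, n_grad_evals,
                            diverged, diverged_at, final_state) {
  structure(
    list(series = series, dt = cfg$dt, alpha = cfg$alpha,
         record_stride = cfg$record_stride, burn_in = cfg$burn_in,
         scheme = scheme, n_steps = cfg$n_steps, n_accepted = n_accepted,
         n_grad_evals = n_grad_evals, diverged = diverged,
         diverged_at = diverged_at, final_state = final_state,
         seed = cfg$seed),
    class = "sampler_run"
  )
}

#' @export
print.sampler_run <- function(x, ...) {
  cat(sprintf(
    "<sampler_run> %s: %d steps, dt = %g, alpha = %g%s%s\n",
    x$scheme, x$n_steps, x$dt, x$alpha,
    if (!is.na(x$n_accepted)) sprintf(", accepted %.1f%%",
                                      100 * x$n_accepted / x$n_steps) else "",
    if (x$diverged) sprintf(" [DIVERGED at step %d]", x$diverged_at) else ""
  ))
  invisible(x)
}

# Cheap per-step test: non-finite state or norm beyond threshold. The
# energy-based test (|V| beyond threshold, or V not evaluable) is applied
# at a coarser stride by the integrators since it costs a potential
# evaluation; a state whose energy explodes drags the state norm or the
# next gradient with it within a few steps.
run_blown_up <- function(x, blowup_norm) {
  !all(is.finite(x)) || sqrt(sum(x^2)) > blowup_norm
}

energy_blown_up <- function(x, blowup_norm, target) {
  v <- tryCatch(target$V(x), error = function(e) Inf)
  !is.finite(v) || abs(v) > blowup_norm
}

#' Euler-Maruyama integrator for the nonreversible Langevin SDE
#'
#' Simulates
#' \deqn{X^{(n+1)} = X^{(n)} + \Delta t\,[\nabla\log\pi(X^{(n)}) +
#'   \alpha\gamma(X^{(n)})] + \sqrt{2\Delta t}\,\xi_n,}
#' with standard-normal \eqn{\xi_n}, wrapping torus coordinates into
#' `[0, L)` after each step. Exactly one gradient evaluation is counted per
#' step. Divergence (non-finite state, or state/energy norm beyond the
#' configured threshold) truncates the recorded series and raises a flag
#' instead of an error.
#'
#' @param target a [target_density()].
#' @param field optional perturbation field (required when `alpha != 0`).
#' @param cfg a [sampler_config()].
#' @param observables an observable or list of observables to record.
#' @return A `"sampler_run"` object.
#' @export
euler_maruyama <- function(target, field = NULL, cfg, observables) {
  stopifnot(inherits(target, "target_density"), inherits(cfg, "sampler_config"))
  if (cfg$alpha != 0 && is.null(field)) stop("nonzero `alpha` needs a `field`")
  obs <- as_observable_list(observables)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  d <- target$dim
  dt <- cfg$dt
  sq <- sqrt(2 * dt)
  alpha <- cfg$alpha
  stride <- cfg$record_stride
  bn <- cfg$blowup_norm
  grad_lp <- target$grad_log_density
  gam <- if (alpha != 0) field$gamma else NULL
  on_torus <- target$domain == "torus"
  period <- target$period
  add_noise <- cfg$noise
  x <- if (on_torus) cfg$x0 %% period else cfg$x0
  n_rec <- cfg$n_steps %/% stride
  series <- matrix(NA_real_, n_rec, length(obs),
                   dimnames = list(NULL, names(obs)))
  obs_fns <- lapply(obs, `[[`, "eval")
  diverged <- FALSE; diverged_at <- NA_integer_
  k <- 0L
  for (n in seq_len(cfg$n_steps)) {
    drift <- grad_lp(x)
    if (alpha != 0) drift <- drift + alpha * gam(x)
    x <- x + dt * drift
    if (add_noise) x <- x + sq * stats::rnorm(d)
    if (on_torus) x <- x %% period
    if (run_blown_up(x, bn) ||
        (n %% 64L == 0L && energy_blown_up(x, bn, target))) {
      diverged <- TRUE; diverged_at <- n
      break
    }
    if (n %% stride == 0L) {
      k <- k + 1L
      for (j in seq_along(obs_fns)) series[k, j] <- obs_fns[[j]](x)
    }
  }
  new_sampler_run(series[seq_len(k), , drop = FALSE], cfg, "em",
                  n_accepted = NA_integer_, n_grad_evals = cfg$n_steps,
                  diverged = diverged, diverged_at = diverged_at,
                  final_state = x)
}

# One MALA accept/reject step. Proposal X~ = N(x + dt*b(x), 2*dt*I), with
# b = grad log pi (+ alpha*gamma for the nonreversible-proposal variant);
# acceptance ratio pi(X~) q(X~ -> x) / (pi(x) q(x -> X~)). The gradient at
# the current state is cached by the caller, so each step costs one fresh
# gradient evaluation (amortised).
mala_step <- function(x, lp_x, b_x, target, field, alpha, dt, noise = TRUE) {
  drift_at <- function(y, g) if (alpha != 0) g + alpha * field$gamma(y) else g
  prop_mean <- x + dt * b_x
  xi <- if (noise) stats::rnorm(length(x)) else numeric(length(x))
  y <- prop_mean + sqrt(2 * dt) * xi
  g_y <- target$grad_log_density(y)
  b_y <- drift_at(y, g_y)
  lp_y <- target$log_density(y)
  # log q(x -> y) = -|y - x - dt b(x)|^2 / (4 dt), up to a common constant
  log_q_fwd <- -sum((y - x - dt * b_x)^2) / (4 * dt)
  log_q_bwd <- -sum((x - y - dt * b_y)^2) / (4 * dt)
  log_acc <- lp_y - lp_x + log_q_bwd - log_q_fwd
  accept <- log(stats::runif(1)) < log_acc
  if (accept) {
    list(x = y, lp = lp_y, b = b_y, accepted = TRUE)
  } else {
    list(x = x, lp = lp_x, b = b_x, accepted = FALSE)
  }
}

#' Metropolis-adjusted Langevin algorithm
#'
#' Proposals follow one Euler-Maruyama step of the (optionally
#' nonreversibly-perturbed) Langevin dynamics, with covariance
#' \eqn{2\Delta t I}, corrected by a Metropolis-Hastings accept/reject step.
#' Without a perturbation field the chain is reversible and exactly
#' \eqn{\pi}-invariant for any stepsize; with a field the proposal is
#' nonreversible but the accept/reject step enforces detailed balance, which
#' negates the perturbation's variance reduction (this variant exists to
#' quantify that effect).
#'
#' @inheritParams euler_maruyama
#' @param field optional perturbation field for the nonreversible-proposal
#'   variant.
#' @return A `"sampler_run"` object; `n_accepted` counts accepted proposals.
#' @export
mala <- function(target, cfg, observables, field = NULL) {
  stopifnot(inherits(target, "target_density"), inherits(cfg, "sampler_config"))
  obs <- as_observable_list(observables)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  alpha <- if (is.null(field)) 0 else cfg$alpha
  dt <- cfg$dt
  sq <- sqrt(2 * dt)
  stride <- cfg$record_stride
  bn <- cfg$blowup_norm
  log_pi <- target$log_density
  grad_lp <- target$grad_log_density
  gam <- if (alpha != 0) field$gamma else NULL
  on_torus <- target$domain == "torus"
  period <- target$period
  add_noise <- cfg$noise
  d <- target$dim
  x <- if (on_torus) cfg$x0 %% period else cfg$x0
  lp <- log_pi(x)
  b <- grad_lp(x)
  if (alpha != 0) b <- b + alpha * gam(x)
  n_rec <- cfg$n_steps %/% stride
  series <- matrix(NA_real_, n_rec, length(obs),
                   dimnames = list(NULL, names(obs)))
  obs_fns <- lapply(obs, `[[`, "eval")
  n_acc <- 0L; k <- 0L
  diverged <- FALSE; diverged_at <- NA_integer_
  for (n in seq_len(cfg$n_steps)) {
    # propose from the Euler step; the current gradient is cached so each
    # step costs one fresh gradient evaluation
    mu_fwd <- x + dt * b
    y <- if (add_noise) mu_fwd + sq * stats::rnorm(d) else mu_fwd
    b_y <- grad_lp(y)
    if (alpha != 0) b_y <- b_y + alpha * gam(y)
    lp_y <- log_pi(y)
    dy <- y - mu_fwd
    dx <- x - y - dt * b_y
    log_acc <- lp_y - lp + (sum(dy * dy) - sum(dx * dx)) / (4 * dt)
    if (log(stats::runif(1)) < log_acc) {
      n_acc <- n_acc + 1L
      x <- if (on_torus) y %% period else y
      lp <- lp_y; b <- b_y
    }
    if (run_blown_up(x, bn) ||
        (n %% 64L == 0L && energy_blown_up(x, bn, target))) {
      diverged <- TRUE; diverged_at <- n
      break
    }
    if (n %% stride == 0L) {
      k <- k + 1L
      for (j in seq_along(obs_fns)) series[k, j] <- obs_fns[[j]](x)
    }
  }
  new_sampler_run(series[seq_len(k), , drop = FALSE], cfg, "mala",
                  n_accepted = n_acc, n_grad_evals = cfg$n_steps + 1L,
                  diverged = diverged, diverged_at = diverged_at,
                  final_state = x)
}

#' Fourth-order Runge-Kutta flow of the nonreversible drift
#'
#' Integrates the deterministic flow \eqn{\dot z = \alpha\gamma(z)} over a
#' time `dt` with `n_substeps` classical RK4 steps. Used as the
#' nonreversible sub-flow of the splitting integrator; when \eqn{\gamma}
#' derives from a potential the exact flow conserves `V`, and RK4 tracks it
#' to \eqn{O(\Delta t^4)} locally.
#'
#' @param field a perturbation field.
#' @param alpha perturbation strength.
#' @param x starting point.
#' @param dt total flow time (`> 0`).
#' @param n_substeps number of RK4 steps (default 1).
#' @return The endpoint of the flow.
#' @export
rk4_flow <- function(field, alpha, x, dt, n_substeps = 1) {
  if (dt <= 0) stop("`dt` must be positive")
  if (alpha == 0) return(x)
  h <- dt / n_substeps
  f <- function(z) alpha * field$gamma(z)
  for (i in seq_len(n_substeps)) {
    k1 <- f(x)
    k2 <- f(x + h / 2 * k1)
    k3 <- f(x + h / 2 * k2)
    k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

#' Strang-splitting integrator for the nonreversible dynamics
#'
#' Each step composes a reversible MALA substep of size \eqn{\Delta t/2},
#' the deterministic RK4 flow of \eqn{\alpha\gamma} over \eqn{\Delta t}, and
#' a second MALA substep of size \eqn{\Delta t/2}. With \eqn{\alpha = 0} the
#' scheme reduces exactly to MALA at stepsize \eqn{\Delta t/2} (same RNG
#' stream). Gradient cost is accounted as six evaluations of
#' \eqn{\nabla\log\pi} per step (two MALA proposals plus four RK4 stages,
#' after reusing two evaluations between substeps).
#'
#' @inheritParams euler_maruyama
#' @param field a perturbation field.
#' @return A `"sampler_run"` object; `n_accepted` counts accepted MALA
#'   substeps (out of `2 * n_steps`).
#' @export
splitting <- function(target, field, cfg, observables) {
  stopifnot(inherits(target, "target_density"), inherits(cfg, "sampler_config"))
  obs <- as_observable_list(observables)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dt <- cfg$dt
  x <- wrap_state(cfg$x0, target)
  lp <- target$log_density(x)
  b <- target$grad_log_density(x)   # reversible substeps: b = grad log pi
  n_rec <- cfg$n_steps %/% cfg$record_stride
  series <- matrix(NA_real_, n_rec, length(obs),
                   dimnames = list(NULL, names(obs)))
  n_acc <- 0L; k <- 0L
  diverged <- FALSE; diverged_at <- NA_integer_
  for (n in seq_len(cfg$n_steps)) {
    st <- mala_step(x, lp, b, target, NULL, 0, dt / 2, cfg$noise)
    if (st$accepted) n_acc <- n_acc + 1L
    x <- st$x
    if (cfg$alpha != 0) {
      x <- wrap_state(rk4_flow(field, cfg$alpha, x, dt), target)
      lp <- target$log_density(x)
      b <- target$grad_log_density(x)
    } else {
      lp <- st$lp; b <- st$b
    }
    st <- mala_step(x, lp, b, target, NULL, 0, dt / 2, cfg$noise)
    if (st$accepted) n_acc <- n_acc + 1L
    x <- st$x; lp <- st$lp; b <- st$b
    if (run_blown_up(x, cfg$blowup_norm) ||
        (n %% 64L == 0L && energy_blown_up(x, cfg$blowup_norm, target))) {
      diverged <- TRUE; diverged_at <- n
      break
    }
    if (n %% cfg$record_stride == 0L) {
      k <- k + 1L
      for (j in seq_along(obs)) series[k, j] <- obs[[j]]$eval(x)
    }
  }
  new_sampler_run(series[seq_len(k), , drop = FALSE], cfg, "splitting",
                  n_accepted = n_acc, n_grad_evals = 6L * cfg$n_steps + 1L,
                  diverged = diverged, diverged_at = diverged_at,
                  final_state = x)
}

#' Per-step gradient-evaluation cost of a scheme
#'
#' Used by the experiment drivers to equalise gradient-evaluation budgets
#' across schemes: Euler-Maruyama and MALA cost one evaluation per step
#' (amortised), the splitting integrator six.
#'
#' @param scheme `"em"`, `"mala"`, `"mh-nonrev"` or `"splitting"`.
#' @return Integer cost per step.
#' @export
grad_evals_per_step <- function(scheme) {
  switch(scheme,
         em = 1L, mala = 1L, `mh-nonrev` = 1L, splitting = 6L,
         stop("unknown scheme: ", scheme))
}
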