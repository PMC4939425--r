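#' Time-average (ergodic) estimator
#'
#' Mean of the recorded observable values after discarding `burn_in`
#' initial samples — the Riemann approximation of
#' \eqn{\pi_T(f) = T^{-1}\int_0^T f(X_t)\,dt}.
#'
#' @param series numeric vector of recorded observable values.
#' @param dt sampling interval (unused by the plain mean; kept so callers
#'   can pass run metadata through uniformly).
#' @param burn_in number of initial samples to drop.
#' @return The post-burn-in mean.
#' @export
ergodic_average <- function(series, dt = NULL, burn_in = 0) {
  series <- as.numeric(series)
  if (burn_in > 0) series <- series[-seq_len(min(burn_in, length(series)))]
  if (length(series) == 0) stop("empty series after burn-in")
  mean(series)
}

new_variance_estimate <- function(estimate, sigma2, sigma2_se, ci, method,
                                  T, n) {
  structure(
    list(estimate = estimate, sigma2 = sigma2, sigma2_se = sigma2_se,
         ci_low = ci[1], ci_high = ci[2], method = method, T = T, n = n),
    class = "variance_estimate"
  )
}

#' @export
print.variance_estimate <- function(x, ...) {
  cat(sprintf(
    "<variance_estimate> [%s] estimate = %.6g (95%% CI %.6g..%.6g), sigma2 = %.6g, T = %g, n = %d\n",
    x$method, x$estimate, x$ci_low, x$ci_high, x$sigma2, x$T, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.variance_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, sigma2 = x$sigma2,
                 sigma2_se = x$sigma2_se, ci_low = x$ci_low,
                 ci_high = x$ci_high, method = x$method, T = x$T, n = x$n)
}

#' @export
glance.variance_estimate <- function(x, ...) tidy.variance_estimate(x)

#' Ensemble (cross-replica) estimator of the asymptotic variance
#'
#' Given time-average estimates \eqn{\pi_T(f)} from independent replicas of
#' common length `T`, the central limit theorem
#' \eqn{\sqrt T(\pi_T(f) - \pi(f)) \to N(0, \sigma_f^2)} identifies
#' \eqn{\sigma_f^2 \approx T \cdot \mathrm{Var}[\pi_T(f)]}, estimated here
#' with the cross-replica sample variance. The point estimate is the
#' cross-replica mean, with a normal-theory confidence interval.
#'
#' @param replica_estimates numeric vector of per-replica time averages
#'   (length `>= 2`); non-finite entries (diverged replicas) are dropped.
#' @param T total simulated time per replica.
#' @param level confidence level (default 0.95).
#' @return A `"variance_estimate"` (method `"ensemble"`); `sigma2_se` is the
#'   normal-theory standard error of `sigma2` itself,
#'   \eqn{\sigma^2\sqrt{2/(R-1)}}.
#' @export
ensemble_sigma2 <- function(replica_estimates, T, level = 0.95) {
  est <- replica_estimates[is.finite(replica_estimates)]
  R <- length(est)
  if (R < 2) stop("need at least 2 (finite) replica estimates")
  m <- mean(est)
  s2 <- T * stats::var(est)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(s2 / (T * R))        # CI of the pooled estimate
  new_variance_estimate(m, s2, s2 * sqrt(2 / (R - 1)),
                        c(m - half, m + half), "ensemble", T, R)
}

#' Batch-means estimator of the asymptotic variance
#'
#' Splits a single post-burn-in series into `n_batches` contiguous batches
#' of equal time length \eqn{T_b} (trailing remainder discarded) and
#' estimates \eqn{\sigma_f^2 = T_b \cdot} sample variance of the batch
#' means. Valid when \eqn{T_b} greatly exceeds the correlation time.
#'
#' @param series numeric vector of recorded observable values.
#' @param dt time between recorded values.
#' @param n_batches number of batches (`>= 2`, default 30).
#' @param burn_in initial samples to drop.
#' @param level confidence level.
#' @return A `"variance_estimate"` (method `"batch_means"`).
#' @export
batch_means_sigma2 <- function(series, dt, n_batches = 30, burn_in = 0,
                               level = 0.95) {
  series <- as.numeric(series)
  if (burn_in > 0) series <- series[-seq_len(min(burn_in, length(series)))]
  if (n_batches < 2) stop("`n_batches` must be >= 2")
  n <- length(series)
  if (n < 2 * n_batches) stop("series too short for the requested batches")
  m <- n %/% n_batches
  used <- series[seq_len(m * n_batches)]
  bm <- colMeans(matrix(used, nrow = m))
  Tb <- m * dt
  s2 <- Tb * stats::var(bm)
  Ttot <- length(used) * dt
  est <- mean(used)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(s2 / Ttot)
  new_variance_estimate(est, s2, s2 * sqrt(2 / (n_batches - 1)),
                        c(est - half, est + half), "batch_means",
                        Ttot, as.integer(n_batches))
}

#' Mean squared error of replica estimates against a reference
#'
#' \eqn{\mathrm{Err}^2 = E|\pi_{T}(f) - \pi(f)|^2} across replicas, with
#' non-finite (diverged) replicas excluded and their fraction reported.
#' The relative variant divides by `reference^2`.
#'
#' @param estimates numeric vector of replica estimates.
#' @param reference the true (or high-accuracy) value of \eqn{\pi(f)}.
#' @param relative report relative MSE.
#' @return A list with `mse`, `relative`, `n_replicas` (finite ones used)
#'   and `diverged_fraction`.
#' @export
mse <- function(estimates, reference, relative = FALSE) {
  if (!is.finite(reference)) stop("`reference` must be finite")
  if (relative && reference == 0) stop("relative MSE needs nonzero reference")
  ok <- is.finite(estimates)
  if (!any(ok)) {
    return(list(mse = NA_real_, relative = relative, n_replicas = 0L,
                diverged_fraction = 1))
  }
  e <- mean((estimates[ok] - reference)^2)
  if (relative) e <- e / reference^2
  list(mse = e, relative = relative, n_replicas = sum(ok),
       diverged_fraction = mean(!ok))
}

#' Normal-theory confidence interval for a time-average estimator
#'
#' \eqn{\pi_T(f) \mp z_{level}\sqrt{\sigma^2/T}}, the interval implied by
#' the central limit theorem for the time average.
#'
#' @param estimate point estimate.
#' @param sigma2 asymptotic variance (`>= 0`).
#' @param T total simulated time (`> 0`).
#' @param level confidence level in (0, 1).
#' @return Numeric `c(low, high)`.
#' @export
confidence_interval <- function(estimate, sigma2, T, level = 0.95) {
  if (sigma2 < 0) stop("`sigma2` must be >= 0")
  if (T <= 0) stop("`T` must be positive")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  half <- stats::qnorm(1 - (1 - level) / 2) * sqrt(sigma2 / T)
  c(estimate - half, estimate + half)
}
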