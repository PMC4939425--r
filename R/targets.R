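#' Construct a target density
#'
#' A target density represents an unnormalised Gibbs distribution
#' \eqn{\pi(x) \propto e^{-\beta V(x)}} on Euclidean space or on a torus.
#' Both the potential `V` and its gradient are stored, together with the
#' inverse temperature `beta`, so that `log_density(x)` returns
#' \eqn{-\beta V(x)} (up to an additive constant) and
#' `grad_log_density(x)` returns \eqn{-\beta \nabla V(x)}.
#'
#' @param V function mapping a point (numeric vector of length `dim`) to the
#'   potential value.
#' @param grad_V function mapping a point to the gradient of `V`.
#' @param dim dimension of the state space.
#' @param domain `"euclidean"` or `"torus"`.
#' @param period for torus domains, the period `L` per coordinate (scalar,
#'   recycled to length `dim`).
#' @param beta inverse temperature (dimensionless, `> 0`).
#' @param name label used in printing.
#'
#' @return An object of class `"target_density"` with elements `V`, `grad_V`,
#'   `log_density`, `grad_log_density`, `dim`, `domain`, `period`, `beta`.
#' @export
target_density <- function(V, grad_V, dim, domain = c("euclidean", "torus"),
                           period = NULL, beta = 1, name = "custom") {
  domain <- match.arg(domain)
  stopifnot(is.function(V), is.function(grad_V))
  if (!is.numeric(dim) || length(dim) != 1L || dim < 1)
    stop("`dim` must be a positive integer")
  if (!is.numeric(beta) || beta <= 0) stop("`beta` must be positive")
  if (domain == "torus") {
    if (is.null(period)) period <- 1
    period <- rep_len(period, dim)
    if (any(period <= 0)) stop("torus period must be positive")
  }
  structure(
    list(
      V = V, grad_V = grad_V,
      log_density = function(x) -beta * V(x),
      grad_log_density = function(x) -beta * grad_V(x),
      dim = as.integer(dim), domain = domain, period = period,
      beta = beta, name = name
    ),
    class = "target_density"
  )
}

#' @export
print.target_density <- function(x, ...) {
  cat(sprintf("<target_density> %s: dim = %d, domain = %s, beta = %g\n",
              x$name, x$dim, x$domain, x$beta))
  invisible(x)
}

#' Standard Gaussian target
#'
#' The standard normal distribution \eqn{\pi(x) \propto e^{-|x|^2/2}} in
#' `dim` dimensions, with `beta = 1`.
#'
#' @param dim dimension (`>= 1`).
#' @return A [target_density()].
#' @export
make_gaussian <- function(dim) {
  if (dim < 1) stop("`dim` must be >= 1")
  target_density(
    V = function(x) sum(x^2) / 2,
    grad_V = function(x) x,
    dim = dim, beta = 1, name = sprintf("gaussian-%dd", dim)
  )
}

#' Warped Gaussian target
#'
#' Two-dimensional target with potential
#' \eqn{V(x) = x_1^2/100 + (x_2 + b x_1^2 - 100 b)^2}: the mass concentrates
#' along the parabola \eqn{x_2 = 100b - b x_1^2}, making reversible samplers
#' slow to traverse the ridge.
#'
#' @param b warp strength (`> 0`, default `0.05`).
#' @return A [target_density()] with `dim = 2`, `beta = 1`.
#' @export
make_warped_gaussian <- function(b = 0.05) {
  if (!is.numeric(b) || b <= 0) stop("`b` must be positive")
  target_density(
    V = function(x) x[1]^2 / 100 + (x[2] + b * x[1]^2 - 100 * b)^2,
    grad_V = function(x) {
      u <- x[2] + b * x[1]^2 - 100 * b
      c(x[1] / 50 + 4 * b * x[1] * u, 2 * u)
    },
    dim = 2, beta = 1, name = sprintf("warped-gaussian(b=%g)", b)
  )
}

#' Periodic two-dimensional target
#'
#' Gibbs distribution on the unit torus with potential
#' \eqn{V(x) = \sin(2\pi x_1)\cos(2\pi x_2)}.
#'
#' @param beta inverse temperature (default 10, i.e. temperature 0.1).
#' @return A [target_density()] on the torus with period 1.
#' @export
make_periodic <- function(beta = 10) {
  if (!is.numeric(beta) || beta <= 0) stop("`beta` must be positive")
  target_density(
    V = function(x) sin(2 * pi * x[1]) * cos(2 * pi * x[2]),
    grad_V = function(x) {
      c(2 * pi * cos(2 * pi * x[1]) * cos(2 * pi * x[2]),
        -2 * pi * sin(2 * pi * x[1]) * sin(2 * pi * x[2]))
    },
    dim = 2, domain = "torus", period = 1, beta = beta,
    name = sprintf("periodic(beta=%g)", beta)
  )
}

#' Parameters of the dimer-in-solvent model
#'
#' A two-dimensional periodic box of side `box_length` containing
#' `n_particles` particles. Particles 1 and 2 form a dimer bound by a
#' double-well potential; all other pairs (solvent-solvent and
#' dimer-solvent) interact through the purely repulsive WCA potential
#' (Lennard-Jones truncated and shifted at its minimum
#' \eqn{r_0 = 2^{1/6}\sigma}).
#'
#' @param n_particles number of particles `N >= 2` (default 16).
#' @param box_length side length `L` of the periodic box. Default `5 * sigma`
#'   (a moderate two-dimensional density for the default N = 16).
#' @param epsilon,sigma WCA energy and length scales (`> 0`).
#' @param h height of the dimer double-well barrier (`> 0`).
#' @param w half-separation of the double-well minima (`> 0`); the compact
#'   state sits at \eqn{r_0} and the stretched state at \eqn{r_0 + 2w}.
#' @param beta inverse temperature.
#' @return An object of class `"dimer_params"`. The cutoff `r0` is always
#'   derived from `sigma`, never stored independently.
#' @export
dimer_params <- function(n_particles = 16, box_length = 5 * sigma,
                         epsilon = 1, sigma = 1, h = 1, w = 0.5, beta = 1) {
  if (n_particles < 2) stop("`n_particles` must be >= 2")
  if (epsilon <= 0 || sigma <= 0 || h <= 0) {
    stop("`epsilon`, `sigma` and `h` must be positive")
  }
  if (!is.numeric(w) || w <= 0) {
    stop("`w` must be strictly positive (w = 0 makes the dimer potential ",
         "and the reaction coordinate singular)")
  }
  if (box_length <= 0) stop("`box_length` must be positive")
  structure(
    list(n_particles = as.integer(n_particles), box_length = box_length,
         epsilon = epsilon, sigma = sigma, h = h, w = w, beta = beta,
         r0 = 2^(1 / 6) * sigma),
    class = "dimer_params"
  )
}

# Minimum-image displacement on a square torus of side L.
min_image <- function(dx, L) dx - L * round(dx / L)

wca_energy <- function(r, epsilon, sigma, r0) {
  ifelse(r <= r0,
         4 * epsilon * ((sigma / r)^12 - (sigma / r)^6) + epsilon,
         0)
}

wca_dudr <- function(r, epsilon, sigma, r0) {
  ifelse(r <= r0,
         4 * epsilon * (-12 * sigma^12 / r^13 + 6 * sigma^6 / r^7),
         0)
}

dimer_well_energy <- function(r, h, w, r0) {
  h * (1 - (r - r0 - w)^2 / w^2)^2
}

dimer_well_dudr <- function(r, h, w, r0) {
  u <- (r - r0 - w) / w
  -4 * h * (1 - u^2) * u / w
}

#' Dimer-in-solvent target
#'
#' Builds the Gibbs target for the dimer model: total energy
#' \deqn{V(q) = V_S(|q_1 - q_2|) + \sum_{3 \le i < j \le N} V_{WCA}(|q_i-q_j|)
#'   + \sum_{i=1,2}\sum_{j \ge 3} V_{WCA}(|q_i-q_j|),}
#' with all distances taken under the minimum-image convention in the
#' periodic box. Configurations are flat vectors
#' \eqn{q = (x_1, y_1, \dots, x_N, y_N)} of length `2N`.
#'
#' Coinciding particles (zero pair distance) raise an error rather than an
#' infinite energy, so samplers can flag divergence deterministically.
#'
#' @param params a [dimer_params()] object.
#' @return A [target_density()] on the `2N`-torus of period `box_length`.
#' @export
make_dimer <- function(params) {
  stopifnot(inherits(params, "dimer_params"))
  N <- params$n_particles
  L <- params$box_length
  eps <- params$epsilon; sig <- params$sigma
  h <- params$h; w <- params$w; r0 <- params$r0

  pair_terms <- function(q) {
    xy <- matrix(q, ncol = 2, byrow = TRUE)   # N x 2
    dx <- min_image(outer(xy[, 1], xy[, 1], "-"), L)
    dy <- min_image(outer(xy[, 2], xy[, 2], "-"), L)
    r <- sqrt(dx^2 + dy^2)
    list(xy = xy, dx = dx, dy = dy, r = r)
  }

  wca_pair_mask <- function() {
    # TRUE for (i, j), i < j, interacting through the WCA potential:
    # all pairs except the dimer pair (1, 2).
    m <- upper.tri(matrix(TRUE, N, N))
    m[1, 2] <- FALSE
    m
  }
  mask <- wca_pair_mask()

  V <- function(q) {
    p <- pair_terms(q)
    r12 <- p$r[1, 2]
    if (r12 == 0 || any(p$r[mask] == 0)) {
      stop("overlapping particles (r = 0) in dimer configuration")
    }
    dimer_well_energy(r12, h, w, r0) +
      sum(wca_energy(p$r[mask], eps, sig, r0))
  }

  grad_V <- function(q) {
    p <- pair_terms(q)
    r <- p$r
    r12 <- r[1, 2]
    if (r12 == 0 || any(r[mask] == 0)) {
      stop("overlapping particles (r = 0) in dimer configuration")
    }
    # dV/dr / r for every ordered pair; zero on the diagonal.
    fac <- matrix(0, N, N)
    act <- mask & (r <= r0)
    fac[act] <- wca_dudr(r[act], eps, sig, r0) / r[act]
    fac <- fac + t(fac)
    fs <- dimer_well_dudr(r12, h, w, r0) / r12
    fac[1, 2] <- fac[1, 2] + fs
    fac[2, 1] <- fac[2, 1] + fs
    # grad on particle i: sum_j fac[i,j] * (q_i - q_j) (minimum image)
    gx <- rowSums(fac * p$dx)
    gy <- rowSums(fac * p$dy)
    as.vector(t(cbind(gx, gy)))
  }

  target_density(
    V = V, grad_V = grad_V, dim = 2L * N, domain = "torus", period = L,
    beta = params$beta, name = sprintf("dimer(N=%d)", N)
  )
}

#' Dimer reaction coordinate
#'
#' \eqn{\xi(q) = (|q_1 - q_2| - r_0) / (2w)} with the minimum-image distance:
#' 0 in the compact state, 1 in the stretched state.
#'
#' @param q configuration vector of length `2N`.
#' @param params a [dimer_params()] object (must have `w > 0`).
#' @return Scalar reaction-coordinate value.
#' @export
reaction_coordinate <- function(q, params) {
  stopifnot(inherits(params, "dimer_params"))
  d <- min_image(q[1:2] - q[3:4], params$box_length)
  (sqrt(sum(d^2)) - params$r0) / (2 * params$w)
}

#' Define an observable
#'
#' @param name label.
#' @param fn function mapping a point to a real value.
#' @param known_mean optional analytically known value of \eqn{\pi(f)}.
#' @return An object of class `"observable"`.
#' @export
make_observable <- function(name, fn, known_mean = NULL) {
  stopifnot(is.function(fn))
  structure(list(name = name, eval = fn, known_mean = known_mean),
            class = "observable")
}

#' Quadratic observable
#'
#' \eqn{f(x) = x \cdot Mx + l \cdot x + k} for a symmetric matrix `M`.
#' When `k` is omitted it is set to \eqn{-\mathrm{Tr}\,M}, which centres the
#' observable with respect to a standard Gaussian target
#' (\eqn{E[x \cdot Mx] = \mathrm{Tr}\,M}).
#'
#' @param M symmetric matrix.
#' @param l linear coefficient vector (default zero).
#' @param k constant offset; default `-sum(diag(M))` (auto-centering).
#' @param name label.
#' @param known_mean optional known mean; defaults to 0 when `k` is
#'   auto-centred (exact under the standard Gaussian).
#' @return An [make_observable()] object.
#' @export
make_observable_quadratic <- function(M, l = NULL, k = NULL,
                                      name = "quadratic", known_mean = NULL) {
  M <- as.matrix(M)
  if (max(abs(M - t(M))) > 1e-12 * max(1, max(abs(M)))) {
    stop("`M` must be symmetric")
  }
  d <- nrow(M)
  if (is.null(l)) l <- numeric(d)
  stopifnot(length(l) == d)
  auto <- is.null(k)
  if (auto) k <- -sum(diag(M))
  if (is.null(known_mean) && auto) known_mean <- 0
  make_observable(
    name = name,
    fn = function(x) sum(x * (M %*% x)) + sum(l * x) + k,
    known_mean = known_mean
  )
}

# Central finite-difference gradient, used by the validation helpers and
# by tests as an independent oracle.
fd_gradient <- function(f, x, h = 1e-5) {
  d <- length(x)
  vapply(seq_len(d), function(i) {
    e <- numeric(d); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' Verify a target's gradient by finite differences
#'
#' Compares `grad_log_density` against a central finite difference of
#' `log_density` at the supplied points.
#'
#' @param target a [target_density()].
#' @param points list of points (or a matrix with one point per row).
#' @param h finite-difference step.
#' @return Maximum absolute error over all points and components.
#' @export
check_gradient <- function(target, points, h = 1e-5) {
  if (is.matrix(points)) points <- asplit(points, 1)
  errs <- vapply(points, function(x) {
    max(abs(target$grad_log_density(x) - fd_gradient(target$log_density, x, h)))
  }, numeric(1))
  max(errs)
}
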