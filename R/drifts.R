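#' @keywords internal
check_antisymmetric <- function(J, label = "J") {
  J <- as.matrix(J)
  s <- max(1, max(abs(J)))
  if (max(abs(J + t(J))) > 1e-10 * s) {
    stop(sprintf("`%s` must be antisymmetric (J = -t(J))", label))
  }
  J
}

new_perturbation_field <- function(gamma, construction, dim, J = NULL,
                                   psi = NULL) {
  structure(list(gamma = gamma, construction = construction,
                 dim = as.integer(dim), J = J, psi = psi),
            class = "perturbation_field")
}

#' @export
print.perturbation_field <- function(x, ...) {
  cat(sprintf("<perturbation_field> construction = %s, dim = %d\n",
              x$construction, x$dim))
  invisible(x)
}

#' Divergence-free drift from a constant antisymmetric matrix
#'
#' Builds the perturbation field \eqn{\gamma(x) = J \nabla \log \pi(x)}
#' for an antisymmetric matrix `J`; the antisymmetry makes
#' \eqn{\nabla \cdot (\gamma \pi) = 0}, so the perturbed dynamics keep
#' \eqn{\pi} invariant while breaking detailed balance.
#'
#' With `beta_free = TRUE` the field is built from the bare potential,
#' \eqn{\gamma(x) = -J \nabla V(x)}, so that the assembled drift of the
#' sampler is \eqn{-(\beta I + \alpha J)\nabla V}. The two conventions agree
#' for `beta = 1` targets and differ only by a rescaling of the strength
#' \eqn{\alpha} by \eqn{\beta} otherwise.
#'
#' @param J antisymmetric matrix of the target's dimension.
#' @param target a [target_density()].
#' @param beta_free build the field from \eqn{-\nabla V} instead of
#'   \eqn{\nabla\log\pi}.
#' @return A perturbation field.
#' @export
constant_J_drift <- function(J, target, beta_free = FALSE) {
  J <- check_antisymmetric(J)
  stopifnot(inherits(target, "target_density"), nrow(J) == target$dim)
  gamma <- if (beta_free) {
    function(x) as.vector(J %*% (-target$grad_V(x)))
  } else {
    function(x) as.vector(J %*% target$grad_log_density(x))
  }
  new_perturbation_field(gamma, "constant_J", target$dim, J = J)
}

#' Smoothed (bounded) divergence-free drift
#'
#' \eqn{\gamma(x) = J \nabla V(x)\, \psi(V(x))} for a smooth scalar function
#' \eqn{\psi}. When \eqn{\psi} is compactly supported and
#' \eqn{\psi(V)|\nabla V| \le 1} the field is bounded, and it remains
#' divergence-free with respect to \eqn{\pi} for any smooth \eqn{\psi}
#' because \eqn{\nabla V \cdot J \nabla V = 0}. The flow of \eqn{\gamma}
#' conserves `V`.
#'
#' @param J antisymmetric matrix.
#' @param target a [target_density()].
#' @param psi smooth scalar function of the potential value.
#' @return A perturbation field.
#' @export
smoothed_drift <- function(J, target, psi) {
  J <- check_antisymmetric(J)
  stopifnot(inherits(target, "target_density"), is.function(psi),
            nrow(J) == target$dim)
  gamma <- function(x) {
    as.vector(J %*% target$grad_V(x)) * psi(target$V(x))
  }
  new_perturbation_field(gamma, "smoothed", target$dim, J = J, psi = psi)
}

#' Divergence-free drift from a skew-symmetric matrix field
#'
#' \eqn{\gamma(x) = -J(x)\nabla V(x) + (\nabla \cdot J)(x)}, where
#' \eqn{(\nabla\cdot J)_i = \sum_j \partial_j J_{ij}}. For constant `J(x)`
#' the divergence term vanishes and the construction reduces to
#' [constant_J_drift()] in its `beta_free` convention.
#'
#' @param J_of_x function mapping a point to a skew-symmetric matrix.
#' @param target a [target_density()].
#' @param div_J optional function returning \eqn{\nabla\cdot J} at a point;
#'   when omitted it is computed by central finite differences.
#' @param h finite-difference step for the default divergence.
#' @return A perturbation field.
#' @export
matrix_field_drift <- function(J_of_x, target, div_J = NULL, h = 1e-6) {
  stopifnot(inherits(target, "target_density"), is.function(J_of_x))
  d <- target$dim
  check_antisymmetric(J_of_x(numeric(d)), "J(x)")
  if (is.null(div_J)) {
    div_J <- function(x) {
      vapply(seq_len(d), function(i) {
        sum(vapply(seq_len(d), function(j) {
          e <- numeric(d); e[j] <- h
          (J_of_x(x + e)[i, j] - J_of_x(x - e)[i, j]) / (2 * h)
        }, numeric(1)))
      }, numeric(1))
    }
  }
  gamma <- function(x) {
    as.vector(-J_of_x(x) %*% target$grad_V(x)) + div_J(x)
  }
  new_perturbation_field(gamma, "matrix_field", d)
}

#' Numerical check that a field is divergence-free with respect to the target
#'
#' Evaluates the residual \eqn{|\nabla\cdot(\gamma\pi)|/\pi =
#' |\nabla\cdot\gamma + \gamma\cdot\nabla\log\pi|} by central finite
#' differences at the supplied points.
#'
#' @param field a perturbation field.
#' @param target a [target_density()].
#' @param points list of points (or matrix, one point per row).
#' @param h finite-difference step (`> 0`).
#' @return A list with `max`, `mean` and the vector of `residuals`.
#' @export
divergence_check <- function(field, target, points, h = 1e-4) {
  stopifnot(inherits(field, "perturbation_field"),
            inherits(target, "target_density"))
  if (h <= 0) stop("`h` must be positive")
  if (is.matrix(points)) points <- asplit(points, 1)
  d <- target$dim
  res <- vapply(points, function(x) {
    div_gamma <- sum(vapply(seq_len(d), function(i) {
      e <- numeric(d); e[i] <- h
      (field$gamma(x + e)[i] - field$gamma(x - e)[i]) / (2 * h)
    }, numeric(1)))
    abs(div_gamma + sum(field$gamma(x) * target$grad_log_density(x)))
  }, numeric(1))
  list(max = max(res), mean = mean(res), residuals = res)
}

#' Optimal antisymmetric matrix for a linear observable
#'
#' For \eqn{f(x) = l\cdot x} under a standard-Gaussian (linear-drift) target,
#' the asymptotic variance \eqn{2 l\cdot(I+\alpha^2 J^\top J)^{-1} l} decays
#' fastest when `l` is an eigenvector of \eqn{J^\top J} with maximal
#' eigenvalue. That is achieved by the unit-Frobenius rank-2 matrix
#' \deqn{J = (\tilde l \otimes \omega - \omega \otimes \tilde l)/\sqrt 2,
#'   \qquad \tilde l = l/|l|,}
#' for any unit vector \eqn{\omega \perp l}; then \eqn{J^\top J} is half the
#' projector onto \eqn{\mathrm{span}\{l, \omega\}}.
#'
#' @param l nonzero coefficient vector (`length >= 2`).
#' @param omega optional unit vector orthogonal to `l`. The default is
#'   deterministic: the first canonical basis vector not parallel to `l`,
#'   Gram-Schmidt orthogonalised against it (no randomness, so results are
#'   reproducible).
#' @return An antisymmetric matrix with unit Frobenius norm.
#' @export
optimal_linear_J <- function(l, omega = NULL) {
  l <- as.numeric(l)
  if (all(l == 0)) stop("`l` must be nonzero")
  if (length(l) < 2) stop("`l` must have length >= 2")
  lt <- l / sqrt(sum(l^2))
  if (is.null(omega)) {
    i <- which.min(abs(lt))      # basis vector least aligned with l
    e <- numeric(length(l)); e[i] <- 1
    omega <- e - sum(e * lt) * lt
    omega <- omega / sqrt(sum(omega^2))
  } else {
    omega <- as.numeric(omega)
    if (abs(sqrt(sum(omega^2)) - 1) > 1e-8) stop("`omega` must be a unit vector")
    if (abs(sum(omega * lt)) > 1e-8) stop("`omega` must be orthogonal to `l`")
  }
  (outer(lt, omega) - outer(omega, lt)) / sqrt(2)
}

#' Eigen-pairing antisymmetric matrix for a quadratic observable
#'
#' For \eqn{f(x) = x\cdot Mx - \mathrm{Tr} M} the large-strength limit of the
#' asymptotic variance under a rotation built from pairs of eigenvectors of
#' `M` is minimised by pairing the k-th smallest eigenvalue with the k-th
#' largest. This constructs
#' \deqn{J = \sum_k e_{i_k}\otimes e_{j_k} - e_{j_k}\otimes e_{i_k},
#'   \quad i_k = k,\ j_k = d-k+1,}
#' with eigenvalues sorted ascending. For odd `d` the middle eigenvector is
#' left unpaired (it receives no perturbation). Eigenvector sign ambiguity is
#' resolved by making each eigenvector's first nonzero component positive,
#' so the result is deterministic.
#'
#' @param M symmetric matrix.
#' @param normalize rescale to unit Frobenius norm (the unnormalised matrix
#'   has \eqn{\|J\|_F = \sqrt{2\lfloor d/2\rfloor}}); strength rescaling of
#'   \eqn{\alpha} makes the two equivalent in the large-\eqn{\alpha} limit.
#' @return An antisymmetric `d x d` matrix.
#' @export
pairing_J <- function(M, normalize = FALSE) {
  M <- as.matrix(M)
  if (max(abs(M - t(M))) > 1e-10 * max(1, max(abs(M)))) {
    stop("`M` must be symmetric")
  }
  d <- nrow(M)
  es <- eigen(M, symmetric = TRUE)
  ord <- order(es$values)                    # ascending
  vecs <- es$vectors[, ord, drop = FALSE]
  for (k in seq_len(d)) {
    v <- vecs[, k]
    i <- which(abs(v) > 1e-8)[1]
    if (v[i] < 0) vecs[, k] <- -v
  }
  J <- matrix(0, d, d)
  for (k in seq_len(d %/% 2)) {
    ei <- vecs[, k]; ej <- vecs[, d - k + 1]
    J <- J + outer(ei, ej) - outer(ej, ei)
  }
  if (normalize) J <- J / sqrt(sum(J^2))
  J
}

#' Antisymmetric matrices for the dimer model
#'
#' Two ready-made `2N x 2N` antisymmetric matrices:
#' * `"block_circulant"`: block-circulant with \eqn{I_2} on the block
#'   superdiagonal, \eqn{-I_2} on the block subdiagonal and wrap-around
#'   blocks \eqn{-I_2} (top-right) and \eqn{I_2} (bottom-left) — couples
#'   every particle to its neighbours in index order.
#' * `"corner_rotation"`: zero except for a 4x4 rotation-like block `R`
#'   (with \eqn{R^2 = -I_4}) acting on the four coordinates of the two dimer
#'   particles only; the solvent drift is untouched.
#'
#' @param n_particles number of particles `N >= 2`.
#' @param kind `"block_circulant"` or `"corner_rotation"`.
#' @return An antisymmetric `2N x 2N` matrix.
#' @export
dimer_J <- function(n_particles, kind = c("block_circulant", "corner_rotation")) {
  kind <- match.arg(kind)
  N <- as.integer(n_particles)
  if (N < 2) stop("`n_particles` must be >= 2")
  d <- 2L * N
  J <- matrix(0, d, d)
  if (kind == "block_circulant") {
    I2 <- diag(2)
    blk <- function(i, j) (2 * (i - 1) + 1):(2 * i) # rows of block i
    for (i in seq_len(N)) {
      j <- if (i == N) 1L else i + 1L
      J[blk(i), blk(j)] <- J[blk(i), blk(j)] + I2
      J[blk(j), blk(i)] <- J[blk(j), blk(i)] - I2
    }
  } else {
    R <- rbind(c(0, 0, 1, 0),
               c(0, 0, 0, 1),
               c(-1, 0, 0, 0),
               c(0, -1, 0, 0))
    J[1:4, 1:4] <- R
  }
  J
}
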