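# Shared fixtures and independent oracles, all built in code.

# Planar rotation generator: with gamma = J grad log pi = -J x this gives the
# flow (x2, -x1) on the standard 2-D Gaussian.
J_rot <- rbind(c(0, -1), c(1, 0))

# 3x3 antisymmetric matrix with kernel span{(1, -1, 1)}.
J_3 <- rbind(c(0, 1, 1), c(-1, 0, 1), c(-1, -1, 0)) / sqrt(6)

# 4x4 two-block symmetric matrix with eigenvalues 1, 2, 3, 4.
M_1 <- rbind(c(3 / 2, -1 / 2, 0, 0),
             c(-1 / 2, 3 / 2, 0, 0),
             c(0, 0, 7 / 2, -1 / 2),
             c(0, 0, -1 / 2, 7 / 2))

# Closed form for the planar-rotation model with f = 2 x1^2.
sigma2_closed_form <- function(alpha) 4 * (1 + 1 / (1 + alpha^2))

# Independent central-difference gradient oracle (kept separate from the
# package's own checker).
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Random antisymmetric matrix.
random_antisym <- function(d) {
  A <- matrix(rnorm(d * d), d, d)
  (A - t(A)) / 2
}

# Random symmetric matrix.
random_sym <- function(d) {
  A <- matrix(rnorm(d * d), d, d)
  (A + t(A)) / 2
}

# Matrix exponential by scaling-and-squaring on the series (oracle use only;
# small matrices, modest accuracy requirements).
mat_exp <- function(A, scale_pow = 20) {
  d <- nrow(A)
  B <- A / 2^scale_pow
  X <- diag(d); term <- diag(d)
  for (k in 1:18) {
    term <- term %*% B / k
    X <- X + term
  }
  for (i in seq_len(scale_pow)) X <- X %*% X
  X
}

# Quadrature oracle for the quadratic-term integral
# 2 int_0^inf e^{-2s} Tr[e^{aJs} M e^{-aJs} M'] ds  (rotation-form quadratic).
quad_term_quadrature <- function(J, M, alpha, upper = 40, n = 4000) {
  s <- seq(0, upper, length.out = n + 1)
  f <- vapply(s, function(si) {
    E <- mat_exp(alpha * J * si)
    exp(-2 * si) * sum(diag(E %*% M %*% t(E) %*% t(M)))
  }, numeric(1))
  h <- upper / n
  2 * h * (sum(f) - (f[1] + f[n + 1]) / 2)
}
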