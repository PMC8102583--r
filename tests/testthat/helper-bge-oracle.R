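# Numerical-integration oracles for the BGe marginal likelihood, independent
# of the closed-form implementation: the mean is integrated analytically, the
# precision (1-D) or its Cholesky factor (2-D) numerically.

# log marginal of a single column: one-dimensional integral over the
# precision w ~ Gamma(dof/2, t_scale/2).
bge_oracle_1d <- function(x, hyper) {
  n <- length(x)
  am <- hyper$alpha_mu
  dof <- hyper$alpha_w - hyper$d + 1
  tsc <- hyper$t_scale
  q <- sum(x^2) - sum(x)^2 / (am + n)
  logf <- function(w) {
    stats::dgamma(w, shape = dof / 2, rate = tsc / 2, log = TRUE) +
      (-n / 2) * log(2 * pi) + (n / 2) * log(w) -
      0.5 * log(1 + n / am) - 0.5 * w * q
  }
  ws <- seq(0.001, 50, length.out = 400)
  mx <- max(logf(ws))
  v <- stats::integrate(function(w) exp(logf(w) - mx), 0, Inf,
                        rel.tol = 1e-12)$value
  mx + log(v)
}

# log marginal of a two-column matrix: three nested integrals over the
# Cholesky factor of the 2x2 precision matrix W.
bge_oracle_2d <- function(X, hyper) {
  n <- nrow(X)
  am <- hyper$alpha_mu
  dof <- hyper$alpha_w - hyper$d + 2
  tsc <- hyper$t_scale
  xbar <- colMeans(X)
  C <- crossprod(sweep(X, 2, xbar)) + (n * am / (n + am)) * tcrossprod(xbar)
  logpost <- function(l11, l21, l22) {
    L <- matrix(c(l11, l21, 0, l22), 2, 2)
    W <- L %*% t(L)
    ((dof - 3) / 2) * log(det(W)) - 0.5 * tsc * sum(diag(W)) +
      dof * log(tsc) - dof * log(2) -
      chemoswitch:::cs_lmvgamma(dof / 2, 2) -
      n * log(2 * pi) + (n / 2) * log(det(W)) + log(am / (am + n)) -
      0.5 * sum(W * C) +
      2 * log(2) + 2 * log(l11) + log(l22)  # Jacobian dW -> dL
  }
  best <- -Inf
  for (a in seq(0.1, 6, by = 0.25)) {
    for (b in seq(-3, 3, by = 0.25)) {
      for (cc in seq(0.1, 6, by = 0.25)) {
        v <- logpost(a, b, cc)
        if (v > best) best <- v
      }
    }
  }
  f <- function(l11v) {
    vapply(l11v, function(a) {
      stats::integrate(function(l21v) {
        vapply(l21v, function(b) {
          stats::integrate(function(l22v)
            vapply(l22v, function(cc) exp(logpost(a, b, cc) - best),
                   numeric(1)),
            1e-8, 30, rel.tol = 1e-9)$value
        }, numeric(1))
      }, -30, 30, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  v <- stats::integrate(f, 1e-8, 30, rel.tol = 1e-9)$value
  best + log(v)
}
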