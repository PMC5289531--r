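# Independent oracles and small data builders shared across test files.
# Every oracle is written from the textbook definition, not from the package
# code paths it checks.

# textbook normal-equation OLS (no intercept)
ols_oracle <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# Single-response PLS via its Krylov-subspace characterisation: the h-component
# coefficient vector is the least-squares solution constrained to
# span{X'y, (X'X) X'y, ..., (X'X)^{h-1} X'y} (orthonormalized for stability).
pls_krylov_oracle <- function(X, y, h) {
  G <- crossprod(X)
  b <- drop(crossprod(X, y))
  K <- matrix(0, ncol(X), h)
  v <- b
  for (l in seq_len(h)) {
    K[, l] <- v
    v <- drop(G %*% v)
  }
  Q <- qr.Q(qr(K))
  drop(Q %*% solve(crossprod(Q, G %*% Q), crossprod(Q, b)))
}

# Closed-form elastic net for an orthonormal design X'X = I, from the
# objective ||y - Xb||^2 + l1 |b| + l2 b^2: coordinate-wise
# soft(X'y, l1/2) / (1 + l2), then the (1 + l2/n) rescale.
enet_ortho_oracle <- function(X, y, l1, l2) {
  z <- drop(crossprod(X, y))
  naive <- sign(z) * pmax(abs(z) - l1 / 2, 0) / (1 + l2)
  (1 + l2 / nrow(X)) * naive
}

# random matrix with exactly orthonormal columns (p <= n)
rand_orthonormal <- function(n, p, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * p), n, p)))[, seq_len(p), drop = FALSE]
}

# quick random spectra dataset (unstructured, for mechanics tests)
rand_spectra <- function(n, p, seed, sigma = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, sd = sigma)
  spectra(X, y)
}
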