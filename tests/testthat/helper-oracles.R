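# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks.

# --- explicit Clifford representation of the link-field algebra ----------
# Jordan-Wigner construction: for m anticommuting generators use
# q = ceiling(m / 2) qubits; generator 2j-1 = Z^(j-1) (x) X (x) I...,
# generator 2j = Z^(j-1) (x) Y (x) I... . Each squares to the identity and
# distinct ones anticommute, so (1/d) Tr of a product is an exact oracle for
# the symbolic trace reduction.
pauli_x <- matrix(c(0, 1, 1, 0), 2, 2)
pauli_y <- matrix(c(0, 1i, -1i, 0), 2, 2)
pauli_z <- matrix(c(1, 0, 0, -1), 2, 2)

clifford_generators <- function(m) {
  q <- max(1L, ceiling(m / 2))
  lapply(seq_len(m), function(a) {
    j <- (a + 1L) %/% 2L               # which qubit carries X/Y
    op <- if (a %% 2 == 1L) pauli_x else pauli_y
    g <- matrix(1 + 0i, 1, 1)
    for (k in seq_len(q)) {
      factor <- if (k < j) pauli_z else if (k == j) op else diag(2)
      g <- kronecker(g, factor)
    }
    g
  })
}

# (1/d) Tr of an ordered product of link fields, by brute matrix multiply
clifford_trace <- function(links) {
  if (nrow(links) == 0) return(1)
  keys <- paste(links[, 1], links[, 2])
  gen_of <- match(keys, unique(keys))
  gens <- clifford_generators(length(unique(keys)))
  d <- nrow(gens[[1]])
  acc <- diag(d) + 0i
  for (g in gen_of) acc <- acc %*% gens[[g]]
  val <- sum(diag(acc)) / d
  stopifnot(abs(Im(val)) < 1e-10)
  Re(val)
}

# --- determinant of a complex matrix (base det() is real-only) -----------
det_complex <- function(m) prod(eigen(m, only.values = TRUE)$values)

# --- random skew-symmetric matrix ----------------------------------------
random_skew <- function(n) {
  a <- matrix(stats::rnorm(n * n), n, n)
  a - t(a)
}

# --- Catalan's constant by its alternating series ------------------------
# G = sum_{k>=0} (-1)^k / (2k+1)^2; truncation error below 1e-13 at 2e6 terms
catalan_constant <- local({
  k <- 0:2000000
  sum((-1)^k / (2 * k + 1)^2)
})

# --- Gauss-Legendre product quadrature of the raw 2D integral ------------
# Direct two-dimensional quadrature of
# (1/(4 pi^2)) int int ln[x^2 (1+cos t) + y^2 (1+cos s)] dt ds + (1/4) ln 2,
# independent of the closed-form inner integral used by the implementation.
ln_z_site_2d_quadrature <- function(x, y, n_nodes = 400) {
  gl <- pracma::gaussLegendre(n_nodes, 0, pi)
  vals <- outer(gl$x, gl$x, function(t, s) {
    log(x^2 * (1 + cos(t)) + y^2 * (1 + cos(s)))
  })
  log(2) / 4 + as.numeric(t(gl$w) %*% vals %*% gl$w) / (4 * pi^2)
}
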