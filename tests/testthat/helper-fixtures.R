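# in-code fixtures shared across test files

# strictly positive row-stochastic matrix (irreducible, aperiodic)
rand_stochastic <- function(n) {
  M <- matrix(-log(runif(n * n)), n, n)
  M / rowSums(M)
}

# strictly positive rate set on an n-cycle
rand_rates <- function(n, lo = 0.1, hi = 5) {
  rate_set(runif(n, lo, hi), runif(n, lo, hi))
}

# independent oracle: exact stationary distribution by linear solve of
# pi (P - I) = 0, sum(pi) = 1
stationary_solve <- function(P) {
  M <- unclass(as.matrix(P))
  n <- nrow(M)
  as.numeric(qr.solve(rbind(t(M) - diag(n), rep(1, n)), c(rep(0, n), 1)))
}

expect_prob_vector <- function(p, tol = 1e-12) {
  expect_true(all(p >= -tol))
  expect_equal(sum(p), 1, tolerance = tol)
}
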