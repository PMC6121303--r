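test_that("transition-matrix validation reports row stochasticity", {
  v <- validate_transition_matrix(diag(4))
  expect_true(v$pass)
  expect_equal(nrow(v$report), 4)

  bad <- diag(4)
  bad[2, 2] <- 0.9
  v <- validate_transition_matrix(bad)
  expect_false(v$pass)
  expect_equal(which(!v$report$ok), 2L)

  expect_error(validate_transition_matrix(matrix(1, 2, 3)),
               class = "pumploop_structural_error")
  neg <- matrix(c(1.2, -0.2, 0, 1), 2, byrow = TRUE)
  expect_false(validate_transition_matrix(neg)$pass)
})

test_that("state spaces require unique non-empty labels", {
  expect_error(state_space(c("E1", "E1")), class = "pumploop_structural_error")
  expect_error(state_space(character()), class = "pumploop_structural_error")
  expect_equal(post_albers_states(), c("E1", "E1P", "E2P", "E2"))
})

test_that("one-step evolution conserves probability and fixes invariants", {
  P <- default_post_albers_matrix()
  d <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(sum(step_distribution(d, P)), 1, tolerance = 1e-12)

  expect_equal(unname(step_distribution(d, transition_matrix(diag(4)))), d)

  swap <- transition_matrix(matrix(c(0, 1, 1, 0), 2), states = c("A", "B"))
  expect_equal(unname(step_distribution(c(1, 0), swap)), c(0, 1))

  # uniform is invariant under any doubly stochastic map
  ds <- matrix(c(0.2, 0.3, 0.5,
                 0.5, 0.2, 0.3,
                 0.3, 0.5, 0.2), 3, byrow = TRUE)
  expect_equal(unname(step_distribution(rep(1 / 3, 3), transition_matrix(ds))),
               rep(1 / 3, 3), tolerance = 1e-14)

  expect_error(step_distribution(c(0.5, 0.5), P),
               class = "pumploop_structural_error")
})

test_that("power-iteration stationary distribution matches the exact solve", {
  expect_equal(stationary_distribution(transition_matrix(matrix(0.5, 2, 2)))$pi,
               c(0.5, 0.5), tolerance = 1e-12)

  # circulant rows are doubly stochastic: uniform stationary law
  r <- c(0.1, 0.6, 0.2, 0.1)
  circ <- t(sapply(0:3, function(k) r[(seq_len(4) - 1 - k) %% 4 + 1]))
  expect_equal(stationary_distribution(transition_matrix(circ))$pi,
               rep(0.25, 4), tolerance = 1e-10)

  P <- default_post_albers_matrix()
  pi <- stationary_distribution(P, tol = 1e-12)
  expect_equal(pi$pi, stationary_solve(P), tolerance = 1e-10)
  expect_prob_vector(pi$pi)
  # stationarity: one more step leaves pi unchanged
  expect_equal(unname(step_distribution(pi$pi, P)), pi$pi, tolerance = 1e-10)

  withr::with_seed(42, {
    for (i in 1:20) {
      M <- transition_matrix(rand_stochastic(sample(2:7, 1)))
      expect_equal(stationary_distribution(M, tol = 1e-12)$pi,
                   stationary_solve(M), tolerance = 1e-10)
    }
  })
})

test_that("periodic and reducible chains are handled explicitly", {
  # deterministic 4-cycle is periodic; damping still finds the uniform law
  cyc <- transition_matrix(diag(4)[c(2, 3, 4, 1), ])
  expect_equal(stationary_distribution(cyc)$pi, rep(0.25, 4), tolerance = 1e-10)

  two_blocks <- as.matrix(Matrix::bdiag(matrix(0.5, 2, 2), matrix(0.5, 2, 2)))
  expect_error(stationary_distribution(two_blocks),
               class = "pumploop_validation_error")
})

test_that("hidden-state expansion conserves path probability", {
  P <- default_post_albers_matrix()
  expect_identical(expand_hidden_states(P, NULL), P)
  expect_identical(expand_hidden_states(P, data.frame()), P)

  plan <- data.frame(from = "E1", to = "E1P", hidden = "E1.Na", dwell = 0)
  E <- expand_hidden_states(P, plan)
  expect_true(validate_transition_matrix(E)$pass)
  expect_equal(dim(as.matrix(E)), c(5, 5))
  # interleaved right after its source, and hop probabilities multiply back
  expect_equal(rownames(as.matrix(E))[2], "E1.Na")
  expect_equal(E["E1", "E1.Na"] * E["E1.Na", "E1P"], P["E1", "E1P"])
  expect_equal(E["E1", "E1P"], 0)

  # with zero hidden dwell, the renormalized visible occupancy is unchanged
  pi0 <- stationary_distribution(P, tol = 1e-12)
  piE <- marginalize_hidden(stationary_distribution(E, tol = 1e-12),
                            hidden = "E1.Na")
  expect_equal(piE$pi, pi0$pi, tolerance = 1e-9)

  # expanding every edge of a full plan keeps the matrix stochastic (8 states)
  plan8 <- data.frame(from = c("E1", "E1P", "E2P", "E2"),
                      to = c("E1P", "E2P", "E2", "E1"),
                      hidden = paste0("H", 1:4),
                      dwell = c(0, 0.2, 0.5, 0))
  E8 <- expand_hidden_states(P, plan8)
  expect_equal(dim(as.matrix(E8)), c(8, 8))
  expect_true(validate_transition_matrix(E8)$pass)

  zero_edge <- data.frame(from = "E1", to = "E2P", hidden = "Z", dwell = 0)
  P0 <- transition_matrix(matrix(c(0.5, 0.5, 0, 0,
                                   0, 0.5, 0.5, 0,
                                   0, 0, 0.5, 0.5,
                                   0.5, 0, 0, 0.5), 4, byrow = TRUE))
  expect_error(expand_hidden_states(P0, zero_edge),
               class = "pumploop_validation_error")
})

test_that("seeded path sampling is reproducible and converges to pi", {
  P <- default_post_albers_matrix()
  expect_error(simulate_chain(P, 0), class = "pumploop_argument_error")

  idp <- simulate_chain(transition_matrix(diag(4)), 10, seed = 7)
  expect_true(all(idp$state == "E1"))

  cyc <- transition_matrix(diag(4)[c(2, 3, 4, 1), ])
  path <- simulate_chain(cyc, 7, seed = 3)
  expect_equal(as.character(path$state),
               c("E1", "E1P", "E2P", "E2")[(0:7) %% 4 + 1])

  expect_identical(simulate_chain(P, 500, seed = 11),
                   simulate_chain(P, 500, seed = 11))

  n <- 1e5
  occ <- occupancy(simulate_chain(P, n, seed = 2024))
  pi <- stationary_distribution(P)
  se <- sqrt(pi$pi * (1 - pi$pi) / n)
  # autocorrelation inflates the naive binomial error; 3 SE with headroom
  expect_true(all(abs(occ$freq - pi$pi) < 3 * se + 5 / n))
})

test_that("transition matrices round-trip through CSV exactly", {
  P <- transition_matrix(rand_stochastic(5) * 1)  # arbitrary doubles
  f <- withr::local_tempfile(fileext = ".csv")
  write_transition_matrix(P, f)
  P2 <- read_transition_matrix(f)
  expect_identical(unclass(as.matrix(P2)), unclass(as.matrix(P)))
})
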