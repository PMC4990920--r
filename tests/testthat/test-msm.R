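test_that("transition counting matches direct enumeration", {
  expect_equal(count_transitions(c(1L, 1L, 2L, 2L, 1L), lag = 1)$counts,
               matrix(c(1, 1, 1, 1), 2, byrow = TRUE), ignore_attr = TRUE)
  ## lag-2 pairs are (t1, t3) and (t2, t4); the two self-loop states are
  ## mutually unreachable, so the full counts are diagonal and trimming
  ## retains a single state
  cm22 <- count_transitions(c(1L, 2L, 1L, 2L), lag = 2)
  expect_equal(cm22$counts_full, diag(c(1, 1)), ignore_attr = TRUE)
  expect_identical(cm22$n_states, 1L)
  ## brute-force pair-counting oracle on random streams, both modes
  set.seed(44)
  for (rep in 1:5) {
    s <- sample(1:4, 60, replace = TRUE)
    for (lag in c(1, 3)) {
      for (mode in c("sliding", "strided")) {
        starts <- if (mode == "sliding") 1:(60 - lag)
                  else seq(1, 60 - lag, by = lag)
        brute <- matrix(0, 4, 4)
        for (t in starts) brute[s[t], s[t + lag]] <- brute[s[t], s[t + lag]] + 1
        cm <- count_transitions(s, lag = lag, mode = mode, n_states = 4)
        keep <- cm$ergodic_subset
        expect_equal(cm$counts, brute[keep, keep], ignore_attr = TRUE)
      }
    }
  }
  expect_error(count_transitions(c(1L, 2L), lag = 5), "lag 5")
})

test_that("ergodic trimming keeps the largest strongly connected component", {
  ## state 3 is a one-way sink from which data never return
  s <- c(1L, 2L, 1L, 2L, 1L, 2L, 3L, 3L)
  cm <- count_transitions(s, lag = 1)
  expect_identical(cm$ergodic_subset, 1:2)
  expect_identical(cm$dropped, 3L)
})

test_that("nonreversible MLE is row normalization with a valid spectrum", {
  C <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)
  m <- estimate_nonreversible(C)
  expect_equal(m$T, matrix(c(0.8, 0.2, 0.1, 0.9), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(m$eigenvalues, c(1, 0.7))
  m1 <- estimate_nonreversible(matrix(5, 1, 1))
  expect_equal(m1$T, matrix(1, 1, 1), ignore_attr = TRUE)
  set.seed(10)
  C <- matrix(rpois(25, 6) + 1, 5)
  ## asymmetric counts can have complex eigenvalue pairs; they are flagged
  m <- suppressWarnings(estimate_nonreversible(C))
  expect_equal(unname(rowSums(m$T)), rep(1, 5), tolerance = 1e-12)
  expect_equal(m$T, C / rowSums(C), ignore_attr = TRUE)
})

test_that("reversible MLE satisfies detailed balance and maximizes likelihood", {
  ## symmetric counts: MLE equals row normalization exactly
  Cs <- matrix(c(4, 2, 2, 4), 2, byrow = TRUE)
  m <- estimate_reversible_mle(Cs)
  expect_identical(m$T, Cs / rowSums(Cs))

  C <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)
  m <- estimate_reversible_mle(C)
  db <- outer(m$pi, rep(1, 2)) * m$T
  expect_lt(max(abs(db - t(db))), 1e-10)
  ## local-search oracle: no nearby reversible matrix beats the MLE
  base <- count_loglik(C, m$T)
  set.seed(77)
  x <- outer(m$pi, rep(1, 2)) * m$T
  for (r in 1:200) {
    pert <- x * exp(matrix(rnorm(4, 0, 0.02), 2))
    pert <- (pert + t(pert)) / 2
    Tp <- pert / rowSums(pert)
    expect_lte(count_loglik(C, Tp), base + 1e-12)
  }
})

test_that("reversible MLE recovers a planted reversible chain", {
  T_true <- random_reversible_T(4, seed = 3)
  spec <- chain_spec(n_states = 4, T_true = T_true,
                     n_trajectories = 60, length_mean = 500,
                     length_max = 2000, seed = 19)
  sim <- simulate_chain(spec, features = FALSE)
  cm <- count_transitions(sim$labels, lag = 1)
  m <- estimate_reversible_mle(cm)
  counts <- cm$counts
  for (i in 1:4) for (j in 1:4) {
    se <- sqrt(T_true[i, j] * (1 - T_true[i, j]) / sum(counts[i, ]))
    expect_lt(abs(m$T[i, j] - T_true[i, j]), 3 * se + 1e-12)
  }
  ## detailed-balance-consistent counts: reversible MLE = row normalization
  pi_t <- stationary_distribution(T_true)
  Cdb <- 1e4 * pi_t * T_true   # symmetric by construction
  m2 <- estimate_reversible_mle(Cdb)
  expect_equal(m2$T, T_true, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("spectral analysis reproduces closed-form 2x2 results", {
  m_id <- spectral_analysis(diag(2))
  expect_equal(m_id$eigenvalues, c(1, 1))
  expect_true(all(is.infinite(m_id$implied_timescales)))

  m <- spectral_analysis(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                         lag_time = 1)
  expect_equal(m$eigenvalues, c(1, 0.7), tolerance = 1e-12)
  expect_equal(m$pi, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(m$implied_timescales[2], -1 / log(0.7), tolerance = 1e-12)
  expect_error(spectral_analysis(matrix(c(0.5, 0.2, 0.4, 0.8), 2,
                                        byrow = TRUE)),
               "stochastic")
})

test_that("spectra match the pi-symmetrization oracle on reversible matrices", {
  for (seed in 1:10) {
    T_mat <- random_reversible_T(5, seed)
    m <- spectral_analysis(T_mat, reversible = TRUE)
    pi_t <- stationary_distribution(T_mat)
    S <- diag(sqrt(pi_t)) %*% T_mat %*% diag(1 / sqrt(pi_t))
    es <- eigen((S + t(S)) / 2, symmetric = TRUE)
    expect_equal(m$eigenvalues, es$values, tolerance = 1e-8)
    ## eigenvectors match up to the documented normalization and sign
    for (k in 2:5) {
      phi_oracle <- sqrt(pi_t) * es$vectors[, k]
      phi_oracle <- phi_oracle / sqrt(sum(phi_oracle^2))
      ## sign rule: positive amplitude from a uniform start
      if (sum(es$vectors[, k] / sqrt(pi_t)) < 0) phi_oracle <- -phi_oracle
      expect_equal(m$phi[, k], phi_oracle, tolerance = 1e-8)
    }
    ## biorthonormality and the sign convention
    expect_equal(crossprod(m$psi, m$phi), diag(5), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(colSums(m$psi[, -1]) > -1e-7))
  }
})

test_that("eigenmode propagation equals iterated matrix application", {
  for (seed in c(2, 5)) {
    T_mat <- random_reversible_T(4, seed)
    m <- spectral_analysis(T_mat, reversible = TRUE)
    p0 <- c(1, 0, 0, 0)
    traj <- propagate(m, p0, 50)
    p <- p0
    for (k in 0:50) {
      expect_equal(unname(traj[k + 1, ]), p, tolerance = 1e-10)
      p <- as.numeric(p %*% T_mat)
    }
    expect_equal(unname(rowSums(traj)), rep(1, 51), tolerance = 1e-10)
    expect_true(all(traj >= -1e-12))
  }
  T_mat <- random_reversible_T(3, 9)
  m <- spectral_analysis(T_mat, reversible = TRUE)
  expect_equal(unname(propagate(m, m$pi, 7)[8, ]), m$pi, tolerance = 1e-10)
  expect_equal(unname(propagate(m, c(1, 0, 0), 0)[1, ]), c(1, 0, 0))
})

test_that("implied timescales are flat for Markovian data and show the planted gap", {
  T3 <- planted_chain_3state()
  expect_equal(sort(eigen(T3)$values, decreasing = TRUE), c(1, 0.95, 0.5))
  spec <- chain_spec(n_states = 3, T_true = T3,
                     emission_means = diag(3), emission_sd = 0.05,
                     n_trajectories = 120, length_mean = 500,
                     length_max = 2000, seed = 23)
  sim <- simulate_chain(spec, features = FALSE)
  tab <- implied_timescale_curves(sim$labels, lags = c(1, 2, 5, 10))
  tau1_true <- -1 / log(0.95)
  expect_true(all(abs(tab$tau_1 - tau1_true) / tau1_true < 0.15))
  expect_equal(tab$gap_ratio[1], log(0.5) / log(0.95), tolerance = 0.15)
  single <- implied_timescale_curves(sim$labels, lags = 1)
  expect_identical(nrow(single), 1L)
  ## timescales are invariant to state relabeling
  relabeled <- lapply(sim$labels, function(s) c(3L, 1L, 2L)[s])
  tab2 <- implied_timescale_curves(relabeled, lags = c(1, 2, 5, 10))
  expect_equal(tab2$tau_1, tab$tau_1, tolerance = 1e-10)
})
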