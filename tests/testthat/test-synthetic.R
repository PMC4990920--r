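test_that("trajectory lengths follow the truncated-exponential law", {
  spec <- chain_spec(length_mean = 67, length_max = 945,
                     n_trajectories = 10000, seed = 11)
  lens <- sample_lengths(spec)
  expect_true(all(lens >= 2))
  expect_true(all(lens <= 945))
  ## oracle: exact mean of max(2, ceiling(X)) for X ~ Exp(67) truncated at 945
  k <- 1:945
  pk <- (pexp(k, 1 / 67) - pexp(k - 1, 1 / 67)) / pexp(945, 1 / 67)
  oracle_mean <- sum(pmax(2, k) * pk)
  expect_lt(abs(mean(lens) - oracle_mean) / oracle_mean, 0.05)
})

test_that("degenerate length law and determinism contracts hold", {
  spec2 <- chain_spec(length_mean = 2, length_max = 2, n_trajectories = 200,
                      seed = 3)
  expect_true(all(sample_lengths(spec2) == 2))
  spec <- chain_spec(n_trajectories = 50, seed = 5)
  expect_identical(sample_lengths(spec), sample_lengths(spec))
  ## counter-derived seeds: growing the ensemble never reshuffles early ones
  spec_big <- chain_spec(n_trajectories = 80, seed = 5)
  expect_identical(sample_lengths(spec_big)[1:50], sample_lengths(spec))
  expect_error(chain_spec(length_mean = -1), "length_mean")
})

test_that("simulated chains follow the planted transition matrix", {
  ## identity chain is absorbing
  spec_id <- chain_spec(n_states = 2, T_true = diag(2),
                        emission_means = rbind(c(0, 0), c(5, 5)),
                        n_trajectories = 8, length_mean = 30,
                        length_max = 60, seed = 2)
  sim <- simulate_chain(spec_id, features = FALSE)
  for (s in sim$labels) expect_true(all(s == s[1]))

  ## empirical transition frequencies match T within 3 binomial SEs
  T2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  spec <- chain_spec(n_states = 2, T_true = T2,
                     emission_means = rbind(c(0, 0), c(4, 4)),
                     n_trajectories = 200, length_mean = 300,
                     length_max = 1000, seed = 9)
  sim <- simulate_chain(spec, features = FALSE)
  cm <- count_transitions(sim$labels, lag = 1)
  counts <- cm$counts
  for (i in 1:2) for (j in 1:2) {
    n_i <- sum(counts[i, ])
    p_hat <- counts[i, j] / n_i
    se <- sqrt(T2[i, j] * (1 - T2[i, j]) / n_i)
    expect_lt(abs(p_hat - T2[i, j]), 3 * se)
  }
})

test_that("round-robin starts and zero-noise emissions are exact", {
  spec <- chain_spec(n_trajectories = 10, n_initial_states = 4,
                     length_mean = 20, length_max = 40, seed = 1,
                     emission_sd = 0)
  sim <- simulate_chain(spec)
  starts <- vapply(sim$labels, `[`, integer(1), 1)
  expect_identical(starts, rep(1:4, length.out = 10))
  ## features equal the per-state means exactly: nearest-mean decodes labels
  for (i in seq_along(sim$labels)) {
    decoded <- apply(sim$features[[i]], 1, function(f)
      which.min(colSums((t(spec$emission_means) - f)^2)))
    expect_identical(as.integer(decoded), sim$labels[[i]])
  }
  expect_error(chain_spec(n_initial_states = 10), "n_initial_states")
})

test_that("long-chain state frequencies approach the stationary distribution", {
  spec <- chain_spec(n_trajectories = 40, length_mean = 400,
                     length_max = 2000, seed = 21)
  sim <- simulate_chain(spec, features = FALSE)
  pi_true <- stationary_distribution(spec$T_true)
  pooled <- unlist(sim$labels)
  tv_of <- function(x) 0.5 * sum(abs(tabulate(x, 4) / length(x) - pi_true))
  short <- unlist(lapply(sim$labels, utils::head, 20))
  expect_lt(tv_of(pooled), tv_of(short))
  expect_lt(tv_of(pooled), 0.05)
})

test_that("double-well dynamics respect barrier, symmetry and Boltzmann weights", {
  ## 50 kT barrier: no crossing in a short run started in the left well
  high <- double_well_spec(barrier_height = 50, n_steps = 2000, seed = 4,
                           time_step = 0.001)
  xy <- simulate_double_well(high)
  expect_true(all(xy[, "x"] < 0))

  ## moderate barrier: symmetric occupancy and Boltzmann-distributed x
  spec <- double_well_spec(barrier_height = 1, n_steps = 200000, seed = 8)
  xy <- simulate_double_well(spec)
  expect_lt(abs(mean(xy[, "x"] > 0) - 0.5), 0.1)
  breaks <- seq(-2.6, 2.6, by = 0.4)
  xs <- xy[, "x"]
  xs <- xs[xs > breaks[1] & xs < breaks[length(breaks)]]
  emp <- hist(xs, breaks = breaks, plot = FALSE)$counts
  emp <- emp / sum(emp)
  ## oracle: normalized exp(-U) integrated per bin on a fine grid
  grid <- seq(-2.6, 2.6, length.out = 4001)
  dens <- exp(-double_well_potential(grid, 0, spec))
  bin <- cut(grid, breaks)
  ref <- tapply(dens, bin, sum)
  ref <- ref / sum(ref)
  expect_lt(0.5 * sum(abs(emp - ref)), 0.1)

  ## instability detection
  bad <- double_well_spec(time_step = 10, n_steps = 500, seed = 1)
  expect_error(simulate_double_well(bad), "instability")
})

test_that("random feature lift preserves nearest-mean decodability", {
  spec <- chain_spec(n_trajectories = 6, length_mean = 60, length_max = 120,
                     seed = 13, emission_sd = 0.3)
  sim <- simulate_chain(spec)
  correct <- 0; total <- 0
  for (i in seq_along(sim$labels)) {
    decoded <- apply(sim$features[[i]], 1, function(f)
      which.min(colSums((t(spec$emission_means) - f)^2)))
    correct <- correct + sum(decoded == sim$labels[[i]])
    total <- total + length(decoded)
  }
  expect_gt(correct / total, 0.99)
})
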