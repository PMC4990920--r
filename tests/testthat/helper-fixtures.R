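# Shared fixtures: all built in code at test time.

# Minimal PDB writer (ATOM records only) for toy structures.
write_toy_pdb <- function(file, resno, xyz, elety = "CA", chain = "A",
                          resid = "GLY") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (length(resno) == 1) resno <- rep(resno, n)
  if (length(elety) == 1) elety <- rep(elety, n)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
    seq_len(n), substr(elety, 1, 4), resid, chain, resno,
    xyz[, 1], xyz[, 2], xyz[, 3], substr(elety, 1, 1))
  writeLines(c(lines, "END"), file)
  file
}

# Random reversible row-stochastic matrix from symmetric counts.
random_reversible_T <- function(n, seed) {
  set.seed(seed)
  w <- matrix(stats::runif(n * n, 0.2, 2), n)
  w <- w + t(w)
  w / rowSums(w)
}

# Row-stochastic 3-state matrix with exact spectrum {1, 0.95, 0.5}.
planted_chain_3state <- function() {
  u2 <- c(1, -1, 0) / sqrt(2)
  u3 <- c(1, 1, -2) / sqrt(6)
  matrix(1 / 3, 3, 3) + 0.5 * outer(u2, u2) + 0.95 * outer(u3, u3)
}

# Multinomial log-likelihood of transition matrix T under counts C.
count_loglik <- function(C, T_mat) {
  ok <- C > 0
  sum(C[ok] * log(T_mat[ok]))
}

# Split pooled labels back into trajectories (mirrors internal helper).
split_pooled <- function(labels, lengths) {
  ends <- cumsum(lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  Map(function(a, b) labels[a:b], starts, ends)
}

# Small simulated ensemble from the planted 4-state chain.
small_chain_sim <- function(n_traj = 30, length_mean = 150, length_max = 600,
                            seed = 7, emission_sd = 0.5) {
  spec <- chain_spec(n_trajectories = n_traj, length_mean = length_mean,
                     length_max = length_max, seed = seed,
                     emission_sd = emission_sd)
  simulate_chain(spec)
}
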