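#' Planted four-state reversible chain
#'
#' Exact reversible, doubly stochastic 4x4 transition matrix with eigenvalues
#' {1, 0.95, 0.5, 0.3}, built from a two-block construction: a slow 2-state
#' exchange between blocks \{1,2\} and \{3,4\} (spectral contrast 0.95) with
#' faster within-block mixing (contrasts 0.5 and 0.3).  This is the default
#' ground truth used by [chain_spec()]: its slowest implied timescale is
#' -1/log(0.95) = 19.496 steps and the timescale gap tau1/tau2 = 13.5, a
#' clean two-state system with internal structure, mimicking the diffuse
#' two-basin kinetics of a disordered lid region.
#'
#' @return A 4x4 row-stochastic matrix.
#' @export
#' @examples
#' eigen(planted_chain_4state())$values  # 1, 0.95, 0.5, 0.3
planted_chain_4state <- function() {
  matrix(c(
    0.7375, 0.2375, 0.0125, 0.0125,
    0.2375, 0.7375, 0.0125, 0.0125,
    0.0125, 0.0125, 0.6375, 0.3375,
    0.0125, 0.0125, 0.3375, 0.6375
  ), nrow = 4, byrow = TRUE)
}

#' Specification for a synthetic Markov-chain trajectory ensemble
#'
#' Defines the ground truth for the synthetic-data generator: a planted
#' transition matrix, Gaussian emission model, and a trajectory-length law
#' emulating an adaptively sampled distributed-computing dataset (many short
#' trajectories with roughly exponential length distribution, truncated at a
#' maximum length, started round-robin from a fixed set of initial states).
#'
#' Defaults mirror the statistics of the trajectory dataset the model targets:
#' exponential mean length 67 frames, maximum 945 frames, and 24 initial
#' conditions (capped at `n_states`).
#'
#' @param n_states Number of hidden states.
#' @param T_true Row-stochastic transition matrix (`n_states` x `n_states`).
#' @param emission_means `n_states` x `n_features` matrix of per-state feature
#'   means, or `NULL` to draw them once from a seeded standard normal scaled by
#'   `mean_scale`.
#' @param emission_sd Isotropic emission standard deviation.
#' @param n_features Feature-space dimension.
#' @param length_mean,length_max Mean and maximum trajectory length, frames.
#' @param n_trajectories Number of trajectories to generate.
#' @param n_initial_states Trajectories start round-robin in states
#'   `1..n_initial_states`.  Must not exceed `n_states`.
#' @param seed Integer master seed; expanded to per-trajectory seeds by a
#'   splitmix-style counter scheme so changing `n_trajectories` never
#'   reshuffles earlier trajectories.
#' @param mean_scale Scale applied to randomly drawn emission means.
#'
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(n_states = 4L,
                       T_true = planted_chain_4state(),
                       emission_means = NULL,
                       emission_sd = 0.5,
                       n_features = 10L,
                       length_mean = 67,
                       length_max = 945,
                       n_trajectories = 100L,
                       n_initial_states = min(24L, n_states),
                       seed = 1L,
                       mean_scale = 2) {
  if (length_mean <= 0) stop("invalid spec: length_mean must be positive")
  if (!(length_max >= length_mean && length_mean >= 2))
    stop("invalid spec: need length_max >= length_mean >= 2")
  if (n_initial_states > n_states)
    stop("invalid spec: n_initial_states exceeds n_states")
  T_true <- as.matrix(T_true)
  if (nrow(T_true) != n_states || ncol(T_true) != n_states)
    stop("invalid spec: T_true must be n_states x n_states")
  if (any(T_true < 0) || any(abs(rowSums(T_true) - 1) > 1e-12))
    stop("invalid spec: T_true rows must be probability distributions")
  if (is.null(emission_means)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(.expand_seed(seed, 0L))
    emission_means <- matrix(stats::rnorm(n_states * n_features), n_states) * mean_scale
  }
  emission_means <- as.matrix(emission_means)
  if (nrow(emission_means) != n_states)
    stop("invalid spec: emission_means needs one row per state")
  if (n_states > 1 &&
      min(stats::dist(emission_means)) < sqrt(.Machine$double.eps))
    stop("invalid spec: emission_means must be pairwise distinct")
  structure(list(
    n_states = as.integer(n_states), T_true = T_true,
    emission_means = emission_means, emission_sd = emission_sd,
    n_features = ncol(emission_means),
    length_mean = length_mean, length_max = length_max,
    n_trajectories = as.integer(n_trajectories),
    n_initial_states = as.integer(n_initial_states),
    seed = as.integer(seed)
  ), class = "chain_spec")
}

## splitmix-style counter scheme: seed i derived from (master, i) alone,
## kept below 2^31 so it is a valid R integer seed
.expand_seed <- function(seed, i) {
  z <- (as.double(seed) %% 2147483647) + (as.double(i) + 1) * 2654435761
  z <- z %% 2147483647
  z <- (z * 48271) %% 2147483647
  as.integer(z)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

## one trajectory length: exponential, resampled above length_max, floored at 2
.draw_length <- function(length_mean, length_max) {
  repeat {
    x <- stats::rexp(1, rate = 1 / length_mean)
    if (x <= length_max) break
  }
  max(2L, as.integer(ceiling(x)))
}

#' Sample trajectory lengths from the truncated-exponential length law
#'
#' Lengths are exponential with mean `length_mean`, resampled above
#' `length_max` and floored at 2 frames.  Each trajectory draws from its own
#' counter-derived seed, so the i-th length is a function of `(seed, i)` only.
#'
#' @param spec A [chain_spec()].
#' @return Integer vector of `n_trajectories` lengths (frames).
#' @export
sample_lengths <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  vapply(seq_len(spec$n_trajectories), function(i) {
    set.seed(.expand_seed(spec$seed, i))
    .draw_length(spec$length_mean, spec$length_max)
  }, integer(1))
}

#' Simulate a trajectory ensemble from a planted Markov chain
#'
#' Generates `n_trajectories` state-label trajectories following `T_true`,
#' starting round-robin from the first `n_initial_states` states, with
#' per-frame feature vectors equal to the state's emission mean plus isotropic
#' Gaussian noise.  Labels and features are index-aligned.
#'
#' @param spec A [chain_spec()].
#' @param features If `FALSE`, skip emission sampling and return labels only.
#' @return A list with `labels` (list of integer vectors, states in
#'   `1..n_states`) and `features` (list of frames x n_features matrices, or
#'   `NULL`), plus the `spec`.
#' @export
simulate_chain <- function(spec, features = TRUE) {
  stopifnot(inherits(spec, "chain_spec"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  cum <- t(apply(spec$T_true, 1, cumsum))
  labels <- vector("list", spec$n_trajectories)
  feats <- if (features) vector("list", spec$n_trajectories) else NULL
  for (i in seq_len(spec$n_trajectories)) {
    set.seed(.expand_seed(spec$seed, i))
    len <- .draw_length(spec$length_mean, spec$length_max)
    s <- integer(len)
    s[1] <- ((i - 1L) %% spec$n_initial_states) + 1L
    u <- stats::runif(len - 1L)
    for (t in seq_len(len - 1L)) {
      s[t + 1L] <- findInterval(u[t], cum[s[t], ], left.open = TRUE) + 1L
    }
    labels[[i]] <- s
    if (features) {
      noise <- matrix(stats::rnorm(len * spec$n_features), len) * spec$emission_sd
      feats[[i]] <- spec$emission_means[s, , drop = FALSE] + noise
    }
  }
  list(labels = labels, features = feats, spec = spec)
}

#' Specification for overdamped dynamics on a 2-D double-well potential
#'
#' Continuous analogue of a diffuse two-basin landscape:
#' `U(x, y) = barrier_height * ((x/a)^2 - 1)^2 + y^2 / (2 * diffusive_width^2)`
#' with `a = well_separation / 2`, so the wells sit at x = -a and x = +a and
#' the y coordinate is a broad harmonic ("diffuse") degree of freedom.
#' Energies are in units of kT.
#'
#' @param barrier_height Barrier height at x = 0, kT.  Must be positive.
#' @param well_separation Distance between the two well minima.
#' @param diffusive_width Standard-deviation scale of the orthogonal
#'   coordinate.
#' @param time_step Integrator step (dimensionless).
#' @param friction Friction coefficient (dimensionless).
#' @param n_steps Number of steps to integrate.
#' @param seed Integer seed.
#' @return An object of class `double_well_spec`.
#' @export
double_well_spec <- function(barrier_height = 2, well_separation = 2,
                             diffusive_width = 1, time_step = 0.01,
                             friction = 1, n_steps = 10000L, seed = 1L) {
  if (barrier_height <= 0) stop("invalid spec: barrier_height must be > 0")
  if (well_separation <= 0) stop("invalid spec: well_separation must be > 0")
  structure(list(barrier_height = barrier_height,
                 well_separation = well_separation,
                 diffusive_width = diffusive_width,
                 time_step = time_step, friction = friction,
                 n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "double_well_spec")
}

#' Double-well potential energy
#'
#' @param x,y Coordinates (vectorized).
#' @param spec A [double_well_spec()].
#' @return Potential energy in kT.
#' @export
double_well_potential <- function(x, y = 0, spec) {
  a <- spec$well_separation / 2
  spec$barrier_height * ((x / a)^2 - 1)^2 + 0.5 * (y / spec$diffusive_width)^2
}

#' Simulate overdamped Langevin dynamics on the 2-D double well
#'
#' Euler--Maruyama integration of the overdamped Langevin equation at kT = 1:
#' `dx = -(dt / friction) * dU/dx + sqrt(2 dt / friction) * N(0, 1)`.
#' The walker starts at the left well minimum `(-well_separation/2, 0)`.
#' Integration aborts with an error if |x| exceeds 10 * well_separation,
#' which indicates a divergent time step.
#'
#' @param spec A [double_well_spec()].
#' @param start Optional numeric length-2 start point.
#' @return `n_steps + 1` x 2 matrix of (x, y) coordinates.
#' @export
simulate_double_well <- function(spec, start = NULL) {
  stopifnot(inherits(spec, "double_well_spec"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(spec$seed)
  a <- spec$well_separation / 2
  h <- spec$barrier_height
  dt <- spec$time_step
  g <- spec$friction
  amp <- sqrt(2 * dt / g)
  xy <- matrix(0, spec$n_steps + 1L, 2L,
               dimnames = list(NULL, c("x", "y")))
  xy[1, ] <- if (is.null(start)) c(-a, 0) else start
  nx <- stats::rnorm(spec$n_steps)
  ny <- stats::rnorm(spec$n_steps)
  x <- xy[1, 1]; y <- xy[1, 2]
  w2 <- spec$diffusive_width^2
  for (t in seq_len(spec$n_steps)) {
    fx <- 4 * h * x * ((x / a)^2 - 1) / a^2
    fy <- y / w2
    x <- x - dt / g * fx + amp * nx[t]
    y <- y - dt / g * fy + amp * ny[t]
    if (abs(x) > 10 * spec$well_separation)
      stop("integration instability: |x| exceeded 10 * well_separation at step ", t)
    xy[t + 1L, ] <- c(x, y)
  }
  xy
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of `T` at eigenvalue 1, normalized to sum to 1.
#'
#' @param T_mat Row-stochastic matrix.
#' @return Probability vector.
#' @export
stationary_distribution <- function(T_mat) {
  e <- eigen(t(T_mat))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}
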