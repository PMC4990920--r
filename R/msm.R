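#' Count state-to-state transitions at a lag
#'
#' Counts observed `i -> j` transitions at lag `lag` over a set of discrete
#' label trajectories.  Sliding mode counts every pair `(t, t + lag)` (uses
#' all data; the default, consistent with likelihood estimation at short
#' lags); strided mode counts pairs at `t = 1, 1 + lag, 1 + 2 lag, ...` for
#' statistical-independence checks.  The count graph is trimmed to its
#' largest strongly connected component and the retained-state mapping is
#' recorded; a report of dropped states is always part of the result.
#'
#' @param label_trajs List of integer state-label vectors (1-based), or one
#'   vector.
#' @param lag Lag in frames, >= 1.
#' @param mode `"sliding"` or `"strided"`.
#' @param n_states Total number of states; defaults to the maximum label.
#' @param dt Time per frame (ps), carried into downstream models.
#' @return A `count_matrix`: `counts` (trimmed to the ergodic subset),
#'   `counts_full` (untrimmed), `lag`, `dt`, `n_states` (retained),
#'   `ergodic_subset` (original indices retained), `n_states_full`,
#'   `dropped`.
#' @export
count_transitions <- function(label_trajs, lag = 1L,
                              mode = c("sliding", "strided"),
                              n_states = NULL, dt = 1) {
  mode <- match.arg(mode)
  if (!is.list(label_trajs)) label_trajs <- list(label_trajs)
  lag <- as.integer(lag)
  if (lag < 1) stop("lag must be >= 1")
  if (is.null(n_states)) n_states <- max(unlist(lapply(label_trajs, max)))
  n <- as.integer(n_states)
  counts <- matrix(0L, n, n)
  any_pairs <- FALSE
  for (s in label_trajs) {
    len <- length(s)
    if (len <= lag) next
    any_pairs <- TRUE
    starts <- if (mode == "sliding") seq_len(len - lag)
              else seq.int(1L, len - lag, by = lag)
    from <- s[starts]; to <- s[starts + lag]
    counts <- counts + matrix(tabulate((from - 1L) * n + to, n * n),
                              n, n, byrow = TRUE)
  }
  if (!any_pairs)
    stop("no trajectory longer than lag ", lag)
  keep <- .largest_scc(counts)
  dropped <- setdiff(seq_len(n), keep)
  structure(list(counts = counts[keep, keep, drop = FALSE],
                 counts_full = counts,
                 lag = lag, dt = dt, n_states = length(keep),
                 ergodic_subset = keep, n_states_full = n,
                 dropped = dropped),
            class = "count_matrix")
}

## states of the largest strongly connected component of the count graph
.largest_scc <- function(counts) {
  g <- igraph::graph_from_adjacency_matrix(counts > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership, comp$no)
  ## break size ties toward the component holding the most counts
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    w <- vapply(best, function(b) {
      s <- which(comp$membership == b)
      sum(counts[s, s])
    }, numeric(1))
    best <- best[which.max(w)]
  }
  sort(which(comp$membership == best))
}

.as_count_matrix <- function(counts, lag = 1L, dt = 1) {
  if (inherits(counts, "count_matrix")) return(counts)
  counts <- as.matrix(counts)
  structure(list(counts = counts, lag = as.integer(lag), dt = dt,
                 n_states = nrow(counts),
                 ergodic_subset = seq_len(nrow(counts)),
                 n_states_full = nrow(counts), dropped = integer(0)),
            class = "count_matrix")
}

#' Non-reversible maximum-likelihood transition matrix
#'
#' The multinomial MLE: `T_ij = C_ij / sum_j C_ij`, followed by spectral
#' analysis.  Eigenvalues of a non-reversible estimate may be complex; real
#' parts are retained and complex pairs flagged, never silently truncated.
#'
#' @param counts A `count_matrix` (or plain matrix).
#' @param dt Time per frame if `counts` is a plain matrix.
#' @return A `transition_model`; see [spectral_analysis()].
#' @export
estimate_nonreversible <- function(counts, dt = NULL) {
  cm <- .as_count_matrix(counts, dt = if (is.null(dt)) 1 else dt)
  C <- cm$counts
  rs <- rowSums(C)
  if (any(rs == 0))
    stop("internal error: state with no outgoing counts survived trimming")
  T_mat <- C / rs
  m <- spectral_analysis(T_mat, lag_time = cm$lag * cm$dt, reversible = FALSE)
  m$counts <- cm
  m
}

#' Reversible maximum-likelihood transition matrix
#'
#' Maximizes the multinomial likelihood `prod T_ij^{C_ij}` subject to
#' detailed balance `pi_i T_ij = pi_j T_ji`, by the standard fixed-point
#' iteration on symmetric auxiliary variables:
#' `x_ij <- (C_ij + C_ji) / (C_i / x_i + C_j / x_j)`, with
#' `T_ij = x_ij / x_i` and `x_i = sum_j x_ij`.  On symmetric count matrices
#' the fixed point is reached immediately and the estimate equals plain row
#' normalization exactly.
#'
#' @param counts Connected `count_matrix` (or plain matrix).
#' @param tol Convergence threshold on the maximum relative change of `x`
#'   (default 1e-10).
#' @param max_iter Iteration cap (default 1e6).
#' @param dt Time per frame if `counts` is a plain matrix.
#' @return A `transition_model` with `reversible = TRUE`.
#' @export
estimate_reversible_mle <- function(counts, tol = 1e-10, max_iter = 1e6,
                                    dt = NULL) {
  cm <- .as_count_matrix(counts, dt = if (is.null(dt)) 1 else dt)
  C <- cm$counts
  Ci <- rowSums(C)
  if (any(Ci == 0))
    stop("internal error: state with no outgoing counts survived trimming")
  Cs <- C + t(C)
  conn <- Cs > 0
  x <- Cs
  converged <- FALSE
  rel <- NA_real_
  for (it in seq_len(max_iter)) {
    xi <- rowSums(x)
    denom <- outer(Ci / xi, Ci / xi, "+")
    xnew <- ifelse(conn, Cs / denom, 0)
    rel <- max(abs(xnew - x)[conn] / x[conn])
    x <- xnew
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("reversible MLE did not converge: residual ", format(rel),
         " after ", max_iter, " iterations")
  xi <- rowSums(x)
  T_mat <- x / xi
  pi_hat <- xi / sum(xi)
  m <- spectral_analysis(T_mat, lag_time = cm$lag * cm$dt, reversible = TRUE,
                         pi = pi_hat)
  m$counts <- cm
  m
}

#' Spectral analysis of a transition matrix
#'
#' Completes a row-stochastic matrix `T` into a `transition_model`:
#' eigenvalues sorted descending by real part, biorthonormal mode pairs, the
#' stationary distribution, and implied timescales
#' `tau_n = -lag_time / log(mu_n)` (infinite for the stationary mode, `NA`
#' where `mu_n <= 0`).
#'
#' Two families of eigenvectors are stored following the master-equation
#' convention for distribution dynamics: `phi` are the distribution-like
#' modes (columns; `phi_0` equals the stationary distribution `pi`, i.e. the
#' left eigenvectors of the row-stochastic `T`), and `psi` are the
#' observable-like projectors (`psi_0` is the constant vector, the right
#' eigenvectors), scaled so that `sum(psi_m * phi_n) = delta_mn`.  Population
#' vectors then evolve as
#' `p(k tau) = sum_n (psi_n . p0) mu_n^k phi_n` (see [propagate()]).  Note
#' for transposed (column-stochastic) external conventions the phi/psi roles
#' swap; conversion belongs at the I/O boundary.
#'
#' Sign convention: each mode pair is flipped so that `sum(psi_n) >= 0`,
#' making every amplitude `(psi_n . p0)` non-negative when `p0` is uniform —
#' dynamics started from a uniform distribution are then a superposition of
#' positive-amplitude decaying modes.  (The entries of `phi_n` themselves
#' sum to zero for `n >= 1`, by biorthogonality with the constant mode, so a
#' sign cannot be carried there; if `sum(psi_n)` is zero within tolerance
#' the first nonzero entry of `phi_n` is made positive.)
#'
#' Deliberately uses the general dense eigensolver for both reversible and
#' non-reversible input, so that the similarity transform
#' `D^{1/2} T D^{-1/2}` remains an independent cross-check.
#'
#' @param T_mat Row-stochastic matrix.
#' @param lag_time Physical lag time (e.g. ps) used for timescales.
#' @param reversible Logical flag stored on the model; when `TRUE` the
#'   spectrum is validated to be real.
#' @param pi Optional stationary distribution (used to validate/normalize);
#'   estimated from the spectrum if missing.
#' @return A `transition_model` list: `T`, `lag_time`, `eigenvalues`, `phi`,
#'   `psi`, `pi`, `implied_timescales`, `reversible`, `complex_modes`.
#' @export
spectral_analysis <- function(T_mat, lag_time = 1, reversible = FALSE,
                              pi = NULL) {
  T_mat <- as.matrix(T_mat)
  n <- nrow(T_mat)
  if (ncol(T_mat) != n || any(T_mat < -1e-12) ||
      any(abs(rowSums(T_mat) - 1) > 1e-8))
    stop("input is not a row-stochastic matrix")
  e <- eigen(T_mat)
  ord <- order(-Re(e$values), abs(Im(e$values)))
  vals <- e$values[ord]
  R <- e$vectors[, ord, drop = FALSE]     # right (observable-like)
  L <- t(solve(R))                        # left  (distribution-like), L^T R = I
  complex_modes <- abs(Im(vals)) > 1e-12
  if (reversible && any(complex_modes))
    stop("reversible model has a complex spectrum; estimation is inconsistent")
  vals <- Re(vals)
  phi <- Re(L); psi <- Re(R)
  if (any(complex_modes)) {
    ## keep real parts, biorthonormality only guaranteed for real modes
    warning(sum(complex_modes), " complex eigenvalue(s) in non-reversible ",
            "spectrum; real parts retained")
  }
  ## normalize: phi_0 = pi (sums to 1); other modes to unit norm, sign fixed
  s0 <- sum(phi[, 1])
  phi[, 1] <- phi[, 1] / s0
  psi[, 1] <- psi[, 1] * s0
  if (n > 1) for (k in 2:n) {
    nk <- sqrt(sum(phi[, k]^2))
    if (nk > 0) { phi[, k] <- phi[, k] / nk; psi[, k] <- psi[, k] * nk }
    ## positive amplitude from a uniform start: sum(psi_n) >= 0 (the mode
    ## amplitudes (psi_n . p0) are then non-negative for uniform p0); ties
    ## resolved by making the first nonzero entry of phi_n positive
    sk <- sum(psi[, k])
    flip <- if (abs(sk) > 1e-8 * n) sk < 0
            else {
              nz <- which(abs(phi[, k]) > 1e-12)[1]
              !is.na(nz) && phi[nz, k] < 0
            }
    if (isTRUE(flip)) { phi[, k] <- -phi[, k]; psi[, k] <- -psi[, k] }
  }
  if (is.null(pi)) pi <- phi[, 1]
  pi <- pi / sum(pi)
  tau <- rep(NA_real_, n)
  tau[abs(vals - 1) <= 1e-10] <- Inf
  dec <- vals < 1 - 1e-10 & vals > 0
  tau[dec] <- -lag_time / log(vals[dec])
  structure(list(T = T_mat, lag_time = lag_time, eigenvalues = vals,
                 phi = phi, psi = psi, pi = pi,
                 implied_timescales = tau, reversible = reversible,
                 complex_modes = complex_modes),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Transition model:", nrow(x$T), "states, lag_time =", x$lag_time,
      if (x$reversible) "(reversible MLE)" else "(non-reversible)", "\n")
  k <- min(5, length(x$eigenvalues))
  cat("  eigenvalues:", paste(signif(x$eigenvalues[seq_len(k)], 4),
                              collapse = ", "),
      if (length(x$eigenvalues) > k) "...", "\n")
  cat("  implied timescales:",
      paste(signif(x$implied_timescales[seq_len(k)], 4), collapse = ", "),
      if (length(x$eigenvalues) > k) "...", "\n")
  invisible(x)
}

#' Propagate a population vector through the eigenmode expansion
#'
#' Solves the discrete master equation by spectral superposition:
#' `p(k tau) = sum_n (psi_n . p0) mu_n^k phi_n`, where the stationary
#' (`mu_0 = 1`) term is time-independent.  `mu^k` coincides with
#' `exp(-t / tau_n)` for `0 < mu_n < 1` and remains well defined for
#' non-positive eigenvalues, so the expansion reproduces iterated application
#' of `T` exactly.  Starting at `p0 = pi` returns `pi` at every time.
#'
#' @param model A `transition_model` with complete spectra.
#' @param p0 Initial population vector (non-negative, sums to 1).
#' @param n_steps Number of lag steps to propagate.
#' @return `(n_steps + 1)` x n matrix; row `k + 1` is the population after
#'   `k` lag steps.  Row names give the physical time.
#' @export
propagate <- function(model, p0, n_steps) {
  stopifnot(inherits(model, "transition_model"))
  if (is.null(model$phi) || is.null(model$psi))
    stop("model spectra are incomplete")
  n <- nrow(model$T)
  if (length(p0) != n) stop("p0 has wrong length")
  if (any(p0 < -1e-12) || abs(sum(p0) - 1) > 1e-10)
    stop("p0 is not a probability vector")
  amps <- as.numeric(crossprod(model$psi, p0))   # psi_n . p0
  ks <- 0:n_steps
  powers <- outer(model$eigenvalues, ks, "^")    # n_modes x (n_steps+1)
  out <- t(model$phi %*% (powers * amps))
  rownames(out) <- ks * model$lag_time
  out
}

#' Implied timescale curves over a set of lag times
#'
#' For each lag: count transitions (sliding window), trim to the ergodic
#' subset, estimate the (by default reversible) MLE transition matrix, and
#' report the slowest `n_timescales` implied timescales together with the
#' gap ratio `tau_1 / tau_2`.  A flat curve indicates Markovian behavior at
#' that discretization; a persistent gap between the slowest and next-slowest
#' timescale diagnoses effective two-state kinetics.
#'
#' @param label_trajs List of integer label trajectories.
#' @param lags Ascending integer vector of lags (frames).
#' @param n_timescales Number of slow timescales to report (default 2).
#' @param dt Time per frame (ps).
#' @param reversible Use the reversible MLE (default) or the plain MLE.
#' @return Data frame with one row per lag: `lag`, `lag_time`, `tau_1` ...,
#'   and `gap_ratio`.
#' @export
implied_timescale_curves <- function(label_trajs, lags, n_timescales = 2L,
                                     dt = 1, reversible = TRUE) {
  if (is.unsorted(lags, strictly = TRUE)) stop("lags must be ascending")
  rows <- lapply(lags, function(lg) {
    cm <- count_transitions(label_trajs, lag = lg, dt = dt)
    m <- if (reversible) estimate_reversible_mle(cm)
         else estimate_nonreversible(cm)
    ## slowest timescales exclude the stationary mode
    tau <- m$implied_timescales[-1]
    tau <- tau[seq_len(min(n_timescales, length(tau)))]
    length(tau) <- n_timescales
    gap <- if (n_timescales >= 2 && !is.na(tau[2]) && tau[2] > 0)
      tau[1] / tau[2] else NA_real_
    c(lag = lg, lag_time = lg * dt, stats::setNames(tau,
      paste0("tau_", seq_len(n_timescales))), gap_ratio = gap)
  })
  as.data.frame(do.call(rbind, rows))
}
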