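#' Fit time-lagged independent component analysis (tICA)
#'
#' Estimates the slowest linear collective coordinates of a set of feature
#' trajectories from mean-free, symmetrized covariance estimators pooled over
#' all transition pairs (each pair weighted equally, not each trajectory):
#' \deqn{C_0 = \langle x x^T \rangle, \quad
#'       C_\tau = \tfrac12 \langle x(t) x(t+\tau)^T + x(t+\tau) x(t)^T \rangle}
#' and solves the generalized eigenproblem
#' `ctau v = lambda (c0 + regularization * I) v`.  Symmetrization forces a
#' real spectrum (appropriate for reversible dynamics); the small default
#' ridge keeps the problem well posed when some features are frozen.
#'
#' Components are sorted by eigenvalue descending, normalized so that
#' `t(v) %*% (c0 + reg I) %*% v = I`, and given a deterministic sign (the
#' largest-magnitude loading of each component is positive).  For adequately
#' sampled reversible data all eigenvalues lie in `[-1, 1]`; at lag 1 on a
#' univariate AR(1) signal the single eigenvalue equals the lag-1
#' autocorrelation.
#'
#' @param trajs List of [feature_trajectory()] objects or numeric matrices
#'   (frames x features), or a single one.
#' @param lag Lag time in frames (default 1, one snapshot).
#' @param regularization Ridge added to `c0`; default
#'   `1e-10 * trace(c0) / n_features`.  Set to 0 to disable (an explicit
#'   conditioning error naming zero-variance features is raised if `c0` is
#'   then singular).
#' @return A `tica_model` with fields `mean`, `c0`, `ctau`, `lag`,
#'   `eigenvalues`, `components` (columns), `regularization`.
#' @export
fit_tica <- function(trajs, lag = 1L, regularization = NULL) {
  if (!is.list(trajs) || inherits(trajs, "feature_trajectory"))
    trajs <- list(trajs)
  mats <- lapply(trajs, .feature_values)
  usable <- vapply(mats, nrow, integer(1)) > lag
  if (!any(usable))
    stop("insufficient data: no trajectory longer than lag ", lag)
  mats <- mats[usable]
  d <- ncol(mats[[1]])
  s0 <- numeric(d); s1 <- numeric(d); n_pairs <- 0
  for (x in mats) {
    nt <- nrow(x) - lag
    s0 <- s0 + colSums(x[seq_len(nt), , drop = FALSE])
    s1 <- s1 + colSums(x[lag + seq_len(nt), , drop = FALSE])
    n_pairs <- n_pairs + nt
  }
  mu <- (s0 + s1) / (2 * n_pairs)
  c0 <- matrix(0, d, d); ctau <- matrix(0, d, d)
  for (x in mats) {
    nt <- nrow(x) - lag
    x0 <- sweep(x[seq_len(nt), , drop = FALSE], 2, mu)
    x1 <- sweep(x[lag + seq_len(nt), , drop = FALSE], 2, mu)
    c0 <- c0 + crossprod(x0) + crossprod(x1)
    ctau <- ctau + crossprod(x0, x1) + crossprod(x1, x0)
  }
  c0 <- c0 / (2 * n_pairs)
  ctau <- ctau / (2 * n_pairs)
  if (is.null(regularization))
    regularization <- 1e-10 * sum(diag(c0)) / d
  c0r <- c0 + diag(regularization, d)
  ch <- tryCatch(chol(c0r), error = function(e) NULL)
  if (is.null(ch)) {
    frozen <- which(diag(c0) < 1e-14)
    stop("instantaneous covariance is singular",
         if (length(frozen)) paste0("; zero-variance features: ",
                                    paste(frozen, collapse = ", "))
         else "; features are linearly dependent",
         " (increase regularization)")
  }
  w <- backsolve(ch, diag(d))          # c0r^{-1} = w %*% t(w)
  m <- crossprod(w, ctau %*% w)
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  comps <- w %*% e$vectors
  ## deterministic sign: largest-magnitude loading positive
  for (k in seq_len(d)) {
    j <- which.max(abs(comps[, k]))
    if (comps[j, k] < 0) comps[, k] <- -comps[, k]
  }
  structure(list(mean = mu, c0 = c0, ctau = ctau, lag = as.integer(lag),
                 eigenvalues = e$values, components = comps,
                 regularization = regularization),
            class = "tica_model")
}

#' Project a feature trajectory onto tICA components
#'
#' `values = (x - mean) %*% components[, 1:n_components]`.  Projecting the
#' model's own mean gives the zero vector.
#'
#' @param model A `tica_model` from [fit_tica()].
#' @param traj A [feature_trajectory()] or numeric matrix with the model's
#'   feature dimension.
#' @param n_components Number of leading components to keep (default 2, the
#'   number found sufficient to capture the slowest motions).
#' @return A `tica_projection` with fields `values` (frames x n_components),
#'   `lag`, `component_ids`.
#' @export
project_tica <- function(model, traj, n_components = 2L) {
  stopifnot(inherits(model, "tica_model"))
  x <- .feature_values(traj)
  if (ncol(x) != length(model$mean))
    stop("feature dimension ", ncol(x), " does not match model (",
         length(model$mean), ")")
  if (n_components > ncol(model$components))
    stop("n_components exceeds available components")
  v <- sweep(x, 2, model$mean) %*%
    model$components[, seq_len(n_components), drop = FALSE]
  colnames(v) <- paste0("tIC", seq_len(n_components))
  structure(list(values = v, lag = model$lag,
                 component_ids = seq_len(n_components)),
            class = "tica_projection")
}

.projection_values <- function(x) {
  if (inherits(x, "tica_projection")) x$values else as.matrix(x)
}

#' Pool projections of several trajectories
#'
#' Convenience wrapper: projects each trajectory and returns the stacked
#' frame matrix plus the per-trajectory frame counts, so pooled clustering
#' results can be split back into trajectories.
#'
#' @inheritParams project_tica
#' @param trajs List of trajectories.
#' @return List with `values` (pooled matrix), `lengths` (frames per
#'   trajectory).
#' @export
project_all <- function(model, trajs, n_components = 2L) {
  vs <- lapply(trajs, function(x) project_tica(model, x, n_components)$values)
  list(values = do.call(rbind, vs),
       lengths = vapply(vs, nrow, integer(1)))
}
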