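## squared Euclidean distances between rows of x and rows of centers
.dist2 <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

#' Deterministic k-centers clustering
#'
#' Farthest-point traversal: the first center is the frame at `start_index`;
#' each subsequent center is the frame with maximum distance to its nearest
#' existing center, ties broken by lowest frame index.  Fully deterministic,
#' giving bit-reproducible discretizations.  The cover radius of the result
#' is within a factor 2 of the optimal k-center radius.
#'
#' @param data Numeric matrix of pooled frames (n x d), or a
#'   `tica_projection`.
#' @param k Number of centers; must not exceed the number of frames.
#' @param start_index Frame index of the first center (default 1).
#' @return A `cluster_model` with `centers` (k x d), `method`, `k`,
#'   `seed_or_start`, and `center_frames` (frame indices of the centers).
#' @export
k_centers <- function(data, k, start_index = 1L) {
  x <- .projection_values(data)
  n <- nrow(x)
  if (k > n) stop("k = ", k, " exceeds the number of frames (", n, ")")
  idx <- integer(k)
  idx[1] <- start_index
  mind2 <- .dist2(x, x[start_index, , drop = FALSE])[, 1]
  if (k > 1) for (c in 2:k) {
    idx[c] <- which.max(mind2)   # first index on ties
    mind2 <- pmin(mind2, .dist2(x, x[idx[c], , drop = FALSE])[, 1])
  }
  structure(list(centers = x[idx, , drop = FALSE], method = "k-centers",
                 k = as.integer(k), seed_or_start = as.integer(start_index),
                 center_frames = idx),
            class = "cluster_model")
}

#' Lloyd k-means from the deterministic k-centers initialization
#'
#' Standard Lloyd iterations started from the [k_centers()] solution;
#' converged when the maximum center movement falls below `tol` or after
#' `max_iter` iterations.  A cluster that empties is re-seeded at the frame
#' farthest from its assigned center.  Deterministic given the data.
#'
#' @inheritParams k_centers
#' @param seed Stored for provenance; the algorithm itself is deterministic.
#' @param tol Convergence threshold on center movement (default 1e-8).
#' @param max_iter Iteration cap (default 500).
#' @return A `cluster_model` with `method = "k-means"`.
#' @export
k_means_lloyd <- function(data, k, seed = 1L, tol = 1e-8, max_iter = 500L) {
  x <- .projection_values(data)
  centers <- k_centers(x, k)$centers
  for (it in seq_len(max_iter)) {
    d2 <- .dist2(x, centers)
    lab <- max.col(-d2, ties.method = "first")
    newc <- centers
    for (c in seq_len(k)) {
      rows <- lab == c
      if (!any(rows)) {
        ## empty cluster: re-seed at the globally farthest point
        own <- d2[cbind(seq_len(nrow(x)), lab)]
        newc[c, ] <- x[which.max(own), ]
      } else {
        newc[c, ] <- colMeans(x[rows, , drop = FALSE])
      }
    }
    moved <- max(sqrt(rowSums((newc - centers)^2)))
    centers <- newc
    if (moved < tol) break
  }
  structure(list(centers = centers, method = "k-means",
                 k = as.integer(k), seed_or_start = as.integer(seed)),
            class = "cluster_model")
}

#' Assign frames to their nearest cluster center
#'
#' Euclidean nearest-center rule; ties go to the lowest center index.
#'
#' @param model A `cluster_model`.
#' @param data Numeric matrix (n x d), `tica_projection`, or a list of
#'   either (assigned per element).
#' @return Integer label vector in `1..k`, or a list of such vectors.
#' @export
assign_states <- function(model, data) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.list(data) && !inherits(data, "tica_projection"))
    return(lapply(data, assign_states, model = model))
  x <- .projection_values(data)
  if (ncol(x) != ncol(model$centers))
    stop("dimension mismatch: data has ", ncol(x), " columns, centers have ",
         ncol(model$centers))
  max.col(-.dist2(x, model$centers), ties.method = "first")
}
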