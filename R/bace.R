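## log Bayes factor for merging states i and j of count matrix C:
## sum_k [ C_ik log(p_ik/q_k) + C_jk log(p_jk/q_k) ]
## with p the states' own outgoing probability rows and q the
## count-weighted average row of the merged state.  Small for states whose
## outgoing distributions are statistically indistinguishable.
.bace_lnbf <- function(C, i, j) {
  ci <- C[i, ]; cj <- C[j, ]
  ni <- sum(ci); nj <- sum(cj)
  p_i <- ci / ni; p_j <- cj / nj
  q <- (ci + cj) / (ni + nj)
  ti <- ci > 0; tj <- cj > 0
  sum(ci[ti] * log(p_i[ti] / q[ti])) + sum(cj[tj] * log(p_j[tj] / q[tj]))
}

#' BACE-style Bayesian agglomerative coarse-graining
#'
#' Iteratively merges the pair of kinetically connected microstates with the
#' smallest log Bayes factor between their outgoing transition count
#' distributions (the log-likelihood-ratio leading term of the BACE
#' criterion), re-aggregating counts after each merge, until `n_macro`
#' macrostates remain.  Only pairs with at least one observed transition
#' between them are merge candidates, so kinetically disconnected states are
#' never merged; ties are broken toward the lowest index pair, making the
#' merge sequence deterministic.
#'
#' Two states with identical outgoing count rows have log Bayes factor 0 and
#' merge first.  Total transition counts are conserved exactly under
#' aggregation, so the coarse stationary distribution of a lumpable chain
#' equals the aggregated fine stationary distribution.
#'
#' @param counts A `count_matrix` (see [count_transitions()]) or plain
#'   count matrix.
#' @param n_macro Target number of macrostates.
#' @return A `macrostate_model`: `mapping` (microstate -> macrostate labels,
#'   `1..n_macro`), `n_macrostates`, `merge_log` (data frame of merges with
#'   their log Bayes factors, in merge order, states given as original
#'   microstate representatives), `coarse_counts` (aggregated
#'   `count_matrix`).
#' @export
bace_merge <- function(counts, n_macro) {
  cm <- .as_count_matrix(counts)
  C <- cm$counts * 1.0
  n <- nrow(C)
  if (n_macro > n) stop("n_macro exceeds the number of states")
  mapping <- seq_len(n)           # microstate -> current group representative
  alive <- seq_len(n)             # rows of C still active (representatives)
  merge_log <- list()
  while (length(alive) > n_macro) {
    A <- C[alive, alive, drop = FALSE]
    conn <- which(A + t(A) > 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(conn) == 0)
      stop("count graph is disconnected: cannot reach ", n_macro,
           " macrostates by merging connected pairs")
    lnbf <- vapply(seq_len(nrow(conn)), function(r)
      .bace_lnbf(A, conn[r, 1], conn[r, 2]), numeric(1))
    ## ties toward the lowest index pair: conn is ordered by (col, row) from
    ## which(); re-order to (row-major) lowest (i, j)
    ord <- order(lnbf, conn[, 1], conn[, 2])
    pick <- conn[ord[1], ]
    i <- alive[pick[1]]; j <- alive[pick[2]]
    merge_log[[length(merge_log) + 1L]] <-
      data.frame(state_a = i, state_b = j, log_bayes_factor = lnbf[ord[1]])
    C[i, ] <- C[i, ] + C[j, ]
    C[, i] <- C[, i] + C[, j]
    alive <- setdiff(alive, j)
    mapping[mapping == j] <- i
  }
  ## relabel representatives to 1..n_macro preserving order
  final <- match(mapping, sort(unique(mapping)))
  ind <- diag(length(alive))[final, , drop = FALSE]
  coarse <- t(ind) %*% cm$counts %*% ind
  structure(list(mapping = final, n_macrostates = length(alive),
                 merge_log = if (length(merge_log))
                   do.call(rbind, merge_log)
                 else data.frame(state_a = integer(0), state_b = integer(0),
                                 log_bayes_factor = numeric(0)),
                 coarse_counts = .as_count_matrix(coarse, lag = cm$lag,
                                                 dt = cm$dt)),
            class = "macrostate_model")
}
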