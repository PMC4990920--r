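#' Generalized matrix Rayleigh quotient (GMRQ) score
#'
#' Scores how well the leading eigenvectors of a training MSM capture the
#' slow dynamics of held-out data.  With `A` the first `m` training
#' eigenvectors expressed on the state basis (observable-like right
#' eigenvectors, the first being the constant mode), `S` the diagonal matrix
#' of test-set state-visit frequencies and `C` the symmetrized test
#' transition frequencies,
#' \deqn{GMRQ = tr[(A^T S A)^{-1} (A^T C A)]}
#' which equals the sum of `m` generalized Rayleigh quotients and, at the
#' optimum, the sum of the leading `m` eigenvalues of the underlying
#' propagator (variational bound).  `m = 1` always scores 1.
#'
#' Training states never visited in the test set make `A^T S A` singular; a
#' documented pseudocount fallback (1e-10 on the `S` diagonal) is applied
#' with a warning.
#'
#' @param model A `transition_model` fit on training labels.
#' @param test_label_trajs Held-out label trajectories on the same state
#'   space (labels outside the model's retained ergodic subset are dropped
#'   from the pair counts).
#' @param m Number of modes to score, including the stationary mode
#'   (default 3: stationary + two slow modes).
#' @return Scalar GMRQ score.
#' @export
gmrq_score <- function(model, test_label_trajs, m = 3L) {
  stopifnot(inherits(model, "transition_model"))
  n <- nrow(model$T)
  if (m > n) stop("m exceeds the number of states")
  lag <- if (!is.null(model$counts)) model$counts$lag else 1L
  states <- if (!is.null(model$counts)) model$counts$ergodic_subset
            else seq_len(n)
  if (!is.list(test_label_trajs)) test_label_trajs <- list(test_label_trajs)
  nf <- max(states, unlist(lapply(test_label_trajs, max)))
  Cfull <- matrix(0, nf, nf)
  got <- FALSE
  for (s in test_label_trajs) {
    if (length(s) <= lag) next
    got <- TRUE
    from <- s[seq_len(length(s) - lag)]
    to <- s[-seq_len(lag)]
    Cfull <- Cfull + matrix(tabulate((from - 1L) * nf + to, nf * nf),
                            nf, nf, byrow = TRUE)
  }
  if (!got) stop("test data contain no pairs at lag ", lag)
  C <- Cfull[states, states, drop = FALSE]
  ntot <- sum(C)
  if (ntot == 0) stop("test data never visit the model's states")
  Cs <- (C + t(C)) / (2 * ntot)
  svec <- rowSums(Cs)
  if (any(svec == 0)) {
    warning("training state(s) never visited in test set; ",
            "adding 1e-10 pseudocount to the overlap diagonal")
    svec <- svec + 1e-10
  }
  A <- model$psi[, seq_len(m), drop = FALSE]
  sa <- crossprod(A, svec * A)
  ca <- crossprod(A, Cs %*% A)
  sum(diag(solve(sa, ca)))
}

#' Cross-validated GMRQ model selection
#'
#' Trajectory-level k-fold cross-validation over a grid of MSM
#' hyperparameter settings.  Folds split whole trajectories (never frames),
#' preserving temporal correlation structure.  For each setting and fold the
#' pipeline tICA -> clustering -> reversible MSM is fit on the training
#' trajectories and scored on the held-out ones with [gmrq_score()];
#' settings that fail on a fold are recorded as `NA`, never dropped
#' silently.
#'
#' @param trajs List of feature trajectories (matrices or
#'   [feature_trajectory()] objects).
#' @param grid Data frame of settings with any of the columns `method`
#'   (`"kcenters"` or `"kmeans"`), `k`, `n_components`, `lag`; missing
#'   columns take the defaults `"kcenters"`, 50, 2, 1.
#' @param n_folds Number of folds (must not exceed the number of
#'   trajectories).
#' @param m Modes per score (default 3).
#' @param seed Seed for the shuffled fold assignment.
#' @param tica_lag Lag for the tICA stage (default 1 frame).
#' @return A `gmrq_result`: `scores` (tidy data frame: setting columns,
#'   `fold`, `train_score`, `test_score`), `summary` (mean and sd per
#'   setting), `best` (row index of the best mean test score),
#'   `fold_assignments`, `m`, `seed`.
#' @export
cross_validate_gmrq <- function(trajs, grid, n_folds = 5L, m = 3L, seed = 1L,
                                tica_lag = 1L) {
  if (length(trajs) < 2) stop("need at least 2 trajectories")
  if (n_folds > length(trajs)) stop("n_folds exceeds n_trajectories")
  grid <- as.data.frame(grid)
  if (is.null(grid$method)) grid$method <- "kcenters"
  if (is.null(grid$k)) grid$k <- 50L
  if (is.null(grid$n_components)) grid$n_components <- 2L
  if (is.null(grid$lag)) grid$lag <- 1L
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  shuffled <- sample(length(trajs))
  folds <- rep_len(seq_len(n_folds), length(trajs))[order(shuffled)]
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    st <- grid[g, ]
    for (f in seq_len(n_folds)) {
      train <- trajs[folds != f]
      test <- trajs[folds == f]
      res <- tryCatch({
        tica <- fit_tica(train, lag = tica_lag)
        ptr <- project_all(tica, train, st$n_components)
        cl <- if (st$method == "kmeans")
          k_means_lloyd(ptr$values, st$k)
        else k_centers(ptr$values, st$k)
        train_labels <- .split_labels(assign_states(cl, ptr$values),
                                      ptr$lengths)
        cm <- count_transitions(train_labels, lag = st$lag)
        msm <- estimate_reversible_mle(cm)
        test_labels <- lapply(test, function(x)
          assign_states(cl, project_tica(tica, x, st$n_components)))
        c(train = gmrq_score(msm, train_labels, m),
          test = gmrq_score(msm, test_labels, m))
      }, error = function(e) {
        warning("setting ", g, " fold ", f, " failed: ",
                conditionMessage(e))
        c(train = NA_real_, test = NA_real_)
      })
      rows[[length(rows) + 1L]] <-
        data.frame(setting = g, method = st$method, k = st$k,
                   n_components = st$n_components, lag = st$lag, fold = f,
                   train_score = res[["train"]], test_score = res[["test"]])
    }
  }
  scores <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(scores, scores$setting), function(d)
    data.frame(setting = d$setting[1], method = d$method[1], k = d$k[1],
               n_components = d$n_components[1], lag = d$lag[1],
               mean_test = mean(d$test_score, na.rm = TRUE),
               sd_test = stats::sd(d$test_score, na.rm = TRUE),
               mean_train = mean(d$train_score, na.rm = TRUE))))
  structure(list(scores = scores, summary = agg,
                 best = agg$setting[which.max(agg$mean_test)],
                 fold_assignments = folds, m = m, seed = seed),
            class = "gmrq_result")
}

.split_labels <- function(labels, lengths) {
  ends <- cumsum(lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  Map(function(a, b) labels[a:b], starts, ends)
}
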