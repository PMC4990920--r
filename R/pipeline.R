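.default_config <- function() {
  list(seed = 1, n_trajectories = 100, n_states = 4,
       length_mean = 500, length_max = 5000,
       emission_sd = 0.5, n_features = 10,
       tica_lag = 1, n_components = 2,
       cluster_method = "kcenters", k = 50,
       msm_lags = c(1, 2, 5, 10, 20), n_timescales = 2,
       dt = 1, n_macro = 0)
}

#' Run the simulate -> tICA -> cluster -> MSM pipeline
#'
#' Executes the full modeling chain on a synthetic trajectory ensemble with
#' planted ground truth: trajectory simulation from the built-in four-state
#' chain, tICA at `tica_lag`, k-centers (or k-means) discretization into `k`
#' microstates, reversible MSM estimation and implied-timescale curves over
#' `msm_lags`, and, if `n_macro > 0`, BACE coarse-graining.  Every stage
#' failure halts the run with the failing stage named; outputs written so
#' far are retained.
#'
#' The run directory receives the resolved configuration (`config.txt`),
#' per-trajectory label files, the cluster centers, the timescale table,
#' and a machine-readable `summary.txt` recording the slowest implied
#' timescale, the timescale gap ratio, the stationary entropy, and the
#' state/frame counts.  Reruns with the same seed and inputs are
#' byte-identical.
#'
#' @param config Named list of settings or path to a `key: value` file; see
#'   [read_config()].  Unspecified keys take documented defaults.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return Invisibly, a list with the fitted objects (`tica`, `clusters`,
#'   `msm`, `timescales`, optionally `macro`) and the `summary` list.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(.default_config(), config)
  unknown <- setdiff(names(config), names(.default_config()))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(cfg, file.path(out_dir, "config.txt"))
  }
  sim <- stage("simulate", {
    spec <- chain_spec(n_states = cfg$n_states,
                       emission_sd = cfg$emission_sd,
                       n_features = cfg$n_features,
                       length_mean = cfg$length_mean,
                       length_max = cfg$length_max,
                       n_trajectories = cfg$n_trajectories,
                       seed = cfg$seed)
    simulate_chain(spec)
  })
  tica <- stage("tica", fit_tica(sim$features, lag = cfg$tica_lag))
  proj <- stage("tica", project_all(tica, sim$features, cfg$n_components))
  cl <- stage("cluster", {
    if (identical(cfg$cluster_method, "kmeans"))
      k_means_lloyd(proj$values, cfg$k)
    else k_centers(proj$values, cfg$k)
  })
  labels <- stage("cluster",
                  .split_labels(assign_states(cl, proj$values), proj$lengths))
  msm <- stage("msm", {
    cm <- count_transitions(labels, lag = cfg$msm_lags[1], dt = cfg$dt)
    estimate_reversible_mle(cm)
  })
  ts_tab <- stage("timescales",
                  implied_timescale_curves(labels, sort(cfg$msm_lags),
                                           n_timescales = cfg$n_timescales,
                                           dt = cfg$dt))
  macro <- NULL
  if (cfg$n_macro > 0)
    macro <- stage("bace", bace_merge(msm$counts, cfg$n_macro))
  p <- msm$pi
  summary <- list(
    tau_1 = msm$implied_timescales[2],
    gap_ratio = msm$implied_timescales[2] / msm$implied_timescales[3],
    stationary_entropy = -sum(p[p > 0] * log(p[p > 0])),
    n_states = nrow(msm$T),
    n_frames = sum(proj$lengths),
    n_trajectories = length(labels))
  if (!is.null(out_dir)) {
    for (i in seq_along(labels))
      write_labels(labels[[i]],
                   file.path(out_dir, sprintf("labels_%04d.txt", i)))
    write_features(cl$centers, file.path(out_dir, "centers.txt"),
                   comments = c("stage: cluster",
                                paste0("method: ", cl$method),
                                paste0("k: ", cl$k)))
    utils::write.table(ts_tab, file.path(out_dir, "timescales.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_counts(msm$counts, file.path(out_dir, "counts.txt"))
    write_config(lapply(summary, function(v) signif(v, 12)),
                 file.path(out_dir, "summary.txt"))
  }
  invisible(list(tica = tica, clusters = cl, labels = labels, msm = msm,
                 timescales = ts_tab, macro = macro, summary = summary))
}
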