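#' Validate a table of docking records
#'
#' A dock-record table has one row per pose with columns `ligand_id`,
#' `receptor_id`, `pose_rank`, `score` (lower is better) and `rmsd`
#' (Angstrom versus the crystal pose).  Ranks must be unique within each
#' (ligand, receptor) cell and RMSDs non-negative.
#'
#' @param records Data frame of poses.
#' @return The validated data frame (invisibly classed `dock_records`).
#' @export
dock_records <- function(records) {
  need <- c("ligand_id", "receptor_id", "pose_rank", "score", "rmsd")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(records$rmsd < 0)) stop("negative pose RMSD")
  key <- paste(records$ligand_id, records$receptor_id)
  dup <- vapply(split(records$pose_rank, key), anyDuplicated, integer(1))
  if (any(dup > 0))
    stop("duplicate pose ranks within (ligand, receptor): ",
         paste(names(dup)[dup > 0], collapse = "; "))
  class(records) <- unique(c("dock_records", class(records)))
  records
}

#' Read a dock-record table from a tab-separated file
#'
#' @param file Path to a TSV with header
#'   `ligand_id receptor_id pose_rank score rmsd`.
#' @return A validated `dock_records` data frame.
#' @export
read_dock_records <- function(file) {
  dock_records(utils::read.table(file, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
}

#' Classify one docking outcome
#'
#' For the poses of one (ligand, receptor) pair: `"success"` if the
#' best-scoring pose is within `threshold` of the crystal pose;
#' `"scoring_failure"` if it is not but some sampled pose is (a correct pose
#' was generated, not top-scored); `"sampling_failure"` if no sampled pose
#' is within the threshold.
#'
#' @param records Data frame of poses for a single (ligand, receptor) pair
#'   with columns `score` and `rmsd`.
#' @param threshold Success RMSD threshold in Angstrom (default 2.0).
#' @return Character scalar outcome class.
#' @export
classify_outcome <- function(records, threshold = 2.0) {
  if (NROW(records) == 0) stop("no poses to classify")
  best_rmsd <- records$rmsd[which.min(records$score)]
  if (best_rmsd <= threshold) "success"
  else if (any(records$rmsd <= threshold)) "scoring_failure"
  else "sampling_failure"
}

#' Cross-docking outcome matrix
#'
#' Applies [classify_outcome()] to every (ligand, receptor) cell of a
#' dock-record table.  The three outcome classes partition the cells.
#'
#' @param records A `dock_records` table (or plain data frame).
#' @param threshold Success RMSD threshold in Angstrom (default 2.0).
#' @return Data frame with one row per (ligand, receptor): `ligand_id`,
#'   `receptor_id`, `best_score`, `best_score_rmsd`, `outcome`.
#' @export
outcome_matrix <- function(records, threshold = 2.0) {
  cells <- split(records,
                 list(records$ligand_id, records$receptor_id), drop = TRUE)
  out <- lapply(cells, function(d) {
    i <- which.min(d$score)
    data.frame(ligand_id = d$ligand_id[1], receptor_id = d$receptor_id[1],
               best_score = d$score[i], best_score_rmsd = d$rmsd[i],
               outcome = classify_outcome(d, threshold))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$ligand_id, out$receptor_id), ]
}

#' Pose RMSD in the receptor frame
#'
#' Root-mean-square deviation between a docked pose and the reference
#' (crystal) pose, computed in the receptor frame with no superposition
#' (the docking convention).  Atoms are matched by name when `name` columns
#' are present; unmatched names are an error.
#'
#' @param pose,reference Either numeric n x 3 coordinate matrices (matched
#'   row-by-row) or data frames with columns `name`, `x`, `y`, `z`.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(pose, reference) {
  as_xyz <- function(z) {
    if (is.data.frame(z) && all(c("name", "x", "y", "z") %in% names(z)))
      return(list(xyz = as.matrix(z[, c("x", "y", "z")]), names = z$name))
    list(xyz = as.matrix(z), names = NULL)
  }
  p <- as_xyz(pose); r <- as_xyz(reference)
  if (!is.null(p$names) && !is.null(r$names)) {
    unmatched <- c(setdiff(p$names, r$names), setdiff(r$names, p$names))
    if (length(unmatched))
      stop("unmatched atom name(s): ", paste(unique(unmatched), collapse = ", "))
    r$xyz <- r$xyz[match(p$names, r$names), , drop = FALSE]
  }
  if (nrow(p$xyz) != nrow(r$xyz))
    stop("atom counts differ: ", nrow(p$xyz), " vs ", nrow(r$xyz))
  sqrt(mean(rowSums((p$xyz - r$xyz)^2)))
}

#' Top-N true-positive enrichment curve
#'
#' For each ligand, receptors are ranked by their best pose score
#' (ascending; score ties broken by receptor id).  A ligand counts as
#' correctly docked at depth `N` if any of its top-`N` receptors is a
#' docking success.  `TPR(N)` is the fraction of ligands correct at `N`;
#' it is non-decreasing in `N` and reaches the ligand success fraction when
#' `N` spans all receptors.
#'
#' @param records A dock-record table covering at least `max(N_list)`
#'   receptors per ligand.
#' @param N_list Depths at which to evaluate the true positive rate.
#' @param threshold Success RMSD threshold (default 2.0 Angstrom).
#' @return Data frame with columns `N` and `tpr`.
#' @export
enrichment_curve <- function(records, N_list, threshold = 2.0) {
  om <- outcome_matrix(records, threshold)
  per_ligand <- split(om, om$ligand_id)
  nrec <- vapply(per_ligand, nrow, integer(1))
  if (any(nrec < max(N_list)))
    stop("every ligand needs at least max(N_list) = ", max(N_list),
         " scored receptors")
  first_success <- vapply(per_ligand, function(d) {
    d <- d[order(d$best_score, d$receptor_id), ]
    hit <- which(d$outcome == "success")
    if (length(hit)) hit[1] else Inf
  }, numeric(1))
  data.frame(N = N_list,
             tpr = vapply(N_list, function(N) mean(first_success <= N),
                          numeric(1)))
}

#' Funnel table: score versus pose RMSD per ligand
#'
#' Flat export of (score, rmsd) pairs for scatter plotting, with the
#' Spearman rank correlation between score and RMSD per ligand — a positive
#' correlation indicates a funnel-like landscape where low scores predict
#' good poses.
#'
#' @param records A dock-record table.
#' @return List with `table` (columns `ligand_id`, `receptor_id`, `score`,
#'   `rmsd`) and `correlations` (`ligand_id`, `spearman`).
#' @export
funnel_table <- function(records) {
  tab <- records[, c("ligand_id", "receptor_id", "score", "rmsd")]
  cors <- do.call(rbind, lapply(split(tab, tab$ligand_id), function(d)
    data.frame(ligand_id = d$ligand_id[1],
               spearman = stats::cor(d$score, d$rmsd, method = "spearman"))))
  rownames(cors) <- NULL
  list(table = tab, correlations = cors)
}
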