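#' Inter-residue contacts along a trajectory
#'
#' A residue pair is in contact in a frame when the chosen inter-residue
#' distance is below `cutoff`.  Two definitions are supported: the minimum
#' distance over heavy atoms (default, cutoff 4.5 Angstrom) and the
#' C-alpha--C-alpha distance (cutoff 8.0 Angstrom).
#'
#' @param frames List of per-frame atom tables: data frames with columns
#'   `resno`, `elety`, `x`, `y`, `z` (heavy atoms; hydrogens, if present,
#'   should be excluded by the caller).
#' @param pairs Two-column matrix of residue number pairs to evaluate.
#' @param cutoff Contact cutoff in Angstrom; defaults to 4.5 for
#'   `"heavy"` and 8.0 for `"ca"`.
#' @param definition `"heavy"` (minimum heavy-atom distance) or `"ca"`.
#' @return A `contact_trajectory`: `contacts` (frames x n_pairs logical
#'   matrix), `pair_labels`, `cutoff`, `definition`.
#' @export
compute_contacts <- function(frames, pairs, cutoff = NULL,
                             definition = c("heavy", "ca")) {
  definition <- match.arg(definition)
  if (is.null(cutoff)) cutoff <- if (definition == "heavy") 4.5 else 8.0
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (is.data.frame(frames)) frames <- list(frames)
  res_dist <- function(fr, ri, rj) {
    ai <- fr[fr$resno == ri, , drop = FALSE]
    aj <- fr[fr$resno == rj, , drop = FALSE]
    if (definition == "ca") {
      ai <- ai[ai$elety == "CA", , drop = FALSE]
      aj <- aj[aj$elety == "CA", , drop = FALSE]
    }
    if (nrow(ai) == 0 || nrow(aj) == 0)
      stop("missing atoms for residue pair (", ri, ", ", rj, ") under the '",
           definition, "' definition")
    xi <- as.matrix(ai[, c("x", "y", "z")])
    xj <- as.matrix(aj[, c("x", "y", "z")])
    sqrt(max(min(outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj)), 0))
  }
  contacts <- matrix(NA, length(frames), nrow(pairs))
  for (f in seq_along(frames)) for (p in seq_len(nrow(pairs)))
    contacts[f, p] <- res_dist(frames[[f]], pairs[p, 1], pairs[p, 2]) < cutoff
  labels <- paste0(pairs[, 1], "-", pairs[, 2])
  colnames(contacts) <- labels
  structure(list(contacts = contacts, pair_labels = labels,
                 pairs = pairs, cutoff = cutoff, definition = definition),
            class = "contact_trajectory")
}

#' Partition frames into quadrants of the tICA plane
#'
#' Quadrants are defined by the signs of `tIC1 - center1` and
#' `tIC2 - center2`, with centers at the per-component data medians
#' (robust to sign/offset conventions) or at zero.  Frames exactly on a
#' boundary go to the lower quadrant index, so a fully degenerate input is
#' assigned entirely to Q1.
#'
#' Quadrant labels: Q1 = (low, low), Q2 = (high, low), Q3 = (low, high),
#' Q4 = (high, high).
#'
#' @param projection A `tica_projection` or numeric matrix with at least two
#'   columns.
#' @param center `"median"` (default) or `"zero"`.
#' @return Factor of labels `Q1..Q4`, one per frame.
#' @export
quadrant_partition <- function(projection, center = c("median", "zero")) {
  center <- match.arg(center)
  v <- .projection_values(projection)
  if (ncol(v) < 2) stop("need at least two components for quadrants")
  c1 <- if (center == "median") stats::median(v[, 1]) else 0
  c2 <- if (center == "median") stats::median(v[, 2]) else 0
  q <- 1L + (v[, 1] > c1) + 2L * (v[, 2] > c2)
  factor(paste0("Q", q), levels = paste0("Q", 1:4))
}

#' Bayes-factor contact enrichment for a region of the landscape
#'
#' For each residue pair, compares the pseudocount-smoothed contact odds
#' inside a region against the odds over all frames:
#' `f = (k + a) / (n + 2a)` with pseudocount `a`, and
#' `BF = [f_r / (1 - f_r)] / [f_a / (1 - f_a)]`, the posterior odds ratio.
#' `BF > 1` marks contacts enriched in the region; the complement event has
#' exactly the reciprocal Bayes factor, and pseudocounts keep all values
#' finite and positive.
#'
#' @param contacts A `contact_trajectory` from [compute_contacts()].
#' @param region_labels Per-frame region labels (e.g. from
#'   [quadrant_partition()]).
#' @param region The region to score; must be non-empty.
#' @param pseudocount Smoothing pseudocount `a` (default 1).
#' @return An `enrichment_map`: data frame with `res_i`, `res_j`, `bf`, and
#'   attributes `region_id` and `pseudocount`.
#' @export
#' @examples
#' ## a pair always bound in a 10-frame region but rare overall gives BF 991
bayes_factor_map <- function(contacts, region_labels, region,
                             pseudocount = 1) {
  stopifnot(inherits(contacts, "contact_trajectory"))
  cmat <- contacts$contacts
  if (length(region_labels) != nrow(cmat))
    stop("region_labels length must equal the number of frames")
  inr <- region_labels == region
  if (!any(inr)) stop("empty region: ", region)
  a <- pseudocount
  odds <- function(k, n) {
    f <- (k + a) / (n + 2 * a)
    f / (1 - f)
  }
  k_r <- colSums(cmat[inr, , drop = FALSE]); n_r <- sum(inr)
  k_a <- colSums(cmat); n_a <- nrow(cmat)
  bf <- odds(k_r, n_r) / odds(k_a, n_a)
  out <- data.frame(res_i = contacts$pairs[, 1], res_j = contacts$pairs[, 2],
                    bf = unname(bf))
  attr(out, "region_id") <- as.character(region)
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("enrichment_map", "data.frame")
  out
}
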