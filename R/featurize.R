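#' Select binding-site residues by proximity to a bound ligand
#'
#' Returns the receptor residues having any atom within `cutoff` of any ligand
#' atom, together with a caller-supplied disordered-region ("lid") residue
#' range.  The union of the two lists is what distance featurization uses.
#' Residue numbering is 1-based PDB `resno`.
#'
#' @param receptor,ligand `bio3d` pdb objects or paths to PDB files.
#' @param cutoff Distance cutoff in Angstrom; must be > 0 (default 5).
#' @param lid_residues Residue indices of the disordered region (default
#'   `1:24`, the N-terminal lid).
#' @return A `residue_selection` list with sorted, duplicate-free `lid` and
#'   `site` residue vectors, the `cutoff`, and `index_base = 1`.
#' @export
select_binding_site <- function(receptor, ligand, cutoff = 5,
                                lid_residues = 1:24) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  rec <- .as_pdb(receptor)
  lig <- .as_pdb(ligand)
  if (nrow(lig$atom) == 0) stop("empty ligand: no atoms to define a site")
  rx <- as.matrix(rec$atom[, c("x", "y", "z")])
  lx <- as.matrix(lig$atom[, c("x", "y", "z")])
  ## min distance from each receptor atom to any ligand atom
  d2 <- outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * rx %*% t(lx)
  near <- sqrt(pmax(apply(d2, 1, min), 0)) <= cutoff
  site <- sort(unique(rec$atom$resno[near]))
  structure(list(lid = sort(unique(as.integer(lid_residues))),
                 site = as.integer(site),
                 cutoff = cutoff, index_base = 1L),
            class = "residue_selection")
}

.as_pdb <- function(x) {
  if (inherits(x, "pdb")) return(x)
  if (is.character(x) && length(x) == 1) {
    out <- tryCatch(bio3d::read.pdb(x, verbose = FALSE),
                    error = function(e) stop("cannot parse PDB file '", x,
                                             "': ", conditionMessage(e)))
    return(out)
  }
  stop("expected a bio3d 'pdb' object or a PDB file path")
}

#' Construct a feature trajectory
#'
#' Frames x features real matrix with a uniform time step.  Distance features
#' are in Angstrom.
#'
#' @param values Numeric matrix, one frame per row.  All entries finite.
#' @param dt Time per frame, ps (default 100, one snapshot).
#' @param feature_labels Optional character vector naming features (length
#'   must equal `ncol(values)`).
#' @param source_id Trajectory identifier.
#' @return A `feature_trajectory` object.
#' @export
feature_trajectory <- function(values, dt = 100, feature_labels = NULL,
                               source_id = "traj") {
  values <- as.matrix(values)
  if (nrow(values) < 1) stop("feature trajectory needs at least one frame")
  if (!all(is.finite(values))) stop("non-finite entries in feature trajectory")
  if (is.null(feature_labels))
    feature_labels <- paste0("f", seq_len(ncol(values)))
  if (length(feature_labels) != ncol(values))
    stop("feature_labels length must equal the number of features")
  colnames(values) <- feature_labels
  structure(list(values = values, dt = dt, feature_labels = feature_labels,
                 source_id = source_id),
            class = "feature_trajectory")
}

.feature_values <- function(x) {
  if (inherits(x, "feature_trajectory")) x$values else as.matrix(x)
}

#' Extract per-frame C-alpha coordinates from a (multi-model) PDB
#'
#' @param pdb A `bio3d` pdb object or PDB file path (multi-model supported).
#' @return List with `coords`, a frames x n_residues x 3 array, and
#'   `residue_ids`, the corresponding `resno` values.
#' @export
ca_coordinates <- function(pdb) {
  pdb <- if (is.character(pdb)) {
    tryCatch(bio3d::read.pdb(pdb, multi = TRUE, verbose = FALSE),
             error = function(e) stop("cannot parse PDB: ", conditionMessage(e)))
  } else pdb
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  if (length(sel$atom) == 0) stop("no C-alpha atoms found")
  resno <- pdb$atom$resno[sel$atom]
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  n_frames <- nrow(xyz)
  coords <- array(NA_real_, c(n_frames, length(resno), 3))
  for (f in seq_len(n_frames))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  list(coords = coords, residue_ids = as.integer(resno))
}

#' Pairwise C-alpha distance features
#'
#' Computes per-frame Euclidean distances (Angstrom) between C-alpha atoms of
#' selected residues.  Two pair rules are offered: `"all"` takes all unordered
#' pairs over the union of lid and site residues; `"cross"` takes only
#' lid x site pairs.  The rule used is recorded in the output labels header.
#'
#' @param coords frames x n_residues x 3 array of C-alpha coordinates (a
#'   single n x 3 matrix is treated as one frame), or the list returned by
#'   [ca_coordinates()].
#' @param selection A `residue_selection` from [select_binding_site()], or
#'   `NULL` to use all residues under the `"all"` rule.
#' @param residue_ids Residue numbers for the second array dimension; taken
#'   from `coords$residue_ids` when `coords` is a [ca_coordinates()] list.
#' @param pairs Pair rule, `"all"` or `"cross"`.
#' @param dt Time per frame, ps.
#' @param source_id Trajectory identifier.
#' @return A [feature_trajectory()] with labels `"d_i_j"` for residue pairs
#'   (i, j) and attribute `pair_rule`.
#' @export
pairwise_ca_distances <- function(coords, selection = NULL, residue_ids = NULL,
                                  pairs = c("all", "cross"), dt = 100,
                                  source_id = "traj") {
  pairs <- match.arg(pairs)
  if (is.list(coords) && !is.null(coords$coords)) {
    residue_ids <- coords$residue_ids
    coords <- coords$coords
  }
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  if (is.null(residue_ids)) residue_ids <- seq_len(dim(coords)[2])
  if (is.null(selection)) {
    use <- residue_ids
    pair_idx <- t(utils::combn(length(use), 2))
  } else {
    if (pairs == "all") {
      use <- sort(union(selection$lid, selection$site))
      pair_idx <- t(utils::combn(length(use), 2))
    } else {
      lid <- selection$lid
      site <- setdiff(selection$site, selection$lid)
      use <- c(lid, site)
      pair_idx <- as.matrix(expand.grid(seq_along(lid),
                                        length(lid) + seq_along(site)))
    }
    missing <- setdiff(use, residue_ids)
    if (length(missing))
      stop("missing C-alpha atom for residue(s) ",
           paste(missing, collapse = ", "))
  }
  col <- match(use, residue_ids)
  n_frames <- dim(coords)[1]
  if (anyNA(coords[, col, , drop = FALSE])) {
    bad <- which(apply(is.na(coords[, col, , drop = FALSE]), c(1, 2), any),
                 arr.ind = TRUE)
    stop("missing C-alpha coordinates for residue ", use[bad[1, 2]],
         " in frame ", bad[1, 1])
  }
  i <- pair_idx[, 1]; j <- pair_idx[, 2]
  vals <- matrix(0, n_frames, nrow(pair_idx))
  for (f in seq_len(n_frames)) {
    xyz <- coords[f, col, , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    dxyz <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
    vals[f, ] <- sqrt(rowSums(dxyz^2))
  }
  labels <- paste0("d_", use[i], "_", use[j])
  out <- feature_trajectory(vals, dt = dt, feature_labels = labels,
                            source_id = source_id)
  attr(out, "pair_rule") <- pairs
  out
}

#' Secondary-structure fractions from DSSP letter strings
#'
#' Maps DSSP assignments to helix (letters G, H, I) and sheet (letters B, E)
#' fractions.  Any other character, including unknown ones, counts as coil.
#'
#' @param dssp_string Character vector, one string per frame.
#' @return Data frame with one row per input string and columns `helix` and
#'   `sheet` (fractions in `[0, 1]`).
#' @export
#' @examples
#' ss_fractions("HHHGGGBEE")  # helix 6/9, sheet 3/9
ss_fractions <- function(dssp_string) {
  if (length(dssp_string) == 0 || any(!nzchar(dssp_string)))
    stop("empty DSSP string")
  count_in <- function(s, set) {
    ch <- strsplit(s, "")[[1]]
    sum(ch %in% set)
  }
  n <- nchar(dssp_string)
  helix <- vapply(dssp_string, count_in, numeric(1),
                  set = c("G", "H", "I")) / n
  sheet <- vapply(dssp_string, count_in, numeric(1),
                  set = c("B", "E")) / n
  data.frame(helix = unname(helix), sheet = unname(sheet))
}
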