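## Heavy-atom sidechain templates for the 20 standard amino acids.
## Per atom: element, number of polar (O-H / N-H) hydrogens, and whether the
## atom is sp3 (conjugated/aromatic/carbonyl atoms are not).  Protonation
## follows the dominant species at pH 7 (Asp/Glu deprotonated, Lys/Arg
## protonated, His neutral).  Bonds listed per residue; CA is the backbone
## attachment.
.aa_templates <- local({
  A <- function(name, element, polar_h = 0L, sp3 = TRUE)
    data.frame(name = name, element = element, polar_h = polar_h, sp3 = sp3)
  B <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  list(
    A = list(three = "ALA", atoms = A("CB", "C"), bonds = B("CA", "CB")),
    R = list(three = "ARG",
             atoms = rbind(A("CB", "C"), A("CG", "C"), A("CD", "C"),
                           A("NE", "N", 1L, FALSE), A("CZ", "C", 0L, FALSE),
                           A("NH1", "N", 2L, FALSE), A("NH2", "N", 2L, FALSE)),
             bonds = B("CA", "CB", "CB", "CG", "CG", "CD", "CD", "NE",
                       "NE", "CZ", "CZ", "NH1", "CZ", "NH2")),
    N = list(three = "ASN",
             atoms = rbind(A("CB", "C"), A("CG", "C", 0L, FALSE),
                           A("OD1", "O", 0L, FALSE), A("ND2", "N", 2L, FALSE)),
             bonds = B("CA", "CB", "CB", "CG", "CG", "OD1", "CG", "ND2")),
    D = list(three = "ASP",
             atoms = rbind(A("CB", "C"), A("CG", "C", 0L, FALSE),
                           A("OD1", "O", 0L, FALSE), A("OD2", "O", 0L, FALSE)),
             bonds = B("CA", "CB", "CB", "CG", "CG", "OD1", "CG", "OD2")),
    C = list(three = "CYS",
             atoms = rbind(A("CB", "C"), A("SG", "S", 1L)),
             bonds = B("CA", "CB", "CB", "SG")),
    Q = list(three = "GLN",
             atoms = rbind(A("CB", "C"), A("CG", "C"), A("CD", "C", 0L, FALSE),
                           A("OE1", "O", 0L, FALSE), A("NE2", "N", 2L, FALSE)),
             bonds = B("CA", "CB", "CB", "CG", "CG", "CD", "CD", "OE1",
                       "CD", "NE2")),
    E = list(three = "GLU",
             atoms = rbind(A("CB", "C"), A("CG", "C"), A("CD", "C", 0L, FALSE),
                           A("OE1", "O", 0L, FALSE), A("OE2", "O", 0L, FALSE)),
             bonds = B("CA", "CB", "CB", "CG", "CG", "CD", "CD", "OE1",
                       "CD", "OE2")),
    G = list(three = "GLY", atoms = NULL, bonds = NULL),
    H = list(three = "HIS",
             atoms = rbind(A("CB", "C"), A("CG", "C", 0L, FALSE),
                           A("ND1", "N", 1L, FALSE), A("CD2", "C", 0L, FALSE),
                           A("CE1", "C", 0L, FALSE), A("NE2", "N", 0L, FALSE)),
             bonds = B("CA", "CB", "CB", "CG", "CG", "ND1", "CG", "CD2",
                       "ND1", "CE1", "CD2", "NE2", "CE1", "NE2")),
    I = list(three = "ILE",
             atoms = rbind(A("CB", "C"), A("CG1", "C"), A("CG2", "C"),
                           A("CD1", "C")),
             bonds = B("CA", "CB", "CB", "CG1", "CB", "CG2", "CG1", "CD1")),
    L = list(three = "LEU",
             atoms = rbind(A("CB", "C"), A("CG", "C"), A("CD1", "C"),
                           A("CD2", "C")),
             bonds = B("CA", "CB", "CB", "CG", "CG", "CD1", "CG", "CD2")),
    K = list(three = "LYS",
             atoms = rbind(A("CB", "C"), A("CG", "C"), A("CD", "C"),
                           A("CE", "C"), A("NZ", "N", 3L)),
             bonds = B("CA", "CB", "CB", "CG", "CG", "CD", "CD", "CE",
                       "CE", "NZ")),
    M = list(three = "MET",
             atoms = rbind(A("CB", "C"), A("CG", "C"), A("SD", "S"),
                           A("CE", "C")),
             bonds = B("CA", "CB", "CB", "CG", "CG", "SD", "SD", "CE")),
    F = list(three = "PHE",
             atoms = rbind(A("CB", "C"), A("CG", "C", 0L, FALSE),
                           A("CD1", "C", 0L, FALSE), A("CD2", "C", 0L, FALSE),
                           A("CE1", "C", 0L, FALSE), A("CE2", "C", 0L, FALSE),
                           A("CZ", "C", 0L, FALSE)),
             bonds = B("CA", "CB", "CB", "CG", "CG", "CD1", "CG", "CD2",
                       "CD1", "CE1", "CD2", "CE2", "CE1", "CZ", "CE2", "CZ")),
    P = list(three = "PRO",
             atoms = rbind(A("CB", "C"), A("CG", "C"), A("CD", "C")),
             bonds = B("CA", "CB", "CB", "CG", "CG", "CD", "CD", "N")),
    S = list(three = "SER",
             atoms = rbind(A("CB", "C"), A("OG", "O", 1L)),
             bonds = B("CA", "CB", "CB", "OG")),
    T = list(three = "THR",
             atoms = rbind(A("CB", "C"), A("OG1", "O", 1L), A("CG2", "C")),
             bonds = B("CA", "CB", "CB", "OG1", "CB", "CG2")),
    W = list(three = "TRP",
             atoms = rbind(A("CB", "C"), A("CG", "C", 0L, FALSE),
                           A("CD1", "C", 0L, FALSE), A("CD2", "C", 0L, FALSE),
                           A("NE1", "N", 1L, FALSE), A("CE2", "C", 0L, FALSE),
                           A("CE3", "C", 0L, FALSE), A("CZ2", "C", 0L, FALSE),
                           A("CZ3", "C", 0L, FALSE), A("CH2", "C", 0L, FALSE)),
             bonds = B("CA", "CB", "CB", "CG", "CG", "CD1", "CG", "CD2",
                       "CD1", "NE1", "NE1", "CE2", "CD2", "CE2",
                       "CD2", "CE3", "CE2", "CZ2", "CE3", "CZ3",
                       "CZ2", "CH2", "CZ3", "CH2")),
    Y = list(three = "TYR",
             atoms = rbind(A("CB", "C"), A("CG", "C", 0L, FALSE),
                           A("CD1", "C", 0L, FALSE), A("CD2", "C", 0L, FALSE),
                           A("CE1", "C", 0L, FALSE), A("CE2", "C", 0L, FALSE),
                           A("CZ", "C", 0L, FALSE), A("OH", "O", 1L, FALSE)),
             bonds = B("CA", "CB", "CB", "CG", "CG", "CD1", "CG", "CD2",
                       "CD1", "CE1", "CD2", "CE2", "CE1", "CZ", "CE2", "CZ",
                       "CZ", "OH")),
    V = list(three = "VAL",
             atoms = rbind(A("CB", "C"), A("CG1", "C"), A("CG2", "C")),
             bonds = B("CA", "CB", "CB", "CG1", "CB", "CG2"))
  )
})

#' Describe a peptide ligand
#'
#' @param sequence One-letter amino-acid string (standard residues only).
#' @param n_term N-terminus form: `"charged"` (NH3+, default) or
#'   `"neutral"` (NH2).
#' @param c_term C-terminus form: `"charged"` (COO-, default) or
#'   `"neutral"` (COOH).
#' @param cyclized Add the artificial backbone-rigidifying bond between the
#'   terminal alpha-carbons (default `FALSE`).  The variant bond between the
#'   backbone N- and C-termini is selected in [build_peptide_topology()].
#' @return A `peptide_ligand` object.
#' @export
peptide_ligand <- function(sequence, n_term = c("charged", "neutral"),
                           c_term = c("charged", "neutral"),
                           cyclized = FALSE) {
  n_term <- match.arg(n_term)
  c_term <- match.arg(c_term)
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("sequence must be a non-empty one-letter string")
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(letters1, names(.aa_templates))
  if (length(unknown))
    stop("unknown residue letter(s): ", paste(unique(unknown), collapse = ", "))
  structure(list(sequence = paste(letters1, collapse = ""),
                 residues = letters1, n_term = n_term, c_term = c_term,
                 cyclized = isTRUE(cyclized)),
            class = "peptide_ligand")
}

#' Build the heavy-atom bond graph of a peptide, with ring perception
#'
#' Assembles backbone and sidechain heavy atoms from residue templates,
#' joins residues by peptide bonds, optionally closes the artificial
#' rigidifying macrocycle, and perceives rings: a bond is in a ring exactly
#' when it is not a bridge of the bond graph, which covers aromatic rings,
#' the proline pyrrolidine, and the artificial macrocycle uniformly.
#'
#' @param ligand A [peptide_ligand()] or a plain sequence string (then built
#'   with charged termini, linear).
#' @param cyclization_bond Where the artificial bond is placed when the
#'   ligand is cyclized: `"calpha"` (between terminal alpha-carbons, the
#'   default) or `"termini"` (between the backbone N and C terminal atoms).
#' @return A `peptide_topology`: `atoms` (data frame: `idx`, `res_index`,
#'   `res_name`, `name`, `element`, `polar_h`, `sp3`), `bonds` (data frame:
#'   `a`, `b`, `in_ring`, `artificial`), `graph` (igraph object), and the
#'   `ligand`.
#' @export
build_peptide_topology <- function(ligand,
                                   cyclization_bond = c("calpha", "termini")) {
  cyclization_bond <- match.arg(cyclization_bond)
  if (is.character(ligand)) ligand <- peptide_ligand(ligand)
  stopifnot(inherits(ligand, "peptide_ligand"))
  nres <- length(ligand$residues)
  if (ligand$cyclized && nres < 2)
    stop("cyclization needs at least 2 residues")
  atoms <- list(); bonds <- list()
  aid <- function(res, name) paste0(res, "/", name)
  for (i in seq_len(nres)) {
    tpl <- .aa_templates[[ligand$residues[i]]]
    is_pro <- tpl$three == "PRO"
    ## backbone N: sp3 protonated amine at residue 1, planar amide otherwise
    n_h <- if (i == 1L) {
      base <- if (is_pro) 1L else 2L
      base + (ligand$n_term == "charged")
    } else if (is_pro) 0L else 1L
    bb <- data.frame(
      name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      polar_h = c(n_h, 0L, 0L, 0L),
      sp3 = c(i == 1L, TRUE, FALSE, FALSE))
    res_atoms <- rbind(bb, tpl$atoms)
    res_atoms$res_index <- i
    res_atoms$res_name <- tpl$three
    atoms[[i]] <- res_atoms
    rb <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"), tpl$bonds)
    bonds[[i]] <- data.frame(a = aid(i, rb[, 1]), b = aid(i, rb[, 2]))
    if (i > 1)
      bonds[[i]] <- rbind(bonds[[i]],
                          data.frame(a = aid(i - 1, "C"), b = aid(i, "N")))
  }
  ## C-terminal carboxylate / carboxylic acid oxygen
  oxt <- data.frame(name = "OXT", element = "O",
                    polar_h = as.integer(ligand$c_term == "neutral"),
                    sp3 = FALSE, res_index = nres,
                    res_name = atoms[[nres]]$res_name[1])
  atoms[[nres]] <- rbind(atoms[[nres]], oxt)
  bonds[[nres + 1L]] <- data.frame(a = aid(nres, "C"), b = aid(nres, "OXT"))
  atoms <- do.call(rbind, atoms)
  atoms$idx <- seq_len(nrow(atoms))
  atoms$atom_id <- paste0(atoms$res_index, "/", atoms$name)
  bonds <- do.call(rbind, bonds)
  bonds$artificial <- FALSE
  if (ligand$cyclized) {
    art <- if (cyclization_bond == "calpha")
      data.frame(a = aid(1, "CA"), b = aid(nres, "CA"), artificial = TRUE)
    else
      data.frame(a = aid(1, "N"), b = aid(nres, "C"), artificial = TRUE)
    bonds <- rbind(bonds, art)
  }
  g <- igraph::graph_from_data_frame(bonds[, c("a", "b")], directed = FALSE,
                                     vertices = atoms$atom_id)
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nrow(bonds))
  in_ring[as.integer(br)] <- FALSE
  bonds$in_ring <- in_ring
  rownames(atoms) <- rownames(bonds) <- NULL
  structure(list(atoms = atoms, bonds = bonds, graph = g, ligand = ligand,
                 cyclization_bond = if (ligand$cyclized) cyclization_bond
                                    else NA_character_),
            class = "peptide_topology")
}

#' Count rotatable torsions of a peptide under the DOCK-style convention
#'
#' A bond is a rotatable torsion when it is a single, acyclic (non-ring)
#' bond and either
#' \itemize{
#'   \item both of its atoms have at least one further heavy-atom neighbor
#'     (rotation moves heavy atoms on both sides), or
#'   \item its terminal atom is an sp3 oxygen or nitrogen carrying at least
#'     one polar hydrogen, attached to an sp3 atom (hydroxyl and amine
#'     rotors: Ser/Thr/Cys, Lys NZ, the charged or neutral N-terminal
#'     amine).
#' }
#' Consequences of the convention: backbone phi, psi and amide omega bonds
#' count in the linear form; all bonds inside any perceived ring — aromatic
#' rings, the proline pyrrolidine, and the artificial rigidifying macrocycle
#' — are rigid; methyl and other all-hydrogen carbon rotors are not counted;
#' the tyrosine phenol and the Asn/Gln amide N-H are excluded as conjugated;
#' the terminal alpha-carbon--carboxylate bond and the N-terminal amine
#' remain rotatable after alpha-carbon cyclization because they dangle
#' outside the macrocycle.
#'
#' @param topology A `peptide_topology` from [build_peptide_topology()].
#' @return A `torsion_count`: `total`, `by_category` (named integer vector:
#'   `backbone_phi`, `backbone_psi`, `backbone_omega`, `sidechain_heavy`,
#'   `polar_hydrogen_rotors`, `terminal_rotors`), `rotatable` (logical per
#'   bond), and `excluded_terminal` (all-hydrogen terminal bonds that were
#'   not counted).
#' @export
#' @examples
#' count_torsions(build_peptide_topology("ETFSDLWKLLPE"))$total          # 61
#' count_torsions(build_peptide_topology(
#'   peptide_ligand("ETFSDLWKLLPE", cyclized = TRUE)))$total             # 29
count_torsions <- function(topology) {
  stopifnot(inherits(topology, "peptide_topology"))
  atoms <- topology$atoms
  bonds <- topology$bonds
  deg <- igraph::degree(topology$graph)[atoms$atom_id]
  lookup <- function(id) atoms[match(id, atoms$atom_id), ]
  cats <- c(backbone_phi = 0L, backbone_psi = 0L, backbone_omega = 0L,
            sidechain_heavy = 0L, polar_hydrogen_rotors = 0L,
            terminal_rotors = 0L)
  rotatable <- logical(nrow(bonds))
  excluded_terminal <- 0L
  for (r in seq_len(nrow(bonds))) {
    if (bonds$in_ring[r]) next
    a <- lookup(bonds$a[r]); b <- lookup(bonds$b[r])
    da <- deg[[a$atom_id]]; db <- deg[[b$atom_id]]
    if (da >= 2 && db >= 2) {
      nm <- sort(c(a$name, b$name))
      cat <- if (a$res_index == b$res_index && identical(nm, c("CA", "N")))
        "backbone_phi"
      else if (a$res_index == b$res_index && identical(nm, c("C", "CA")))
        "backbone_psi"
      else if (a$res_index != b$res_index && identical(nm, c("C", "N")))
        "backbone_omega"
      else "sidechain_heavy"
      cats[cat] <- cats[cat] + 1L
      rotatable[r] <- TRUE
    } else {
      term <- if (da == 1) a else b
      anchor <- if (da == 1) b else a
      if (term$polar_h >= 1 && term$sp3 && anchor$sp3) {
        cats["polar_hydrogen_rotors"] <- cats["polar_hydrogen_rotors"] + 1L
        rotatable[r] <- TRUE
      } else {
        excluded_terminal <- excluded_terminal + 1L
      }
    }
  }
  structure(list(total = sum(cats), by_category = cats,
                 rotatable = rotatable,
                 excluded_terminal = excluded_terminal),
            class = "torsion_count")
}

#' @export
print.torsion_count <- function(x, ...) {
  cat("Rotatable torsions:", x$total, "\n")
  for (nm in names(x$by_category))
    cat(sprintf("  %-22s %d\n", nm, x$by_category[[nm]]))
  invisible(x)
}

#' Report rigid segments of a peptide topology
#'
#' Lists the connected rigid fragments obtained by deleting all rotatable
#' bonds, for anchor selection reporting: fragments with at least
#' `min_atoms` heavy atoms are candidate anchors (no search is performed).
#'
#' @param topology A `peptide_topology`.
#' @param min_atoms Minimum fragment size to report (default 5).
#' @return Data frame with one row per rigid segment: `segment`, `n_atoms`,
#'   `atoms` (comma-separated atom ids).
#' @export
rigid_segments <- function(topology, min_atoms = 5L) {
  tc <- count_torsions(topology)
  keep <- topology$bonds[!tc$rotatable, c("a", "b")]
  g <- igraph::graph_from_data_frame(keep, directed = FALSE,
                                     vertices = topology$atoms$atom_id)
  comp <- igraph::components(g)
  sizes <- comp$csize
  segs <- which(sizes >= min_atoms)
  out <- lapply(seq_along(segs), function(k) {
    ids <- names(comp$membership)[comp$membership == segs[k]]
    data.frame(segment = k, n_atoms = length(ids),
               atoms = paste(ids, collapse = ","))
  })
  if (!length(out))
    return(data.frame(segment = integer(0), n_atoms = integer(0),
                      atoms = character(0)))
  do.call(rbind, out)
}
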