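test_that("peptide topology builds open backbones and closed macrocycles", {
  lin <- build_peptide_topology("GG")
  expect_true(all(!lin$bonds$in_ring))   # no rings anywhere in GG
  cyc <- build_peptide_topology(peptide_ligand("GG", cyclized = TRUE))
  ca_ids <- cyc$atoms$atom_id[cyc$atoms$name == "CA"]
  ring_bonds <- cyc$bonds[cyc$bonds$in_ring, ]
  expect_true(all(ca_ids %in% c(ring_bonds$a, ring_bonds$b)))
  expect_true(any(cyc$bonds$artificial & cyc$bonds$in_ring))
  expect_error(peptide_ligand("GXG"), "unknown residue")
})

test_that("the p53 peptide macrocycle spans all alpha-carbons", {
  top <- build_peptide_topology(peptide_ligand("ETFSDLWKLLPE",
                                               cyclized = TRUE))
  ca <- top$atoms[top$atoms$name == "CA", ]
  expect_identical(nrow(ca), 12L)
  ring_atoms <- unique(unlist(top$bonds[top$bonds$in_ring, c("a", "b")]))
  expect_true(all(ca$atom_id %in% ring_atoms))
  ## the proline pyrrolidine is perceived as a separate ring
  pro <- top$atoms[top$atoms$res_name == "PRO", ]
  pro_ring <- top$bonds$in_ring[top$bonds$a %in% pro$atom_id &
                                  top$bonds$b %in% pro$atom_id]
  expect_true(any(pro_ring))
})

test_that("torsion accounting matches the documented convention peptide by peptide", {
  count <- function(seq, cyclized = FALSE)
    count_torsions(build_peptide_topology(
      peptide_ligand(seq, cyclized = cyclized)))
  lin <- count("ETFSDLWKLLPE")
  expect_identical(lin$total, 61L)
  expect_identical(unname(lin$by_category["backbone_phi"]), 10L)  # Pro rigid
  expect_identical(unname(lin$by_category["backbone_psi"]), 12L)
  expect_identical(unname(lin$by_category["backbone_omega"]), 11L)
  expect_identical(unname(lin$by_category["sidechain_heavy"]), 24L)
  expect_identical(unname(lin$by_category["polar_hydrogen_rotors"]), 4L)
  cyc <- count("ETFSDLWKLLPE", cyclized = TRUE)
  expect_identical(cyc$total, 29L)
  expect_identical(count("TSFAEYWALLSP", cyclized = TRUE)$total, 21L)
  ## the full crystallographic p53 TAD fragment in linear form
  expect_identical(count("ETFSDLWKLLPEN")$total, 66L)
  ## single-residue sanity: free glycine has amine + C-terminal rotor
  expect_identical(count("G")$total, 2L)
})

test_that("cyclization removes exactly the rotors absorbed into the macrocycle", {
  for (seq in c("ETFSDLWKLLPE", "TSFAEYWALLSP", "ACDEFGHIKLMN")) {
    lin_top <- build_peptide_topology(seq)
    cyc_top <- build_peptide_topology(peptide_ligand(seq, cyclized = TRUE))
    lin <- count_torsions(lin_top)
    cyc <- count_torsions(cyc_top)
    expect_lte(cyc$total, lin$total)
    ## bonds rotatable in the linear form that lie in a ring once cyclized
    key <- function(top) paste(top$bonds$a, top$bonds$b)
    absorbed <- sum(lin$rotatable &
                      key(lin_top) %in% key(cyc_top)[cyc_top$bonds$in_ring])
    expect_identical(lin$total - cyc$total, as.integer(absorbed))
  }
})

test_that("rigid segments of five or more atoms are reported as anchors", {
  top <- build_peptide_topology(peptide_ligand("ETFSDLWKLLPE",
                                               cyclized = TRUE))
  segs <- rigid_segments(top, min_atoms = 5)
  expect_gte(nrow(segs), 3)  # macrocycle, Phe and Trp rings at least
  expect_true(any(segs$n_atoms >= 12))  # the backbone macrocycle
})

test_that("outcome classification follows the 2 Angstrom success rule", {
  rec <- data.frame(score = c(-30, -20, -10), rmsd = c(1.2, 3.0, 6.0))
  expect_identical(classify_outcome(rec), "success")
  rec2 <- data.frame(score = c(-30, -20), rmsd = c(3.5, 1.8))
  expect_identical(classify_outcome(rec2), "scoring_failure")
  rec3 <- data.frame(score = c(-30, -20), rmsd = c(2.1, 4.0))
  expect_identical(classify_outcome(rec3), "sampling_failure")
  expect_error(classify_outcome(rec[0, ]), "no poses")
})

test_that("pose RMSD matches the per-atom formula with no superposition", {
  set.seed(9)
  a <- matrix(rnorm(30), ncol = 3)
  expect_equal(pose_rmsd(a, a), 0)
  expect_equal(pose_rmsd(a + rep(c(3, 0, 0), each = 10), a), 3)
  b <- a + matrix(rnorm(30, sd = 0.5), ncol = 3)
  expect_equal(pose_rmsd(a, b), sqrt(mean(rowSums((a - b)^2))))
  ## name-based correspondence reorders atoms and flags mismatches
  pa <- data.frame(name = paste0("C", 1:5), x = rnorm(5), y = rnorm(5),
                   z = rnorm(5))
  pb <- pa[c(3, 1, 5, 2, 4), ]
  expect_equal(pose_rmsd(pa, pb), 0)
  pb2 <- pb; pb2$name[1] <- "ZZ"
  expect_error(pose_rmsd(pa, pb2), "ZZ")
})

test_that("enrichment curves match hand-enumerated true positive rates", {
  mk <- function(lig, first_success, n_rec = 10) {
    do.call(rbind, lapply(seq_len(n_rec), function(r)
      data.frame(ligand_id = lig, receptor_id = sprintf("r%02d", r),
                 pose_rank = 1L, score = r,
                 rmsd = if (r == first_success) 1 else 5)))
  }
  rec <- rbind(mk("L1", 1), mk("L2", 1), mk("L3", 3), mk("L4", 7))
  expect_equal(enrichment_curve(rec, N_list = 3)$tpr, 0.75)
  expect_equal(enrichment_curve(rec, c(1, 2, 3, 7, 10))$tpr,
               c(0.5, 0.5, 0.75, 1, 1))
  one <- mk("L1", 3)
  expect_equal(enrichment_curve(one, c(2, 3))$tpr, c(0, 1))
  none <- mk("L1", 0)    # no success anywhere
  expect_true(all(enrichment_curve(none, c(1, 5, 10))$tpr == 0))
})

test_that("funnel tables report exact Spearman correlations", {
  rec <- data.frame(ligand_id = "L", receptor_id = sprintf("r%02d", 1:20),
                    pose_rank = 1L, score = 1:20, rmsd = (1:20) / 2)
  expect_equal(funnel_table(rec)$correlations$spearman, 1)
  rec$rmsd <- rev(rec$rmsd)
  expect_equal(funnel_table(rec)$correlations$spearman, -1)
  set.seed(13)
  rec$rmsd <- rec$score + rnorm(20, sd = 4)
  expect_equal(funnel_table(rec)$correlations$spearman,
               cor(rec$score, rec$rmsd, method = "spearman"))
})

test_that("dock record validation catches malformed tables", {
  rec <- data.frame(ligand_id = "L", receptor_id = "R", pose_rank = c(1, 1),
                    score = c(-1, -2), rmsd = c(1, 2))
  expect_error(dock_records(rec), "duplicate pose ranks")
  rec$pose_rank <- 1:2
  expect_silent(dock_records(rec))
  rec$rmsd[1] <- -0.1
  expect_error(dock_records(rec), "negative")
})
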