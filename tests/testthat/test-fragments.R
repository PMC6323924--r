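test_that("molecules below the heavy-atom floor yield no fragments", {
  expect_equal(nrow(fragment_molecule("CC")), 0)          # ethane
  expect_equal(nrow(fragment_molecule("c1ccccc1")), 0)    # no acyclic bonds
})

test_that("a linear C14 alkane fragments to the four long sub-chains", {
  fr <- fragment_molecule(strrep("C", 14))
  # sub-chains of length 10-13; equal-length internal and terminal chains
  # deduplicate to one canonical SMILES each
  expect_equal(sort(fr$smiles),
               sort(vapply(10:13, function(k) strrep("C", k), character(1))))
  expect_equal(sort(fr$heavy_atoms), 10:13)
})

test_that("fragmentation matches an independent cut-set enumeration", {
  panel <- c(
    "CCCCCCCCCCCC",              # linear C12
    "CC(C)CCCCCCCC",             # branched C11
    "CCc1ccc(-c2ccccc2)cc1",     # decorated biphenyl
    "CC(=O)Nc1ccc(O)cc1",        # anilide with heteroatoms
    "CCOCCc1ccccc1",             # ether linker
    "CC(C)(C)c1ccc(CN)cc1",      # quaternary branch point
    "c1ccc(-c2ccccc2)cc1"        # exactly one cuttable bond
  )
  for (smi in panel) {
    got <- fragment_molecule(smi, max_cuts = 3, min_heavy_atoms = 6)
    want <- enum_fragments_oracle(smi, max_cuts = 3, min_heavy = 6)
    expect_equal(sort(got$smiles), want, info = smi)
  }
})

test_that("every fragment is a substructure of its parent", {
  panel <- c("CCc1ccc(-c2ccccc2)cc1", "CC(=O)Nc1ccc(O)cc1",
             "CCOCCc1ccccc1")
  for (smi in panel) {
    fr <- fragment_molecule(smi, min_heavy_atoms = 6)
    for (f in fr$smiles) expect_true(is_substructure(f, smi), info = f)
  }
})

test_that("fragmentation is invariant to the input atom ordering", {
  forms <- c("CC(=O)Nc1ccc(OCC)cc1", "CCOc1ccc(NC(=O)C)cc1",
             "O(CC)c1ccc(cc1)NC(C)=O")
  sets <- lapply(forms, function(s) {
    sort(fragment_molecule(s, min_heavy_atoms = 5)$smiles)
  })
  expect_equal(sets[[2]], sets[[1]])
  expect_equal(sets[[3]], sets[[1]])
})

test_that("multi-component and garbage SMILES are rejected", {
  expect_error(fragment_molecule("CCCCCCCCCC.CCCCCCCCCC"), "multi-component")
  expect_error(fragment_molecule("xx(("), "parse")
})

test_that("clustering groups duplicates and separates dissimilar molecules", {
  dup <- tibble::tibble(
    smiles = rep("CCCCCCCCCC", 5),
    heavy_atoms = rep(10L, 5),
    parents = as.list(paste0("L", 1:5))
  )
  out <- cluster_fragments(dup)
  expect_equal(unique(out$cluster_id), 1L)
  expect_equal(sum(out$is_representative), 1)
  expect_equal(out$smiles[out$is_representative], "CCCCCCCCCC")

  two <- tibble::tibble(
    smiles = c("c1ccccc1", "CCCCCCCCCC"),
    heavy_atoms = c(6L, 10L),
    parents = as.list(c("a", "b"))
  )
  expect_equal(dplyr::n_distinct(cluster_fragments(two)$cluster_id), 2)
})

test_that("clustering matches a straight-line leader loop", {
  set.seed(42)
  pool <- c(
    vapply(6:12, function(k) strrep("C", k), character(1)),
    "CCOCC", "CCOCCO", "CCNCC", "CCCNCCC", "c1ccccc1", "Cc1ccccc1",
    "CCc1ccccc1", "c1ccncc1", "Cc1ccncc1", "CC(C)CC", "CC(C)CCC",
    "CC(C)(C)CC", "OCCCCO", "OCCCCCO", "NCCCCN", "c1ccc(O)cc1",
    "c1ccc(N)cc1", "c1ccc(F)cc1", "CCCOC", "CCCOCC", "CCCCOC",
    "CCSCC", "CCCSC", "CCCSCC"
  )
  frags <- tibble::tibble(
    smiles = pool,
    heavy_atoms = kinconform:::heavy_atom_count(pool),
    parents = as.list(pool)
  )
  got <- cluster_fragments(frags, cutoff = 0.90)
  want <- leader_oracle(frags$smiles, frags$heavy_atoms, cutoff = 0.90)
  expect_equal(got$smiles, want$smiles)
  expect_equal(got$cluster_id, want$cluster)
})

test_that("cutoff 1 merges exactly identical fingerprints, tiny cutoff merges kin", {
  pool <- c(strrep("C", 8), strrep("C", 9), strrep("C", 10), "CCCCCCCCO",
            "CCCCCCCN")
  frags <- tibble::tibble(
    smiles = pool,
    heavy_atoms = kinconform:::heavy_atom_count(pool),
    parents = as.list(letters[1:5])
  )
  strict <- cluster_fragments(frags, cutoff = 1)
  # cluster count equals the number of distinct bit sets (long alkane
  # homologues legitimately share every radius-2 environment)
  fps <- lapply(pool, morgan_fingerprint)
  n_distinct_fp <- length(unique(vapply(fps, paste, character(1),
                                        collapse = ",")))
  expect_equal(dplyr::n_distinct(strict$cluster_id), n_distinct_fp)
  # within a cluster, members match the representative fingerprint exactly
  for (cl in unique(strict$cluster_id)) {
    members <- which(strict$cluster_id == cl)
    rep_fp <- morgan_fingerprint(strict$smiles[strict$cluster_id == cl &
                                                 strict$is_representative])
    for (i in members) {
      expect_equal(tanimoto(morgan_fingerprint(strict$smiles[i]), rep_fp), 1)
    }
  }
  # everything with any shared environment merges as the cutoff vanishes
  loose <- cluster_fragments(frags, cutoff = 1e-6)
  expect_equal(dplyr::n_distinct(loose$cluster_id), 1)
})

test_that("pocket ligand extraction respects distance and the additive list", {
  near <- make_toy_kinase(ligand = list(resname = "STU", resno = 401,
                                        offset = c(0, 0, 3)))
  got <- extract_pocket_ligands(near$structure, near$motifs)
  expect_equal(got$ligand_id, "STU_401")
  expect_lte(got$min_dist, 6)

  far <- make_toy_kinase(ligand = list(resname = "STU", resno = 401,
                                       offset = c(20, 0, 0)))
  expect_equal(nrow(extract_pocket_ligands(far$structure, far$motifs)), 0)

  water <- make_toy_kinase(ligand = list(resname = "HOH", resno = 501,
                                         offset = c(0, 0, 3)))
  expect_equal(nrow(extract_pocket_ligands(water$structure, water$motifs)), 0)
})
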