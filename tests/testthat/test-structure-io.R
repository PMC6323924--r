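test_that("a minimal synthetic PDB parses to an identity structure", {
  txt <- c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0),
    pdb_line(3, "C", "ALA", "A", 1, 3.0, 0, 0),
    pdb_line(4, "CA", "GLY", "A", 2, 5.0, 0, 0),
    pdb_line(5, "CA", "SER", "A", 3, 8.5, 0, 0)
  )
  s <- read_kinase_pdb(paste(txt, collapse = "\n"))
  expect_s3_class(s, "kinase_structure")
  expect_equal(nrow(s$residues), 3)
  expect_equal(s$residues$resname, c("ALA", "GLY", "SER"))
  expect_equal(s$chain_id, "A")
  expect_equal(s$atoms$x[s$atoms$atom == "CA"], c(1.5, 5.0, 8.5))
})

test_that("chain selection honours the hint and rejects absent chains", {
  txt <- c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "B", 1, 5, 0, 0),
    pdb_line(3, "CA", "SER", "B", 2, 8, 0, 0)
  )
  sB <- read_kinase_pdb(txt, chain = "B")
  expect_equal(sB$residues$resname, c("GLY", "SER"))
  sA <- read_kinase_pdb(txt)  # first protein chain by default
  expect_equal(sA$residues$resname, "ALA")
  expect_error(read_kinase_pdb(txt, chain = "C"), "not found")
})

test_that("alternate locations resolve to altloc A or highest occupancy", {
  txt <- c(
    pdb_line(1, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.4, alt = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 2.0, 0, 0, occ = 0.6, alt = "B"),
    pdb_line(3, "CA", "GLY", "A", 2, 4.0, 0, 0)
  )
  s <- read_kinase_pdb(txt)
  ca1 <- s$atoms[s$atoms$ordinal == 1 & s$atoms$atom == "CA", ]
  expect_equal(nrow(ca1), 1)
  expect_equal(ca1$altloc, "A")    # 'A' preferred despite lower occupancy
  expect_equal(ca1$x, 1.0)

  # no A/blank present: highest occupancy wins
  txt2 <- c(
    pdb_line(1, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.3, alt = "B"),
    pdb_line(2, "CA", "ALA", "A", 1, 2.0, 0, 0, occ = 0.7, alt = "C"),
    pdb_line(3, "CA", "GLY", "A", 2, 4.0, 0, 0)
  )
  s2 <- read_kinase_pdb(txt2)
  ca2 <- s2$atoms[s2$atoms$ordinal == 1 & s2$atoms$atom == "CA", ]
  expect_equal(ca2$x, 2.0)
})

test_that("protein HETATM residues stay in the chain, others become ligands", {
  txt <- c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "SEP", "A", 2, 3.8, 0, 0, type = "HETATM"),
    pdb_line(3, "CA", "GLY", "A", 3, 7.6, 0, 0),
    pdb_line(4, "O", "HOH", "A", 101, 20, 0, 0, type = "HETATM"),
    pdb_line(5, "C1", "STU", "A", 201, 10, 5, 0, type = "HETATM")
  )
  s <- read_kinase_pdb(txt)
  expect_equal(s$residues$resname, c("ALA", "SEP", "GLY"))
  expect_setequal(s$ligand_atoms$resname, c("HOH", "STU"))
  expect_true("STU_201" %in% s$ligand_atoms$ligand_id)
})

test_that("input without ATOM records is a format error", {
  txt <- pdb_line(1, "O", "HOH", "A", 1, 0, 0, 0, type = "HETATM")
  expect_error(read_kinase_pdb(txt), "no ATOM records")
})

test_that("only MODEL 1 of a multi-model file is read", {
  txt <- c(
    "MODEL        1",
    pdb_line(1, "CA", "ALA", "A", 1, 1, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_line(1, "CA", "ALA", "A", 1, 99, 0, 0),
    "ENDMDL"
  )
  s <- read_kinase_pdb(txt)
  expect_equal(s$atoms$x, 1)
})

test_that("parse -> serialize -> re-parse is the identity", {
  toy <- make_toy_kinase(seed = 3, ligand = list(resname = "LIG",
                                                 resno = 401,
                                                 offset = c(0, 0, 3)))
  s1 <- toy$structure
  s2 <- read_kinase_pdb(write_kinase_pdb(s1), chain = s1$chain_id,
                        source_id = s1$source_id)
  expect_equal(s2$residues, s1$residues)
  expect_equal(s2$atoms, s1$atoms)
  expect_equal(s2$ligand_atoms, s1$ligand_atoms)
})

test_that("validation reports breaks, missing backbone and odd residues", {
  toy <- make_toy_kinase()
  expect_equal(nrow(validate_structure(toy$structure)), 0)

  # delete one residue mid-chain -> one chain break
  s <- toy$structure
  gone <- 15L
  s$atoms <- s$atoms[s$atoms$ordinal != gone, , drop = FALSE]
  s$residues <- s$residues[s$residues$ordinal != gone, , drop = FALSE]
  s$atoms$ordinal[s$atoms$ordinal > gone] <- s$atoms$ordinal[s$atoms$ordinal > gone] - 1L
  s$residues$ordinal <- seq_len(nrow(s$residues))
  issues <- validate_structure(s)
  expect_equal(sum(issues$issue == "chain_break"), 1)

  # remove a Calpha -> exactly one missing-backbone issue
  s2 <- drop_atoms(toy$structure, 5L, "CA")
  issues2 <- validate_structure(s2)
  expect_equal(sum(issues2$issue == "missing_backbone"), 1)
  expect_equal(issues2$ordinal[issues2$issue == "missing_backbone"], 5L)

  # nonstandard residue name is reported, not fatal
  s3 <- toy$structure
  s3$residues$resname[2] <- "XYZ"
  expect_equal(sum(validate_structure(s3)$issue == "nonstandard_residue"), 1)
})

test_that("motif location recovers the generator ground truth across seeds", {
  for (seed in c(1, 7, 123)) {
    toy <- make_toy_kinase(seed = seed)
    m <- locate_motifs(toy$structure)
    expect_equal(m$dfg_asp, toy$motifs$dfg_asp)
    expect_equal(m$dfg_phe, toy$motifs$dfg_phe)
    expect_equal(m$dfg_gly, toy$motifs$dfg_gly)
    expect_equal(m$beta3_lys, toy$motifs$beta3_lys)
    expect_equal(m$alphac_glu, toy$motifs$alphac_glu)
    expect_equal(m$alphac_span, toy$motifs$alphac_span)
  }
})

test_that("with two DFG triplets the downstream one is selected", {
  toy <- make_toy_kinase(decoy_dfg = 4)
  m <- locate_motifs(toy$structure)
  expect_equal(m$dfg_asp, toy$motifs$dfg_asp)  # 45, not the decoy at 4
})

test_that("motif location is invariant under rigid-body motion", {
  toy <- make_toy_kinase(seed = 2)
  set.seed(11)
  for (rep in 1:5) {
    s <- transform_structure(toy$structure, random_rotation(),
                             rnorm(3, sd = 20))
    m <- locate_motifs(s)
    expect_equal(m$dfg_asp, toy$motifs$dfg_asp)
    expect_equal(m$alphac_span, toy$motifs$alphac_span)
    expect_equal(m$beta3_lys, toy$motifs$beta3_lys)
  }
})

test_that("overrides are used verbatim, flagged when identities are odd", {
  toy <- make_toy_kinase()
  # point the DFG override at a run of ALA residues: accepted with warning
  m <- locate_motifs(toy$structure, dfg_asp = 50, beta3_lys = 10,
                     alphac_glu = 26)
  expect_true(m$override)
  expect_true(m$warning_flag)
  expect_equal(m$dfg_asp, 50)
  # matching identities carry no warning
  m2 <- locate_motifs(toy$structure, dfg_asp = 45, beta3_lys = 10,
                      alphac_glu = 26)
  expect_false(m2$warning_flag)
  expect_error(locate_motifs(toy$structure, dfg_asp = 999, beta3_lys = 10,
                             alphac_glu = 26), "no such residue")
})

test_that("absent DFG triplet without overrides is a motif error", {
  toy <- make_toy_kinase()
  s <- toy$structure
  s$residues$resname[s$residues$resname == "ASP"] <- "ALA"
  expect_error(locate_motifs(s), "no ASP-PHE-GLY")
})
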