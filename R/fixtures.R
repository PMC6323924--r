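## Synthetic ground-truth generators: toy kinase structures with known
## motif placements, labeled descriptor datasets with controllable class
## separation, and ligand corpora with a planted conformation-enriched
## substructure. All generators are bit-reproducible given their seed.

#' Generate a toy kinase structure with known motif geometry
#'
#' Builds a single-chain backbone: an ideal alpha-helix (1.5 A rise, 100
#' degree twist, 2.3 A radius) over `helix_span`, flanked by connected
#' extended (zig-zag) segments. Side-chain pseudo-atoms are placed so the
#' descriptors are realized by construction: the beta3-Lys NZ sits exactly
#' `saltbridge_dist` from the alphaC-Glu CD (axis-aligned so the distance
#' survives the 3-decimal PDB coordinate format), and the DFG-Phe ring
#' centroid sits at `phe_displacement` in the descriptor local frame
#' anchored at the alphaC-Glu Calpha (exact to coordinate precision,
#' ~0.002 A). Residues that no descriptor touches receive seed-dependent
#' coordinate jitter; motif geometry is identical across seeds.
#'
#' @param n_residues Chain length (default 60, minimum 40).
#' @param helix_span Ordinals (first, last) of the alphaC-helix
#'   (default 20:32).
#' @param beta3_lys,alphac_glu,dfg_asp Motif ordinals (must satisfy
#'   beta3_lys < alphac_glu < dfg_asp, with the glutamate inside the
#'   helix).
#' @param saltbridge_dist Lys NZ to Glu CD distance in Angstrom
#'   (default 3.0, must exceed 1.5).
#' @param phe_displacement Ring-centroid position in the local descriptor
#'   frame (x along helix axis, z toward the beta3-lysine), in Angstrom.
#' @param seed Integer seed for the irrelevant-residue jitter.
#' @param decoy_dfg Optional ordinal of a second ASP-PHE-GLY triplet
#'   upstream of the helix.
#' @param ligand Optional list(resname, resno, offset) planting a 3-atom
#'   HETATM ligand at DFG-Phe Calpha + offset.
#' @return List with `pdb_text`, `structure` (the parsed
#'   `kinase_structure`), `motifs` (ground-truth `motif_annotation`) and
#'   `params`.
#' @export
make_toy_kinase <- function(n_residues = 60, helix_span = c(20, 32),
                            beta3_lys = 10, alphac_glu = 26, dfg_asp = 45,
                            saltbridge_dist = 3.0,
                            phe_displacement = c(6, 2, 4), seed = 1,
                            decoy_dfg = NULL, ligand = NULL) {
  h1 <- helix_span[1]; h2 <- helix_span[2]
  stopifnot(n_residues >= 40, h2 - h1 + 1 >= 6,
            beta3_lys < h1, alphac_glu >= h1, alphac_glu <= h2,
            dfg_asp > h2, dfg_asp + 2 <= n_residues,
            beta3_lys < alphac_glu, alphac_glu < dfg_asp,
            saltbridge_dist > 1.5, length(phe_displacement) == 3)
  if (!is.null(decoy_dfg)) stopifnot(decoy_dfg >= 2, decoy_dfg + 2 < h1)
  set.seed(seed)

  ca <- matrix(NA_real_, n_residues, 3)
  ## pre-helix extended zig-zag
  for (i in seq_len(h1 - 1)) {
    ca[i, ] <- c(3.67 * (i - 1), 0.5 * (i %% 2), 0)
  }
  ## ideal helix, axis along +x
  c1 <- ca[h1 - 1, ] + c(3.4, 0, 1.5)
  origin <- c1 - c(0, 2.3, 0)
  for (i in h1:h2) {
    k <- i - h1
    th <- 100 * k * pi / 180
    ca[i, ] <- origin + c(1.5 * k, 2.3 * cos(th), 2.3 * sin(th))
  }
  ## post-helix extended zig-zag
  last <- ca[h2, ]
  for (i in (h2 + 1):n_residues) {
    k <- i - h2
    ca[i, ] <- last + c(3.67 * k, 0.5 * (k %% 2), 0)
  }
  ## non-planarity around the DFG triad so the pseudo-dihedral is generic
  ca[dfg_asp + 1, 3] <- ca[dfg_asp + 1, 3] + 0.6

  ## jitter residues no descriptor touches
  protected <- unique(c(h1:h2, beta3_lys,
                        (dfg_asp - 1):(dfg_asp + 2)))
  for (i in setdiff(seq_len(n_residues), protected)) {
    ca[i, 2:3] <- ca[i, 2:3] + runif(2, -0.05, 0.05)
  }
  ca <- round(ca, 3)

  resname <- rep("ALA", n_residues)
  resname[beta3_lys] <- "LYS"
  resname[alphac_glu] <- "GLU"
  resname[dfg_asp + 0:2] <- c("ASP", "PHE", "GLY")
  if (!is.null(decoy_dfg)) resname[decoy_dfg + 0:2] <- c("ASP", "PHE", "GLY")

  atoms <- list()
  add_atom <- function(ord, name, elem, xyz) {
    atoms[[length(atoms) + 1L]] <<- tibble::tibble(
      ordinal = ord, resno = ord, ins = "", resname = resname[ord],
      atom = name, element = elem,
      x = round(xyz[1], 3), y = round(xyz[2], 3), z = round(xyz[3], 3),
      occ = 1, altloc = ""
    )
  }
  for (i in seq_len(n_residues)) {
    add_atom(i, "N", "N", ca[i, ] + c(-1.2, 0.4, 0))
    add_atom(i, "CA", "C", ca[i, ])
    add_atom(i, "C", "C", ca[i, ] + c(1.2, 0.4, 0))
  }

  ## Glu CD: 1.5 A radially outward from the helix axis
  th_glu <- 100 * (alphac_glu - h1) * pi / 180
  cd <- round(ca[alphac_glu, ] + 1.5 * c(0, cos(th_glu), sin(th_glu)), 3)
  add_atom(alphac_glu, "CD", "C", cd)
  ## Lys NZ: exactly saltbridge_dist from CD along -y (exact at 3 decimals)
  add_atom(beta3_lys, "NZ", "N", cd + c(0, -saltbridge_dist, 0))

  ## Phe ring: hexagon whose centroid realizes phe_displacement in the
  ## local descriptor frame (computed from the rounded Calpha trace)
  frame <- descriptor_frame(ca[h1:h2, , drop = FALSE], ca[alphac_glu, ],
                            ca[beta3_lys, ])
  centroid <- ca[alphac_glu, ] +
    phe_displacement[1] * frame$x + phe_displacement[2] * frame$y +
    phe_displacement[3] * frame$z
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  for (j in seq_along(ring_names)) {
    ang <- (j - 1) * 60 * pi / 180
    add_atom(dfg_asp + 1L, ring_names[j], "C",
             centroid + 1.39 * (cos(ang) * frame$y + sin(ang) * frame$z))
  }

  atom_tbl <- dplyr::bind_rows(atoms)
  atom_tbl <- atom_tbl[order(atom_tbl$ordinal), , drop = FALSE]
  lig_tbl <- atom_tbl[0, ]
  lig_tbl$ligand_id <- character()
  if (!is.null(ligand)) {
    base <- ca[dfg_asp + 1, ] + ligand$offset
    lig_tbl <- tibble::tibble(
      ordinal = NA_integer_, resno = ligand$resno, ins = "",
      resname = ligand$resname,
      atom = c("C1", "C2", "C3"), element = "C",
      x = round(base[1] + c(0, 1.4, 2.8), 3),
      y = round(rep(base[2], 3), 3), z = round(rep(base[3], 3), 3),
      occ = 1, altloc = "",
      ligand_id = paste(ligand$resname, ligand$resno, sep = "_")
    )
  }

  skeleton <- structure(
    list(source_id = "toy_kinase", chain_id = "A",
         residues = tibble::tibble(ordinal = seq_len(n_residues),
                                   resno = seq_len(n_residues),
                                   ins = "", resname = resname),
         atoms = atom_tbl, ligand_atoms = lig_tbl),
    class = "kinase_structure"
  )
  pdb_text <- write_kinase_pdb(skeleton)
  parsed <- read_kinase_pdb(pdb_text, chain = "A", source_id = "toy_kinase")

  list(
    pdb_text = pdb_text,
    structure = parsed,
    motifs = new_motif_annotation(dfg_asp, beta3_lys, alphac_glu,
                                  c(h1, h2)),
    params = list(n_residues = n_residues, helix_span = c(h1, h2),
                  beta3_lys = beta3_lys, alphac_glu = alphac_glu,
                  dfg_asp = dfg_asp, saltbridge_dist = saltbridge_dist,
                  phe_displacement = phe_displacement, seed = seed)
  )
}

## Unit-scale class centroids: DFG-in/out separates along d2-d5 and d7,
## alphaC-in/out along d1 and d6; wCD sits between. Mirrors the biological
## meaning of the two motifs.
CLASS_CENTROID_PATTERN <- rbind(
  CIDI = c(-1, -1, -1, -1, -1, -1, -1, 0),
  CIDO = c(-1, +1, +1, +1, +1, -1, +1, 0),
  CODI = c(+1, -1, -1, -1, -1, +1, -1, 0),
  CODO = c(+1, +1, +1, +1, +1, +1, +1, 0),
  wCD = c(0, 0, 0, 0, 0, 0, 0, 0)
)

#' Generate a labeled synthetic descriptor dataset
#'
#' Gaussian clusters per conformation class: class centroids are the unit
#' pattern scaled by `separation * spread`, so each discriminative
#' descriptor sits `separation` standard deviations from the midpoint
#' (opposing classes differ by twice that). The cosine descriptor is squashed through tanh to stay in
#' (-1, 1). Stage labels (dfg_class, ac_class) are derived from the
#' conformation; missing cells are placed uniformly at `missing_rate`.
#'
#' @param n_per_class Rows per conformation class (default 50).
#' @param separation Class separation in units of `spread` (default 3).
#' @param spread Within-class standard deviation (default 1).
#' @param missing_rate Probability a descriptor cell is missing
#'   (default 0).
#' @param seed Integer seed.
#' @return Tibble with the eight descriptor columns, `conformation`,
#'   `dfg_class`, `ac_class`.
#' @export
make_descriptor_dataset <- function(n_per_class = 50, separation = 3,
                                    spread = 1, missing_rate = 0, seed = 1) {
  stopifnot(n_per_class >= 2, missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  rows <- lapply(CONFORMATION_LEVELS, function(cl) {
    mu <- CLASS_CENTROID_PATTERN[cl, ] * separation * spread
    m <- matrix(rnorm(n_per_class * 8, mean = rep(mu, each = n_per_class),
                      sd = spread), n_per_class, 8)
    colnames(m) <- DESCRIPTOR_NAMES
    df <- tibble::as_tibble(m)
    df$conformation <- cl
    df
  })
  out <- dplyr::bind_rows(rows)
  out$d6_helix_cos_angle <- tanh(out$d6_helix_cos_angle / 2)
  out <- dplyr::bind_cols(out, split_conformation(out$conformation))
  if (missing_rate > 0) {
    mask <- matrix(runif(nrow(out) * 8) < missing_rate, nrow(out), 8)
    for (j in seq_len(8)) {
      out[[DESCRIPTOR_NAMES[j]]][mask[, j]] <- NA_real_
    }
  }
  out
}

## Background scaffolds: two ring systems joined by a single bond, 11-12
## heavy atoms, no substituents — so no fragment other than the scaffold
## itself survives the 10-heavy-atom floor. Sixteen distinct scaffolds keep
## every background cluster's prevalence low enough that the discrete
## Fisher support cannot reach the Bonferroni threshold under permuted
## labels (family-wise error well below nominal).
BACKGROUND_SCAFFOLDS <- c(
  "c1ccc(-c2ccncc2)cc1",
  "c1ccc(-c2cccnc2)cc1",
  "c1ccc(-c2ccccn2)cc1",
  "c1ccc(-c2ccco2)cc1",
  "c1ccc(-c2ccoc2)cc1",
  "c1ccc(-c2cccs2)cc1",
  "c1ccc(-c2ccsc2)cc1",
  "c1ccc(-c2ncccn2)cc1",
  "c1ccc(-c2cnccn2)cc1",
  "c1ccc(nc1)-c2ccncc2",
  "c1ccc(-C2CCNCC2)cc1",
  "c1ccc(-C2CCOCC2)cc1",
  "c1ccc(-C2CCSCC2)cc1",
  "c1ccc(-C2CCCCC2)cc1",
  "c1ccc(-C2CCCC2)cc1",
  "c1ccc(-C2CCNC2)cc1"
)

## Single-heavy-atom decorations: a decorated ligand fragments to exactly
## its scaffold, keeping the cluster structure of the corpus predictable.
LIGAND_DECORATIONS <- c("C", "N", "O", "F", "Cl")

#' Generate a ligand corpus with a planted enriched substructure
#'
#' Ligands of the enriched conformation are the planted substructure
#' decorated with one random small appendage; the other conformations draw
#' scaffolds round-robin from the background alphabet (also decorated).
#' Both the planted substructure and the background scaffolds are chosen
#' so that their only fragment above the heavy-atom floor is the scaffold
#' itself.
#'
#' @param n_per_conformation Ligands per conformation class (default 20).
#' @param planted_substructure SMILES of the planted substructure
#'   (default biphenyl; must have at least 10 heavy atoms and accept a
#'   prepended substituent).
#' @param enriched_conformation Conformation receiving the planted
#'   substructure (default `"CIDO"`); `NULL` for a background-only corpus;
#'   `"all"` plants it equally in every class.
#' @param background_alphabet SMILES of background scaffolds.
#' @param seed Integer seed.
#' @return List with `ligands` (tibble: ligand_id, smiles, conformation)
#'   and `truth` (canonical planted SMILES and enriched conformation).
#' @export
make_ligand_corpus <- function(n_per_conformation = 20,
                               planted_substructure = "c1ccc(-c2ccccc2)cc1",
                               enriched_conformation = "CIDO",
                               background_alphabet = BACKGROUND_SCAFFOLDS,
                               seed = 1) {
  stopifnot(n_per_conformation >= 1)
  if (heavy_atom_count(planted_substructure) < 10) {
    stop("planted substructure has fewer than 10 heavy atoms; ",
         "it would be filtered out", call. = FALSE)
  }
  if (!is.null(enriched_conformation) && enriched_conformation != "all") {
    stopifnot(enriched_conformation %in% CONFORMATION_LEVELS)
  }
  set.seed(seed)
  bg_cycle <- 0L
  next_background <- function() {
    bg_cycle <<- bg_cycle + 1L
    background_alphabet[((bg_cycle - 1L) %% length(background_alphabet)) + 1L]
  }
  decorate <- function(core) {
    paste0(sample(LIGAND_DECORATIONS, 1), core)
  }
  rows <- list()
  for (cl in CONFORMATION_LEVELS) {
    for (i in seq_len(n_per_conformation)) {
      planted_here <- if (is.null(enriched_conformation)) {
        FALSE
      } else if (identical(enriched_conformation, "all")) {
        i <= n_per_conformation / 2
      } else {
        cl == enriched_conformation
      }
      core <- if (planted_here) planted_substructure else next_background()
      rows[[length(rows) + 1L]] <- tibble::tibble(
        ligand_id = sprintf("L%s%03d", cl, i),
        smiles = decorate(core),
        conformation = cl
      )
    }
  }
  list(
    ligands = dplyr::bind_rows(rows),
    truth = list(
      planted = canonical_smiles(planted_substructure),
      enriched_conformation = if (identical(enriched_conformation, "all"))
        NULL else enriched_conformation
    )
  )
}
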