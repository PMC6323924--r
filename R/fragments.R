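## Ligand fragmentation and fingerprint clustering.
##
## "Exhaustive" fragmentation enumerates every subset of up to `max_cuts`
## acyclic (bridge) single bonds, deletes them, and emits each connected
## component as a hydrogen-capped standalone molecule; fragments below the
## heavy-atom floor are dropped and the intact parent is never emitted.
## Representative substructures come from leader-style (sphere-exclusion)
## clustering on circular fingerprints with Tanimoto similarity.

#' Exhaustively fragment a molecule
#'
#' @param smiles Single-component SMILES of the parent molecule.
#' @param max_cuts Maximum number of simultaneous bond cuts (default 3).
#' @param min_heavy_atoms Heavy-atom floor for emitted fragments
#'   (default 10).
#' @param id Parent identifier recorded in `parents`; defaults to the
#'   canonical parent SMILES.
#' @return Tibble of unique fragments: `smiles` (canonical),
#'   `heavy_atoms`, `parents` (list column of parent ids).
#' @export
fragment_molecule <- function(smiles, max_cuts = 3, min_heavy_atoms = 10,
                              id = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (grepl("\\.", smiles, fixed = FALSE)) {
    stop("multi-component SMILES are not supported", call. = FALSE)
  }
  mol <- parse_smiles(smiles)
  if (is.null(id)) id <- canonical_smiles(smiles)

  empty <- tibble::tibble(smiles = character(), heavy_atoms = integer(),
                          parents = list())
  g <- mol_igraph(mol)
  if (igraph::components(g)$no > 1) {
    stop("multi-component SMILES are not supported", call. = FALSE)
  }
  cuttable <- intersect(
    as.integer(igraph::bridges(g)),
    which(mol$bonds$order == 1)
  )
  if (length(cuttable) == 0 || mol$n < min_heavy_atoms) return(empty)

  ## enumerate cut-sets; collect unique component atom-sets first so each
  ## distinct component is canonicalized only once
  seen <- new.env(parent = emptyenv())
  for (ncut in seq_len(min(max_cuts, length(cuttable)))) {
    # combn() would treat a scalar first argument as seq_len(x)
    sets <- if (length(cuttable) == 1L) list(cuttable)
            else combn(cuttable, ncut, simplify = FALSE)
    for (cutset in sets) {
      gc <- igraph::delete_edges(g, cutset)
      memb <- igraph::components(gc)$membership
      for (comp in unique(memb)) {
        atoms <- which(memb == comp)
        if (length(atoms) < min_heavy_atoms || length(atoms) == mol$n) next
        key <- paste(atoms, collapse = ",")
        if (is.null(seen[[key]])) seen[[key]] <- atoms
      }
    }
  }
  atom_sets <- as.list(seen)
  if (length(atom_sets) == 0) return(empty)

  frags <- unname(lapply(atom_sets, function(atoms) mol_subgraph(mol, atoms)))
  smi <- mols_to_canonical_smiles(frags)
  heavy <- vapply(frags, function(m) m$n, integer(1))
  keep <- !duplicated(smi)
  tibble::tibble(
    smiles = smi[keep],
    heavy_atoms = heavy[keep],
    parents = lapply(seq_len(sum(keep)), function(i) id)
  ) |>
    dplyr::arrange(dplyr::desc(.data$heavy_atoms), .data$smiles)
}

#' Fragment a table of ligands and merge identical fragments
#'
#' Applies [fragment_molecule()] to every ligand and merges fragments with
#' identical canonical SMILES, accumulating the set of parent ligands.
#'
#' @param ligands Data frame with `ligand_id` and `smiles` columns.
#' @inheritParams fragment_molecule
#' @return Tibble of unique fragments with list-column `parents` holding
#'   the ligand ids each fragment came from.
#' @export
fragment_ligands <- function(ligands, max_cuts = 3, min_heavy_atoms = 10) {
  stopifnot(is.data.frame(ligands),
            all(c("ligand_id", "smiles") %in% names(ligands)))
  per <- purrr::map2(ligands$smiles, ligands$ligand_id, function(s, id) {
    fragment_molecule(s, max_cuts = max_cuts,
                      min_heavy_atoms = min_heavy_atoms, id = id)
  })
  all_frags <- dplyr::bind_rows(per)
  if (nrow(all_frags) == 0) return(all_frags)
  all_frags |>
    dplyr::group_by(.data$smiles) |>
    dplyr::summarise(
      heavy_atoms = .data$heavy_atoms[1],
      parents = list(sort(unique(unlist(.data$parents)))),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$heavy_atoms), .data$smiles)
}

#' Cluster fragments into representative substructures
#'
#' Deterministic leader (sphere-exclusion) clustering: fragments are
#' processed in descending heavy-atom count (ties by SMILES, C locale); a
#' fragment joins the first existing cluster whose representative has
#' Tanimoto similarity at or above `cutoff` on the circular fingerprint,
#' otherwise it founds a new cluster and becomes its representative.
#'
#' @param fragments Fragment tibble (from [fragment_molecule()] or
#'   [fragment_ligands()]) with `smiles` and `heavy_atoms`.
#' @param cutoff Tanimoto similarity cutoff in (0, 1] (default 0.90).
#' @param fp_radius,fp_bits Fingerprint parameters (default radius 2,
#'   2048 bits).
#' @return The input with `cluster_id` and `is_representative` columns,
#'   in processing order.
#' @export
cluster_fragments <- function(fragments, cutoff = 0.90, fp_radius = 2,
                              fp_bits = 2048) {
  stopifnot(is.data.frame(fragments), cutoff > 0, cutoff <= 1)
  if (nrow(fragments) == 0) {
    out <- fragments
    out$cluster_id <- integer()
    out$is_representative <- logical()
    return(out)
  }
  ord <- order(-fragments$heavy_atoms, fragments$smiles, method = "radix")
  out <- fragments[ord, , drop = FALSE]
  fps <- lapply(out$smiles, function(s) {
    mol_fingerprint(parse_smiles(s), radius = fp_radius, nbits = fp_bits)
  })
  cluster_id <- integer(nrow(out))
  rep_fps <- list()
  rep_idx <- integer()
  for (i in seq_len(nrow(out))) {
    assigned <- 0L
    for (cl in seq_along(rep_fps)) {
      if (tanimoto(fps[[i]], rep_fps[[cl]]) >= cutoff) {
        assigned <- cl
        break
      }
    }
    if (assigned == 0L) {
      rep_fps[[length(rep_fps) + 1L]] <- fps[[i]]
      rep_idx <- c(rep_idx, i)
      assigned <- length(rep_fps)
    }
    cluster_id[i] <- assigned
  }
  out$cluster_id <- cluster_id
  out$is_representative <- seq_len(nrow(out)) %in% rep_idx
  out
}

#' Ligands in contact with the ATP-pocket motifs
#'
#' A ligand qualifies when any of its atoms lies within `radius` of any
#' atom of the DFG triad, the beta3-lysine or the alphaC-glutamate.
#' Crystallographic additives (waters, buffers, ions) never qualify.
#'
#' @param structure A `kinase_structure` parsed with ligand atoms retained.
#' @param motifs A `motif_annotation` for the structure.
#' @param radius Contact radius in Angstrom (default 6).
#' @return Tibble of qualifying ligands: `ligand_id`, `resname`, `resno`,
#'   `n_atoms`, `min_dist`.
#' @export
extract_pocket_ligands <- function(structure, motifs, radius = 6.0) {
  stopifnot(inherits(structure, "kinase_structure"),
            inherits(motifs, "motif_annotation"))
  lig <- structure$ligand_atoms
  lig <- lig[!lig$resname %in% ADDITIVE_RESNAMES, , drop = FALSE]
  empty <- tibble::tibble(ligand_id = character(), resname = character(),
                          resno = integer(), n_atoms = integer(),
                          min_dist = numeric())
  if (nrow(lig) == 0) return(empty)
  pocket_ords <- c(motifs$dfg_asp, motifs$dfg_phe, motifs$dfg_gly,
                   motifs$beta3_lys, motifs$alphac_glu)
  pocket <- structure$atoms[structure$atoms$ordinal %in% pocket_ords, ,
                            drop = FALSE]
  if (nrow(pocket) == 0) return(empty)
  pm <- as.matrix(pocket[, c("x", "y", "z")])
  lig |>
    dplyr::group_by(.data$ligand_id, .data$resname, .data$resno) |>
    dplyr::summarise(
      n_atoms = dplyr::n(),
      min_dist = {
        lm <- cbind(.data$x, .data$y, .data$z)
        d2 <- outer(rowSums(lm^2), rep(1, nrow(pm))) +
          outer(rep(1, nrow(lm)), rowSums(pm^2)) - 2 * lm %*% t(pm)
        sqrt(max(0, min(d2)))
      },
      .groups = "drop"
    ) |>
    dplyr::filter(.data$min_dist <= radius) |>
    dplyr::arrange(.data$ligand_id)
}
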