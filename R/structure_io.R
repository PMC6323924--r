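## PDB reading and motif location for single kinase domains.
##
## Parsing is delegated to bio3d::read.pdb; this layer selects one chain,
## resolves alternate locations, separates ligand (HETATM) atoms, and finds
## the functional motifs (DFG triad, beta3-lysine, alphaC-glutamate,
## alphaC-helix) that the geometric descriptors are built on.

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

## Modified residues frequently seen in kinase structures, mapped to their
## parent residue for protein-ness and validation purposes.
MODIFIED_AA <- c(SEP = "SER", TPO = "THR", PTR = "TYR", MSE = "MET")

## Crystallographic additives that never count as pocket ligands.
ADDITIVE_RESNAMES <- c(
  "HOH", "WAT", "DOD", "SO4", "PO4", "GOL", "EDO", "PEG", "PGE", "PG4",
  "DMS", "ACT", "FMT", "MPD", "TRS", "MES", "EPE", "IMD", "BME", "NO3",
  "CL", "BR", "IOD", "NA", "K", "MG", "ZN", "CA", "MN", "CD", "NI", "CO"
)

is_protein_resname <- function(resname) {
  resname %in% c(STANDARD_AA, names(MODIFIED_AA))
}

#' Read a kinase chain from PDB-format input
#'
#' Reads PDB text (or a file), keeps only the first MODEL, selects one
#' protein chain, resolves alternate locations (altloc 'A' or blank wins,
#' remaining ties broken by highest occupancy), and separates non-protein
#' HETATM records into a ligand-atom table. HETATM records of modified
#' protein residues (SEP, TPO, PTR, MSE) are retained as protein residues.
#'
#' @param pdb Path to a PDB file, a single string of PDB text, or a
#'   character vector of PDB lines.
#' @param chain Optional chain identifier; default is the first chain
#'   containing protein residues.
#' @param source_id Free-text identifier stored on the result.
#' @return An object of class `kinase_structure`: a list with `source_id`,
#'   `chain_id`, `residues` (tibble: ordinal, resno, ins, resname), `atoms`
#'   (tibble: ordinal, resno, ins, resname, atom, element, x, y, z, occ,
#'   altloc) and `ligand_atoms` (same columns plus `ligand_id`).
#' @export
read_kinase_pdb <- function(pdb, chain = NULL, source_id = NULL) {
  stopifnot(is.character(pdb), length(pdb) >= 1L)
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
    if (is.null(source_id)) source_id <- basename(path)
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(pdb) == 1L) strsplit(pdb, "\n")[[1]] else pdb, path)
    if (is.null(source_id)) source_id <- "pdb_text"
  }
  raw <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse PDB input: ", conditionMessage(e),
                             call. = FALSE)
  )
  at <- tibble::as_tibble(raw$atom)
  if (!any(at$type == "ATOM")) {
    stop("PDB input contains no ATOM records", call. = FALSE)
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  protein <- at$type == "ATOM" | (at$type == "HETATM" & is_protein_resname(at$resid))
  chains <- unique(at$chain[protein])
  if (is.null(chain)) {
    chain <- chains[1]
  } else if (!chain %in% chains) {
    stop("chain '", chain, "' not found (protein chains: ",
         paste(chains, collapse = ", "), ")", call. = FALSE)
  }
  at <- at[at$chain %in% chain, , drop = FALSE]
  protein <- at$type == "ATOM" | (at$type == "HETATM" & is_protein_resname(at$resid))

  resolve_alt <- function(df) {
    df <- df |>
      dplyr::group_by(.data$resno, .data$insert, .data$resid, .data$elety) |>
      dplyr::arrange(dplyr::desc(.data$alt %in% c("", "A")),
                     dplyr::desc(.data$o), .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    df[order(match(df$eleno, at$eleno)), , drop = FALSE]
  }

  tidy_atoms <- function(df, ord_key) {
    if (nrow(df) == 0) {
      return(tibble::tibble(
        ordinal = integer(), resno = integer(), ins = character(),
        resname = character(), atom = character(), element = character(),
        x = numeric(), y = numeric(), z = numeric(), occ = numeric(),
        altloc = character()
      ))
    }
    tibble::tibble(
      ordinal = ord_key, resno = as.integer(df$resno), ins = df$insert,
      resname = df$resid, atom = df$elety, element = df$elesy,
      x = df$x, y = df$y, z = df$z, occ = df$o, altloc = df$alt
    )
  }

  prot <- resolve_alt(at[protein, , drop = FALSE])
  lig <- resolve_alt(at[!protein, , drop = FALSE])
  if (any(!is.finite(c(prot$x, prot$y, prot$z)))) {
    stop("non-finite coordinates in PDB input", call. = FALSE)
  }

  res_key <- paste(prot$resno, prot$insert, sep = "|")
  ordinal <- match(res_key, unique(res_key))
  residues <- tibble::tibble(
    ordinal = seq_along(unique(res_key)),
    resno = as.integer(prot$resno[!duplicated(res_key)]),
    ins = prot$insert[!duplicated(res_key)],
    resname = prot$resid[!duplicated(res_key)]
  )
  atoms <- tidy_atoms(prot, ordinal)
  lig_atoms <- tidy_atoms(lig, rep(NA_integer_, nrow(lig)))
  if (nrow(lig_atoms) > 0) {
    lig_atoms$ligand_id <- paste(lig_atoms$resname, lig_atoms$resno,
                                 sep = "_")
  } else {
    lig_atoms$ligand_id <- character()
  }

  structure(
    list(source_id = source_id, chain_id = chain, residues = residues,
         atoms = atoms, ligand_atoms = lig_atoms),
    class = "kinase_structure"
  )
}

#' @export
print.kinase_structure <- function(x, ...) {
  cat("<kinase_structure> ", x$source_id, " chain ", x$chain_id, ": ",
      nrow(x$residues), " residues, ", nrow(x$atoms), " atoms, ",
      nrow(x$ligand_atoms), " ligand atoms\n", sep = "")
  invisible(x)
}

#' Serialize a kinase structure back to PDB text
#'
#' Writes the protein atoms (as ATOM records) and ligand atoms (as HETATM
#' records) of a [read_kinase_pdb()] result. Parsing, re-serializing and
#' re-parsing is stable.
#'
#' @param structure A `kinase_structure`.
#' @param file Optional path; when `NULL` the PDB text is returned.
#' @return PDB text as a single string (invisibly when `file` is given).
#' @export
write_kinase_pdb <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "kinase_structure"))
  a <- structure$atoms
  l <- structure$ligand_atoms
  all_at <- dplyr::bind_rows(a, l[, names(a)])
  type <- c(rep("ATOM", nrow(a)), rep("HETATM", nrow(l)))
  path <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(
    pdb = NULL, file = path,
    type = type,
    xyz = as.vector(t(as.matrix(all_at[, c("x", "y", "z")]))),
    resno = all_at$resno, resid = all_at$resname,
    eleno = seq_len(nrow(all_at)), elety = all_at$atom,
    chain = rep(structure$chain_id, nrow(all_at)),
    insert = all_at$ins,
    o = all_at$occ, b = rep(0, nrow(all_at)), elesy = all_at$element
  )
  txt <- paste(readLines(path), collapse = "\n")
  if (is.null(file)) {
    unlink(path)
    txt
  } else {
    invisible(txt)
  }
}

## Cα coordinate matrix in residue-ordinal order (rows of NA when absent).
ca_matrix <- function(structure) {
  n <- nrow(structure$residues)
  m <- matrix(NA_real_, n, 3)
  ca <- structure$atoms[structure$atoms$atom == "CA", , drop = FALSE]
  m[ca$ordinal, ] <- as.matrix(ca[, c("x", "y", "z")])
  m
}

atom_xyz <- function(structure, ordinal, atom) {
  sel <- structure$atoms$ordinal == ordinal & structure$atoms$atom == atom
  if (!any(sel)) return(NULL)
  as.numeric(structure$atoms[which(sel)[1], c("x", "y", "z")])
}

#' Validate a kinase structure
#'
#' Report-only checks: chain breaks (consecutive residues with a Cα–Cα
#' distance above 4.5 Å), missing backbone atoms (N, CA, C) and
#' non-standard residue names (not one of the 20 standard amino acids or a
#' known modified residue). Never raises on valid input.
#'
#' @param structure A `kinase_structure`.
#' @return A tibble of issues with columns `issue`, `ordinal`, `resno`,
#'   `detail`; zero rows when the structure is clean.
#' @export
validate_structure <- function(structure) {
  stopifnot(inherits(structure, "kinase_structure"))
  res <- structure$residues
  issues <- list()

  ca <- ca_matrix(structure)
  if (nrow(res) >= 2) {
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-nrow(ca), , drop = FALSE])^2))
    brk <- which(!is.na(d) & d > 4.5)
    if (length(brk) > 0) {
      issues$breaks <- tibble::tibble(
        issue = "chain_break", ordinal = brk, resno = res$resno[brk],
        detail = sprintf("Ca-Ca distance %.2f A to next residue", d[brk])
      )
    }
  }

  for (bb in c("N", "CA", "C")) {
    have <- unique(structure$atoms$ordinal[structure$atoms$atom == bb])
    miss <- setdiff(res$ordinal, have)
    if (length(miss) > 0) {
      issues[[paste0("bb_", bb)]] <- tibble::tibble(
        issue = "missing_backbone", ordinal = miss, resno = res$resno[miss],
        detail = paste("missing", bb)
      )
    }
  }

  odd <- which(!is_protein_resname(res$resname))
  if (length(odd) > 0) {
    issues$odd <- tibble::tibble(
      issue = "nonstandard_residue", ordinal = odd, resno = res$resno[odd],
      detail = res$resname[odd]
    )
  }

  if (length(issues) == 0) {
    return(tibble::tibble(issue = character(), ordinal = integer(),
                          resno = integer(), detail = character()))
  }
  dplyr::arrange(dplyr::bind_rows(issues), .data$ordinal, .data$issue)
}

## Helical residues by Cα geometry: residue i is marked when both the
## (i, i+3) and (i, i+4) Cα distances fall in alpha-helical ranges; a
## maximal run of marked residues i..j spans helix residues i..j+4.
detect_helices <- function(ca) {
  n <- nrow(ca)
  if (n < 7) return(tibble::tibble(first = integer(), last = integer()))
  d_k <- function(k) {
    d <- rep(NA_real_, n)
    idx <- seq_len(n - k)
    d[idx] <- sqrt(rowSums((ca[idx + k, , drop = FALSE] - ca[idx, , drop = FALSE])^2))
    d
  }
  d3 <- d_k(3); d4 <- d_k(4)
  marked <- !is.na(d3) & !is.na(d4) & d3 >= 4.5 & d3 <= 5.5 & d4 >= 5.0 & d4 <= 6.8
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + 4L) >= 6L
  tibble::tibble(first = starts[keep], last = pmin(ends[keep] + 4L, n))
}

new_motif_annotation <- function(dfg_asp, beta3_lys, alphac_glu, alphac_span,
                                 override = FALSE, warning_flag = FALSE) {
  structure(
    list(dfg_asp = dfg_asp, dfg_phe = dfg_asp + 1L, dfg_gly = dfg_asp + 2L,
         beta3_lys = beta3_lys, alphac_glu = alphac_glu,
         alphac_span = alphac_span, override = override,
         warning_flag = warning_flag),
    class = "motif_annotation"
  )
}

#' @export
print.motif_annotation <- function(x, ...) {
  cat("<motif_annotation> DFG ", x$dfg_asp, "-", x$dfg_gly,
      ", beta3-Lys ", x$beta3_lys, ", alphaC-Glu ", x$alphac_glu,
      ", alphaC-helix ", x$alphac_span[1], "-", x$alphac_span[2],
      if (x$warning_flag) " [warning: unexpected residue identities]", "\n",
      sep = "")
  invisible(x)
}

#' Locate kinase functional motifs
#'
#' Finds the DFG triad, beta3-lysine, alphaC-glutamate and alphaC-helix of
#' a kinase domain. When explicit residue numbers are supplied they are
#' validated for existence and used verbatim (with a warning flag when the
#' residue identities are not ASP/PHE/GLY, LYS, GLU). Otherwise: helices
#' are assigned from Cα geometry; the alphaC-helix is the helix whose
#' glutamate side chain lies nearest an upstream lysine NZ (that lysine is
#' the beta3-lysine); among ASP-PHE-GLY triplets downstream of the helix,
#' the one whose ASP Cα is nearest the alphaC-glutamate Cα is the DFG
#' motif (ties broken by lowest ordinal).
#'
#' @param structure A `kinase_structure`.
#' @param dfg_asp,beta3_lys,alphac_glu Optional author residue numbers
#'   overriding the automatic scan (all three must be given together).
#' @return A `motif_annotation` with 1-based residue ordinals `dfg_asp`,
#'   `dfg_phe`, `dfg_gly`, `beta3_lys`, `alphac_glu` and `alphac_span`.
#' @export
locate_motifs <- function(structure, dfg_asp = NULL, beta3_lys = NULL,
                          alphac_glu = NULL) {
  stopifnot(inherits(structure, "kinase_structure"))
  res <- structure$residues
  overrides <- !is.null(dfg_asp) || !is.null(beta3_lys) || !is.null(alphac_glu)
  if (overrides) {
    if (is.null(dfg_asp) || is.null(beta3_lys) || is.null(alphac_glu)) {
      stop("overrides require dfg_asp, beta3_lys and alphac_glu together",
           call. = FALSE)
    }
    to_ord <- function(num, what) {
      hit <- which(res$resno == num)
      if (length(hit) == 0) {
        stop("override ", what, " = ", num, ": no such residue", call. = FALSE)
      }
      hit[1]
    }
    asp <- to_ord(dfg_asp, "dfg_asp")
    lys <- to_ord(beta3_lys, "beta3_lys")
    glu <- to_ord(alphac_glu, "alphac_glu")
    if (asp + 2L > nrow(res)) {
      stop("override dfg_asp = ", dfg_asp, ": no room for the full triad",
           call. = FALSE)
    }
    warn <- !identical(res$resname[asp + 0:2], c("ASP", "PHE", "GLY")) ||
      res$resname[lys] != "LYS" || res$resname[glu] != "GLU"
    helices <- detect_helices(ca_matrix(structure))
    inside <- which(helices$first <= glu & helices$last >= glu)
    span <- if (length(inside) > 0) {
      c(helices$first[inside[1]], helices$last[inside[1]])
    } else {
      c(max(1L, glu - 3L), min(nrow(res), glu + 3L))
    }
    return(new_motif_annotation(asp, lys, glu, span, override = TRUE,
                                warning_flag = warn))
  }

  if (nrow(res) < 30) {
    stop("structure has fewer than 30 residues; supply motif overrides",
         call. = FALSE)
  }
  name3 <- res$resname
  triads <- which(
    name3[seq_len(nrow(res) - 2L)] == "ASP" &
      name3[seq_len(nrow(res) - 2L) + 1L] == "PHE" &
      name3[seq_len(nrow(res) - 2L) + 2L] == "GLY"
  )
  if (length(triads) == 0) {
    stop("no ASP-PHE-GLY triplet found; supply motif overrides", call. = FALSE)
  }

  ca <- ca_matrix(structure)
  helices <- detect_helices(ca)
  if (nrow(helices) == 0) {
    stop("no helix detected; cannot assign the alphaC-helix", call. = FALSE)
  }

  ## alphaC-helix: helix GLU whose side chain is nearest an upstream LYS NZ
  best <- NULL
  for (h in seq_len(nrow(helices))) {
    glus <- which(name3 == "GLU" & res$ordinal >= helices$first[h] &
                    res$ordinal <= helices$last[h])
    lyss <- which(name3 == "LYS")
    for (g in glus) {
      g_xyz <- atom_xyz(structure, g, "CD")
      if (is.null(g_xyz)) g_xyz <- atom_xyz(structure, g, "CA")
      if (is.null(g_xyz)) next
      for (l in lyss[lyss < g]) {
        l_xyz <- atom_xyz(structure, l, "NZ")
        if (is.null(l_xyz)) l_xyz <- atom_xyz(structure, l, "CA")
        if (is.null(l_xyz)) next
        d <- sqrt(sum((g_xyz - l_xyz)^2))
        if (is.null(best) || d < best$d) {
          best <- list(d = d, helix = h, glu = g, lys = l)
        }
      }
    }
  }
  if (is.null(best)) {
    stop("no glutamate/lysine pair found for the alphaC-helix", call. = FALSE)
  }
  span <- c(helices$first[best$helix], helices$last[best$helix])

  ## DFG triad: downstream of the helix, ASP Calpha nearest the Glu Calpha
  down <- triads[triads > span[2]]
  if (length(down) == 0) down <- triads
  glu_ca <- ca[best$glu, ]
  d_asp <- vapply(down, function(t) sqrt(sum((ca[t, ] - glu_ca)^2)), numeric(1))
  asp <- down[order(d_asp, down)][1]

  new_motif_annotation(asp, best$lys, best$glu, span)
}
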