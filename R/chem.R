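## Molecular-graph layer over ChemmineR/ChemmineOB.
##
## Molecules are handled as heavy-atom graphs: a character vector of element
## symbols plus a bond table (i, j, order). SMILES parsing and canonical
## SMILES generation are delegated to Open Babel (via ChemmineOB); everything
## graph-topological (bridges, components, substructure matching) runs on
## igraph.

## Default valences used to infer implicit hydrogen counts from a kekulized
## bond table. Only neutral organic subset elements are supported; anything
## else gets 0 implicit hydrogens (fingerprints degrade gracefully).
DEFAULT_VALENCE <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
  F = 1, Cl = 1, Br = 1, I = 1, H = 1, Si = 4
)

strip_ob_title <- function(x) {
  x <- sub("[\t ].*$", "", x)
  x[nzchar(x)]
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to Open Babel canonical SMILES. Canonical SMILES are a
#' fixed point: canonicalizing twice gives the same string.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length and order.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character())
  out <- strip_ob_title(strsplit(
    ChemmineOB::convertFormat("SMI", "CAN", paste(smiles, collapse = "\n")),
    "\n"
  )[[1]])
  if (length(out) != length(smiles)) {
    stop("cannot canonicalize SMILES input (", length(out), " of ",
         length(smiles), " converted)")
  }
  out
}

## Parse one SMILES into a mol_graph (heavy atoms only).
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  ## single heavy atom: below what an SDF round-trip can represent
  m <- regmatches(smiles,
                  regexec("^\\[?([A-Z][a-z]?)(H[0-9]*)?([+-][0-9]*)?\\]?$",
                          smiles))[[1]]
  if (length(m) > 0 && m[2] %in% names(DEFAULT_VALENCE)) {
    g <- new_mol_graph(m[2], tibble::tibble(i = integer(), j = integer(),
                                            order = integer()))
    g$smiles <- smiles
    return(g)
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("cannot parse SMILES '", smiles, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  g <- mol_from_sdf(sdf[[1]])
  if (g$n == 0L) stop("cannot parse SMILES '", smiles, "': no atoms", call. = FALSE)
  g$smiles <- smiles
  g
}

## Build a mol_graph from a ChemmineR SDF object; explicit hydrogens are
## stripped so atom indices refer to heavy atoms only.
mol_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(ab)) || ncol(ab) < 3) {
    stop("cannot parse molecule: malformed atom block", call. = FALSE)
  }
  elements <- sub("_.*$", "", rownames(ab))
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0), ncol = max(3L, length(bb)))
  bonds <- if (nrow(bb) > 0) {
    tibble::tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  } else {
    tibble::tibble(i = integer(), j = integer(), order = integer())
  }
  heavy <- which(elements != "H")
  idx <- match(seq_along(elements), heavy)
  bonds <- bonds[!is.na(idx[bonds$i]) & !is.na(idx[bonds$j]), , drop = FALSE]
  bonds$i <- idx[bonds$i]
  bonds$j <- idx[bonds$j]
  new_mol_graph(elements[heavy], bonds)
}

new_mol_graph <- function(elements, bonds) {
  structure(list(elements = elements, bonds = bonds, n = length(elements)),
            class = "mol_graph")
}

## Induced sub-molecule on a set of heavy-atom indices.
mol_subgraph <- function(mol, atoms) {
  atoms <- sort(atoms)
  idx <- match(seq_len(mol$n), atoms)
  keep <- !is.na(idx[mol$bonds$i]) & !is.na(idx[mol$bonds$j])
  bonds <- mol$bonds[keep, , drop = FALSE]
  bonds$i <- idx[bonds$i]
  bonds$j <- idx[bonds$j]
  new_mol_graph(mol$elements[atoms], bonds)
}

mol_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n = mol$n, directed = FALSE)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  }
  g
}

implicit_h <- function(mol) {
  val <- DEFAULT_VALENCE[mol$elements]
  val[is.na(val)] <- 0
  deg <- numeric(mol$n)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[k]
      deg[mol$bonds$i[k]] <- deg[mol$bonds$i[k]] + o
      deg[mol$bonds$j[k]] <- deg[mol$bonds$j[k]] + o
    }
  }
  pmax(0, val - deg)
}

## V2000 molblock for a mol_graph (coordinates are irrelevant for SMILES
## generation and written as zeros).
mol_to_molblock <- function(mol, title = "frag") {
  header <- paste0(title, "\n  kinconform\n\n",
                   sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000\n",
                           mol$n, nrow(mol$bonds)))
  atoms <- paste0(sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, mol$elements
  ), collapse = "\n")
  bonds <- if (nrow(mol$bonds) > 0) {
    paste0(sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j, mol$bonds$order),
           collapse = "\n")
  } else {
    NULL
  }
  paste0(header, atoms, "\n", if (!is.null(bonds)) paste0(bonds, "\n"),
         "M  END\n$$$$\n")
}

## Canonical SMILES for a list of mol_graphs (batched through Open Babel).
mols_to_canonical_smiles <- function(mols) {
  if (length(mols) == 0L) return(character())
  blocks <- vapply(mols, mol_to_molblock, character(1))
  out <- strip_ob_title(strsplit(
    ChemmineOB::convertFormat("SDF", "CAN", paste(blocks, collapse = "")),
    "\n"
  )[[1]])
  if (length(out) != length(mols)) {
    stop("molblock to SMILES conversion lost molecules (", length(out),
         " of ", length(mols), ")")
  }
  out
}

## Deterministic integer hash of an integer vector (exact in doubles).
hash_ints <- function(x) {
  h <- 0
  for (v in x) h <- (h * 1000003 + (v %% 2147483647)) %% 2147483647
  h
}

#' Circular (Morgan-style) fingerprint of a molecule
#'
#' Hashed circular fingerprint over the heavy-atom graph: the initial atom
#' invariant combines element, heavy degree and implicit hydrogen count;
#' each iteration rehashes an atom's invariant together with the (bond
#' order, neighbour invariant) multiset, up to `radius` shells. All
#' identifiers from all shells are folded onto `nbits` bits.
#'
#' @param smiles A single SMILES string.
#' @param radius Neighbourhood radius (default 2).
#' @param nbits Number of bits to fold onto (default 2048).
#' @return Sorted integer vector of set bit positions (0-based).
#' @export
morgan_fingerprint <- function(smiles, radius = 2, nbits = 2048) {
  mol_fingerprint(parse_smiles(smiles), radius = radius, nbits = nbits)
}

mol_fingerprint <- function(mol, radius = 2, nbits = 2048) {
  if (mol$n == 0L) return(integer())
  elem_code <- match(mol$elements, names(DEFAULT_VALENCE))
  elem_code[is.na(elem_code)] <- length(DEFAULT_VALENCE) + 1L
  nbrs <- vector("list", mol$n)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
      nbrs[[i]] <- rbind(nbrs[[i]], c(j, o))
      nbrs[[j]] <- rbind(nbrs[[j]], c(i, o))
    }
  }
  deg <- vapply(nbrs, function(m) if (is.null(m)) 0L else nrow(m), integer(1))
  nh <- implicit_h(mol)
  inv <- vapply(seq_len(mol$n), function(a) {
    hash_ints(c(elem_code[a], deg[a], nh[a]))
  }, numeric(1))
  ids <- inv
  if (radius >= 1) {
    for (r in seq_len(radius)) {
      inv_new <- vapply(seq_len(mol$n), function(a) {
        if (is.null(nbrs[[a]])) return(hash_ints(c(r, inv[a])))
        pairs <- cbind(nbrs[[a]][, 2], inv[nbrs[[a]][, 1]])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        hash_ints(c(r, inv[a], as.vector(t(pairs))))
      }, numeric(1))
      inv <- inv_new
      ids <- c(ids, inv)
    }
  }
  sort(unique(as.integer(ids %% nbits)))
}

#' Tanimoto similarity of two bit-set fingerprints
#'
#' @param a,b Integer vectors of set bit positions, as returned by
#'   [morgan_fingerprint()].
#' @return Similarity in \[0, 1\]; two empty fingerprints score 1.
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) parse_smiles(s)$n, integer(1), USE.NAMES = FALSE)
}

## Maximum common induced substructure size (heavy atoms), via the maximum
## clique of the modular product: vertices are element-compatible atom
## pairs, edges connect pairs that agree on adjacency. Bond orders are not
## compared so aromatic kekulization differences do not matter.
mcs_atom_count <- function(mol_a, mol_b) {
  na <- mol_a$n; nb <- mol_b$n
  if (na == 0L || nb == 0L) return(0L)
  pairs <- which(outer(mol_a$elements, mol_b$elements, "=="), arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(0L)
  adj_a <- matrix(FALSE, na, na)
  if (nrow(mol_a$bonds) > 0) {
    adj_a[cbind(mol_a$bonds$i, mol_a$bonds$j)] <- TRUE
    adj_a[cbind(mol_a$bonds$j, mol_a$bonds$i)] <- TRUE
  }
  adj_b <- matrix(FALSE, nb, nb)
  if (nrow(mol_b$bonds) > 0) {
    adj_b[cbind(mol_b$bonds$i, mol_b$bonds$j)] <- TRUE
    adj_b[cbind(mol_b$bonds$j, mol_b$bonds$i)] <- TRUE
  }
  np <- nrow(pairs)
  ok <- outer(pairs[, 1], pairs[, 1], "!=") &
    outer(pairs[, 2], pairs[, 2], "!=") &
    (adj_a[pairs[, 1], pairs[, 1], drop = FALSE] ==
       adj_b[pairs[, 2], pairs[, 2], drop = FALSE])
  ok[lower.tri(ok, diag = TRUE)] <- FALSE
  ij <- which(ok, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = np, directed = FALSE)
  if (nrow(ij) > 0) g <- igraph::add_edges(g, as.vector(t(ij)))
  as.integer(igraph::clique_num(g))
}
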