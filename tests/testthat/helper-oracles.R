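# Independent oracles and fixture builders used across the suite.

# --- PDB text construction -------------------------------------------------

pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     occ = 1, alt = "", elem = substr(name, 1, 1),
                     type = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, paste0(" ", name), alt, resn, chain, resno,
          x, y, z, occ, 0, elem)
}

# --- geometry --------------------------------------------------------------

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_structure <- function(structure, rot, trans) {
  for (fld in c("atoms", "ligand_atoms")) {
    a <- structure[[fld]]
    if (nrow(a) == 0) next
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot)
    a$x <- xyz[, 1] + trans[1]
    a$y <- xyz[, 2] + trans[2]
    a$z <- xyz[, 3] + trans[3]
    structure[[fld]] <- a
  }
  structure
}

mirror_structure <- function(structure) {
  structure$atoms$x <- -structure$atoms$x
  if (nrow(structure$ligand_atoms) > 0) {
    structure$ligand_atoms$x <- -structure$ligand_atoms$x
  }
  structure
}

# remove all atoms of given names from one residue ordinal
drop_atoms <- function(structure, ordinal, names) {
  keep <- !(structure$atoms$ordinal == ordinal &
              structure$atoms$atom %in% names)
  structure$atoms <- structure$atoms[keep, , drop = FALSE]
  structure
}

# --- Fisher: exhaustive enumeration over fixed margins ---------------------

enum_fisher_greater <- function(a, b, c, d) {
  m <- a + b  # with substructure
  n <- c + d  # without
  k <- a + c  # in conformation X
  xs <- max(0, k - n):min(m, k)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= a])
}

# --- similarity: brute force -----------------------------------------------

masked_distance_oracle <- function(va, vb) {
  sh <- !is.na(va) & !is.na(vb)
  sqrt(8 / sum(sh)) * sqrt(sum((va[sh] - vb[sh])^2))
}

brute_force_neighbors <- function(database, query_vec) {
  m <- as.matrix(as.data.frame(database)[, descriptor_names()])
  d <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) d[i] <- masked_distance_oracle(query_vec, m[i, ])
  ord <- order(d, database$structure_id, method = "radix")
  data.frame(structure_id = database$structure_id[ord], distance = d[ord])
}

random_descriptor_table <- function(n, seed, missing_rate = 0) {
  set.seed(seed)
  m <- matrix(rnorm(n * 8), n, 8)
  if (missing_rate > 0) m[matrix(runif(n * 8) < missing_rate, n, 8)] <- NA
  df <- tibble::as_tibble(as.data.frame(m))
  names(df) <- descriptor_names()
  df
}

# --- fragmentation: independent cut-set enumeration ------------------------

# Brute-force fragment enumeration working on a plain adjacency list with
# its own bridge test (edge removal + BFS) and component search; shares only
# the SMILES parser and serializer with the implementation.
enum_fragments_oracle <- function(smiles, max_cuts = 3, min_heavy = 10) {
  mol <- kinconform:::parse_smiles(smiles)
  n <- mol$n
  bonds <- mol$bonds
  adj <- lapply(seq_len(n), function(i) integer())
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], k)
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], k)
  }
  reach <- function(start, dropped) {
    seen <- logical(n)
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (e %in% dropped) next
        w <- if (bonds$i[e] == v) bonds$j[e] else bonds$i[e]
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    seen
  }
  is_bridge <- function(e) {
    !reach(bonds$i[e], e)[bonds$j[e]]
  }
  cuttable <- which(bonds$order == 1 & vapply(seq_len(nrow(bonds)),
                                              is_bridge, logical(1)))
  out_sets <- list()
  if (length(cuttable) > 0 && n >= min_heavy) {
    for (nc in seq_len(min(max_cuts, length(cuttable)))) {
      cut_sets <- if (length(cuttable) == 1L) list(cuttable)
                  else utils::combn(cuttable, nc, simplify = FALSE)
      for (cs in cut_sets) {
        assigned <- logical(n)
        for (v in seq_len(n)) {
          if (assigned[v]) next
          comp <- which(reach(v, cs))
          assigned[comp] <- TRUE
          if (length(comp) >= min_heavy && length(comp) < n) {
            out_sets[[paste(sort(comp), collapse = ",")]] <- sort(comp)
          }
        }
      }
    }
  }
  if (length(out_sets) == 0) return(character())
  subs <- lapply(out_sets, function(at) kinconform:::mol_subgraph(mol, at))
  sort(unique(kinconform:::mols_to_canonical_smiles(subs)))
}

# element-colored subgraph match: is `frag_smiles` a substructure of
# `parent_smiles`?
is_substructure <- function(frag_smiles, parent_smiles) {
  f <- kinconform:::parse_smiles(frag_smiles)
  p <- kinconform:::parse_smiles(parent_smiles)
  gf <- kinconform:::mol_igraph(f)
  gp <- kinconform:::mol_igraph(p)
  elems <- union(f$elements, p$elements)
  igraph::V(gf)$color <- match(f$elements, elems)
  igraph::V(gp)$color <- match(p$elements, elems)
  igraph::subgraph_isomorphic(gf, gp, method = "vf2")
}

# --- leader clustering: straight-line loop oracle --------------------------

leader_oracle <- function(smiles, heavy, cutoff) {
  ord <- order(-heavy, smiles, method = "radix")
  fps <- lapply(smiles[ord], morgan_fingerprint)
  cl <- integer(length(ord))
  reps <- list()
  for (i in seq_along(ord)) {
    hit <- 0L
    if (length(reps) > 0) {
      for (r in seq_along(reps)) {
        if (tanimoto(fps[[i]], reps[[r]]) >= cutoff) { hit <- r; break }
      }
    }
    if (hit == 0L) { reps[[length(reps) + 1L]] <- fps[[i]]; hit <- length(reps) }
    cl[i] <- hit
  }
  data.frame(smiles = smiles[ord], cluster = cl)
}

# --- MCS: recursive backtracking oracle ------------------------------------

mcs_oracle <- function(smiles_a, smiles_b) {
  a <- kinconform:::parse_smiles(smiles_a)
  b <- kinconform:::parse_smiles(smiles_b)
  adj <- function(mol) {
    m <- matrix(FALSE, mol$n, mol$n)
    if (nrow(mol$bonds) > 0) {
      m[cbind(mol$bonds$i, mol$bonds$j)] <- TRUE
      m[cbind(mol$bonds$j, mol$bonds$i)] <- TRUE
    }
    m
  }
  aa <- adj(a); ab <- adj(b)
  best <- 0L
  extend <- function(ma, mb) {
    best <<- max(best, length(ma))
    start <- if (length(ma) == 0) 1L else ma[length(ma)] + 1L
    if (start > a$n || length(ma) + (a$n - start + 1L) <= best) return()
    for (va in start:a$n) {
      for (vb in setdiff(which(b$elements == a$elements[va]), mb)) {
        ok <- TRUE
        for (t in seq_along(ma)) {
          if (aa[ma[t], va] != ab[mb[t], vb]) { ok <- FALSE; break }
        }
        if (ok) extend(c(ma, va), c(mb, vb))
      }
      # va may also be skipped entirely
    }
  }
  extend(integer(), integer())
  best
}
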