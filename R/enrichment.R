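## Substructure-conformation association: one-sided Fisher's exact tests
## with Bonferroni family-wise control, plus SMILES search of the annotated
## library by maximum-common-substructure score.

#' One-sided Fisher's exact test for substructure over-representation
#'
#' For the 2x2 table (a = ligands with the substructure bound to
#' conformation X, b = with it bound elsewhere, c = without it bound to X,
#' d = without it bound elsewhere), returns the exact hypergeometric upper
#' tail `P(A >= a)` given fixed margins — the one-sided ("greater")
#' Fisher p-value. A zero margin gives p = 1.
#'
#' @param a,b,c,d Nonnegative integer cell counts (vectorized).
#' @return p-values in \[0, 1\].
#' @export
fisher_one_sided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  cells <- cbind(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("contingency counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(cells) < 1)) {
    stop("contingency table total must be at least 1", call. = FALSE)
  }
  ## P(A >= a) with A ~ Hypergeometric(m = a+b, n = c+d, k = a+c)
  phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1) (default 0.05).
#' @param n_tests Number of tests (at least 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(length(alpha) == 1, length(n_tests) == 1)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (!(n_tests >= 1) || n_tests != round(n_tests)) {
    stop("n_tests must be a positive integer", call. = FALSE)
  }
  alpha / n_tests
}

#' Test every representative substructure against every conformation
#'
#' For each representative substructure and each of the five conformations,
#' builds the ligand-level contingency table (a ligand "contains" a
#' substructure when any fragment of that substructure's cluster lists the
#' ligand as a parent), computes the one-sided Fisher p-value, and flags
#' significance at the Bonferroni threshold with `n_tests` = the number of
#' representative substructures. Each substructure's conformational
#' specificity is the conformation with its smallest significant p-value,
#' otherwise `"none"`.
#'
#' @param fragments Clustered fragment tibble (from [cluster_fragments()])
#'   with `smiles`, `heavy_atoms`, `parents`, `cluster_id`,
#'   `is_representative`.
#' @param ligand_conformations Data frame mapping `ligand_id` to
#'   `conformation` (one of CIDI, CIDO, CODI, CODO, wCD).
#' @param alpha Family-wise error rate before correction (default 0.05).
#' @return An `enrichment_result` tibble: `substructure_id`, `smiles`,
#'   `conformation`, `a`, `b`, `c`, `d`, `p_value`, `alpha_corrected`,
#'   `significant`, `specificity`.
#' @export
enrich_library <- function(fragments, ligand_conformations, alpha = 0.05) {
  stopifnot(is.data.frame(fragments),
            all(c("smiles", "parents", "cluster_id", "is_representative")
                %in% names(fragments)),
            is.data.frame(ligand_conformations),
            all(c("ligand_id", "conformation") %in% names(ligand_conformations)))
  conf_map <- setNames(ligand_conformations$conformation,
                       ligand_conformations$ligand_id)
  stopifnot(all(conf_map %in% CONFORMATION_LEVELS))
  all_parents <- unique(unlist(fragments$parents))
  unmapped <- setdiff(all_parents, names(conf_map))
  if (length(unmapped) > 0) {
    stop("parent ligands without a conformation mapping: ",
         paste(head(unmapped, 5), collapse = ", "), call. = FALSE)
  }

  reps <- fragments[fragments$is_representative, , drop = FALSE]
  n_tests <- nrow(reps)
  alpha_c <- bonferroni_threshold(alpha, max(1L, n_tests))
  n_total <- length(conf_map)
  n_by_conf <- table(factor(conf_map, levels = CONFORMATION_LEVELS))

  rows <- purrr::map(seq_len(n_tests), function(k) {
    cl <- reps$cluster_id[k]
    members <- unique(unlist(
      fragments$parents[fragments$cluster_id == cl]
    ))
    n_with <- length(members)
    conf_members <- table(factor(conf_map[members],
                                 levels = CONFORMATION_LEVELS))
    tibble::tibble(
      substructure_id = paste0("S", cl),
      smiles = reps$smiles[k],
      conformation = CONFORMATION_LEVELS,
      a = as.integer(conf_members),
      b = n_with - as.integer(conf_members),
      c = as.integer(n_by_conf) - as.integer(conf_members),
      d = n_total - n_with - as.integer(n_by_conf) +
        as.integer(conf_members)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      substructure_id = character(), smiles = character(),
      conformation = character(), a = integer(), b = integer(),
      c = integer(), d = integer(), p_value = numeric(),
      alpha_corrected = numeric(), significant = logical(),
      specificity = character()
    )
    class(out) <- c("enrichment_result", class(out))
    return(out)
  }
  out$p_value <- fisher_one_sided(out$a, out$b, out$c, out$d)
  out$alpha_corrected <- alpha_c
  out$significant <- out$p_value <= alpha_c
  out <- out |>
    dplyr::group_by(.data$substructure_id) |>
    dplyr::mutate(
      specificity = if (any(.data$significant)) {
        .data$conformation[.data$significant][
          which.min(.data$p_value[.data$significant])]
      } else {
        "none"
      }
    ) |>
    dplyr::ungroup()
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Search the substructure library by SMILES
#'
#' Computes the maximum common substructure (MCS; largest common induced
#' subgraph, atoms matched by element) between the query and each library
#' entry. The match score is the MCS heavy-atom count divided by the
#' library entry's heavy-atom count; entries scoring at least `min_score`
#' are returned sorted by score (descending) then p-value (ascending).
#'
#' @param query A SMILES string.
#' @param library Data frame with a `smiles` column; `conformation` and
#'   `p_value` columns (e.g. a filtered [enrich_library()] result) are
#'   carried into the output and used for ranking when present.
#' @param top_k Maximum number of matches returned (default 25).
#' @param min_score Minimum match score (default 0.8).
#' @return Tibble of matches with `smiles`, `mcs_atoms`, `score` and any
#'   annotation columns present in `library`.
#' @export
search_by_smiles <- function(query, library, top_k = 25, min_score = 0.8) {
  stopifnot(is.data.frame(library), "smiles" %in% names(library))
  qmol <- parse_smiles(query)
  lib <- tibble::as_tibble(library)
  mols <- lapply(lib$smiles, parse_smiles)
  lib$mcs_atoms <- vapply(mols, function(m) mcs_atom_count(qmol, m),
                          integer(1))
  lib$score <- lib$mcs_atoms / vapply(mols, function(m) m$n, integer(1))
  lib <- lib[lib$score >= min_score, , drop = FALSE]
  ord <- if ("p_value" %in% names(lib)) {
    order(-lib$score, lib$p_value, lib$smiles, method = "radix")
  } else {
    order(-lib$score, lib$smiles, method = "radix")
  }
  head(lib[ord, , drop = FALSE], n = top_k)
}
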