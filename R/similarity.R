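## Descriptor-space similarity: Euclidean distance in the normalized
## descriptor space, with a masked variant for vectors carrying missing
## entries, and a brute-force neighbour ranking over a database table.

as_descriptor_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1, all(DESCRIPTOR_NAMES %in% names(x)))
    return(as.numeric(as.data.frame(x)[1, DESCRIPTOR_NAMES]))
  }
  if (is.numeric(x) && !is.null(names(x)) && all(DESCRIPTOR_NAMES %in% names(x))) {
    return(as.numeric(x[DESCRIPTOR_NAMES]))
  }
  stopifnot(is.numeric(x), length(x) == 8)
  as.numeric(x)
}

#' Euclidean descriptor distance with missing-value masking
#'
#' Distance over the descriptors observed in both vectors, rescaled by
#' `sqrt(8 / n_shared)` so distances stay comparable across missingness
#' patterns. Both vectors must live on the same normalized scale; when both
#' carry normalization provenance it is checked.
#'
#' @param a,b Descriptor vectors: one-row data frames or numeric vectors of
#'   length 8 (NA = missing).
#' @return Nonnegative distance.
#' @export
descriptor_distance <- function(a, b) {
  pa <- attr(a, "normalized_with"); pb <- attr(b, "normalized_with")
  if (!is.null(pa) && !is.null(pb) && !identical(pa, pb)) {
    stop("descriptor vectors were normalized with different ranges",
         call. = FALSE)
  }
  va <- as_descriptor_vector(a)
  vb <- as_descriptor_vector(b)
  shared <- !is.na(va) & !is.na(vb)
  n <- sum(shared)
  if (n == 0) stop("no shared observed descriptors; distance undefined",
                   call. = FALSE)
  sqrt(8 / n) * sqrt(sum((va[shared] - vb[shared])^2))
}

#' Rank database structures by descriptor distance from a query
#'
#' @param database Data frame with a `structure_id` column, the eight
#'   descriptor columns, and optionally `conformation`.
#' @param query Descriptor vector (one-row data frame or numeric length 8).
#' @param k Number of neighbours to return (larger than the database
#'   returns all).
#' @param ranges Optional `descriptor_ranges`; when given, both the query
#'   and the database are normalized before distances are computed.
#' @return Tibble of `structure_id`, `distance` (ascending; ties broken
#'   lexicographically by `structure_id`) and `conformation` when present.
#' @export
rank_neighbors <- function(database, query, k = 25, ranges = NULL) {
  stopifnot(is.data.frame(database), nrow(database) > 0, k >= 1,
            "structure_id" %in% names(database),
            all(DESCRIPTOR_NAMES %in% names(database)))
  if (!is.null(ranges)) {
    database <- normalize_descriptors(database, ranges)
    if (is.data.frame(query)) {
      query <- normalize_descriptors(query, ranges)
    } else {
      qdf <- tibble::as_tibble(as.list(setNames(as_descriptor_vector(query),
                                                DESCRIPTOR_NAMES)))
      query <- normalize_descriptors(qdf, ranges)
    }
  }
  qv <- as_descriptor_vector(query)
  attr(qv, "normalized_with") <- attr(query, "normalized_with")
  m <- as.matrix(as.data.frame(database)[, DESCRIPTOR_NAMES])
  d <- vapply(seq_len(nrow(m)), function(i) {
    vi <- m[i, ]
    attr(vi, "normalized_with") <- attr(database, "normalized_with")
    descriptor_distance(qv, vi)
  }, numeric(1))
  ord <- order(d, database$structure_id, method = "radix")
  out <- tibble::tibble(
    structure_id = database$structure_id[ord],
    distance = d[ord]
  )
  if ("conformation" %in% names(database)) {
    out$conformation <- database$conformation[ord]
  }
  head(out, n = min(k, nrow(out)))
}
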