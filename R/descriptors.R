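## The eight geometric descriptors of the alphaC-helix / DFG-motif
## configuration, plus min-max normalization onto (-1, 1).
##
## Descriptor order is fixed; a missing value (required atoms absent from
## the structure) is represented as NA, never zero-filled.

DESCRIPTOR_NAMES <- c(
  "d1_saltbridge_dist",   # beta3-Lys NZ <-> alphaC-Glu CD distance (A)
  "d2_phe_helix_dist",    # DFG-Phe ring centroid to helix axis (A)
  "d3_phe_proj_x",        # ring centroid, local frame x (A, along helix axis)
  "d4_phe_proj_y",        # ring centroid, local frame y (A)
  "d5_phe_proj_z",        # ring centroid, local frame z (A)
  "d6_helix_cos_angle",   # cos(helix axis, Glu Ca -> Asp Ca), in [-1, 1]
  "d7_dfg_pseudo_dihedral", # Ca pseudo-dihedral around the DFG triad (deg)
  "d8_glu_phe_dist"       # alphaC-Glu Ca <-> DFG-Phe Ca distance (A)
)

## d6 is already dimensionless in [-1, 1] and is exempt from normalization.
EXEMPT_DESCRIPTORS <- "d6_helix_cos_angle"

#' Names of the eight geometric descriptors, in canonical order
#' @return Character vector of length 8.
#' @export
descriptor_names <- function() DESCRIPTOR_NAMES

unit <- function(v) v / sqrt(sum(v^2))

## Least-squares helix axis: first principal axis of the helix Ca cloud,
## oriented N-terminus to C-terminus. Returns the axis direction and the
## centroid it passes through.
helix_axis <- function(helix_ca) {
  ctr <- colMeans(helix_ca)
  ax <- prcomp(helix_ca, center = TRUE)$rotation[, 1]
  if (sum(ax * (helix_ca[nrow(helix_ca), ] - helix_ca[1, ])) < 0) ax <- -ax
  list(axis = unit(ax), centre = ctr)
}

## Local frame anchored at the alphaC-Glu Ca: x along the helix axis, z the
## component of (beta3-Lys Ca - Glu Ca) orthogonal to x, y = z cross x
## (right-handed).
descriptor_frame <- function(helix_ca, glu_ca, lys_ca) {
  hx <- helix_axis(helix_ca)
  x <- hx$axis
  v <- lys_ca - glu_ca
  z <- v - sum(v * x) * x
  if (sqrt(sum(z^2)) < 1e-9) return(NULL)
  z <- unit(z)
  y <- unit(pracma_cross(z, x))
  list(x = x, y = y, z = z, origin = glu_ca, axis_centre = hx$centre)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Pseudo-dihedral (degrees, in (-180, 180]) over four points.
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) return(NA_real_)
  m1 <- pracma_cross(n1, unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

PHE_RING_ATOMS <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")

## Ring centroid of the DFG-Phe: mean of the six ring carbons, falling back
## to CG alone when the ring is incomplete; NULL when no ring atom exists.
phe_ring_centroid <- function(structure, phe_ord) {
  sel <- structure$atoms$ordinal == phe_ord &
    structure$atoms$atom %in% PHE_RING_ATOMS
  ring <- structure$atoms[sel, , drop = FALSE]
  if (nrow(ring) == 6) return(colMeans(as.matrix(ring[, c("x", "y", "z")])))
  cg <- atom_xyz(structure, phe_ord, "CG")
  if (!is.null(cg)) return(cg)
  NULL
}

#' Compute the eight geometric descriptors of a kinase structure
#'
#' Distances are in Angstrom, the pseudo-dihedral in degrees, the helix
#' angle as a cosine. A descriptor whose required atoms are absent is NA.
#'
#' @param structure A `kinase_structure`.
#' @param motifs A `motif_annotation` for the same structure.
#' @return A one-row tibble with the eight descriptor columns (see
#'   [descriptor_names()]); NA marks a missing descriptor.
#' @export
compute_descriptors <- function(structure, motifs) {
  stopifnot(inherits(structure, "kinase_structure"),
            inherits(motifs, "motif_annotation"))
  n <- nrow(structure$residues)
  ords <- c(motifs$dfg_asp, motifs$dfg_phe, motifs$dfg_gly, motifs$beta3_lys,
            motifs$alphac_glu, motifs$alphac_span)
  if (any(ords < 1 | ords > n)) {
    stop("motif annotation refers to residues outside the structure",
         call. = FALSE)
  }

  ca <- ca_matrix(structure)
  span <- motifs$alphac_span[1]:motifs$alphac_span[2]
  helix_ca <- ca[span, , drop = FALSE]
  helix_ok <- !anyNA(helix_ca) && nrow(helix_ca) >= 3

  glu_ca <- ca[motifs$alphac_glu, ]
  lys_ca <- ca[motifs$beta3_lys, ]
  asp_ca <- ca[motifs$dfg_asp, ]
  phe_ca <- ca[motifs$dfg_phe, ]

  frame <- if (helix_ok && !anyNA(glu_ca) && !anyNA(lys_ca)) {
    descriptor_frame(helix_ca, glu_ca, lys_ca)
  }

  nz <- atom_xyz(structure, motifs$beta3_lys, "NZ")
  cd <- atom_xyz(structure, motifs$alphac_glu, "CD")
  d1 <- if (!is.null(nz) && !is.null(cd)) sqrt(sum((nz - cd)^2)) else NA_real_

  centroid <- phe_ring_centroid(structure, motifs$dfg_phe)
  d2 <- d3 <- d4 <- d5 <- NA_real_
  if (!is.null(centroid) && !is.null(frame)) {
    w <- centroid - frame$axis_centre
    d2 <- sqrt(sum((w - sum(w * frame$x) * frame$x)^2))
    v <- centroid - frame$origin
    d3 <- sum(v * frame$x); d4 <- sum(v * frame$y); d5 <- sum(v * frame$z)
  }

  d6 <- if (!is.null(frame) && !anyNA(asp_ca) && !anyNA(glu_ca)) {
    sum(frame$x * unit(asp_ca - glu_ca))
  } else {
    NA_real_
  }

  d7 <- NA_real_
  if (motifs$dfg_asp > 1) {
    pre_ca <- ca[motifs$dfg_asp - 1L, ]
    gly_ca <- ca[motifs$dfg_gly, ]
    if (!anyNA(c(pre_ca, asp_ca, phe_ca, gly_ca))) {
      d7 <- dihedral_deg(pre_ca, asp_ca, phe_ca, gly_ca)
    }
  }

  d8 <- if (!anyNA(glu_ca) && !anyNA(phe_ca)) sqrt(sum((glu_ca - phe_ca)^2)) else NA_real_

  out <- tibble::tibble(d1, d2, d3, d4, d5, d6, d7, d8)
  names(out) <- DESCRIPTOR_NAMES
  out
}

#' Fit (-1, 1) normalization ranges from a descriptor table
#'
#' Ranges are the observed per-descriptor minimum and maximum, ignoring
#' missing entries. The cosine descriptor is already on the (-1, 1) scale
#' and is exempt.
#'
#' @param data Data frame containing the eight descriptor columns.
#' @return A `descriptor_ranges` tibble with columns `descriptor`, `low`,
#'   `high`, `exempt`.
#' @export
fit_normalization <- function(data) {
  stopifnot(is.data.frame(data), all(DESCRIPTOR_NAMES %in% names(data)))
  if (nrow(data) < 2) stop("need at least 2 descriptor vectors", call. = FALSE)
  rows <- lapply(DESCRIPTOR_NAMES, function(d) {
    v <- data[[d]]
    obs <- v[!is.na(v)]
    exempt <- d %in% EXEMPT_DESCRIPTORS
    if (!exempt) {
      if (length(obs) < 2) {
        stop("descriptor ", d, " observed fewer than twice", call. = FALSE)
      }
      if (max(obs) - min(obs) <= 0) {
        stop("descriptor ", d, " is constant; degenerate range", call. = FALSE)
      }
    }
    tibble::tibble(descriptor = d,
                   low = if (exempt) -1 else min(obs),
                   high = if (exempt) 1 else max(obs),
                   exempt = exempt)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("descriptor_ranges", class(out))
  out
}

ranges_id <- function(ranges) {
  signif(sum(ranges$low * seq_len(nrow(ranges))) +
           sum(ranges$high * (seq_len(nrow(ranges)) + 100)), 12)
}

#' Normalize descriptor values onto (-1, 1)
#'
#' Affine min-max rescaling `2 (v - low) / (high - low) - 1`; values
#' outside the fitted range are clamped to +/-1 so unseen conformations
#' still classify. Missing values stay missing and exempt descriptors pass
#' through unchanged.
#'
#' @param data Data frame containing the eight descriptor columns (extra
#'   columns are carried through untouched).
#' @param ranges A `descriptor_ranges` from [fit_normalization()].
#' @return `data` with descriptor columns rescaled; carries a provenance
#'   attribute identifying the ranges used.
#' @export
normalize_descriptors <- function(data, ranges) {
  stopifnot(is.data.frame(data), inherits(ranges, "descriptor_ranges"))
  out <- tibble::as_tibble(data)
  for (k in seq_len(nrow(ranges))) {
    d <- ranges$descriptor[k]
    if (ranges$exempt[k]) next
    v <- out[[d]]
    vn <- 2 * (v - ranges$low[k]) / (ranges$high[k] - ranges$low[k]) - 1
    out[[d]] <- pmin(1, pmax(-1, vn))
  }
  attr(out, "normalized_with") <- ranges_id(ranges)
  out
}
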