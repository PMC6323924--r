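---
title: "Classifying kinase conformations from geometric descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying kinase conformations from geometric descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Protein kinases switch between a small number of pharmacologically
distinct conformations, defined by two mobile elements of the ATP pocket:
the DFG motif (the Asp-Phe-Gly triad at the start of the activation loop)
and the alphaC-helix, whose conserved glutamate pairs with the
beta3-strand lysine in the active state. The four in/out combinations of
the two elements give CIDI (the active state), CIDO (the type-II inhibitor
pocket), CODI and CODO; structures whose DFG motif sits between in and out
are collected in a fifth, intermediate class, written `wCD` in this
package. kinconform classifies a kinase domain into these five classes
from its atomic coordinates, ranks other structures by conformational
similarity, and associates ligand substructures with conformations.

## Geometric descriptors

Eight descriptors summarize the alphaC/DFG configuration. Distances are in
Angstrom, the pseudo-dihedral in degrees:

| descriptor | meaning |
|---|---|
| `d1_saltbridge_dist` | beta3-Lys NZ to alphaC-Glu CD distance (the salt bridge) |
| `d2_phe_helix_dist` | DFG-Phe ring centroid to the alphaC-helix axis |
| `d3..d5_phe_proj_*` | ring centroid in a local frame at the alphaC-Glu Calpha |
| `d6_helix_cos_angle` | cosine between the helix axis and Glu->Asp Calpha vector |
| `d7_dfg_pseudo_dihedral` | Calpha pseudo-dihedral across the DFG triad |
| `d8_glu_phe_dist` | alphaC-Glu Calpha to DFG-Phe Calpha distance |

The helix axis is the first principal axis of the helix Calpha cloud,
oriented N- to C-terminus; the local frame takes x along that axis, z as
the component of the Lys-Glu Calpha vector orthogonal to x, and y
completing a right-handed system. The set separates the two biological
degrees of freedom: the salt bridge and helix angle (d1, d6) track the
alphaC state, the ring placement and pseudo-dihedral (d2-d5, d7) track the
DFG state. Descriptors whose atoms are absent from a structure are
reported missing, never zero-filled; the Phe ring centroid falls back to
the CG atom when the ring is incomplete, so mildly truncated side chains
degrade gracefully rather than fail.

All descriptors are invariant under rigid-body motion (tested to 1e-8). A
mirror flip negates the pseudo-dihedral and leaves the distances
unchanged, so chirality is visible to the classifier.

Before classification every non-angular descriptor is min-max rescaled to
(-1, 1) from the ranges observed in the training table; `d6` is already on
that scale and passes through. At prediction time, values outside the
fitted range are clamped to the boundary rather than rejected — an
uploaded structure in an unseen conformation must still classify.

## The two-stage forest

Classification runs in two stages of 1000-tree random forests
(`randomForest`, conventional defaults: `mtry = floor(sqrt(p))`,
unlimited depth, bootstrap sampling; the tree count matches the method
this package implements). Stage 1 predicts the DFG class (in / out /
intermediate) from the eight descriptors. Stage 2 predicts the alphaC
class (in / out) from the descriptors plus the DFG class, encoded as three
indicator columns to avoid imposing an ordinal scale. Rows with an
intermediate DFG motif are excluded from stage-2 training: their alphaC
state is by definition distorted, and at prediction time the intermediate
branch bypasses stage 2 entirely. Five-class probabilities are products of
the stage probabilities,

    P(wCD)  = P(DFG-intermediate)
    P(CIDI) = P(DFG-in)  * P(alphaC-in  | DFG-in)
    P(CODI) = P(DFG-in)  * P(alphaC-out | DFG-in)
    P(CIDO) = P(DFG-out) * P(alphaC-in  | DFG-out)
    P(CODO) = P(DFG-out) * P(alphaC-out | DFG-out)

with the label the arg-max, ties broken in the fixed class order. Whether
the stage probabilities should instead feed a separate calibration is an
open design question; the product rule is the simplest coherent choice and
keeps the stage calls inspectable.

Missing training cells are imputed before normalization by a
proximity-based loop in the style of `rfImpute`: initialize each missing
cell with its per-class column median, then for five iterations fit a
forest, compute row proximities (the fraction of trees in which two rows
share a terminal node) and replace each missing cell with the
proximity-weighted average of the observed values in its column. The loop
is deterministic given the seed. At prediction time — where no labels
exist — missing entries are filled by proximity to the training rows
through the stage-1 forest's terminal nodes; an all-missing vector falls
back to training medians and is flagged low-confidence.

The out-of-bag (OOB) error is reported per stage and for the combined
five-class call (stage-1 OOB call routes each row, non-intermediate rows
then take their stage-2 OOB call). Training is reproducible bit-for-bit
from `(data, seed)`.

## Similarity search

Structures are ranked by Euclidean distance in the normalized descriptor
space, so no descriptor dominates by its units. With missing entries the
distance is computed over the descriptors observed in both vectors and
rescaled by `sqrt(8 / n_shared)`, which keeps distances comparable across
missingness patterns instead of silently dropping incomplete database
rows. Ties order lexicographically by structure id, which makes ranking
independent of database row order.

## Fragment enrichment

Ligands in contact with the ATP pocket (any atom within 6 A of the DFG
triad, beta3-lysine or alphaC-glutamate; crystallographic additives
excluded by a built-in list) are exhaustively fragmented: every subset of
up to `max_cuts = 3` acyclic single bonds is deleted and each connected
component kept, hydrogen-capped, canonicalized, deduplicated and filtered
at `min_heavy_atoms = 10`. The cut-set bound makes "exhaustive"
well-defined — unbounded cut sets explode combinatorially — and is a
config knob. Capping open valences with hydrogens (rather than attachment
dummies) makes every fragment a valid standalone molecule for
fingerprinting. Note that positionally distinct but chemically identical
fragments (an internal and a terminal decane in a long alkane, say)
deduplicate to one record, since records are keyed by canonical SMILES.

Fragments are grouped by leader (sphere-exclusion) clustering on a
circular fingerprint (radius 2, 2048 bits, a Morgan-style hashed
fingerprint computed over the heavy-atom graph) at Tanimoto cutoff 0.90.
Processing order is descending heavy-atom count with ties broken by SMILES
in the C locale, so clustering is deterministic and the representative of
each cluster is its founder — the largest member.

Each representative substructure is tested against each of the five
conformations with a one-sided Fisher's exact test (the hypergeometric
upper tail, evaluated through `phyper`, accurate to well below 1e-12) on
the ligand-level 2x2 table; the counting unit is the ligand-structure
pair, so a ligand co-crystallized with k structures contributes k
observations. Significance uses a Bonferroni threshold of `alpha /
n_representatives` — dividing by the representative count (not
representatives x conformations) is what reproduces the corrected alpha of
4.7e-6 for a 10535-substructure library at alpha 0.05, which fixes that
interpretation. A substructure's conformational specificity is the
conformation with its smallest significant p-value, else `"none"`.

The annotated library is searchable by SMILES: the match score of a
library entry is the maximum common substructure size divided by the
entry's heavy-atom count, with matches at score >= 0.8 ranked by score
then p-value. MCS here is the maximum common induced subgraph with atoms
matched by element (bond orders and aromaticity are not compared, which
makes the match robust to kekulization differences at the cost of treating
e.g. cyclohexyl and phenyl as equivalent), computed exactly as a maximum
clique of the modular product graph. This is practical for fragment-sized
molecules; it is not intended for large-molecule screening.

## What the synthetic generators emulate

Three generators provide ground-truth-bearing inputs so the whole pipeline
is testable without downloads.

**Toy kinases** build an ideal alpha-helix (1.5 A rise, 100 degrees per
residue, 2.3 A radius) flanked by connected zig-zag segments, with
side-chain pseudo-atoms placed only where descriptors look: the Lys NZ
exactly `saltbridge_dist` from the Glu CD (axis-aligned, so the distance
survives the PDB format's 3-decimal coordinates), and the Phe ring
centroid at a requested position in the local descriptor frame (exact to
coordinate precision, about 0.002 A). The DFG-neighbourhood trace is made
deliberately non-planar so the pseudo-dihedral is generic. Residues no
descriptor touches get seed-dependent jitter; motif geometry is identical
across seeds. These fixtures exercise parsing, motif location and
descriptor geometry — they are not physically realistic proteins, and
passing tests on them says nothing about Ramachandran validity or real
side-chain packing.

**Descriptor datasets** draw Gaussian clusters at class centroids that
mirror the biology: DFG-in/out classes separate along d2-d5 and d7,
alphaC-in/out along d1 and d6, the intermediate class at the origin.
`separation` scales the centroids in units of the within-class standard
deviation; at `separation = 0` all classes coincide and any classifier
must hit chance. The default acceptance surrogate (50 rows per class,
3-sigma separation) trains in about two seconds and reaches zero OOB
error; real kinase descriptor tables are noisier, unbalanced and
correlated across descriptors, so the surrogate demonstrates the
machinery, not the field error rate.

**Ligand corpora** plant a substructure (default biphenyl) in every ligand
of one conformation and draw the other classes round-robin from sixteen
two-ring background scaffolds; every ligand is decorated with one random
single-atom substituent. Both the planted substructure and the scaffolds
are chosen so that no cut leaves a component at or above the heavy-atom
floor other than the scaffold itself, which makes the cluster structure of
the corpus exactly predictable. The alphabet size is a deliberate design
point: each substructure is tested against five conformations while the
Bonferroni divisor counts substructures only, so the family-wise error
under label permutation is controlled by the discreteness of the
hypergeometric support rather than by the union bound alone. With 100
ligands in classes of 20, sixteen background scaffolds keep every
background cluster's prevalence at 5, where the smallest attainable
p-value that could be called significant has probability well below 1e-3
per test — the exact calculation puts the per-replicate family-wise error
near 2%. With only eight scaffolds (prevalence 10) the same calculation
gives about 16%, which is why the default alphabet has sixteen.

## Numerical choices and edge cases

- Helix detection marks residue i helical when the Calpha(i)-Calpha(i+3)
  distance lies in [4.5, 5.5] A and Calpha(i)-Calpha(i+4) in [5.0, 6.8] A;
  runs of marked residues spanning at least 6 residues form a helix. This
  is robust to missing side chains and needs no hydrogen-bond assignment.
- Residue ordinals are 1-based positions in the parsed chain, the natural
  indexing in R; user-facing overrides use author numbering with insertion
  codes, since files in the wild do.
- Alternate locations keep altloc 'A' or blank, remaining ties broken by
  highest occupancy. Only MODEL 1 of multi-model files is read.
- The DFG triad is chosen among Asp-Phe-Gly triplets downstream of the
  alphaC-helix by proximity of the Asp Calpha to the Glu Calpha, ties to
  the lowest residue number; a triplet upstream of the helix (it happens
  in real sequences) is never preferred over a downstream one.
- `phyper` gives p = 1 automatically for zero-margin tables; contingency
  cells are validated as nonnegative integers.
- Fragmentation only ever cuts bridge bonds of order 1, so ring systems
  are never opened and every fragment is an induced subgraph of its
  parent.
- Imputation skips its forest refinement when no descriptor column varies
  (the proximity-weighted average would reproduce the initialization, and
  the underlying forest code cannot split constant data).

## Problem sizes

The test-suite and acceptance script run on: 250-row descriptor tables
(50 per class) with 1000-tree stages, 100-row similarity databases over
ten seeds, a 100-ligand corpus with 50 label permutations, exhaustive
Fisher verification over all 1819 tables with total at most 12, and 100
random rigid-body transforms of the toy kinase. These sizes were chosen to
exercise every code path at full statistical strength while keeping a
complete run near one minute.

## Limitations

- mmCIF, biological assemblies and multi-domain chains are out of scope;
  one kinase domain per run.
- The package ships no model trained on real structures; users train on
  their own labeled descriptor tables (`train --table`).
- Corpus-scale counts from real, PDB-wide ligand sets depend on the ligand
  universe and the exact fragmentation rules of other tools and are not
  reproduced here.
- The MCS definition (induced, element-matched) and the fingerprint
  (hashed circular, radius 2, 2048 bits) are fixed, documented choices;
  both are exposed as parameters where they matter.
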