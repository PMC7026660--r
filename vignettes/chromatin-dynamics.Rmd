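---
title: "Comparative chromatin dynamics with Gaussian network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative chromatin dynamics with Gaussian network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromodyn)
```

## The model

chromodyn treats a Hi-C contact map as the complete specification of
an elastic network: each genomic locus (a fixed-width bin, 50 kb by
default) is a node fluctuating isotropically about its mean position,
and each observed contact `M[i, j]` is a harmonic spring of that
strength. Under this Gaussian network model the statistics of the
fluctuations are entirely determined by the Kirchhoff matrix
`Gamma = diag(rowSums(M)) - M` (self-contacts carry no spring meaning
and are dropped). Its eigenvectors are the collective modes of motion,
sorted by eigenvalue so that mode 1 is the softest, most global
motion; `1/lambda_k` acts as the statistical weight of mode `k`. The
mode-restricted covariance `C = sum_k u_k u_k^T / lambda_k` gives the
per-locus mean-square fluctuation (its diagonal) and the
locus-locus correlation cosines `D = cov2cor(C)`.

The key assumptions are those of any elastic-network treatment:
contacts define springs up to one global scale (so all mobilities are
relative, and profiles are normalized to mean 1 before comparison);
the network is analysed at equilibrium; and a single connected
component is required, because every extra component contributes one
more zero mode. `filter_bins()` enforces connectivity by dropping
contact-free bins and keeping the largest connected component, while
recording a validity mask so every downstream profile can be
re-indexed to original genomic coordinates. Cells whose filtered maps
differ (e.g. in centromeric gaps) are compared after `align_fits()`
intersects their masks and renormalizes each mode shape on the shared
bins.

## Comparing cells

Mode shapes of two cells are compared by absolute correlation cosines
(the direction of a harmonic fluctuation is immaterial), collected in
an overlap matrix. Because similar shapes need not occupy the same
spectral position in two cells, equivalent modes are identified by
solving a linear assignment problem with cost `1 - overlap`,
restricted to a candidate window of `window_factor * m` modes
(default 4, so the top `m` reference modes may be matched by up to
`4m` candidate modes). The solver is an exact Jonker-Volgenant
shortest-augmenting-path implementation; ties between equally cheap
candidates resolve to the smaller mode index so outputs are
reproducible. Two summaries of a matching are provided, because
"change in mode population" admits two readings: the default
`replacement_fraction()` counts reference modes whose equivalent lies
beyond the candidate's own first `m` (the mode population actually
changed), while `kind = "displaced"` counts any index disagreement.

Whole-covariance similarity uses the covariance overlap `L`, computed
from normalized mode weights `w_k` rather than raw variances so that
libraries sequenced to different depths remain comparable, and is
converted to the arc distance `acos(L)` for tree building. The
conservation profile averages diagonal overlaps over all unordered
cell pairs — the mean, not the pair-count-scaled sum, since the
quantity is read as a per-mode conservation level in [0, 1].

Mobility profiles restricted to equivalent modes (`matched_mobility`)
keep each matched candidate mode's own eigenvalue by default; a
`reference_weights` flag substitutes the reference's weights instead.
The default is preferred because it answers "what does this cell's
dynamics look like through the reference's mode ordering" without
mixing the two cells' spectra.

## Dendrograms

Per-chromosome arc distances are aggregated per cell pair (maximum by
default — the most conservative statement of dissimilarity across
chromosomes; mean is available) into a complete distance graph. Two
trees are built: a Prim minimum spanning tree, in which biologically
intermediate cells may surface as internal, high-degree vertices, and
a Saitou-Nei neighbor-joining tree, in which every cell is a leaf.
Prim edge ties break lexicographically by label pair. NJ can return
negative branch lengths on non-additive inputs; these are clamped to
zero with the deficit shifted to the sister branch, preserving
leaf-to-leaf path lengths. Newick files carry the computed arc
distances as branch lengths; display scaling is left to the user.

## What the synthetic generator emulates

The generators provide planted ground truth for every downstream
stage. A base map combines three features Hi-C maps show: power-law
distance decay of cis contacts (`lag^-alpha`, default `alpha = 1`),
multiplicative enrichment inside TAD blocks (default 3x), and a weak
uniform trans background (1% of the cis baseline) that keeps the
genome-scope network connected. Counts receive multiplicative gamma
noise at a chosen coefficient of variation (default 0.1, a moderate
replicate-level variability; 0 gives the exact expectation).

"Cell types" are derived from a base map by spectral surgery: the
first K mode shapes are kept (optionally perturbed by a random
rotation of magnitude `strength`; matched-shape overlap is then
`1/sqrt(1 + strength^2)`, e.g. 0.96 at strength 0.3) while their
eigenvalues are reshuffled by a planted permutation. The low-frequency
subspace is widened to `2K + 10` modes and re-assembled with an
orthonormal complement so the surgery never leaks into the
high-frequency residual. Converting the modified Kirchhoff matrix
back to contacts requires a nonnegativity repair; chromodyn adds a
uniform background contact to all pairs instead of clipping negative
entries, because a uniform addition shifts every nonzero eigenvalue
by `c * n` while preserving all eigenvectors and their order exactly
— clipping, by contrast, removes a large fraction of off-diagonal
mass at realistic reshuffling magnitudes and destroys the planted
spectrum the generator is supposed to guarantee. Highly mobile loci
are planted by weakening a locus's contacts (factor 0.5), which
raises its mean-square fluctuation.

What the generator does *not* emulate: polymer-physics constraints,
restriction-site and mappability biases, compartment checkerboards,
copy-number effects, or the 125 real cell lines of expression
databases. Tests passing on these cohorts therefore demonstrate the
correctness and sensitivity of the machinery under the stated
generative model, not performance on real Hi-C libraries.

The 3D-structure generator inverts the cube-law contact-distance
relation `n = (k/d)^3` (used "forward" by `structure_to_contacts()`)
and embeds the resulting distances by classical multidimensional
scaling; absent contacts are placed at twice the largest finite
distance. Embeddings are validated by requiring Spearman correlation
above 0.8 between back-calculated and target contacts.

## Numerical choices

- Eigenvalues below `1e-10 * lambda_max` are treated as zero modes;
  a connected network must have exactly one, and `decompose()` errors
  on more unless `allow_disconnected = TRUE` (used when counting
  components).
- Dense `eigen()` below n = 2000 (or when most of the spectrum is
  requested); sparse shift-invert partial eigendecomposition above.
- Eigenvector signs are fixed so the largest-magnitude component is
  positive; within near-degenerate eigenvalue clusters (relative gap
  < 1e-9) modes are ordered by the index of their largest component.
  Overlaps within a degenerate cluster remain basis-dependent.
- The covariance-overlap bracket is snapped to zero below 1e-12
  because the outer square root amplifies floating-point residue
  (`sqrt(1e-16) = 1e-8`); correlation cosines and overlaps are clipped
  only for excesses below 1e-9, larger violations are errors.
- `call_hm_loci()` returns exactly `ceiling(fraction * n)` loci, ties
  at the threshold resolved toward the lower bin index. The top
  fraction is taken over all genome bins jointly.
- `jaccard()` of two empty sets is 0, keeping screening ranks total;
  screening ties order alphabetically.
- Gene-bin overlap uses the BED convention: half-open intervals,
  inclusion at >= 1 bp of intersection.
- Trans contacts are passed into the genome-scope network unscaled;
  no ICE/KR balancing is applied anywhere — raw counts are accepted
  as spring constants.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `bin_size` | 50 000 bp | locus width; all generators and readers agree on it |
| `n_modes` | 500 | retained softest modes; the slow end dominates mobility, so profiles stabilise well before the full spectrum |
| `window_factor` | 4 | candidate pool size for equivalent-mode search |
| `hm fraction` | 0.10 | top share of relative mobility called highly mobile |
| `aggregate` | max | per-pair aggregation of chromosome arc distances |
| `strength` | 0.2 | generator shape perturbation; 0.3 still leaves overlaps ~0.96 |
| `noise_level` | 0.1 | CV of multiplicative count noise |
| `intra_tad_boost` | 3 | contact enrichment within TAD blocks |

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` exercise: pseudoinverse
agreement on 50 random connected maps of up to 50 loci; assignment
optimality against exhaustive enumeration on 200 instances up to
7x7; permutation recovery on 400-locus maps with the first 20 modes
reshuffled at strength 0.3 across 10 seeds; two-family dendrogram
cohorts of 6 cells at 120 loci; and the gene screen on 6-cell
cohorts at 240 loci with 30 decoy sets at contamination 0.2. These
sizes were chosen so each property is measured on cohorts large
enough to be diagnostic while the whole verification remains quick to
rerun.

## Interfaces

The package is a library: `gnm()` and the comparison functions are
the API, and `run_pipeline()` plays the role of a command-line driver,
consuming a YAML config and emitting TSV/Newick/BED/GMT files plus a
checksum manifest. The canonical on-disk interchange format for maps
is the sparse-triplet TSV (`bin1 bin2 count`) with a companion bin
table (`chrom start end`); a dense TSV reader is provided for small
matrices. Container-format (HDF5-backed) coolers are intentionally
not parsed.

## Known limitations

- Raw counts are trusted as spring constants; maps normalised with
  different pipelines should not be mixed in one cohort.
- Mode matching is quadratic in the window size in memory and cubic
  in time; at 500 modes and window 2000 the assignment is the
  dominant cost of a comparison.
- Overlap-based statistics within degenerate eigenvalue clusters
  depend on the eigenbasis returned by the solver.
- The NJ clamp-and-shift repair preserves path lengths but can place
  zero-length internal branches; consumers should tolerate
  polytomy-like geometry.
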