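# chromodyn

Chromatin intrinsic dynamics from Hi-C contact maps via the Gaussian
network model (GNM), with tools for comparing the dynamics across cell
types.

## The problem

A Hi-C experiment yields a symmetric matrix *M* whose entry
*M<sub>ij</sub>* counts (or weighs) the contacts between genomic loci
*i* and *j* at a fixed resolution (50 kb per locus by default). Treating
the loci as nodes of an elastic network with spring constants given by
the contacts, the equilibrium fluctuations of the chromatin are fully
determined by the Kirchhoff (graph Laplacian) matrix

&nbsp;&nbsp;&nbsp;&nbsp;Γ<sub>ij</sub> = −M<sub>ij</sub> (i ≠ j),
&nbsp;&nbsp;Γ<sub>ii</sub> = Σ<sub>j≠i</sub> M<sub>ij</sub>.

Eigenvalue decomposition of Γ yields normal modes (λ<sub>k</sub>,
**u**<sub>k</sub>): mode shapes **u**<sub>k</sub> describe collective
displacement patterns of the loci and 1/λ<sub>k</sub> is each mode's
statistical weight. From the *m* softest modes the package computes

- the covariance matrix C = Σ<sub>k</sub> (1/λ<sub>k</sub>)
  **u**<sub>k</sub>**u**<sub>k</sub><sup>T</sup>, whose diagonal is the
  per-locus mean-square fluctuation (MSF, the "mobility" of a locus);
- directional cross-correlations D<sub>ij</sub> =
  C<sub>ij</sub>/√(C<sub>ii</sub>C<sub>jj</sub>) ∈ [−1, 1];
- the degree of collectivity of each mode (exponential entropy of
  **u**<sub>k</sub>²).

For comparing two cells A and B it provides

- mode–mode overlaps [S(A,B)]<sub>kl</sub> = |**v**<sub>k</sub><sup>A</sup> ·
  **v**<sub>l</sub><sup>B</sup>| and their cohort-averaged conservation
  profile ⟨S⟩<sub>k</sub>;
- optimal *equivalent-mode* matching: the injective assignment of A's
  first *m* modes into B's first 4*m* modes minimising Σ(1 − S<sub>kl</sub>),
  solved exactly by a Jonker–Volgenant (Hungarian-family) algorithm;
- the covariance overlap L(A,B) ∈ [0, 1] built from normalised mode
  weights w<sub>k</sub> = (1/λ<sub>k</sub>)/Σ(1/λ<sub>l</sub>), and the
  arc distance d<sub>cov</sub> = arccos L;
- cell dendrograms over the arc distances: Prim minimum spanning tree
  and Saitou–Nei neighbor joining, both Newick-serialisable;
- a mobility screen: relative mobilities Δ⟨Δr²⟩<sub>q</sub> (cell MSF
  minus cohort mean), highly mobile loci (top 10%), their genes
  (HMGs), and Jaccard-ranked matches J = |HMG ∩ HEG| / |HMG ∪ HEG|
  against highly-expressed-gene collections (GMT format).

Because the package is exercised on synthetic data, it also ships
generators with planted ground truth: TAD-structured distance-decaying
contact maps, families of "cell types" that share mode shapes but have
reshuffled mode frequencies, gene annotations, contaminated gene-set
collections, and 3D structure embeddings obeying the inverse-cube
contact–distance law n = (k/d)³.

## Worked example

```r
library(chromodyn)

spec <- synth_spec(n_loci = 120, tad_boundaries = c(30, 60, 90),
                   noise_level = 0.1, seed = 7)
map <- filter_bins(generate_contact_map(spec))
fit <- gnm(map, n_modes = 40, label = "base")
fit
#> Gaussian network model fit (base)
#>   loci: 120   modes retained: 40   zero modes removed: 1
#>   eigenvalue range: [ 213.1214 , 2034.628 ]

head(coef(fit), 5)          # softest eigenvalues (frequency scale)
#> [1] 213.1214 347.6782 461.9793 817.2880 831.4168
head(collectivity(fit), 3)  # slow modes are delocalized
#> [1] 0.6958266 0.9169024 0.6855295
```

Plant a frequency reshuffle (mode shapes kept, eigenvalues of the
first five modes permuted by π = (3, 1, 2, 4, 5)) and recover it:

```r
fam <- generate_cell_family(map,
  list(planted_perturbation(c(3, 1, 2, 4, 5), integer(), "shuffled")),
  strength = 0.2, seed = 1)
other <- gnm(fam$shuffled, n_modes = 40, label = "shuffled")
mm <- match_modes(fit, other, m = 5)
data.frame(ref_mode = 1:5, cand_mode = mm$assignment,
           overlap = round(mm$overlaps, 3))
#>   ref_mode cand_mode overlap
#> 1        1         3   0.981
#> 2        2         1   0.981
#> 3        3         2   0.981
#> 4        4         4   0.981
#> 5        5         5   0.981
```

The matching sends reference mode *k* to candidate mode π(k): the
planted permutation is recovered exactly, with matched-shape overlaps
0.98 (= 1/√(1+0.2²), the expected value at perturbation strength 0.2).
Cell–cell similarity of the full covariances:

```r
L <- covariance_overlap(fit, other)
c(L = L, d_cov = covariance_distance(L))
#> covariance overlap L = 0.798   arc distance = 0.647
```

`run_pipeline(config)` chains all stages (simulate → fit → match →
trees → gene screen) from one YAML/list config and writes TSV/Newick/
BED/GMT outputs plus a checksum manifest; see `?run_pipeline`.

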