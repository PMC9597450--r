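---
title: "Methods: dominant-marker diversity and karyotype asymmetry with bandkaryo"
author: "bandkaryo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant-marker diversity and karyotype asymmetry with bandkaryo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandkaryo)
```

# The analysis bandkaryo implements

Crop germplasm surveys routinely characterize a handful of genotypes with
three complementary data layers: dominant DNA fingerprints (ISSR, SCoT),
protein profiles (SDS-PAGE), and classical cytogenetics (metaphase
chromosome measurements). The raw data are small — a binary band-scoring
matrix per marker system and a table of chromosome arm lengths — but the
derived statistics span marker informativeness, Hardy–Weinberg-based
diversity estimates, karyotype asymmetry indices, and similarity-based
clustering. `bandkaryo` implements that full chain as composable, tested
functions plus a deterministic pipeline.

# Band matrices and band classes

The atomic observation is a *band*: a fragment of a given size produced by
one assay (a PCR primer or a protein gel), scored 1/0 for presence in each
genotype. Bands are classified from their presence pattern across the
`n` genotypes:

* **monomorphic** (MB) — present in all `n`;
* **unique positive** — present in exactly one genotype;
* **unique negative** — absent from exactly one;
* **polymorphic** otherwise.

Unique bands of both kinds are genotype-specific markers and are counted
inside the polymorphic total, so `MB + PB = TAB` always holds, and
`UB <= PB`. A band present in no genotype can arise in synthetic data; it
is never "scored", so it is excluded from `TAB`. Missing data is not
modelled: only clearly scored bands enter the matrix, so every cell must be
0 or 1 and the reader rejects anything else, naming the offending row and
column.

Two accountings of genotype-specific markers coexist in this literature:
per-assay UB columns in primer tables, and per-genotype catalogues of
positive/negative specific bands. These need not reconcile when bands are
re-scored between analyses, so the package exposes both
(`summarize_assays()` and `unique_band_catalogue()`) and leaves
reconciliation to the analyst.

# Marker informativeness

For an assay with `PB` polymorphic bands out of `TAB`, and per-band carrier
frequencies `f_b` (fraction of genotypes carrying band `b`):

* polymorphism percentage `P% = 100 PB / TAB`;
* effective multiplex ratio `EMR = PB (PB / TAB)`;
* marker index `MI = PIC × EMR` (unrounded PIC);
* resolving power `Rp = Σ_b (1 − 2 |0.5 − f_b|)`.

Two PIC conventions are supported, because the dominant-marker literature
uses both without always saying which:

* `per_band_mean`: mean of `2 f_b (1 − f_b)`, bounded by 0.5;
* `phenotype_freq` (default): each genotype's multilocus banding pattern
  for the assay is one phenotype class with frequency `p_j`, and
  `PIC = 1 − Σ p_j²`, bounded by `1 − 1/n`.

The default is `phenotype_freq` because published assay-level PIC values
for multiband dominant fingerprints regularly exceed the 0.5 ceiling of the
per-band formula (values above 0.9 are reported for highly discriminating
primers), which is only possible under a multilocus-phenotype definition.
`f_b` is always computed over genotype columns. Report tables carry both a
`Total` row (summed counts; pooled `P% = 100 ΣPB / ΣTAB`) and an `Average`
row (arithmetic means of per-assay values); the two polymorphism summaries
answer different questions and are both emitted (`pooled_p_percent`,
`mean_p_percent` attributes). All values are kept at full precision
in-memory; rounding (default 2 decimals) happens only in
`write_report_table()`.

# Dominant-marker population genetics

A dominant band cannot separate homozygous from heterozygous carriers, so
allele frequencies are back-calculated under Hardy–Weinberg equilibrium
from the band frequency `f` within a population of `N` individuals:
`q = sqrt(1 − f)` (band-absent allele), `p = 1 − q`. Per locus:

* `Na` = number of segregating alleles (1 or 2);
* `Ne = 1 / (p² + q²)`, in `[1, 2]`;
* `I = −(p ln p + q ln q)` with `0 ln 0 = 0`, at most `ln 2`;
* `He = 2pq`, at most 0.5, maximal at `f = 0.75`;
* `uHe = [2N / (2N − 1)] He`.

`popgen_summary()` averages these over **all** loci — a locus fixed within
a population still contributes `Na = 1, Ne = 1, He = 0` — matching the
convention of the standard binary-data diversity software this replicates.
`N` is the number of individual columns in the population. Meaningful
positive `He` therefore requires several scored individuals per genotype: a
single column per genotype forces `He = 0` everywhere. The synthetic module
provides `generate_population_samples()` exactly for this, expanding each
genotype profile into replicate individuals with a small per-cell flip
probability. The per-genotype diversity tables published for this kind of
study cannot be reproduced numerically without knowing how many individuals
were scored per genotype (that count is typically unprinted), so the module
is validated structurally (closed forms per locus, brute-force re-summation)
rather than against printed diversity values. The narrative also includes a
harvest index helper, `100 × seed / (seed + stover)`, for the phenotype
table.

# Karyotype asymmetry

From haploid arm measurements (`s` short, `l` long, normalized `l >= s`,
lengths in µm), with `CL = s + l` and centromeric index `ci = s / CL`:

| index | definition |
|---|---|
| `HCL` | `Σ CL` |
| `TF%` | `100 Σs / ΣCL` (pooled), complement `AsK% = 100 − TF%` |
| `S%`  | `100 min(CL) / max(CL)` (Arano symmetry) |
| `CI`  | mean `ci` |
| `A`   | mean `(l − s)/(l + s)` (Watanabe), `MCA = 100 A` |
| `CVcl`, `CVci` | `100 sd/mean` of `CL` and `ci` |
| `A1`  | `1 − mean(s/l)` (Romero–Zarco intrachromosomal) |
| `A2`  | `sd(CL)/mean(CL) = CVcl/100` (interchromosomal) |
| `AI`  | `CVcl × CVci / 100` (Paszko) |

Chromosomes are classed on the arm ratio `r = l/s` with Levan-style bands
`nm [1, 1.7)`, `nsm (-) [1.7, 3)`, `nst [3, 7)`, `nt [7, ∞)`; the bands are
configurable because "nearly"-class software conventions vary and are
usually unprinted. The karyotype formula doubles the haploid class tallies
(fixed class order nsm (-), nst, nm, nt), so counts sum to 2n. The Stebbins
category combines the proportion of chromosomes with `r > 2` (rows 1–4)
with the largest/smallest length ratio (columns A, B, C at 2 and 4).
Telocentric chromosomes (`s = 0`) get `ci = 0`, an infinite arm ratio
(class `nt`, Stebbins `r > 2`), and contribute 0 to the `s/l` mean in `A1`.

Numerical conventions, all chosen where the field's tools are silent and
all switchable or documented: CVs use the sample standard deviation
(`n − 1`; `sd_type = "population"` switches); `CI` is the mean centromeric
index rather than the pooled `Σs/ΣCL`, which would simply duplicate
`TF%/100`; `S%` is implemented as the shortest/longest chromosome ratio,
consistent with published value ranges for this index. `AI` is reported for
completeness but published `AI` columns are not always consistent with the
`CVcl × CVci / 100` definition and the printed CVs, so it should be
cross-checked before comparison across studies. Useful identities — checked
as invariants on 1,000 random karyotypes in the test suite — are
`TF% + AsK% = 100`, `MCA = 100 A`, `A2 = CVcl / 100`, scale invariance of
every shape index, and permutation invariance in chromosome order.

# Similarity, trees, ordination

Genotype profiles are compared with the Dice coefficient
`2a / (2a + b + c)` (undefined only for two all-zero profiles). Trees use
classical UPGMA on `d = 1 − s`: size-weighted average-linkage agglomeration,
node height = half the merge distance (so the tree is ultrametric and
cophenetic distances equal merge distances), with a deterministic tie-break
by lexicographically smallest member label. UPGMA is implemented in the
package — the tie-break and height conventions are part of its contract —
and is verified in the tests against both `stats::hclust(method =
"average")` and a brute-force reference that recomputes every cluster
distance as the mean over all original cross pairs.

"PCA" on a similarity matrix in this literature is principal-coordinates
analysis: `pcoa()` double-centers `−d²/2`, eigendecomposes, scales
eigenvectors by the square root of their eigenvalues, clamps negative
eigenvalues (Dice distances need not be Euclidean) and reports explained
variance over the positive spectrum only. Planar configurations are
recovered to Procrustes residual below 1e−8 in the tests. Published
per-axis variance percentages from any particular study are functions of
the raw matrices, so they cannot be reproduced without those matrices;
ordination checks here are property-based.

`combined_feature_matrix()` prepares the multi-layer heatmap input: binary
marker columns concatenated with z-scored karyotype indices (zero-variance
indices dropped with a warning), with per-column provenance recorded, plus
UPGMA orders for rendering by external heatmap tools.

# The synthetic generators are constructive, not statistical

Because studies of this kind rarely deposit raw band matrices or arm
measurements, the generators build data whose *summary statistics hit the
published marginals exactly*, rather than sampling from a stochastic model
of evolution:

* `generate_band_matrix()` lays down exactly the requested numbers of
  monomorphic, unique-positive, unique-negative and other-polymorphic
  bands; "other polymorphic" carrier counts are drawn uniformly from
  `2..(n − 2)` so they can never collapse into the unique or monomorphic
  classes, making `summarize_assay(generate(spec)) = spec` an identity
  (property-tested over 500 random specs). With two genotypes a
  negative-unique pattern is indistinguishable from a positive-unique one,
  so specs demand `n >= 3` for negative uniques and `n >= 4` for other
  polymorphic bands. Fragment sizes are sampled without replacement purely
  as identifiers.
* `generate_karyotype()` has three constructive modes: a pooled short-arm
  fraction target (every chromosome split at `TF%/100`, exact), a uniform
  M-value target (`(l − s)/(l + s)` exact per chromosome, fixing `A` and
  `MCA`), and a chromosome-length CV target (a two-point length set solved
  by root finding to within 1e−9 of the requested sample CV, fixing `A2`).
  The two arm-split targets are mutually exclusive; either combines with
  the CV target. CV mode alone splits arms at a default M-value of 0.15, a
  mid-range value for near-metacentric complements, keeping the modes
  orthogonal.
* `generate_population_samples()` models within-genotype scoring variation
  as independent per-cell flips (rate `< 0.5`); it emulates replicate
  individuals, not drift or mutation.

All generators route randomness through a single integer seed
(`withr::with_seed`), leaving the caller's RNG untouched; equal seeds give
bit-identical output. What passing tests on these fixtures shows is that
the *arithmetic chain* from scored bands and arm lengths to every reported
index is correct; it says nothing about gel scoring quality, band
co-migration, or measurement error in real images, none of which are
modelled.

# Pipeline determinism and problem sizes

`run_pipeline()` composes the stages (read → markers → unique bands →
popgen → karyotype → clustering → phenotypes), writes every table as TSV
(display rounding only), newick trees, ideogram SVGs and a JSON manifest
(package version, config hash, seed); identical configs and inputs
regenerate byte-identical bundles, and every table value equals the
corresponding function applied directly. Stage failures are reported with
the stage name.

The test suite exercises the sizes this field actually works at — six to
twelve genotypes, tens of bands per assay, 13-chromosome complements —
plus exhaustive pattern enumeration to 8 genotypes (256 patterns), 200
random 6-leaf UPGMA cases against the brute-force reference, 1,000 random
karyotypes for the index identities and 500 generator round-trips; the
whole suite runs in well under a minute.

# Known limitations

* No missing-data convention: ambiguous bands must be resolved before
  import.
* He/uHe assume Hardy–Weinberg within populations; for selfing crops
  (sesame among them) the HWE back-calculation systematically biases
  allele frequencies, a known limitation of dominant-marker diversity
  estimates generally.
* UPGMA is the only tree method (matching the tools this workflow
  replicates); no bootstrap support.
* AMOVA, F-statistics and gene flow are out of scope.
* Ideogram SVG output is schematic (no banding patterns or satellites).
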