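# bandkaryo

Genetic-diversity analysis for small germplasm panels that combine
**dominant multilocus fingerprints** (ISSR, SCoT, SDS-PAGE protein
profiles) with **classical cytogenetics**. `bandkaryo` takes the two small
tables such studies actually produce — a binary band-scoring matrix and a
chromosome arm-measurement table — and computes every standard derived
statistic, reproducibly:

* **Band accounting** — monomorphic / polymorphic / genotype-specific
  (positive and negative unique) band classification per assay, with the
  invariant `MB + PB = TAB`.
* **Marker informativeness** — `P% = 100·PB/TAB`, polymorphism information
  content (`PIC`, per-band `2f(1−f)` or multilocus-phenotype `1 − Σp²`),
  effective multiplex ratio `EMR = PB·(PB/TAB)`, marker index
  `MI = PIC·EMR`, resolving power `Rp = Σ(1 − 2|0.5 − f_b|)`.
* **Dominant-marker population genetics** under Hardy–Weinberg
  (`q = √(1−f)`, `p = 1−q`): `Na`, `Ne = 1/(p²+q²)`,
  Shannon `I = −(p ln p + q ln q)`, `He = 2pq`,
  `uHe = [2N/(2N−1)]·He`, percent polymorphic loci.
* **Karyotype asymmetry** — `HCL`, `TF%`/`AsK%`, `S%`, centromeric index,
  Watanabe `A` and `MCA = 100·A`, `CVcl`/`CVci`, Romero–Zarco `A1`/`A2`,
  Paszko `AI`, Stebbins category, karyotype formula, ideogram coordinates
  and SVG export.
* **Clustering** — Dice similarity `2a/(2a+b+c)`, deterministic UPGMA with
  newick export, principal-coordinates ordination, and a combined
  marker + karyotype feature matrix for heatmaps.
* **Constructive synthetic data** — generators whose summaries hit
  user-specified targets *exactly* (band-class counts; pooled short-arm
  fraction, per-chromosome M-value, or chromosome-length CV), for fixtures
  and power studies when raw data are not deposited.
* **Pipeline** — `run_pipeline()` chains everything from a YAML config to
  a byte-reproducible bundle of report tables, trees and a JSON manifest.

## Worked example

```r
library(bandkaryo)

# three assays emulating typical primer-table structures over 6 genotypes
specs <- list(
  assay_spec("ISSR_1", n_genotypes = 6, n_monomorphic = 5,
             n_other_polymorphic = 1),
  assay_spec("ISSR_2", n_genotypes = 6, n_unique_pos = 9,
             n_other_polymorphic = 10),
  assay_spec("ISSR_3", n_genotypes = 6, n_monomorphic = 1,
             n_unique_pos = 6, n_other_polymorphic = 6)
)
bands <- generate_band_matrix(specs, seed = 42)
informativeness_table(bands)
```

```
  assay_id MB UB    PB   TAB FS_larger FS_smaller  PIC   EMR    MI P_percent    Rp
1   ISSR_1  5  0  1.00  6.00      1401        708 0.44  0.17  0.07     16.67  0.67
2   ISSR_2  0  9 19.00 19.00      2018         90 0.83 19.00 15.83    100.00 11.00
3   ISSR_3  1  6 12.00 13.00      1999         99 0.83 11.08  9.23     92.31  6.67
4    Total  6 15 32.00 38.00        NA         NA 2.11 30.24 25.14     84.21 18.33
5  Average  2  5 10.67 12.67        NA         NA 0.70 10.08  8.38     69.66  6.11
```

(values shown rounded to 2 decimals). An assay with a single polymorphic
band out of six scores `P% = 16.67` and `EMR = 0.17`; an all-polymorphic
19-band assay reaches `P% = 100` and `EMR = 19`. The `Total` row pools the
counts (`P% = 100·ΣPB/ΣTAB = 84.21`), the `Average` row is the mean of
per-assay values.

```r
k <- generate_karyotype(n_chromosomes = 13, total_length = 108.47,
                        tf_percent = 41.5, seed = 42)
karyotype_summary(k)[c("HCL", "TF_percent", "AsK_percent", "A", "MCA",
                       "CVcl", "A2")]
#>    HCL  TF_percent AsK_percent     A    MCA   CVcl    A2
#> 108.47       41.50       58.50  0.17  17.00  21.47  0.21
```

Fixing the pooled short-arm fraction at 41.5% forces the asymmetry
percentage to its complement, `AsK% = 58.50`; `MCA = 100·A` and
`A2 = CVcl/100` by identity.

```r
tree <- upgma(similarity_to_distance(dice_matrix(bands)))
ape::write.tree(tree)
#> ((G1:0.17647...,G5:0.17647...):0.06439...,(((G2:0.13636...,G3:0.13636...):
#> 0.06212...,G6:0.19848...):0.01966...,G4:0.21815...):0.02270...);
```

The tree is ultrametric; each leaf sits at half its cluster's merge
distance from the node, so cophenetic leaf-to-leaf distances equal the
UPGMA merge distances.

For a full run, write a YAML config naming the band-matrix files per marker
system (optionally karyotype measurements, a population map and a phenotype
table) and call `run_pipeline("config.yaml")`, or use the thin CLI at
`inst/cli/bandkaryo.R`. See the methods vignette
(`vignettes/bandkaryo-methods.Rmd`) for the statistical conventions and
their rationale.

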