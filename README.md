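# charmod

Differential chromatin accessibility modules from ATAC-seq cut-site
counts.

`charmod` is for epigenomics analysts working downstream of an ATAC-seq
experiment that compares T-cell states across biological conditions —
the motivating design contrasts naive CD8 T cells with antigen-specific
cells during primary HIV infection, after one year of antiretroviral
therapy, and after one year untreated. Starting from per-condition peak
calls (narrowPeak/BED) and per-sample fragment files (BED3), it builds
the merged peak universe, counts Tn5 cut sites per region, computes
FRiP and TSS-enrichment QC, tests every region for differential
accessibility between all condition pairs, clusters the differential
regions into accessibility modules, scores each module for
over-representation of exhaustion-state region categories, and calls
super-enhancer–associated genes from the ranked gene/region-count
curve. A deterministic synthetic-data generator with planted ground
truth makes the whole pipeline testable without any external data.

## The statistics at the core

* **Counting unit.** Each fragment contributes its two Tn5 insertion
  points; entry (r, s) of the count matrix is the number of cut sites
  of sample s inside universe region r. Coordinates are BED 0-based
  half-open throughout.
* **Differential testing.** Negative binomial, Var(Y) = mu + alpha mu^2,
  with median-of-ratios size factors, per-region method-of-moments
  dispersions moderated toward the cross-region center
  (alpha* = (d·alpha_r + d0·alpha0)/(d + d0), d0 = 10), and a Wald test
  on the condition coefficient referred to t with d + d0 df.
  Benjamini–Hochberg within each pairwise comparison; the differential
  set is the union over comparisons at FDR < 0.05.
* **Modules.** k-means (k = 4, k-means++ seeding, 10 restarts) on the
  row z-scored matrix of per-condition means of log2(normalized + 1)
  counts; labels ordered by cluster size for reproducibility.
* **Enrichment.** Hypergeometric fold enrichment
  FE = (k/n)/(K/N) with upper-tail p = P(X >= k),
  X ~ Hypergeom(N, K, n), per module and exhaustion-state category.
* **Super-enhancer genes.** GREAT-style basal-plus-extension regulatory
  domains (5 kb up / 1 kb down, extension to 1 Mb or the neighbor's
  basal boundary), region-to-gene assignment by midpoint containment,
  unit scaling of the ranked count curve, elbow at maximum
  perpendicular distance to the endpoint chord, SE genes = counts
  strictly above the elbow.

The methods vignette (`vignettes/charmod-methods.Rmd`) documents every
model, default and design decision, including the calibration evidence
for the dispersion moderation and the known bias of median-of-ratios
normalization under asymmetric differential composition.

## Worked example

```r
library(charmod)

sim_dir <- file.path(tempdir(), "example_study")
truth <- simulate_dataset(sim_dir, seed = 42)   # writes peaks, fragments,
                                                # counts, annotation, truth
res <- run_pipeline(sim_dir, file.path(sim_dir, "results"))
#> 1151 differential region(s) out of a universe of 2050

head(res$qc, 3)
#>   sample_id n_fragments     frip tss_enrichment
#> 1  naive_s1       20000 0.596525       8.042539
#> 2  naive_s2       20000 0.599925       7.779886
#> 3  naive_s3       20000 0.595650       9.340463

subset(res$enrichment, cluster == "A")
#>   cluster         category  k   n   K    N fold_enrichment      p_value
#> 1       A            naive 32 394 179 2050       0.9301534 7.139187e-01
#> 2       A         effector 32 394 158 2050       1.0537814 3.992628e-01
#> 3       A           memory 33 394 165 2050       1.0406091 4.287563e-01
#> 4       A early_exhaustion 33 394 159 2050       1.0798774 3.366098e-01
#> 5       A  late_exhaustion 76 394 153 2050       2.5845194 5.921183e-19

res$se_up
#> elbow_result: 35 ranked genes, elbow at rank 6 (count 1), 5 SE gene(s)
setequal(res$se_up$se_genes, truth$se_genes)
#> [1] TRUE
```

Reading the output: 1,151 of 2,050 universe regions are differential in
at least one pairwise comparison at FDR < 0.05. QC shows each simulated
library near its planted FRiP target of 0.6 and strongly TSS-enriched
(promoter regions concentrate cut sites around TSSs). The largest
module (cluster A here) carries the planted 3x late-exhaustion
enrichment: 76 of its 394 regions carry that category against a
universe rate of 153/2050, a 2.58-fold enrichment with a vanishing
hypergeometric p — the other categories sit at fold enrichment ~1. The
therapy-direction elbow call recovers exactly the five planted
super-enhancer genes.

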