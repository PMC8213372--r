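---
title: "Methods: differential chromatin accessibility modules from ATAC-seq cut sites"
author: "charmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential chromatin accessibility modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charmod)
```

# Scope and data model

`charmod` implements the downstream statistical analysis of an ATAC-seq
study of antigen-specific CD8 T cells sampled across four biological
conditions — naive cells, antigen-specific cells during primary
infection (baseline), after one year of antiretroviral therapy, and
after one year untreated. The package starts from called peaks and
aligned fragment coordinates; read processing, alignment and peak
calling are upstream and out of scope.

All coordinates are BED-convention 0-based half-open intervals,
everywhere. The analysis objects are:

* a **peak universe**: the union of per-condition peak calls with
  overlapping *and bookended* intervals merged. Bookended merging
  (`end == next start`) keeps region identifiers stable under small
  peak-boundary jitter between conditions.
* a **cut-site count matrix**: each sequenced fragment contributes its
  two Tn5 insertion points (first base, last base); entry (r, s) counts
  insertion points of sample s inside region r. Counting cut sites
  rather than whole fragments keeps one counting currency for the
  matrix and for FRiP-style QC.
* per-sample **QC metrics**: FRiP (fraction of cut sites in universe
  regions) and a TSS enrichment score.

The optional `+4/-5` Tn5 offset is applied at ingest only on request
(`apply_shift`), because most fragment files emitted by modern
pipelines are already shifted.

# Quality control

**FRiP** is the fraction of cut sites falling in any universe region; a
region boundary is start-inclusive, end-exclusive like every other
interval in the package.

**TSS enrichment** aggregates cut-site counts over ±`window` bp
(default 1000) around all TSSs, reversing minus-strand profiles, then
scores

$$\mathrm{TSS} = \frac{\max_t \tilde{c}(t)}{\bar{c}_{\text{flank}}}$$

where $\tilde{c}$ is the aggregate profile smoothed by a centered
moving average (default 51 bp) and $\bar{c}_{\text{flank}}$ is the mean
*raw* count over the outermost `flank` positions (default 100) on each
side. The smoothing step is essential, not cosmetic: the maximum of an
unsmoothed noisy profile is biased upward (for ~50 counts per position
the bias is ~50%), so an unsmoothed score cannot approach 1 on uniform
background at realistic depths. With the default 51 bp window the score
concentrates within ~±0.1 of 1 under uniform background at $10^5$
sites, while a sharp insertion peak at the TSS still dominates the
smoothed maximum. All three parameters (window, flank, smooth) are
exposed in the configuration.

# Differential accessibility

The count model is negative binomial with mean–dispersion
parameterization, $\mathrm{Var}(Y) = \mu + \alpha\mu^2$.

**Normalization.** Median-of-ratios size factors: the reference for
region r is the geometric mean of its counts across samples (rows with
any zero excluded); the factor for sample s is the median over rows of
$c_{rs}/\mathrm{ref}_r$, computed in log space and rescaled to
geometric mean 1. This reproduces the standard tool's estimator to
numerical precision (cross-checked in the test suite).

**Dispersion.** Per-region method of moments on normalized counts,
pooling the within-condition variance over all conditions with at
least two replicates: $\hat\alpha_r = \max(\text{floor},
(s_r^2 - \bar m_r)/\bar m_r^2)$ with floor $10^{-8}$. At 4–5
replicates per condition these estimates are noisy, and using them
directly in a Wald test is anti-conservative (null rejection at 5%
runs near 9%), while a plain $t_{n-2}$ correction gives up too much
power (sensitivity ~0.5 at a planted two-unit log2 effect). The
package therefore moderates the raw estimates toward the 10%-trimmed
cross-region mean with prior weight `prior_df` (default 10):

$$\alpha_r^\ast = \frac{d_r\,\hat\alpha_r + d_0\,\bar\alpha}{d_r + d_0},$$

where $d_r$ is the pooled residual df, and refers the Wald statistic
to a $t$ distribution with $d_r + d_0$ df. This is the moment-space
analogue of the empirical-Bayes variance moderation familiar from
microarray/RNA-seq linear modelling. Under the package's own
simulations (2,000 regions, 5+5 samples, $\alpha = 0.2$, mean depth
50) the null rejection rate at $p<0.05$ sits in 0.045–0.06 with
Kolmogorov–Smirnov distance from uniform below 0.03, and sensitivity
for a planted log2 fold change of 2 is 0.85–0.90 at an empirical FDR
below 0.05. No dispersion–mean trend, fold-change shrinkage, or
independent filtering is applied: the contract is calibrated error
control, not replication of any particular tool's output.

**Testing.** Per region, an NB log-linear model with the condition
indicator as the only covariate and log size factors as offsets is fit
by iteratively reweighted least squares with the fixed moderated
dispersion (convergence: coefficient change $<10^{-8}$, max 100
iterations; all-zero or non-converged regions are reported as `NA` and
excluded from the multiple-testing family). Fold changes are reported
as the second condition relative to the first. Benjamini–Hochberg
adjustment is applied *within each pairwise comparison*; the
differential ChAR set is the union of regions with $q < 0.05$ in at
least one of the six comparisons — the reading most consistent with
selecting regions "differential in at least one pairwise comparison".
The subject identifier is carried in the sample table but not
modelled; a paired design is out of scope.

A caveat that matters when half the universe is differential with a
directional skew (as in this study design, where ~30% of regions are
more accessible in antigen-experienced cells and only ~10% in naive
cells): median-of-ratios normalization assumes most regions are
unchanged between any two samples, and under this asymmetry the naive
samples' size factors absorb ~0.2 log2 units of bias. The two
comparisons against naive cells then run at a realized FDR of ~0.08
rather than 0.05, and the union of six comparisons carries an
empirical FDR of ~0.10. This is a property of the normalization
method itself (the reference implementation behaves identically), and
it is left visible rather than patched, because any correction would
change the normalization contract.

# Accessibility modules

For the differential set, normalized counts are transformed as
$\log_2(c/sf + 1)$ (a simple variance-stabilizing choice, recorded in
the configuration) and averaged within condition; each row is then
z-scored using the population (n-divisor) standard deviation, so
modules reflect the *shape* of accessibility across conditions rather
than baseline level. Constant rows become all-zero and are flagged.

k-means with `k = 4` (the four archetypes visible in the study's
clustered heatmap: naive-high; baseline/untreated-high; therapy-high;
shared) runs with k-means++ seeding and 10 restarts from a seeded
generator; the best within-cluster sum of squares wins, and labels
A, B, C, … are assigned by descending cluster size with ties broken by
the smallest member row index, so labels are reproducible run to run.

# Exhaustion-category enrichment

Regions carry at most one exhaustion-state category (naive, effector,
memory, early/late exhaustion — the standard murine chronic-infection
chromatin classes, supplied as an annotation table; the cross-species
mapping that produces it is out of scope). For a module of size $n$ in
a universe of size $N$ with $K$ category regions, $k$ of them in the
module:

$$\mathrm{FE} = \frac{k/n}{K/N}, \qquad
p = P(X \ge k),\; X \sim \mathrm{Hypergeom}(N, K, n).$$

The default background is the full universe; `background =
"differential"` restricts it to the differential set, since the
published description does not pin this choice down. An absent
category ($K=0$) yields an undefined fold enrichment (`NA`) with
$p = 1$.

# Super-enhancer–associated genes

Differential regions significant in the baseline-versus-therapy
comparison, filtered by fold-change sign (each direction analysed
separately), are assigned to genes via GREAT-style basal-plus-extension
regulatory domains: basal = 5 kb upstream / 1 kb downstream of the TSS
(strand-aware); each side extends to the nearer of 1 Mb from the TSS or
the adjacent gene's basal boundary; extension never shrinks the basal
domain; coordinates clip at zero. A region is assigned to *every* gene
whose extended domain contains the region midpoint — midpoint
containment gives each region–gene test a unique geometric answer,
where any-overlap rules do not.

Genes with zero regions are dropped; the rest are ranked by descending
count (ties broken by gene identifier), the curve is scaled to the unit
square ($x = (\text{rank}-1)/(n-1)$, $y = c/c_{\max}$), and the elbow
is the point of maximum perpendicular distance to the chord through the
first and last points — the documented behaviour of the cited elbow
finder, reimplemented deterministically and checked against a
brute-force distance scan. Ties go to the smallest index; a collinear
curve is flagged and yields an empty SE set. SE-associated genes are
those with counts *strictly greater* than the elbow gene's count (the
literal reading of "higher number of regions than the inflection
point"); a rank-based alternative would be easy to add but is not the
default.

# The synthetic study generator

`simulate_dataset()` emulates the study design end to end with one
master seed: identical seeds reproduce every file byte for byte.

* **Geometry.** Genes (default 200, minimum TSS spacing 20 kb) occupy
  one chromosome; bulk distal regions (default 2,000 total regions, 500
  bp, ≥300 bp apart) occupy a second, gene-free chromosome. Every gene
  receives one 500 bp promoter region centered on its TSS inside the
  basal domain. This separation makes the planted super-enhancer truth
  *identifiable*: a gene's associated-region count is driven only by
  its own TSS-proximal regions plus any planted excess, never by
  shared intergenic territory, and false-positive differential calls
  (which live on the distal chromosome) cannot leak into gene counts.
  Real genomes interleave genes and distal elements, so real rank
  curves have much heavier per-gene background; the SE recovery tests
  validate the caller's logic, not its behaviour on such backgrounds.
* **Modules.** Labels A–D with proportions (.1, .2, .1, .1) and 50%
  non-differential background, with per-condition multipliers of the
  planted log2 effect (default 2): A = naive-high (1,0,0,0);
  B = baseline/untreated-high (0,1,0,1); C = therapy-high (0,0,1,0);
  D = (0,1,0.75,1). The D archetype's "partial" therapy multiplier is
  0.75: at 0.5 the z-scored B and D templates are closer than the
  condition-mean noise at the default depth and replication, and no
  clusterer can separate them (nearest-true-template assignment tops
  out at ARI 0.80), which would defeat the purpose of planting
  recoverable structure.
* **Counts.** $c_{rs} \sim \mathrm{NB}(\mu_{rs}, \alpha)$ with
  $\mu_{rs} = \text{depth} \cdot b_r \cdot 2^{\text{template} \cdot
  \text{lfc}} \cdot s_s$; baseline accessibility $b_r$ log-normal
  (sdlog 0.5), sample size multipliers $s_s$ log-normal (sdlog 0.25)
  to exercise normalization, depth 50, $\alpha = 0.2$, 4 replicates
  per condition — negative-binomial counts at bulk-ATAC-like depth and
  replication. $\alpha = 0$ falls back to Poisson.
* **Categories.** The late-exhaustion label is planted so that module
  B's rate is exactly `enrichment_factor` (default 3) times the
  universe-wide rate — i.e. the quantity the hypergeometric fold
  enrichment estimates — with the other four categories uniform at 8%.
  Infeasible factors fail with the feasible bound in the message.
* **Super-enhancers.** Five genes receive 10 planted module-C regions
  (150 bp at 200 bp pitch) tiled inside their basal domains, about
  10 times the per-gene background of one promoter region.
* **Fragments.** Per-sample BED3 files place the target fraction
  (default 0.6) of fragments fully inside universe regions and the
  rest fully outside, with a three-component length mixture
  (sub-nucleosomal/mono/di, capped at 1 kb). Fragment files carry
  FRiP and TSS signal but deliberately uniform accessibility — the
  quantitative signal for the differential stages is the simulated
  count matrix, which `run_pipeline()` prefers when present. No GC
  bias, nucleosome periodicity or duplicate structure is modelled.

# Pipeline, determinism, problem sizes

`run_pipeline(input_dir, out_dir, config)` executes universe → counting
→ QC → differential → modules → enrichment → SE calling, validates all
inputs before any computation, writes every stage output as plain
BED/TSV/JSON, and records a `manifest.json` with the configuration,
input checksums, seed and stage timings. Rerunning on identical inputs
and configuration reproduces every stage output byte-identically
(manifest timings excepted). `validate_config()` applies defaults
(FDR 0.05; k = 4; GREAT 5000/1000/1 Mb; fragment cap 1000 bp; TSS
window 1000/flank 100/smooth 51), rejects unknown keys and
out-of-range values. There is no shell entry point: the exported
functions and this vignette are the interface, and the simulation
plus `run_pipeline()` cover the orchestration surface.

Test and validation problem sizes are chosen to exercise every
statistic at full fidelity while keeping the whole suite in the
low minutes on one CPU: 2,000-region universes, 4 conditions × 4
replicates for structure recovery, 2,000 × (5+5) for calibration,
$10^5$ sites for QC targets, and 10 generator seeds for
super-enhancer recovery.

# Known limitations

* Median-of-ratios normalization is biased when differential direction
  is heavily asymmetric (see above); comparisons against the naive
  condition are slightly anti-conservative in that regime.
* The NB engine deliberately omits dispersion–mean trends, fold-change
  shrinkage and independent filtering; results will not match any
  specific external tool region for region.
* Subject pairing is not modelled.
* The generator's clean gene/distal separation and one-category-per-
  region annotation are idealizations; passing recovery tests certifies
  the algorithms, not performance on real, messier data.
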