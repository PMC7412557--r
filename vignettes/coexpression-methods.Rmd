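---
title: "Methods: signed co-expression networks and target-TF discovery for aphid-infested switchgrass"
author: "switchnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed co-expression networks and target-TF discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchnet)
```

## The analysis in one paragraph

Switchgrass infested by greenbugs (GB) or yellow sugarcane aphids (YSA)
mounts transcriptional defense programs that unfold over days.
`switchnet` reconstructs the standard analysis route for such a study:
normalize RNA-seq counts, call per-contrast differentially expressed
genes (DEGs), build a signed weighted co-expression network over the
expressed genes, detect co-expression modules, select *target
transcription factors* (TFs likely to drive each module) by a
three-criterion cascade, extract each target TF's top-1% topological
overlap subnetwork, test modules and subnetworks for pathway enrichment
against the network background, and finally summarize transcript and
metabolite responses per pathway as *occupancy* percentages. Because
the real study's sequencing data are not bundled, the package ships a
synthetic-data generator that plants the study's qualitative structure
— six module profiles over a 3 treatment x 3 timepoint x 3 replicate
design — so every stage is testable end to end.

## Network model

For expressed genes $i, j$ with Pearson correlation $r_{ij}$ across all
27 samples (treatments pooled, since modules are defined by
treatment-responsive profiles), the signed adjacency is

$$a_{ij} = \left(\frac{1 + r_{ij}}{2}\right)^\beta,$$

which maps anticorrelation to weight near 0 rather than folding it onto
positive correlation. The topological overlap between two genes adds
shared-neighbour evidence:

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{u \ne i} a_{iu},$$

and $1 - \mathrm{TOM}$ is the clustering dissimilarity. Both are
implemented from these formulas (and tested against brute-force
oracles), not delegated.

The soft power $\beta$ is chosen as the smallest candidate whose
connectivity distribution passes a signed scale-free fit
($R^2 \ge 0.8$) while keeping mean connectivity $\ge 1$ — powers that
shatter the network into isolated nodes can fit a straight line
spuriously. When no candidate qualifies (the planted-block simulations
are deliberately not scale-free, so this is their normal path) the
signed-network convention $\beta = 12$ is used.

### Module detection

Average-linkage hierarchical clustering on $1-\mathrm{TOM}$ is cut
statically at height 0.90; clusters below 30 genes are pooled into the
unassigned set; modules whose eigengenes (first principal component of
the gene-standardized module submatrix, sign-fixed so mean member kME is
positive) correlate above 0.85 are merged iteratively; and finally genes
whose own-module kME falls below 0.5 are returned to the unassigned pool
— the static-cut analogue of WGCNA's `minKMEtoStay`.

Two of these defaults deserve justification, because a higher static
cut (0.99+) is common on real 30k-gene networks. At this fixture's
scale (2,000 genes, 27 samples) average-linkage chaining merges
unrelated clusters at heights around 0.94–0.99: background genes share
a weak size-factor-induced component that pulls them into the large
modules, and the two GB-responsive modules differ in only a few design
cells. A conservative cut (0.90) splits aggressively; the eigengene
merge step then repairs over-splitting, and kME pruning strips the
weakly attached bystanders. This combination recovers the six planted
modules with adjusted Rand index ≥ 0.85 across seeds, where a 0.995 cut
collapses everything into three mixed blocks. Both parameters are
exposed in `pipeline_config()` and `detect_modules()`; on larger, real
networks a higher cut is appropriate, and the cut stage is deliberately
a small, swappable function.

## DEG stand-in

The original analysis used a count-model Wald test and variance
stabilization. Reimplementing that machinery is not this package's
purpose; the network and TF stages only need a *calibrated DEG oracle*.
The stand-in is documented and swappable: median-of-ratios size factors
(geometric-mean reference over all-positive genes, total-count fallback)
with $\log_2(x/s_j + 1)$ values, then a per-gene Welch $t$-test of each
aphid treatment against control at the same timepoint,
Benjamini–Hochberg correction within contrast, and DEG =
$\mathrm{FDR} < 0.05$ and fold change $> 2$ (both strict, both
configurable).

Welch's test at $n = 3$ per group is intrinsically conservative: its
null rejection rate at nominal 0.05 is ≈ 0.033 even on Gaussian data
(the Satterthwaite degrees of freedom are estimated from two variances
of three values). The calibration test asserts the raw-p false-positive
rate within 0.05 ± 0.02 and power ≥ 0.8 at a planted two-unit log2 fold
change — both at the raw-p level, since the thresholding cascade above
it is deterministic arithmetic. With 3 replicates the BH step only
yields DEG calls when many genes move together, which is exactly the
situation the generator (and the original infestation experiment)
produces.

## The target-TF cascade

Within each module, a TF is a *target TF* when

1. it lies in the top 10% of own-module kME (ceiling count, boundary
   ties included);
2. its peak expression — the maximum of its nine condition means — is at
   or above the 75th percentile (linear-interpolation quantile) of peak
   expression over all expressed genes; and
3. it is a DEG, in the matching direction, in at least one of the
   module's *active cells*.

A detected module carries no planted profile, so criterion 3 derives the
active cells from the module itself: for each (aphid, timepoint) cell
the eigengene's infested-minus-control delta is computed, and cells with
$|\delta| \ge 0.5 \cdot \max|\delta|$ are active, with the delta's sign
giving the expected DEG direction. This operationalizes "maximal
expression differences associated with each module profile" without a
second statistic; the reported `delta` (the TF's normalized difference
at the module's strongest cell) preserves the "maximal" ranking for
presentation.

Per-TF subnetworks take the top $\lceil 0.01 (N-1) \rceil$ genes by TOM
score to the TF (row-wise, per TF — not a global TOM percentile — so
every subnetwork has a fixed size plus boundary ties).

## Enrichment and occupancy

Pathway enrichment of a module or subnetwork is a one-sided
hypergeometric (Fisher) right-tail test against the expressed-gene
background, $p = \sum_{x=k}^{\min(n,K)} \binom{K}{x}
\binom{N-K}{n-x} / \binom{N}{n}$. Significance is flagged on the raw
$p \le 0.05$, as in the original analysis, with BH-adjusted values
reported alongside for the reader.

Metabolite differential abundance runs a one-way ANOVA across the three
treatments per metabolite and timepoint on log abundances (LC-MS
abundances are right-skewed), followed by Tukey HSD contrasts of each
aphid treatment versus control when the ANOVA passes; running per
timepoint matches the per-date mean separations of the original
figures, and the scope is configurable.

Pathway occupancy is reporting arithmetic: per pathway, contrast and
direction, the percentage of the pathway's expressed genes (detected
metabolites) that are DEGs (differentially abundant) — numerator over
denominator, nothing more. Genes in several pathways count once per
pathway. Heatmap z-scores standardize each gene across all samples with
the sample standard deviation (ddof 1).

## What the generator plants, and what it does not

`simulate_dataset()` draws a 3x3x3 factorial with six module profiles
matching the published response table qualitatively: M1 suppressed by
both aphids, M7 an early burst at 5 DAI under both, M2 up at (GB, 5)
and (YSA, 15), M3 GB-only, M4 GB plus late YSA, M6 YSA-only. Cell
magnitudes ramp between 0.6 and 1.2 within each profile (responses grow
or fade over the infestation); this also keeps profiles that share
cells — M3/M4, M2/M7 — statistically separable, as separately detected
modules must be.

Per module, an eigenprofile is the profile times `effect_size` (default
3 log2 units at loading 1, i.e. 8-fold at the strongest cell — typical
of defense-gene induction and comfortably above the 2-fold DEG
threshold) plus per-sample replicate noise (sd 0.3). A member gene with
loading $L \in [0.5, 0.88]$ contributes $L$ times the eigenprofile on
top of its baseline, plus a per-(gene, condition) distortion with sd
$2(1-L) \cdot \mathrm{effect}/3$: loading controls both amplitude and
*fidelity*, so module membership (kME) genuinely orders genes by
coupling rather than saturating near 1 for everyone. The distortion
scales with the effect size and vanishes in a null simulation. Hub TFs
(5 per module) are tightly coupled drivers with $L \in [0.95, 1]$ —
disjoint from the member range, because hub status is a coupling
property, not the tail of the member distribution.

Baselines are centred so a gene's mean log2 abundance is uniform on
[5, 9] regardless of module sign (treatment effects redistribute
expression around a gene's characteristic level); hub TFs draw their
level from [7, 9], emulating robustly expressed regulators — the kind
the peak-expression criterion is designed to retain. Background genes
have loading 0 and independent per-sample biological noise (sd 0.3);
counts are negative binomial with dispersion 0.01, a deliberately small
value because biological variability is already modeled explicitly
(replicate noise, distortion, background noise) and should not be
counted twice.

Annotations flag the planted hubs as TFs (plus ~5% of background genes,
so selection precision is measurable), with family labels drawn from
families observed in switchgrass defense modules (WRKY, NAC, MYB, bHLH,
bZIP, AP2/ERF, C2H2, FAR1); the labels are cosmetic and never read by
selection. One pathway per module draws 60% of its members from that
module. Metabolites come in four planted sets (GB-biased peaking at 10
DAI, YSA-biased peaking at 15 DAI, and two shared sets with opposite
biases) plus unresponsive nulls, with lognormal noise.

The generator emulates the *statistical* structure the pipeline
assumes. It does not emulate sequencing depth effects beyond size
factors, transcript-length bias, batch structure (the study pooled four
plants per replicate and modeled no batch), correlated pathway
co-membership, or hormone kinetics. Passing tests therefore demonstrate
that the machinery recovers known structure under realistic noise — not
that it would reproduce any particular real dataset.

## Numerical choices and degenerate inputs

* Quantiles use R's default linear interpolation (type 7); all top-$k$
  rules use ceiling counts with boundary ties included, so tied genes
  are never silently dropped.
* Zero-variance genes are dropped (with a warning) before correlation,
  flagged with kME 0, and excluded from z-score tables; a module of
  all-constant genes has no eigengene and is an error.
* Degenerate test inputs (identical groups) give $p = 1$; separated
  constant groups give $p = 0$.
* Correlation round-off is clamped so adjacency and TOM stay exactly in
  $[0, 1]$; TOM is symmetrized after the matrix products.
* All randomness flows from explicit integer seeds; two runs with the
  same configuration and seed write byte-identical tables.

## Problem sizes

The bundled analyses and tests run the study-scale fixture: 6 x 150
module genes + 1,100 background genes, 27 samples, 40 pathways of 60
genes, 200 metabolites. At this size the full pipeline (network
included) completes in well under a minute on one CPU; the package has
no compiled code and scales as the dense 2,000-square TOM allows.
Block-wise processing for much larger networks is out of scope.

## Known limitations

* The Welch stand-in is conservative at $n = 3$ and underpowered for
  isolated effects; it is the documented, swappable oracle behind
  `call_degs()`, not a reimplementation of a count model.
* Static-cut clustering needs a scale-appropriate cut height; the
  default is tuned to the fixture scale (see above), not to 30k-gene
  networks.
* The module whitelist question — which detected modules are
  "defense-related" — is interpretive and left to the user; the
  pipeline reports all detected modules.
* Fisher significance on raw p mirrors the original analysis; users
  wanting family-wise control should read the reported `p_bh` column
  instead.
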