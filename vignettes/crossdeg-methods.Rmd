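---
title: "Methods: sign-concordance meta-analysis of cross-study fold changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sign-concordance meta-analysis of cross-study fold changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossdeg)
```

## The model

The unit of analysis is a *DEG record*: one gene's signed log2 fold
change in one published two-condition contrast, together with its study,
species, and tissue. The package relates a *seed* contrast (tame versus
aggressive rat hippocampus) to a stack of *partner* contrasts
(hypertensive versus normotensive subjects; domestic versus wild
lineages) through three statistical layers, each chosen to be exact at
the sample sizes that actually occur.

**Homology is data.** A rodent beta-globin and a primate delta-globin are
family-level homologs that no string rule can connect, so the pairing
stage consumes a curated map as a first-class input and adds only exact
normalized-symbol matches as a fallback (on by default, approximating the
implicit one-to-one matches of symbol-keyed compilations). A partner gene
differentially expressed in k study-tissue records contributes k pairs:
the record, not the gene, is the sampling unit throughout.

**Association of paired fold changes.** Four measures are reported
side by side because they weight the data differently: Pearson's r (the
fold-change magnitudes), Spearman's R and Kendall's tau-b (ranks), and
the Goodman–Kruskal gamma = (C − D)/(C + D), which drops tied pairs
entirely and is the natural statistic when many fold changes are printed
at two decimals and tie heavily. Gamma's p-value uses the classical
asymptotic statistic z = gamma * sqrt((C + D)/(n(1 − gamma^2))); it is
reported as `NA` at |gamma| = 1 where that variance vanishes. Pearson,
Spearman, and Kendall delegate to `stats::cor.test()` (Kendall exact only
for n <= 10 without ties); gamma is computed in-package by explicit pair
counting and is cross-checked in the tests against an independent
double-loop enumeration.

**Principal components of the standardized pair.** In correlation mode
the 2x2 matrix [[1, r], [r, 1]] has eigenvalues 1 − r and 1 + r with
fixed eigenvectors (1, −1)/sqrt(2) and (1, 1)/sqrt(2). For negatively
correlated pairs the leading component is therefore the *half-difference*
of the two fold changes and the second the *half-sum* — which is why the
sign-concordance counts below are labelled N_PC1 (opposite signs, i.e.
difference-aligned) and N_PC2 (matching signs, sum-aligned). The
implementation uses this closed form (tested against a generic
eigensolver to 1e-10) rather than a numeric decomposition; bootstrap
intervals resample the pairs with replacement under an explicit seed,
sign-align each replicate's eigenvectors to the point estimate by dot
product, and take percentile bounds on the loadings (default 999
replicates — a conventional odd count for percentile intervals).

**Exact sign-concordance test.** For one seed gene with N1 opposite-sign
and N2 matching-sign partner records, the null of sign-indifference is a
fair coin over N1 + N2 records, and the reported p-value is the one-sided
tail of the *larger* count, p = P(X >= max(N1, N2)). This rule is the one
that reproduces the published two-decimal p-values from their printed
counts — e.g. (6, 6) -> 0.61, (4, 1) -> 0.19, (0, 4) -> 0.06,
(15, 12) -> 0.35 — and it is symmetric in its arguments, strictly
decreasing in |N1 − N2| at fixed total, and equal to an exact
rational-arithmetic oracle for all totals <= 30 (all asserted in the test
suite). Tail summation uses `stats::pbinom()`, which is exact summation
in double precision at these totals; no normal approximation is ever
used. Partner records with log2 exactly 0 have no sign: they are excluded
from both counts and reported separately (`n_excluded_zero`). A seed gene
with no partner records is "not detected" (`ND`), carrying `NA` rather
than a number. The multiple-comparison correction is Bonferroni with
multiplier m = the number of seed genes *including* ND rows (42 in the
bundled study), overridable; with that convention the (10, 0) marker gene
gives 2^-10 * 42 = 0.041 < 0.05, consistent with the published
significance call. One bundled row, (7, 5), prints 0.83 where the
max-tail rule gives 0.387; no binomial-tail convention reproduces it, and
the acceptance tests document the discrepancy instead of modelling it.
The published adjusted value 0.05 for the (10, 0) row appears to be
rounded up from 0.041; the package reports unrounded values.

**Divergence contrast.** For domestic-versus-wild records, log2 < 0 means
the gene is downregulated in the domestic lineage relative to the most
recent common ancestor (and upregulated in the wild one); log2 = 0 is an
error, not a silent drop. Each polarized record contributes *two*
observations to the lineage-by-direction table — its downregulated state
with the annotated human consequence of downregulation, and its
upregulated state with the complement — so ten records yield the n = 20
table. Fisher's exact test uses the point-probability two-sided rule
(the convention of mainstream statistics suites, matched here by
`stats::fisher.test()` and cross-checked against a full hypergeometric
enumeration oracle); the chi-square statistic is Pearson's without the
Yates correction, which is the variant that reproduces the published
value 20.00 on the bundled table (Yates gives 16.2). Both variants are
exposed. Per-row exact binomial tails and their two-row product are
reported and labelled; the product is an interpretation, since the
published order-of-magnitude entry is ambiguous about the intended
combination. Likewise the neutral-drift "acceptance probability"
1 − P(X <= N_increase) for directional SNP-marker counts is labelled an
interpretation of the conventional genome-scan summary.

**qPCR layer.** Relative expression is the efficiency-corrected quantity
E_t^(−Cq_t) normalized by the *geometric mean* of the reference-gene
quantities (the standard multi-reference recommendation; amplification
factors are constrained to (1, 2]). An optional calibrator divides the
result, and common Cq baseline shifts cancel — asserted as an invariance
test. Group summaries are per-animal means over technical replicates,
then arithmetic means across animals; a "not detected" replicate or
animal is treated as missing, not as zero. The published group
dispersions (e.g. "± 1.71") are not recoverable from the printed
per-animal values by SD, SEM, or pooled-replicate formulas; the package
reports the SD of per-animal means and leaves it at that. The group
comparison is a Mann–Whitney U test whose null distribution is obtained
by complete enumeration of all choose(n1 + n2, n1) labelings of the
pooled mid-ranks (exact under ties, unlike the shift-algorithm
implementations) for combined n <= 25, and a tie-corrected normal
approximation beyond; `stats::wilcox.test()` serves as an independent
oracle for tie-free cases in the tests.

**DE caller.** The two-group stage computes per-gene
log2((mean_A + c)/(mean_B + c)) on counts-per-million-scaled values
(pseudocount c = 0.5 by default, configurable; scaling can be switched
off for pre-normalized input) and an unpooled-SE z statistic on the
log2-transformed values. The published pipeline names a "Z-test" without
a formula, so the reference distribution is a documented interpretation:
the default is Student's t with n_A + n_B − 2 degrees of freedom — for
balanced designs the unpooled-SE statistic coincides with the pooled one,
making that reference exactly calibrated at the 3-versus-3 sizes this
stage targets — while `reference = "normal"` gives the literal
2(1 − Phi(|z|)) formulation, which is anti-conservative at small n
(empirically ~0.12 at nominal 0.05 for n = 3). A Welch-df reference was
considered and measured conservative (~0.03) at n = 3; the pooled-df
choice keeps the null calibration tests meaningful. Degenerate inputs are
explicit: identical constant groups give z = 0, p = 1; zero pooled SE
with unequal means is an error. Multiplicity uses Benjamini–Hochberg via
`stats::p.adjust()`, validated to (0, 1] first. Name filtering removes
placeholder symbols (`LOC`/`RGD` prefixes, "predicted", "hypothetical",
"tentative", "uncharacterized", `-ps` pseudogene suffixes) and, when a
`biotype` column is present, non-protein-coding genes.

## The synthetic-data generators

The generators exist so every downstream stage can be tested against
planted truth, and their defaults are the bundled study's conditions:
151 homolog pairs at target correlation rho = −0.29; 42 seed genes with
1–10 family-level homologs each; 3-versus-3 negative-binomial count
matrices; 8 + 8 animals with 3 technical replicates for qPCR.

- `simulate_paired_log2()` draws from a zero-mean bivariate normal with
  common standard deviation `sigma_log2` (default 2, a typical spread for
  log2 fold changes of called DEGs) and correlation `rho`. Bivariate
  normality is a modelling assumption — the published data report only
  the observed correlations, not a distributional family. Continuous
  margins mean exact zeros never occur, so the sign counter's
  zero-exclusion path is exercised by hand-built fixtures instead.
- `simulate_deg_tables()` plants sign structure exactly: a
  round(`frac_discordant` * n) subset of seed genes receives partners
  whose log2 sign is always opposite to the seed's, the rest always
  matching, so the sign counter must recover the planted classification
  perfectly in the noise-free case (asserted).
- `simulate_counts()` uses the negative-binomial noise model standard for
  RNA-Seq counts (mean 200, dispersion 0.1 by default; variance
  mu + dispersion * mu^2); planted DEGs split a stated log2 effect
  symmetrically between the groups. The published study's upstream count
  model (a shrinkage-based DE framework) is out of scope; this generator
  feeds the package's own DE stage only.
- `simulate_qpcr()` applies a multiplicative group effect to log-normal
  measurement noise (CV 0.2 by default, typical for technical qPCR
  replicates).

All generators take an explicit integer seed through `sim_config()` and
touch no global RNG state (`withr::with_seed()`); fixed seed implies
byte-identical output, which the tests assert. What the generators do
*not* emulate: library-size artefacts, batch effects, correlated genes,
heavy-tailed fold-change distributions, or amplification-curve
pathologies. Passing tests on synthetic data therefore demonstrate
algorithmic correctness and calibration under the stated models, not
robustness to real-data pathologies.

## Numerical choices and problem sizes

- Exact binomial and hypergeometric quantities are double-precision tail
  sums; the oracle comparisons bound the error at < 1e-12 for the totals
  that occur (<= 64).
- The PCA tie at r = 0 is broken toward the difference direction, with a
  1e-12 tolerance so an exactly decorrelated sample is treated as a tie;
  |r| >= 1 − 1e-12 is treated as rank-deficient (warning, second
  eigenvalue 0).
- `impose_correlation()` rescales any paired sample to an *exact* target
  sample correlation (residual orthogonalization, then remixing); it is
  how the tests and the acceptance script study the PCA geometry at the
  observed correlation −0.29 without pretending a random sample hit it.
- Calibration studies use sizes chosen to finish in seconds while keeping
  Monte-Carlo error well below the asserted tolerances: 1000 replicates
  for generator-correlation recovery (SE ~ 0.0025 against a ±0.01 band),
  2000 null simulations for type-I error (SE ~ 0.005 against ±0.02), 200
  matrices of 50 genes for p-value uniformity (±2 SE band), 30–50
  matrices for the planted-recovery regression (full-scale power
  measured at 0.999, frozen as >= 0.9).

## Known limitations

- The full published pair set is not redistributable here; the bundled
  partner records cover the two marker-gene families only, so the
  battery/PCA stages on bundled data run at n = 37 and their published
  full-set values are exercised through the generators instead.
- The gamma p-value is asymptotic; at n < ~10 with heavy ties it is
  indicative only (the battery requires n >= 3 and refuses constant
  input).
- The DE caller is deliberately minimal — no dispersion shrinkage, no
  filtering on expression level — and is not a substitute for a
  full-featured DE framework on real counts.
- Family-level homology is only as good as the curated map; the fallback
  exact-symbol match can pair genes that share a symbol but not ancestry
  in pathological nomenclature cases.
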