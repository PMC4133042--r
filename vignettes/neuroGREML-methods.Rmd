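---
title: "Methods: SNP heritability of brain responses and network structure"
author: "neuroGREML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP heritability of brain responses and network structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroGREML)
```

## The scientific question

Individual differences in how the brain responds to facial expressions are
partly heritable. With a cohort of unrelated adolescents genotyped on a
genome-wide SNP array and scanned with a block-design fMRI face paradigm,
one can ask how much of the variance in each region's response is captured
jointly by common genotyped variants (the "SNP heritability", VG/Vp), and
whether that quantity relates to each region's role in the
face-processing network. neuroGREML implements that full analysis chain —
genotype QC, genomic relationship matrix (GRM), restricted-maximum-likelihood
variance components, functional-connectivity graphs, and second-level
count/trend statistics — driven by a synthetic-data generator with known
ground truth, since the original cohort data are access-restricted.

## The variance-component model

For a phenotype vector $y$ ($n$ unrelated individuals) the model is

$$ y = X\beta + g + \varepsilon, \qquad
   \mathrm{var}(y) = A\,V_G + I\,V_E, $$

where $A$ is the GRM computed from standardized dosages,

$$ A_{jk} = \frac{1}{N_{jk}} \sum_i
   \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2p_i(1-p_i)}, $$

with in-sample allele frequencies $p_i$, missing dosages imputed at $2p_i$
(contributing zero), and $N_{jk}$ the per-pair count of non-missing SNPs.
The heritability estimate is $V_G / V_p$ with $V_p = V_G + V_E$.

`remlUnivariate()` maximizes the restricted likelihood with one EM warm-up
step from $V_G = V_E = V_p/2$ followed by average-information (AI) updates,
to a relative log-likelihood tolerance of $10^{-8}$ (at most 100
iterations). The GRM is eigendecomposed once, so each iteration costs
$O(np^2)$. Numerical safeguards, chosen once and tested:

* **Constraint floor.** In constrained mode (the default) components are
  truncated at $10^{-6} V_p$. When a step pins one component at the floor,
  the AI step is re-solved for the free component (an active-set step), so
  the boundary cannot stall the other parameter.
* **Monotone ascent.** Any step that would lower the restricted likelihood
  is halved toward the current point until it does not; a singular AI
  matrix falls back to an EM step. Non-convergence flags the result rather
  than raising.
* **Standard errors** come from the inverse AI matrix, with the delta
  method for the ratio. At a boundary the AI matrix can be singular; the
  SE is then `NA` rather than a fabricated number.

### Testing against the null

Because $V_G \ge 0$ is a boundary constraint, the likelihood-ratio
statistic $2(\log L_{\text{full}} - \log L_{\text{null}})$ is null-distributed
as the 50:50 mixture of a point mass at zero and $\chi^2_1$. The
$\alpha = 0.05$ critical value of this mixture is the 0.90 quantile of
$\chi^2_1$:

```{r}
mixtureCriticalValue(0.05)
```

A constrained full model can sit a hair *below* the null likelihood
(the genetic component is pinned at $10^{-6}V_p$, not 0); `lrtVg()`
tolerates a deficit up to $10^{-3}$ and clamps the statistic at zero,
which is also where the mixture puts half its mass.

### Bivariate model

`remlBivariate()` extends the same machinery to two traits sharing one GRM,
with six components $(V_{G1}, V_{G2}, \mathrm{cov}_G, V_{E1}, V_{E2},
\mathrm{cov}_E)$ and the genetic correlation
$r_G = \mathrm{cov}_G / \sqrt{V_{G1} V_{G2}}$. After rotation by the GRM
eigenvectors the covariance is block-diagonal in $2\times2$ blocks, so all
projections vectorize over samples. Covariances are kept inside the
positive-definite cone ($|\mathrm{cov}| \le 0.9999\sqrt{V_1 V_2}$), which
is why a degenerate fit (the same trait twice) reports $r_G = 0.9999$
rather than exactly 1. When either genetic variance sits at its floor,
$r_G$ is ill-defined and the result is flagged `unstable`.

## Genotype QC and the GRM

`snpQC()` applies the three per-SNP filters in the order the counts are
reported for the emulated study — missingness $> 5\%$, Hardy–Weinberg exact
test $p \le 10^{-4}$, minor allele frequency $< 0.01$ — and records
per-filter removals (the counts are order-dependent, so the order is part
of the contract). `sampleQC()` removes samples with call rate strictly
below 97%. The HWE test (`hweExactTest()`) enumerates all heterozygote
counts compatible with the observed allele counts and sums the
probabilities of outcomes no more probable than the observed one; it is
tested exhaustively against an independently coded closed form for every
genotype triple with total $\le 50$.

Relatedness pruning (`pruneRelated()`) greedily removes the individual in
the most pairs above the 0.05 cutoff, ties to the lower index, until no
pair exceeds the cutoff — deterministic, and guaranteed sufficient by
construction. Ancestry covariates come from `grmPCA()`, the top
eigenvectors of the double-centered GRM (the study describes
identity-by-state PCs; with standardized dosages the two matrices carry the
same leading structure, and the GRM is used for both pruning and PCs).

A note on scale: the off-diagonal noise floor of a GRM is $1/\sqrt{m}$.
At the study's $m \approx 5\times10^5$ the 0.05 cutoff isolates true
relatives; at the demo scale of a few thousand SNPs it sits inside the
noise, so scaled-down pipeline runs raise the cutoff accordingly.

## The synthetic cohort

The generator's defaults state the emulated study: $n = 1620$ unrelated
individuals; an (independent-SNP) panel scaled down from the ~511K
genotyped SNPs, MAF uniform on $[0.05, 0.5]$; 200 causal SNPs per
phenotype; generating $V_G/V_p = 0.5$ — the value the study's power
analysis calls correctly estimable near this sample size; 25 ROIs; 8
acquisition sites; 160-volume sessions at TR 2.2 s.

* **Genotypes** are two summed Bernoulli($p$) draws per SNP
  (Hardy–Weinberg sampling), with optional missingness completely at
  random.
* **Phenotypes**: causal effects are drawn standard normal on standardized
  dosages and rescaled so the population $V_G$ equals the target exactly
  (the standard GCTA-style simulation); environmental noise is multivariate
  normal across ROIs with an exchangeable correlation of 0.3 by default
  (the study reports correlated ROI outcomes but no generative values; the
  default is configurable and deliberately modest). Additive per-site
  offsets (SD 0.3) and a small sex effect (0.1) are layered on for the
  covariate pipeline to remove. The within/between-subject split of the
  response is not stated anywhere; session noise (below) is a configurable
  default, not an inference.
* **BOLD sessions**: 19 task blocks of 8 volumes (9 control interleaved
  with 5 ambiguous and 5 angry) plus 8 rest volumes. 18-s blocks at TR
  2.2 s span 8.18 volumes; blocks are fixed at 8 volumes, matching the
  extraction arithmetic, and the remainder pads the run. Condition
  mean-shifts implementing the ground-truth percent signal change are
  placed 2 TRs late — the analysis only uses shifted block means, so no
  hemodynamic convolution is modelled. ROIs joined by an edge in the
  subject's connectivity graph draw their task-block noise from a
  multivariate normal whose pairwise correlation equals the coupling
  parameter (default 0.5, above the 0.3 edge threshold).

Two generator choices deserve emphasis. First, coupling acts during *all*
task blocks (face and control), not only face blocks: the condition series
that the connectivity step correlates concatenates 40 face with 72 control
volumes, so face-only coupling would dilute the realized correlation by
40/112 and no coupling value could reach the default 0.5. Second, for
dense graphs the target matrix $I + c\,A_{\text{adj}}$ is indefinite; it is
projected to the nearest correlation matrix (eigenvalue clip plus
rescaling). The projection preserves the edge/non-edge ordering (projected
edge correlations ~0.3–0.5, non-edges ~0.03) but the realized correlation
of a connected pair is no longer exactly the coupling value, and with 112
samples an edge near the threshold is misclassified in roughly 10% of
draws. Sparse configurations — the regime in which per-pair connection
proportions are asserted quantitatively — are exact. A green connectivity
test therefore establishes the graph pipeline's correctness and the
calibration of sparse worlds, not that dense observed proportions equal
the generating probabilities.

What the generator does **not** emulate: voxel-level images, motion,
hemodynamic shape, linkage disequilibrium between SNPs, and any real-data
estimate. Green tests establish parameter recovery inside this stated
world, nothing more.

## Connectivity and phenotype extraction

For each subject and face condition, `extractConditionSeries()` takes the
8 volumes starting 2 TRs after each block onset, mean-centers within
block, and concatenates (faces: 40 volumes; control: 72). The condition
correlation matrix concatenates face and control blocks by default (the
realization described for the emulated study); a face-only flag exists
because the published choice is not fully unambiguous. Edges are strict
$r > 0.3$; negative correlations never create edges; a shifted window that
would run off the session is an error, never a silent truncation. Percent
signal change is a transparent stand-in for the original SPM extraction:
$100 \times (\text{mean shifted condition} - \text{mean shifted control}) /
\text{mean whole run}$, preserving the contrast structure (condition
versus non-biological-motion control). Phenotypes are z-scored per
acquisition site; sex stays as a covariate.

## Second-level inference

* `expectedFalsePositives()`: $n \times \alpha$ (1.25 for 25 tests at
  0.05).
* `mcCountPvalue()`: the observed count of significant ROIs is referred to
  a Monte-Carlo null that draws correlated outcomes from the phenotypic
  correlation matrix (50,000 realizations by default), converts each
  coordinate to a null p-value, and tabulates the count. How the original
  analysis generated null statistics from the correlation matrix is not
  stated; the default converts correlated z-scores to two-sided normal
  p-values, and a `mechanism = "mixture"` option mirrors the
  boundary-mixture GREML null instead — results name the mechanism. The
  p-value uses the add-one estimator $(1 + \#\{count \ge obs\}) /
  (1 + N)$, standard permutation practice, so a count of 0 reports exactly
  1.
* `fitLinearTrend()` / `fitQuadraticTrend()`: OLS across the 25 ROIs with
  the overall F test — at $n = 25$ the quadratic fit has $F(2, 22)$, the
  printed degrees of freedom.
* `classifySubnetworks()`: the published subnetwork definition is verbal
  ("highest variance with intermediate mean" versus "highest mean with
  lowest variance"), so every quantile in the default rule is an explicit,
  recorded parameter: Optional = top-4 by degree SD within the
  interquartile band of means; Obligatory = top-4 by mean within the
  lowest SD tertile; ties break by ROI index.
* `splitHalfR2()` / `randomSplitHalfR2()`: squared correlation of per-ROI
  mean phenotypes across a seeded random half-split.

## Known limitations

* SNPs are simulated independent; linkage disequilibrium, MAF-stratified
  GRMs and mixed-model association are out of scope (the emulated analysis
  used plain OLS association).
* The bivariate fit reports a Wald p for $\mathrm{cov}_G = 0$; no
  bivariate LRT is implemented.
* Dense connectivity worlds are calibrated only up to the nearest
  correlation-matrix projection, as described above.
* Binary PLINK (BED) files are not read; the text PED/MAP dialect is the
  exchange format.
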