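---
title: "GRS-stratified phenotype clustering: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GRS-stratified phenotype clustering: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcdgrs)
```

## The analysis this package implements

Candidate-gene studies of heterogeneous diseases such as adult asthma often
fail when cases are treated as a single group: a variant that predisposes to
one phenotype and not another dilutes to nothing in the pooled contrast.
`pcdgrs` implements the alternative strategy of *stratifying first*: build a
small unweighted genetic risk score (GRS) from a curated panel of
candidate-gene SNPs, cluster the patients on the GRS together with the two
clinical axes that best discriminate asthma phenotypes (%predicted FEV~1~
and age of onset), identify the clusters whose GRS is extreme relative to
healthy controls, and only then ask which individual panel SNPs differ
between the GRS-high and GRS-low patient groups, pooling cohorts by
meta-analysis.

The motivating application is a panel of 12 common SNPs with molecular
consequences (missense or 3'-UTR) in five genes causative for primary
ciliary dyskinesia (PCD) — *CCDC164*, *DNAH5*, *DNAH11*, *TXNDC3*,
*DYX1C1* — studied in three adult Japanese case-control cohorts. The
package ships that panel (`default_panel()`) and the published cohort-level
summary tables (`ref_cluster_summaries()` and friends), but every stage is
generic and the synthetic-cohort module makes the whole pipeline testable
with no access to subject-level data.

## The score

For individual $i$ and a panel of $K$ variants, the score is the plain
allele count

$$\mathrm{GRS}_i = \sum_{k=1}^{K} \mathrm{RA}_{ik},$$

where $\mathrm{RA}_{ik} \in \{0, 1, 2\}$ is the number of copies of variant
$k$'s *risk allele* — defined here as the allele with the reported
molecular consequence, whether or not it is the minor allele. For the
12-SNP panel the score lies in $0..24$; under Hardy–Weinberg equilibrium
its mean is $2\sum_k p_k$ and its variance $\sum_k 2p_k(1-p_k)$, and being
a sum of 12 independent bounded variables it is close to normal (the
package's tests check skewness of the simulated healthy distribution).

Missing dosages contribute 0 by default and are counted per individual in
`n_missing_loci`; a mean-imputation policy is available
(`compute_grs(..., missing_policy = "mean")`). The zero policy was chosen
as the default because it is conservative and keeps the score integral;
the source analysis appears to have had complete panel data, so the choice
is not load-bearing there.

## Panel curation and genotype QC

The filter chain mirrors standard chip practice, with every threshold
inclusive on the side printed in its rule:

| stage | rule | default |
|---|---|---|
| candidate MAF | keep MAF $\ge$ threshold | 0.10 |
| imputation quality | keep imputed variants with $r^2 \ge$ threshold; directly genotyped always pass | 0.30 |
| LD pruning | greedy scan in (chromosome, position) order; drop a variant whose dosage $r^2$ with any retained variant exceeds the cap | 0.50 |
| QC MAF | keep MAF $\ge$ | 0.01 |
| QC HWE | keep exact-test $p \ge$ (evaluated in controls) | $10^{-6}$ |
| call rates | keep samples, then variants, with call rate $>$ | 0.90 |

LD is computed as the squared Pearson correlation of unphased dosages
(composite LD), since phase is unavailable from a dosage matrix. Greedy
pruning keeps the earlier variant of a correlated pair; which member the
original analysis kept is not recoverable, and keeping the earlier one is
the deterministic convention. The Hardy–Weinberg test is the exact
conditional test on heterozygote counts, computed in log space; the test
suite checks it against full enumeration from the factorial formula.

## Two-step clustering

Patients are clustered on standardized (GRS, %predicted FEV~1~, onset age).
The similarity model is the log-likelihood distance for continuous
attributes. Cluster $v$ with $N_v$ members has tightness

$$\xi_v = -N_v \sum_{k=1}^{p} \tfrac{1}{2}
  \log\!\left(\hat\sigma_k^2 + \hat\sigma_{vk}^2\right),$$

where $\hat\sigma_{vk}^2$ is the within-cluster biased variance of feature
$k$ and $\hat\sigma_k^2$ the whole-sample biased variance, which acts as a
regularizer so singletons ($\hat\sigma_{vk}^2 = 0$) remain finite. The
cost of merging clusters $j$ and $s$ is
$d(j,s) = \xi_j + \xi_s - \xi_{j\cup s} \ge 0$, and
$\mathrm{BIC}(J) = -2\sum_{j=1}^{J}\xi_j + 2pJ\log n$ with one mean and one
variance per feature per cluster.

Two deliberate deviations from the streaming original of this procedure:

* **No CF-tree pre-clustering.** At desk scale ($n$ up to a few thousand)
  agglomeration starts from singletons. This removes the input-order
  sensitivity of the streaming pre-cluster step; the tests verify that row
  permutation leaves the partition unchanged.
* **Assignment is the merge-tree cut.** The chosen-$k$ partition is read
  directly off the agglomeration, with no reassignment pass. This keeps
  the fit deterministic and auditable; the cost is occasional borderline
  points near a boundary (visible as adjusted Rand indices slightly below
  1 in recovery simulations).

The number of clusters is selected in two stages with the conventional
constants 0.04 and 1.15. Stage one returns 1 immediately if
$\mathrm{BIC}(2) \ge \mathrm{BIC}(1)$, otherwise takes the largest $J$
whose BIC improvement ratio $(\mathrm{BIC}(J)-\mathrm{BIC}(J-1)) /
(\mathrm{BIC}(2)-\mathrm{BIC}(1))$ still exceeds 0.04. Stage two compares
the merge-cost ratios $R(J) = d_J / d_{J+1}$ (cost of dissolving $J$
clusters relative to $J+1$) among $2 \le J \le J_c$: if the largest ratio
beats the runner-up by more than a factor 1.15 its $J$ wins, otherwise the
larger of the two candidate $J$'s. A subtlety worth recording: the
indexing of the ratio test matters. With the convention used here
($d_J$ = cost of the merge performed while $J$ clusters were active) the
peak lands on the true $k$ for planted mixtures; shifting the index by one
lands on $k-1$. The package follows the convention that makes planted
recovery correct, which is also the published formulation of the procedure
it reimplements.

Ties in the minimum merge cost are broken toward the earliest cluster pair
in storage order — ties are measure-zero for continuous data, but the rule
makes the fit bit-reproducible. Listwise deletion is applied to the three
clustering features before fitting, and the deletion count is kept in the
fit object, since the original cohort tables also reflect complete-case
clustering.

## Extreme-group contrast

Clusters are lettered A, B, … by decreasing mean GRS (ties by size, then
original index — pure relabeling). A cluster is *GRS-high* if its Tukey
HSD contrast against the cohort's healthy controls has family-wise
adjusted $p < \alpha$ (default 0.05) and its mean lies above the healthy
mean; *GRS-low* symmetrically. The Tukey comparisons use Tukey–Kramer
standard errors from the pooled MSE, so they can be reproduced exactly
from printed group summaries (`tukey_from_summary()`), a form the test
suite holds to the raw-data implementation at machine precision.

High clusters pooled across cohorts form Group 1, low clusters Group 2,
everything else Group 3; the three groups partition the clustered cases,
and pooled continuous summaries are size-weighted means of cluster
summaries. Per SNP, the Lo-vs-Hi contrast (Hi as reference) is an
allele-based 2×2 chi-squared with a cross-product odds ratio
(Haldane–Anscombe +0.5 only when a zero cell occurs), pooled across
cohorts by inverse-variance fixed-effect meta-analysis with Cochran's
$Q$ and $I^2$ reported. Fixed-effect inverse variance is the default of
the GWAS toolchain this emulates; no random-effects option is provided.
Per-group side tables compare each extreme group against either the
remaining cases (default) or the healthy controls — the source tables are
ambiguous about the comparator, so both modes exist and the mode is
recorded in the output.

Beyond Tukey's family-wise control, no multiple-testing adjustment is
applied to the 12 per-SNP tests, mirroring the reporting style of the
analysis this package reimplements.

## The synthetic world

`sim_config()` states a world; the generator draws from it exactly:

* **Genotypes.** Unlinked variants are binomial$(2, p_k)$ per individual
  (HWE by construction). Variants sharing an `ld_block` are generated from
  a per-haplotype Gaussian factor model thresholded at $\Phi^{-1}(p_k)$,
  with the factor loading calibrated by 1-D quadrature so the realized
  pairwise dosage $r^2$ tracks the block's target; `block_r2 = 1` with
  equal frequencies degenerates to identical columns. Marginal allele
  frequencies are exact in expectation under either route.
* **Case mixture.** Each case's latent cluster is drawn with probability
  $\propto w_c \exp(\delta_c S_i)$, where $S_i$ is the case's centered,
  effect-weighted allele count. The logistic tilt leaves marginal allele
  frequencies untouched and makes $\delta_c$ interpretable as a log-odds
  slope per unit of score. `mode = "null"` forces all $\delta_c = 0$,
  decoupling genotype from phenotype. The per-variant `effect_weight`
  (default 1 everywhere) lets a test plant a single enriched SNP: with one
  heavily weighted variant the tilt concentrates on it, and the meta
  contrast should rank it first.
* **Phenotypes.** Cluster-specific normal onset and FEV~1~ (clipped to
  plausible clinical ranges), plus covariates (sex, BMI, smoking, atopy,
  log IgE, eosinophilia) that are realistic in range but intentionally
  simple in structure.
* **Defaults.** Three cohorts of 565/537, 965/242 and 673/446
  healthy/case individuals; the 12-SNP panel with risk-allele frequencies
  0.49 (rs2277046) and 0.31 (rs1530496) as published and fixed values in
  [0.1, 0.5] for the ten SNPs whose population frequencies are not
  published; four latent components echoing the canonical adult-asthma
  patterns (late-onset/preserved function coupled to high GRS, a smoker
  component with airflow limitation, early-onset atopic, late-onset
  coupled to low GRS) with couplings $\pm 0.4$. No within-gene LD by
  default, so the HWE and moment invariants hold exactly in the default
  world; LD blocks are opted into per configuration.

What the generator does **not** emulate: population structure and
admixture, imputation error, genotyping batch effects, informative
missingness, and the real joint distribution of clinical covariates.
A green planted-recovery test therefore establishes that the estimator
recovers the stated structure under the model's own assumptions — not
that the original cohort partitions would be reproduced, which requires
the original subject-level data. Because the risk alleles of the real
panel are consequence alleles (not necessarily minor), the published
healthy GRS mean of 12.54 is a property of the real frequencies, which
are mostly unpublished; the simulated default world has mean
$2\sum p_k \approx 7.2$, and the 12.54 identity is instead verified from
the bundled printed summary tables.

* **Seeding.** One root seed; each cohort derives a 32-bit child seed, so
  any cohort can be regenerated bit-identically on its own.

## Numerical choices

* HWE exact test in log space with the parity-respecting recurrence range;
  p-values capped at 1 and compared with a $1+10^{-10}$ slack when summing
  "at most as probable" configurations, the standard guard against ties
  lost to floating rounding.
* Within-cluster variances are clamped at 0 when rounding makes them
  tiny-negative; the global-variance regularizer keeps every logarithm
  finite for singletons.
* The merge loop maintains sufficient statistics $(N, \sum x, \sum x^2)$
  per cluster and a full cost matrix with `Inf` sentinels, giving an
  $O(n^2)$-memory, effectively $O(n^2)$–$O(n^3)$-time fit that handles the
  desk-scale $n$ of this design in well under a second.
* Logistic separation is detected from the IRLS warning plus an SE
  blow-up guard and reported as a flag with no estimate, rather than a
  huge finite OR.
* Odds-ratio continuity correction only on zero cells, never otherwise,
  so printed-style ORs are unchanged when all cells are positive.

## Known limitations

* The clustering is quadratic in memory and is not meant beyond
  $n \sim 10^4$–$10^5$ rows; the categorical extension of the two-step
  distance is out of scope.
* `ld_prune()` is greedy in panel order: it guarantees the survivor set's
  pairwise $r^2$ bound but not maximality of the set.
* The allele-based 2×2 test assumes HWE within groups (alleles treated as
  independent draws); the logistic dosage models do not.
* VCF support covers biallelic GT records (the panel's use case), not
  multi-allelic sites or dosage (DS) fields; strand harmonization against
  a reference is the caller's responsibility.
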