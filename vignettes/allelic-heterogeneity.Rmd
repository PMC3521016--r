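---
title: "Dissecting allelic heterogeneity from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting allelic heterogeneity from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleleHet)
```

## The problem

Genome-wide association studies of polygenic traits usually report one
lead SNP per associated region, yet a single locus often harbours several
variants with independent effects on the trait (allelic heterogeneity).
Detecting those secondary signals classically requires conditional
association analysis on individual-level genotypes, which are rarely
shareable. `alleleHet` implements an approximate conditional analysis
that needs only per-SNP summary statistics — two-sided p-value, direction
of effect, sample size N, and an allele frequency — plus a phased
reference haplotype panel for linkage disequilibrium (LD).

## The model

**Effect recovery.** For a trait standardized to unit variance, a SNP
with signed z-score $z$ (the normal quantile of the two-sided p-value,
signed by the reported direction), effect-allele frequency $f$ and sample
size $N$ has approximate allelic effect and standard error

$$\hat\beta = \frac{z}{\sqrt{2f(1-f)N}}, \qquad
  \mathrm{se}(\hat\beta) = \frac{1}{\sqrt{2f(1-f)N}},$$

because the dosage variance under Hardy–Weinberg equilibrium (HWE) is
$2f(1-f)$. A variant that absorbs the SNP's own contribution to the
trait variance, $\sqrt{2f(1-f)(N+z^2)}$ in the denominator, is available
via `effect_from_summary(..., method = "cojo")`; the two differ
noticeably only when $z^2$ is not negligible against $N$. The default is
the plain form because it is the exact inverse of the z-statistic for a
standardized trait, which is what the input summaries carry.

**Projection.** Under an additive model, a source SNP $s$ with effect
$\beta_s$ induces an apparent effect at a linked SNP $t$ of
$\beta_s\,\mathrm{Cov}(g_s,g_t)/\mathrm{Var}(g_t)$. With haplotype-level
LD coefficient $D = p_{st} - f_s f_t$, HWE gives
$\mathrm{Cov}(g_s,g_t) = 2D$ and $\mathrm{Var}(g_t) = 2f_t(1-f_t)$, so
the projected effect is $\beta_s D / (f_t(1-f_t))$.

**Conditioning.** The conditional effect of SNP $t$ given a set of
already-selected SNPs is its marginal effect minus the sum of their
projections; the conditional p-value is the two-sided normal tail of
(conditional effect)/se, with the standard error kept at its marginal
value. This is the deliberate simplification at the heart of the method:
each pair of SNPs is considered once, and the selected set is never
refitted jointly. Two consequences worth knowing:

* the conditional estimate of a true secondary effect is attenuated by
  roughly $(1-r^2)$ relative to the joint least-squares coefficient,
  where $r^2$ is the genotype correlation with the conditioning SNP —
  negligible for the weakly correlated signals the method targets
  ($r^2 \lesssim 0.3$), and the reason the `r2_guard` skips candidates
  with $r^2 > 0.99$;
* because the standard error is not reduced after conditioning, the
  conditional z of a pure proxy has variance $\approx 1-r^2 \le 1$: the
  test is slightly conservative under the null, which the calibration
  studies confirm empirically.

## Pipeline

1. **Harmonization** (`read_summary`, `harmonize`): summary files carry
   no positions or frequencies, so both are always taken from the panel
   after marker-id matching. Records whose alleles are swapped relative
   to the panel's coded allele have their direction negated; strand
   complements are resolved by complementing; A/T and C/G SNPs are
   dropped by default since a direction-only file cannot disambiguate
   strand. p-values below the smallest positive double are clamped to it
   rather than rejected, so genuine 1e-300-scale associations survive.
2. **Clustering** (`cluster_loci`): SNPs with $p < \alpha$ are chained
   into loci whenever consecutive significant SNPs on a chromosome lie
   within a window $L$ (single linkage, gap $= L$ joins). Chaining is
   chosen over distance-to-lead because real associated regions can span
   several Mb as runs of adjacent significant SNPs. The default window
   shrinks with the significance level (500 kb at $5\times10^{-8}$ down
   to 50 kb at $5\times10^{-3}$) because relaxing $\alpha$ sharply
   increases significant-SNP density; an off-grid $\alpha$ snaps to the
   tightest listed level that admits it, the density-conservative choice.
   Short windows can split a genuinely continuous locus, so `window_kb`
   is always overridable.
3. **Stepwise dissection** (`dissect_locus`, `dissect_all`): the lead
   SNP is the rank-1 signal with its marginal effect. Each later round
   computes every remaining member's conditional effect against all
   selected signals, each projecting its *assigned* effect — marginal
   for rank 1, conditional for later ranks (a sequential-residual
   scheme). The smallest conditional p wins the round and is accepted
   iff it beats the per-locus Bonferroni threshold $0.05/m$, with $m$
   the number of clustered SNPs at the locus: multiplicity is controlled
   per locus, not genome-wide, because the goal is quantifying
   heterogeneity rather than establishing each signal at genome-wide
   stringency. Candidates are locus members only. Iteration stops at the
   first rejection or at `max_rank` (default 4 — quaternary; in our
   simulations, as in practice, fourth-rank signals add no score
   variance). Whether round $k$ should project the earlier signals'
   marginal or conditional effects is genuinely open; the
   sequential-residual choice is the default and the alternative sits
   behind `condition_on = "marginal"`.
4. **Scoring** (`adjust_phenotype`, `build_score`, `variance_explained`,
   `score_report`): the weighted genetic score is
   $S_i = \sum_k \hat\beta_k x_{ik}$ over selected signals, with each
   signal's assigned effect as weight. The outcome is the residual of
   trait on age, sex (0 = female, 1 = male) and age×sex; variance
   explained is the squared Pearson correlation between score and
   residuals (identical to univariate OLS $R^2$), reported overall and
   per sex. Samples with missing dosages are rescaled by total/observed
   absolute weight by default (`missing = "strict"` drops them instead).

All LD is computed on phased haplotypes; pairs farther apart than 5 Mb
return $D = 0$ with a flag, bounding the LD ever consulted since loci
span at most a few Mb. Orientation is fixed once during harmonization,
so the sign of $D$ and the sign of every effect refer to the same coded
allele.

## The simulator and what it does (not) emulate

`sim_panel` generates haplotypes by a first-order Markov copying chain:
SNP $k$ copies SNP $k-1$'s allele state with probability $\rho$, else
draws from its marginal frequency. Adjacent-SNP correlation is then
$\approx \rho$ (exactly $\rho$ at equal frequencies) and $r^2$ decays
geometrically with SNP distance — enough structure for a method that
only ever consumes pairwise $D$, while staying exactly
seed-reproducible and fast. `sim_cohort` pairs panel haplotypes at
random (HWE holds in expectation), builds the genetic value from planted
standardized betas, scales Gaussian noise so the standardized residual
has unit variance (betas therefore *are* the standardized truths;
`heritability` rescales them to hit an exact genetic fraction), and
wraps the residual in a cm-scale trait with age, sex and age×sex
structure so the adjustment model has real work to do. `sim_summary`
regresses the standardized residual on each dosage, emitting records in
the same dialect the reader consumes, and `joint_oracle` provides the
exact individual-level multiple regression that conditional estimates
are validated against.

The simulator does **not** emulate realistic genealogies, imputation
uncertainty, genotyping error, population structure, or
reference-vs-study panel mismatch (summary statistics and LD come from
the same sample by default, which is exactly what the oracle comparisons
require; mismatch can be emulated by simulating a second cohort from the
same panel). Passing the validation studies therefore shows the
*procedure* is correct and calibrated under its own assumptions, not
that those assumptions hold in any particular real data set.

## Validation studies and problem sizes

The `study_*` functions rerun the whole pipeline on seeded synthetic
studies; the test suite asserts on their results and
`scripts/acceptance.R` reports them:

* `study_conditional_oracle`: 200 two-causal loci, n = 20 000,
  between-causal $r^2$ up to ~0.3, per-SNP effects sized to $z \approx
  6$; the secondary signal's conditional effect should fall within 3
  joint standard errors of the exact joint fit in ≥95% of replicates.
* `study_signal_recovery`: 4 cohorts × 10 planted loci at n = 50 000,
  primary signals at 0.2% and secondaries at 0.1% of trait variance;
  the planted locus count must be recovered exactly and ≥90% of
  secondaries found. The secondary size is chosen so the secondary SNP
  is itself reliably genome-wide significant: because conditional
  candidates are the clustered (significant) SNPs only, a secondary
  whose marginal z sits at the significance boundary is lost to
  *candidacy* even though the conditional test would detect it with
  near-certain power — at 0.05% variance this caps sensitivity near
  80% regardless of the conditioning arithmetic.
* `study_false_secondary`: 1000 single-causal loci (dense LD,
  $\rho = 0.85$) at n = 50 000; loci reporting a spurious secondary
  should not exceed 7%, the empirical ceiling for a per-locus
  family-wise level of 0.05. Two simulation pitfalls are deliberately
  avoided here, and are worth knowing about when validating any
  summary-statistic method: the reference panel must be large relative
  to the number of simulated causal loci, because chance inter-locus
  panel LD ($r \sim 1/\sqrt{n_\mathrm{hap}}$) becomes real LD in a
  cohort resampled from the panel and inflates every z-score in a way
  within-locus conditioning cannot remove; and proxies whose marginal
  noncentrality straddles the significance threshold enter the locus
  only when their noise is large and positive (membership winner's
  curse), carrying that selection bias into the conditional test.
* `study_null_calibration`: 2000 unlinked null SNPs at n = 2000;
  p-values must be KS-uniform.
* `study_score_gain`: true-weight scores on planted 10%-variance signals
  at n = 5000 recover $R^2 = 0.10 \pm 0.02$; across 100 seeds, adding
  planted secondary signals (0.5% variance each next to 1% primaries)
  strictly increases $R^2$ in ≥90% of seeds.

These sizes keep each study in the minutes range on one CPU while
leaving the assertions' Monte-Carlo error well inside their margins.

## Numerical choices and edge cases

* Ties in lead/candidate selection break by smaller position, then
  lexicographic marker id — results are invariant to input order.
* Monomorphic panel columns are dropped at load (frequency must be
  strictly inside (0,1) for LD to be defined); monomorphic cohort SNPs
  are excluded from simulated summaries with a count.
* `z_from_p` refuses $p \notin (0,1]$; the reader clamps subnormal
  p-values with a warning instead.
* Zero-variance scores yield $R^2 = 0$ with a warning, not an error.
* Cross-chromosome LD is a domain error unless the caller opts into
  treating it as 0.
* A locus member absent from the panel is excluded from candidacy with a
  warning; an empty locus is a domain error.

## Known limitations

The fixed-se conditional test is anti-conservative in high LD and
conservative under the null at moderate LD; the pairwise scheme cannot
distinguish genuine heterogeneity from partial LD with one hidden
functional variant; effects are on the standardized-trait scale and need
rescaling by the phenotype SD for natural units; and the per-locus
Bonferroni is deliberately more permissive than a genome-wide threshold,
so reported secondary signals are evidence of heterogeneity, not
individually genome-wide-significant discoveries.
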