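# alleleHet

Dissecting allelic heterogeneity at trait-associated loci from GWAS
summary statistics alone.

Many loci associated with polygenic traits harbour several variants with
independent effects, but detecting those secondary signals classically
requires conditional analysis on individual-level genotypes. `alleleHet`
implements an approximate conditional analysis that needs only per-SNP
summary statistics — two-sided p-value, direction of effect and sample
size N — plus a phased reference haplotype panel for allele frequencies
and linkage disequilibrium (LD). It is aimed at statistical geneticists
working with published meta-analysis summaries (e.g. the GIANT-style
whitespace-delimited dialect) and HapMap-style or VCF reference panels.

## The method

For a standardized trait, a SNP with signed z-score
*z* = direction × Φ⁻¹(1 − p/2), effect-allele frequency *f* and sample
size *N* has approximate allelic effect and standard error

    beta = z / sqrt(2 f (1 − f) N),    se = 1 / sqrt(2 f (1 − f) N)

since the dosage variance under Hardy–Weinberg equilibrium is 2f(1−f).
SNPs significant at level α are clustered into loci by physical
adjacency (single-linkage chaining with a level-dependent window, 500 kb
at 5×10⁻⁸ down to 50 kb at 5×10⁻³). Within each locus, the lead SNP is
the primary signal; the effect it induces at a linked SNP *t* is the
projected effect `beta_lead × D / (f_t (1 − f_t))`, with D the
haplotype-level LD coefficient (genotype covariance 2D under HWE).
Subtracting the projections of all selected signals from a SNP's
marginal effect gives its conditional effect; the SNP with the smallest
conditional p-value becomes the next signal if it beats the per-locus
Bonferroni threshold 0.05/m (m = clustered SNPs at the locus), iterating
to tertiary and quaternary signals. Weighted genetic scores
S = Σ beta·dosage built from the selected signals, regressed on
age/sex/interaction-adjusted trait residuals, quantify the variance the
signals explain in an independent cohort.

## Worked example

Simulate a study with one two-causal locus and one single-causal locus,
write the summary file in the GIANT-style dialect, and run the pipeline:

```r
library(alleleHet)

loci <- list(
  sim_locus(8, start = 1e6, rho = 0.5, causal = c(1, 5), beta = c(0.08, 0.07)),
  sim_locus(6, start = 5e6, causal = 2, beta = 0.09))
cfg <- sim_config(loci, n_haplotypes = 2000, n_individuals = 20000)
panel  <- sim_panel(cfg, seed = 11)
cohort <- sim_cohort(panel, cfg, seed = 12)
summ   <- sim_summary(cohort$genotypes, cohort$residual_std, panel)

f <- tempfile(); write_giant(summ, f)
rec <- harmonize(read_summary(f), panel)$records
dis <- dissect_all(cluster_loci(rec, alpha = 5e-8), panel)
dis$signals[, c("locus_id", "rank", "marker_id", "pos", "beta", "se", "cond_p")]
#>    locus_id rank marker_id     pos   beta     se   cond_p
#> 1 locus_001    1     rs1_5 1020000 0.0829 0.0109 2.42e-14
#> 2 locus_001    2     rs1_1 1000000 0.0702 0.0108 8.62e-11
#> 3 locus_002    1     rs2_2 5005000 0.0961 0.0110 1.89e-18
dis$summary
#>   n_loci n_secondary pct_secondary n_tertiary pct_tertiary
#> 1      2           1            50          0            0
```

Both planted causal SNPs at the first locus are recovered (the planted
effects were 0.08 and 0.07 on the standardized-trait scale; the
conditional estimate of the secondary, 0.0702, is its effect after
removing the lead's LD projection), and the single-causal locus yields
exactly one signal. Scoring the same cohort:

```r
resid <- adjust_phenotype(cohort$pheno)
score_report(dis$signals, cohort$genotypes, resid)
#>   ranks n_snps stratum      r2     n
#> 1     1      2     all 0.00656 20000
#> 4   1-2      3     all 0.00858 20000
#> 7   1-3      3     all 0.00858 20000
#> ...
```

Adding the secondary signal raises the variance explained from 0.66% to
0.86% (the three planted signals carry ~1% of trait variance in total);
female/male strata are reported alongside.

The same analysis runs from the shell via the thin wrapper in `exec/`:

```sh
alleleHet simulate --out simdir --seed 5 --n-individuals 20000
alleleHet run --summary simdir/summary.tsv --panel simdir/panel.vcf \
              --genotypes simdir/dosages.tsv --pheno simdir/pheno.tsv \
              --alpha 5e-8 --out results/
```

which writes `loci.tsv`, `signals.tsv`, `het_summary.json`,
`score_report.tsv` and a run manifest.

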