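# Shared fixtures, all built in code at test time.

# Tiny panel assembled directly from a hand-written haplotype matrix.
# Columns: m1 (A/G, f=0.5), m2 identical to m1, m3 orthogonal to m1,
# m4 (A/T ambiguous, f=0.25), m5 on another chromosome.
toy_panel <- function() {
  H <- cbind(
    m1 = c(1L, 1L, 0L, 0L),
    m2 = c(1L, 1L, 0L, 0L),
    m3 = c(1L, 0L, 1L, 0L),
    m4 = c(1L, 0L, 0L, 0L),
    m5 = c(0L, 1L, 0L, 1L))
  v <- data.frame(
    marker_id = c("m1", "m2", "m3", "m4", "m5"),
    chrom = c("1", "1", "1", "1", "2"),
    pos = c(100L, 200L, 300L, 400L, 100L),
    a0 = c("A", "C", "C", "A", "A"),
    a1 = c("G", "T", "G", "T", "C"),
    stringsAsFactors = FALSE)
  alleleHet:::new_panel(v, H)
}

# Hand-written phased VCF mirroring toy_panel's chromosome 1 content.
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    "1\t100\tm1\tA\tG\t.\tPASS\t.\tGT\t1|1\t0|0",
    "1\t200\tm2\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|0",
    "1\t300\tm3\tC\tG\t.\tPASS\t.\tGT\t1|0\t1|0"), path)
  path
}

# Summary-record rows built directly (already harmonized when chrom/pos set).
make_records <- function(marker, chrom, pos, p, direction, n = 10000,
                         freq = 0.5, ea = "G", oa = "A") {
  data.frame(marker_id = marker, chrom = chrom, pos = as.integer(pos),
             effect_allele = ea, other_allele = oa, p = p,
             direction = direction, n_obs = n, freq = freq,
             stringsAsFactors = FALSE)
}

# One simulated study: panel + cohort + summary records, shared conditions.
sim_study <- function(seed, loci, n_individuals, n_haplotypes = 2000,
                      heritability = NULL) {
  cfg <- sim_config(loci, n_haplotypes = n_haplotypes,
                    n_individuals = n_individuals,
                    heritability = heritability)
  panel <- sim_panel(cfg, seed = seed)
  cohort <- sim_cohort(panel, cfg, seed = seed + 100000L)
  summ <- sim_summary(cohort$genotypes, cohort$residual_std, panel)
  list(cfg = cfg, panel = panel, cohort = cohort, summary = summ)
}

# Noise-free summary records implied by true causal effects and panel LD:
# each marker's marginal effect is the sum of Cov/Var projections of the
# causal effects, converted to z and p exactly. Lets stepwise behaviour be
# checked against hand arithmetic without sampling noise.
noise_free_records <- function(panel, true_beta, n = 1e5) {
  v <- panel$variants
  beta_marg <- vapply(v$marker_id, function(t) {
    ft <- allele_freq(panel, t)
    sum(vapply(names(true_beta), function(cs) {
      d <- pair_ld(panel, cs, t)$d
      projected_effect(true_beta[[cs]], d, ft)
    }, 0))
  }, 0)
  se <- 1 / sqrt(2 * v$freq * (1 - v$freq) * n)
  z <- beta_marg / se
  dir <- ifelse(z >= 0, 1, -1)
  p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
  data.frame(marker_id = v$marker_id, chrom = v$chrom, pos = v$pos,
             effect_allele = v$a1, other_allele = v$a0, p = p,
             direction = dir, n_obs = n, freq = v$freq,
             stringsAsFactors = FALSE)
}
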