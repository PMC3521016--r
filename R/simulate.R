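#' Simulation configuration
#'
#' Describes a synthetic study: a phased haplotype panel with controllable
#' LD, a cohort of diploid individuals, and a trait with planted causal
#' SNPs. Each locus is a list made by [sim_locus()]. The heritability
#' target, when given, rescales the planted effects so the genetic
#' variance fraction of the standardized trait residual hits it exactly
#' in the realized cohort.
#'
#' @param loci List of locus descriptions from [sim_locus()].
#' @param n_haplotypes Number of panel haplotypes (even).
#' @param n_individuals Cohort size.
#' @param heritability Target genetic variance fraction in [0,1), or NULL
#'   to use the planted betas as given (noise variance then 1 - Var(g)).
#' @param p_male Probability an individual is male (default 0.433, a
#'   typical field-cohort sex ratio).
#' @return Object of class `SimConfig`.
#' @export
sim_config <- function(loci, n_haplotypes = 2000, n_individuals = 2000,
                       heritability = NULL, p_male = 0.433) {
  if (n_haplotypes %% 2 != 0) ah_config_error("n_haplotypes must be even")
  if (!is.null(heritability) && (heritability < 0 || heritability >= 1))
    ah_config_error("heritability must lie in [0, 1)")
  for (l in loci) {
    if (any(l$freqs <= 0.02 | l$freqs >= 0.98))
      ah_config_error("allele frequencies must lie in (0.02, 0.98)")
    if (any(diff(l$positions) <= 0))
      ah_config_error("positions must be strictly increasing within a locus")
    if (any(l$causal < 1 | l$causal > length(l$positions)))
      ah_config_error("causal index outside locus")
  }
  structure(list(loci = loci, n_haplotypes = n_haplotypes,
                 n_individuals = n_individuals, heritability = heritability,
                 p_male = p_male), class = "SimConfig")
}

#' Describe one simulated locus
#'
#' @param n_snps Number of SNPs.
#' @param start First SNP position (bp).
#' @param spacing Distance between adjacent SNPs (bp, default 5000).
#' @param freqs Coded-allele frequencies (recycled; default 0.3).
#' @param rho Copying probability of the Markov LD model in [0,1]: SNP k
#'   copies SNP k-1's haplotype state with probability rho, else draws
#'   from its marginal frequency, so pairwise r2 decays geometrically
#'   with SNP distance.
#' @param causal Indices of causal SNPs (possibly empty).
#' @param beta Standardized allelic effects of the causal SNPs.
#' @param chrom Chromosome label.
#' @param positions Explicit positions overriding start/spacing.
#' @return List consumed by [sim_config()].
#' @export
sim_locus <- function(n_snps, start = 1e6, spacing = 5000, freqs = 0.3,
                      rho = 0.6, causal = integer(), beta = numeric(),
                      chrom = "1", positions = NULL) {
  if (length(causal) != length(beta))
    ah_config_error("causal and beta must have equal length")
  if (is.null(positions)) positions <- start + spacing * (seq_len(n_snps) - 1L)
  list(n_snps = n_snps, positions = positions, chrom = chrom,
       freqs = rep_len(freqs, n_snps), rho = rho,
       causal = causal, beta = beta)
}

# Non-ambiguous allele pairs assigned cyclically so harmonization keeps
# every simulated SNP under the default strand filter.
sim_allele_pairs <- matrix(c("A", "G", "A", "C", "T", "C", "T", "G"),
                           ncol = 2, byrow = TRUE)

#' Simulate a phased haplotype panel
#'
#' Haplotypes are generated per locus by a first-order Markov copying
#' chain: the allele state at SNP k equals SNP k-1's state with
#' probability rho, otherwise it is a fresh Bernoulli draw at the SNP's
#' marginal frequency. This yields pairwise r² that decays geometrically
#' with the number of intervening SNPs while keeping LD exactly
#' seed-reproducible. Loci are mutually unlinked.
#'
#' @param config A `SimConfig`.
#' @param seed Optional RNG seed (restores global RNG state afterwards).
#' @return A `HaplotypePanel` whose marker ids are `rs<locus>_<snp>`.
#' @export
sim_panel <- function(config, seed = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  with_seed(seed, {
    nh <- config$n_haplotypes
    vars <- NULL
    mats <- list()
    for (li in seq_along(config$loci)) {
      l <- config$loci[[li]]
      H <- matrix(0L, nrow = nh, ncol = l$n_snps)
      H[, 1] <- stats::rbinom(nh, 1L, l$freqs[1])
      if (l$n_snps > 1) for (k in 2:l$n_snps) {
        copy <- stats::runif(nh) < l$rho
        fresh <- stats::rbinom(nh, 1L, l$freqs[k])
        H[, k] <- ifelse(copy, H[, k - 1], fresh)
      }
      mats[[li]] <- H
      ap <- sim_allele_pairs[((seq_len(l$n_snps) - 1L) %% 4L) + 1L, , drop = FALSE]
      vars <- rbind(vars, data.frame(
        marker_id = sprintf("rs%d_%d", li, seq_len(l$n_snps)),
        chrom = l$chrom, pos = as.integer(l$positions),
        a0 = ap[, 1], a1 = ap[, 2], stringsAsFactors = FALSE))
    }
    H <- do.call(cbind, mats)
    ord <- order(vars$chrom, vars$pos)
    new_panel(vars[ord, , drop = FALSE], H[, ord, drop = FALSE])
  })
}

#' Simulate a cohort with planted causal effects
#'
#' Individuals are formed by pairing panel haplotypes drawn with
#' replacement (random mating, hence HWE in expectation). The genetic
#' value is the weighted sum of causal dosages; the standardized trait
#' residual is genetic value plus Gaussian noise scaled so the total
#' residual variance is 1 (making the planted betas standardized-scale
#' truths); the recorded trait adds age, sex and age-by-sex effects plus
#' a cm-scale residual SD, so that [adjust_phenotype()] must actually
#' remove them.
#'
#' @param panel Panel from [sim_panel()].
#' @param config The same `SimConfig`.
#' @param seed Optional RNG seed.
#' @return List with `genotypes` (samples x markers dosage matrix),
#'   `pheno` (data frame id/trait/age/sex), `residual_std` (the
#'   standardized genetic + noise residual actually generated), and
#'   `truth`: causal marker ids, betas after any heritability rescaling,
#'   per-causal variance fractions and the realized genetic fraction.
#' @export
sim_cohort <- function(panel, config, seed = NULL) {
  stopifnot(inherits(panel, "HaplotypePanel"), inherits(config, "SimConfig"))
  with_seed(seed, {
    n <- config$n_individuals
    nh <- nrow(panel$haplotypes)
    i1 <- sample.int(nh, n, replace = TRUE)
    i2 <- sample.int(nh, n, replace = TRUE)
    X <- panel$haplotypes[i1, , drop = FALSE] + panel$haplotypes[i2, , drop = FALSE]
    rownames(X) <- sprintf("ind_%05d", seq_len(n))

    causal <- unlist(lapply(seq_along(config$loci), function(li) {
      l <- config$loci[[li]]
      sprintf("rs%d_%d", li, l$causal)
    }))
    beta <- unlist(lapply(config$loci, function(l) l$beta))
    causal_in <- causal %in% colnames(X)
    causal <- causal[causal_in]; beta <- beta[causal_in]

    if (length(causal)) {
      g <- as.numeric(X[, causal, drop = FALSE] %*% beta)
      vg <- stats::var(g)
    } else {
      g <- numeric(n); vg <- 0
    }
    h2 <- config$heritability
    if (!is.null(h2) && h2 > 0) {
      if (vg == 0) ah_config_error("heritability target unreachable: zero genetic variance")
      beta <- beta * sqrt(h2 / vg)
      g <- g * sqrt(h2 / vg)
      vg <- h2
    }
    if (vg >= 1) ah_config_error("genetic variance >= 1 on the standardized scale")
    e <- stats::rnorm(n, 0, sqrt(1 - vg))
    r_std <- g + e

    age <- stats::runif(n, 18, 90)
    sex <- stats::rbinom(n, 1L, config$p_male)
    trait <- 162 - 0.05 * age + 12 * sex + 0.015 * age * sex + 6.5 * r_std
    pheno <- data.frame(id = rownames(X), trait = trait, age = age,
                        sex = ifelse(sex == 1, "M", "F"),
                        stringsAsFactors = FALSE)
    fr <- colMeans(X[, causal, drop = FALSE]) / 2
    truth <- list(causal = causal, beta = beta,
                  var_fraction = 2 * fr * (1 - fr) * beta^2,
                  realized_genetic_fraction = vg)
    list(genotypes = X, pheno = pheno,
         residual_std = stats::setNames(r_std, rownames(X)), truth = truth)
  })
}

#' Per-SNP summary statistics from a simulated cohort
#'
#' Simple linear regression of the standardized phenotype residual on
#' each SNP's dosage: two-sided p from the t statistic, direction the
#' sign of the slope, N the cohort size, frequency the cohort
#' coded-allele frequency. Records are emitted in the same shape
#' [read_summary()] produces, with alleles in the panel's orientation, so
#' the simulated file dialect round-trips through the summary reader and
#' harmonizer. Monomorphic SNPs in the cohort are excluded with a count.
#'
#' @param genotypes Dosage matrix from [sim_cohort()].
#' @param residuals Residual vector (standardized internally).
#' @param panel Panel supplying allele labels.
#' @return Summary-record data frame with attribute `n_monomorphic`.
#' @export
sim_summary <- function(genotypes, residuals, panel) {
  X <- genotypes
  y <- residuals[rownames(X)]
  y <- (y - mean(y)) / stats::sd(y)
  n <- length(y)
  xm <- colMeans(X)
  sxx <- colSums(X^2) - n * xm^2
  mono <- sxx <= 0
  sxy <- as.numeric(crossprod(X, y))  # y centered
  b <- ifelse(mono, NA_real_, sxy / sxx)
  syy <- sum(y^2)
  r <- ifelse(mono, NA_real_, sxy / sqrt(sxx * syy))
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)

  idx <- match(colnames(X), panel$variants$marker_id)
  out <- data.frame(
    marker_id = colnames(X), chrom = NA_character_, pos = NA_integer_,
    effect_allele = panel$variants$a1[idx],
    other_allele = panel$variants$a0[idx],
    p = p, direction = ifelse(b >= 0, 1, -1),
    n_obs = n, freq = xm / 2, stringsAsFactors = FALSE)
  out <- out[!mono, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_monomorphic") <- sum(mono)
  out
}

#' Exact joint least-squares oracle
#'
#' Multiple regression of the standardized residual on the dosages of a
#' selected marker set — the individual-level answer that the
#' summary-level conditional approximation is meant to track. Refuses
#' near-collinear sets.
#'
#' @param genotypes Dosage matrix.
#' @param residuals Residual vector (standardized internally).
#' @param markers Markers to fit jointly.
#' @param max_kappa Condition-number guard on the genotype correlation
#'   matrix (default 1e6).
#' @return Data frame with `marker_id`, `beta`, `se`, `p`.
#' @export
joint_oracle <- function(genotypes, residuals, markers, max_kappa = 1e6) {
  miss <- setdiff(markers, colnames(genotypes))
  if (length(miss)) ah_input_error(sprintf("markers absent from genotypes: %s",
                                           paste(miss, collapse = ", ")))
  X <- genotypes[, markers, drop = FALSE]
  y <- residuals[rownames(X)]
  y <- (y - mean(y)) / stats::sd(y)
  if (length(markers) > 1) {
    k <- kappa(stats::cor(X), exact = TRUE)
    if (!is.finite(k) || k > max_kappa)
      ah_numeric_error(sprintf("collinear marker set (condition number %.3g): %s",
                               k, paste(markers, collapse = ", ")))
  }
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)$coefficients
  est <- sm[-1, , drop = FALSE]
  data.frame(marker_id = markers, beta = est[, 1], se = est[, 2],
             p = est[, 4], row.names = NULL, stringsAsFactors = FALSE)
}

# ---- plain-text emitters for the simulated study --------------------------

#' Write summary records in the GIANT-style dialect
#'
#' Whitespace-delimited with header MarkerName Allele1 Allele2 Direction
#' p N (no chromosome, position or frequency columns), readable by
#' [read_summary()] with the `"giant"` preset.
#'
#' @param records Summary-record data frame.
#' @param path Output path.
#' @export
write_giant <- function(records, path) {
  d <- data.frame(MarkerName = records$marker_id,
                  Allele1 = records$effect_allele,
                  Allele2 = records$other_allele,
                  Direction = ifelse(records$direction > 0, "+", "-"),
                  p = records$p, N = records$n_obs)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a haplotype panel as a phased VCF
#'
#' @param panel A `HaplotypePanel`.
#' @param path Output path (uncompressed VCF).
#' @export
write_vcf_panel <- function(panel, path) {
  v <- panel$variants
  H <- panel$haplotypes
  ns <- nrow(H) / 2
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sprintf("sample_%04d", seq_len(ns))),
                     collapse = "\t")), con)
  gt <- matrix("", nrow = nrow(v), ncol = ns)
  for (s in seq_len(ns))
    gt[, s] <- paste0(H[2 * s - 1, ], "|", H[2 * s, ])
  lines <- paste(v$chrom, v$pos, v$marker_id, v$a0, v$a1, ".", "PASS", ".",
                 "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write a haplotype panel in the HapMap Phase 2 legend/phased dialect
#'
#' Emits `<prefix>_legend.txt`, `<prefix>_phased` and
#' `<prefix>_sample.txt`, readable by [load_panel()] with
#' `format = "hapmap_phased"`.
#'
#' @param panel A `HaplotypePanel`.
#' @param prefix Output file prefix.
#' @export
write_hapmap_panel <- function(panel, prefix) {
  v <- panel$variants
  legend <- data.frame(rs = v$marker_id, position = v$pos,
                       `0` = v$a0, `1` = v$a1, check.names = FALSE)
  utils::write.table(legend, paste0(prefix, "_legend.txt"), sep = " ",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$haplotypes, paste0(prefix, "_phased"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("sample_%04d", seq_len(nrow(panel$haplotypes) / 2)),
             paste0(prefix, "_sample.txt"))
  invisible(prefix)
}

#' Write a dosage matrix as TSV
#' @param genotypes Samples x markers matrix.
#' @param path Output path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  d <- data.frame(id = rownames(genotypes), genotypes, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phenotype table as TSV
#' @param pheno Data frame id/trait/age/sex.
#' @param path Output path.
#' @export
write_pheno_tsv <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
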