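test_that("a singleton locus yields exactly its lead as the only signal", {
  study <- sim_study(seed = 3L,
                     loci = list(sim_locus(1, causal = 1, beta = 0.25)),
                     n_individuals = 3000)
  rec <- harmonize(study$summary, study$panel)$records
  loci <- cluster_loci(rec, alpha = 5e-8)
  expect_length(loci, 1L)
  sig <- dissect_locus(loci[[1]], study$panel)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$rank, 1L)
  expect_equal(sig$marker_id, loci[[1]]$lead)
  expect_equal(sig$source, "marginal")
  expect_equal(sig$cond_p, loci[[1]]$lead_p)
})

test_that("pure proxies of the lead produce no further signals", {
  # all columns identical (r2 = 1): full projection plus the r2 guard
  H <- matrix(rep(c(1L, 1L, 0L, 0L, 1L, 0L), 3), ncol = 3)
  v <- data.frame(marker_id = c("s1", "s2", "s3"), chrom = "1",
                  pos = c(100L, 200L, 300L), a0 = "A", a1 = "G",
                  stringsAsFactors = FALSE)
  panel <- alleleHet:::new_panel(v, H)
  rec <- noise_free_records(panel, c(s1 = 0.1), n = 1e5)
  loci <- cluster_loci(rec, alpha = 5e-8, window_kb = 500)
  sig <- dissect_locus(loci[[1]], panel)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$marker_id, "s1")
})

test_that("two planted causal SNPs are both recovered with joint-accurate effects", {
  study <- sim_study(seed = 17L,
                     loci = list(sim_locus(6, freqs = 0.4, rho = 0.35,
                                           causal = c(2, 5),
                                           beta = c(0.07, 0.06))),
                     n_individuals = 50000)
  rec <- harmonize(study$summary, study$panel)$records
  loci <- cluster_loci(rec, alpha = 5e-8)
  expect_length(loci, 1L)
  sig <- dissect_locus(loci[[1]], study$panel)
  expect_gte(nrow(sig), 2L)
  expect_setequal(sig$marker_id[1:2], c("rs1_2", "rs1_5"))
  joint <- joint_oracle(study$cohort$genotypes, study$cohort$residual_std,
                        sig$marker_id[1:2])
  expect_lt(abs(sig$beta[2] - joint$beta[joint$marker_id == sig$marker_id[2]]),
            3 * joint$se[joint$marker_id == sig$marker_id[2]])
})

test_that("signals never repeat a marker and are capped by max_rank and m", {
  study <- sim_study(seed = 29L,
                     loci = list(sim_locus(8, rho = 0.5, causal = c(1, 4, 8),
                                           beta = c(0.08, 0.07, 0.06))),
                     n_individuals = 40000)
  rec <- harmonize(study$summary, study$panel)$records
  loci <- cluster_loci(rec, alpha = 5e-8)
  sig <- dissect_locus(loci[[1]], study$panel, max_rank = 4)
  expect_equal(anyDuplicated(sig$marker_id), 0L)
  expect_lte(nrow(sig), min(4, nrow(loci[[1]]$members)))
  expect_equal(sig$rank, seq_len(nrow(sig)))
  capped <- dissect_locus(loci[[1]], study$panel, max_rank = 1)
  expect_equal(nrow(capped), 1L)
  # ranks >= 2 all pass their recorded Bonferroni threshold
  expect_true(all(sig$cond_p[-1] < sig$threshold[-1]))
  expect_equal(unique(sig$threshold), 0.05 / nrow(loci[[1]]$members))
})

test_that("a stricter Bonferroni base never admits more signals", {
  study <- sim_study(seed = 31L,
                     loci = list(sim_locus(8, rho = 0.5, causal = c(1, 5),
                                           beta = c(0.07, 0.05))),
                     n_individuals = 30000)
  rec <- harmonize(study$summary, study$panel)$records
  loci <- cluster_loci(rec, alpha = 5e-8)
  counts <- vapply(c(0.05, 0.01, 0.001, 1e-6), function(b)
    nrow(dissect_locus(loci[[1]], study$panel, bonferroni_base = b)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("members missing from the panel are excluded with a warning", {
  cfg <- sim_config(list(sim_locus(4, rho = 0.6)), n_haplotypes = 2000)
  panel <- sim_panel(cfg, seed = 37L)
  rec <- noise_free_records(panel, c(rs1_1 = 0.1), n = 1e5)
  loci <- cluster_loci(rec, alpha = 5e-8, window_kb = 500)
  expect_gte(nrow(loci[[1]]$members), 2L)
  drop_id <- setdiff(loci[[1]]$members$marker_id, loci[[1]]$lead)[1]
  keep <- panel$variants$marker_id != drop_id
  panel2 <- panel
  panel2$haplotypes <- panel2$haplotypes[, keep, drop = FALSE]
  panel2$variants <- panel2$variants[keep, , drop = FALSE]
  expect_warning(sig <- dissect_locus(loci[[1]], panel2), "absent from panel")
  expect_false(drop_id %in% sig$marker_id)
  empty <- loci[[1]]
  empty$members <- empty$members[0, ]
  expect_error(dissect_locus(empty, panel), class = "ah_domain_error")
})

test_that("later rounds project the assigned (rank-conditional) effects", {
  # 3-causal noise-free locus; replay the documented sequential-residual
  # arithmetic by hand and require exact agreement
  cfg <- sim_config(list(sim_locus(5, freqs = c(0.3, 0.45, 0.5, 0.35, 0.4),
                                   rho = 0.4, causal = integer())),
                    n_haplotypes = 4000)
  panel <- sim_panel(cfg, seed = 53L)
  truth <- c(rs1_1 = 0.08, rs1_3 = 0.06, rs1_5 = 0.05)
  rec <- noise_free_records(panel, truth, n = 2e5)
  loci <- cluster_loci(rec, alpha = 5e-8, window_kb = 500)
  sig <- dissect_locus(loci[[1]], panel, max_rank = 3)
  expect_equal(nrow(sig), 3L)

  est_of <- function(id) {
    r <- rec[rec$marker_id == id, ]
    effect_from_summary(z_from_p(r$p, r$direction), r$freq, r$n_obs)
  }
  proj_of <- function(b, from, to) {
    projected_effect(b, pair_ld(panel, from, to)$d, allele_freq(panel, to))
  }
  # replay: rank 1 marginal; rank 2 conditional on rank 1's marginal beta;
  # rank 3 conditional on rank 1's marginal and rank 2's *conditional* beta
  m1 <- sig$marker_id[1]; m2 <- sig$marker_id[2]; m3 <- sig$marker_id[3]
  b1 <- est_of(m1)$beta
  expect_equal(sig$beta[1], b1)
  b2 <- est_of(m2)$beta - proj_of(b1, m1, m2)
  expect_equal(sig$beta[2], b2, tolerance = 1e-12)
  b3 <- est_of(m3)$beta - proj_of(b1, m1, m3) - proj_of(b2, m2, m3)
  expect_equal(sig$beta[3], b3, tolerance = 1e-12)
  # the alternative flag projects marginal effects of all selected SNPs
  alt <- dissect_locus(loci[[1]], panel, max_rank = 3,
                       condition_on = "marginal")
  b3_alt <- est_of(alt$marker_id[3])$beta -
    proj_of(est_of(alt$marker_id[1])$beta, alt$marker_id[1], alt$marker_id[3]) -
    proj_of(est_of(alt$marker_id[2])$beta, alt$marker_id[2], alt$marker_id[3])
  expect_equal(alt$beta[3], b3_alt, tolerance = 1e-12)
})

test_that("dissect_all tabulates heterogeneity over loci", {
  study <- sim_study(seed = 43L,
                     loci = list(
                       sim_locus(6, start = 1e6, rho = 0.3,
                                 causal = c(1, 4), beta = c(0.09, 0.08)),
                       sim_locus(4, start = 9e6, causal = 1, beta = 0.1),
                       sim_locus(4, start = 18e6, causal = 2, beta = 0.1)),
                     n_individuals = 40000)
  rec <- harmonize(study$summary, study$panel)$records
  loci <- cluster_loci(rec, alpha = 5e-8)
  expect_length(loci, 3L)
  dis <- dissect_all(loci, study$panel)
  expect_equal(dis$summary$n_loci, 3L)
  expect_gte(dis$summary$n_secondary, 1L)
  expect_equal(dis$summary$pct_secondary,
               100 * dis$summary$n_secondary / 3)
  expect_equal(sort(unique(dis$signals$locus_id)),
               vapply(loci, function(l) l$locus_id, ""))
  # capping at rank 1 forces one signal per locus and 0% heterogeneity
  dis1 <- dissect_all(loci, study$panel, max_rank = 1)
  expect_equal(nrow(dis1$signals), 3L)
  expect_equal(dis1$summary$pct_secondary, 0)
  empty <- dissect_all(list(), study$panel)
  expect_equal(empty$summary$n_loci, 0L)
})
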