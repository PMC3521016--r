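test_that("adjustment removes exactly linear age/sex structure", {
  ph <- data.frame(id = sprintf("i%02d", 1:20),
                   age = rep(20:29, 2), sex = rep(c("F", "M"), each = 10))
  ph$trait <- 150 + 0.5 * ph$age + 3 * (ph$sex == "M") +
    0.1 * ph$age * (ph$sex == "M")
  res <- adjust_phenotype(ph)
  expect_lt(max(abs(res)), 1e-10)
  expect_equal(attr(res, "n_dropped"), 0L)
  expect_equal(as.numeric(attr(res, "sex")), rep(c(0, 1), each = 10))
})

test_that("row order does not change any id's residual; missing rows are dropped", {
  set.seed(8)
  ph <- data.frame(id = sprintf("i%03d", 1:100), age = runif(100, 20, 80),
                   sex = sample(c("F", "M"), 100, TRUE))
  ph$trait <- 160 + 0.2 * ph$age + 5 * (ph$sex == "M") + rnorm(100, 0, 4)
  a <- adjust_phenotype(ph)
  b <- adjust_phenotype(ph[sample.int(100), ])
  expect_equal(a[sort(names(a))], b[sort(names(b))],
               tolerance = 1e-12, ignore_attr = TRUE)
  ph$trait[3] <- NA; ph$age[7] <- NA
  d <- adjust_phenotype(ph)
  expect_equal(attr(d, "n_dropped"), 2L)
  expect_false(any(c("i003", "i007") %in% names(d)))
})

test_that("residual variance approaches the generative noise variance", {
  set.seed(15)
  n <- 1000
  ph <- data.frame(id = seq_len(n), age = runif(n, 20, 80),
                   sex = rbinom(n, 1, 0.5))
  e <- rnorm(n, 0, 2)
  ph$trait <- 0.5 * ph$age + 3 * ph$sex + e
  res <- adjust_phenotype(ph)
  expect_lt(abs(var(res) / 4 - 1), 0.10)
})

test_that("degenerate phenotype tables are input errors", {
  expect_error(adjust_phenotype(data.frame(id = 1, trait = 1, age = 1, sex = 0)),
               class = "ah_input_error")
  ph <- data.frame(id = 1:10, trait = rnorm(10), age = 50, sex = rep(0:1, 5))
  expect_error(adjust_phenotype(ph), class = "ah_input_error")
  expect_error(adjust_phenotype(data.frame(id = 1:3, trait = 1:3)),
               class = "ah_input_error")
})

test_that("build_score is the weighted dosage sum with linear structure", {
  X <- matrix(c(2, 1, 0, 2), nrow = 2,
              dimnames = list(c("i1", "i2"), c("a", "b")))
  sg <- data.frame(marker_id = c("a", "b"), beta = c(0.1, -0.2))
  s <- build_score(sg, X)
  expect_equal(unname(s["i1"]), 0.1 * 2 - 0.2 * 0)
  expect_equal(unname(s["i2"]), 0.1 * 1 - 0.2 * 2)
  # all-zero weights
  sg0 <- transform(sg, beta = 0)
  expect_equal(unname(build_score(sg0, X)), c(0, 0))
  # splitting a weight across duplicate entries changes nothing
  sg_dup <- data.frame(marker_id = c("a", "a", "b"), beta = c(0.05, 0.05, -0.2))
  expect_equal(build_score(sg_dup, X), s)
  # markers absent from genotypes: dropped with warning, or error if none left
  sg_extra <- rbind(sg, data.frame(marker_id = "zz", beta = 1))
  expect_warning(s2 <- build_score(sg_extra, X), "absent")
  expect_equal(s2, s)
  expect_error(build_score(data.frame(marker_id = "zz", beta = 1), X),
               class = "ah_input_error")
})

test_that("missing dosages rescale by observed weight or drop the sample", {
  X <- matrix(c(2, 1, NA, 2, 1, 1), nrow = 3,
              dimnames = list(c("i1", "i2", "i3"), c("a", "b")))
  sg <- data.frame(marker_id = c("a", "b"), beta = c(0.1, 0.3))
  s <- build_score(sg, X)
  expect_equal(unname(s["i1"]), 0.1 * 2 + 0.3 * 2)
  expect_equal(unname(s["i3"]), (0.3 * 1) * (0.4 / 0.3))
  strict <- build_score(sg, X, missing = "strict")
  expect_true(is.na(strict["i3"]))
  expect_equal(strict["i1"], s["i1"])
})

test_that("variance_explained is squared correlation, affine-invariant, stratified", {
  set.seed(22)
  n <- 200
  res <- rnorm(n)
  names(res) <- sprintf("i%03d", 1:n)
  sex <- setNames(rbinom(n, 1, 0.5), names(res))
  # residuals identical to score
  v <- variance_explained(res, res, strata = sex)
  expect_equal(v$r2[v$stratum == "all"], 1)
  expect_equal(v$n[v$stratum == "female"], sum(sex == 0))
  # affine rescaling leaves r2 unchanged
  score <- res + rnorm(n)
  v1 <- variance_explained(score, res, strata = sex)
  v2 <- variance_explained(3 * score - 7, res, strata = sex)
  expect_equal(v1$r2, v2$r2)
  expect_true(all(v1$r2 >= 0 & v1$r2 <= 1))
  # zero-variance score warns and reports 0
  expect_warning(v0 <- variance_explained(setNames(rep(1, n), names(res)), res),
                 "zero-variance")
  expect_equal(v0$r2[1], 0)
})

test_that("an independent score explains essentially nothing", {
  set.seed(31)
  n <- 1e4
  res <- setNames(rnorm(n), seq_len(n))
  score <- setNames(rnorm(n), seq_len(n))
  v <- variance_explained(score, res)
  expect_lt(v$r2[1], 0.01)
})

test_that("true-weight scores recover the planted variance fraction", {
  study <- sim_study(seed = 55L,
                     loci = list(
                       sim_locus(3, start = 1e6, rho = 0.2, causal = 2, beta = 1),
                       sim_locus(3, start = 9e6, rho = 0.2, causal = 1, beta = 1)),
                     n_individuals = 5000, heritability = 0.10)
  truth <- study$cohort$truth
  sg <- data.frame(marker_id = truth$causal, beta = truth$beta)
  s <- build_score(sg, study$cohort$genotypes)
  res <- adjust_phenotype(study$cohort$pheno)
  v <- variance_explained(s, res)
  expect_lt(abs(v$r2[v$stratum == "all"] - 0.10), 0.02)
})

test_that("score_report nests rank sets consistently", {
  study <- sim_study(seed = 59L,
                     loci = list(sim_locus(5, rho = 0.3, causal = c(1, 4),
                                           beta = c(0.15, 0.12))),
                     n_individuals = 8000)
  rec <- harmonize(study$summary, study$panel)$records
  loci <- cluster_loci(rec, alpha = 5e-8)
  dis <- dissect_all(loci, study$panel)
  res <- adjust_phenotype(study$cohort$pheno)
  rep_ <- score_report(dis$signals, study$cohort$genotypes, res)
  # the rank-1 row equals a primaries-only score
  prim <- build_score(dis$signals[dis$signals$rank == 1, ],
                      study$cohort$genotypes)
  v1 <- variance_explained(prim, res)
  expect_equal(rep_$r2[rep_$ranks == "1" & rep_$stratum == "all"],
               v1$r2[v1$stratum == "all"])
  expect_equal(rep_$n_snps[rep_$ranks == "1"][1],
               sum(dis$signals$rank == 1))
  # adding a zero-effect pseudo-signal leaves r2 unchanged
  aug <- rbind(dis$signals,
               transform(dis$signals[1, ], rank = 2, beta = 0,
                         marker_id = setdiff(colnames(study$cohort$genotypes),
                                             dis$signals$marker_id)[1]))
  rep_aug <- score_report(aug, study$cohort$genotypes, res)
  expect_equal(rep_aug$r2[rep_aug$ranks == "1-2" & rep_aug$stratum == "all"],
               rep_$r2[rep_$ranks == "1-2" & rep_$stratum == "all"])
})

test_that("dosage matrices round-trip through TSV and VCF genotypes load", {
  study <- sim_study(seed = 61L,
                     loci = list(sim_locus(3, causal = 1, beta = 0.1)),
                     n_individuals = 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(study$cohort$genotypes, f)
  X <- read_genotypes(f, format = "tsv")
  expect_equal(X, study$cohort$genotypes)
  # GT-based dosage from a phased VCF equals haplotype-sum dosages
  fv <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_panel(study$panel, fv)
  Xv <- read_genotypes(fv, format = "vcf")
  H <- study$panel$haplotypes
  expect_equal(unname(Xv[1, ]), unname(H[1, ] + H[2, ]))
})
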