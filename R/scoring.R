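#' Age/sex-adjusted phenotype residuals
#'
#' Ordinary least-squares residuals of the trait on intercept, age, sex
#' and the age-by-sex interaction. Sex is coded 0/1 (female/male); "F"/"M"
#' labels are accepted. Rows with any missing field are dropped with a
#' count.
#'
#' @param pheno Data frame with columns `id`, `trait`, `age`, `sex`.
#' @return Named numeric vector of residuals (names = id), mean zero,
#'   with attributes `n_dropped` and `sex` (the 0/1 coding of retained
#'   rows, for stratified scoring).
#' @export
adjust_phenotype <- function(pheno) {
  need <- c("id", "trait", "age", "sex")
  if (!all(need %in% names(pheno)))
    ah_input_error(sprintf("phenotype table needs columns: %s",
                           paste(need, collapse = ", ")))
  sex <- pheno$sex
  if (is.character(sex) || is.factor(sex)) {
    sex <- toupper(as.character(sex))
    sx <- rep(NA_real_, length(sex))
    sx[sex %in% c("F", "FEMALE", "0")] <- 0
    sx[sex %in% c("M", "MALE", "1")] <- 1
    sex <- sx
  }
  d <- data.frame(id = as.character(pheno$id), trait = as.numeric(pheno$trait),
                  age = as.numeric(pheno$age), sex = as.numeric(sex),
                  stringsAsFactors = FALSE)
  cc <- stats::complete.cases(d)
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  if (nrow(d) < 3L) ah_input_error("fewer than 3 complete phenotype rows")
  if (stats::var(d$age) == 0 || stats::var(d$sex) == 0)
    ah_input_error("age or sex is constant; adjustment model is unidentifiable")
  fit <- stats::lm(trait ~ age * sex, data = d)
  res <- stats::residuals(fit)
  names(res) <- d$id
  attr(res, "n_dropped") <- n_dropped
  attr(res, "sex") <- stats::setNames(d$sex, d$id)
  res
}

#' Weighted genetic score
#'
#' S_i = sum_k beta_k x_ik, where x_ik is individual i's dosage of signal
#' k's effect allele and beta_k the signal's assigned effect (marginal for
#' primaries, conditional for higher ranks). Signals whose marker is
#' absent from the genotype matrix are dropped with a warning. A sample
#' with missing dosages is, by default, scored over its observed markers
#' and rescaled by total |weight| / observed |weight|; `missing =
#' "strict"` returns NA for such samples.
#'
#' @param signals Signal table from [dissect_all()] (needs `marker_id`,
#'   `beta`).
#' @param genotypes Numeric matrix of dosages in [0,2], samples x markers,
#'   with dimnames; columns must be aligned to the signals' effect alleles.
#' @param missing `"scale"` (default) or `"strict"`.
#' @return Named numeric vector of scores.
#' @export
build_score <- function(signals, genotypes, missing = c("scale", "strict")) {
  missing <- match.arg(missing)
  keep <- signals$marker_id %in% colnames(genotypes)
  if (!any(keep)) ah_input_error("no signal marker present in genotypes")
  if (!all(keep))
    warning(sprintf("%d signal marker(s) absent from genotypes dropped",
                    sum(!keep)))
  sg <- signals[keep, , drop = FALSE]
  X <- genotypes[, sg$marker_id, drop = FALSE]
  w <- sg$beta
  if (anyNA(X)) {
    obs <- !is.na(X)
    Xz <- X; Xz[!obs] <- 0
    s <- as.numeric(Xz %*% w)
    if (missing == "strict") {
      s[rowSums(!obs) > 0] <- NA_real_
    } else {
      wobs <- as.numeric(obs %*% abs(w))
      tot <- sum(abs(w))
      scale <- ifelse(wobs > 0, tot / wobs, NA_real_)
      s <- s * scale
    }
  } else {
    s <- as.numeric(X %*% w)
  }
  stats::setNames(s, rownames(genotypes))
}

#' Variance explained by a genetic score
#'
#' The fraction of variance in adjusted trait residuals explained by the
#' score: the squared Pearson correlation between score and residuals,
#' identical to the R² of a univariate linear regression of residuals on
#' the score. Computed for all paired samples and, when sex labels are
#' supplied, separately per sex using only that stratum's samples.
#'
#' @param score Named score vector from [build_score()].
#' @param residuals Named residual vector from [adjust_phenotype()].
#' @param strata Optional named 0/1 sex vector (0 female, 1 male);
#'   defaults to the `sex` attribute of `residuals` when present.
#' @return Data frame with columns `stratum` ("all", "female", "male"),
#'   `r2`, `n`.
#' @export
variance_explained <- function(score, residuals, strata = attr(residuals, "sex")) {
  ids <- intersect(names(score), names(residuals))
  if (length(ids) < 3L) ah_input_error("fewer than 3 paired score/residual samples")
  s <- score[ids]; r <- residuals[ids]
  r2_of <- function(s, r) {
    if (length(s) < 3L) return(NA_real_)
    if (stats::var(s) == 0) {
      warning("zero-variance score; r2 set to 0")
      return(0)
    }
    stats::cor(s, r)^2
  }
  out <- data.frame(stratum = "all", r2 = r2_of(s, r), n = length(ids),
                    stringsAsFactors = FALSE)
  if (!is.null(strata)) {
    sx <- strata[ids]
    for (lab in c(female = 0, male = 1)) {
      i <- which(!is.na(sx) & sx == lab)
      out <- rbind(out, data.frame(
        stratum = names(which(c(female = 0, male = 1) == lab)),
        r2 = if (length(i) >= 3) r2_of(s[i], r[i]) else NA_real_,
        n = length(i), stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Variance explained by rank-nested signal sets
#'
#' Builds scores from primaries only, primaries + secondaries, and
#' primaries + secondaries + tertiaries (configurable), and reports the
#' variance explained for each set in each stratum — the shape in which
#' cumulative gains from allelic heterogeneity are usually tabulated.
#'
#' @param signals Signal table from [dissect_all()].
#' @param genotypes Dosage matrix (samples x markers).
#' @param residuals Adjusted residuals from [adjust_phenotype()].
#' @param max_ranks Integer vector of rank cutoffs (default 1:3).
#' @param strata Optional sex vector; see [variance_explained()].
#' @return Data frame with `ranks` ("1".."1-3"), `n_snps`, `stratum`, `r2`, `n`.
#' @export
score_report <- function(signals, genotypes, residuals, max_ranks = 1:3,
                         strata = attr(residuals, "sex")) {
  out <- NULL
  for (k in max_ranks) {
    sg <- signals[signals$rank <= k, , drop = FALSE]
    s <- build_score(sg, genotypes)
    ve <- variance_explained(s, residuals, strata)
    ve$ranks <- if (k == 1) "1" else sprintf("1-%d", k)
    ve$n_snps <- nrow(sg)
    out <- rbind(out, ve[, c("ranks", "n_snps", "stratum", "r2", "n")])
  }
  rownames(out) <- NULL
  out
}

#' Read a dosage matrix
#'
#' Either a TSV with sample ids in the first column and one column per
#' marker (values in [0,2]), or a VCF read via the DS FORMAT field when
#' present, else phased/unphased GT converted to ALT-allele counts.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @return Numeric matrix, samples x markers.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) ah_input_error(sprintf("genotype file not found: %s", path))
  if (format == "tsv") {
    con <- open_text(path)
    on.exit(close(con))
    d <- utils::read.table(con, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
    X <- as.matrix(d[, -1, drop = FALSE])
    rownames(X) <- as.character(d[[1]])
    storage.mode(X) <- "double"
    return(X)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getFIX(vcf)[, "ID"]
  ds <- tryCatch(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (!is.null(ds) && !all(is.na(ds))) {
    X <- t(ds)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    cnt <- matrix(vapply(strsplit(gsub("\\|", "/", gt), "/"),
                         function(a) sum(as.integer(a)), 0L),
                  nrow = nrow(gt))
    X <- t(cnt)
  }
  colnames(X) <- ids
  storage.mode(X) <- "double"
  X
}
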