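#' Construct a haplotype panel object
#'
#' Internal constructor shared by the VCF and HapMap readers and by the
#' simulator. Columns of `haplotypes` are variants, rows are haplotypes
#' (2 per diploid sample); an entry of 1 means the haplotype carries the
#' coded allele `a1`. Monomorphic columns are dropped (their frequency
#' would leave LD undefined) and counted.
#'
#' @param variants Data frame with `marker_id`, `chrom`, `pos`, `a0`, `a1`.
#' @param haplotypes 0/1 matrix, one column per row of `variants`.
#' @return Object of class `HaplotypePanel`: list with `variants` (plus a
#'   `freq` column, the coded-allele frequency), `haplotypes`, and
#'   `n_dropped_mono`.
#' @keywords internal
new_panel <- function(variants, haplotypes) {
  stopifnot(nrow(variants) == ncol(haplotypes))
  if (!all(haplotypes %in% c(0L, 1L)))
    ah_input_error("haplotype matrix entries must be 0/1")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p)) ah_input_error(sprintf(
      "variant positions not sorted on chromosome %s", ch))
  }
  freq <- colMeans(haplotypes)
  mono <- freq <= 0 | freq >= 1
  variants <- variants[!mono, , drop = FALSE]
  haplotypes <- haplotypes[, !mono, drop = FALSE]
  variants$freq <- freq[!mono]
  rownames(variants) <- NULL
  colnames(haplotypes) <- variants$marker_id
  structure(list(variants = variants, haplotypes = haplotypes,
                 n_dropped_mono = sum(mono)),
            class = "HaplotypePanel")
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  cat(sprintf("HaplotypePanel: %d variants x %d haplotypes (%d samples)\n",
              nrow(x$variants), nrow(x$haplotypes), nrow(x$haplotypes) / 2))
  cat(sprintf("  chromosomes: %s; monomorphic sites dropped: %d\n",
              paste(unique(x$variants$chrom), collapse = ","),
              x$n_dropped_mono))
  invisible(x)
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    ah_config_error(sprintf("malformed region '%s' (expected chr:start-end)", region))
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

#' Load a phased haplotype reference panel
#'
#' Two input dialects are supported. `format = "vcf"` reads a VCF whose GT
#' fields are phased and diploid (e.g. `0|1`); each sample contributes two
#' haplotype rows and the ALT allele is the coded allele. `format =
#' "hapmap_phased"` reads the HapMap Phase 2 trio of files
#' `<prefix>_legend.txt` (rs, position, allele coded 0, allele coded 1),
#' `<prefix>_phased` (one row per haplotype of 0/1 states) and
#' `<prefix>_sample.txt`; the legend's allele "1" is the coded allele.
#' Only biallelic SNPs are retained; monomorphic sites are dropped with a
#' count. Coordinates are 1-based and region intervals closed.
#'
#' @param path VCF file, or the HapMap file prefix.
#' @param format `"vcf"` or `"hapmap_phased"`.
#' @param region Optional `"chr:start-end"` restriction.
#' @param chrom Chromosome label for the HapMap dialect (its legend has no
#'   chromosome column); defaults to a `chr<k>` token found in `path`, else
#'   `"1"`.
#' @return A `HaplotypePanel`.
#' @export
load_panel <- function(path, format = c("vcf", "hapmap_phased"),
                       region = NULL, chrom = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    panel <- load_panel_vcf(path)
  } else {
    panel <- load_panel_hapmap(path, chrom = chrom)
  }
  if (!is.null(region)) {
    rg <- parse_region(region)
    keep <- panel$variants$chrom == rg$chrom &
      panel$variants$pos >= rg$start & panel$variants$pos <= rg$end
    if (!any(keep))
      ah_input_error(sprintf("region %s contains no panel variant", region))
    panel$haplotypes <- panel$haplotypes[, keep, drop = FALSE]
    panel$variants <- panel$variants[keep, , drop = FALSE]
    rownames(panel$variants) <- NULL
  }
  panel
}

load_panel_vcf <- function(path) {
  if (!file.exists(path)) ah_input_error(sprintf("VCF not found: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  bases <- c("A", "C", "G", "T")
  bi <- fix[, "REF"] %in% bases & fix[, "ALT"] %in% bases
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  gt <- gt[bi, , drop = FALSE]
  fix <- fix[bi, , drop = FALSE]
  if (nrow(fix) == 0L) ah_input_error("VCF contains no biallelic SNP")
  ok <- grepl("^[01]\\|[01]$", gt)
  dim(ok) <- dim(gt)
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    ah_input_error(sprintf(
      "unphased or non-diploid genotype at %s (sample %s)",
      fix[bad[1, 1], "ID"], colnames(gt)[bad[1, 2]]))
  h1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  h2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  # interleave the two haplotypes of each sample as consecutive rows
  haps <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
  haps[seq(1, nrow(haps), by = 2), ] <- t(h1)
  haps[seq(2, nrow(haps), by = 2), ] <- t(h2)
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix[blank, "CHROM"], ":", fix[blank, "POS"])
  variants <- data.frame(marker_id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         a0 = fix[, "REF"], a1 = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  ord <- order(variants$chrom, variants$pos)
  new_panel(variants[ord, , drop = FALSE], haps[, ord, drop = FALSE])
}

load_panel_hapmap <- function(prefix, chrom = NULL) {
  legend_f <- paste0(prefix, "_legend.txt")
  phased_f <- paste0(prefix, "_phased")
  sample_f <- paste0(prefix, "_sample.txt")
  for (f in c(legend_f, phased_f, sample_f))
    if (!file.exists(f)) ah_input_error(sprintf("HapMap dialect file not found: %s", f))
  legend <- utils::read.table(legend_f, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(legend) < 4L) ah_input_error("legend must have rs/position/allele0/allele1")
  phased <- as.matrix(utils::read.table(phased_f, header = FALSE))
  if (ncol(phased) != nrow(legend))
    ah_input_error(sprintf("legend (%d SNPs) and phased (%d columns) disagree",
                           nrow(legend), ncol(phased)))
  samples <- readLines(sample_f)
  samples <- samples[nzchar(trimws(samples))]
  if (nrow(phased) != 2L * length(samples))
    ah_input_error(sprintf("phased has %d haplotype rows for %d samples",
                           nrow(phased), length(samples)))
  if (is.null(chrom)) {
    m <- regmatches(prefix, regexpr("chr[0-9XY]+", prefix))
    chrom <- if (length(m) && nzchar(m)) sub("^chr", "", m) else "1"
  }
  bases <- c("A", "C", "G", "T")
  bi <- toupper(legend[[3]]) %in% bases & toupper(legend[[4]]) %in% bases
  variants <- data.frame(marker_id = as.character(legend[[1]][bi]),
                         chrom = chrom, pos = as.integer(legend[[2]][bi]),
                         a0 = toupper(legend[[3]][bi]),
                         a1 = toupper(legend[[4]][bi]),
                         stringsAsFactors = FALSE)
  haps <- phased[, bi, drop = FALSE]
  storage.mode(haps) <- "integer"
  ord <- order(variants$pos)
  new_panel(variants[ord, , drop = FALSE], haps[, ord, drop = FALSE])
}

panel_index <- function(panel, marker) {
  i <- match(marker, panel$variants$marker_id)
  if (any(is.na(i)))
    ah_error("ah_lookup_error",
             sprintf("marker(s) not in panel: %s",
                     paste(marker[is.na(i)], collapse = ", ")))
  i
}

#' Coded-allele frequency of a panel marker
#'
#' @param panel A `HaplotypePanel`.
#' @param marker Marker id.
#' @return Frequency of the coded allele, strictly in (0,1).
#' @export
allele_freq <- function(panel, marker) {
  panel$variants$freq[panel_index(panel, marker)]
}

#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Computes the LD coefficient D = p_ij - f_i f_j, the haplotype-frequency
#' covariance between the coded alleles of two markers, and r² =
#' D² / (f_i(1-f_i) f_j(1-f_j)). D is computed on haplotypes; under
#' Hardy-Weinberg equilibrium the genotype (dosage) covariance is 2D,
#' which is what the conditional-effect projection uses. Pairs farther
#' apart than `max_bp` return D = 0 with `windowed = TRUE`, bounding the
#' amount of LD ever consulted (trait loci span at most a few Mb).
#'
#' @param panel A `HaplotypePanel`.
#' @param marker_i,marker_j Marker ids on the same chromosome.
#' @param max_bp Maximum pair distance for a non-zero result (default 5 Mb).
#' @param allow_cross_chrom Treat cross-chromosome LD as 0 instead of
#'   raising a domain error.
#' @return List with `d`, `r2`, `f_i`, `f_j`, `windowed`.
#' @export
pair_ld <- function(panel, marker_i, marker_j, max_bp = 5e6,
                    allow_cross_chrom = FALSE) {
  i <- panel_index(panel, marker_i)
  j <- panel_index(panel, marker_j)
  v <- panel$variants
  fi <- v$freq[i]; fj <- v$freq[j]
  if (v$chrom[i] != v$chrom[j]) {
    if (!allow_cross_chrom)
      ah_domain_error(sprintf("%s and %s lie on different chromosomes",
                              marker_i, marker_j))
    return(list(d = 0, r2 = 0, f_i = fi, f_j = fj, windowed = TRUE))
  }
  if (abs(v$pos[i] - v$pos[j]) > max_bp)
    return(list(d = 0, r2 = 0, f_i = fi, f_j = fj, windowed = TRUE))
  pij <- mean(panel$haplotypes[, i] * panel$haplotypes[, j])
  d <- pij - fi * fj
  r2 <- d^2 / (fi * (1 - fi) * fj * (1 - fj))
  list(d = d, r2 = r2, f_i = fi, f_j = fj, windowed = FALSE)
}
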