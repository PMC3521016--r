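#' Default adjacency window for a clustering significance level
#'
#' The window length used to define "physical adjacency" shrinks as the
#' significance level is relaxed, because relaxing the level greatly
#' increases the density of significant SNPs. The default mapping is
#' 5e-8 -> 500 kb, 5e-7 -> 400, 5e-6 -> 300, 5e-5 -> 200, 5e-4 -> 100,
#' 5e-3 -> 50. An off-grid level takes the window of the tightest listed
#' level that still admits it (the smallest listed level >= alpha), so the
#' window is never too long for the SNP density alpha implies; levels
#' above 5e-3 use 50 kb.
#'
#' @param alpha Significance level in (0,1).
#' @return Window length in kb.
#' @export
#' @examples
#' default_window(5e-8)  # 500
#' default_window(1e-6)  # 300 (nearest level is 5e-6)
default_window <- function(alpha) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  levels_ <- c(5e-8, 5e-7, 5e-6, 5e-5, 5e-4, 5e-3)
  windows <- c(500, 400, 300, 200, 100, 50)
  i <- which(levels_ >= alpha)
  if (length(i) == 0L) return(windows[length(windows)])
  windows[i[1]]
}

#' Cluster significant SNPs into loci by physical adjacency
#'
#' SNPs with p below `alpha` are grouped, per chromosome, into the
#' connected components of the graph linking SNPs at most `window_kb`
#' apart (single-linkage chaining, gap = L joins). Chaining — rather than
#' distance to the lead SNP — is used deliberately: it lets a run of
#' adjacent significant SNPs form one locus spanning several Mb. The lead
#' SNP of a locus is its smallest-p member, ties broken by smaller
#' position then marker id.
#'
#' @param records Harmonized summary records (chrom/pos present).
#' @param alpha Clustering significance level.
#' @param window_kb Adjacency length L in kb; `NULL` uses
#'   [default_window()].
#' @return List of `Locus` objects, sorted by chromosome then span start.
#'   Each is a list with `locus_id`, `chrom`, `members` (records ordered by
#'   position), `lead` (marker id), `lead_p`, `span`.
#' @export
cluster_loci <- function(records, alpha, window_kb = NULL) {
  if (is.null(window_kb)) window_kb <- default_window(alpha)
  if (window_kb <= 0) ah_domain_error("window_kb must be positive")
  if (any(is.na(records$chrom)) || any(is.na(records$pos)))
    ah_input_error("records must be harmonized (chrom/pos present) before clustering")
  sig <- records[records$p < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) return(list())
  L <- window_kb * 1000
  loci <- list()
  for (ch in sort(unique(sig$chrom))) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos, s$marker_id), , drop = FALSE]
    breaks <- which(diff(s$pos) > L)
    comp <- cumsum(c(1L, seq_len(nrow(s) - 1L) %in% breaks))
    for (k in unique(comp)) {
      mem <- s[comp == k, , drop = FALSE]
      rownames(mem) <- NULL
      ord <- order(mem$p, mem$pos, mem$marker_id)
      loci[[length(loci) + 1L]] <- structure(list(
        locus_id = NA_character_, chrom = ch, members = mem,
        lead = mem$marker_id[ord[1L]], lead_p = mem$p[ord[1L]],
        span = c(min(mem$pos), max(mem$pos))), class = "Locus")
    }
  }
  ord <- order(vapply(loci, function(l) l$chrom, ""),
               vapply(loci, function(l) l$span[1], 0))
  loci <- loci[ord]
  for (i in seq_along(loci)) loci[[i]]$locus_id <- sprintf("locus_%03d", i)
  loci
}

#' @export
print.Locus <- function(x, ...) {
  cat(sprintf("Locus %s: chr%s:%d-%d, %d SNP(s), lead %s (p=%.3g)\n",
              x$locus_id, x$chrom, x$span[1], x$span[2], nrow(x$members),
              x$lead, x$lead_p))
  invisible(x)
}

#' Tabulate a locus list
#'
#' @param loci Result of [cluster_loci()].
#' @return Data frame with one row per locus (id, chrom, start, end,
#'   n_snps, lead marker, lead p).
#' @export
loci_table <- function(loci) {
  do.call(rbind, lapply(loci, function(l) data.frame(
    locus_id = l$locus_id, chrom = l$chrom, start = l$span[1],
    end = l$span[2], n_snps = nrow(l$members), lead = l$lead,
    lead_p = l$lead_p, stringsAsFactors = FALSE)))
}

#' Export locus spans as BED
#'
#' BED is 0-based, half-open; a locus spanning positions [s, e] (1-based,
#' inclusive) becomes the interval (s-1, e).
#'
#' @param loci Result of [cluster_loci()].
#' @param path Output path.
#' @export
write_loci_bed <- function(loci, path) {
  tab <- loci_table(loci)
  bed <- data.frame(chrom = tab$chrom, start = tab$start - 1L, end = tab$end,
                    name = tab$locus_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
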