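#' Iterative signal extraction at one locus
#'
#' Rank 1 is the locus lead with its marginal effect. In each later round,
#' every not-yet-selected member's conditional effect is its marginal
#' effect minus the summed LD projections of all selected signals, each
#' projection using that signal's assigned effect (marginal for rank 1,
#' conditional for ranks >= 2 — a sequential-residual scheme; the selected
#' set is never refit jointly). The candidate with the smallest
#' conditional p-value is accepted as the next signal iff that p-value is
#' below the per-locus Bonferroni threshold `bonferroni_base / m`, where m
#' is the number of SNPs clustered into the locus. Iteration stops at the
#' first non-acceptance, at `max_rank`, or when members are exhausted.
#'
#' Candidates in near-perfect LD (r² > `r2_guard`) with any selected
#' signal are skipped: with the standard error kept at its marginal value,
#' such candidates carry almost no independent information and the
#' conditional z becomes numerically unstable.
#'
#' @param locus A `Locus` from [cluster_loci()].
#' @param panel The `HaplotypePanel` supplying frequencies and LD.
#' @param max_rank Maximum number of signals to extract (default 4:
#'   primary through quaternary; in practice quaternary signals add no
#'   score variance).
#' @param bonferroni_base Numerator of the per-locus threshold (default 0.05).
#' @param r2_guard Skip candidates with r² above this to any selected
#'   signal (default 0.99).
#' @param method Effect approximation passed to [effect_from_summary()].
#' @param condition_on `"assigned"` (default) projects each selected
#'   signal's assigned rank-conditional effect; `"marginal"` projects its
#'   marginal effect instead.
#' @return Data frame of signals: `locus_id`, `rank`, `marker_id`,
#'   `chrom`, `pos`, `effect_allele`, `beta`, `se`, `z`, `cond_p`,
#'   `threshold`, `source`.
#' @export
dissect_locus <- function(locus, panel, max_rank = 4, bonferroni_base = 0.05,
                          r2_guard = 0.99, method = "standard",
                          condition_on = c("assigned", "marginal")) {
  condition_on <- match.arg(condition_on)
  stopifnot(inherits(locus, "Locus"))
  if (max_rank < 1) ah_domain_error("max_rank must be >= 1")
  mem <- locus$members
  if (nrow(mem) == 0L) ah_domain_error("locus has no members")
  m <- nrow(mem)
  threshold <- bonferroni_base / m

  in_panel <- mem$marker_id %in% panel$variants$marker_id
  if (!all(in_panel)) {
    warning(sprintf("locus %s: %d member(s) absent from panel excluded",
                    locus$locus_id, sum(!in_panel)))
    mem <- mem[in_panel, , drop = FALSE]
    if (nrow(mem) == 0L) ah_domain_error("no locus member present in panel")
  }

  # marginal estimates for every member, frequencies from the panel
  f <- allele_freq(panel, mem$marker_id)
  z <- z_from_p(mem$p, mem$direction)
  marg <- effect_from_summary(z, f, mem$n_obs, method = method)

  ord <- order(mem$p, mem$pos, mem$marker_id)
  lead_i <- ord[1L]
  sel <- data.frame(idx = lead_i, rank = 1L,
                    beta = marg$beta[lead_i], se = marg$se[lead_i],
                    z = marg$z[lead_i], cond_p = mem$p[lead_i],
                    source = "marginal", stringsAsFactors = FALSE)

  rank <- 1L
  while (rank < max_rank) {
    cand <- setdiff(seq_len(nrow(mem)), sel$idx)
    if (length(cand) == 0L) break
    best <- NULL
    for (t in cand) {
      ld <- lapply(sel$idx, function(s)
        pair_ld(panel, mem$marker_id[s], mem$marker_id[t]))
      if (any(vapply(ld, function(x) x$r2, 0) > r2_guard)) next
      src_beta <- if (condition_on == "assigned") sel$beta else marg$beta[sel$idx]
      proj <- mapply(function(b, x) projected_effect(b, x$d, f[t]), src_beta, ld)
      est <- conditional_effect(marg[t, , drop = FALSE], proj)
      p <- conditional_p(est)
      if (is.null(best) || p < best$p ||
          (p == best$p && (mem$pos[t] < mem$pos[best$t] ||
                           (mem$pos[t] == mem$pos[best$t] &&
                            mem$marker_id[t] < mem$marker_id[best$t])))) {
        best <- list(t = t, est = est, p = p)
      }
    }
    if (is.null(best) || best$p >= threshold) break
    rank <- rank + 1L
    sel <- rbind(sel, data.frame(
      idx = best$t, rank = rank, beta = best$est$beta, se = best$est$se,
      z = best$est$z, cond_p = best$p, source = "conditional",
      stringsAsFactors = FALSE))
  }

  data.frame(locus_id = locus$locus_id, rank = sel$rank,
             marker_id = mem$marker_id[sel$idx], chrom = mem$chrom[sel$idx],
             pos = mem$pos[sel$idx], effect_allele = mem$effect_allele[sel$idx],
             beta = sel$beta, se = sel$se, z = sel$z, cond_p = sel$cond_p,
             threshold = threshold, source = sel$source,
             stringsAsFactors = FALSE)
}

#' Dissect every locus and summarize allelic heterogeneity
#'
#' Runs [dissect_locus()] over a locus list and tabulates how many loci
#' carry secondary (rank >= 2) and tertiary (rank >= 3) signals.
#'
#' @inheritParams dissect_locus
#' @param loci List of loci from [cluster_loci()].
#' @param ... Passed to [dissect_locus()].
#' @return List with `signals` (row-bound signal table) and `summary`, a
#'   one-row data frame: `n_loci`, `n_secondary`, `pct_secondary`,
#'   `n_tertiary`, `pct_tertiary`.
#' @export
dissect_all <- function(loci, panel, max_rank = 4, ...) {
  if (length(loci) == 0L)
    return(list(signals = NULL,
                summary = data.frame(n_loci = 0L, n_secondary = 0L,
                                     pct_secondary = NA_real_,
                                     n_tertiary = 0L,
                                     pct_tertiary = NA_real_)))
  signals <- do.call(rbind, lapply(loci, dissect_locus, panel = panel,
                                   max_rank = max_rank, ...))
  rownames(signals) <- NULL
  max_ranks <- tapply(signals$rank, signals$locus_id, max)
  n_loci <- length(loci)
  n2 <- sum(max_ranks >= 2); n3 <- sum(max_ranks >= 3)
  list(signals = signals,
       summary = data.frame(n_loci = n_loci, n_secondary = n2,
                            pct_secondary = 100 * n2 / n_loci,
                            n_tertiary = n3,
                            pct_tertiary = 100 * n3 / n_loci))
}
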