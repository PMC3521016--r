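#' Signed z-score from a two-sided p-value
#'
#' z = direction * Phi^-1(1 - p/2): the magnitude is the standard-normal
#' quantile of the two-sided p-value and the sign is the reported
#' direction of effect.
#'
#' @param p Two-sided p-value(s) in (0, 1].
#' @param direction Sign(s) in {+1, -1}.
#' @return Signed z-score(s).
#' @export
#' @examples
#' z_from_p(0.05, 1)    # 1.959964
#' z_from_p(5e-8, -1)   # -5.45131
z_from_p <- function(p, direction) {
  if (any(p <= 0 | p > 1)) ah_domain_error("p must lie in (0, 1]")
  if (any(!direction %in% c(-1, 1))) ah_domain_error("direction must be +1 or -1")
  direction * stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Allelic effect and standard error from summary statistics
#'
#' For a phenotype standardized to unit variance, the allelic effect of a
#' SNP with signed z-score z, effect-allele frequency f and sample size N
#' is approximated by beta = z / sqrt(2 f (1-f) N) with standard error
#' se = 1 / sqrt(2 f (1-f) N), since the genotype variance under
#' Hardy-Weinberg equilibrium is 2f(1-f). `method = "cojo"` uses the
#' variant sqrt(2 f (1-f) (N + z^2)) in the denominator, which absorbs the
#' variance contributed by the SNP itself and matters only for large
#' effects.
#'
#' @param z Signed z-score(s).
#' @param f Effect-allele frequency in (0,1); take it from the LD panel,
#'   not the summary file, so effects and LD share one orientation.
#' @param n Sample size (>= 2).
#' @param method `"standard"` (default) or `"cojo"`.
#' @return Data frame with `beta`, `se`, `z`, `source = "marginal"`.
#' @export
effect_from_summary <- function(z, f, n, method = c("standard", "cojo")) {
  method <- match.arg(method)
  if (any(f <= 0 | f >= 1)) ah_domain_error("frequency must lie strictly in (0, 1)")
  if (any(n < 2)) ah_domain_error("sample size must be at least 2")
  denom <- if (method == "cojo") 2 * f * (1 - f) * (n + z^2) else 2 * f * (1 - f) * n
  se <- 1 / sqrt(denom)
  data.frame(beta = z * se, se = se, z = z, source = "marginal",
             stringsAsFactors = FALSE)
}

#' LD-projected effect at a neighbouring SNP
#'
#' The apparent marginal effect induced at SNP t by a source SNP s with
#' effect beta_s is beta_s * Cov(g_s, g_t) / Var(g_t). With phased-panel
#' LD coefficient D and coded-allele frequency f_t, HWE gives Cov = 2D and
#' Var = 2 f_t (1 - f_t), so the projection is beta_s * D / (f_t (1-f_t)).
#'
#' @param beta_source Effect at the source SNP.
#' @param d LD coefficient D between source and target (haplotype scale).
#' @param f_target Coded-allele frequency of the target SNP.
#' @return Projected effect at the target.
#' @export
projected_effect <- function(beta_source, d, f_target) {
  if (any(f_target <= 0 | f_target >= 1))
    ah_domain_error("frequency must lie strictly in (0, 1)")
  beta_source * d / (f_target * (1 - f_target))
}

#' Conditional effect after removing projected contributions
#'
#' Subtracts the summed LD projections of already-selected SNPs from a
#' SNP's observed (marginal) effect. The standard error is kept at the
#' marginal value — the procedure treats each pair of SNPs once rather
#' than refitting a joint model — so the conditional z is
#' (beta - sum of projections) / se. This is a deliberate approximation;
#' it is slightly anti-conservative when the SNP is in strong LD with a
#' selected SNP (see the package vignette).
#'
#' @param observed One-row data frame from [effect_from_summary()].
#' @param projections Numeric vector of projected effects (possibly empty).
#' @return One-row data frame with `beta`, `se`, `z`, `source = "conditional"`.
#' @export
conditional_effect <- function(observed, projections = numeric()) {
  beta <- observed$beta - sum(projections)
  data.frame(beta = beta, se = observed$se, z = beta / observed$se,
             source = "conditional", stringsAsFactors = FALSE)
}

#' Rescale standardized effects to trait units
#'
#' Effects estimated from summary statistics are on the
#' standardized-phenotype scale (trait SD = 1). To compare against
#' effects published in natural units (e.g. cm of height), multiply
#' beta and se by the phenotype standard deviation.
#'
#' @param signals Signal or effect table with `beta` and `se` columns.
#' @param trait_sd Phenotype standard deviation in natural units.
#' @return The table with `beta` and `se` rescaled.
#' @export
rescale_effects <- function(signals, trait_sd) {
  if (trait_sd <= 0) ah_domain_error("trait_sd must be positive")
  signals$beta <- signals$beta * trait_sd
  signals$se <- signals$se * trait_sd
  signals
}

#' Two-sided p-value of an effect estimate
#'
#' p = 2 (1 - Phi(|beta/se|)), the normal two-sided tail probability.
#' Inverse of [z_from_p()] on the marginal path.
#'
#' @param estimate Data frame with `beta` and `se` (or `beta` given
#'   directly with `se`).
#' @param se Standard error, when `estimate` is a bare numeric beta.
#' @return Two-sided p-value(s).
#' @export
conditional_p <- function(estimate, se = NULL) {
  if (is.data.frame(estimate)) {
    beta <- estimate$beta; se <- estimate$se
  } else beta <- estimate
  if (any(se <= 0)) ah_domain_error("se must be positive")
  2 * stats::pnorm(-abs(beta / se))
}
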