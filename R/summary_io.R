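#' Column-mapping presets for summary-statistics dialects
#'
#' A column map is a named character vector assigning file column names to
#' the roles `marker`, `effect_allele`, `other_allele`, `p`, `direction`,
#' `n`, and optionally `freq`. The `"giant"` preset matches the GIANT
#' consortium stage-1 height file layout (MarkerName / Allele1 / Allele2 /
#' a +/- direction column / p / N), which carries no chromosome, position
#' or frequency columns.
#'
#' @param preset Preset name; currently `"giant"`.
#' @return Named character vector mapping roles to column names.
#' @export
#' @examples
#' column_preset("giant")
column_preset <- function(preset = "giant") {
  switch(preset,
    giant = c(marker = "MarkerName", effect_allele = "Allele1",
              other_allele = "Allele2", direction = "Direction",
              p = "p", n = "N"),
    ah_config_error(sprintf("unknown column preset '%s'", preset))
  )
}

parse_direction <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  out[x %in% c("+", "+1", "1")] <- 1
  out[x %in% c("-", "−", "-1")] <- -1
  suppress <- is.na(out) & grepl("^[-+]?[0-9.eE]+$", x)
  if (any(suppress)) out[suppress] <- sign(as.numeric(x[suppress]))
  out[out == 0] <- NA_real_
  out
}

#' Read GWAS summary statistics
#'
#' Reads a whitespace- or tab-delimited summary file with a header line,
#' optionally gzip-compressed, and returns one record per parseable row.
#' Rows with a missing or out-of-domain mandatory field (p outside (0,1],
#' unparseable direction, N < 1, non-ACGT or identical alleles) are skipped
#' and counted. Two-sided p-values smaller than the smallest positive
#' double are clamped to it with a warning so that extreme associations
#' (e.g. 1e-300) survive.
#'
#' @param path Path to the summary file.
#' @param column_map Named character vector mapping roles to column names;
#'   see [column_preset()]. Roles `marker`, `effect_allele`, `other_allele`,
#'   `p`, `direction`, `n` are mandatory; `freq` is optional.
#' @return A data frame with columns `marker_id`, `chrom`, `pos` (NA until
#'   harmonized), `effect_allele`, `other_allele`, `p`, `direction`,
#'   `n_obs`, `freq`, carrying attribute `n_skipped`.
#' @seealso [harmonize()] to align records with a haplotype panel.
#' @export
read_summary <- function(path, column_map = column_preset("giant")) {
  if (!file.exists(path)) ah_input_error(sprintf("summary file not found: %s", path))
  con <- open_text(path)
  on.exit(close(con))
  raw <- utils::read.table(con, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "", check.names = FALSE)
  if (nrow(raw) == 0L) ah_input_error("summary file has a header but no data rows")

  required <- c("marker", "effect_allele", "other_allele", "p", "direction", "n")
  for (role in required) {
    if (!role %in% names(column_map))
      ah_config_error(sprintf("column_map lacks mandatory role '%s'", role))
    if (!column_map[[role]] %in% names(raw))
      ah_config_error(sprintf("column '%s' (role '%s') absent from file",
                              column_map[[role]], role))
  }

  rec <- data.frame(
    marker_id = as.character(raw[[column_map[["marker"]]]]),
    chrom = NA_character_,
    pos = NA_integer_,
    effect_allele = toupper(as.character(raw[[column_map[["effect_allele"]]]])),
    other_allele = toupper(as.character(raw[[column_map[["other_allele"]]]])),
    p = suppressWarnings(as.numeric(raw[[column_map[["p"]]]])),
    direction = parse_direction(raw[[column_map[["direction"]]]]),
    n_obs = suppressWarnings(as.numeric(raw[[column_map[["n"]]]])),
    freq = NA_real_,
    stringsAsFactors = FALSE
  )
  if ("freq" %in% names(column_map) && column_map[["freq"]] %in% names(raw))
    rec$freq <- suppressWarnings(as.numeric(raw[[column_map[["freq"]]]]))

  tiny <- !is.na(rec$p) & rec$p > 0 & rec$p < .Machine$double.xmin
  if (any(tiny)) {
    rec$p[tiny] <- .Machine$double.xmin
    warning(sprintf("%d p-value(s) below the smallest positive double were clamped",
                    sum(tiny)))
  }

  bases <- c("A", "C", "G", "T")
  ok <- !is.na(rec$marker_id) & nzchar(rec$marker_id) &
    rec$effect_allele %in% bases & rec$other_allele %in% bases &
    rec$effect_allele != rec$other_allele &
    !is.na(rec$p) & rec$p > 0 & rec$p <= 1 &
    !is.na(rec$direction) &
    !is.na(rec$n_obs) & rec$n_obs >= 1
  out <- rec[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Harmonize summary records against a haplotype panel
#'
#' Restricts records to markers present in the panel, fills chromosome,
#' position and effect-allele frequency from the panel, and re-orients each
#' record so that its effect allele is the panel's coded allele: when the
#' summary alleles are swapped relative to the panel the direction of
#' effect is negated; strand-complement matches are resolved by
#' complementing both alleles (with a further flip if also swapped).
#' Strand-ambiguous SNPs (A/T, C/G) are dropped by default because their
#' orientation cannot be verified from a direction-only summary file;
#' records whose alleles cannot be reconciled with the panel are dropped.
#'
#' @param records Data frame from [read_summary()].
#' @param panel A [HaplotypePanel][load_panel].
#' @param drop_ambiguous Drop A/T and C/G SNPs (default TRUE).
#' @return List with `records` (harmonized data frame; every effect allele
#'   equals the panel's coded allele) and `report`, a named integer vector
#'   with counts `matched`, `flipped`, `complemented`, `dropped`,
#'   `unmatched` partitioning the input rows.
#' @export
harmonize <- function(records, panel, drop_ambiguous = TRUE) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  v <- panel$variants
  idx <- match(records$marker_id, v$marker_id)
  unmatched <- is.na(idx)
  if (all(unmatched)) ah_input_error("no summary marker overlaps the panel")

  r <- records
  a1 <- v$a1[idx]; a0 <- v$a0[idx]           # a1 = coded allele
  ce <- complement_allele(r$effect_allele)
  co <- complement_allele(r$other_allele)

  direct  <- !unmatched & r$effect_allele == a1 & r$other_allele == a0
  swapped <- !unmatched & r$effect_allele == a0 & r$other_allele == a1
  comp    <- !unmatched & !direct & !swapped & ce == a1 & co == a0
  compsw  <- !unmatched & !direct & !swapped & ce == a0 & co == a1
  ambig   <- !unmatched & is_ambiguous_pair(r$effect_allele, r$other_allele)
  if (drop_ambiguous) {
    direct <- direct & !ambig; swapped <- swapped & !ambig
    comp <- comp & !ambig; compsw <- compsw & !ambig
  } else {
    # without strand information an ambiguous pair is taken at face value
    comp <- comp & !ambig; compsw <- compsw & !ambig
  }
  keep <- direct | swapped | comp | compsw
  dropped <- !unmatched & !keep

  r$direction[swapped | compsw] <- -r$direction[swapped | compsw]
  r$effect_allele[keep] <- a1[keep]
  r$other_allele[keep] <- a0[keep]
  r$chrom[keep] <- v$chrom[idx][keep]
  r$pos[keep] <- v$pos[idx][keep]
  r$freq[keep] <- v$freq[idx][keep]

  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- c(matched = sum(direct), flipped = sum(swapped),
              complemented = sum(comp | compsw),
              dropped = sum(dropped), unmatched = sum(unmatched))
  list(records = out, report = report)
}
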