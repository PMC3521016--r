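#' Run the full summary-to-signals pipeline
#'
#' Reads and harmonizes summary statistics against a haplotype panel,
#' clusters significant SNPs into loci, extracts conditional signals per
#' locus, and — when genotypes and phenotypes are supplied — builds
#' weighted genetic scores and reports variance explained by rank-nested
#' signal sets. All tabular artifacts carry a provenance comment line
#' with the config hash; a JSON manifest records inputs, checksums,
#' parameters and per-stage record counts.
#'
#' @param config Named list: `summary`, `panel` (paths), `outdir`;
#'   optional `panel_format` ("vcf"/"hapmap_phased"), `region`,
#'   `genotypes`, `genotypes_format` ("tsv"/"vcf"), `pheno`, `alpha`
#'   (default 5e-8), `window_kb` (NULL = [default_window()]), `max_rank`
#'   (4), `bonferroni_base` (0.05), `preset` ("giant"), `drop_ambiguous`
#'   (TRUE).
#' @return Invisibly, a list with the computed objects and the manifest.
#' @export
run_pipeline <- function(config) {
  for (key in c("summary", "panel", "outdir"))
    if (is.null(config[[key]]))
      ah_config_error(sprintf("config field '%s' is required", key))
  alpha <- config$alpha %||% 5e-8
  if (alpha <= 0 || alpha >= 1) ah_config_error("alpha must lie in (0,1)")
  max_rank <- config$max_rank %||% 4
  if (max_rank < 1) ah_config_error("max_rank must be >= 1")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  cfg_hash <- substr(digest_config(config[setdiff(names(config), "outdir")]), 1, 12)
  log <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log <<- c(log, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      e$message <- sprintf("[stage %s] %s", name, conditionMessage(e))
      stop(e)
    })
  }

  panel <- stage("panel", load_panel(config$panel,
                                     format = config$panel_format %||% "vcf",
                                     region = config$region))
  note("panel: %d variants, %d haplotypes, %d monomorphic dropped",
       nrow(panel$variants), nrow(panel$haplotypes), panel$n_dropped_mono)

  records <- stage("summary", read_summary(config$summary,
                                           column_preset(config$preset %||% "giant")))
  note("summary: %d records read, %d rows skipped",
       nrow(records), attr(records, "n_skipped"))

  harm <- stage("harmonize", harmonize(records, panel,
                                       drop_ambiguous = config$drop_ambiguous %||% TRUE))
  note("harmonize: %s", paste(names(harm$report), harm$report,
                              sep = "=", collapse = " "))

  loci <- stage("cluster", cluster_loci(harm$records, alpha = alpha,
                                        window_kb = config$window_kb))
  note("cluster: %d loci at alpha=%g", length(loci), alpha)

  dis <- stage("dissect", dissect_all(loci, panel, max_rank = max_rank,
                                      bonferroni_base = config$bonferroni_base %||% 0.05))
  note("dissect: %d signals, %d/%d loci with secondary",
       if (is.null(dis$signals)) 0L else nrow(dis$signals),
       dis$summary$n_secondary, dis$summary$n_loci)

  provenance <- sprintf("alleleHet %s config=%s",
                        as.character(utils::packageVersion("alleleHet")), cfg_hash)
  paths <- list()
  rep_df <- data.frame(category = names(harm$report),
                       count = as.integer(harm$report))
  paths$harmonization_report <- write_tsv(rep_df,
    file.path(outdir, "harmonization_report.tsv"), provenance)
  if (length(loci)) {
    paths$loci <- write_tsv(loci_table(loci), file.path(outdir, "loci.tsv"),
                            provenance)
    paths$loci_bed <- write_loci_bed(loci, file.path(outdir, "loci.bed"))
  }
  if (!is.null(dis$signals))
    paths$signals <- write_tsv(dis$signals, file.path(outdir, "signals.tsv"),
                               provenance)
  het <- as.list(dis$summary)
  jsonlite::write_json(het, file.path(outdir, "het_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$het_summary <- file.path(outdir, "het_summary.json")

  report <- NULL
  if (!is.null(config$genotypes) && !is.null(config$pheno) &&
      !is.null(dis$signals)) {
    geno <- stage("genotypes", read_genotypes(config$genotypes,
                                              format = config$genotypes_format %||% "tsv"))
    resid <- stage("phenotype", adjust_phenotype(
      utils::read.table(config$pheno, header = TRUE, stringsAsFactors = FALSE)))
    report <- stage("score", score_report(dis$signals, geno, resid,
                                          max_ranks = seq_len(min(max_rank, 3))))
    note("score: %d samples, r2(all, primaries)=%.4f",
         report$n[report$stratum == "all"][1],
         report$r2[report$stratum == "all"][1])
    paths$score_report <- write_tsv(report,
      file.path(outdir, "score_report.tsv"), provenance)
  }

  paths$manifest <- file.path(outdir, "manifest.json")
  inputs <- Filter(Negate(is.null),
                   config[c("summary", "panel", "genotypes", "pheno")])
  manifest <- list(
    package = "alleleHet",
    version = as.character(utils::packageVersion("alleleHet")),
    config = config[setdiff(names(config), "outdir")],
    config_hash = cfg_hash,
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    artifacts = lapply(paths, basename),
    log = log)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(panel = panel, records = harm$records, loci = loci,
                 signals = dis$signals, het_summary = dis$summary,
                 score_report = report, paths = paths))
}

# Stable hash of the run configuration (order-independent).
digest_config <- function(config) {
  config <- config[order(names(config))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
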