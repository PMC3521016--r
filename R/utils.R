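# Classed conditions so callers (and the CLI) can map failures to exit codes.

ah_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ah_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ah_config_error <- function(msg, ...) ah_error("ah_config_error", msg, ...)
ah_input_error  <- function(msg, ...) ah_error("ah_input_error", msg, ...)
ah_domain_error <- function(msg, ...) ah_error("ah_domain_error", msg, ...)
ah_numeric_error <- function(msg, ...) ah_error("ah_numeric_error", msg, ...)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# DNA complement for strand resolution; anything non-ACGT maps to NA.
complement_allele <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A")[toupper(x)]
}

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Open a text connection, transparently handling gzip by file extension.
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

# Evaluate expr under a temporary RNG seed, restoring global state after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
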