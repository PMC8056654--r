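# Internal helpers shared across the pipeline stages.

#' Classed stop with a dignet_* condition class
#' @noRd
dn_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "dignet_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

dn_warn <- function(msg) warning(msg, call. = FALSE)

#' Derive a per-stage seed from a root seed
#'
#' All stochastic stages draw their seed from one root seed so that a full
#' pipeline run is bitwise reproducible while stages stay decoupled.
#' Kept below 2^31 so it is always a valid R integer.
#'
#' @param seed root integer seed.
#' @param stage character stage tag.
#' @return an integer seed.
#' @export
fan_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}

# Simple deterministic checksum of a config list (no digest dependency).
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Header comment lines stamped on every output file.
output_header <- function(seed = NULL, cfg_hash = NULL) {
  c(
    sprintf("# dignet %s", as.character(utils::packageVersion("dignet"))),
    if (!is.null(cfg_hash)) sprintf("# config_hash: %s", cfg_hash),
    if (!is.null(seed)) sprintf("# seed: %s", format(seed))
  )
}

#' Write a TSV with a commented provenance header
#' @noRd
write_tsv <- function(df, path, seed = NULL, cfg_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, cfg_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by this package (comment lines allowed)
#' @noRd
read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
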