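# Readers and writers for the plain-text interchange formats used by the
# pipeline: GCT v1.2 matrices, GMT gene-set collections, report tables,
# id maps and fingerprint tables.  All formats are line-oriented text so
# fixtures can be generated and inspected by hand.

#' Read an expression matrix (GCT v1.2 or plain TSV)
#'
#' GCT v1.2: line 1 `#1.2`, line 2 `<nrow>\t<ncol>`, line 3 the header
#' (`Name`, `Description`, profile ids), then one row per gene.  A plain
#' TSV with the gene id in the first column is accepted as well.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows (rownames), profiles in columns.
#' @export
read_gct <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#1.2")) {
    dims <- scan(path, what = integer(), skip = 1L, nlines = 1L, quiet = TRUE)
    tab <- utils::read.delim(path, skip = 2L, stringsAsFactors = FALSE,
                             check.names = FALSE)
    m <- as.matrix(tab[, -(1:2), drop = FALSE])
    rownames(m) <- tab[[1L]]
    if (nrow(m) != dims[1L] || ncol(m) != dims[2L])
      dn_stop("GCT dimension line disagrees with table body", "dignet_parse_error")
  } else {
    tab <- read_tsv(path)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab[[1L]]
  }
  storage.mode(m) <- "double"
  if (anyNA(m))
    dn_stop("expression matrix contains missing values; dense input required",
            "dignet_parse_error")
  m
}

#' Write a matrix as GCT v1.2
#' @param m numeric matrix with rownames (genes) and colnames (profiles).
#' @param path destination path.
#' @export
write_gct <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  tab <- data.frame(Name = rownames(m), Description = rownames(m),
                    m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: per line `term<TAB>description<TAB>gene1<TAB>...`.
#' @param universe optional background gene vector; sets are intersected
#'   with it when given.
#' @return a `gene_set_collection`: list with `sets` (named list of gene
#'   vectors), `names` (term id -> description) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    dn_stop("duplicate term ids in GMT", "dignet_parse_error")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  descr <- vapply(parts, `[[`, "", 2L)
  names(descr) <- ids
  gene_set_collection(sets, descr, universe)
}

#' Write a GMT gene-set collection
#' @param collection a `gene_set_collection` (or named list of gene vectors).
#' @param path destination path.
#' @export
write_gmt <- function(collection, path) {
  if (inherits(collection, "gene_set_collection")) {
    sets <- collection$sets
    descr <- collection$names
  } else {
    sets <- collection
    descr <- stats::setNames(names(sets), names(sets))
  }
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descr[[id]], sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an adverse-event report table
#'
#' Expected columns: `report_id`, `drug`, `adr`, `source` (header required).
#' @param path TSV path.
#' @return an `ade_dataset` data frame.
#' @export
read_reports <- function(path) {
  tab <- read_tsv(path)
  ade_dataset(tab)
}

#' Write an adverse-event report table
#' @param dataset an `ade_dataset`.
#' @param path destination path.
#' @param seed optional seed recorded in the file header.
#' @export
write_reports <- function(dataset, path, seed = NULL) {
  write_tsv(as.data.frame(dataset), path, seed = seed)
}

#' Read a two-column synonym map (`raw_term`, `preferred_term`)
#' @param path TSV path.
#' @return named character vector raw -> preferred.
#' @export
read_synonyms <- function(path) {
  tab <- read_tsv(path)
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Read a drug-to-ATC map (`drug`, `atc_code`; one row per code)
#' @param path TSV path.
#' @return data.frame with columns `drug` and `atc_code`.
#' @export
read_atc_map <- function(path) {
  tab <- read_tsv(path)
  names(tab)[1:2] <- c("drug", "atc_code")
  tab
}

#' Read profile metadata
#'
#' Columns: `profile_id, drug, cell_type, dose, time, n_replicates, p_value`.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_profile_meta <- function(path) {
  tab <- read_tsv(path)
  need <- c("profile_id", "drug", "cell_type", "n_replicates", "p_value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    dn_stop(paste0("profile metadata missing column(s): ",
                   paste(miss, collapse = ", ")), "dignet_schema_error")
  tab
}

#' Read binary fingerprints (`drug`, `bits` as a 0/1 string)
#' @param path TSV path.
#' @param hex logical; bits encoded as hexadecimal instead of 0/1.
#' @return integer matrix, one row per drug, one column per bit.
#' @export
read_fingerprints <- function(path, hex = FALSE) {
  tab <- read_tsv(path, colClasses = "character")
  bits <- as.character(tab[[2L]])
  if (hex) {
    bits <- vapply(bits, function(h) {
      paste(vapply(strsplit(h, "")[[1]], function(ch) {
        paste(rev(as.integer(intToBits(strtoi(ch, 16L))[1:4])), collapse = "")
      }, ""), collapse = "")
    }, "")
  }
  if (length(unique(nchar(bits))) != 1L)
    dn_stop("fingerprints have unequal lengths", "dignet_parse_error")
  m <- do.call(rbind, lapply(strsplit(bits, ""), as.integer))
  rownames(m) <- as.character(tab[[1L]])
  m
}

#' Write binary fingerprints as TSV
#' @param fp 0/1 matrix with drug rownames.
#' @param path destination path.
#' @export
write_fingerprints <- function(fp, path) {
  df <- data.frame(drug = rownames(fp),
                   bits = apply(fp, 1L, paste, collapse = ""),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
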