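# Expression-profile preparation: representative-profile selection,
# differential-gene election, and the site-of-action tissue-propensity
# contrast.

#' Construct a profile set
#'
#' Couples a genes-by-profiles perturbation matrix (signed, unitless
#' differential-expression coefficients) with per-profile metadata.
#'
#' @param matrix numeric matrix, genes in rows (unique rownames),
#'   profiles in columns.
#' @param meta data.frame with one row per column of `matrix`, columns
#'   `profile_id, drug, cell_type, n_replicates, p_value` (plus any
#'   extras such as dose and time).
#' @return a `profile_set` (list with `matrix` and `meta`).
#' @export
profile_set <- function(matrix, meta) {
  need <- c("profile_id", "drug", "cell_type", "n_replicates", "p_value")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    dn_stop(paste0("profile metadata missing column(s): ",
                   paste(miss, collapse = ", ")), "dignet_schema_error")
  if (nrow(meta) != ncol(matrix))
    dn_stop("metadata rows must match matrix columns 1:1",
            "dignet_schema_error")
  if (anyDuplicated(rownames(matrix)))
    dn_stop("gene ids must be unique", "dignet_schema_error")
  if (anyNA(matrix))
    dn_stop("perturbation matrix contains missing values",
            "dignet_schema_error")
  colnames(matrix) <- meta$profile_id
  structure(list(matrix = matrix, meta = meta), class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %d genes x %d profiles (%d drugs, %d cell types)\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$meta$drug)),
              length(unique(x$meta$cell_type))))
  invisible(x)
}

subset_profiles <- function(ps, keep) {
  profile_set(ps$matrix[, keep, drop = FALSE],
              ps$meta[keep, , drop = FALSE])
}

#' Select representative drug-perturbation profiles
#'
#' Drops profiles without biological replicates (`n_replicates < 2`),
#' then keeps, per drug (or per drug and cell type), the most perturbed
#' profile: minimum perturbation p-value subject to `p < p_max`.  Drugs
#' with no qualifying profile are dropped and reported.
#'
#' @param profiles a [profile_set()].
#' @param p_max perturbation p-value ceiling (default 0.01).
#' @param per `"drug_cell"` to pick one representative per drug and
#'   cell type (tissue-contrast path) or `"drug"` for one global
#'   representative per drug (co-expression path).
#' @param quiet suppress the dropped-drug message.
#' @return a filtered [profile_set()].
#' @export
select_representative_profiles <- function(profiles, p_max = 0.01,
                                           per = c("drug_cell", "drug"),
                                           quiet = FALSE) {
  per <- match.arg(per)
  meta <- profiles$meta
  ok <- meta$n_replicates >= 2 & meta$p_value < p_max
  key <- if (per == "drug") meta$drug else paste(meta$drug, meta$cell_type,
                                                 sep = "\r")
  # deterministic argmin: order by p then profile_id, keep first per key
  ord <- order(key, meta$p_value, meta$profile_id)
  ord <- ord[ok[ord]]
  keep <- ord[!duplicated(key[ord])]
  dropped <- setdiff(unique(meta$drug), unique(meta$drug[keep]))
  if (length(dropped) && !quiet)
    message(sprintf("select_representative_profiles: dropped %d drug(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  subset_profiles(profiles, sort(keep))
}

#' Elect differentially expressed genes per profile
#'
#' Per profile the `n_top` genes of largest absolute perturbation; ties
#' are broken by lexicographic gene id so the election is deterministic.
#'
#' @param profiles a [profile_set()].
#' @param n_top genes per profile (default 100).
#' @return named list (one character vector of gene ids per profile),
#'   class `deg_sets`.
#' @export
select_degs <- function(profiles, n_top = 100L) {
  stopifnot(n_top >= 1)
  m <- profiles$matrix
  if (n_top > nrow(m)) {
    dn_warn(sprintf("n_top (%d) exceeds gene count (%d); truncated",
                    n_top, nrow(m)))
    n_top <- nrow(m)
  }
  genes <- rownames(m)
  lex <- xtfrm(factor(genes, levels = sort(genes, method = "radix")))
  out <- lapply(seq_len(ncol(m)), function(j) {
    v <- abs(m[, j])
    ord <- order(-v, lex)             # lexicographic tie-break
    genes[ord[seq_len(n_top)]]
  })
  names(out) <- colnames(m)
  structure(out, class = "deg_sets")
}

#' Site-of-action tissue-propensity contrast
#'
#' For every profile the mean (absolute, by default) perturbation over
#' its DEGs is the profile's "average perturbation".  Within each cell
#' type, profiles split into a site-of-action group (the drug's ATC
#' first letters include the cell's organ letter) versus the rest, and
#' a one-sided Wilcoxon rank-sum test asks whether the SOA group is
#' more perturbed.
#'
#' @param profiles a [profile_set()].
#' @param degs [select_degs()] output for the same profiles.
#' @param atc_map data.frame `drug`, `atc_code`.
#' @param cell_organ_map data.frame `cell_type`, `organ_letter`; every
#'   cell type must map to exactly one organ.
#' @param absolute use `|perturbation|` (default) or signed values.
#' @return data.frame, one row per cell type: group sizes, group mean
#'   average-perturbations and one-sided p.
#' @export
tissue_propensity <- function(profiles, degs, atc_map, cell_organ_map,
                              absolute = TRUE) {
  meta <- profiles$meta
  org <- cell_organ_map
  if (anyDuplicated(org$cell_type))
    dn_stop("a cell type maps to more than one organ", "dignet_mapping_error")
  organ <- stats::setNames(as.character(org$organ_letter),
                           as.character(org$cell_type))
  unmapped <- setdiff(unique(meta$cell_type), names(organ))
  if (length(unmapped))
    dn_stop(paste0("unmapped cell type(s): ", paste(unmapped, collapse = ", ")),
            "dignet_mapping_error")
  codes <- split(as.character(atc_map$atc_code), as.character(atc_map$drug))
  avg <- vapply(seq_len(nrow(meta)), function(j) {
    v <- profiles$matrix[degs[[meta$profile_id[j]]], j]
    mean(if (absolute) abs(v) else v)
  }, 0)
  is_soa <- vapply(seq_len(nrow(meta)), function(j) {
    any(startsWith(codes[[meta$drug[j]]] %||% character(),
                   organ[[meta$cell_type[j]]]))
  }, TRUE)
  rows <- lapply(unique(meta$cell_type), function(ct) {
    sel <- meta$cell_type == ct
    x <- avg[sel & is_soa]; y <- avg[sel & !is_soa]
    data.frame(cell_type = ct, organ = organ[[ct]],
               n_soa = length(x), n_other = length(y),
               mean_soa = if (length(x)) mean(x) else NA_real_,
               mean_other = if (length(y)) mean(y) else NA_real_,
               p = if (length(x) && length(y))
                 rank_sum_p(x, y, "greater") else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
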