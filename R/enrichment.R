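# Gene-set over-representation by one-sided Fisher exact test with
# Benjamini-Hochberg FDR, and target-module selection by required terms.

#' Construct a gene-set collection
#'
#' @param sets named list of gene id vectors (term id -> genes).
#' @param names optional named character vector term id -> description.
#' @param universe optional background gene vector; sets are restricted
#'   to it when given.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, names = NULL, universe = NULL) {
  if (anyDuplicated(base::names(sets)))
    dn_stop("term ids must be unique", "dignet_schema_error")
  if (is.null(names))
    names <- stats::setNames(base::names(sets), base::names(sets))
  if (!is.null(universe)) {
    universe <- unique(universe)
    sets <- lapply(sets, intersect, universe)
  }
  structure(list(sets = sets, names = names, universe = universe),
            class = "gene_set_collection")
}

#' Gene-set over-representation analysis
#'
#' One-sided Fisher exact test per term: the hypergeometric upper tail
#' `P(X >= k)` for overlap `k` between the query (size `n`) and the
#' term's genes (size `K`) in a universe of size `N`, with
#' Benjamini-Hochberg adjustment across all tested terms.
#'
#' @param genes query gene vector; genes outside the universe are
#'   dropped with a warning.
#' @param collection a [gene_set_collection()]; its `universe` must be
#'   set or supplied here.
#' @param universe optional background override.
#' @return data.frame sorted by p: `term_id, term_name, k, K, n, N, p, q`.
#' @export
enrich <- function(genes, collection, universe = NULL) {
  universe <- unique(universe %||% collection$universe)
  if (is.null(universe))
    dn_stop("no background universe supplied", "dignet_schema_error")
  sets <- lapply(collection$sets, intersect, universe)
  drop <- setdiff(genes, universe)
  if (length(drop))
    dn_warn(sprintf("enrich: %d query gene(s) outside the universe dropped",
                    length(drop)))
  q <- unique(intersect(genes, universe))
  if (!length(q))
    dn_stop("empty query after restriction to the universe",
            "dignet_empty_input")
  n <- length(q); n_univ <- length(universe)
  k <- vapply(sets, function(s) length(intersect(s, q)), 0L)
  kk <- lengths(sets)
  p <- stats::phyper(k - 1L, kk, n_univ - kk, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(sets),
                    term_name = unname(collection$names[names(sets)]),
                    k = k, K = kk, n = n, N = n_univ,
                    p = p, q = stats::p.adjust(p, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' Select target modules by required enrichment terms
#'
#' Runs [enrich()] on every module's gene list and returns the modules
#' in which every required term is enriched at `q <= q_max`, ordered by
#' decreasing module size.
#'
#' @param module_set a `module_set` (labels used).
#' @param collection a [gene_set_collection()].
#' @param required_terms term ids that must all be enriched; empty
#'   vector returns all modules.
#' @param q_max FDR ceiling (default 0.05).
#' @param universe background genes (default: all labelled genes).
#' @return integer vector of qualifying module ids.
#' @export
select_target_module <- function(module_set, collection,
                                 required_terms, q_max = 0.05,
                                 universe = names(module_set$labels)) {
  miss <- setdiff(required_terms, names(collection$sets))
  if (length(miss))
    dn_stop(paste0("required term(s) absent from collection: ",
                   paste(miss, collapse = ", ")), "dignet_lookup_error")
  mods <- sort(setdiff(unique(module_set$labels), 0L))
  sizes <- vapply(mods, function(m) sum(module_set$labels == m), 0L)
  mods <- mods[order(-sizes, mods)]
  ok <- vapply(mods, function(m) {
    tab <- enrich(module_genes(module_set, m), collection, universe)
    if (!length(required_terms)) return(TRUE)
    rows <- tab[match(required_terms, tab$term_id), ]
    all(rows$q <= q_max)
  }, TRUE)
  mods[ok]
}
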