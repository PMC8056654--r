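# Protein-protein interaction graph handling and hub-gene extraction by
# Maximal Clique Centrality (exact clique enumeration) and shortest-path
# betweenness.

#' Construct a scored PPI graph
#'
#' Undirected, simple (self-loops dropped with a warning, duplicate
#' edges collapsed keeping the maximum score), confidence scores in
#' `[0, 1000]`.
#'
#' @param edges data.frame `protein1, protein2, combined_score`.
#' @param nodes optional node universe (isolated nodes allowed).
#' @return a `ppi_graph` (list with `edges` and `nodes`).
#' @export
ppi_graph <- function(edges, nodes = NULL) {
  names(edges)[1:3] <- c("protein1", "protein2", "combined_score")
  edges$protein1 <- as.character(edges$protein1)
  edges$protein2 <- as.character(edges$protein2)
  edges$combined_score <- as.numeric(edges$combined_score)
  if (anyNA(edges$combined_score))
    dn_stop("non-numeric interaction score", "dignet_parse_error")
  if (any(edges$combined_score < 0 | edges$combined_score > 1000))
    dn_stop("scores must lie in [0, 1000]", "dignet_schema_error")
  loops <- edges$protein1 == edges$protein2
  if (any(loops)) {
    dn_warn(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$protein1, edges$protein2)
  b <- pmax(edges$protein1, edges$protein2)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -edges$combined_score)
  keep <- ord[!duplicated(key[ord])]
  edges <- data.frame(protein1 = a[keep], protein2 = b[keep],
                      combined_score = edges$combined_score[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$protein1, edges$protein2), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(nodes, edges$protein1, edges$protein2)))
  structure(list(edges = edges, nodes = nodes), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("protein1", "protein2")], directed = FALSE,
    vertices = data.frame(name = graph$nodes))
  g
}

#' Load a STRING-style interaction edge list
#'
#' Whitespace- or tab-separated `protein1 protein2 combined_score`; a
#' header line is tolerated.  Edges below `score_min` are discarded.
#'
#' @param path file path.
#' @param score_min minimum combined score kept (default 400).
#' @return a [ppi_graph()].
#' @export
load_edges <- function(path, score_min = 400) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    dn_stop(sprintf("malformed edge row at line %d", bad[1]),
            "dignet_parse_error")
  p1 <- vapply(parts, `[[`, "", 1L)
  p2 <- vapply(parts, `[[`, "", 2L)
  sc <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (is.na(sc[1]) && length(sc) >= 1L) {  # header line
    p1 <- p1[-1]; p2 <- p2[-1]; sc <- sc[-1]
  }
  if (anyNA(sc))
    dn_stop(sprintf("non-numeric score at line %d", which(is.na(sc))[1]),
            "dignet_parse_error")
  keep <- sc >= score_min
  ppi_graph(data.frame(protein1 = p1[keep], protein2 = p2[keep],
                       combined_score = sc[keep], stringsAsFactors = FALSE))
}

#' Restrict a PPI graph to a gene subset
#' @param graph a [ppi_graph()].
#' @param genes gene ids to keep.
#' @return the induced [ppi_graph()].
#' @export
induce_subgraph <- function(graph, genes) {
  keep <- graph$edges$protein1 %in% genes & graph$edges$protein2 %in% genes
  ppi_graph(graph$edges[keep, , drop = FALSE],
            nodes = intersect(graph$nodes, genes))
}

#' Maximal Clique Centrality
#'
#' `MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!`,
#' with maximal cliques (size >= 2) enumerated exactly (Bron-Kerbosch
#' with pivoting).  A node whose neighborhood induces no edges thereby
#' scores its degree (each incident edge is a maximal 2-clique);
#' isolated nodes score 0.
#'
#' @param graph a [ppi_graph()].
#' @param max_nodes guard on exact clique enumeration (default 2000).
#' @return data.frame `gene, mcc` (decreasing mcc).
#' @export
mcc_scores <- function(graph, max_nodes = 2000L) {
  if (length(graph$nodes) > max_nodes)
    dn_stop(sprintf(
      "graph has %d nodes (> %d); restrict to a subgraph for exact MCC",
      length(graph$nodes), max_nodes), "dignet_size_error")
  mcc <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges)) {
    g <- as_igraph(graph)
    cliques <- igraph::max_cliques(g, min = 2L)
    for (cl in cliques) {
      w <- factorial(length(cl) - 1L)
      nm <- igraph::V(g)$name[cl]
      mcc[nm] <- mcc[nm] + w
    }
  }
  out <- data.frame(gene = names(mcc), mcc = unname(mcc),
                    stringsAsFactors = FALSE)
  out[order(-out$mcc, out$gene), , drop = FALSE]
}

#' Shortest-path betweenness centrality
#'
#' Unnormalized and exact; each unordered pair of distinct endpoints is
#' counted once, split over the pair's shortest paths.  Scores are
#' ignored (topological shortest paths).
#'
#' @param graph a [ppi_graph()].
#' @return data.frame `gene, betweenness` (decreasing).
#' @export
betweenness_scores <- function(graph) {
  g <- as_igraph(graph)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  out <- data.frame(gene = igraph::V(g)$name, betweenness = unname(b),
                    stringsAsFactors = FALSE)
  out[order(-out$betweenness, out$gene), , drop = FALSE]
}

#' Select hub genes
#'
#' Genes with `MCC >= mcc_min` and `betweenness > betweenness_gt`,
#' sorted by decreasing MCC then gene id.
#'
#' @param mcc [mcc_scores()] output.
#' @param betweenness [betweenness_scores()] output.
#' @param mcc_min MCC floor (default 5).
#' @param betweenness_gt strict betweenness floor (default 0).
#' @return data.frame `gene, mcc, betweenness, is_hub` (all scored
#'   genes; hubs first).
#' @export
select_hubs <- function(mcc, betweenness, mcc_min = 5, betweenness_gt = 0) {
  tab <- merge(mcc, betweenness, by = "gene")
  tab$is_hub <- tab$mcc >= mcc_min & tab$betweenness > betweenness_gt
  tab[order(-tab$is_hub, -tab$mcc, tab$gene), , drop = FALSE]
}

#' Diagnostic: interaction-count enrichment against a binomial null
#'
#' Compares the observed edge count with a binomial null in which every
#' node pair is independently connected at `background_density`.  This
#' mirrors the "PPI enrichment p" gates of interaction databases as a
#' warning-only diagnostic (their exact null models are service-side).
#'
#' @param graph a [ppi_graph()].
#' @param background_density expected background edge probability.
#' @param p_max warn when the upper-tail p exceeds this (default 0.01).
#' @return invisible list `(n_edges, n_pairs, p)`.
#' @export
ppi_enrichment_check <- function(graph, background_density, p_max = 0.01) {
  n <- length(graph$nodes)
  n_pairs <- n * (n - 1) / 2
  m <- nrow(graph$edges)
  p <- stats::pbinom(m - 1, n_pairs, background_density, lower.tail = FALSE)
  if (p >= p_max)
    dn_warn(sprintf(
      "PPI enrichment diagnostic: %d edges not enriched over background (p = %.3g)",
      m, p))
  invisible(list(n_edges = m, n_pairs = n_pairs, p = p))
}
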