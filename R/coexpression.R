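# From-scratch weighted co-expression core: soft-threshold adjacency,
# scale-free fit, topological overlap, average-linkage clustering with a
# static tree cut, module eigengenes, eigengene-dissimilarity merging and
# module membership (kME).

#' Soft-threshold adjacency matrix
#'
#' Unsigned network: `a_ij = |pearson(g_i, g_j)|^beta`.  The diagonal is
#' zero (it is excluded from all connectivity sums).  Constant-variance
#' genes get correlation 0 with a warning.
#'
#' @param matrix genes-by-profiles numeric matrix (>= 3 profiles).
#' @param beta soft power (>= 1; default 5).
#' @return an `adjacency` matrix with attribute `beta`.
#' @export
soft_adjacency <- function(matrix, beta = 5) {
  if (ncol(matrix) < 3)
    dn_stop("need >= 3 profiles for co-expression", "dignet_insufficient_data")
  if (beta < 1) dn_stop("beta must be >= 1", "dignet_parameter_error")
  sds <- apply(matrix, 1L, stats::sd)
  if (any(sds == 0))
    dn_warn(sprintf("%d constant gene(s) assigned correlation 0",
                    sum(sds == 0)))
  cc <- suppressWarnings(stats::cor(t(matrix)))
  cc[!is.finite(cc)] <- 0
  a <- abs(cc)^beta
  diag(a) <- 0
  structure(a, beta = beta, class = c("adjacency", "matrix", "array"))
}

#' Scale-free topology fit
#'
#' Bins the connectivity `k_i = sum_j a_ij` into `n_bins` equal-width
#' bins and returns the R-squared of the least-squares line of
#' log10(mean bin frequency) on log10(mean bin connectivity) over the
#' occupied bins.
#'
#' @param adjacency an [soft_adjacency()] matrix.
#' @param n_bins number of connectivity bins (default 10).
#' @return R-squared in `[0, 1]`.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10L) {
  k <- rowSums(adjacency)
  if (diff(range(k)) == 0)
    dn_stop("all connectivities identical; scale-free fit undefined",
            "dignet_degenerate_error")
  bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  ok <- !is.na(mean_k) & mean_k > 0 & !is.na(freq)
  if (sum(ok) < 2)
    dn_stop("fewer than 2 occupied bins", "dignet_degenerate_error")
  x <- log10(mean_k[ok]); y <- log10(freq[ok])
  if (sum(ok) == 2) return(1.0)
  fit <- stats::lm.fit(cbind(1, x), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Topological overlap matrix
#'
#' Classic unsigned TOM:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
#' with `TOM_ii = 1`.  The clustering dissimilarity is `1 - TOM`.
#'
#' @param adjacency an [soft_adjacency()] matrix (zero diagonal).
#' @return TOM matrix with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- unclass(adjacency)
  attr(a, "beta") <- NULL
  l <- a %*% a                       # zero diagonal => u != i, j terms only
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules by average-linkage clustering
#'
#' Builds the average-linkage dendrogram of the dissimilarity and cuts
#' it statically at the given quantile of its merge heights (the
#' "tree" variant of dynamic tree cutting).  Branches smaller than
#' `min_module_size` are left unassigned (label 0); remaining modules
#' are numbered by decreasing size.
#'
#' @param dissimilarity square symmetric matrix with zero diagonal
#'   (typically `1 - TOM`).
#' @param min_module_size smallest branch kept as a module (default 30).
#' @param cut_height_quantile quantile of merge heights for the static
#'   cut (default 0.99).
#' @return a `module_set` with `labels` (named integer vector) and
#'   `dendrogram` (the hclust object); eigengenes are attached by
#'   [module_eigengenes()] / [merge_modules()].
#' @export
detect_modules <- function(dissimilarity, min_module_size = 30L,
                           cut_height_quantile = 0.99) {
  d <- as.matrix(dissimilarity)
  genes <- rownames(d) %||% sprintf("G%04d", seq_len(nrow(d)))
  if (nrow(d) < min_module_size) {
    dn_warn("fewer genes than min_module_size; all genes unassigned")
    return(module_set(stats::setNames(integer(length(genes)), genes), NULL))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # guard against floating non-monotone heights (ties in the input)
  hc$height <- cummax(hc$height)
  h <- stats::quantile(hc$height, cut_height_quantile, names = FALSE)
  raw <- stats::cutree(hc, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(genes))
  names(labels) <- genes
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]  # big first, stable
    for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
  }
  module_set(labels, hc)
}

#' Construct a module set
#' @param labels named integer vector gene -> module id (0 unassigned).
#' @param dendrogram optional hclust object.
#' @param eigengenes optional profiles-by-modules eigengene matrix.
#' @return a `module_set` list.
#' @export
module_set <- function(labels, dendrogram = NULL, eigengenes = NULL) {
  structure(list(labels = labels, dendrogram = dendrogram,
                 eigengenes = eigengenes), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$labels), 0L))
  cat(sprintf("<module_set> %d genes in %d modules (%d unassigned)\n",
              length(x$labels), n_mod, sum(x$labels == 0L)))
  invisible(x)
}

module_genes <- function(ms, m) names(ms$labels)[ms$labels == m]

#' Module eigengenes
#'
#' Per module: genes are standardized across profiles (mean 0, sd 1),
#' and the eigengene is the first right singular vector of the
#' standardized submatrix -- unit norm, sign-oriented so that its
#' correlation with the module's mean standardized profile is >= 0.
#' Zero-variance genes are dropped from their module with a warning.
#'
#' @param matrix genes-by-profiles matrix covering all labelled genes.
#' @param labels named integer vector gene -> module (0 ignored).
#' @return profiles-by-modules matrix; column `ME<m>` per module.
#' @export
module_eigengenes <- function(matrix, labels) {
  mods <- sort(setdiff(unique(labels), 0L))
  if (!length(mods)) dn_stop("no modules to summarize", "dignet_degenerate_error")
  me <- vapply(mods, function(m) {
    genes <- names(labels)[labels == m]
    sub <- matrix[genes, , drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    if (any(sds == 0)) {
      dn_warn(sprintf("module %d: dropped %d zero-variance gene(s)",
                      m, sum(sds == 0)))
      sub <- sub[sds > 0, , drop = FALSE]
    }
    if (nrow(sub) == 0)
      dn_stop(sprintf("module %d has no usable genes", m),
              "dignet_degenerate_error")
    z <- (sub - rowMeans(sub)) / apply(sub, 1L, stats::sd)
    v <- svd(z, nu = 0, nv = 1)$v[, 1]
    co <- suppressWarnings(stats::cor(v, colMeans(z)))
    if (!is.na(co) && co < 0) v <- -v
    v
  }, numeric(ncol(matrix)))
  colnames(me) <- paste0("ME", mods)
  rownames(me) <- colnames(matrix)
  me
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the smallest eigengene
#' dissimilarity `1 - pearson(ME_a, ME_b)` while that dissimilarity is
#' below `dissim_threshold`, recomputing eigengenes after every merge.
#' Final modules are renumbered by decreasing size and eigengenes are
#' attached.
#'
#' @param module_set a `module_set` with labels.
#' @param matrix the genes-by-profiles matrix the labels refer to.
#' @param dissim_threshold eigengene dissimilarity below which modules
#'   merge (default 0.3, i.e. correlation above 0.7).
#' @return the merged `module_set` (labels, dendrogram, eigengenes).
#' @export
merge_modules <- function(module_set, matrix, dissim_threshold = 0.3) {
  labels <- module_set$labels
  repeat {
    mods <- sort(setdiff(unique(labels), 0L))
    if (length(mods) < 2L) break
    me <- module_eigengenes(matrix, labels)
    d <- 1 - stats::cor(me)
    diag(d) <- Inf
    ij <- arrayInd(which.min(d), dim(d))
    if (d[ij] >= dissim_threshold) break
    from <- mods[max(ij)]; into <- mods[min(ij)]
    labels[labels == from] <- into
  }
  # renumber by decreasing size, stable on old id
  mods <- setdiff(unique(labels), 0L)
  sizes <- vapply(mods, function(m) sum(labels == m), 0L)
  mods <- mods[order(-sizes, mods)]
  new <- labels
  for (i in seq_along(mods)) new[labels == mods[i]] <- i
  me <- if (length(mods)) module_eigengenes(matrix, new) else NULL
  module_set(new, module_set$dendrogram, me)
}

#' Module membership (kME)
#'
#' `MM[g, m] = pearson(expression of gene g, eigengene of module m)`.
#' Zero-variance genes are excluded with a warning.
#'
#' @param matrix genes-by-profiles matrix.
#' @param module_set a `module_set` with eigengenes (see
#'   [merge_modules()]), or a profiles-by-modules eigengene matrix.
#' @return genes-by-modules correlation matrix in `[-1, 1]`.
#' @export
module_membership <- function(matrix, module_set) {
  me <- if (inherits(module_set, "module_set")) module_set$eigengenes
        else module_set
  if (is.null(me)) dn_stop("eigengenes not computed", "dignet_schema_error")
  sds <- apply(matrix, 1L, stats::sd)
  if (any(sds == 0))
    dn_warn(sprintf("%d zero-variance gene(s) excluded from kME",
                    sum(sds == 0)))
  keep <- sds > 0
  mm <- stats::cor(t(matrix[keep, , drop = FALSE]), me)
  mm
}

#' Select core genes of a module by membership
#'
#' @param membership [module_membership()] matrix.
#' @param module module id (column `ME<id>`).
#' @param mm_min strict membership threshold (default 0.95).
#' @param labels optional gene -> module labels; when given, selection
#'   is restricted to genes assigned to `module`.
#' @return character vector of core gene ids (decreasing membership).
#' @export
select_core_genes <- function(membership, module, mm_min = 0.95,
                              labels = NULL) {
  col <- paste0("ME", module)
  if (!col %in% colnames(membership))
    dn_stop(sprintf("module %s not in membership matrix", module),
            "dignet_lookup_error")
  v <- membership[, col]
  if (!is.null(labels))
    v <- v[names(v) %in% names(labels)[labels == module]]
  v <- v[v > mm_min]
  names(v)[order(-v, names(v))]
}
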