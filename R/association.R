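# Drug-group association statistics: the group-label permutation test of
# expression differences, per-gene logistic odds-ratio + AUC risk
# assessment, biomarker panel selection and the significance-strength
# correlation.

#' Group-label permutation test of expression differences
#'
#' Per gene the observed difference is `mean(group A) - mean(group B)`.
#' The null relabels the pooled drugs into groups of the same sizes:
#' exhaustive enumeration when `choose(|A|+|B|, |A|)` does not exceed
#' `n_perm`, otherwise `n_perm` uniform random relabelings (the same
#' relabelings applied to every gene, preserving the inter-gene
#' correlation of the null).  The one-sided left-tail p counts ties in
#' the tail with the finite-sample correction:
#' `p = (#\{d* <= d\} + 1) / (N + 1)`; the raw strict proportion
#' `#\{d* < d\}/N` is also reported.
#'
#' @param matrix genes-by-drugs matrix of (typically drug-level mean)
#'   expression values; columns named by drug.
#' @param group_A,group_B disjoint drug vectors (>= 2 each), both
#'   present among the columns.
#' @param n_perm requested permutations (default 10000).
#' @param seed integer seed (used only when sampling).
#' @return data.frame `gene, obs_diff, n_null, p, p_raw, exact`.
#' @export
permutation_test <- function(matrix, group_A, group_B, n_perm = 10000L,
                             seed = 1L) {
  if (length(intersect(group_A, group_B)))
    dn_stop("groups overlap", "dignet_grouping_error")
  if (length(group_A) < 2L || length(group_B) < 2L)
    dn_stop("each group needs >= 2 drugs", "dignet_grouping_error")
  miss <- setdiff(c(group_A, group_B), colnames(matrix))
  if (length(miss))
    dn_stop(paste0("drug(s) absent from matrix: ",
                   paste(miss, collapse = ", ")), "dignet_grouping_error")
  x <- matrix[, c(group_A, group_B), drop = FALSE]
  na <- length(group_A); nb <- length(group_B); n <- na + nb
  obs <- rowMeans(x[, seq_len(na), drop = FALSE]) -
    rowMeans(x[, na + seq_len(nb), drop = FALSE])
  exact <- choose(n, na) <= n_perm
  if (exact) {
    sel <- utils::combn(n, na)
    w <- matrix(-1 / nb, n, ncol(sel))
    for (j in seq_len(ncol(sel))) w[sel[, j], j] <- 1 / na
  } else {
    set.seed(as.integer(seed))
    w <- vapply(seq_len(n_perm), function(i) {
      v <- rep(-1 / nb, n)
      v[sample.int(n, na)] <- 1 / na
      v
    }, numeric(n))
  }
  null_d <- x %*% w                    # genes x N null differences
  n_null <- ncol(null_d)
  # tie comparison up to floating error (the observed regrouping is part
  # of the exact enumeration but reaches the null side via a different
  # arithmetic path)
  tol <- 1e-9 * (abs(obs) + apply(abs(null_d), 1L, max) + 1e-300)
  le <- rowSums(null_d <= obs + tol)
  lt <- rowSums(null_d < obs - tol)
  data.frame(gene = rownames(x), obs_diff = unname(obs),
             n_null = n_null,
             p = unname((le + 1) / (n_null + 1)),
             p_raw = unname(lt / n_null),
             exact = exact, row.names = NULL, stringsAsFactors = FALSE)
}

#' AUC by midrank Mann-Whitney
#'
#' @param x numeric score vector.
#' @param y binary labels (0/1 or logical), 1 = positive class.
#' @return area under the ROC curve in `[0, 1]`.
#' @export
auc_midrank <- function(x, y) {
  y <- as.integer(as.logical(y))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    dn_stop("both label classes required for AUC", "dignet_degenerate_error")
  r <- rank(x)                         # midranks for ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-gene logistic risk assessment
#'
#' For each gene, a univariate logistic regression of the binary label
#' on the gene's expression (`logit p = b0 + b1 x`, fit by iteratively
#' reweighted least squares, max 100 iterations, tolerance 1e-8) gives
#' the log-odds slope `beta` and `OR = exp(beta)` per expression unit;
#' the AUC is the midrank Mann-Whitney statistic of x against the
#' labels.  Non-convergence or complete separation flags the record and
#' the OR is reported as an infinite sentinel.
#'
#' Both the reported OR and AUC quantify association *strength*
#' regardless of direction -- `or = exp(|beta|)` and
#' `auc = max(a, 1 - a)` -- because a gene whose down-regulation marks
#' the outcome is as much a biomarker as one whose up-regulation does;
#' the direction survives in the sign of `beta` (and `direction`).
#' This matches how single-gene ROC utilities (e.g. `colAUC`) fold the
#' curve.
#'
#' @param matrix genes-by-profiles matrix.
#' @param labels per-profile binary outcome (0/1), both classes present.
#' @return data.frame `gene, beta, or, auc, direction, flagged`.
#' @export
gene_risk <- function(matrix, labels) {
  y <- as.integer(as.logical(labels))
  if (length(y) != ncol(matrix))
    dn_stop("labels must match profiles 1:1", "dignet_schema_error")
  if (length(unique(y)) < 2L)
    dn_stop("labels contain a single class", "dignet_degenerate_error")
  rows <- lapply(rownames(matrix), function(g) {
    xg <- matrix[g, ]
    if (!all(is.finite(xg)))
      dn_stop(sprintf("non-finite expression for gene %s", g),
              "dignet_schema_error")
    fit <- suppressWarnings(
      stats::glm(y ~ xg, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
    beta <- unname(stats::coef(fit)[2])
    a <- auc_midrank(xg, y)
    auc <- max(a, 1 - a)
    mu <- stats::fitted(fit)
    separated <- !fit$converged || is.na(beta) ||
      all(abs(mu - y) < 1e-8) || abs(beta) > 30
    or <- if (is.na(beta)) NA_real_
          else if (separated) Inf
          else exp(abs(beta))
    data.frame(gene = g, beta = beta, or = or, auc = auc,
               direction = sign(beta %||% NA_real_),
               flagged = separated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the biomarker panel
#'
#' Genes with `OR > or_min` and `AUC > auc_min` (strict), sorted by
#' decreasing OR then gene id.
#'
#' @param records [gene_risk()] output.
#' @param or_min odds-ratio floor (default 6).
#' @param auc_min AUC floor (default 0.7).
#' @return character vector of panel gene ids.
#' @export
select_panel <- function(records, or_min = 6, auc_min = 0.7) {
  sel <- records[!is.na(records$or) & records$or > or_min &
                   records$auc > auc_min, , drop = FALSE]
  sel$gene[order(-sel$or, sel$gene)]
}

#' Correlation between differential significance and association strength
#'
#' Pearson correlation of `-log10(permutation p)` against the logistic
#' odds ratio over the genes shared by the two tables, with the
#' two-sided t-distribution p-value.
#'
#' @param perm [permutation_test()] output.
#' @param risk [gene_risk()] output; flagged/infinite ORs are excluded.
#' @return list `(r, p, n)`.
#' @export
significance_strength_correlation <- function(perm, risk) {
  risk <- risk[is.finite(risk$or), , drop = FALSE]
  shared <- merge(perm[, c("gene", "p")], risk[, c("gene", "or")],
                  by = "gene")
  if (nrow(shared) < 3L)
    dn_stop("fewer than 3 shared genes", "dignet_insufficient_data")
  x <- -log10(shared$p); y <- shared$or
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    dn_stop("constant vector; correlation undefined",
            "dignet_degenerate_error")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(shared))
}
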