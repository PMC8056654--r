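# Chemical diversity summaries of a drug set: pairwise Tanimoto
# similarity on binary fingerprints and coefficient-of-variation of a
# physicochemical property table.

#' Pairwise Tanimoto similarity matrix
#'
#' `T(A, B) = |A & B| / |A | B|` on binary fingerprints; the diagonal
#' is 1 and the reported average is over distinct unordered pairs only.
#' A pair of two all-zero fingerprints is undefined (`NA`) and excluded
#' from the average with a warning.
#'
#' @param fingerprints 0/1 matrix, one drug per row (>= 2 rows).
#' @return list with `matrix` (drugs-by-drugs) and `average`.
#' @export
tanimoto_matrix <- function(fingerprints) {
  fp <- as.matrix(fingerprints)
  if (nrow(fp) < 2L)
    dn_stop("need >= 2 fingerprints", "dignet_insufficient_data")
  if (!all(fp %in% c(0L, 1L)))
    dn_stop("fingerprints must be binary", "dignet_schema_error")
  storage.mode(fp) <- "double"
  inter <- fp %*% t(fp)
  ones <- rowSums(fp)
  uni <- outer(ones, ones, `+`) - inter
  tm <- inter / uni
  tm[uni == 0] <- NA_real_                 # two all-zero prints
  diag(tm) <- ifelse(ones > 0, 1, NA_real_)
  if (anyNA(tm[upper.tri(tm)]))
    dn_warn("all-zero fingerprint pair(s) excluded from the average")
  list(matrix = tm, average = mean(tm[upper.tri(tm)], na.rm = TRUE))
}

#' Coefficient of variation of drug properties
#'
#' Per numeric property `CV = sd / |mean|` (sample standard deviation);
#' properties whose absolute mean falls below `tol` are excluded with a
#' warning, and the average CV is the mean over the retained ones.
#'
#' @param table drugs-by-properties data.frame or matrix (>= 2 rows,
#'   numeric columns).
#' @param tol absolute-mean exclusion tolerance (default 1e-12).
#' @return list with `cv` (named vector) and `average`.
#' @export
property_cv <- function(table, tol = 1e-12) {
  m <- as.matrix(table)
  if (!is.numeric(m))
    dn_stop("properties must be numeric", "dignet_schema_error")
  if (nrow(m) < 2L)
    dn_stop("need >= 2 drugs", "dignet_insufficient_data")
  mu <- colMeans(m)
  keep <- abs(mu) > tol
  if (!any(keep))
    dn_stop("all properties have near-zero means", "dignet_degenerate_error")
  if (!all(keep))
    dn_warn(sprintf("%d near-zero-mean propert(ies) excluded", sum(!keep)))
  cv <- apply(m[, keep, drop = FALSE], 2L, stats::sd) / abs(mu[keep])
  list(cv = cv, average = mean(cv))
}
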