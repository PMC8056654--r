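# Disproportionality mining of adverse-event report collections: term
# standardization, 2x2 contingency tables, reporting odds ratios with
# Fisher exact significance, the significant/strong association scan,
# and the ATC-category contrast.

#' Construct an adverse-event report dataset
#'
#' One row per report with exactly one drug and one ADR term (multi-drug
#' reports are expected to be expanded or filtered upstream).
#'
#' @param x data.frame with columns `report_id`, `drug`, `adr` and
#'   optionally `source`.
#' @return an `ade_dataset` (a validated data.frame).
#' @export
ade_dataset <- function(x) {
  need <- c("report_id", "drug", "adr")
  miss <- setdiff(need, names(x))
  if (length(miss))
    dn_stop(paste0("report table missing column(s): ",
                   paste(miss, collapse = ", ")), "dignet_schema_error")
  if (!"source" %in% names(x)) x$source <- "unknown"
  x <- x[, c("report_id", "drug", "adr", "source")]
  x[] <- lapply(x, as.character)
  class(x) <- c("ade_dataset", "data.frame")
  x
}

#' @export
print.ade_dataset <- function(x, ...) {
  cat(sprintf("<ade_dataset> %d reports, %d drugs, %d ADR terms\n",
              nrow(x), length(unique(x$drug)), length(unique(x$adr))))
  invisible(x)
}

#' Standardize ADR terms through a synonym map
#'
#' Every raw term found in the map is replaced by its preferred term;
#' chains (a -> b, b -> c) are resolved to their terminal term; unmapped
#' terms are kept verbatim.  The report count never changes.
#'
#' @param dataset an [ade_dataset()].
#' @param synonym_map named character vector, raw term -> preferred term.
#' @param quiet suppress the message listing unmapped terms.
#' @return the dataset with standardized `adr` column.
#' @export
standardize_terms <- function(dataset, synonym_map, quiet = FALSE) {
  dataset <- ade_dataset(dataset)
  if (length(synonym_map) == 0L) return(dataset)
  if (is.null(names(synonym_map)))
    dn_stop("synonym map must be a named vector", "dignet_config_error")
  resolved <- vapply(names(synonym_map), function(raw) {
    seen <- character()
    cur <- raw
    while (cur %in% names(synonym_map) && synonym_map[[cur]] != cur) {
      if (cur %in% seen)
        dn_stop(sprintf("cyclic synonym map at term '%s'", raw),
                "dignet_config_error")
      seen <- c(seen, cur)
      cur <- synonym_map[[cur]]
    }
    cur
  }, "")
  hit <- dataset$adr %in% names(resolved)
  unmapped <- setdiff(unique(dataset$adr[!hit]), resolved)
  if (length(unmapped) && !quiet)
    message(sprintf("standardize_terms: %d term(s) kept verbatim (unmapped)",
                    length(unmapped)))
  dataset$adr[hit] <- unname(resolved[dataset$adr[hit]])
  dataset
}

#' Build the 2x2 drug-by-ADR contingency table
#'
#' Cells: `a` drug & ADR, `b` drug & other ADR, `c` other drug & ADR,
#' `d` neither.  `a+b+c+d` equals the dataset size.
#'
#' @param dataset an [ade_dataset()].
#' @param drug,adr the pair to tabulate.
#' @param strict error when the drug or ADR is absent from the dataset
#'   universe (default TRUE); with `strict = FALSE` an absent id simply
#'   yields zero cells.
#' @return a `contingency` list with integer fields a, b, c, d.
#' @export
build_contingency <- function(dataset, drug, adr, strict = TRUE) {
  dataset <- ade_dataset(dataset)
  if (strict && !drug %in% dataset$drug)
    dn_stop(sprintf("drug '%s' not in dataset", drug), "dignet_lookup_error")
  if (strict && !adr %in% dataset$adr)
    dn_stop(sprintf("ADR '%s' not in dataset", adr), "dignet_lookup_error")
  is_d <- dataset$drug == drug
  is_a <- dataset$adr == adr
  structure(list(a = sum(is_d & is_a), b = sum(is_d & !is_a),
                 c = sum(!is_d & is_a), d = sum(!is_d & !is_a)),
            class = "contingency")
}

#' Reporting odds ratio and Fisher exact p for a 2x2 table
#'
#' The odds ratio is `(a*d)/(b*c)`; when any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to all four cells so the OR
#' stays finite.  The p-value is the two-sided Fisher exact probability:
#' the sum of hypergeometric probabilities (at fixed margins) no larger
#' than the observed table's.
#'
#' @param table a `contingency` from [build_contingency()] or a numeric
#'   vector `c(a, b, c, d)`.
#' @param correction apply the zero-cell correction (default TRUE).
#' @return list with `or`, `p` and `corrected`.
#' @export
odds_ratio <- function(table, correction = TRUE) {
  tb <- unlist(table[c("a", "b", "c", "d")], use.names = FALSE)
  if (is.null(tb) || anyNA(tb)) tb <- as.numeric(unlist(table))[1:4]
  if (any(tb < 0)) dn_stop("negative cell count", "dignet_schema_error")
  n <- sum(tb)
  if (n == 0) dn_stop("all-zero contingency table", "dignet_degenerate_error")
  a <- tb[1]; b <- tb[2]; c_ <- tb[3]; d <- tb[4]
  corrected <- correction && any(tb == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c_)
  list(or = or, p = fisher_p(tb[1], tb[2], tb[3], tb[4]), corrected = corrected)
}

# Two-sided Fisher exact p by the probability-mass criterion on the
# hypergeometric distribution with fixed margins.
fisher_p <- function(a, b, c, d) {
  m <- a + b          # drug margin
  n <- c + d
  k <- a + c          # ADR margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Scan all drugs against one ADR term
#'
#' For every drug with at least `min_reports` co-reports with `adr`, the
#' 2x2 table, odds ratio and Fisher p are computed, together with the
#' two standard flags: `significant` (OR > 2 and p < 0.05) and `strong`
#' (OR > 10 and p < 0.01).
#'
#' @param dataset an [ade_dataset()] with standardized terms.
#' @param adr ADR term to scan.
#' @param min_reports minimum drug-and-ADR co-report count (default 3).
#' @param or_sig,p_sig thresholds for the `significant` flag.
#' @param or_strong,p_strong thresholds for the `strong` flag.
#' @return data.frame sorted by decreasing odds ratio with columns
#'   `drug, adr, a, b, c, d, odds_ratio, fisher_p, significant, strong`.
#' @export
association_scan <- function(dataset, adr, min_reports = 3L,
                             or_sig = 2, p_sig = 0.05,
                             or_strong = 10, p_strong = 0.01) {
  dataset <- ade_dataset(dataset)
  n_tot <- nrow(dataset)
  is_a <- dataset$adr == adr
  a_cnt <- table(factor(dataset$drug)[is_a])
  drug_cnt <- table(factor(dataset$drug, levels = names(a_cnt)))
  keep <- names(a_cnt)[a_cnt >= min_reports]
  if (length(keep) == 0L) {
    return(data.frame(drug = character(), adr = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), odds_ratio = double(),
                      fisher_p = double(), significant = logical(),
                      strong = logical()))
  }
  n_adr <- sum(is_a)
  rows <- lapply(keep, function(dr) {
    a <- as.integer(a_cnt[[dr]])
    b <- as.integer(drug_cnt[[dr]]) - a
    c_ <- n_adr - a
    d <- n_tot - a - b - c_
    st <- odds_ratio(c(a = a, b = b, c = c_, d = d))
    data.frame(drug = dr, adr = adr, a = a, b = b, c = c_, d = d,
               odds_ratio = st$or, fisher_p = st$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$odds_ratio > or_sig & out$fisher_p < p_sig
  out$strong <- out$odds_ratio > or_strong & out$fisher_p < p_strong
  out[order(-out$odds_ratio, out$drug), , drop = FALSE]
}

#' Contrast association strength between one ATC category and the rest
#'
#' Splits scanned drugs into in-category (any assigned ATC code starts
#' with `category`) versus out-of-category and compares their odds
#' ratios with a one-sided Wilcoxon rank-sum test (alternative:
#' in-category greater).
#'
#' @param records output of [association_scan()].
#' @param atc_map data.frame `drug`, `atc_code` (one row per code).
#' @param category single ATC letter, e.g. `"S"`.
#' @return list with `p`, `mean_in`, `mean_out`, `n_in`, `n_out`.
#' @export
compare_categories <- function(records, atc_map, category) {
  codes <- split(as.character(atc_map$atc_code), as.character(atc_map$drug))
  in_cat <- vapply(records$drug, function(dr) {
    any(startsWith(codes[[dr]] %||% character(), category))
  }, TRUE)
  if (!any(in_cat) || all(in_cat))
    dn_stop("one ATC group is empty", "dignet_grouping_error")
  x <- records$odds_ratio[in_cat]
  y <- records$odds_ratio[!in_cat]
  list(p = rank_sum_p(x, y, alternative = "greater"),
       mean_in = mean(x), mean_out = mean(y),
       n_in = length(x), n_out = length(y))
}

#' One-sided Wilcoxon rank-sum p-value
#'
#' Exact (via the null Wilcoxon distribution) when both groups have at
#' most `exact_max` observations and there are no ties; otherwise the
#' normal approximation with midranks and the tie-corrected variance,
#' without continuity correction (so identical groups give exactly 0.5).
#'
#' @param x,y numeric samples.
#' @param alternative `"greater"` (x tends larger) or `"less"`.
#' @param exact_max exact-enumeration size cap per group (default 12).
#' @return the one-sided p-value.
#' @export
rank_sum_p <- function(x, y, alternative = c("greater", "less"),
                       exact_max = 12L) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L)
    dn_stop("empty group in rank-sum test", "dignet_grouping_error")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2   # Mann-Whitney U for x
  ties <- any(duplicated(c(x, y)))
  if (!ties && nx <= exact_max && ny <= exact_max) {
    p_greater <- stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    p_less <- stats::pwilcox(u, nx, ny)
  } else {
    n <- nx + ny
    t_tab <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(t_tab^3 - t_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(0.5)  # all observations tied
    z <- (u - nx * ny / 2) / sqrt(sigma2)
    p_greater <- stats::pnorm(z, lower.tail = FALSE)
    p_less <- stats::pnorm(z)
  }
  if (alternative == "greater") p_greater else p_less
}
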