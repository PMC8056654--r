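# Synthetic-data generators.  Each generator plants structure with known
# ground truth -- drug-ADR association strengths, co-expression modules,
# group-wise down-regulation, PPI cliques, fingerprint similarity -- so
# that every downstream stage of the pipeline can be tested for exact
# recovery at desk scale.

#' Ground truth for the adverse-event report generator
#'
#' @param planted_pairs data.frame with columns `drug`, `adr`, `or`
#'   (target reporting odds ratio, > 0).
#' @param drug_rates named numeric vector of per-drug report
#'   frequencies (normalized internally).
#' @param adr_rates named numeric vector of per-ADR marginal
#'   probabilities (normalized internally to a background categorical).
#' @return an `ade_truth` object.
#' @export
ade_truth <- function(planted_pairs, drug_rates, adr_rates) {
  stopifnot(all(c("drug", "adr", "or") %in% names(planted_pairs)))
  if (any(planted_pairs$or <= 0))
    dn_stop("target odds ratios must be > 0", "dignet_parameter_error")
  if (any(drug_rates <= 0) || any(adr_rates <= 0))
    dn_stop("rates must be positive", "dignet_parameter_error")
  if (anyDuplicated(names(drug_rates)) || anyDuplicated(names(adr_rates)))
    dn_stop("drug/ADR ids must be unique", "dignet_parameter_error")
  if (anyDuplicated(planted_pairs[c("drug", "adr")]))
    dn_stop("duplicate planted pairs", "dignet_parameter_error")
  structure(list(planted_pairs = planted_pairs,
                 drug_rates = drug_rates / sum(drug_rates),
                 adr_rates = adr_rates / sum(adr_rates)),
            class = "ade_truth")
}

#' Simulate adverse-event reports with planted drug-ADR odds ratios
#'
#' Each report carries one drug (drawn from the background drug rates)
#' and one ADR drawn from a per-drug categorical.  For a planted pair
#' the ADR probability is solved in closed form from the target odds
#' ratio and the background ADR probability (`p1 = OR*q/(1-q+OR*q)` for
#' background probability `q`), so the expected 2x2 table has exactly
#' the target OR; the remaining ADR mass is shared proportionally.
#'
#' @param truth an [ade_truth()].
#' @param n_reports number of reports to draw.
#' @param seed integer seed; identical seeds reproduce identical data.
#' @return an [ade_dataset()].
#' @export
simulate_ade_reports <- function(truth, n_reports, seed = 1L) {
  stopifnot(inherits(truth, "ade_truth"), n_reports >= 1)
  adrs <- names(truth$adr_rates)
  drugs <- names(truth$drug_rates)
  bad <- setdiff(truth$planted_pairs$drug, drugs)
  if (length(bad))
    dn_stop("planted drug not in background rates", "dignet_parameter_error")
  # Solve the planted conditional probabilities jointly: the reference
  # odds for pair (d, a) are those of the ADR among all OTHER drugs, so
  # when several planted drugs share an ADR the solution is a fixed
  # point (each planted drug inflates the background of the others).
  w <- truth$drug_rates
  cond <- matrix(rep(truth$adr_rates, each = length(drugs)),
                 length(drugs), length(adrs),
                 dimnames = list(drugs, adrs))
  pl <- truth$planted_pairs
  idx <- cbind(match(pl$drug, drugs), match(pl$adr, adrs))
  for (it in seq_len(200L)) {
    old <- cond[idx]
    for (r in seq_len(nrow(pl))) {
      i <- idx[r, 1L]; a <- idx[r, 2L]
      p0 <- sum(w[-i] * cond[-i, a]) / sum(w[-i])
      odds <- pl$or[r] * p0 / (1 - p0)
      cond[i, a] <- odds / (1 + odds)
    }
    if (max(abs(cond[idx] - old)) < 1e-12) break
  }
  probs <- lapply(seq_along(drugs), function(i) {
    p <- cond[i, ]
    planted_a <- idx[idx[, 1L] == i, 2L]
    if (length(planted_a)) {
      if (sum(p[planted_a]) >= 1)
        dn_stop(sprintf("planted ORs for drug '%s' imply ADR probability >= 1",
                        drugs[i]), "dignet_parameter_error")
      rest <- setdiff(seq_along(adrs), planted_a)
      p[rest] <- p[rest] * (1 - sum(p[planted_a])) / sum(p[rest])
    }
    p
  })
  names(probs) <- drugs
  set.seed(as.integer(seed))
  drug_of <- sample(drugs, n_reports, replace = TRUE, prob = truth$drug_rates)
  adr_of <- character(n_reports)
  for (dr in drugs) {
    idx <- which(drug_of == dr)
    if (length(idx))
      adr_of[idx] <- sample(adrs, length(idx), replace = TRUE,
                            prob = probs[[dr]])
  }
  ade_dataset(data.frame(
    report_id = sprintf("R%07d", seq_len(n_reports)),
    drug = drug_of, adr = adr_of, source = "synthetic",
    stringsAsFactors = FALSE))
}

#' Ground truth for the expression-profile generator
#'
#' @param module_assignment named integer vector gene -> planted module
#'   id (>= 1); genes of the same module share a latent factor.
#' @param group_A_drugs,group_B_drugs disjoint drug id vectors; group A
#'   receives the planted down-regulation.
#' @param downregulated_genes subset of the assigned genes shifted by
#'   `-effect_size` in group A profiles.
#' @param effect_size mean perturbation shift (expression units, >= 0).
#' @param noise_sd residual standard deviation.
#' @param factor_sd latent factor standard deviation (default 1).
#' @param loading_range range of per-gene factor loadings (positive by
#'   default so eigengene orientation is testable).
#' @param mixed_sign if TRUE half the loadings flip sign.
#' @param extra_drugs drugs with profiles but no planted perturbation
#'   (their profile p-values are uniform, so the replicate/p filters
#'   have something to drop).
#' @return an `expression_truth` object.
#' @export
expression_truth <- function(module_assignment, group_A_drugs, group_B_drugs,
                             downregulated_genes = character(),
                             effect_size = 2, noise_sd = 0.25,
                             factor_sd = 1, loading_range = c(0.85, 1),
                             mixed_sign = FALSE, extra_drugs = character()) {
  if (length(intersect(group_A_drugs, group_B_drugs)))
    dn_stop("drug groups must be disjoint", "dignet_parameter_error")
  if (effect_size < 0)
    dn_stop("effect_size must be >= 0", "dignet_parameter_error")
  if (length(setdiff(downregulated_genes, names(module_assignment))))
    dn_stop("downregulated genes must be assigned to a module",
            "dignet_parameter_error")
  if (any(table(module_assignment) < 2L))
    dn_stop("every planted module needs >= 2 genes", "dignet_parameter_error")
  structure(list(module_assignment = module_assignment,
                 group_A_drugs = group_A_drugs,
                 group_B_drugs = group_B_drugs,
                 downregulated_genes = downregulated_genes,
                 effect_size = effect_size, noise_sd = noise_sd,
                 factor_sd = factor_sd, loading_range = loading_range,
                 mixed_sign = mixed_sign, extra_drugs = extra_drugs),
            class = "expression_truth")
}

#' Simulate drug-perturbation expression profiles
#'
#' Linear latent-factor model: for gene g in module m and profile p,
#' `x[g,p] = loading_g * F[m,p] + shift[g,p] + N(0, noise_sd)`, where F
#' is the module factor (`N(0, factor_sd)` per profile) and the shift is
#' `-effect_size` for down-regulated genes under group-A drugs.  Genes
#' beyond the assigned ones are unassigned background noise (unit sd).
#' Perturbation p-values are small (< 0.01) for group A/B drugs and
#' uniform for `extra_drugs`; each drug's second profile is given a
#' single replicate so the replicate filter is exercised.
#'
#' @param truth an [expression_truth()].
#' @param n_genes total gene count (>= number of assigned genes).
#' @param n_profiles_per_drug profiles per drug (default 3).
#' @param seed integer seed.
#' @param cell_types cell types cycled over drugs (default `"CT1"`).
#' @return a [profile_set()].
#' @export
simulate_expression_profiles <- function(truth, n_genes,
                                         n_profiles_per_drug = 3L,
                                         seed = 1L, cell_types = "CT1") {
  stopifnot(inherits(truth, "expression_truth"))
  assigned <- names(truth$module_assignment)
  if (n_genes < length(assigned))
    dn_stop("n_genes smaller than the number of assigned genes",
            "dignet_parameter_error")
  set.seed(as.integer(seed))
  genes <- c(assigned,
             sprintf("BG%04d", seq_len(n_genes - length(assigned))))
  drugs <- c(truth$group_A_drugs, truth$group_B_drugs, truth$extra_drugs)
  perturbed <- c(truth$group_A_drugs, truth$group_B_drugs)
  n_prof <- length(drugs) * n_profiles_per_drug
  meta <- data.frame(
    profile_id = sprintf("P%04d", seq_len(n_prof)),
    drug = rep(drugs, each = n_profiles_per_drug),
    cell_type = rep(rep_len(cell_types, length(drugs)),
                    each = n_profiles_per_drug),
    dose = "10 uM", time = "24 h",
    n_replicates = 3L, stringsAsFactors = FALSE)
  if (n_profiles_per_drug >= 2L) {
    second <- seq(2L, n_prof, by = n_profiles_per_drug)
    meta$n_replicates[second] <- 1L   # dropped by the replicate filter
  }
  meta$p_value <- ifelse(meta$drug %in% perturbed,
                         stats::runif(n_prof, 1e-5, 0.009),
                         stats::runif(n_prof, 0, 1))

  mods <- sort(unique(truth$module_assignment))
  fac <- matrix(stats::rnorm(length(mods) * n_prof, 0, truth$factor_sd),
                length(mods), n_prof, dimnames = list(mods, NULL))
  load <- stats::runif(length(assigned), truth$loading_range[1],
                       truth$loading_range[2])
  if (truth$mixed_sign)
    load <- load * sample(c(-1, 1), length(load), replace = TRUE)
  x <- matrix(stats::rnorm(n_genes * n_prof, 0,
                           c(rep(truth$noise_sd, length(assigned)),
                             rep(1, n_genes - length(assigned)))),
              n_genes, n_prof, dimnames = list(genes, meta$profile_id))
  x[assigned, ] <- x[assigned, , drop = FALSE] +
    load * fac[as.character(truth$module_assignment[assigned]), , drop = FALSE]
  if (length(truth$downregulated_genes) && truth$effect_size > 0) {
    inA <- meta$drug %in% truth$group_A_drugs
    x[truth$downregulated_genes, inA] <-
      x[truth$downregulated_genes, inA, drop = FALSE] - truth$effect_size
  }
  ps <- profile_set(x, meta)
  attr(ps, "latent_factors") <- fac
  attr(ps, "loadings") <- stats::setNames(load, assigned)
  ps
}

#' Simulate a scored protein-protein interaction graph with a planted clique
#'
#' Any two core genes are connected with probability `p_core`, any other
#' pair with probability `p_background`; confidence scores are drawn
#' uniformly in (400, 999] for core-core edges and (150, 999] otherwise.
#'
#' @param core_genes,background_genes disjoint gene id vectors.
#' @param p_core,p_background edge probabilities,
#'   `0 <= p_background <= p_core <= 1`.
#' @param seed integer seed.
#' @return a [ppi_graph()].
#' @export
simulate_ppi <- function(core_genes, background_genes,
                         p_core = 0.9, p_background = 0.05, seed = 1L) {
  if (length(intersect(core_genes, background_genes)))
    dn_stop("core and background gene lists must be disjoint",
            "dignet_parameter_error")
  if (!(p_background >= 0 && p_background <= p_core && p_core <= 1))
    dn_stop("need 0 <= p_background <= p_core <= 1", "dignet_parameter_error")
  set.seed(as.integer(seed))
  nodes <- c(core_genes, background_genes)
  if (length(nodes) < 2L)
    return(ppi_graph(data.frame(protein1 = character(),
                                protein2 = character(),
                                combined_score = double()), nodes = nodes))
  pairs <- utils::combn(nodes, 2L)
  core <- pairs[1, ] %in% core_genes & pairs[2, ] %in% core_genes
  p <- ifelse(core, p_core, p_background)
  keep <- stats::runif(ncol(pairs)) < p
  score <- round(ifelse(core[keep], stats::runif(sum(keep), 400, 999),
                        stats::runif(sum(keep), 150, 999)))
  ppi_graph(data.frame(protein1 = pairs[1, keep], protein2 = pairs[2, keep],
                       combined_score = score, stringsAsFactors = FALSE),
            nodes = nodes)
}

#' Simulate binary drug fingerprints and a physicochemical property table
#'
#' Fingerprints mix a shared template block with independent random
#' bits so that the expected pairwise Tanimoto similarity equals
#' `mean_similarity` (within about 0.1).  `mean_similarity = 1` yields
#' identical fingerprints; `mean_similarity = 0` yields disjoint on-bit
#' blocks (requires `n_bits >= n_drugs`).
#'
#' @param n_drugs number of drugs.
#' @param n_bits fingerprint length (>= 8).
#' @param mean_similarity target expected pairwise Tanimoto in `[0, 1]`.
#' @param seed integer seed.
#' @param drug_ids optional drug names (default D001...).
#' @return list with `fingerprints` (0/1 matrix) and `properties`
#'   (data.frame of 4 numeric columns: mw, logp, tpsa, hbd).
#' @export
simulate_drug_chemistry <- function(n_drugs, n_bits = 256,
                                    mean_similarity = 0.4, seed = 1L,
                                    drug_ids = sprintf("D%03d", seq_len(n_drugs))) {
  if (n_bits < 8) dn_stop("n_bits must be >= 8", "dignet_parameter_error")
  if (mean_similarity < 0 || mean_similarity > 1)
    dn_stop("mean_similarity must be in [0, 1]", "dignet_parameter_error")
  set.seed(as.integer(seed))
  s <- mean_similarity
  if (s == 0) {
    if (n_bits < n_drugs)
      dn_stop("mean_similarity = 0 needs n_bits >= n_drugs",
              "dignet_parameter_error")
    fp <- matrix(0L, n_drugs, n_bits)
    width <- n_bits %/% n_drugs
    for (i in seq_len(n_drugs)) fp[i, ((i - 1) * width + 1):(i * width)] <- 1L
  } else if (s == 1) {
    tpl <- as.integer(stats::runif(n_bits) < 0.5)
    fp <- matrix(tpl, n_drugs, n_bits, byrow = TRUE)
  } else {
    # shared fraction f of template bits (density .5) + independent rest:
    # E[T] = (.25 + .25 f)/(.75 - .25 f) = s  =>  f = (3 s - 1)/(1 + s);
    # below s = 1/3 use f = 0 with bit density p = 2 s/(1 + s).
    if (s >= 1 / 3) {
      f <- (3 * s - 1) / (1 + s)
      dens <- 0.5
    } else {
      f <- 0
      dens <- 2 * s / (1 + s)
    }
    n_shared <- round(f * n_bits)
    tpl <- as.integer(stats::runif(n_shared) < 0.5)
    fp <- t(vapply(seq_len(n_drugs), function(i) {
      c(tpl, as.integer(stats::runif(n_bits - n_shared) < dens))
    }, integer(n_bits)))
  }
  empty <- rowSums(fp) == 0
  if (any(empty)) fp[empty, sample.int(n_bits, 1L)] <- 1L
  rownames(fp) <- drug_ids
  props <- data.frame(
    row.names = drug_ids,
    mw = round(stats::rlnorm(n_drugs, log(350), 0.35), 1),
    logp = round(stats::rnorm(n_drugs, 2.5, 1.5), 2),
    tpsa = round(stats::rgamma(n_drugs, shape = 4, scale = 20), 1),
    hbd = stats::rpois(n_drugs, 2))
  list(fingerprints = fp, properties = props)
}
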