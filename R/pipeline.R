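# Pipeline orchestration: configuration, the seeded synthetic study
# fixture, and the end-to-end run binding every stage together
# (association mining -> drug selection -> profile prep -> co-expression
# -> enrichment -> core genes -> hubs -> permutation test -> risk ->
# panel).

#' Default pipeline configuration
#'
#' All thresholds in one auditable list.  Defaults mirror the standard
#' analysis: soft power 5, eigengene merge dissimilarity 0.3, module
#' membership 0.95, MCC floor 5 with betweenness > 0, 10,000
#' permutations, panel cutoffs OR > 6 and AUC > 0.7, significant
#' association OR > 2 / p < 0.05, strong OR > 10 / p < 0.01.
#'
#' @param ... overrides of the defaults (paths and thresholds).
#' @return a named list (class `dignet_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    # input paths (filled per run)
    reports = NULL, synonyms = NULL, atc = NULL,
    matrix = NULL, meta = NULL, gmt = NULL, ppi_edges = NULL,
    fingerprints = NULL, properties = NULL, cell_organ = NULL,
    out_dir = NULL,
    # association mining
    adr_term = "Glaucoma", min_reports = 3L,
    or_sig = 2, p_sig = 0.05, or_strong = 10, p_strong = 0.01,
    category = "S",
    # profile preparation
    rep_p_max = 0.01, n_top_degs = 100L,
    # co-expression
    beta = 5, n_bins = 10L, min_module_size = 30L,
    cut_height_quantile = 0.99, merge_dissim = 0.3,
    # enrichment / core genes
    required_terms = "GO:0007601", q_max = 0.05, mm_min = 0.95,
    # hub network
    score_min = 400, mcc_min = 5, betweenness_gt = 0,
    # association statistics
    n_perm = 10000L, or_min = 6, auc_min = 0.7,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    dn_stop(paste0("unknown config field(s): ", paste(bad, collapse = ", ")),
            "dignet_config_error")
  cfg[names(over)] <- over
  structure(cfg, class = c("dignet_config", "list"))
}

#' Read / write a pipeline configuration (YAML)
#' @param path YAML file path.
#' @return a `dignet_config`.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a `dignet_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}

#' Generate a complete seeded synthetic study
#'
#' Writes every pipeline input to `dir` with planted, recoverable
#' structure: 13 "case" drugs with a strong planted association to the
#' target ADR term and sensory-organ (S) ATC codes, 63 S-category
#' comparator drugs at the null, non-S background drugs (some with a
#' planted association, so category selection has something to
#' exclude), a 4-module latent-factor expression world whose first
#' module carries the planted down-regulated genes, a gene-set
#' collection with a "visual perception"-style term concentrated in
#' that module, a PPI graph with a planted clique over the
#' down-regulated genes, and fingerprints/properties for the case
#' drugs.
#'
#' @param dir output directory (created).
#' @param seed root integer seed.
#' @param n_reports adverse-event reports to draw (default 200000).
#' @param n_genes total genes (default 300: 4 modules of 50 plus 100
#'   unassigned background genes).
#' @param n_downregulated planted down-regulated genes in module 1
#'   (default 20).
#' @param planted_or planted odds ratio of case drugs (default 25).
#' @param effect_size planted group-A down-shift (default 3
#'   expression units: the panel bar OR > 6 demands |beta| > log 6
#'   per unit, i.e. a shift well above the unit profile variance).
#' @param noise_sd residual expression noise (default 0.1; modules must
#'   be tight enough that a strict membership filter such as kME > 0.95
#'   keeps them, as it does in real co-expression analyses).
#' @param mean_similarity target fingerprint similarity (default 0.4).
#' @return list with `paths` (all written files), `truth` (planted
#'   ground truth) and `config` (a ready-to-run [default_config()]).
#' @export
simulate_study <- function(dir, seed = 1L, n_reports = 200000L,
                           n_genes = 300L, n_downregulated = 20L,
                           planted_or = 25, effect_size = 3,
                           noise_sd = 0.1, mean_similarity = 0.4) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)

  case_drugs <- sprintf("SDRUG%02d", 1:13)       # planted, S category
  comp_drugs <- sprintf("SDRUG%02d", 14:76)      # null, S category
  nonS_assoc <- sprintf("NDRUG%02d", 1:10)       # planted but non-S
  bg_drugs <- sprintf("BDRUG%03d", 1:110)        # null, non-S
  drugs <- c(case_drugs, comp_drugs, nonS_assoc, bg_drugs)

  adrs <- c("Glaucoma", sprintf("ADR%02d", 1:29))
  set.seed(fan_seed(seed, "rates"))
  drug_rates <- stats::setNames(stats::runif(length(drugs), 0.5, 1.5), drugs)
  adr_rates <- stats::setNames(c(0.004, stats::runif(29, 0.01, 0.05)), adrs)

  truth_ade <- ade_truth(
    planted_pairs = data.frame(
      drug = c(case_drugs, nonS_assoc), adr = "Glaucoma",
      or = c(rep(planted_or, 13), rep(15, 10)),
      stringsAsFactors = FALSE),
    drug_rates = drug_rates, adr_rates = adr_rates)
  reports <- simulate_ade_reports(truth_ade, n_reports,
                                  seed = fan_seed(seed, "ade"))
  # un-standardized variants so term standardization has work to do
  set.seed(fan_seed(seed, "synonyms"))
  gl <- which(reports$adr == "Glaucoma")
  raw <- sample(gl, floor(length(gl) * 0.3))
  reports$adr[raw] <- sample(c("glaucoma NOS", "Glaucoma aggravated"),
                             length(raw), replace = TRUE)
  write_reports(reports, path("reports.tsv"), seed = seed)
  syn <- data.frame(raw_term = c("glaucoma NOS", "Glaucoma aggravated"),
                    preferred_term = "Glaucoma")
  write_tsv(syn, path("synonyms.tsv"))

  atc <- data.frame(
    drug = drugs,
    atc_code = c(paste0("S01E", LETTERS[(0:75) %% 5 + 1],
                        sprintf("%02d", (0:75) %% 90)),
                 paste0("N05A", LETTERS[(0:9) %% 4 + 1],
                        sprintf("%02d", 1:10)),
                 paste0("C09X", LETTERS[(0:109) %% 6 + 1],
                        sprintf("%02d", (0:109) %% 90))),
    stringsAsFactors = FALSE)
  write_tsv(atc, path("atc.tsv"))

  module_sizes <- c(50L, 50L, 50L, 50L)
  genes <- unlist(lapply(1:4, function(m)
    sprintf("M%dG%02d", m, seq_len(module_sizes[m]))))
  assignment <- stats::setNames(rep(1:4, module_sizes), genes)
  down <- sprintf("M1G%02d", seq_len(n_downregulated))
  truth_expr <- expression_truth(
    module_assignment = assignment,
    group_A_drugs = case_drugs, group_B_drugs = comp_drugs,
    downregulated_genes = down, effect_size = effect_size,
    noise_sd = noise_sd,
    extra_drugs = sprintf("XDRUG%02d", 1:5))
  profiles <- simulate_expression_profiles(
    truth_expr, n_genes = n_genes, n_profiles_per_drug = 3L,
    seed = fan_seed(seed, "expr"), cell_types = "RPE")
  write_gct(profiles$matrix, path("matrix.gct"))
  write_tsv(profiles$meta, path("meta.tsv"), seed = seed)
  write_tsv(data.frame(cell_type = "RPE", organ_letter = "S"),
            path("cell_organ.tsv"))

  all_genes <- rownames(profiles$matrix)
  set.seed(fan_seed(seed, "gmt"))
  sets <- c(
    list("GO:0007601" = sprintf("M1G%02d", 1:40),
         "GO:0050953" = sprintf("M1G%02d", 5:45)),
    stats::setNames(lapply(1:8, function(i) sample(all_genes, 40)),
                    sprintf("GO:%07d", 1000000 + (1:8) * 111)))
  descr <- stats::setNames(c("visual perception",
                             "sensory perception of light stimulus",
                             sprintf("random process %d", 1:8)), names(sets))
  write_gmt(gene_set_collection(sets, descr), path("sets.gmt"))

  ppi <- simulate_ppi(core_genes = down,
                      background_genes = setdiff(all_genes, down),
                      p_core = 0.9, p_background = 0.02,
                      seed = fan_seed(seed, "ppi"))
  write_tsv(ppi$edges, path("ppi.tsv"))

  chem <- simulate_drug_chemistry(length(case_drugs),
                                  n_bits = 256,
                                  mean_similarity = mean_similarity,
                                  seed = fan_seed(seed, "chem"),
                                  drug_ids = case_drugs)
  write_fingerprints(chem$fingerprints, path("fingerprints.tsv"))
  write_tsv(cbind(drug = rownames(chem$properties), chem$properties),
            path("properties.tsv"))

  paths <- list(reports = path("reports.tsv"), synonyms = path("synonyms.tsv"),
                atc = path("atc.tsv"), matrix = path("matrix.gct"),
                meta = path("meta.tsv"), gmt = path("sets.gmt"),
                ppi_edges = path("ppi.tsv"),
                fingerprints = path("fingerprints.tsv"),
                properties = path("properties.tsv"),
                cell_organ = path("cell_organ.tsv"))
  # static cut at the 0.90 height quantile: with 13 profiles the
  # module junctions sit inside the background-merge regime near the
  # dendrogram top, so the package default (0.99, suited to thousands
  # of genes) keeps too few branches at this fixture scale
  config <- do.call(default_config,
                    c(paths, list(out_dir = file.path(dir, "out"),
                                  seed = seed,
                                  cut_height_quantile = 0.90)))
  truth <- list(case_drugs = case_drugs, comp_drugs = comp_drugs,
                nonS_assoc = nonS_assoc,
                module_assignment = assignment,
                downregulated_genes = down,
                planted_or = planted_or, effect_size = effect_size)
  list(paths = paths, truth = truth, config = config)
}

halt_if_empty <- function(x, stage) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  if (n == 0L)
    dn_stop(sprintf("pipeline halted: empty selection at stage '%s'", stage),
            "dignet_stage_error")
  invisible(x)
}

#' Run the full pipeline
#'
#' Executes association mining, drug selection (strong association and
#' target ATC category), representative-profile selection, the
#' co-expression core, enrichment-driven target-module selection, core
#' genes, hub extraction, the permutation test, the logistic risk
#' assessment and panel selection; writes every stage output plus a
#' machine-readable run report under `config$out_dir`.  A stage with an
#' empty selection halts with a diagnostic naming the stage.
#'
#' @param config a [default_config()] with input paths set.
#' @return invisible list with all stage results and the run report.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  if (is.null(cfg$out_dir)) dn_stop("out_dir not set", "dignet_config_error")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg[!vapply(cfg, is.null, TRUE)])
  out <- function(f) file.path(cfg$out_dir, f)
  put <- function(df, f) write_tsv(df, out(f), seed = cfg$seed, cfg_hash = hash)

  # 1. association mining ---------------------------------------------
  reports <- read_reports(cfg$reports)
  if (!is.null(cfg$synonyms))
    reports <- standardize_terms(reports, read_synonyms(cfg$synonyms),
                                 quiet = TRUE)
  scan <- association_scan(reports, cfg$adr_term,
                           min_reports = cfg$min_reports,
                           or_sig = cfg$or_sig, p_sig = cfg$p_sig,
                           or_strong = cfg$or_strong,
                           p_strong = cfg$p_strong)
  halt_if_empty(scan, "association_scan")
  put(scan, "associations.tsv")
  atc <- read_atc_map(cfg$atc)
  codes <- split(atc$atc_code, atc$drug)
  in_cat <- vapply(scan$drug, function(dr)
    any(startsWith(codes[[dr]] %||% character(), cfg$category)), TRUE)
  selected <- scan$drug[scan$strong & in_cat]
  halt_if_empty(selected, "drug_selection")
  writeLines(c(output_header(cfg$seed, hash), selected),
             out("selected_drugs.txt"))
  category_contrast <- tryCatch(
    compare_categories(scan[scan$significant, , drop = FALSE], atc,
                       cfg$category),
    dignet_error = function(e) NULL)

  # 2. expression preparation -----------------------------------------
  profiles <- profile_set(read_gct(cfg$matrix), read_profile_meta(cfg$meta))
  reps <- select_representative_profiles(profiles, p_max = cfg$rep_p_max,
                                         per = "drug", quiet = TRUE)
  halt_if_empty(reps$meta, "representative_profiles")
  put(reps$meta, "representative_profiles.tsv")
  group_A <- intersect(selected, reps$meta$drug)
  halt_if_empty(group_A, "group_A")
  s_drugs <- names(codes)[vapply(codes, function(cc)
    any(startsWith(cc, cfg$category)), TRUE)]
  group_B <- setdiff(intersect(reps$meta$drug, s_drugs), group_A)
  halt_if_empty(group_B, "group_B")
  drug_mat <- reps$matrix
  colnames(drug_mat) <- reps$meta$drug

  # 3. co-expression on the selected (group A) drug profiles ----------
  x_a <- drug_mat[, group_A, drop = FALSE]
  adj <- soft_adjacency(x_a, beta = cfg$beta)
  sff <- scale_free_fit(adj, n_bins = cfg$n_bins)
  tom <- topological_overlap(adj)
  ms0 <- detect_modules(1 - tom, min_module_size = cfg$min_module_size,
                        cut_height_quantile = cfg$cut_height_quantile)
  n_pre <- length(setdiff(unique(ms0$labels), 0L))
  halt_if_empty(setdiff(unique(ms0$labels), 0L), "module_detection")
  ms <- merge_modules(ms0, x_a, dissim_threshold = cfg$merge_dissim)
  n_post <- length(setdiff(unique(ms$labels), 0L))
  put(data.frame(gene = names(ms$labels), module = unname(ms$labels)),
      "modules.tsv")
  put(data.frame(profile = rownames(ms$eigengenes), ms$eigengenes,
                 check.names = FALSE), "eigengenes.tsv")

  # 4. enrichment-driven target module --------------------------------
  collection <- read_gmt(cfg$gmt, universe = rownames(x_a))
  targets <- select_target_module(ms, collection, cfg$required_terms,
                                  q_max = cfg$q_max)
  halt_if_empty(targets, "module_selection")
  target <- targets[1L]

  # 5. core genes ------------------------------------------------------
  mm <- module_membership(x_a, ms)
  put(data.frame(gene = rownames(mm), mm, check.names = FALSE),
      "membership.tsv")
  core <- select_core_genes(mm, target, mm_min = cfg$mm_min,
                            labels = ms$labels)
  halt_if_empty(core, "core_genes")
  writeLines(c(output_header(cfg$seed, hash), core), out("core_genes.txt"))

  # 6. hub extraction ---------------------------------------------------
  ppi <- load_edges(cfg$ppi_edges, score_min = cfg$score_min)
  sub <- induce_subgraph(ppi, core)
  halt_if_empty(sub$edges, "ppi_subgraph")
  full_density <- nrow(ppi$edges) /
    (length(ppi$nodes) * (length(ppi$nodes) - 1) / 2)
  enr <- suppressWarnings(ppi_enrichment_check(sub, full_density))
  hubs_tab <- select_hubs(mcc_scores(sub), betweenness_scores(sub),
                          mcc_min = cfg$mcc_min,
                          betweenness_gt = cfg$betweenness_gt)
  put(hubs_tab, "hub_scores.tsv")
  hubs <- hubs_tab$gene[hubs_tab$is_hub]
  halt_if_empty(hubs, "hub_selection")

  # 7. permutation test on hub genes -----------------------------------
  perm <- permutation_test(drug_mat[hubs, , drop = FALSE],
                           group_A, group_B, n_perm = cfg$n_perm,
                           seed = fan_seed(cfg$seed, "permtest"))
  put(perm, "permutation.tsv")

  # 8. logistic risk + AUC on hub genes --------------------------------
  ab <- c(group_A, group_B)
  risk <- gene_risk(drug_mat[hubs, ab, drop = FALSE],
                    as.integer(ab %in% group_A))
  put(risk, "risk.tsv")
  corr <- tryCatch(significance_strength_correlation(perm, risk),
                   dignet_error = function(e) NULL)

  # 9. biomarker panel ---------------------------------------------------
  panel <- select_panel(risk, or_min = cfg$or_min, auc_min = cfg$auc_min)
  halt_if_empty(panel, "panel_selection")
  writeLines(c(output_header(cfg$seed, hash), panel), out("panel_genes.txt"))

  # 10. chemical diversity of the selected drugs ------------------------
  chem <- NULL
  if (!is.null(cfg$fingerprints)) {
    fp <- read_fingerprints(cfg$fingerprints)
    fp <- fp[intersect(rownames(fp), group_A), , drop = FALSE]
    tan <- if (nrow(fp) >= 2) tanimoto_matrix(fp)$average else NA_real_
    cv <- NA_real_
    if (!is.null(cfg$properties)) {
      pr <- read_tsv(cfg$properties)
      rownames(pr) <- pr[[1L]]
      pr <- pr[intersect(rownames(pr), group_A), -1L, drop = FALSE]
      if (nrow(pr) >= 2) cv <- property_cv(pr)$average
    }
    chem <- list(average_tanimoto = tan, average_cv = cv)
  }

  report <- list(
    tool = "dignet", version = as.character(utils::packageVersion("dignet")),
    seed = cfg$seed, config_hash = hash,
    config = cfg[!vapply(cfg, is.null, TRUE)],
    counts = list(
      n_reports = nrow(reports),
      n_scanned_drugs = nrow(scan),
      n_significant = sum(scan$significant),
      n_strong = sum(scan$strong),
      n_selected_drugs = length(selected),
      n_group_A = length(group_A), n_group_B = length(group_B),
      n_modules_premerge = n_pre, n_modules_postmerge = n_post,
      n_core_genes = length(core),
      n_ppi_edges = nrow(sub$edges),
      n_hubs = length(hubs),
      n_perm_significant = sum(perm$p < 0.05),
      n_panel_genes = length(panel)),
    scale_free_r2 = sff,
    category_contrast = category_contrast,
    ppi_enrichment = enr,
    significance_strength = corr,
    chem_diversity = chem)
  jsonlite::write_json(report, out("run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(list(report = report, scan = scan, selected = selected,
                 group_A = group_A, group_B = group_B,
                 modules = ms, scale_free_r2 = sff, target_module = target,
                 membership = mm, core = core, hubs = hubs_tab,
                 hub_genes = hubs, perm = perm, risk = risk,
                 correlation = corr, panel = panel, chem = chem))
}
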