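---
title: "dignet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dignet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Some adverse drug reactions — drug-induced glaucoma is the motivating
example — are caused by many chemically unrelated drugs, so the usual
drug–target reasoning fails. `dignet` implements an alternative,
network-level strategy as a reusable, fully testable pipeline:

1. **Disproportionality mining.** From a spontaneous-report collection,
   score every drug against a target reaction term by the reporting
   odds ratio $\mathrm{OR} = ad/bc$ of the $2\times2$ report table,
   with two-sided Fisher exact significance. Drugs with a *strong*
   association (OR > 10, p < 0.01) in the relevant ATC category (first
   letter, e.g. "S" for sensory organs) become the case group.
2. **Expression preparation.** Drug-perturbation profiles (signed
   differential-expression coefficients, as distributed by large
   perturbation compendia) are filtered to one representative per drug:
   replicated experiments only, minimum perturbation p-value subject to
   p < 0.01.
3. **Co-expression.** A weighted gene co-expression network over the
   case-drug profiles: unsigned soft-threshold adjacency
   $a_{ij} = |\mathrm{cor}(g_i,g_j)|^\beta$ (default $\beta = 5$),
   topological overlap, average-linkage clustering with a static tree
   cut, module eigengenes (first principal component of the
   standardized module submatrix), and eigengene merging below
   dissimilarity 0.3.
4. **Module selection and core genes.** The target module is the one
   enriched (one-sided Fisher with Benjamini–Hochberg FDR) for required
   terms such as visual perception; its core genes are those with
   module membership $kME > 0.95$.
5. **Hub extraction.** On the protein–protein interaction subgraph over
   the core genes, hubs satisfy Maximal Clique Centrality
   $\mathrm{MCC}(v) = \sum_{C \ni v} (|C|-1)!$ (exact maximal-clique
   enumeration) at least 5 and betweenness strictly positive.
6. **Association statistics.** A group-label permutation test contrasts
   hub-gene expression under case versus comparator drugs; a per-gene
   univariate logistic model plus ROC/AUC ranks biomarker candidates;
   the panel keeps genes with OR > 6 and AUC > 0.7.
7. **Chemical diversity.** Average pairwise Tanimoto similarity of
   binary fingerprints and average coefficient of variation of
   physicochemical properties describe the case drugs' heterogeneity.

The real data behind such studies (full pharmacovigilance extracts,
perturbation compendia, interaction databases, ADR vocabularies) are
external and large, so the package ships a synthetic-data generator
that plants recoverable structure in *every* input. Every pipeline
stage is tested against that ground truth and against independent
brute-force oracles.

# The synthetic world

`simulate_study()` writes a complete input set with one root seed:

* **Reports.** 199 drugs, 30 ADR terms, 200,000 reports by default.
  13 case drugs carry a planted OR of 25 against the target term, 10
  non-S drugs a planted OR of 15 (so category selection has something
  to exclude), the rest are null. A drug's ADR categorical is solved
  from the target OR and the background odds; when several planted
  drugs share one ADR the single-pair closed form understates the
  realized OR (each planted drug inflates the others' background), so
  the conditional probabilities are solved jointly by fixed-point
  iteration — the planted OR is then the exact expectation of the
  scanned 2×2 table.
* **Expression.** A linear latent-factor model: gene $g$ in module $m$
  has $x_{gp} = \lambda_g F_{mp} + s_{gp} + \varepsilon_{gp}$ with
  factor sd 1, loadings in $[0.85, 1]$, noise sd 0.1 and a shift
  $s = -3$ for the 20 planted down-regulated genes under case drugs.
  Four modules of 50 genes plus 100 unassigned background genes.
  Loadings are positive by default so eigengene sign orientation is
  testable; a mixed-sign mode exists.
* **Perturbation p-values** are small (< 0.01) for the case/comparator
  drugs and uniform for a handful of extra drugs; every drug's second
  profile has a single replicate, so the replicate and p filters are
  both exercised.
* **PPI.** Edge probability 0.9 between planted down-regulated genes,
  0.02 elsewhere, scores in the STRING-like 0–1000 range.
* **Chemistry.** Fingerprints mix a shared template block with
  independent bits so the expected pairwise Tanimoto hits a target
  (default 0.4); the property table has four numeric columns.

## What the generator does *not* emulate

Report deduplication and rechallenge structure, multi-drug reports,
dose–response, realistic chemical structure, and the heavy-tailed
degree structure of real interactomes. A green end-to-end test
establishes that the pipeline recovers planted structure under its own
stated model — not that the model captures every pathology of real
pharmacovigilance or perturbation data.

## Chosen constants, and why

* **noise sd 0.1, loadings 0.85–1 (end-to-end world).** The core-gene
  filter $kME > 0.95$ presupposes very tight modules; with loading
  $\lambda$ and noise $\sigma$ the population membership is
  $\lambda/\sqrt{\lambda^2+\sigma^2}$, which at $\sigma = 0.25$ sits
  exactly at 0.95 and the filter keeps a coin-flip half of the module.
  The planted world must clear the bar it is tested against, hence
  $\sigma = 0.1$ (population kME ≈ 0.99). The looser
  $\sigma = 0.3$ world is used where module-recovery *power* is the
  question (ARI and factor-recovery tests).
* **effect size 3 (end-to-end world).** The panel bar OR > 6 demands a
  log-odds slope above $\log 6 \approx 1.79$ per expression unit.
  With a shift $s$ against unit-variance profiles the fitted slope
  magnitude is of order $s$, with substantial sampling spread at 13
  case drugs; $s = 2$ leaves fitted ORs straddling the bar, $s = 3$
  clears it with margin. The permutation-power tests keep the spec'd
  $s = 2$, $\sigma = 0.5$ world.
* **cut quantile 0.90 (end-to-end config).** The package default cuts
  the dendrogram at the 0.99 quantile of merge heights, which keeps
  the top ~1% of branches — appropriate for thousands of genes. At
  300 genes and 13 profiles the module junctions sit inside the
  background-merge regime near the dendrogram top, so the study config
  cuts at 0.90. Both are configuration, chosen from fixture scale.
* **planted OR 25.** The motivating study's strong drugs average an OR
  near 21; 25 keeps the planted drugs comfortably above the strong
  threshold of 10 after sampling noise.

# Numerical and convention choices

* **Zero cells.** The Haldane–Anscombe correction (add 0.5 to all four
  cells) is applied iff any cell is zero — standard pharmacovigilance
  practice; the Fisher p always uses the uncorrected counts.
* **Two-sided Fisher p** by the probability-mass criterion: the sum of
  hypergeometric probabilities not exceeding the observed table's
  (with a $1+10^{-7}$ relative guard against floating ties), matching
  common implementations. Whether the original analysis was one- or
  two-sided is not stated anywhere authoritative; two-sided is the
  conservative default.
* **Scan floor.** Drugs enter the association scan with at least 3
  co-reports (configurable). Degenerate one-report ORs are otherwise
  unbounded.
* **Rank-sum test.** Exact null distribution when both groups have ≤ 12
  observations and no ties; otherwise normal approximation with
  midranks and tie-corrected variance, *without* continuity correction
  so identical groups give exactly p = 0.5.
* **Permutation test.** One-sided left tail (the question is
  down-regulation under case drugs). Ties count into the tail and the
  finite-sample +1 correction is applied:
  $p = (\#\{d^* \le d\} + 1)/(N+1)$ — a valid estimator, never zero;
  the raw strict proportion is reported alongside. When
  $\binom{n_A+n_B}{n_A} \le$ `n_perm` the null is enumerated
  exhaustively. One relabeling per iteration is shared across all
  genes, preserving the genes' correlation under the null.
* **Logistic risk.** Reported OR and AUC are direction-folded
  association strengths: $\mathrm{or} = e^{|\beta|}$,
  $\mathrm{auc} = \max(a, 1-a)$, with the direction kept as the sign
  of $\beta$. A biomarker whose *down*-regulation marks the outcome
  would otherwise have OR < 1 and AUC < 0.5 and could never pass an
  OR > 6 / AUC > 0.7 panel bar, which is how such panels are
  reported in practice (single-gene ROC utilities fold the curve).
  Complete separation or non-convergence flags the record and reports
  an infinite OR sentinel rather than silently penalizing; a flagged
  record still qualifies for the panel (its evidence of association is
  overwhelming, not absent).
* **Eigengene orientation.** The first right singular vector is
  sign-oriented towards the module's mean standardized profile, making
  kME reproducible.
* **Static tree cut.** The "tree" variant (cut at a height quantile,
  drop branches below `min_module_size`) replaces the hybrid dynamic
  tree cut: the hybrid algorithm's many unstated parameters add
  irreproducible complexity, and the acceptance surface here is
  planted-structure recovery, which the tree variant satisfies.
  Heights are made non-decreasing (`cummax`) before cutting to guard
  against floating-point ties.
* **Missing values** are rejected at load; perturbation matrices are
  dense by construction, so pairwise-complete correlation paths are
  deliberately not provided.
* **MCC.** Maximal cliques (size ≥ 2) are enumerated exactly
  (Bron–Kerbosch with pivoting); summing $(|C|-1)!$ over maximal
  2-cliques automatically reproduces the "degree" special case for
  nodes whose neighborhood induces no edges. Betweenness is exact,
  unnormalized and unweighted — the hub filter is "> 0", which
  normalization cannot change.
* **PPI enrichment gate.** Interaction databases gate networks on a
  service-side enrichment p; `ppi_enrichment_check()` reproduces the
  idea as a warning-only binomial diagnostic against a user-supplied
  background density, never blocking the pipeline.
* **CV.** Sample (n−1) standard deviation over |mean|, with properties
  whose |mean| is below $10^{-12}$ excluded — signed properties (logP)
  can have near-zero means.
* **Seeds.** All stage seeds fan out from one root via `fan_seed()`
  (kept below $2^{31}$), so a pipeline run is bitwise reproducible.

# What a green acceptance run establishes

The acceptance suite (`tests/testthat/test-acceptance.R`) checks:

1. **Oracle equivalence** — Fisher p against exhaustive enumeration on
   every 2×2 table with total ≤ 40; MCC against a subset-enumeration
   oracle on 100 random graphs; TOM against a triple-loop oracle; AUC
   against hand-computed midrank cases; permutation p against full
   regrouping enumeration.
2. **Calibration** — permutation p-values KS-uniform under a null
   13-vs-63 contrast at 2,000 genes; the null association scan's
   false-flag rate inside the binomial 99% interval.
3. **Parameter recovery** — planted ORs {2, 5, 10} within 20% at
   $10^5$ reports; logistic $\beta = 1$ within 3 SE at $n = 5000$;
   planted 4-module structure at ARI ≥ 0.9 with factor–eigengene
   $R^2 \ge 0.9$.
4. **End-to-end** — the full pipeline on the seeded synthetic study
   recovers ≥ 90% of planted down-regulated genes in the final panel
   with zero false panel genes, identically across repeated runs.
5. **Worked micro-examples** — the closed-form toy cases
   (K4 MCC = 6, OR(10,90,10,890) = 9.889, Fisher(5,0,0,5) = 2/252,
   Tanimoto(1100,1010) = 1/3, CV(2,4,6) = 0.5, BH, exact Wilcoxon).

It does **not** establish agreement with any published full-scale
analysis: those numbers depend on proprietary inputs and unstated
preprocessing, which is precisely why the acceptance surface is
property-based.

# Known limitations

* Clique enumeration is exponential in the worst case; `mcc_scores()`
  refuses graphs above 2,000 nodes (configurable) and is intended for
  core-gene subgraphs of a few hundred nodes.
* The static tree cut needs a scale-appropriate height quantile; there
  is no automatic selection.
* The logistic fit is unpenalized by design (matching the modelled
  analysis); a Firth-style fallback is out of scope, separation is
  flagged instead.
* Multi-drug reports must be expanded upstream; the report model is
  one drug, one reaction per row.
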