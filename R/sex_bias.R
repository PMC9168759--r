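#' Wilcoxon rank-sum comparison of a feature between sexes
#'
#' Two-sided rank-sum test. Exact enumeration is used when both groups have
#' fewer than 8 observations (and no ties); otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping (factor, logical or character).
#' @return A one-row tibble with `statistic` (the rank-sum U of the first
#'   level) and `p`.
#' @export
wrs_test <- function(values, groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    input_error("wrs_test needs two non-empty groups")
  }
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  exact <- length(x) < 8 && length(y) < 8
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = TRUE)
  )
  tibble(statistic = unname(res$statistic), p = res$p.value)
}

#' Welch two-sample t comparison between sexes
#'
#' Unpaired two-sided t-test with Welch-Satterthwaite degrees of freedom.
#' The sign convention is female minus male: a positive `t_score` means the
#' feature is higher in females.
#'
#' @param values Numeric vector.
#' @param sex Factor with levels `male`, `female` (or coercible).
#' @return A one-row tibble with `t_score`, `df`, `p`, and a `degenerate`
#'   flag (both groups constant).
#' @export
welch_t <- function(values, sex) {
  sex <- factor(as.character(sex), levels = c("male", "female"))
  xm <- values[sex == "male"]
  xf <- values[sex == "female"]
  if (length(xm) < 2 || length(xf) < 2) {
    input_error("welch_t needs at least two values per sex")
  }
  if (var(xm) == 0 && var(xf) == 0) {
    if (mean(xm) == mean(xf)) {
      return(tibble(t_score = 0, df = NA_real_, p = 1, degenerate = FALSE))
    }
    return(tibble(t_score = sign(mean(xf) - mean(xm)) * Inf,
                  df = NA_real_, p = 0, degenerate = TRUE))
  }
  res <- t.test(xf, xm, alternative = "two.sided", var.equal = FALSE)
  tibble(t_score = unname(res$statistic), df = unname(res$parameter),
         p = res$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in the original order, capped at 1.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    input_error("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Scan every tumor-microenvironment feature for sex bias
#'
#' Runs the full male-versus-female comparison battery on one cohort:
#' rank-sum tests for the four summary features (TMB, immune score, stromal
#' score, tumor purity), Welch t-tests per immune-cell enrichment score and
#' per immune-checkpoint gene (ICG) expression. FDR is controlled separately
#' within the cell family and the ICG family.
#'
#' @param scores Per-sample score tibble from [compute_sample_scores()].
#' @param expression Wide expression tibble (for ICG tests); may be `NULL`
#'   to skip the ICG family.
#' @param clinical Clinical tibble with `sample` and `sex`.
#' @param icg_genes Character vector of checkpoint gene identifiers; unknown
#'   genes are skipped with a warning.
#' @param p_cut P-value threshold for the summary (rank-sum) family.
#' @param fdr_cut FDR threshold for the t-test families.
#' @return An object of class `sex_bias_scan`: list with tibbles
#'   `summary_tests`, `cell_tests`, `icg_tests` and counts `n_male`,
#'   `n_female`. Each tibble carries `feature`, test statistics, `p`,
#'   (`fdr` for t families), `direction` and `significant`.
#' @export
sex_bias_scan <- function(scores, expression = NULL, clinical,
                          icg_genes = NULL, p_cut = 0.05, fdr_cut = 0.25) {
  dat <- inner_join(scores, clinical[c("sample", "sex")], by = "sample")
  dat <- dat[!is.na(dat$sex), , drop = FALSE]
  n_male <- sum(dat$sex == "male")
  n_female <- sum(dat$sex == "female")
  if (min(n_male, n_female) < 10) {
    warn(sprintf("fewer than 10 samples per sex (male=%d, female=%d); low power",
                 n_male, n_female))
  }
  direction_of <- function(stat) {
    ifelse(stat > 0, "female_biased", ifelse(stat < 0, "male_biased", "none"))
  }

  summary_feats <- intersect(c("tmb", "immune_score", "stromal_score", "purity"),
                             names(dat))
  summary_tests <- list_rbind(map(summary_feats, function(f) {
    w <- wrs_test(dat[[f]], dat$sex)
    delta <- median(dat[[f]][dat$sex == "female"]) -
      median(dat[[f]][dat$sex == "male"])
    tibble(feature = f, statistic = w$statistic, p = w$p,
           direction = direction_of(delta))
  }))
  summary_tests$significant <- summary_tests$p < p_cut

  cell_cols <- setdiff(names(scores),
                       c("sample", "tmb", "immune_score", "stromal_score",
                         "estimate_score", "purity"))
  cell_tests <- list_rbind(map(cell_cols, function(f) {
    tt <- welch_t(dat[[f]], dat$sex)
    tibble(feature = f, t_score = tt$t_score, p = tt$p,
           direction = direction_of(tt$t_score))
  }))
  if (nrow(cell_tests) > 0) {
    cell_tests$fdr <- bh_fdr(cell_tests$p)
    cell_tests$significant <- cell_tests$fdr < fdr_cut
  }

  icg_tests <- tibble(feature = character(), t_score = numeric(),
                      p = numeric(), direction = character(),
                      fdr = numeric(), significant = logical())
  if (!is.null(expression) && length(icg_genes) > 0) {
    m <- expr_matrix(expression)
    m <- m[, dat$sample, drop = FALSE]
    known <- intersect(icg_genes, rownames(m))
    if (length(known) < length(icg_genes)) {
      warn(sprintf("%d checkpoint gene(s) absent from the expression matrix; skipped",
                   length(icg_genes) - length(known)))
    }
    if (length(known) > 0) {
      icg_tests <- list_rbind(map(known, function(g) {
        tt <- welch_t(m[g, ], dat$sex)
        tibble(feature = g, t_score = tt$t_score, p = tt$p,
               direction = direction_of(tt$t_score))
      }))
      icg_tests$fdr <- bh_fdr(icg_tests$p)
      icg_tests$significant <- icg_tests$fdr < fdr_cut
    }
  }

  structure(
    list(summary_tests = summary_tests, cell_tests = cell_tests,
         icg_tests = icg_tests, n_male = n_male, n_female = n_female),
    class = "sex_bias_scan"
  )
}

#' Classify a cancer type as strongly or weakly sex-biased
#'
#' Seven binary features feed the call: significant sex bias (P < 0.05) in
#' TMB, immune score, stromal score and tumor purity, plus a non-zero
#' fraction of FDR-significant immune cells, checkpoint genes and immune
#' pathways. A cancer with at least four of the seven features is labeled
#' `strong`, otherwise `weak`.
#'
#' @param tmb_sig,immune_sig,stromal_sig,purity_sig,cells_sig,icg_sig,pathways_sig
#'   Logical scalars (vectorized over cancers).
#' @return Character vector, `"strong"` or `"weak"`.
#' @export
classify_cancer <- function(tmb_sig, immune_sig, stromal_sig, purity_sig,
                            cells_sig, icg_sig, pathways_sig) {
  flags <- cbind(tmb_sig, immune_sig, stromal_sig, purity_sig,
                 cells_sig, icg_sig, pathways_sig)
  if (any(is.na(flags))) input_error("all seven feature flags must be non-missing")
  ifelse(rowSums(flags) >= 4, "strong", "weak")
}

#' Summarise one cohort's sex-bias features and classify it
#'
#' Collapses a [sex_bias_scan()] result (and optionally a pathway GSEA
#' table) into the seven-feature summary used by [classify_cancer()].
#'
#' @param scan A `sex_bias_scan` object.
#' @param pathway_results Optional tibble from [gsea_permutation()] with an
#'   `fdr` column; `NULL` counts the pathway feature as not significant.
#' @param cancer_label Label for the output row.
#' @param fdr_cut FDR threshold for the fraction-type features.
#' @return A one-row tibble with the four P-value flags, the three
#'   significant-feature fractions and flags, and the `group` call.
#' @export
cancer_feature_summary <- function(scan, pathway_results = NULL,
                                   cancer_label = "cohort", fdr_cut = 0.25) {
  st <- scan$summary_tests
  flag_of <- function(f) {
    hit <- st$significant[st$feature == f]
    if (length(hit) == 0) NA else hit
  }
  frac <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0) 0 else mean(tab$fdr < fdr_cut)
  }
  cells_frac <- frac(scan$cell_tests)
  icg_frac <- frac(scan$icg_tests)
  path_frac <- frac(pathway_results)
  out <- tibble(
    cancer_label = cancer_label,
    tmb_sig = flag_of("tmb"),
    immune_sig = flag_of("immune_score"),
    stromal_sig = flag_of("stromal_score"),
    purity_sig = flag_of("purity"),
    cells_frac = cells_frac, cells_sig = cells_frac > 0,
    icg_frac = icg_frac, icg_sig = icg_frac > 0,
    pathways_frac = path_frac, pathways_sig = path_frac > 0
  )
  out$group <- classify_cancer(out$tmb_sig, out$immune_sig, out$stromal_sig,
                               out$purity_sig, out$cells_sig, out$icg_sig,
                               out$pathways_sig)
  out
}
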