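#' Binary gene-mutation matrix with a frequency filter
#'
#' An entry is 1 if the sample carries at least one non-silent mutation in
#' the gene. Genes with mutation frequency strictly greater than `min_freq`
#' (default 5%) across the cohort are retained.
#'
#' @param mutations Mutation tibble.
#' @param samples Cohort sample ids (columns of the matrix).
#' @param min_freq Retention threshold on per-gene mutation frequency.
#' @return A list with `matrix` (genes x samples, 0/1) and `freq` (a tibble
#'   `gene`, `n_mutated`, `freq` for the retained genes). Empty (with a
#'   warning) when no gene passes.
#' @export
mutation_matrix <- function(mutations, samples, min_freq = 0.05) {
  if (length(samples) == 0) input_error("'samples' must be non-empty")
  rec <- mutations[mutations$variant_classification %in% NONSILENT_CLASSES &
                     mutations$sample %in% samples, , drop = FALSE]
  rec <- distinct(rec[c("gene", "sample")])
  genes <- sort(unique(rec$gene))
  mat <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (nrow(rec) > 0) {
    mat[cbind(match(rec$gene, genes), match(rec$sample, samples))] <- 1L
  }
  freq <- rowMeans(mat)
  keep <- freq > min_freq
  if (!any(keep)) {
    warn("no gene exceeds the mutation-frequency threshold; empty matrix")
  }
  mat <- mat[keep, , drop = FALSE]
  list(
    matrix = mat,
    freq = tibble(gene = rownames(mat), n_mutated = as.integer(rowSums(mat)),
                  freq = unname(rowMeans(mat)))
  )
}

#' Sex-biased mutated genes by chi-square test
#'
#' Per gene, a 2x2 Pearson chi-square of mutation status against sex, with
#' Yates continuity correction applied when any expected cell count is below
#' 5; BH FDR across tested genes. Genes mutated in every sample or none
#' (within the matrix) are skipped.
#'
#' @param mut A result of [mutation_matrix()] (or a bare 0/1 matrix).
#' @param clinical Clinical tibble with `sample` and `sex`.
#' @param fdr_cut Significance threshold on the FDR.
#' @param correct Continuity correction: `"auto"` applies Yates when any
#'   expected cell count is below 5; `"always"` / `"never"` force it.
#' @return A tibble per gene: `freq_male`, `freq_female`, `chi2`,
#'   `corrected` (Yates applied), `p`, `fdr`, `direction`
#'   (`male_biased` / `female_biased` when FDR-significant, else `none`).
#' @export
sex_biased_mutations <- function(mut, clinical, fdr_cut = 0.25,
                                 correct = c("auto", "always", "never")) {
  correct <- match.arg(correct)
  mat <- if (is.list(mut) && !is.data.frame(mut)) mut$matrix else mut
  cl <- clinical[match(colnames(mat), clinical$sample), , drop = FALSE]
  if (any(is.na(cl$sex))) input_error("every matrix sample needs a sex label")
  is_male <- cl$sex == "male"
  if (all(is_male) || !any(is_male)) input_error("both sexes must be present")
  rows <- map(rownames(mat), function(g) {
    v <- mat[g, ]
    if (all(v == 1) || all(v == 0)) {
      warn(sprintf("gene '%s' has no mutation-status variance; skipped", g))
      return(NULL)
    }
    tab <- rbind(
      c(sum(v == 1 & is_male), sum(v == 1 & !is_male)),
      c(sum(v == 0 & is_male), sum(v == 0 & !is_male))
    )
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    yates <- switch(correct, auto = any(expected < 5),
                    always = TRUE, never = FALSE)
    res <- suppressWarnings(chisq.test(tab, correct = yates))
    tibble(
      gene = g,
      freq_male = mean(v[is_male]), freq_female = mean(v[!is_male]),
      chi2 = unname(res$statistic), corrected = yates, p = res$p.value
    )
  })
  out <- list_rbind(rows)
  if (nrow(out) == 0) return(out)
  out$fdr <- bh_fdr(out$p)
  out$direction <- ifelse(
    out$fdr >= fdr_cut | out$freq_male == out$freq_female, "none",
    ifelse(out$freq_male > out$freq_female, "male_biased", "female_biased")
  )
  out
}

#' Immune-cell associations of sex-biased mutated genes
#'
#' For each candidate gene, fits a multivariate logistic regression with
#' mutation status (0/1) as outcome and all standardized cell enrichment
#' scores as joint predictors; reports per-cell Wald tests. A positive
#' coefficient means the cell's infiltration is higher in mutated patients,
#' conditional on the other cells.
#'
#' @param mut A [mutation_matrix()] result (or bare 0/1 matrix).
#' @param cell_scores Tibble with `sample` plus one column per cell (other
#'   score columns — `tmb`, `immune_score`, `stromal_score`,
#'   `estimate_score`, `purity` — are ignored).
#' @param biased_genes Genes to model (must be rows of the matrix).
#' @param p_cut Wald significance threshold for the `significant` flag.
#' @return A tibble (`gene`, `cell`, `coefficient`, `p`, `direction`,
#'   `significant`). Genes whose fit does not converge (e.g. perfect
#'   separation) are excluded with a warning.
#' @export
mutation_cell_association <- function(mut, cell_scores, biased_genes,
                                      p_cut = 0.05) {
  mat <- if (is.list(mut) && !is.data.frame(mut)) mut$matrix else mut
  if (!all(biased_genes %in% rownames(mat))) {
    input_error("biased_genes must all be rows of the mutation matrix")
  }
  cells <- setdiff(names(cell_scores),
                   c("sample", "tmb", "immune_score", "stromal_score",
                     "estimate_score", "purity"))
  samples <- intersect(colnames(mat), cell_scores$sample)
  X <- as.matrix(cell_scores[match(samples, cell_scores$sample), cells])
  X <- scale(X)
  rows <- map(biased_genes, function(g) {
    y <- mat[g, samples]
    dat <- data.frame(y = y, X, check.names = FALSE)
    fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial()))
    sep <- any(fit$fitted.values < 1e-8 & y == 1) ||
      any(fit$fitted.values > 1 - 1e-8 & y == 0)
    if (!fit$converged || sep || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)) {
      warn(sprintf("logistic fit for gene '%s' did not converge; excluded", g))
      return(NULL)
    }
    sm <- summary(fit)$coefficients
    keep <- intersect(rownames(sm), colnames(X))
    tibble(
      gene = g, cell = keep,
      coefficient = sm[keep, "Estimate"],
      p = sm[keep, "Pr(>|z|)"]
    )
  })
  out <- list_rbind(rows)
  if (nrow(out) == 0) return(out)
  out$direction <- ifelse(out$coefficient > 0, "up", "down")
  out$significant <- out$p < p_cut
  out
}
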