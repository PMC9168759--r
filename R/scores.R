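#' Per-sample tumor mutational burden
#'
#' TMB is the number of non-silent somatic mutations divided by the length of
#' the coding genome in megabases (38 Mb by convention for whole-exome data).
#' Non-silent classes are nonsense, missense, splice-site, stop-codon
#' read-through, start-codon change, frame-shift indel and in-frame indel.
#'
#' @param mutations Mutation tibble (`sample`, `gene`,
#'   `variant_classification`).
#' @param samples Character vector of cohort sample ids; samples without any
#'   mutation record receive TMB 0 (a warning reports how many).
#' @param coding_mb Coding-region length in Mb used as denominator.
#' @return A tibble with columns `sample`, `n_mutation`, `tmb`.
#' @export
compute_tmb <- function(mutations, samples, coding_mb = TMB_CODING_MB) {
  if (length(samples) == 0) input_error("'samples' must be non-empty")
  nonsil <- mutations[mutations$variant_classification %in% NONSILENT_CLASSES &
                        mutations$sample %in% samples, , drop = FALSE]
  counts <- table(factor(nonsil$sample, levels = samples))
  absent <- setdiff(samples, unique(mutations$sample))
  if (length(absent) > 0) {
    warn(sprintf("%d sample(s) have no mutation records; TMB set to 0", length(absent)))
  }
  tibble(
    sample = samples,
    n_mutation = as.integer(counts),
    tmb = as.numeric(counts) / coding_mb
  )
}

# rank vector for one sample: gene with highest expression gets rank N, ties
# broken by gene token ascending (the earlier token gets the higher rank).
ssgsea_ranks <- function(expr_vec, genes) {
  n <- length(expr_vec)
  ord <- order(-expr_vec, genes)
  rk <- integer(n)
  rk[ord] <- n:1L
  rk
}

# integrated running-sum ES from the ranks of the in-set genes.
# Writing the running sum D(p) = P_in(p) - P_out(p) over list positions p,
# ES = sum_p D(p) collapses to a closed form in the hit ranks because each
# step at position p contributes to N - p + 1 partial sums (= its rank).
ssgsea_es_from_ranks <- function(hit_ranks, n, alpha) {
  m <- length(hit_ranks)
  total <- n * (n + 1) / 2
  in_part <- sum(hit_ranks^(1 + alpha)) / sum(hit_ranks^alpha)
  out_part <- (total - sum(hit_ranks)) / (n - m)
  in_part - out_part
}

#' Single-sample GSEA enrichment score
#'
#' Rank-based per-sample enrichment of a gene set: genes are ordered by
#' decreasing expression within each sample (ties broken by gene identifier
#' for determinism), in-set steps are weighted by `rank^alpha` and the score
#' is the integral (sum over list positions) of the running difference
#' between the in-set and out-of-set empirical distribution functions.
#' The score is invariant under any strictly monotone transform of a
#' sample's expression vector.
#'
#' @param expression Wide expression tibble (`gene` + sample columns),
#'   typically `log2(FPKM + 1)`.
#' @param gene_set Character vector of member genes (or a gene-set tibble).
#' @param alpha Rank-weighting exponent (0 = unweighted; 0.25 default).
#' @return A tibble with columns `sample`, `es`.
#' @export
ssgsea_score <- function(expression, gene_set, alpha = 0.25) {
  m <- expr_matrix(expression)
  set <- as_gene_set(gene_set)
  members <- intersect(rownames(m), set)
  if (length(members) == 0) {
    abort("gene set has no members in the expression matrix",
          class = "sextme_empty_overlap")
  }
  if (length(members) == nrow(m)) {
    abort("gene set covers every gene in the matrix (degenerate)",
          class = "sextme_degenerate_set")
  }
  idx <- match(members, rownames(m))
  genes <- rownames(m)
  es <- vapply(seq_len(ncol(m)), function(j) {
    rk <- ssgsea_ranks(m[, j], genes)
    ssgsea_es_from_ranks(rk[idx], nrow(m), alpha)
  }, numeric(1))
  tibble(sample = colnames(m), es = es)
}

#' Immune-cell infiltration scores for a signature collection
#'
#' Applies [ssgsea_score()] to each cell-type signature. Signatures without
#' any gene in the matrix are skipped with a warning (their column is absent
#' from the result).
#'
#' @param expression Wide expression tibble.
#' @param signatures Long gene-set tibble (`set`, `description`, `gene`) or a
#'   named list of gene vectors.
#' @param alpha Rank-weighting exponent passed to [ssgsea_score()].
#' @return A tibble with a `sample` column and one score column per
#'   signature; the per-signature overlap counts are attached as the
#'   `"overlap"` attribute.
#' @export
cell_infiltration <- function(expression, signatures, alpha = 0.25) {
  sets <- gene_set_list(signatures)
  if (length(sets) == 0) input_error("empty signature collection")
  m <- expr_matrix(expression)
  genes <- rownames(m)
  n <- nrow(m)
  # one ordering per sample, shared across all signatures
  rk <- apply(m, 2, ssgsea_ranks, genes = genes)
  overlap <- map_dbl(sets, ~ length(intersect(genes, .x)))
  out <- tibble(sample = colnames(m))
  for (name in names(sets)) {
    idx <- match(intersect(genes, sets[[name]]), genes)
    if (length(idx) == 0) {
      warn(sprintf("signature '%s' has no genes in the matrix; column omitted", name))
      next
    }
    if (length(idx) == n) {
      warn(sprintf("signature '%s' covers every gene; column omitted", name))
      next
    }
    out[[name]] <- vapply(seq_len(ncol(m)), function(j) {
      ssgsea_es_from_ranks(rk[idx, j], n, alpha)
    }, numeric(1))
  }
  attr(out, "overlap") <- overlap
  out
}

#' ESTIMATE-style immune/stromal scores and tumor purity
#'
#' Immune and stromal scores are single-sample enrichment scores (alpha =
#' 0.25) of the supplied immune and stromal gene sets; their sum is the
#' ESTIMATE score, from which tumor purity is inferred via
#' [tumor_purity()].
#'
#' @param expression Wide expression tibble.
#' @param stromal_set,immune_set Gene vectors (or gene-set tibbles).
#' @return A tibble with columns `sample`, `immune_score`, `stromal_score`,
#'   `estimate_score`, `purity`.
#' @export
estimate_scores <- function(expression, stromal_set, immune_set) {
  imm <- ssgsea_score(expression, immune_set, alpha = 0.25)
  str <- ssgsea_score(expression, stromal_set, alpha = 0.25)
  out <- tibble(
    sample = imm$sample,
    immune_score = imm$es,
    stromal_score = str$es
  )
  out$estimate_score <- out$immune_score + out$stromal_score
  out$purity <- tumor_purity(out$estimate_score)
  out
}

#' Tumor purity from the ESTIMATE score
#'
#' Applies the published ESTIMATE non-linear calibration
#' `purity = cos(0.6049872018 + 0.0001467884 * estimate_score)`, clamped to
#' \[0, 1\]. Scores whose cosine argument leaves `[0, pi]` (where the curve
#' is monotone and purity well defined) are flagged with a warning.
#'
#' @param estimate_score Numeric vector of ESTIMATE scores.
#' @return Numeric vector of purities in \[0, 1\].
#' @export
tumor_purity <- function(estimate_score) {
  arg <- 0.6049872018 + 0.0001467884 * estimate_score
  out_of_range <- arg < 0 | arg > pi
  if (any(out_of_range)) {
    warn(sprintf("%d ESTIMATE score(s) fall outside the calibrated purity range; purity clamped",
                 sum(out_of_range)))
  }
  pmin(pmax(cos(arg), 0), 1)
}

#' Assemble the per-sample tumor-microenvironment feature table
#'
#' Convenience wrapper producing the full `SampleScores` table: TMB,
#' immune/stromal/ESTIMATE scores, purity, and one enrichment column per
#' cell-type signature.
#'
#' @param expression Wide expression tibble (`log2(FPKM + 1)`).
#' @param mutations Mutation tibble.
#' @param signatures Cell-type signature collection (long tibble or list).
#' @param stromal_set,immune_set Gene sets for the ESTIMATE-style scores.
#' @param coding_mb TMB denominator in Mb.
#' @return A tibble keyed by `sample` with columns `tmb`, `immune_score`,
#'   `stromal_score`, `estimate_score`, `purity`, then one column per cell.
#' @export
compute_sample_scores <- function(expression, mutations, signatures,
                                  stromal_set, immune_set,
                                  coding_mb = TMB_CODING_MB) {
  samples <- expr_samples(expression)
  tmb <- compute_tmb(mutations, samples, coding_mb = coding_mb)
  est <- estimate_scores(expression, stromal_set, immune_set)
  cells <- cell_infiltration(expression, signatures)
  tmb |>
    left_join(est, by = "sample") |>
    left_join(cells, by = "sample") |>
    select(-"n_mutation")
}
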