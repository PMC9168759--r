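# vectorized per-gene Welch t (female - male) for a genes x samples matrix;
# zero-variance-in-both-groups genes get t = 0.
welch_t_matrix <- function(m, is_female) {
  nf <- sum(is_female)
  nm <- sum(!is_female)
  if (nf < 2 || nm < 2) input_error("need at least 2 samples per sex")
  mf <- m[, is_female, drop = FALSE]
  mm <- m[, !is_female, drop = FALSE]
  muf <- rowMeans(mf)
  mum <- rowMeans(mm)
  vf <- rowSums((mf - muf)^2) / (nf - 1)
  vm <- rowSums((mm - mum)^2) / (nm - 1)
  se2 <- vf / nf + vm / nm
  t <- ifelse(se2 == 0, 0, (muf - mum) / sqrt(se2))
  t
}

#' Rank genes by the sex-difference t-score
#'
#' Computes a Welch t statistic (female minus male) per gene and returns the
#' genes ordered by decreasing t (ties broken by gene identifier). This is
#' the ranked list GSEA walks: female-biased genes at the top, male-biased
#' at the bottom.
#'
#' @param expression Wide expression tibble.
#' @param clinical Clinical tibble with `sample` and `sex`.
#' @return A tibble (`gene`, `t_score`) sorted by decreasing `t_score`;
#'   zero-variance genes carry `t_score` 0 and are counted in the
#'   `"n_flat"` attribute.
#' @export
rank_genes_by_t <- function(expression, clinical) {
  m <- expr_matrix(expression)
  cl <- clinical[match(colnames(m), clinical$sample), , drop = FALSE]
  if (any(is.na(cl$sex))) input_error("every expression sample needs a sex label")
  t <- welch_t_matrix(m, cl$sex == "female")
  ord <- order(-t, rownames(m))
  out <- tibble(gene = rownames(m)[ord], t_score = t[ord])
  attr(out, "n_flat") <- sum(t == 0)
  out
}

# signed maximal-deviation ES from sorted hit positions and their |t| weights.
# Between hits the running sum falls linearly, so the extrema can only occur
# immediately after a hit or immediately before one.
gsea_es_core <- function(hit_pos, hit_w, n) {
  m <- length(hit_pos)
  miss_step <- 1 / (n - m)
  wsum <- sum(hit_w)
  hit_w <- if (wsum == 0) rep(1 / m, m) else hit_w / wsum
  cum_w <- cumsum(hit_w)
  after <- cum_w - (hit_pos - seq_len(m)) * miss_step
  before <- c(0, cum_w[-m]) - (hit_pos - seq_len(m)) * miss_step
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' GSEA enrichment score on a ranked gene list
#'
#' Weighted Kolmogorov-Smirnov running sum: walking the ranked list, in-set
#' genes add `|t|^weight` (normalized over set hits), out-of-set genes
#' subtract `1 / (N - n_hits)`; the score is the running-sum value of
#' maximal absolute deviation, keeping its sign. Positive scores mean
#' enrichment at the top (female-biased under the female-minus-male t
#' convention).
#'
#' @param ranked Tibble from [rank_genes_by_t()] (`gene`, `t_score`, sorted).
#' @param gene_set Character vector (or gene-set tibble).
#' @param weight Exponent on `|t|` for hit steps (1 = classic weighted GSEA,
#'   0 = unweighted KS).
#' @return The signed enrichment score (scalar).
#' @export
gsea_es <- function(ranked, gene_set, weight = 1) {
  set <- as_gene_set(gene_set)
  hit <- ranked$gene %in% set
  m <- sum(hit)
  if (m == 0 || m == nrow(ranked)) {
    abort("gene set overlap with the ranked list is empty or complete",
          class = "sextme_degenerate_set")
  }
  gsea_es_core(which(hit), abs(ranked$t_score[hit])^weight, nrow(ranked))
}

#' Phenotype-permutation GSEA over a pathway collection
#'
#' For each pathway, the observed enrichment score on the female-minus-male
#' t ranking is referenced to a null distribution obtained by permuting sex
#' labels and recomputing the full t ranking each time (gene-gene
#' correlation preserved). P-values use an add-one estimator over the
#' same-sign null pool; the normalized enrichment score (NES) divides the
#' observed score by the mean |null ES| of matching sign; FDR follows the
#' sign-matched ratio-of-tails construction on the pooled null NES, capped
#' at 1.
#'
#' @param expression Wide expression tibble.
#' @param clinical Clinical tibble with `sample` and `sex`.
#' @param pathways Gene-set collection (long tibble or named list).
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Integer seed; results are bit-reproducible given it.
#' @param weight Hit-step exponent, as in [gsea_es()].
#' @param min_overlap Pathways with fewer overlapping genes are skipped.
#' @return A tibble with one row per scored pathway: `pathway`, `n_genes`,
#'   `es`, `nes`, `p`, `fdr`, `direction`.
#' @export
gsea_permutation <- function(expression, clinical, pathways, n_perm = 1000,
                             seed = 1, weight = 1, min_overlap = 3) {
  if (n_perm < 100) input_error("n_perm must be at least 100")
  m <- expr_matrix(expression)
  cl <- clinical[match(colnames(m), clinical$sample), , drop = FALSE]
  is_female <- cl$sex == "female"
  if (any(is.na(is_female))) input_error("every expression sample needs a sex label")
  sets <- gene_set_list(pathways)
  genes <- rownames(m)
  n <- length(genes)
  sets <- map(sets, ~ intersect(.x, genes))
  keep <- map_lgl(sets, ~ length(.x) >= min_overlap && length(.x) < n)
  if (any(!keep)) {
    warn(sprintf("%d pathway(s) skipped for insufficient overlap", sum(!keep)))
  }
  sets <- sets[keep]
  if (length(sets) == 0) input_error("no pathway has usable overlap")
  set_idx <- map(sets, ~ match(.x, genes))

  es_for_t <- function(t) {
    ord <- order(-t, genes)
    pos_of <- integer(n)
    pos_of[ord] <- seq_len(n)
    absw <- abs(t)^weight
    vapply(set_idx, function(idx) {
      p <- sort(pos_of[idx])
      gsea_es_core(p, absw[ord][p], n)
    }, numeric(1))
  }

  t_obs <- welch_t_matrix(m, is_female)
  es_obs <- unname(es_for_t(t_obs))

  null_es <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      es_for_t(welch_t_matrix(m, sample(is_female)))
    }, numeric(length(sets)))
  })
  null_es <- matrix(null_es, nrow = length(sets))

  pos_mean <- apply(null_es, 1, function(e) {
    v <- e[e >= 0]
    if (length(v) == 0) NA_real_ else mean(v)
  })
  neg_mean <- apply(null_es, 1, function(e) {
    v <- e[e < 0]
    if (length(v) == 0) NA_real_ else mean(abs(v))
  })
  res <- imap(seq_along(sets), function(i, nm) {
    e <- es_obs[i]
    pool <- null_es[i, ]
    same <- if (e >= 0) pool[pool >= 0] else pool[pool < 0]
    p <- (1 + sum(abs(same) >= abs(e))) / (1 + length(same))
    denom <- if (e >= 0) pos_mean[i] else neg_mean[i]
    nes <- if (is.na(denom) || denom == 0) NA_real_ else e / denom
    tibble(pathway = names(sets)[i], n_genes = length(sets[[i]]),
           es = e, nes = nes, p = p)
  })
  res <- list_rbind(res)

  # pooled null NES for the ratio-of-tails FDR
  null_nes <- null_es / ifelse(null_es >= 0,
                               matrix(pos_mean, nrow(null_es), ncol(null_es)),
                               matrix(neg_mean, nrow(null_es), ncol(null_es)))
  null_nes <- as.numeric(null_nes)
  null_nes <- null_nes[is.finite(null_nes)]
  res$fdr <- vapply(seq_len(nrow(res)), function(i) {
    nes <- res$nes[i]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      null_side <- null_nes[null_nes >= 0]
      obs_side <- res$nes[!is.na(res$nes) & res$nes >= 0]
      num <- mean(null_side >= nes)
      den <- mean(obs_side >= nes)
    } else {
      null_side <- null_nes[null_nes < 0]
      obs_side <- res$nes[!is.na(res$nes) & res$nes < 0]
      num <- mean(null_side <= nes)
      den <- mean(obs_side <= nes)
    }
    if (den == 0) return(1)
    min(1, num / den)
  }, numeric(1))
  res$direction <- ifelse(res$es > 0, "female_biased", "male_biased")
  res
}
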