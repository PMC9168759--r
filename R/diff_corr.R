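#' Spearman rank correlation with optional exact significance
#'
#' Rank correlation with average ranks for ties. By default significance uses
#' the t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees
#' of freedom (two-sided). With `exact = TRUE` (n <= 8) the two-sided
#' p-value is computed by full enumeration of all `n!` orderings of one
#' vector, counting orderings whose |r| is at least the observed |r|.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param exact Use full-permutation significance (only for n <= 8).
#' @return A one-row tibble with `r`, `p`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n) input_error("x and y must have equal length")
  if (n < 4) input_error("spearman_cor requires n >= 4")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant vector",
          class = "sextme_constant_vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  r <- cor(rx, ry)
  if (exact) {
    if (n > 8) input_error("exact mode supported only for n <= 8")
    perms <- all_permutations(n)
    rs <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rs) >= abs(r) - 1e-12)
    return(tibble(r = r, p = p, n = n, method = "exact"))
  }
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(r = r, p = p, n = n, method = "t-approximation")
}

#' Two-sided t-approximation significance for a Spearman coefficient
#'
#' Significance of an observed rank correlation given only `r` and `n`,
#' via `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param r Spearman coefficient, `|r| <= 1`.
#' @param n Number of paired observations (> 2).
#' @return Two-sided p-value.
#' @export
spearman_p <- function(r, n) {
  if (n <= 2) input_error("n must exceed 2")
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}

# all n! permutations of 1..n as rows (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Fisher z-transformation of a correlation coefficient
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, mapping a correlation to a
#' scale on which its sampling distribution is approximately normal with
#' variance `1 / (n - 3)`.
#'
#' @param r Correlation coefficient(s), `|r| < 1`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) {
    abort("fisher_z requires |r| < 1", class = "sextme_domain_error")
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Compare a male and a female correlation via the Fisher transformation
#'
#' Both coefficients are Fisher-transformed and their difference is scaled to
#' a standard-normal score,
#' `z = (z_male - z_female) / sqrt(1/(n1 - 3) + 1/(n2 - 3))`.
#' The default significance convention is the upper-tail probability of the
#' absolute score, `p = 1 - pnorm(|z|)`; `two_sided = TRUE` doubles it.
#'
#' @param r_male,r_female Spearman coefficients, `|r| < 1`.
#' @param n1,n2 Male and female sample sizes, both > 3.
#' @param two_sided Use the two-sided convention instead.
#' @return A one-row tibble with `r_male`, `r_female`, `n1`, `n2`, `z_male`,
#'   `z_female`, `z_score`, `p_diff`.
#' @export
compare_correlations <- function(r_male, n1, r_female, n2, two_sided = FALSE) {
  if (any(c(n1, n2) <= 3)) input_error("both group sizes must exceed 3")
  zm <- fisher_z(r_male)
  zf <- fisher_z(r_female)
  z <- (zm - zf) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- (1 - pnorm(abs(z))) * (if (two_sided) 2 else 1)
  tibble(r_male = r_male, r_female = r_female, n1 = n1, n2 = n2,
         z_male = zm, z_female = zf, z_score = z, p_diff = p)
}

#' Sex-differential correlation of TMB with every TME feature
#'
#' For each tumor-microenvironment feature (immune score, stromal score,
#' purity, and each cell enrichment column), computes the Spearman
#' correlation with TMB within each sex and compares the two coefficients
#' with [compare_correlations()]. Features flagged at `p_diff < p_cut`.
#'
#' @param scores Per-sample score tibble ([compute_sample_scores()]).
#' @param clinical Clinical tibble with `sample` and `sex`.
#' @param two_sided Sidedness convention for the comparison.
#' @param p_cut Flagging threshold on `p_diff`.
#' @return A tibble with one row per feature: `feature`, `r_male`, `p_male`,
#'   `r_female`, `p_female`, `n1`, `n2`, `z_score`, `p_diff`, `significant`.
#'   Features whose correlation is undefined in either sex are dropped with
#'   a warning.
#' @export
diffcorr_scan <- function(scores, clinical, two_sided = FALSE, p_cut = 0.05) {
  dat <- inner_join(scores, clinical[c("sample", "sex")], by = "sample")
  dat <- dat[!is.na(dat$sex), , drop = FALSE]
  male <- dat[dat$sex == "male", , drop = FALSE]
  female <- dat[dat$sex == "female", , drop = FALSE]
  if (nrow(male) < 4 || nrow(female) < 4) {
    input_error("diffcorr_scan needs at least 4 patients per sex")
  }
  feats <- setdiff(names(scores), c("sample", "tmb", "estimate_score"))
  rows <- map(feats, function(f) {
    res <- tryCatch({
      sm <- spearman_cor(male$tmb, male[[f]])
      sf <- spearman_cor(female$tmb, female[[f]])
      cmp <- compare_correlations(sm$r, nrow(male), sf$r, nrow(female),
                                  two_sided = two_sided)
      tibble(feature = f, r_male = sm$r, p_male = sm$p,
             r_female = sf$r, p_female = sf$p,
             n1 = nrow(male), n2 = nrow(female),
             z_score = cmp$z_score, p_diff = cmp$p_diff)
    }, error = function(e) {
      warn(sprintf("feature '%s' skipped: %s", f, conditionMessage(e)))
      NULL
    })
    res
  })
  out <- list_rbind(rows)
  if (nrow(out) > 0) out$significant <- out$p_diff < p_cut
  out
}
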