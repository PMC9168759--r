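#' Sex-stratified AUC of TMB for immune-checkpoint-blockade response
#'
#' Within each sex, the area under the ROC curve for TMB as a classifier of
#' responder versus non-responder, computed through the Mann-Whitney
#' identity: the fraction of (responder, non-responder) pairs in which the
#' responder has the higher TMB, with half credit for ties.
#'
#' @param scores Tibble with `sample` and `tmb` (e.g.
#'   [compute_sample_scores()] output).
#' @param clinical Clinical tibble with `sample`, `sex`, `response`
#'   (`responder` / `nonresponder`; missing responses are dropped).
#' @return An object of class `tmb_auc`: tibble with one row per scored sex
#'   (`sex`, `n_responders`, `n_nonresponders`, `auc`); ROC curve points are
#'   attached as the `"roc"` attribute (tibble `sex`, `fpr`, `tpr`,
#'   `threshold`). Strata missing a class are skipped with a warning.
#' @export
tmb_auc <- function(scores, clinical) {
  dat <- inner_join(scores[c("sample", "tmb")],
                    clinical[c("sample", "sex", "response")], by = "sample")
  dat <- dat[!is.na(dat$response) & !is.na(dat$sex), , drop = FALSE]
  rows <- list()
  roc <- list()
  for (s in c("male", "female")) {
    d <- dat[dat$sex == s, , drop = FALSE]
    pos <- d$tmb[d$response == "responder"]
    neg <- d$tmb[d$response == "nonresponder"]
    if (length(pos) == 0 || length(neg) == 0) {
      warn(sprintf("%s stratum lacks a response class; skipped", s))
      next
    }
    rk <- rank(c(pos, neg))
    u <- sum(rk[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
    auc <- u / (length(pos) * length(neg))
    rows[[s]] <- tibble(sex = s, n_responders = length(pos),
                        n_nonresponders = length(neg), auc = auc)
    thr <- c(Inf, sort(unique(d$tmb), decreasing = TRUE))
    roc[[s]] <- list_rbind(map(thr, function(t) {
      tibble(sex = s, threshold = t,
             fpr = mean(neg >= t), tpr = mean(pos >= t))
    }))
  }
  out <- list_rbind(rows)
  attr(out, "roc") <- list_rbind(roc)
  class(out) <- c("tmb_auc", class(out))
  out
}
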