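#' Univariate Cox proportional-hazards fit for one covariate
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) and reports the
#' log-hazard coefficient, hazard ratio, standard error and Wald p-value.
#'
#' @param time Follow-up times (days).
#' @param event Event indicator (1 = death, 0 = censored).
#' @param covariate Numeric covariate.
#' @param covariate_name Label used in the output.
#' @return A one-row tibble: `covariate`, `beta`, `hr`, `se`, `wald_p`, `n`,
#'   `n_events`, `converged`.
#' @export
cox_univariate <- function(time, event, covariate, covariate_name = "covariate") {
  if (sum(event) < 1) abort("no events in the stratum", class = "sextme_no_events")
  if (sd(covariate) == 0) input_error("constant covariate")
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ covariate,
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)))
  sm <- summary(fit)
  converged <- is.finite(sm$coefficients[1, "se(coef)"]) &&
    abs(coef(fit)[1]) < 15
  tibble(
    covariate = covariate_name,
    beta = unname(coef(fit)[1]),
    hr = unname(exp(coef(fit)[1])),
    se = sm$coefficients[1, "se(coef)"],
    wald_p = sm$coefficients[1, "Pr(>|z|)"],
    n = length(time), n_events = sum(event),
    converged = converged
  )
}

#' Build a sex-specific prognostic immune-cell signature
#'
#' Within one sex stratum, screens every cell enrichment column with a
#' univariate Cox model; cells with Wald p below `p_cut` form the signature,
#' keeping their univariate coefficients as the risk-score weights.
#'
#' @param cell_scores Tibble with `sample` plus cell columns.
#' @param clinical Clinical tibble with `sample`, `sex`, `os_time`,
#'   `os_event`.
#' @param sex `"male"` or `"female"`.
#' @param p_cut Wald p threshold for signature membership.
#' @return An object of class `prognostic_signature`: list with `sex`,
#'   `cox` (all univariate fits), and `signature` (tibble `cell`, `beta`
#'   restricted to significant cells; empty with a warning when none pass).
#' @export
build_signature <- function(cell_scores, clinical, sex, p_cut = 0.05) {
  sex <- match.arg(sex, c("male", "female"))
  cl <- clinical[!is.na(clinical$sex) & clinical$sex == sex &
                   !is.na(clinical$os_time) & !is.na(clinical$os_event), ,
                 drop = FALSE]
  dat <- inner_join(cell_scores, cl[c("sample", "os_time", "os_event")],
                    by = "sample")
  if (nrow(dat) < 10 || sum(dat$os_event) < 5) {
    warn(sprintf("%s stratum has %d patients / %d events; Cox screen under-powered",
                 sex, nrow(dat), sum(dat$os_event)))
  }
  cells <- setdiff(names(cell_scores),
                   c("sample", "tmb", "immune_score", "stromal_score",
                     "estimate_score", "purity"))
  cox <- list_rbind(map(cells, function(cell) {
    tryCatch(
      cox_univariate(dat$os_time, dat$os_event, dat[[cell]], cell),
      error = function(e) {
        warn(sprintf("cell '%s' skipped in Cox screen: %s", cell,
                     conditionMessage(e)))
        NULL
      }
    )
  }))
  sig <- cox[cox$converged & cox$wald_p < p_cut, c("covariate", "beta")]
  names(sig) <- c("cell", "beta")
  if (nrow(sig) == 0) {
    warn(sprintf("no prognostic cells at p < %g in the %s stratum", p_cut, sex))
  }
  structure(list(sex = sex, cox = cox, signature = sig),
            class = "prognostic_signature")
}

#' Risk scores and median-split risk groups from a signature
#'
#' The risk score is the signature-weighted sum of a patient's cell
#' infiltration levels, `sum_k beta_k * a_k`. Patients are split at the
#' median of the stratum's scores: strictly above the median is high-risk;
#' ties at the median go to low-risk.
#'
#' @param signature A `prognostic_signature` (or a tibble `cell`, `beta`).
#' @param cell_scores Tibble with `sample` plus the signature's cell columns.
#' @return A tibble (`sample`, `risk_score`, `group`) with `group` a factor
#'   low/high. Errors if the signature is empty or a cell column is missing.
#' @export
risk_score <- function(signature, cell_scores) {
  sig <- if (inherits(signature, "prognostic_signature")) signature$signature
         else signature
  if (is.null(sig) || nrow(sig) == 0) {
    input_error("empty signature: risk stratification refused")
  }
  missing <- setdiff(sig$cell, names(cell_scores))
  if (length(missing) > 0) {
    input_error(sprintf("cell column(s) missing from scores: %s",
                        paste(missing, collapse = ", ")))
  }
  a <- as.matrix(cell_scores[sig$cell])
  score <- as.numeric(a %*% sig$beta)
  med <- median(score)
  tibble(
    sample = cell_scores$sample,
    risk_score = score,
    group = factor(ifelse(score > med, "high", "low"), levels = c("low", "high"))
  )
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimates per group and the standard two-group log-rank
#' chi-square (hypergeometric variance, 1 df).
#'
#' @param time Follow-up times.
#' @param event Event indicators (0/1).
#' @param groups Two-level grouping.
#' @return A list with `curves` (tibble `group`, `time`, `n_risk`,
#'   `n_event`, `survival`), `chi2`, `p`.
#' @export
km_logrank <- function(time, event, groups) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    input_error("km_logrank needs two non-empty groups")
  }
  sf <- survival::survfit(survival::Surv(time, event) ~ g)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- tibble(
    group = sub("^g=", "", strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    survival = sf$surv
  )
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
  chi2 <- sd_$chisq
  list(curves = curves, chi2 = chi2, p = stats::pchisq(chi2, df = 1,
                                                       lower.tail = FALSE))
}

#' Multivariable Cox adjustment of the risk score
#'
#' Joint Efron partial-likelihood fit of the risk score together with
#' clinical covariates (age, ordinal stage by default). Patients missing a
#' covariate are dropped from this fit only.
#'
#' @param time,event Survival outcome.
#' @param covariates Data frame / tibble of numeric covariate columns
#'   (e.g. `risk_score`, `age`, `stage` already encoded as ordinal).
#' @return A tibble with one row per covariate (`beta`, `hr`, `se`,
#'   `wald_p`, `n`, `n_events`). Errors on a rank-deficient design, naming
#'   the offending columns.
#' @export
cox_multivariable <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  keep <- complete.cases(covariates) & !is.na(time) & !is.na(event)
  covariates <- covariates[keep, , drop = FALSE]
  time <- time[keep]; event <- event[keep]
  X <- as.matrix(covariates)
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    abort(sprintf("collinear covariates among: %s",
                  paste(colnames(X), collapse = ", ")),
          class = "sextme_collinearity")
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ X, ties = "efron",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  sm <- summary(fit)$coefficients
  tibble(
    covariate = colnames(X),
    beta = unname(coef(fit)),
    hr = unname(exp(coef(fit))),
    se = sm[, "se(coef)"],
    wald_p = sm[, "Pr(>|z|)"],
    n = length(time), n_events = sum(event)
  )
}

#' Convert stage labels to ordinal integers
#'
#' Maps roman or arabic stage labels (`I`..`IV`, `Stage I`, `1`..`4`) to
#' integers 1-4; unmatched labels become `NA`.
#'
#' @param stage Character vector of stage labels.
#' @return Integer vector.
#' @export
stage_ordinal <- function(stage) {
  s <- toupper(trimws(sub("(?i)^stage\\s*", "", stage, perl = TRUE)))
  map_ <- c("I" = 1L, "II" = 2L, "III" = 3L, "IV" = 4L,
            "1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L)
  out <- unname(map_[s])
  out
}
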