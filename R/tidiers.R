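#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a sex-bias scan into one long table
#'
#' @param x A `sex_bias_scan` object.
#' @param ... Unused.
#' @return A tibble stacking the summary, cell and ICG test families with a
#'   `family` column.
#' @method tidy sex_bias_scan
#' @export
tidy.sex_bias_scan <- function(x, ...) {
  bind_rows(
    mutate(x$summary_tests, family = "summary"),
    mutate(x$cell_tests, family = "cells"),
    mutate(x$icg_tests, family = "icg")
  )
}

#' @rdname tidy.sex_bias_scan
#' @return For `glance()`: a one-row tibble with per-family significant
#'   fractions and the sex counts.
#' @method glance sex_bias_scan
#' @export
glance.sex_bias_scan <- function(x, ...) {
  frac <- function(tab) if (nrow(tab) == 0) NA_real_ else mean(tab$significant)
  tibble(
    n_male = x$n_male, n_female = x$n_female,
    summary_sig_frac = frac(x$summary_tests),
    cells_sig_frac = frac(x$cell_tests),
    icg_sig_frac = frac(x$icg_tests)
  )
}

#' Tidy methods for prognostic signatures
#'
#' @param x A `prognostic_signature`.
#' @param ... Unused.
#' @return `tidy()` returns the full univariate Cox screen; `glance()` a
#'   one-row summary (stratum, signature size).
#' @method tidy prognostic_signature
#' @export
tidy.prognostic_signature <- function(x, ...) {
  mutate(x$cox, in_signature = .data$covariate %in% x$signature$cell,
         sex = x$sex)
}

#' @rdname tidy.prognostic_signature
#' @method glance prognostic_signature
#' @export
glance.prognostic_signature <- function(x, ...) {
  tibble(sex = x$sex, n_cells_screened = nrow(x$cox),
         n_prognostic = nrow(x$signature))
}

#' @export
print.prognostic_signature <- function(x, ...) {
  cat(sprintf("<prognostic_signature> %s stratum: %d/%d cells at Wald p < 0.05\n",
              x$sex, nrow(x$signature), nrow(x$cox)))
  if (nrow(x$signature) > 0) print(x$signature)
  invisible(x)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d genes x %d samples, %d mutation records, %d signatures\n",
              nrow(x$expression), length(expr_samples(x$expression)),
              nrow(x$mutations), length(unique(x$signatures$set))))
  invisible(x)
}
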