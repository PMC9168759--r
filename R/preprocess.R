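#' Assemble an analysis cohort by filtering samples
#'
#' Retains samples that (i) have sex recorded, (ii) are aged 18 to 85
#' inclusive, and (iii) carry at least moderate immune infiltration
#' (`immune_infiltrated` flag; this flag stands in for an upstream
#' deconvolution-based inclusion call and defaults to `TRUE` when the column
#' is entirely missing, with a warning). Expression columns and mutation
#' records are restricted to the retained samples. Samples with missing age
#' are retained (only an out-of-range age excludes).
#'
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param expression Wide expression tibble; only samples present here enter
#'   the cohort.
#' @param mutations Mutation tibble (see [read_maf()]); may contain samples
#'   without expression, which are dropped.
#' @param cancer_label Optional label carried through to outputs.
#' @return An object of class `sextme_cohort`: a list with elements
#'   `expression`, `mutations`, `clinical`, `cancer_label`, and
#'   `filter_report` (a tibble of per-reason drop counts).
#' @export
filter_samples <- function(clinical, expression, mutations,
                           cancer_label = "cohort") {
  stopifnot(is.data.frame(clinical), is.data.frame(expression))
  expr_ids <- expr_samples(expression)
  cl <- clinical
  cl$sample <- trimws(cl$sample)
  if (all(is.na(cl$immune_infiltrated))) {
    warn("no immune-infiltration flags supplied; assuming all samples pass")
    cl$immune_infiltrated <- TRUE
  }
  in_expr <- cl$sample %in% expr_ids
  has_sex <- !is.na(cl$sex)
  age_ok <- is.na(cl$age) | (cl$age >= 18 & cl$age <= 85)
  infiltrated <- !is.na(cl$immune_infiltrated) & cl$immune_infiltrated
  keep <- in_expr & has_sex & age_ok & infiltrated
  report <- tibble(
    reason = c("no_expression", "missing_sex", "age_out_of_range",
               "not_immune_infiltrated", "retained"),
    n = c(sum(!in_expr), sum(in_expr & !has_sex),
          sum(in_expr & has_sex & !age_ok),
          sum(in_expr & has_sex & age_ok & !infiltrated),
          sum(keep))
  )
  if (!any(keep)) input_error("no samples retained after cohort filters")
  cl <- cl[keep, , drop = FALSE]
  expr <- expression[c("gene", cl$sample)]
  mut <- mutations
  if (!is.null(mut)) {
    mut$sample <- trimws(mut$sample)
    mut <- mut[mut$sample %in% cl$sample, , drop = FALSE]
  }
  n_sex <- table(cl$sex)
  if (any(n_sex < 1)) input_error("cohort requires at least one sample of each sex")
  if (any(n_sex < 10)) {
    warn(sprintf("fewer than 10 samples in a sex stratum (male=%d, female=%d); sex-bias calls will be under-powered",
                 n_sex[["male"]], n_sex[["female"]]))
  }
  structure(
    list(expression = expr, mutations = mut, clinical = cl,
         cancer_label = cancer_label, filter_report = report),
    class = "sextme_cohort"
  )
}

#' Filter low-expressed genes and log-transform
#'
#' Removes genes whose fraction of zero values across samples is strictly
#' greater than `zero_fraction_threshold` (default 0.9, i.e. genes with more
#' than 90% zeros), then transforms the surviving FPKM values to
#' `log2(value + 1)`.
#'
#' @param expression Wide expression tibble of raw (pre-log) FPKM values.
#' @param zero_fraction_threshold Zero-fraction above which a gene is dropped.
#' @return A wide expression tibble of `log2(FPKM + 1)` values.
#' @export
filter_genes <- function(expression, zero_fraction_threshold = 0.9) {
  m <- expr_matrix(expression)
  if (any(!is.finite(m)) || any(m < 0)) {
    input_error("expression values must be finite and non-negative FPKM")
  }
  zero_frac <- rowMeans(m == 0)
  keep <- zero_frac <= zero_fraction_threshold
  if (!any(keep)) input_error("all genes removed by the zero-expression filter")
  expr_tibble(log2(m[keep, , drop = FALSE] + 1))
}
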