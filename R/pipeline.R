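#' Run the full sex-difference microenvironment analysis
#'
#' Wires every stage together on one cohort: sample filters, gene filter and
#' log-transform, per-sample scoring (TMB, immune/stromal/purity, cell
#' enrichment), sex-bias tests, differential TMB correlations, optional
#' pathway GSEA, sex-biased mutations and their cell associations,
#' sex-stratified prognostic signatures with risk-group survival, optional
#' checkpoint-blockade AUC, and the strong/weak classification. Any stage
#' failure aborts with the stage name; results computed so far are kept in
#' the error's `partial` field.
#'
#' @param expression Wide expression tibble of raw FPKM values.
#' @param mutations Mutation tibble.
#' @param clinical Clinical tibble.
#' @param signatures Cell-signature collection (long tibble or list).
#' @param estimate_sets Named list with `immune` and `stromal` gene vectors.
#' @param icg_genes Optional checkpoint gene list.
#' @param pathways Optional pathway collection for GSEA.
#' @param p_cut,fdr_cut,min_mut_freq,zero_frac Thresholds (defaults 0.05,
#'   0.25, 0.05, 0.9).
#' @param n_perm,seed GSEA permutation settings.
#' @param two_sided Sidedness convention for the differential correlations.
#' @param cancer_label Cohort label.
#' @param out_dir Optional directory; when given, every stage table is
#'   written as TSV together with a `manifest.tsv`.
#' @return An object of class `sextme_run`: list of stage outputs
#'   (`cohort`, `scores`, `sex_bias`, `diff_corr`, `gsea`, `mutation_bias`,
#'   `mutation_cells`, `survival` (per sex), `icb`, `classification`,
#'   `manifest`).
#' @export
run_pipeline <- function(expression, mutations, clinical, signatures,
                         estimate_sets, icg_genes = NULL, pathways = NULL,
                         p_cut = 0.05, fdr_cut = 0.25, min_mut_freq = 0.05,
                         zero_frac = 0.9, n_perm = 1000, seed = 1,
                         two_sided = FALSE, cancer_label = "cohort",
                         out_dir = NULL) {
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "sextme_pipeline_error", partial = res)
    })
  }

  res$cohort <- stage("preprocess", {
    cohort <- filter_samples(clinical, expression, mutations, cancer_label)
    cohort$expression <- filter_genes(cohort$expression, zero_frac)
    cohort
  })
  cl <- res$cohort$clinical
  res$scores <- stage("scores", compute_sample_scores(
    res$cohort$expression, res$cohort$mutations, signatures,
    estimate_sets$stromal, estimate_sets$immune))
  res$sex_bias <- stage("sex_bias", sex_bias_scan(
    res$scores, res$cohort$expression, cl, icg_genes,
    p_cut = p_cut, fdr_cut = fdr_cut))
  res$diff_corr <- stage("diff_corr", diffcorr_scan(
    res$scores, cl, two_sided = two_sided, p_cut = p_cut))
  if (!is.null(pathways)) {
    res$gsea <- stage("pathway_gsea", gsea_permutation(
      res$cohort$expression, cl, pathways, n_perm = n_perm, seed = seed))
  }
  res$mutation_bias <- stage("mutation_assoc", {
    mm <- mutation_matrix(res$cohort$mutations, cl$sample, min_mut_freq)
    res$mutation_matrix <- mm
    if (nrow(mm$matrix) == 0) tibble() else sex_biased_mutations(mm, cl, fdr_cut)
  })
  if (nrow(res$mutation_bias) > 0) {
    biased <- res$mutation_bias$gene[res$mutation_bias$direction != "none"]
    if (length(biased) > 0) {
      res$mutation_cells <- stage("mutation_assoc", mutation_cell_association(
        res$mutation_matrix, res$scores, biased, p_cut))
    }
  }
  res$survival <- stage("survival_models", {
    out <- list()
    for (s in c("male", "female")) {
      sig <- withCallingHandlers(
        build_signature(res$scores, cl, s, p_cut),
        warning = function(w) invokeRestart("muffleWarning"))
      entry <- list(signature = sig)
      if (nrow(sig$signature) > 0) {
        strat_cl <- cl[!is.na(cl$sex) & cl$sex == s, , drop = FALSE]
        sc <- res$scores[res$scores$sample %in% strat_cl$sample, , drop = FALSE]
        rs <- risk_score(sig, sc)
        dat <- inner_join(rs, strat_cl, by = "sample")
        entry$risk <- rs
        entry$km <- km_logrank(dat$os_time, dat$os_event, dat$group)
        covs <- data.frame(risk_score = dat$risk_score, age = dat$age,
                           stage = stage_ordinal(dat$stage))
        entry$cox_multi <- tryCatch(
          cox_multivariable(dat$os_time, dat$os_event, covs),
          error = function(e) NULL)
      }
      out[[s]] <- entry
    }
    out
  })
  if (any(!is.na(cl$response))) {
    res$icb <- stage("icb_prediction", tmb_auc(res$scores, cl))
  }
  res$classification <- stage("classification", cancer_feature_summary(
    res$sex_bias, res$gsea, cancer_label, fdr_cut))

  res$manifest <- tibble(
    key = c("package_version", "cancer_label", "seed", "n_perm", "p_cut",
            "fdr_cut", "min_mut_freq", "zero_frac", "n_samples", "n_genes",
            "n_cells_scored", "n_mutation_genes", "group"),
    value = as.character(c(
      as.character(utils::packageVersion("sextme")), cancer_label, seed,
      n_perm, p_cut, fdr_cut, min_mut_freq, zero_frac, nrow(cl),
      nrow(res$cohort$expression),
      nrow(res$sex_bias$cell_tests),
      if (is.null(res$mutation_matrix)) 0 else nrow(res$mutation_matrix$matrix),
      res$classification$group))
  )
  out_obj <- structure(res, class = "sextme_run")
  if (!is.null(out_dir)) write_run(out_obj, out_dir)
  out_obj
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x) && is.data.frame(x) && nrow(x) > 0) {
      readr::write_tsv(x, file.path(out_dir, name))
    }
  }
  w(run$cohort$filter_report, "filter_report.tsv")
  w(run$scores, "scores.tsv")
  w(run$sex_bias$summary_tests, "summary_tests.tsv")
  w(run$sex_bias$cell_tests, "cell_tests.tsv")
  w(run$sex_bias$icg_tests, "icg_tests.tsv")
  w(run$diff_corr, "diffcorr.tsv")
  w(run$gsea, "gsea.tsv")
  w(run$mutation_bias, "mutation_bias.tsv")
  w(run$mutation_cells, "mutation_cell_assoc.tsv")
  for (s in names(run$survival)) {
    ent <- run$survival[[s]]
    w(ent$signature$cox, sprintf("cox_univariate_%s.tsv", s))
    w(ent$signature$signature, sprintf("signature_%s.tsv", s))
    w(ent$risk, sprintf("risk_groups_%s.tsv", s))
    if (!is.null(ent$km)) {
      w(ent$km$curves, sprintf("km_curves_%s.tsv", s))
      readr::write_lines(
        sprintf("logrank_chi2\t%.6g\nlogrank_p\t%.6g", ent$km$chi2, ent$km$p),
        file.path(out_dir, sprintf("logrank_%s.tsv", s)))
    }
    w(ent$cox_multi, sprintf("cox_multivariable_%s.tsv", s))
  }
  if (!is.null(run$icb)) w(as_tibble(run$icb), "icb_auc.tsv")
  w(run$classification, "classification.tsv")
  w(run$manifest, "manifest.tsv")
  invisible(out_dir)
}

#' @export
print.sextme_run <- function(x, ...) {
  cat("<sextme_run>", x$classification$cancer_label, "\n")
  cat(sprintf("  samples: %d (male %d / female %d)\n",
              nrow(x$cohort$clinical), x$sex_bias$n_male, x$sex_bias$n_female))
  cat(sprintf("  classification: %s sex-biased immune group\n",
              x$classification$group))
  invisible(x)
}
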