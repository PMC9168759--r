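#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_col
#'   geom_abline geom_hline labs theme_minimal facet_wrap coord_flip
NULL

#' @export
ggplot2::autoplot

#' ROC curves of TMB for checkpoint-blockade response, by sex
#'
#' @param object A [tmb_auc()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tmb_auc
#' @export
autoplot.tmb_auc <- function(object, ...) {
  roc <- attr(object, "roc")
  ggplot(roc, aes(x = .data$fpr, y = .data$tpr, colour = .data$sex)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    labs(x = "False-positive rate", y = "True-positive rate",
         title = "TMB as a predictor of ICB response") +
    theme_minimal()
}

#' Sex-bias overview: per-feature t-scores with significance
#'
#' @param object A `sex_bias_scan`.
#' @param ... Unused.
#' @return A ggplot of cell (and ICG) t-scores, filled by significance.
#' @method autoplot sex_bias_scan
#' @export
autoplot.sex_bias_scan <- function(object, ...) {
  dat <- bind_rows(
    mutate(object$cell_tests, family = "immune cells"),
    mutate(object$icg_tests, family = "checkpoint genes")
  )
  if (nrow(dat) == 0) input_error("no cell or ICG tests to plot")
  ggplot(dat, aes(x = stats::reorder(.data$feature, .data$t_score),
                  y = .data$t_score, fill = .data$significant)) +
    geom_col() +
    coord_flip() +
    facet_wrap(~family, scales = "free_y") +
    labs(x = NULL, y = "t score (female - male)",
         fill = "FDR < 0.25") +
    theme_minimal()
}

#' Kaplan-Meier plot for a risk stratification
#'
#' @param km A [km_logrank()] result.
#' @return A ggplot of the product-limit curves with the log-rank p in the
#'   title.
#' @export
plot_km <- function(km) {
  curves <- bind_rows(
    km$curves,
    km$curves |> group_by(.data$group) |>
      summarise(time = 0, n_risk = max(.data$n_risk), n_event = 0,
                survival = 1, .groups = "drop")
  ) |> arrange(.data$group, .data$time)
  ggplot(curves, aes(x = .data$time, y = .data$survival,
                     colour = .data$group)) +
    geom_step() +
    labs(x = "Time (days)", y = "Survival probability",
         title = sprintf("Log-rank p = %.3g", km$p)) +
    theme_minimal()
}

#' Differential-correlation overview plot
#'
#' @param diffcorr A [diffcorr_scan()] table.
#' @return A ggplot of per-feature male and female Spearman coefficients.
#' @export
plot_diffcorr <- function(diffcorr) {
  long <- tidyr::pivot_longer(
    diffcorr[c("feature", "r_male", "r_female", "significant")],
    cols = c("r_male", "r_female"), names_to = "sex", values_to = "r",
    names_prefix = "r_")
  ggplot(long, aes(x = .data$feature, y = .data$r, fill = .data$sex,
                   alpha = .data$significant)) +
    geom_col(position = "dodge") +
    coord_flip() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4)) +
    labs(x = NULL, y = "Spearman r with TMB",
         alpha = "sex-differential") +
    theme_minimal()
}
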