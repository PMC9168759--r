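#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows bind_cols rename distinct pull n across
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_lgl map2 imap pmap list_rbind
#' @importFrom stats pnorm pt qnorm p.adjust median cor sd var rnorm runif
#'   rbinom quantile wilcox.test t.test chisq.test glm binomial coef vcov
#'   uniroot rexp ks.test setNames complete.cases
NULL

# MAF controlled vocabulary: classes counted as non-silent (TMB numerator,
# mutation matrix), plus the silent-side labels we recognise without flagging.
NONSILENT_CLASSES <- c(
  "Nonsense_Mutation", "Missense_Mutation", "Splice_Site", "Nonstop_Mutation",
  "Translation_Start_Site", "Frame_Shift_Del", "Frame_Shift_Ins",
  "In_Frame_Del", "In_Frame_Ins"
)

SILENT_CLASSES <- c(
  "Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR", "RNA",
  "Targeted_Region", "De_novo_Start_InFrame", "De_novo_Start_OutOfFrame"
)

MAF_VOCABULARY <- c(NONSILENT_CLASSES, SILENT_CLASSES)

# Coding-region length (Mb) used as the TMB denominator.
TMB_CODING_MB <- 38

format_error <- function(msg) {
  abort(msg, class = "sextme_format_error")
}

input_error <- function(msg) {
  abort(msg, class = "sextme_input_error")
}

#' Convert a wide expression tibble to a numeric matrix
#'
#' Expression data travel through the package as a tibble whose first column
#' (`gene`) holds gene identifiers and whose remaining columns are samples.
#' This converts to the genes-by-samples matrix used internally.
#'
#' @param expr A wide expression tibble (`gene` column plus sample columns).
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "gene" %in% names(expr))
  genes <- as.character(expr$gene)
  m <- as.matrix(expr[setdiff(names(expr), "gene")])
  if (!is.numeric(m)) input_error("expression body must be numeric")
  rownames(m) <- genes
  m
}

#' Convert a genes-by-samples matrix back to the wide expression tibble
#'
#' @param m A numeric matrix with gene rownames and sample colnames.
#' @return A tibble with a `gene` column followed by one column per sample.
#' @export
expr_tibble <- function(m) {
  bind_cols(tibble(gene = rownames(m)), as_tibble(m))
}

expr_samples <- function(expr) setdiff(names(expr), "gene")

# gene sets travel as a long tibble (set, description, gene); this collapses
# to the named list of character vectors most scoring code wants.
gene_set_list <- function(sets) {
  if (is.list(sets) && !is.data.frame(sets)) {
    return(map(sets, ~ unique(as.character(.x))))
  }
  stopifnot(is.data.frame(sets), all(c("set", "gene") %in% names(sets)))
  split(as.character(sets$gene), factor(sets$set, levels = unique(sets$set)))
}

as_gene_set <- function(x) {
  if (is.data.frame(x)) unique(as.character(x$gene)) else unique(as.character(x))
}
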