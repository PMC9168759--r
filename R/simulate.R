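#' Configuration for a synthetic cohort
#'
#' Collects every knob of the generator, with defaults chosen to resemble a
#' mid-sized solid-tumor cohort: 100 patients per sex, 2,000 genes, 24
#' immune-cell signatures of 30 disjoint marker genes each, log-normal
#' latent cell abundances, and a background somatic mutation rate giving a
#' TMB around 1 mutation/Mb.
#'
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param n_male,n_female Patients per sex.
#' @param n_genes Genes in the expression matrix.
#' @param n_cells Number of immune-cell signatures.
#' @param genes_per_signature Marker genes per signature (signatures are
#'   mutually disjoint by construction).
#' @param signature_effect Log2-expression increment per unit latent cell
#'   abundance added to a signature's marker genes.
#' @param latent_sd SD of the latent log-abundance of each cell.
#' @param noise_sd SD of the log2-expression noise.
#' @param sex_cell_effects Named numeric: latent-mean shift (log scale)
#'   added for females, per cell (e.g. `c(cell01 = 1)`).
#' @param background_mutation_rate Per-gene, per-patient probability of a
#'   non-silent mutation (before the patient-level rate factor).
#' @param sex_mutation_rates Named list: gene -> c(male = rate, female =
#'   rate) overriding the background for sex-biased genes.
#' @param tmb_tme_corr Named numeric `c(male = , female = )`: target
#'   correlation, within each sex, between the latent immune abundance and
#'   the patient's latent mutation-rate factor (Gaussian copula).
#' @param mutation_factor_sd Log-scale SD of the patient mutation-rate
#'   factor.
#' @param hazard_gammas Named numeric: log-hazard coefficient per unit cell
#'   abundance (e.g. `c(cell01 = 0.8, cell02 = -0.8)`).
#' @param baseline_hazard Exponential baseline hazard (per day).
#' @param censor_fraction Target fraction of censored patients (uniform
#'   censoring, scale solved numerically).
#' @param icb_tmb_effect Named numeric `c(male = , female = )`: log-odds of
#'   response per TMB unit; `include_response` switches the column on.
#' @param icb_intercept Log-odds intercept of response.
#' @param include_response Emit an ICB response column?
#' @param zero_quantile Fraction of the lowest expression values thresholded
#'   to zero (FPKM scale), exercising the zero-expression gene filter.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_male = 100, n_female = 100,
                       n_genes = 2000, n_cells = 24,
                       genes_per_signature = 30, signature_effect = 1,
                       latent_sd = 0.5, noise_sd = 0.5,
                       sex_cell_effects = numeric(),
                       background_mutation_rate = 0.02,
                       sex_mutation_rates = list(),
                       tmb_tme_corr = c(male = 0, female = 0),
                       mutation_factor_sd = 0.5,
                       hazard_gammas = numeric(),
                       baseline_hazard = log(2) / 1000,
                       censor_fraction = 0.3,
                       icb_tmb_effect = c(male = 0, female = 0),
                       icb_intercept = 0,
                       include_response = FALSE,
                       zero_quantile = 0.05) {
  cfg <- as.list(environment())
  if (any(abs(cfg$tmb_tme_corr) >= 1)) {
    input_error("tmb_tme_corr targets must satisfy |rho| < 1")
  }
  if (!all(c("male", "female") %in% names(cfg$tmb_tme_corr)) ||
      !all(c("male", "female") %in% names(cfg$icb_tmb_effect))) {
    input_error("tmb_tme_corr and icb_tmb_effect need 'male' and 'female' entries")
  }
  if (cfg$censor_fraction < 0 || cfg$censor_fraction >= 1) {
    input_error("censor_fraction must lie in [0, 1)")
  }
  needed <- (n_cells + 2) * genes_per_signature
  if (needed > n_genes) {
    input_error("n_genes too small for the requested signatures")
  }
  structure(cfg, class = "sim_config")
}

cell_names <- function(n) sprintf("cell%02d", seq_len(n))

#' Simulate a full synthetic cohort with planted sex effects
#'
#' Generates, from one seed, a coherent set of inputs for the whole
#' pipeline: a raw FPKM-scale expression matrix driven by latent per-patient
#' cell abundances (log-normal, sex-shiftable means), mutually disjoint
#' cell-marker signatures plus immune/stromal sets for the purity model, a
#' MAF-like mutation table whose patient-level rate factor can be
#' copula-correlated with latent immune abundance per sex, exponential
#' survival with cell-abundance log-hazards and uniform censoring tuned to a
#' target fraction, and (optionally) a TMB-driven checkpoint-blockade
#' response. The planted truth is returned alongside the data.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_cohort`: list with `expression` (wide
#'   tibble, raw FPKM scale), `mutations`, `clinical`, `signatures` (long
#'   gene-set tibble for the cell signatures), `estimate_sets` (named list
#'   with `immune` and `stromal` gene vectors), and `truth` (latent
#'   variables and planted effects).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    n <- cfg$n_male + cfg$n_female
    samples <- sprintf("P%04d", seq_len(n))
    sex <- factor(rep(c("male", "female"), c(cfg$n_male, cfg$n_female)),
                  levels = c("male", "female"))
    cells <- cell_names(cfg$n_cells)
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))

    # disjoint marker blocks: one per cell, then immune + stromal sets
    gps <- cfg$genes_per_signature
    blocks <- split(genes[seq_len((cfg$n_cells + 2) * gps)],
                    rep(seq_len(cfg$n_cells + 2), each = gps))
    sig_genes <- setNames(blocks[seq_len(cfg$n_cells)], cells)
    immune_set <- blocks[[cfg$n_cells + 1]]
    stromal_set <- blocks[[cfg$n_cells + 2]]

    # latent log-abundances, with female mean shifts for planted cells
    shift <- setNames(numeric(cfg$n_cells), cells)
    planted <- intersect(names(cfg$sex_cell_effects), cells)
    shift[planted] <- cfg$sex_cell_effects[planted]
    # a shared per-patient immune tone loads on every cell latent, giving
    # the cell-cell correlation seen in bulk cohorts and a well-defined
    # "latent immune abundance" for the mutation-rate copula
    immune_latent <- rnorm(n, sd = cfg$latent_sd)
    z <- immune_latent +
      matrix(rnorm(n * cfg$n_cells, sd = cfg$latent_sd), n, cfg$n_cells,
             dimnames = list(samples, cells))
    z <- z + outer(as.integer(sex == "female"), shift)
    abundance <- exp(z)
    stromal_latent <- rnorm(n, sd = cfg$latent_sd)

    # expression: baseline + signature_effect * abundance on log2 scale
    base <- rnorm(cfg$n_genes, mean = 3, sd = 1)
    y <- matrix(rnorm(cfg$n_genes * n, sd = cfg$noise_sd), cfg$n_genes, n,
                dimnames = list(genes, samples)) + base
    for (c_i in seq_len(cfg$n_cells)) {
      idx <- match(sig_genes[[c_i]], genes)
      y[idx, ] <- y[idx, ] +
        cfg$signature_effect * matrix(abundance[, c_i], gps, n, byrow = TRUE)
    }
    y[match(immune_set, genes), ] <- y[match(immune_set, genes), ] +
      cfg$signature_effect * matrix(exp(immune_latent), gps, n, byrow = TRUE)
    y[match(stromal_set, genes), ] <- y[match(stromal_set, genes), ] +
      cfg$signature_effect * matrix(exp(stromal_latent), gps, n, byrow = TRUE)
    fpkm <- 2^y
    fpkm[fpkm < quantile(fpkm, cfg$zero_quantile)] <- 0

    # mutation-rate factor: Gaussian copula against the standardized
    # immune latent, with a sex-specific target correlation
    imm_std <- numeric(n)
    for (s in c("male", "female")) {
      i <- sex == s
      imm_std[i] <- (immune_latent[i] - mean(immune_latent[i])) /
        sd(immune_latent[i])
    }
    rho <- cfg$tmb_tme_corr[as.character(sex)]
    w <- rho * imm_std + sqrt(1 - rho^2) * rnorm(n)
    factor_i <- exp(cfg$mutation_factor_sd * w)

    rate <- matrix(cfg$background_mutation_rate, cfg$n_genes, n,
                   dimnames = list(genes, samples))
    for (g in names(cfg$sex_mutation_rates)) {
      rg <- cfg$sex_mutation_rates[[g]]
      rate[g, ] <- ifelse(sex == "male", rg[["male"]], rg[["female"]])
    }
    p <- pmin(0.95, sweep(rate, 2, factor_i, `*`))
    hits <- matrix(rbinom(length(p), 1, p), cfg$n_genes, n) == 1
    rec_idx <- which(hits, arr.ind = TRUE)
    mutations <- tibble(
      sample = samples[rec_idx[, 2]],
      gene = genes[rec_idx[, 1]],
      variant_classification = sample(
        NONSILENT_CLASSES, nrow(rec_idx), replace = TRUE,
        prob = c(0.1, 0.6, 0.06, 0.01, 0.01, 0.08, 0.06, 0.04, 0.04)
      )
    )
    # a sprinkling of silent records, which every downstream count ignores
    n_sil <- ceiling(nrow(mutations) * 0.15)
    if (n_sil > 0) {
      mutations <- bind_rows(mutations, tibble(
        sample = sample(samples, n_sil, replace = TRUE),
        gene = sample(genes, n_sil, replace = TRUE),
        variant_classification = "Silent"
      ))
    }
    tmb <- as.numeric(table(factor(
      mutations$sample[mutations$variant_classification %in% NONSILENT_CLASSES],
      levels = samples))) / TMB_CODING_MB

    # survival: exponential with cell-abundance log-hazards, uniform censoring
    gam <- setNames(numeric(cfg$n_cells), cells)
    gplanted <- intersect(names(cfg$hazard_gammas), cells)
    gam[gplanted] <- cfg$hazard_gammas[gplanted]
    eta <- as.numeric(abundance %*% gam)
    eta <- eta - mean(eta)
    t_event <- rexp(n, rate = cfg$baseline_hazard * exp(eta))
    if (cfg$censor_fraction > 0) {
      cens_scale <- uniroot(
        function(cc) mean(pmin(t_event / cc, 1)) - cfg$censor_fraction,
        lower = min(t_event) * 1e-3, upper = max(t_event) * 1e4,
        tol = 1e-6, extendInt = "downX"
      )$root
      t_cens <- runif(n, 0, cens_scale)
    } else {
      t_cens <- rep(Inf, n)
    }
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)

    response <- rep(NA_character_, n)
    if (cfg$include_response) {
      eff <- cfg$icb_tmb_effect[as.character(sex)]
      pr <- 1 / (1 + exp(-(cfg$icb_intercept + eff * tmb)))
      response <- ifelse(rbinom(n, 1, pr) == 1, "responder", "nonresponder")
    }

    clinical <- tibble(
      sample = samples, sex = sex,
      age = sample(30:84, n, replace = TRUE),
      stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE),
      os_time = os_time, os_event = os_event,
      response = response,
      immune_infiltrated = TRUE
    )
    signatures <- list_rbind(imap(sig_genes, function(g, nm) {
      tibble(set = nm, description = "synthetic cell signature", gene = g)
    }))
    truth <- list(
      config = cfg,
      latent = bind_cols(
        tibble(sample = samples, sex = sex,
               immune_latent = immune_latent,
               stromal_latent = stromal_latent,
               mutation_factor = factor_i,
               log_mutation_factor = cfg$mutation_factor_sd * w,
               tmb = tmb, eta = eta),
        as_tibble(z)
      ),
      sex_cell_effects = shift[shift != 0],
      hazard_gammas = gam[gam != 0],
      sex_mutation_rates = cfg$sex_mutation_rates,
      tmb_tme_corr = cfg$tmb_tme_corr
    )
    structure(
      list(expression = expr_tibble(fpkm), mutations = mutations,
           clinical = clinical, signatures = signatures,
           estimate_sets = list(immune = immune_set, stromal = stromal_set),
           truth = truth),
      class = "sim_cohort"
    )
  })
}

#' Score pipeline calls against the planted truth
#'
#' Compares detection tables from the pipeline with the effects planted by
#' [simulate_cohort()]: sex-biased cells against `sex_cell_effects`,
#' prognostic cells against `hazard_gammas`, and sex-biased mutated genes
#' against `sex_mutation_rates`.
#'
#' @param truth The `truth` element of a `sim_cohort`.
#' @param cell_tests Optional tibble from [sex_bias_scan()] (`$cell_tests`).
#' @param signature Optional `prognostic_signature` (or its tibble).
#' @param mutation_bias Optional tibble from [sex_biased_mutations()].
#' @return A tibble with one row per planted effect (`effect_type`,
#'   `target`, `planted`, `detected`, `sign_ok`) plus, as attribute
#'   `"summary"`, per-type sensitivity and false-positive counts.
#' @export
evaluate_recovery <- function(truth, cell_tests = NULL, signature = NULL,
                              mutation_bias = NULL) {
  rows <- list()
  fp <- list()
  if (!is.null(cell_tests) && length(truth$sex_cell_effects) > 0) {
    for (cell in names(truth$sex_cell_effects)) {
      planted <- truth$sex_cell_effects[[cell]]
      hit <- cell_tests[cell_tests$feature == cell, , drop = FALSE]
      if (nrow(hit) == 0) input_error(sprintf("cell '%s' absent from cell_tests", cell))
      det <- isTRUE(hit$significant)
      sign_ok <- det && ((planted > 0) == (hit$direction == "female_biased"))
      rows[[length(rows) + 1]] <- tibble(
        effect_type = "sex_cell_effect", target = cell, planted = planted,
        detected = det, sign_ok = sign_ok)
    }
    fp$sex_cell_effect <- sum(
      cell_tests$significant &
        !cell_tests$feature %in% names(truth$sex_cell_effects))
  }
  if (!is.null(signature) && length(truth$hazard_gammas) > 0) {
    sig <- if (inherits(signature, "prognostic_signature")) signature$signature
           else signature
    for (cell in names(truth$hazard_gammas)) {
      planted <- truth$hazard_gammas[[cell]]
      hit <- sig[sig$cell == cell, , drop = FALSE]
      det <- nrow(hit) == 1
      sign_ok <- det && sign(hit$beta) == sign(planted)
      rows[[length(rows) + 1]] <- tibble(
        effect_type = "hazard_gamma", target = cell, planted = planted,
        detected = det, sign_ok = sign_ok)
    }
    fp$hazard_gamma <- sum(!sig$cell %in% names(truth$hazard_gammas))
  }
  if (!is.null(mutation_bias) && length(truth$sex_mutation_rates) > 0) {
    for (g in names(truth$sex_mutation_rates)) {
      rg <- truth$sex_mutation_rates[[g]]
      planted <- rg[["male"]] - rg[["female"]]
      hit <- mutation_bias[mutation_bias$gene == g, , drop = FALSE]
      det <- nrow(hit) == 1 && hit$direction != "none"
      sign_ok <- det && ((planted > 0) == (hit$direction == "male_biased"))
      rows[[length(rows) + 1]] <- tibble(
        effect_type = "sex_mutation_rate", target = g, planted = planted,
        detected = det, sign_ok = sign_ok)
    }
    fp$sex_mutation_rate <- sum(
      mutation_bias$direction != "none" &
        !mutation_bias$gene %in% names(truth$sex_mutation_rates))
  }
  out <- list_rbind(rows)
  if (nrow(out) > 0) {
    summ <- out |>
      group_by(.data$effect_type) |>
      summarise(n_planted = n(), sensitivity = mean(.data$detected),
                sign_agreement = mean(.data$sign_ok[.data$detected]),
                .groups = "drop")
    summ$false_positives <- as.integer(unlist(fp)[summ$effect_type])
    attr(out, "summary") <- summ
  }
  out
}
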