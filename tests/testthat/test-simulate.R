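test_that("same config and seed give identical cohorts; different seeds differ", {
  cfg <- sim_config(seed = 5, n_male = 20, n_female = 20, n_genes = 900,
                    n_cells = 6, genes_per_signature = 10)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c_ <- simulate_cohort(sim_config(seed = 6, n_male = 20, n_female = 20,
                                   n_genes = 900, n_cells = 6,
                                   genes_per_signature = 10))
  expect_false(identical(a$expression, c_$expression))
})

test_that("config validation rejects impossible targets", {
  expect_error(sim_config(tmb_tme_corr = c(male = 1, female = 0)),
               class = "sextme_input_error")
  expect_error(sim_config(censor_fraction = 1), class = "sextme_input_error")
  expect_error(sim_config(n_genes = 100), class = "sextme_input_error")
})

test_that("achieved censoring fraction is near target at n = 500", {
  fr <- vapply(1:6, function(s) {
    sim <- simulate_cohort(sim_config(seed = s, n_male = 250, n_female = 250,
                                      n_genes = 900, n_cells = 6,
                                      genes_per_signature = 10,
                                      censor_fraction = 0.3))
    mean(sim$clinical$os_event == 0)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.3), 0.05)
})

test_that("copula hits the target latent TMB-immune correlation per sex", {
  rho <- vapply(1:8, function(s) {
    sim <- simulate_cohort(sim_config(seed = 10 + s, n_male = 250,
                                      n_female = 250, n_genes = 900,
                                      n_cells = 6, genes_per_signature = 10,
                                      tmb_tme_corr = c(male = 0.5, female = 0)))
    tr <- sim$truth$latent
    mle <- tr$sex == "male"
    c(cor(tr$log_mutation_factor[mle], tr$immune_latent[mle]),
      cor(tr$log_mutation_factor[!mle], tr$immune_latent[!mle]))
  }, numeric(2))
  expect_lt(abs(mean(rho[1, ]) - 0.5), 0.08)
  expect_lt(abs(mean(rho[2, ])), 0.08)
  # and the observable TMB inherits the male-only correlation
  sim <- simulate_cohort(sim_config(seed = 3, n_male = 250, n_female = 250,
                                    n_genes = 900, n_cells = 6,
                                    genes_per_signature = 10,
                                    tmb_tme_corr = c(male = 0.5, female = 0)))
  tr <- sim$truth$latent
  mle <- tr$sex == "male"
  expect_gt(cor(tr$tmb[mle], tr$immune_latent[mle], method = "spearman"), 0.3)
  expect_lt(abs(cor(tr$tmb[!mle], tr$immune_latent[!mle],
                    method = "spearman")), 0.15)
})

test_that("marginal mutation frequencies sit inside binomial 99% bounds", {
  cfg <- sim_config(seed = 9, n_male = 150, n_female = 150, n_genes = 900,
                    n_cells = 6, genes_per_signature = 10,
                    background_mutation_rate = 0.02,
                    sex_mutation_rates = list(g0500 = c(male = 0.3,
                                                        female = 0.05)))
  sim <- simulate_cohort(cfg)
  mm <- mutation_matrix(sim$mutations, sim$clinical$sample, min_freq = 0)
  # E[min(0.95, r * factor)] ~ r * E[factor]; factor is lognormal(0, 0.5)
  efac <- exp(0.5^2 / 2)
  p_bg <- 0.02 * efac
  bg <- mm$freq[!mm$freq$gene %in% "g0500", ]
  lo <- qbinom(0.005, 300, p_bg) / 300
  hi <- qbinom(0.995, 300, p_bg) / 300
  expect_gt(mean(bg$freq >= lo & bg$freq <= hi), 0.95)
  # the sex-specific gene's per-sex frequencies track their planted rates
  g <- mm$matrix["g0500", ]
  male <- sim$clinical$sex == "male"
  expect_lt(abs(mean(g[male]) - 0.3 * efac), 3 * sqrt(0.3 * 0.7 / 150))
  expect_lt(abs(mean(g[!male]) - 0.05 * efac), 3 * sqrt(0.05 * 0.95 / 150))
})

test_that("zero thresholding leaves the configured fraction of zeros", {
  sim <- simulate_cohort(sim_config(seed = 2, n_male = 30, n_female = 30,
                                    n_genes = 900, n_cells = 6,
                                    genes_per_signature = 10,
                                    zero_quantile = 0.05))
  m <- expr_matrix(sim$expression)
  expect_equal(mean(m == 0), 0.05, tolerance = 0.01)
  expect_true(all(m >= 0))
})

test_that("evaluate_recovery scores detection, signs and false positives", {
  truth <- list(
    sex_cell_effects = c(cellA = 1),
    hazard_gammas = c(cellB = 0.8),
    sex_mutation_rates = list(g1 = c(male = 0.3, female = 0.05))
  )
  cell_tests <- tibble::tibble(
    feature = c("cellA", "cellB"), significant = c(TRUE, FALSE),
    direction = c("female_biased", "none"))
  sig <- tibble::tibble(cell = c("cellB", "cellC"), beta = c(0.5, 0.2))
  mb <- tibble::tibble(gene = "g1", direction = "male_biased")
  rec <- evaluate_recovery(truth, cell_tests, sig, mb)
  expect_equal(nrow(rec), 3)
  expect_true(all(rec$detected))
  expect_true(all(rec$sign_ok))
  summ <- attr(rec, "summary")
  expect_equal(summ$false_positives[summ$effect_type == "hazard_gamma"], 1)
  expect_error(evaluate_recovery(truth, cell_tests[0, ], NULL, NULL),
               class = "sextme_input_error")
})
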