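test_that("rank-sum test: exact small-sample p-values and contracts", {
  expect_error(wrs_test(c(1, 2), c("a", "a")), class = "sextme_input_error")
  expect_equal(wrs_test(c(1, 2, 3, 4), c("a", "a", "b", "b"))$p, 1 / 3,
               tolerance = 1e-9)
  expect_equal(wrs_test(c(1, 4, 2, 3), c("a", "a", "b", "b"))$p, 1)
  # large shifted samples are overwhelmingly significant
  set.seed(3)
  v <- c(rnorm(200), rnorm(200, 1))
  expect_lt(wrs_test(v, rep(c("a", "b"), each = 200))$p, 1e-10)
})

test_that("Welch t: sign convention female - male, worked example, antisymmetry", {
  same <- welch_t(c(1, 2, 3, 1, 2, 3), rep(c("male", "female"), each = 3))
  expect_equal(same$t_score, 0)
  expect_equal(same$p, 1)

  v <- c(1, 2, 3, 4, 3, 4, 5, 6)
  sex <- rep(c("male", "female"), each = 4)
  r <- welch_t(v, sex)
  expect_equal(r$t_score, 2 / sqrt(5 / 3 / 4 + 5 / 3 / 4), tolerance = 1e-9)
  expect_equal(r$t_score, 2.1909, tolerance = 1e-4)
  expect_equal(r$df, 6, tolerance = 1e-9)
  expect_equal(r$p, 2 * pt(-abs(r$t_score), df = 6), tolerance = 1e-9)
  expect_equal(round(r$p, 2), 0.07)
  # swapping labels flips the sign, p unchanged
  r2 <- welch_t(v, rev(sex))
  expect_equal(r2$t_score, -r$t_score)
  expect_equal(r2$p, r$p)
})

test_that("BH adjustment equals the longhand step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.7), 0.7)
  expect_equal(bh_fdr(c(0.005, 0.5)), c(0.01, 0.5))
  set.seed(77)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "sextme_input_error")
})

test_that("classification rule: at least 4 of 7 features, monotone", {
  expect_equal(classify_cancer(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
               "strong")
  expect_equal(classify_cancer(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
               "weak")
  expect_error(classify_cancer(TRUE, NA, TRUE, TRUE, TRUE, TRUE, TRUE),
               class = "sextme_input_error")
  # monotone: upgrading any flag never demotes strong to weak
  set.seed(12)
  for (i in 1:30) {
    flags <- as.list(runif(7) < 0.5)
    base <- do.call(classify_cancer, flags)
    for (j in 1:7) {
      up <- flags; up[[j]] <- TRUE
      upgraded <- do.call(classify_cancer, up)
      if (base == "strong") expect_equal(upgraded, "strong")
    }
  }
})

test_that("a lung-cohort-like feature profile lands in the strong group", {
  # four summary features significant, 14/24 cells, 31 ICGs, >0 pathways
  expect_equal(
    classify_cancer(0.0078 < 0.05, 0.018 < 0.05, 0.048 < 0.05, 0.018 < 0.05,
                    14 / 24 > 0, 31 / 68 > 0, TRUE),
    "strong"
  )
})

test_that("sex_bias_scan detects a planted female-shifted cell with direction", {
  sim <- simulate_cohort(sim_config(seed = 19, n_male = 60, n_female = 60,
                                    n_genes = 1000, n_cells = 8,
                                    genes_per_signature = 15,
                                    sex_cell_effects = c(cell03 = 1)))
  expr <- filter_genes(sim$expression)
  cells <- cell_infiltration(expr, sim$signatures)
  scan <- sex_bias_scan(cells, clinical = sim$clinical)
  hit <- scan$cell_tests[scan$cell_tests$feature == "cell03", ]
  expect_true(hit$significant)
  expect_equal(hit$direction, "female_biased")
})

test_that("per-cell type-I rate is nominal on null gaussian scores", {
  set.seed(55)
  ps <- replicate(150, {
    v <- rnorm(80)
    welch_t(v, rep(c("male", "female"), 40))$p
  })
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("scan warns on low power but still returns results", {
  set.seed(4)
  scores <- tibble::tibble(sample = paste0("S", 1:15), tmb = rexp(15),
                           cellA = rnorm(15))
  cl <- tiny_clinical(paste0("S", 1:15), c(rep("male", 5), rep("female", 10)))
  expect_warning(scan <- sex_bias_scan(scores, clinical = cl), "low power")
  expect_equal(nrow(scan$summary_tests), 1)  # tmb only
  expect_equal(nrow(scan$cell_tests), 1)
})

test_that("tidy and glance summarise a scan", {
  set.seed(8)
  scores <- tibble::tibble(sample = paste0("S", 1:40), tmb = rexp(40),
                           cellA = rnorm(40), cellB = rnorm(40))
  cl <- tiny_clinical(paste0("S", 1:40), rep(c("male", "female"), 20))
  scan <- sex_bias_scan(scores, clinical = cl)
  td <- generics::tidy(scan)
  expect_true(all(c("feature", "p", "family") %in% names(td)))
  expect_equal(nrow(td), 3)
  gl <- generics::glance(scan)
  expect_equal(gl$n_male, 20)
})
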