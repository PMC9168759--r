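test_that("mutation matrix binarizes and applies the strict 5% filter", {
  samples <- sprintf("S%03d", 1:100)
  maf <- tibble::tibble(
    sample = c(samples[1:6], samples[1:5], samples[1], samples[1]),
    gene = c(rep("keep6", 6), rep("drop5", 5), "dup", "dup"),
    variant_classification = "Missense_Mutation"
  )
  mm <- mutation_matrix(maf, samples, min_freq = 0.05)
  expect_true("keep6" %in% rownames(mm$matrix))    # 0.06 > 0.05
  expect_false("drop5" %in% rownames(mm$matrix))   # 0.05 not > 0.05
  # two records in one sample give a single 1 (check pre-filter via freq)
  mm_all <- mutation_matrix(maf, samples, min_freq = 0)
  expect_equal(unname(mm_all$matrix["dup", "S001"]), 1L)
  expect_equal(mm_all$freq$n_mutated[mm_all$freq$gene == "dup"], 1L)
  # conservation: frequencies x n are the integer counts
  expect_equal(mm_all$freq$freq * 100, mm_all$freq$n_mutated)
})

test_that("chi-square matches the 2x2 closed forms with and without Yates", {
  samples <- paste0("S", 1:20)
  sex <- rep(c("male", "female"), each = 10)
  v <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  mat <- matrix(v, 1, 20, dimnames = list("G", samples))
  cl <- tiny_clinical(samples, sex)
  # expected counts all equal 5 exactly, so the auto rule stays uncorrected:
  # chi2 = n(ad - bc)^2 / (row x col products) = 7.2
  res <- sex_biased_mutations(mat, cl)
  expect_false(res$corrected)
  expect_equal(res$chi2, 7.2, tolerance = 1e-9)
  expect_equal(res$chi2, oracle_chi2_2x2(8, 2, 2, 8), tolerance = 1e-12)
  expect_equal(res$direction, "male_biased")
  # forcing Yates subtracts n/2 from |ad - bc|: chi2 = 5.0
  res_y <- sex_biased_mutations(mat, cl, correct = "always")
  expect_true(res_y$corrected)
  expect_equal(res_y$chi2, 5.0, tolerance = 1e-9)
})

test_that("uncorrected chi-square equals the closed-form oracle on random tables", {
  set.seed(13)
  for (i in 1:60) {
    # large margins keep all expected counts >= 5 so no correction applies
    a <- sample(20:60, 1); b <- sample(20:60, 1)
    c_ <- sample(20:60, 1); d <- sample(20:60, 1)
    sex <- c(rep("male", a + c_), rep("female", b + d))
    v <- c(rep(1, a), rep(0, c_), rep(1, b), rep(0, d))
    n <- length(v)
    mat <- matrix(v, 1, n, dimnames = list("G", paste0("S", 1:n)))
    cl <- tiny_clinical(paste0("S", 1:n), sex)
    res <- sex_biased_mutations(mat, cl)
    expect_false(res$corrected)
    expect_equal(res$chi2, oracle_chi2_2x2(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("equal frequencies give p ~ 1 and direction none; invariant to sample order", {
  samples <- paste0("S", 1:40)
  sex <- rep(c("male", "female"), 20)
  v <- rep(c(1, 1, 0, 0), 10)
  mat <- matrix(v, 1, 40, dimnames = list("G", samples))
  cl <- tiny_clinical(samples, sex)
  res <- sex_biased_mutations(mat, cl)
  expect_gt(res$p, 0.9)
  expect_equal(res$direction, "none")
  perm <- sample(40)
  res2 <- sex_biased_mutations(mat[, perm, drop = FALSE], cl[perm, ])
  expect_equal(res2$chi2, res$chi2)
})

test_that("single-predictor logistic recovers the closed-form log odds ratio", {
  # binary cell indicator, counts [[8,2],[2,8]] -> beta = ln(16)
  y <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  x <- c(rep(1, 10), rep(0, 10))
  mat <- matrix(y, 1, 20, dimnames = list("G", paste0("S", 1:20)))
  sc <- tibble::tibble(sample = paste0("S", 1:20), cellA = x)
  res <- mutation_cell_association(mat, sc, "G")
  # predictor is standardized, so the raw-coding coefficient is beta / sd(x)
  expect_equal(res$coefficient / stats::sd(x), log(16), tolerance = 1e-6)
  expect_equal(res$direction, "up")
})

test_that("planted cell-mutation association is detected; separation is excluded", {
  set.seed(29)
  hits <- 0
  for (s in 1:10) {
    n <- 200
    y <- rbinom(n, 1, 0.3)
    cellA <- rnorm(n) + y          # +1 SD in mutated patients
    cellB <- rnorm(n)
    mat <- matrix(y, 1, n, dimnames = list("G", paste0("S", 1:n)))
    sc <- tibble::tibble(sample = paste0("S", 1:n), cellA = cellA, cellB = cellB)
    res <- mutation_cell_association(mat, sc, "G")
    a <- res[res$cell == "cellA", ]
    if (a$coefficient > 0 && a$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # perfectly separating predictor -> gene excluded with a warning
  y <- rep(c(0, 1), each = 10)
  sep <- tibble::tibble(sample = paste0("S", 1:20), cellA = y * 2 - 1)
  mat <- matrix(y, 1, 20, dimnames = list("G", paste0("S", 1:20)))
  expect_warning(out <- mutation_cell_association(mat, sep, "G"),
                 "converge")
  expect_equal(nrow(out), 0)
})
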