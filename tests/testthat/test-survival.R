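test_that("Cox beta agrees with the grid-search partial-likelihood oracle", {
  # early deaths at the higher covariate level (without separation)
  r <- cox_univariate(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 0, 1, 0))
  expect_gt(r$beta, 0)
  expect_lt(abs(r$beta - oracle_cox_beta(c(1, 2, 3, 4), rep(1, 4),
                                         c(1, 0, 1, 0))), 1e-3)
  expect_equal(r$hr, exp(r$beta))
  # a covariate that perfectly orders the deaths has no finite maximizer
  sep <- cox_univariate(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 0, 0))
  expect_false(sep$converged)
  expect_error(cox_univariate(1:4, rep(1, 4), rep(0, 4)),
               class = "sextme_input_error")
  expect_error(cox_univariate(1:4, rep(0, 4), c(1, 0, 1, 0)),
               class = "sextme_no_events")

  set.seed(47)
  for (i in 1:25) {
    n <- sample(5:8, 1)
    tm <- sample(100, n)          # distinct times, no ties
    ev <- rep(1, n)
    x <- rnorm(n)
    fit <- tryCatch(cox_univariate(tm, ev, x), error = function(e) NULL)
    if (is.null(fit) || !fit$converged || !is.finite(fit$beta) ||
        abs(fit$beta) > 4 || fit$se > 5) next
    expect_lt(abs(fit$beta - oracle_cox_beta(tm, ev, x)), 1e-3)
  }
})

test_that("fitted beta is close to the planted hazard on PH simulations", {
  set.seed(61)
  betas <- vapply(1:20, function(i) {
    n <- 400
    x <- rnorm(n)
    t_event <- rexp(n, rate = 0.002 * exp(0.7 * x))
    cens <- runif(n, 0, quantile(t_event, 0.9) * 2)
    cox_univariate(pmin(t_event, cens), as.integer(t_event <= cens), x)$beta
  }, numeric(1))
  expect_equal(mean(betas), 0.7, tolerance = 0.1)
})

test_that("signature screening keeps Wald-significant cells with their betas", {
  set.seed(71)
  n <- 150
  cellA <- rnorm(n); cellB <- rnorm(n); cellC <- rnorm(n)
  t_event <- rexp(n, rate = 0.001 * exp(0.9 * cellA - 0.9 * cellB))
  cens <- runif(n, 0, quantile(t_event, 0.95) * 1.5)
  cl <- tiny_clinical(paste0("S", 1:n), rep("male", n),
                      os_time = pmin(t_event, cens),
                      os_event = as.integer(t_event <= cens))
  sc <- tibble::tibble(sample = paste0("S", 1:n),
                       cellA = cellA, cellB = cellB, cellC = cellC)
  sig <- build_signature(sc, cl, "male")
  expect_true(all(c("cellA", "cellB") %in% sig$signature$cell))
  expect_gt(sig$signature$beta[sig$signature$cell == "cellA"], 0)
  expect_lt(sig$signature$beta[sig$signature$cell == "cellB"], 0)
  # betas are the univariate coefficients, not a joint refit
  expect_equal(sig$signature$beta[sig$signature$cell == "cellA"],
               cox_univariate(cl$os_time, cl$os_event, cellA)$beta)
  td <- generics::tidy(sig)
  expect_true(all(td$in_signature == (td$covariate %in% sig$signature$cell)))
})

test_that("risk score is the signature-weighted sum; median split, ties to low", {
  sig <- tibble::tibble(cell = c("A", "B"), beta = c(0.5, -1))
  sc <- tibble::tibble(sample = "P1", A = 2, B = 1)
  expect_equal(risk_score(sig, sc)$risk_score, 0)

  sc4 <- tibble::tibble(sample = paste0("P", 1:4), A = c(1, 2, 3, 4),
                        B = rep(0, 4))
  rs <- risk_score(tibble::tibble(cell = c("A", "B"), beta = c(1, 1)), sc4)
  expect_equal(as.character(rs$group), c("low", "low", "high", "high"))

  # a score tied with the median goes to low
  sc3 <- tibble::tibble(sample = paste0("P", 1:3), A = c(1, 2, 3))
  rs3 <- risk_score(tibble::tibble(cell = "A", beta = 1), sc3)
  expect_equal(as.character(rs3$group), c("low", "low", "high"))

  expect_error(risk_score(tibble::tibble(cell = character(), beta = numeric()),
                          sc4), class = "sextme_input_error")
  expect_error(risk_score(tibble::tibble(cell = "Z", beta = 1), sc4),
               class = "sextme_input_error")
})

test_that("log-rank matches hand-computed O/E/V and KM curves behave", {
  km <- km_logrank(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(km$chi2, (2 - 0.83333)^2 / 0.472222, tolerance = 1e-4)
  expect_equal(km$p, 0.0896, tolerance = 1e-3)
  expect_equal(km$chi2, oracle_logrank_chi2(c(1, 2, 3, 4), rep(1, 4),
                                            c("A", "A", "B", "B")),
               tolerance = 1e-9)
  # identical groups: chi2 = 0
  km0 <- km_logrank(rep(c(1, 2, 3), 2), rep(1, 6),
                    rep(c("A", "B"), each = 3))
  expect_lt(km0$chi2, 1e-10)
  # curves start at 1 implicitly (first value <= 1) and never increase
  set.seed(83)
  tm <- rexp(30, 0.01); ev <- rbinom(30, 1, 0.7)
  g <- rep(c("A", "B"), 15)
  cv <- km_logrank(tm, ev, g)$curves
  for (grp in c("A", "B")) {
    s <- cv$survival[cv$group == grp]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(max(s), 1)
  }
  expect_error(km_logrank(tm, ev, rep("A", 30)),
               class = "sextme_input_error")
})

test_that("multivariable Cox: collinearity error, single-covariate consistency, planted effects", {
  set.seed(97)
  n <- 300
  x <- rnorm(n); age <- rnorm(n)
  t_event <- rexp(n, 0.001 * exp(0.6 * x + 0.5 * age))
  cens <- runif(n, 0, quantile(t_event, 0.9) * 2)
  tm <- pmin(t_event, cens); ev <- as.integer(t_event <= cens)

  expect_error(cox_multivariable(tm, ev, data.frame(a = x, b = x)),
               class = "sextme_collinearity")

  single <- cox_multivariable(tm, ev, data.frame(x = x))
  expect_equal(single$beta, cox_univariate(tm, ev, x)$beta, tolerance = 1e-8)

  hits <- vapply(1:10, function(s) {
    set.seed(s)
    x <- rnorm(n); age <- rnorm(n)
    t_event <- rexp(n, 0.001 * exp(0.6 * x + 0.5 * age))
    cens <- runif(n, 0, quantile(t_event, 0.9) * 2)
    fit <- cox_multivariable(pmin(t_event, cens),
                             as.integer(t_event <= cens),
                             data.frame(risk = x, age = age))
    all(fit$wald_p < 0.05)
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("stage labels map to ordinal integers", {
  expect_equal(stage_ordinal(c("I", "Stage II", "iii", "4", "X")),
               c(1L, 2L, 3L, 4L, NA))
})
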