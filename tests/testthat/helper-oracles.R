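# Independent brute-force oracles used across the suite. These deliberately
# re-derive each statistic from first principles, by a different route than
# the package code.

# single-sample enrichment by materializing both ECDFs position by position
oracle_ssgsea <- function(values, genes, set, alpha) {
  n <- length(values)
  ord <- order(-values, genes)
  hit <- genes[ord] %in% set
  w <- ifelse(hit, (n - seq_len(n) + 1)^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!hit) / sum(!hit)
  sum(p_in - p_out)
}

# textbook Benjamini-Hochberg step-up, written longhand
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# all permutations of 1..n, row per permutation (iterative construction,
# unlike the package's recursive generator)
oracle_perms <- function(n) {
  out <- matrix(1L, 1, 1)
  if (n == 1) return(out)
  for (k in 2:n) {
    pieces <- lapply(seq_len(k), function(pos) {
      left <- out[, seq_len(pos - 1), drop = FALSE]
      right <- if (pos <= k - 1) out[, pos:(k - 1), drop = FALSE]
               else out[, 0, drop = FALSE]
      cbind(left, k, right)
    })
    out <- do.call(rbind, pieces)
  }
  out
}

# AUC by explicit pairwise comparison with half credit for ties
oracle_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# Cox partial likelihood for a single covariate (no ties), evaluated on a
# dense beta grid; the argmax is the oracle estimate
oracle_cox_beta <- function(time, event, x, grid = seq(-5, 5, by = 1e-4)) {
  expb <- exp(outer(grid, x))            # |grid| x n
  ll <- numeric(length(grid))
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + grid * x[i] - log(rowSums(expb[, risk, drop = FALSE]))
  }
  grid[which.max(ll)]
}

# two-group log-rank chi-square from explicit risk-set bookkeeping
oracle_logrank_chi2 <- function(time, event, grp) {
  grp <- as.integer(as.factor(grp)) == 1
  dt <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in dt) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & grp)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n - d) / (n - 1) * n1 * (n - n1) / n^2
  }
  (o - e)^2 / v
}

# uncorrected 2x2 chi-square closed form n(ad-bc)^2 / (r1 r2 c1 c2)
oracle_chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# small helpers for building fixtures
tiny_expr <- function(values, genes, samples) {
  m <- matrix(values, nrow = length(genes),
              dimnames = list(genes, samples))
  expr_tibble(m)
}

tiny_clinical <- function(samples, sex, ...) {
  defaults <- tibble::tibble(
    sample = samples,
    sex = factor(sex, levels = c("male", "female")),
    age = 50, stage = "II", os_time = NA_real_, os_event = NA_integer_,
    response = NA_character_, immune_infiltrated = TRUE
  )
  extra <- list(...)
  for (nm in names(extra)) defaults[[nm]] <- extra[[nm]]
  defaults
}
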