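# Independent oracles used across the suite.  None of these share code with
# the package's computational paths.

# Observed-data log-likelihood of a 3x3 genotype count matrix (rows = dosage
# at G, cols = dosage at H) under haplotype frequencies p = (p11,p12,p21,p22),
# written cell by cell from the genotype probabilities.
oracle_loglik <- function(tab, p) {
  p <- pmax(p, 0)
  gp <- matrix(c(
    p[4]^2,          2 * p[3] * p[4],                 p[3]^2,
    2 * p[2] * p[4], 2 * (p[1] * p[4] + p[2] * p[3]), 2 * p[1] * p[3],
    p[2]^2,          2 * p[1] * p[2],                 p[1]^2
  ), nrow = 3, byrow = TRUE)
  keep <- tab > 0
  sum(tab[keep] * log(gp[keep]))
}

# Grid-search maximizer of the observed-data likelihood.  Uses the exact
# M-step identity that the MLE marginals equal the observed allele
# frequencies, reducing the search to a fine 1-d grid over p11 within its
# Frechet range (validated against an unconstrained 3-d grid in the tests).
oracle_grid_mle <- function(tab, step = 1e-4) {
  n <- sum(tab)
  pg <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)        # rows index G dosage
  ph <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  lo <- max(0, pg + ph - 1)
  hi <- min(pg, ph)
  p11 <- seq(lo, hi, by = step)
  ll <- vapply(p11, function(x) {
    oracle_loglik(tab, c(x, pg - x, ph - x, 1 - pg - ph + x))
  }, numeric(1))
  best <- p11[which.max(ll)]
  c(best, pg - best, ph - best, 1 - pg - ph + best)
}

# Unconstrained coarse + local-refine 3-d grid search over (p11, p12, p21).
oracle_grid_mle_3d <- function(tab, coarse = 0.02, fine = 1e-3) {
  eval_grid <- function(p11, p12, p21) {
    keep <- p11 + p12 + p21 <= 1
    p11 <- p11[keep]; p12 <- p12[keep]; p21 <- p21[keep]
    ll <- mapply(function(a, b, c) oracle_loglik(tab, c(a, b, c, 1 - a - b - c)),
                 p11, p12, p21)
    k <- which.max(ll)
    c(p11[k], p12[k], p21[k])
  }
  g <- seq(1e-4, 1 - 1e-4, by = coarse)
  gr <- expand.grid(p11 = g, p12 = g, p21 = g)
  best <- eval_grid(gr$p11, gr$p12, gr$p21)
  f <- function(x) seq(max(1e-6, x - 1.5 * coarse), min(1 - 1e-6, x + 1.5 * coarse), by = fine)
  gr <- expand.grid(p11 = f(best[1]), p12 = f(best[2]), p21 = f(best[3]))
  best <- eval_grid(gr$p11, gr$p12, gr$p21)
  c(best, 1 - sum(best))
}

# Brute-force Benjamini-Hochberg step-up q-values (quadratic time).
oracle_bh <- function(p, m = length(p)) {
  ord <- order(p)
  q <- numeric(length(p))
  for (k in seq_along(ord)) {
    i <- ord[k]
    q[i] <- min(1, min(m * p[ord[k:length(ord)]] /
                         seq(k, length(ord))))
  }
  q
}

# Plain IRLS fit of logit(y) ~ 1 + g + h + g:h, independent of stats::glm.
oracle_irls_logistic <- function(y, g, h, iter = 50) {
  X <- cbind(1, g, h, g * h)
  beta <- rep(0, 4)
  for (k in seq_len(iter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta <- solve(t(X) %*% (X * w), t(X) %*% (w * z))
  }
  eta <- as.vector(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  V <- solve(t(X) %*% (X * (mu * (1 - mu))))
  list(coef = as.vector(beta), wald_int = beta[4]^2 / V[4, 4])
}

# Woolf-style allele-table statistic computed by direct arithmetic from a
# pair of 2x2 tables (b = c(b11, b12, b21, b22)).
oracle_woolf <- function(b_case, b_ctrl) {
  lodds <- function(b) log(b[1] * b[4] / (b[2] * b[3]))
  se2 <- function(b) sum(1 / b)
  (lodds(b_case) - lodds(b_ctrl))^2 / (se2(b_case) + se2(b_ctrl))
}

# Random small two-locus genotype table with n individuals.
random_table <- function(n, rng_p = NULL) {
  if (is.null(rng_p)) {
    p <- stats::runif(4)
    p <- p / sum(p)
  } else {
    p <- rng_p
  }
  spec_cells <- c(
    p[4]^2, 2 * p[3] * p[4], p[3]^2,
    2 * p[2] * p[4], 2 * (p[1] * p[4] + p[2] * p[3]), 2 * p[1] * p[3],
    p[2]^2, 2 * p[1] * p[2], p[1]^2
  )
  cells <- as.vector(stats::rmultinom(1, n, spec_cells))
  matrix(cells, nrow = 3, byrow = TRUE)
}

# Dosage vectors realizing a 9-cell count vector (kernel cell order).
table_to_dosages <- function(tab) {
  cells <- as.vector(t(tab))
  i <- rep(rep(0:2, each = 3), cells)
  j <- rep(rep(0:2, times = 3), cells)
  list(g = i, h = j)
}

# Simulated case/control panel with one planted interacting pair among
# otherwise independent null SNPs.  Returns a genotype_panel.
planted_panel <- function(n_null_snps, n_case, n_ctrl, lambda3, seed,
                          maf_range = c(0.2, 0.5), mode = "recessive") {
  set.seed(seed)
  spec <- population_spec(0.5, 0.5, 0)
  model <- disease_model(mode, lambda3 = lambda3, f0 = 0.1)
  cc <- ascertain(n_case, n_ctrl, spec, model)
  n <- n_case + n_ctrl
  geno <- matrix(NA_integer_, n, n_null_snps + 2)
  geno[, 1] <- c(cc$case$g, cc$control$g)
  geno[, 2] <- c(cc$case$h, cc$control$h)
  for (k in seq_len(n_null_snps)) {
    maf <- stats::runif(1, maf_range[1], maf_range[2])
    geno[, k + 2] <- stats::rbinom(n, 2, maf)
  }
  ids <- c("rs_planted_1", "rs_planted_2",
           sprintf("rs_null_%03d", seq_len(n_null_snps)))
  meta <- tibble::tibble(
    id = ids, chrom = "1", pos = seq_len(n_null_snps + 2) * 1000L,
    allele1 = "A", allele2 = "B"
  )
  hapint:::new_genotype_panel(
    geno, meta, c(rep(1L, n_case), rep(0L, n_ctrl)),
    sample_id = sprintf("ind%05d", seq_len(n))
  )
}
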