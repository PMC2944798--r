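# Vectorized EM / test kernels shared by the user-facing test functions and
# the simulation engine.  All kernels operate on matrices of two-locus
# genotype counts with one row per dataset (replicate) and nine columns in
# cell order (i, j) = (0,0),(0,1),(0,2),(1,0),(1,1),(1,2),(2,0),(2,1),(2,2),
# where i is the dosage of allele G1 at the first locus and j the dosage of
# allele H1 at the second.  Column index = 3*i + j + 1.

CELL_ORDER <- cbind(
  i = rep(0:2, each = 3),
  j = rep(0:2, times = 3)
)

# Unambiguous haplotype counts contributed by the eight phase-certain cells,
# plus the double-heterozygote count.  Returns components of length nrow(N).
.hap_count_components <- function(N) {
  list(
    a11 = 2 * N[, 9] + N[, 8] + N[, 6],  # G1H1 from (2,2),(2,1),(1,2)
    a12 = 2 * N[, 7] + N[, 8] + N[, 4],  # G1H2 from (2,0),(2,1),(1,0)
    a21 = 2 * N[, 3] + N[, 6] + N[, 2],  # G2H1 from (0,2),(1,2),(0,1)
    a22 = 2 * N[, 1] + N[, 4] + N[, 2],  # G2H2 from (0,0),(1,0),(0,1)
    dh  = N[, 5],                        # (1,1): phase ambiguous
    n_hap = 2 * rowSums(N)
  )
}

# EM for pseudohaplotype frequencies, vectorized across rows of N.
# Initialization is the linkage-equilibrium product of the observed allele
# frequencies; the double heterozygotes are the only ambiguous cell, with
# cis-phase posterior phi = p11 p22 / (p11 p22 + p12 p21) (phi = 1/2 when both
# phase products vanish).  Returns a reps x 4 frequency matrix plus
# per-row iteration counts and convergence flags.
.em_freqs_vec <- function(N, tol = 1e-10, max_iter = 1000L) {
  hc <- .hap_count_components(N)
  nh <- hc$n_hap
  if (any(nh == 0)) stop("EM on a table with zero individuals", call. = FALSE)
  p_g <- (hc$a11 + hc$a12 + hc$dh) / nh
  p_h <- (hc$a11 + hc$a21 + hc$dh) / nh
  p11 <- p_g * p_h
  p12 <- p_g * (1 - p_h)
  p21 <- (1 - p_g) * p_h
  p22 <- (1 - p_g) * (1 - p_h)
  iters <- rep.int(0L, nrow(N))
  converged <- rep.int(FALSE, nrow(N))
  # Rows with no double heterozygotes are exact at the direct-count solution.
  exact <- hc$dh == 0
  if (any(exact)) {
    p11[exact] <- hc$a11[exact] / nh[exact]
    p12[exact] <- hc$a12[exact] / nh[exact]
    p21[exact] <- hc$a21[exact] / nh[exact]
    p22[exact] <- hc$a22[exact] / nh[exact]
    converged[exact] <- TRUE
  }
  active <- which(!exact)
  it <- 0L
  while (length(active) > 0L && it < max_iter) {
    it <- it + 1L
    cis <- p11[active] * p22[active]
    trans <- p12[active] * p21[active]
    den <- cis + trans
    phi <- ifelse(den > 0, cis / den, 0.5)
    w <- phi * hc$dh[active]
    v <- (1 - phi) * hc$dh[active]
    n11 <- (hc$a11[active] + w) / nh[active]
    n12 <- (hc$a12[active] + v) / nh[active]
    n21 <- (hc$a21[active] + v) / nh[active]
    n22 <- (hc$a22[active] + w) / nh[active]
    delta <- pmax(
      abs(n11 - p11[active]), abs(n12 - p12[active]),
      abs(n21 - p21[active]), abs(n22 - p22[active])
    )
    p11[active] <- n11; p12[active] <- n12
    p21[active] <- n21; p22[active] <- n22
    iters[active] <- it
    done <- delta < tol
    converged[active[done]] <- TRUE
    active <- active[!done]
  }
  list(
    p = cbind(p11 = p11, p12 = p12, p21 = p21, p22 = p22),
    iterations = iters, converged = converged, n_hap = nh
  )
}

# Observed-data log-likelihood (full multinomial over the nine genotype
# cells) for one frequency vector.
.obs_loglik <- function(N_row, p) {
  gp <- c(
    p[4]^2, 2 * p[3] * p[4], p[3]^2,
    2 * p[2] * p[4], 2 * (p[1] * p[4] + p[2] * p[3]), 2 * p[1] * p[3],
    p[2]^2, 2 * p[1] * p[2], p[1]^2
  )
  keep <- N_row > 0
  sum(N_row[keep] * log(gp[keep]))
}

# Haldane-Anscombe-style continuity correction, vectorized: rows with any
# frequency below `eps` get 0.5 added to each of the four expected haplotype
# counts and are renormalized.  Returns the adjusted matrix and a flag.
.continuity_correct <- function(p, n_hap, eps = 1e-8) {
  bad <- p[, 1] < eps | p[, 2] < eps | p[, 3] < eps | p[, 4] < eps
  if (any(bad)) {
    nh <- n_hap[bad]
    p[bad, ] <- (p[bad, , drop = FALSE] * nh + 0.5) / (nh + 2)
  }
  list(p = p, corrected = bad)
}

# Per-group delta-method variance of the log cross-ratio from the
# observed-data (genotype multinomial) information, vectorized.  With
# theta = (p11, p12, p21) free and p22 = 1 - p11 - p12 - p21, the genotype
# log-likelihood is
#   l = a11 log p11 + a12 log p12 + a21 log p21 + a22 log p22
#       + n11 log(p11 p22 + p12 p21)
# (a's the phase-certain haplotype counts, n11 the double heterozygotes).
# Var(lcr) = g' J^{-1} g with J = -Hessian(l) at the estimate and g the
# gradient of lcr = log(p11 p22 / (p12 p21)).  When n11 = 0 this reduces
# exactly to the phased-haplotype form sum(1/p) / n_hap.  Phase ambiguity
# inflates the variance (by a factor of 2 at linkage equilibrium), which the
# phased-count formula misses.
.lcr_info_variance <- function(N, p) {
  hc <- .hap_count_components(N)
  p11 <- p[, 1]; p12 <- p[, 2]; p21 <- p[, 3]; p22 <- p[, 4]
  S <- p11 * p22 + p12 * p21
  d22 <- p22 - p11
  d21 <- p21 - p11
  d12 <- p12 - p11
  b <- hc$a22 / p22^2
  r <- hc$dh / S^2
  j11 <- hc$a11 / p11^2 + b + r * (2 * S + d22^2)
  j12 <- b + r * (S + d22 * d21)
  j13 <- b + r * (S + d22 * d12)
  j22 <- hc$a12 / p12^2 + b + r * d21^2
  j23 <- b + r * (d21 * d12 - S)
  j33 <- hc$a21 / p21^2 + b + r * d12^2
  # closed-form inverse of the symmetric 3x3 information matrix
  c11 <- j22 * j33 - j23^2
  c12 <- j13 * j23 - j12 * j33
  c13 <- j12 * j23 - j13 * j22
  det <- j11 * c11 + j12 * c12 + j13 * c13
  c22 <- j11 * j33 - j13^2
  c23 <- j12 * j13 - j11 * j23
  c33 <- j11 * j22 - j12^2
  g1 <- 1 / p11 - 1 / p22
  g2 <- -1 / p12 - 1 / p22
  g3 <- -1 / p21 - 1 / p22
  (g1 * (c11 * g1 + c12 * g2 + c13 * g3) +
     g2 * (c12 * g1 + c22 * g2 + c23 * g3) +
     g3 * (c13 * g1 + c23 * g2 + c33 * g3)) / det
}

# T_IH statistic, vectorized over paired case/control count matrices.
.tih_stat_vec <- function(N_case, N_ctrl, tol = 1e-10, max_iter = 1000L,
                          correction = TRUE, case_only = FALSE,
                          variance_method = "information") {
  em_a <- .em_freqs_vec(N_case, tol, max_iter)
  n_a <- rowSums(N_case)
  if (correction) {
    cc_a <- .continuity_correct(em_a$p, em_a$n_hap)
    p_a <- cc_a$p
    corrected <- cc_a$corrected
  } else {
    p_a <- em_a$p
    corrected <- rep.int(FALSE, nrow(N_case))
  }
  lcr_a <- log(p_a[, 1]) + log(p_a[, 4]) - log(p_a[, 2]) - log(p_a[, 3])
  var_a <- if (variance_method == "information") {
    .lcr_info_variance(N_case, p_a)
  } else {
    (1 / (2 * n_a)) * rowSums(1 / p_a)
  }
  if (case_only) {
    measure <- lcr_a
    variance <- var_a
  } else {
    em_g <- .em_freqs_vec(N_ctrl, tol, max_iter)
    n_g <- rowSums(N_ctrl)
    if (correction) {
      cc_g <- .continuity_correct(em_g$p, em_g$n_hap)
      p_g <- cc_g$p
      corrected <- corrected | cc_g$corrected
    } else {
      p_g <- em_g$p
    }
    lcr_g <- log(p_g[, 1]) + log(p_g[, 4]) - log(p_g[, 2]) - log(p_g[, 3])
    measure <- lcr_a - lcr_g
    var_g <- if (variance_method == "information") {
      .lcr_info_variance(N_ctrl, p_g)
    } else {
      (1 / (2 * n_g)) * rowSums(1 / p_g)
    }
    variance <- var_a + var_g
  }
  measure <- unname(measure)
  variance <- unname(variance)
  statistic <- measure^2 / variance
  list(
    measure = measure, variance = variance, statistic = statistic,
    p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
    corrected = unname(corrected),
    case_freqs = p_a,
    ctrl_freqs = if (case_only) NULL else p_g,
    case_em = em_a,
    ctrl_em = if (case_only) NULL else em_g
  )
}

# Allele-based ("fast-epistasis") statistic, vectorized.  The 2x2 allele-pair
# table assigns unambiguous haplotypes from the phase-certain cells and splits
# each double heterozygote's two haplotypes equally between the cis and trans
# resolutions; no EM phase information is used.
.fast_stat_vec <- function(N_case, N_ctrl) {
  tab <- function(N) {
    hc <- .hap_count_components(N)
    b <- cbind(
      hc$a11 + 0.5 * hc$dh, hc$a12 + 0.5 * hc$dh,
      hc$a21 + 0.5 * hc$dh, hc$a22 + 0.5 * hc$dh
    )
    zero <- b[, 1] == 0 | b[, 2] == 0 | b[, 3] == 0 | b[, 4] == 0
    if (any(zero)) b[zero, ] <- b[zero, , drop = FALSE] + 0.5
    lnor <- log(b[, 1]) + log(b[, 4]) - log(b[, 2]) - log(b[, 3])
    list(lnor = lnor, se2 = rowSums(1 / b), corrected = zero)
  }
  ca <- tab(N_case)
  co <- tab(N_ctrl)
  measure <- unname(ca$lnor - co$lnor)
  variance <- unname(ca$se2 + co$se2)
  statistic <- measure^2 / variance
  list(
    measure = measure, variance = variance, statistic = statistic,
    p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
    corrected = ca$corrected | co$corrected
  )
}

# Fast 3x3 cross-tabulation of two dosage vectors into the nine-cell layout,
# dropping pairs missing at either locus.
.count_cells <- function(g, h) {
  keep <- !is.na(g) & !is.na(h)
  tabulate(3L * g[keep] + h[keep] + 1L, nbins = 9L)
}
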