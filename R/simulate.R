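#' Specify a two-locus source population
#'
#' A population of two biallelic loci is parameterized by the allele
#' frequencies `p_g` (allele G1) and `p_h` (allele H1) and the linkage
#' disequilibrium coefficient `d`, so the G1H1 haplotype frequency is
#' `p_g * p_h + d`. `d` must respect the Frechet bounds, i.e. all four
#' implied haplotype frequencies must lie in `[0, 1]`.
#'
#' @param p_g,p_h Allele frequencies in `(0, 1)`.
#' @param d Disequilibrium coefficient (default 0, linkage equilibrium).
#' @return An object of class `population_spec`.
#' @examples
#' population_spec(0.5, 0.5, d = 0.1)
#' @export
population_spec <- function(p_g, p_h, d = 0) {
  stopifnot(p_g > 0, p_g < 1, p_h > 0, p_h < 1)
  hap <- c(
    p11 = p_g * p_h + d,
    p12 = p_g * (1 - p_h) - d,
    p21 = (1 - p_g) * p_h - d,
    p22 = (1 - p_g) * (1 - p_h) + d
  )
  if (any(hap < -1e-12) || any(hap > 1 + 1e-12)) {
    stop("`d` violates the Frechet bounds for these allele frequencies",
         call. = FALSE)
  }
  structure(list(p_g = p_g, p_h = p_h, d = d, hap = pmin(pmax(hap, 0), 1)),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Two-locus population: p_G1 =", x$p_g, ", p_H1 =", x$p_h,
      ", D =", x$d, "\n")
  invisible(x)
}

#' Haplotype distribution implied by a population specification
#'
#' @param spec A [population_spec()].
#' @return Named numeric vector `(p11, p12, p21, p22)` summing to 1.
#' @export
haplotype_distribution <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  spec$hap
}

# Nine-cell joint genotype distribution under random union of gametes
# (Hardy-Weinberg at the haplotype level), in kernel cell order.
genotype_distribution <- function(spec) {
  p <- if (inherits(spec, "population_spec")) spec$hap else as_hap_probs(spec)
  c(
    p[4]^2,                      # (0,0)
    2 * p[3] * p[4],             # (0,1)
    p[3]^2,                      # (0,2)
    2 * p[2] * p[4],             # (1,0)
    2 * (p[1] * p[4] + p[2] * p[3]),  # (1,1)
    2 * p[1] * p[3],             # (1,2)
    p[2]^2,                      # (2,0)
    2 * p[1] * p[2],             # (2,1)
    p[1]^2                       # (2,2)
  )
}

# Expand per-cell counts into dosage vectors (kernel cell order).
cells_to_dosages <- function(counts) {
  i <- rep.int(CELL_ORDER[, "i"], counts)
  j <- rep.int(CELL_ORDER[, "j"], counts)
  tibble::tibble(g = as.integer(i), h = as.integer(j))
}

#' Simulate unphased genotypes from a two-locus population
#'
#' Each individual is formed by random union of two gametes drawn
#' independently from the population haplotype distribution, so genotypes
#' are in Hardy-Weinberg proportions at the haplotype level. Phase is then
#' discarded: only allele dosages per locus are returned.
#'
#' @param n Number of individuals.
#' @param spec A [population_spec()].
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with integer columns `g` and `h` (dosages of G1 and H1).
#' @examples
#' simulate_genotypes(5, population_spec(0.5, 0.5), seed = 1)
#' @export
simulate_genotypes <- function(n, spec, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  p9 <- genotype_distribution(spec)
  idx <- sample.int(9L, n, replace = TRUE, prob = p9)
  tibble::tibble(
    g = as.integer(CELL_ORDER[idx, "i"]),
    h = as.integer(CELL_ORDER[idx, "j"])
  )
}

#' Specify a two-locus disease model
#'
#' Penetrance follows a multiplicative-odds model over mode-specific genotype
#' scores `x`, `y` (recessive: 1 only for the risk homozygote; dominant: 1
#' for carriers; additive: the dosage):
#' `odds(i, j) = delta * lambda1^x * lambda2^y * lambda3^(x*y)`,
#' `f(i, j) = odds / (1 + odds)`. `lambda1` and `lambda2` are the marginal
#' genotype odds ratios, `lambda3` the interaction odds ratio, and the
#' baseline `delta` is solved numerically so the population prevalence
#' equals `f0` (see [penetrance_table()]).
#'
#' @param mode_g,mode_h Per-locus mode: `"recessive"`, `"dominant"` or
#'   `"additive"`.
#' @param lambda1,lambda2 Marginal genotype odds ratios (>= 0).
#' @param lambda3 Interaction odds ratio (>= 0); 1 means no interaction.
#' @param f0 Population prevalence in `(0, 1)`.
#' @return An object of class `disease_model`.
#' @examples
#' disease_model("dominant", "dominant", lambda3 = 2, f0 = 0.1)
#' @export
disease_model <- function(mode_g = c("recessive", "dominant", "additive"),
                          mode_h = mode_g, lambda1 = 1, lambda2 = 1,
                          lambda3 = 1, f0 = 0.1) {
  mode_g <- match.arg(mode_g)
  mode_h <- match.arg(mode_h, c("recessive", "dominant", "additive"))
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0, f0 > 0, f0 < 1)
  structure(
    list(mode_g = mode_g, mode_h = mode_h, lambda1 = lambda1,
         lambda2 = lambda2, lambda3 = lambda3, f0 = f0),
    class = "disease_model"
  )
}

#' @export
print.disease_model <- function(x, ...) {
  cat("Two-locus disease model: ", x$mode_g, " x ", x$mode_h,
      ", lambda = (", x$lambda1, ", ", x$lambda2, ", ", x$lambda3,
      "), f0 = ", x$f0, "\n", sep = "")
  invisible(x)
}

mode_score <- function(dosage, mode) {
  switch(mode,
    recessive = as.integer(dosage == 2),
    dominant  = as.integer(dosage >= 1),
    additive  = as.integer(dosage)
  )
}

#' Penetrance table of a two-locus disease model
#'
#' Computes the 3x3 matrix of penetrances `f(i, j)` for joint dosages
#' `(i, j)` under the multiplicative-odds model of [disease_model()]. The
#' baseline odds factor `delta` is solved by bisection (tolerance 1e-12 on
#' prevalence) so that the expected penetrance over the genotype
#' distribution implied by `spec` equals the model prevalence `f0`.
#'
#' @param model A [disease_model()].
#' @param spec A [population_spec()] supplying the genotype distribution
#'   used to anchor the prevalence.
#' @return A 3x3 penetrance matrix (rows: dosage at G, columns: dosage at
#'   H) with the solved baseline in `attr(, "delta")`.
#' @examples
#' penetrance_table(disease_model("dominant", lambda3 = 2),
#'                  population_spec(0.5, 0.5))
#' @export
penetrance_table <- function(model, spec) {
  stopifnot(inherits(model, "disease_model"))
  p9 <- genotype_distribution(spec)
  x <- mode_score(CELL_ORDER[, "i"], model$mode_g)
  y <- mode_score(CELL_ORDER[, "j"], model$mode_h)
  lam <- model$lambda1^x * model$lambda2^y * model$lambda3^(x * y)
  if (any(!is.finite(lam)) || all(lam == 0)) {
    stop("degenerate odds-ratio parameters: no admissible baseline",
         call. = FALSE)
  }
  prevalence <- function(delta) sum(p9 * delta * lam / (1 + delta * lam))
  lo <- 1e-300
  hi <- 1e300
  if (prevalence(hi) < model$f0) {
    stop("no admissible baseline delta: prevalence cannot reach f0",
         call. = FALSE)
  }
  for (k in seq_len(2000L)) {
    mid <- exp((log(lo) + log(hi)) / 2)
    pm <- prevalence(mid)
    if (abs(pm - model$f0) < 1e-12) break
    if (pm < model$f0) lo <- mid else hi <- mid
  }
  f <- mid * lam / (1 + mid * lam)
  out <- matrix(f, nrow = 3, byrow = TRUE,
                dimnames = list(g_dosage = 0:2, h_dosage = 0:2))
  attr(out, "delta") <- mid
  out
}

# Penetrance in kernel cell order plus the conditional genotype
# distributions given case / control status.
.cc_distributions <- function(model, spec) {
  pen <- penetrance_table(model, spec)
  f <- as.vector(t(pen))           # back to kernel cell order
  p9 <- genotype_distribution(spec)
  f0 <- sum(p9 * f)
  list(
    f = f, p9 = p9, f0 = f0,
    p_case = p9 * f / f0,
    p_ctrl = p9 * (1 - f) / (1 - f0)
  )
}

#' Ascertain a case-control sample under a disease model
#'
#' Rejection sampling from the source population: individuals are drawn from
#' the population genotype distribution, assigned affected status with
#' probability equal to their penetrance, and accumulated until both the
#' case and the control quota are filled.
#'
#' @param n_case,n_ctrl Target group sizes.
#' @param spec A [population_spec()].
#' @param model A [disease_model()].
#' @param seed Optional integer seed.
#' @return A list with tibbles `case` and `control`, each with dosage
#'   columns `g` and `h`.
#' @examples
#' s <- ascertain(50, 50, population_spec(0.5, 0.5),
#'                disease_model("dominant", lambda3 = 3), seed = 1)
#' nrow(s$case)
#' @export
ascertain <- function(n_case, n_ctrl, spec, model, seed = NULL) {
  stopifnot(n_case >= 1, n_ctrl >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- .cc_distributions(model, spec)
  if (d$f0 <= 0 || d$f0 >= 1) {
    stop("ascertainment impossible: population prevalence is 0 or 1",
         call. = FALSE)
  }
  case_counts <- integer(9L)
  ctrl_counts <- integer(9L)
  got_case <- 0L
  got_ctrl <- 0L
  while (got_case < n_case || got_ctrl < n_ctrl) {
    need <- max((n_case - got_case) / max(d$f0, 1e-6),
                (n_ctrl - got_ctrl) / max(1 - d$f0, 1e-6))
    b <- as.integer(min(ceiling(1.2 * need) + 100, 5e6))
    idx <- sample.int(9L, b, replace = TRUE, prob = d$p9)
    aff <- stats::rbinom(b, 1L, d$f[idx]) == 1L
    new_cases <- idx[aff]
    new_ctrls <- idx[!aff]
    take_c <- min(length(new_cases), n_case - got_case)
    take_u <- min(length(new_ctrls), n_ctrl - got_ctrl)
    if (take_c > 0) {
      case_counts <- case_counts +
        tabulate(new_cases[seq_len(take_c)], nbins = 9L)
      got_case <- got_case + take_c
    }
    if (take_u > 0) {
      ctrl_counts <- ctrl_counts +
        tabulate(new_ctrls[seq_len(take_u)], nbins = 9L)
      got_ctrl <- got_ctrl + take_u
    }
  }
  list(case = cells_to_dosages(case_counts),
       control = cells_to_dosages(ctrl_counts))
}

sim_report_row <- function(test, model, spec, n, alpha, reps, seed, rate) {
  if (is.null(model)) {
    mg <- "null"; mh <- "null"; l1 <- NA_real_; l2 <- NA_real_
    l3 <- NA_real_; f0 <- NA_real_
  } else {
    mg <- model$mode_g; mh <- model$mode_h
    l1 <- model$lambda1; l2 <- model$lambda2; l3 <- model$lambda3
    f0 <- model$f0
  }
  tibble::tibble(
    test = test, model = paste(mg, mh, sep = "x"),
    lambda1 = l1, lambda2 = l2, lambda3 = l3, f0 = f0,
    pG = spec$p_g, pH = spec$p_h, D = spec$d,
    n = n, alpha = alpha, reps = reps,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    rate = rate, mc_se = sqrt(rate * (1 - rate) / reps)
  )
}

# Vectorized p-values for `reps` replicate case/control count matrices under
# the named test.
.replicate_pvalues <- function(test, N_case, N_ctrl) {
  if (test == "T_IH") {
    .tih_stat_vec(N_case, N_ctrl)$p_value
  } else if (test == "T_IH_case_only") {
    .tih_stat_vec(N_case, NULL, case_only = TRUE)$p_value
  } else if (test == "fast_epistasis") {
    .fast_stat_vec(N_case, N_ctrl)$p_value
  } else if (grepl("^logistic_", test)) {
    coding <- sub("^logistic_", "", test)
    xg <- mode_score(CELL_ORDER[, "i"],
                     if (coding == "additive") "additive" else coding)
    yh <- mode_score(CELL_ORDER[, "j"],
                     if (coding == "additive") "additive" else coding)
    vapply(seq_len(nrow(N_case)), function(r) {
      yy <- cbind(N_case[r, ], N_ctrl[r, ])
      fit <- tryCatch(
        suppressWarnings(stats::glm(yy ~ xg * yh, family = stats::binomial())),
        error = function(e) NULL
      )
      if (is.null(fit) || is.na(stats::coef(fit)["xg:yh"])) return(NA_real_)
      b <- stats::coef(fit)["xg:yh"]
      v <- stats::vcov(fit)["xg:yh", "xg:yh"]
      stats::pchisq(b^2 / v, 1, lower.tail = FALSE)
    }, numeric(1))
  } else {
    stop("unknown test tag: ", test, call. = FALSE)
  }
}

#' Estimate type I error of an interaction test under the exact null
#'
#' Per replicate, two groups of `n_per_group` individuals are drawn
#' independently from the same two-locus population (no phenotype model, so
#' the null of no interaction holds exactly), the chosen test is applied,
#' and rejection at each nominal level is recorded. The EM and statistic are
#' evaluated vectorized across replicates, so 10,000-replicate runs complete
#' in seconds.
#'
#' @param spec A [population_spec()] for the null population.
#' @param n_per_group Individuals per group ("sample size" of the design).
#' @param reps Number of simulation replicates.
#' @param alphas Nominal significance levels to evaluate.
#' @param seed Optional integer seed.
#' @param test Test tag: `"T_IH"` (default), `"T_IH_case_only"`,
#'   `"fast_epistasis"` or `"logistic_<coding>"`.
#' @return A `hapint_sim_report` tibble with one row per nominal level:
#'   columns `test`, `model`, the population and design parameters, `rate`
#'   (empirical rejection fraction) and `mc_se` (its binomial Monte-Carlo
#'   standard error).
#' @examples
#' estimate_type1_error(population_spec(0.5, 0.5), 100,
#'                      reps = 200, seed = 1)
#' @export
estimate_type1_error <- function(spec, n_per_group, reps = 10000L,
                                 alphas = c(0.05, 0.01, 0.001), seed = NULL,
                                 test = "T_IH") {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  p9 <- genotype_distribution(spec)
  N_case <- t(stats::rmultinom(reps, n_per_group, p9))
  N_ctrl <- t(stats::rmultinom(reps, n_per_group, p9))
  pv <- .replicate_pvalues(test, N_case, N_ctrl)
  ok <- sum(!is.na(pv))
  out <- purrr::map_dfr(alphas, function(a) {
    sim_report_row(test, NULL, spec, n_per_group, a, ok, seed,
                   mean(pv <= a, na.rm = TRUE))
  })
  class(out) <- c("hapint_sim_report", class(out))
  out
}

#' Estimate power of interaction tests across an interaction-effect grid
#'
#' For each value of the interaction odds ratio `lambda3`, case-control
#' samples are ascertained under the two-locus disease model, each requested
#' test is applied, and the rejection fraction at level `alpha` is reported.
#' The default sampler draws the fixed-quota groups directly from the
#' conditional genotype distributions P(genotype | case) and
#' P(genotype | control), which is distributionally identical to rejection
#' sampling individuals until both quotas fill (individuals are iid and the
#' stopping rule carries no genotype information); `sampler = "rejection"`
#' performs the literal rejection design via [ascertain()].
#'
#' @param spec A [population_spec()].
#' @param model A [disease_model()] template; its `lambda3` is replaced by
#'   each grid value in turn.
#' @param lambda3 Grid of interaction odds ratios.
#' @param tests Character vector of test tags (see
#'   [estimate_type1_error()]).
#' @param n_per_group Cases and controls per sample.
#' @param reps Replicates per grid point.
#' @param alpha Significance level.
#' @param seed Optional integer seed.
#' @param sampler `"conditional"` (default) or `"rejection"`.
#' @return A `hapint_sim_report` tibble with one row per
#'   `lambda3` x test combination.
#' @examples
#' estimate_power(population_spec(0.5, 0.5),
#'                disease_model("dominant"), lambda3 = c(1, 3),
#'                n_per_group = 200, reps = 50, seed = 1)
#' @export
estimate_power <- function(spec, model, lambda3 = c(1, 1.5, 2, 2.5, 3, 4),
                           tests = "T_IH", n_per_group = 1000L, reps = 2000L,
                           alpha = 0.05, seed = NULL,
                           sampler = c("conditional", "rejection")) {
  stopifnot(length(lambda3) >= 1, reps >= 1)
  sampler <- match.arg(sampler)
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::map_dfr(lambda3, function(l3) {
    m <- model
    m$lambda3 <- l3
    d <- .cc_distributions(m, spec)
    if (sampler == "conditional") {
      N_case <- t(stats::rmultinom(reps, n_per_group, d$p_case))
      N_ctrl <- t(stats::rmultinom(reps, n_per_group, d$p_ctrl))
    } else {
      draws <- purrr::map(seq_len(reps), function(r) {
        s <- ascertain(n_per_group, n_per_group, spec, m)
        list(case = .count_cells(s$case$g, s$case$h),
             ctrl = .count_cells(s$control$g, s$control$h))
      })
      N_case <- do.call(rbind, purrr::map(draws, "case"))
      N_ctrl <- do.call(rbind, purrr::map(draws, "ctrl"))
    }
    purrr::map_dfr(tests, function(tg) {
      pv <- .replicate_pvalues(tg, N_case, N_ctrl)
      ok <- sum(!is.na(pv))
      sim_report_row(tg, m, spec, n_per_group, alpha, ok, seed,
                     mean(pv <= alpha, na.rm = TRUE))
    })
  })
  class(out) <- c("hapint_sim_report", class(out))
  out
}

#' Read a plain key-value simulation configuration
#'
#' Parses `key = value` lines (comments start with `#`); numeric-looking
#' values are converted. Recognized keys mirror the arguments of
#' [estimate_type1_error()] and [estimate_power()].
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  vals <- lapply(kv, function(x) {
    parts <- strsplit(x[2], "\\s*,\\s*")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  stats::setNames(vals, vapply(kv, `[`, "", 1))
}

#' Write a simulation report as a tab-separated table
#'
#' @param report A `hapint_sim_report` tibble.
#' @param path Output path.
#' @return `report`, invisibly.
#' @export
write_sim_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(report)
}
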