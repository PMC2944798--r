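#' Haplotype odds-ratio interaction measure
#'
#' The multiplicative interaction measure between two biallelic loci is the
#' difference of log haplotype-frequency cross-ratios between cases and
#' controls:
#' `I = ln[(p11 p22)/(p12 p21)] - ln[(q11 q22)/(q12 q21)]`,
#' where `p` are case and `q` control pseudohaplotype frequencies. It is zero
#' exactly when the two cross-ratios coincide (no interaction on the
#' multiplicative odds scale), and it is zero in the population whenever one
#' locus is an unassociated marker.
#'
#' @param case,ctrl Pseudohaplotype frequencies per group: `hap_freqs`
#'   objects or numeric vectors `(p11, p12, p21, p22)`. All eight
#'   frequencies must be strictly positive; apply a continuity correction
#'   first if any is zero.
#' @return The scalar interaction measure (log-odds-ratio units).
#' @examples
#' interaction_measure(c(0.4, 0.1, 0.1, 0.4), c(0.25, 0.25, 0.25, 0.25))
#' @export
interaction_measure <- function(case, ctrl) {
  p <- as_hap_probs(case)
  q <- as_hap_probs(ctrl)
  check_positive_freqs(p, q)
  log_cross_ratio(p) - log_cross_ratio(q)
}

log_cross_ratio <- function(p) log(p[1]) + log(p[4]) - log(p[2]) - log(p[3])

check_positive_freqs <- function(...) {
  if (any(unlist(list(...)) <= 0)) {
    stop("zero haplotype frequency: the cross-ratio is not evaluable; ",
         "apply a continuity correction", call. = FALSE)
  }
  invisible(TRUE)
}

#' Delta-method variance of the interaction measure
#'
#' Treating the EM-estimated haplotype frequencies as observed haplotype
#' proportions over `2n` haplotypes per group, the large-sample variance of
#' the interaction measure is
#' `Var = (1/(2 n_cases)) * sum(1/p) + (1/(2 n_controls)) * sum(1/q)`.
#'
#' @inheritParams interaction_measure
#' @param n_cases,n_controls Number of individuals in each group.
#' @return The strictly positive variance.
#' @export
interaction_variance <- function(case, ctrl, n_cases, n_controls) {
  p <- as_hap_probs(case)
  q <- as_hap_probs(ctrl)
  check_positive_freqs(p, q)
  stopifnot(n_cases >= 1, n_controls >= 1)
  sum(1 / p) / (2 * n_cases) + sum(1 / q) / (2 * n_controls)
}

new_interaction_test <- function(method, measure = NA_real_,
                                 variance = NA_real_, statistic = NA_real_,
                                 p_value = NA_real_, correction_applied = FALSE,
                                 case_freqs = NULL, ctrl_freqs = NULL,
                                 n_cases = NA_integer_, n_controls = NA_integer_,
                                 evaluable = TRUE, reason = NA_character_,
                                 p_clamped = FALSE) {
  structure(
    list(
      measure = measure, variance = variance, statistic = statistic,
      p_value = p_value, df = 1L, method = method,
      correction_applied = correction_applied,
      case_freqs = case_freqs, ctrl_freqs = ctrl_freqs,
      n_cases = n_cases, n_controls = n_controls,
      evaluable = evaluable, reason = reason, p_clamped = p_clamped
    ),
    class = "interaction_test"
  )
}

clamp_p <- function(p) {
  clamped <- is.finite(p) & p < .Machine$double.xmin
  p[clamped] <- .Machine$double.xmin
  list(p = p, clamped = clamped)
}

freqs_from_row <- function(p_row, em, n_hap) {
  structure(
    list(
      p11 = p_row[1], p12 = p_row[2], p21 = p_row[3], p22 = p_row[4],
      n_hap = as.integer(n_hap), loglik = NA_real_,
      converged = em$converged[1], iterations = em$iterations[1],
      loglik_trace = NULL
    ),
    class = "hap_freqs"
  )
}

#' Case-control haplotype odds-ratio interaction test
#'
#' The T_IH test for gene-gene interaction between two biallelic loci.
#' Per group, the 3x3 genotype cross-table is formed
#' ([cross_tabulate()]) and the four pseudohaplotype frequencies are
#' estimated by EM ([em_haplotype_frequencies()]); zero frequencies are
#' handled by a Haldane-Anscombe-style continuity correction (0.5 added to
#' each of the four expected haplotype counts, renormalized). The statistic
#' `T = I^2 / Var` is referred to a chi-squared distribution with one degree
#' of freedom; under the null of no multiplicative interaction it is
#' asymptotically central chi-squared(1) for both linked and unlinked loci.
#'
#' @param case_g,case_h Dosage vectors (0/1/2/NA) at the two loci in cases.
#' @param ctrl_g,ctrl_h Dosage vectors at the two loci in controls.
#' @param correction Apply the continuity correction when an EM frequency
#'   falls below 1e-8? If `FALSE`, such datasets yield a non-evaluable
#'   result.
#' @param tol,max_iter EM convergence controls.
#' @param variance_method `"information"` (default): delta-method variance
#'   from the observed-data (genotype likelihood) Fisher information, which
#'   accounts for the phase ambiguity of double heterozygotes and yields a
#'   calibrated chi-squared(1) null. `"haplotype-count"`: the
#'   phased-haplotype form of [interaction_variance()], which treats the EM
#'   frequencies as directly counted haplotypes and is anti-conservative
#'   when double heterozygotes are common (the two coincide when there are
#'   none).
#' @return An object of class `interaction_test` with elements `measure`,
#'   `variance`, `statistic`, `p_value`, `df`, `method`,
#'   `correction_applied`, the per-group `hap_freqs`, sample sizes, and an
#'   `evaluable` flag with `reason` when the test could not be computed.
#'   Use [tidy()] / [glance()] for tibble summaries.
#' @examples
#' set.seed(1)
#' g <- sample(0:2, 200, TRUE)
#' h <- sample(0:2, 200, TRUE)
#' test_interaction(g[1:100], h[1:100], g[101:200], h[101:200])
#' @export
test_interaction <- function(case_g, case_h, ctrl_g, ctrl_h,
                             correction = TRUE, tol = 1e-10,
                             max_iter = 1000L,
                             variance_method = c("information",
                                                 "haplotype-count")) {
  variance_method <- match.arg(variance_method)
  ca <- cross_tabulate(case_g, case_h)
  co <- cross_tabulate(ctrl_g, ctrl_h)
  if (ca$n_total < 1 || co$n_total < 1) {
    return(new_interaction_test(
      "T_IH", evaluable = FALSE,
      reason = "no complete genotype pairs in one group"
    ))
  }
  res <- .tih_stat_vec(counts_row(ca), counts_row(co),
                       tol = tol, max_iter = max_iter, correction = correction,
                       variance_method = variance_method)
  if (!correction && (any(res$case_freqs <= 0) || any(res$ctrl_freqs <= 0))) {
    return(new_interaction_test(
      "T_IH", evaluable = FALSE,
      n_cases = ca$n_total, n_controls = co$n_total,
      reason = "zero haplotype frequency with correction disabled"
    ))
  }
  pv <- clamp_p(res$p_value)
  new_interaction_test(
    "T_IH",
    measure = res$measure, variance = res$variance,
    statistic = res$statistic, p_value = pv$p,
    correction_applied = res$corrected,
    case_freqs = freqs_from_row(res$case_freqs[1, ], res$case_em, 2 * ca$n_total),
    ctrl_freqs = freqs_from_row(res$ctrl_freqs[1, ], res$ctrl_em, 2 * co$n_total),
    n_cases = ca$n_total, n_controls = co$n_total,
    p_clamped = pv$clamped
  )
}

#' Case-only haplotype odds-ratio interaction test
#'
#' For unlinked loci that are independent in the source population, the
#' control term of [test_interaction()] can be dropped: the measure is the
#' case-group log cross-ratio alone and the variance is the case term alone.
#' The gain in power comes at the cost of requiring population-level
#' independence of the two loci.
#'
#' @inheritParams test_interaction
#' @return An `interaction_test` with `method = "T_IH_case_only"`.
#' @export
test_interaction_case_only <- function(case_g, case_h, correction = TRUE,
                                       tol = 1e-10, max_iter = 1000L,
                                       variance_method = c("information",
                                                           "haplotype-count")) {
  variance_method <- match.arg(variance_method)
  ca <- cross_tabulate(case_g, case_h)
  if (ca$n_total < 1) {
    return(new_interaction_test("T_IH_case_only", evaluable = FALSE,
                                reason = "no complete genotype pairs"))
  }
  res <- .tih_stat_vec(counts_row(ca), NULL, tol = tol, max_iter = max_iter,
                       correction = correction, case_only = TRUE,
                       variance_method = variance_method)
  if (!correction && any(res$case_freqs <= 0)) {
    return(new_interaction_test(
      "T_IH_case_only", evaluable = FALSE, n_cases = ca$n_total,
      reason = "zero haplotype frequency with correction disabled"
    ))
  }
  pv <- clamp_p(res$p_value)
  new_interaction_test(
    "T_IH_case_only",
    measure = res$measure, variance = res$variance,
    statistic = res$statistic, p_value = pv$p,
    correction_applied = res$corrected,
    case_freqs = freqs_from_row(res$case_freqs[1, ], res$case_em, 2 * ca$n_total),
    n_cases = ca$n_total, p_clamped = pv$clamped
  )
}

#' Allele-based ("fast-epistasis") interaction test
#'
#' Comparator test on the allele-pair scale. Per group a 2x2 allele-pair
#' count table is formed from the 3x3 genotype table: the eight phase-certain
#' cells contribute their haplotypes directly and each double heterozygote's
#' two haplotypes are split equally (0.5/0.5) between the cis and trans phase
#' resolutions — no EM phase information is used, which is what distinguishes
#' this test from [test_interaction()]. The statistic is the squared
#' standardized difference of the Woolf log odds-ratios,
#' `[(lnOR_case - lnOR_ctrl) / sqrt(SE_case^2 + SE_ctrl^2)]^2`, with
#' `SE^2` the sum of reciprocal cell counts, referred to chi-squared(1).
#' A zero cell triggers the Haldane-Anscombe correction (0.5 added to all
#' four cells of the affected table).
#'
#' @inheritParams test_interaction
#' @return An `interaction_test` with `method = "fast_epistasis"`.
#' @export
fast_epistasis <- function(case_g, case_h, ctrl_g, ctrl_h) {
  ca <- cross_tabulate(case_g, case_h)
  co <- cross_tabulate(ctrl_g, ctrl_h)
  if (ca$n_total < 1 || co$n_total < 1) {
    return(new_interaction_test(
      "fast_epistasis", evaluable = FALSE,
      reason = "no complete genotype pairs in one group"
    ))
  }
  res <- .fast_stat_vec(counts_row(ca), counts_row(co))
  pv <- clamp_p(res$p_value)
  new_interaction_test(
    "fast_epistasis",
    measure = res$measure, variance = res$variance,
    statistic = res$statistic, p_value = pv$p,
    correction_applied = res$corrected,
    n_cases = ca$n_total, n_controls = co$n_total,
    p_clamped = pv$clamped
  )
}

#' Recode genotype dosages under a penetrance-mode scoring
#'
#' Maps dosages of the risk-increasing allele to the score used by the
#' genotype-based (logistic) interaction test: recessive codes (0, 1, 2) to
#' (0, 0, 1), dominant to (0, 1, 1), additive leaves (0, 1, 2). Missing
#' values propagate.
#'
#' @param g Dosage vector with entries in `{0, 1, 2, NA}`.
#' @param model One of `"recessive"`, `"dominant"`, `"additive"`.
#' @return An integer vector of genotype scores.
#' @examples
#' code_genotypes(c(0, 1, 2), "dominant")
#' @export
code_genotypes <- function(g, model = c("recessive", "dominant", "additive")) {
  model <- match.arg(model)
  g <- check_dosage(g, "g")
  map <- switch(model,
    recessive = c(0L, 0L, 1L),
    dominant  = c(0L, 1L, 1L),
    additive  = c(0L, 1L, 2L)
  )
  map[g + 1L]
}

#' Logistic-regression interaction test
#'
#' Comparator test on the genotype scale: fits
#' `logit P(D = 1) = b0 + b1 G + b2 H + b3 G H` by maximum likelihood on
#' genotype scores ([code_genotypes()]) and tests `b3 = 0` with a 1-df Wald
#' chi-squared (or, optionally, a likelihood-ratio) test. Valid under
#' case-control sampling for the interaction coefficient.
#'
#' @inheritParams test_interaction
#' @param coding Genotype scoring for both loci: `"recessive"`, `"dominant"`
#'   or `"additive"`.
#' @param method `"wald"` (default) or `"lrt"` significance assessment.
#' @return An `interaction_test` with `method = "logistic_<coding>"`;
#'   `measure` is the fitted interaction coefficient `b3` and `variance` its
#'   estimated sampling variance.
#' @export
logistic_interaction <- function(case_g, case_h, ctrl_g, ctrl_h,
                                 coding = c("additive", "dominant", "recessive"),
                                 method = c("wald", "lrt")) {
  coding <- match.arg(coding)
  method <- match.arg(method)
  tag <- paste0("logistic_", coding)
  y <- c(rep(1L, length(case_g)), rep(0L, length(ctrl_g)))
  g <- code_genotypes(c(case_g, ctrl_g), coding)
  h <- code_genotypes(c(case_h, ctrl_h), coding)
  keep <- !is.na(g) & !is.na(h)
  y <- y[keep]; g <- g[keep]; h <- h[keep]
  if (length(y) < 4 || length(unique(y)) < 2) {
    return(new_interaction_test(tag, evaluable = FALSE,
                                reason = "insufficient complete data"))
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm(y ~ g * h, family = stats::binomial())),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || is.na(stats::coef(fit)["g:h"])) {
    return(new_interaction_test(
      tag, evaluable = FALSE,
      n_cases = sum(y), n_controls = sum(1 - y),
      reason = "glm did not converge or design is rank deficient"
    ))
  }
  b3 <- unname(stats::coef(fit)["g:h"])
  v3 <- stats::vcov(fit)["g:h", "g:h"]
  if (method == "wald") {
    statistic <- b3^2 / v3
  } else {
    fit0 <- suppressWarnings(stats::glm(y ~ g + h, family = stats::binomial()))
    statistic <- fit0$deviance - fit$deviance
  }
  pv <- clamp_p(stats::pchisq(statistic, 1, lower.tail = FALSE))
  new_interaction_test(
    tag, measure = b3, variance = v3, statistic = statistic, p_value = pv$p,
    n_cases = sum(y), n_controls = sum(1 - y), p_clamped = pv$clamped
  )
}

#' @export
print.interaction_test <- function(x, digits = 4, ...) {
  cat("\n  ", x$method, " interaction test\n\n", sep = "")
  if (!x$evaluable) {
    cat("  non-evaluable:", x$reason, "\n")
    return(invisible(x))
  }
  cat("  measure = ", format(x$measure, digits = digits),
      ", chi-squared(", x$df, ") = ", format(x$statistic, digits = digits),
      ", p = ", format.pval(x$p_value, digits = digits), "\n", sep = "")
  if (isTRUE(x$correction_applied)) cat("  (continuity correction applied)\n")
  invisible(x)
}

#' Tidy an interaction test
#'
#' @param x An `interaction_test` object.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with `method`, `estimate` (the
#'   interaction measure), `variance`, `statistic`, `df`, `p.value` and
#'   flags. `glance()`: a one-row tibble of fit metadata (group sizes,
#'   evaluability, correction flag).
#' @method tidy interaction_test
#' @export
tidy.interaction_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, estimate = x$measure, variance = x$variance,
    statistic = x$statistic, df = x$df, p.value = x$p_value,
    correction_applied = x$correction_applied, evaluable = x$evaluable
  )
}

#' @rdname tidy.interaction_test
#' @method glance interaction_test
#' @export
glance.interaction_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_cases = x$n_cases, n_controls = x$n_controls,
    evaluable = x$evaluable, correction_applied = x$correction_applied,
    p_clamped = x$p_clamped, reason = x$reason
  )
}
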