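#' Hardy-Weinberg equilibrium test for one SNP
#'
#' Default is the 1-df chi-squared goodness-of-fit test of observed genotype
#' counts against binomial (Hardy-Weinberg) expectations; `method = "exact"`
#' computes the exact two-sided test by summing heterozygote-count
#' probabilities no larger than the observed one (the standard SNP-HWE exact
#' test).
#'
#' @param g Dosage vector (0/1/2/NA).
#' @param method `"chisq"` or `"exact"`.
#' @return The HWE p-value.
#' @export
hwe_test <- function(g, method = c("chisq", "exact")) {
  method <- match.arg(method)
  g <- g[!is.na(g)]
  n <- length(g)
  if (n == 0) return(NA_real_)
  n2 <- sum(g == 2L)
  n1 <- sum(g == 1L)
  n0 <- n - n1 - n2
  p <- (2 * n2 + n1) / (2 * n)
  if (p == 0 || p == 1) return(1)
  if (method == "chisq") {
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    x2 <- sum((c(n0, n1, n2) - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  # exact test: distribution of the heterozygote count given allele counts
  rare <- min(2 * n2 + n1, 2 * n0 + n1)
  het_vals <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- vapply(het_vals, function(h) {
    homr <- (rare - h) / 2
    homc <- n - h - homr
    lchoose(n, h) + lchoose(n - h, homr) + h * log(2) -
      lchoose(2 * n, rare)
  }, numeric(1))
  # normalize via multinomial identities computed directly
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n1, het_vals)] * (1 + 1e-12)])
}

#' Quality-control filter for a genotype panel
#'
#' Removes SNPs with missing-call fraction above `miss_max`, minor allele
#' frequency below `maf_min`, Hardy-Weinberg p-value below `hwe_p_min`, or a
#' duplicated identifier (later occurrences dropped). Filters are evaluated
#' on the unfiltered panel; a SNP failing several criteria is logged with
#' the first reason in the order missing > maf > hwe > duplicate.
#'
#' @param panel A `genotype_panel` (see [read_genotypes()]).
#' @param maf_min Minimum minor allele frequency.
#' @param miss_max Maximum missing fraction.
#' @param hwe_p_min Minimum HWE p-value.
#' @param hwe_sample Compute HWE on `"all"` genotyped individuals (default)
#'   or `"controls"` only.
#' @param hwe_method Passed to [hwe_test()].
#' @return A list with the filtered `panel` and `log`, a tibble
#'   (`id`, `reason`) of removed SNPs. If every SNP is removed the panel is
#'   empty and a warning is raised.
#' @export
qc_filter <- function(panel, maf_min = 0.01, miss_max = 0.05,
                      hwe_p_min = 1e-4, hwe_sample = c("all", "controls"),
                      hwe_method = c("chisq", "exact")) {
  hwe_sample <- match.arg(hwe_sample)
  hwe_method <- match.arg(hwe_method)
  geno <- panel$genotypes
  stopifnot(ncol(geno) >= 1)
  hwe_rows <- if (hwe_sample == "controls") {
    which(!is.na(panel$status) & panel$status == 0L)
  } else {
    seq_len(nrow(geno))
  }
  miss <- colMeans(is.na(geno))
  maf <- apply(geno, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(0)
    f <- mean(g) / 2
    min(f, 1 - f)
  })
  hwe_p <- apply(geno[hwe_rows, , drop = FALSE], 2, hwe_test,
                 method = hwe_method)
  dup <- duplicated(panel$meta$id)
  reason <- rep(NA_character_, ncol(geno))
  reason[dup] <- "duplicate"
  reason[!is.na(hwe_p) & hwe_p < hwe_p_min] <- "hwe"
  reason[maf < maf_min] <- "maf"
  reason[miss > miss_max] <- "missing"
  keep <- is.na(reason)
  if (!any(keep)) warning("all SNPs removed by QC", call. = FALSE)
  filtered <- new_genotype_panel(
    geno[, keep, drop = FALSE], panel$meta[keep, , drop = FALSE],
    panel$status, panel$sample_id
  )
  list(
    panel = filtered,
    log = tibble::tibble(id = panel$meta$id[!keep],
                         reason = reason[!keep])
  )
}
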