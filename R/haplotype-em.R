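#' Cross-tabulate genotype dosages at two loci
#'
#' Builds the 3x3 table of joint genotype counts at two biallelic loci from
#' per-individual allele dosages. Individuals missing a genotype at either
#' locus are excluded from every cell (pairwise complete-case deletion).
#'
#' @param g,h Integer dosage vectors of equal length with entries in
#'   `{0, 1, 2, NA}`, counting copies of the first allele at each locus.
#' @return An object of class `two_locus_counts`: a list with `n`, the 3x3
#'   count matrix indexed by dosage (rows: locus G, columns: locus H), and
#'   `n_total`, the number of individuals complete at both loci.
#' @examples
#' cross_tabulate(c(2, 1, 0), c(2, 1, 0))
#' @export
cross_tabulate <- function(g, h) {
  if (length(g) != length(h)) {
    stop("`g` and `h` must have the same length", call. = FALSE)
  }
  g <- check_dosage(g, "g")
  h <- check_dosage(h, "h")
  cells <- .count_cells(g, h)
  n <- matrix(cells, nrow = 3, byrow = TRUE,
              dimnames = list(g_dosage = 0:2, h_dosage = 0:2))
  structure(list(n = n, n_total = sum(cells)), class = "two_locus_counts")
}

check_dosage <- function(x, name) {
  x <- as.integer(round(x))
  if (any(!is.na(x) & !(x %in% 0:2))) {
    stop("`", name, "` must contain only 0, 1, 2 or NA dosages", call. = FALSE)
  }
  x
}

#' @export
print.two_locus_counts <- function(x, ...) {
  cat("Two-locus genotype counts (", x$n_total, " individuals)\n", sep = "")
  print(x$n)
  invisible(x)
}

# Flatten a two_locus_counts object into the 9-cell row layout used by the
# vectorized kernels (cell order (0,0),(0,1),...,(2,2)).
counts_row <- function(counts) {
  matrix(as.vector(t(counts$n)), nrow = 1)
}

#' Estimate two-locus pseudohaplotype frequencies by EM
#'
#' Maximum-likelihood estimation of the four pseudohaplotype frequencies
#' (G1H1, G1H2, G2H1, G2H2) from unphased genotype counts. Every cell of the
#' 3x3 table except the double heterozygote contributes phase-certain
#' haplotype counts; each double-heterozygous individual is resolved in the
#' E-step with cis-phase posterior weight
#' `phi = p11*p22 / (p11*p22 + p12*p21)` (`phi = 1/2` when both phase
#' products vanish), and the M-step sets each frequency to its expected
#' haplotype count over `2 * n_total`. Iteration starts from the
#' linkage-equilibrium product of the observed allele frequencies and stops
#' when the largest absolute frequency change drops below `tol`. The
#' observed-data log-likelihood is non-decreasing across iterations and is
#' returned (with its per-iteration trace) for diagnostics.
#'
#' @param counts A [cross_tabulate()] result (or a 3x3 count matrix).
#' @param tol Convergence tolerance on the maximum absolute frequency change.
#' @param max_iter Maximum number of EM iterations; if reached, the result is
#'   returned with `converged = FALSE`.
#' @return An object of class `hap_freqs`: frequencies `p11`, `p12`, `p21`,
#'   `p22`, haplotype count `n_hap = 2 * n_total`, final observed-data
#'   log-likelihood `loglik`, `converged`, `iterations`, and the
#'   per-iteration `loglik_trace`. Frequencies that converge below 1e-12 are
#'   reported as exact zeros.
#' @examples
#' tab <- cross_tabulate(c(2, 2, 0, 0, 1), c(2, 2, 0, 0, 1))
#' em_haplotype_frequencies(tab)
#' @export
em_haplotype_frequencies <- function(counts, tol = 1e-10, max_iter = 1000L) {
  if (is.matrix(counts)) {
    counts <- structure(list(n = counts, n_total = sum(counts)),
                        class = "two_locus_counts")
  }
  if (counts$n_total < 1) {
    stop("cannot estimate haplotype frequencies from zero individuals",
         call. = FALSE)
  }
  N <- counts_row(counts)
  hc <- .hap_count_components(N)
  nh <- hc$n_hap
  p_g <- (hc$a11 + hc$a12 + hc$dh) / nh
  p_h <- (hc$a11 + hc$a21 + hc$dh) / nh
  p <- c(p_g * p_h, p_g * (1 - p_h), (1 - p_g) * p_h, (1 - p_g) * (1 - p_h))
  trace <- .obs_loglik(N[1, ], p)
  converged <- FALSE
  iters <- 0L
  if (hc$dh == 0) {
    p <- c(hc$a11, hc$a12, hc$a21, hc$a22) / nh
    trace <- .obs_loglik(N[1, ], p)
    converged <- TRUE
  } else {
    for (it in seq_len(max_iter)) {
      cis <- p[1] * p[4]
      trans <- p[2] * p[3]
      phi <- if (cis + trans > 0) cis / (cis + trans) else 0.5
      p_new <- c(
        hc$a11 + phi * hc$dh, hc$a12 + (1 - phi) * hc$dh,
        hc$a21 + (1 - phi) * hc$dh, hc$a22 + phi * hc$dh
      ) / nh
      delta <- max(abs(p_new - p))
      p <- p_new
      iters <- it
      trace <- c(trace, .obs_loglik(N[1, ], p))
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
  }
  p[p < 1e-12] <- 0
  structure(
    list(
      p11 = p[1], p12 = p[2], p21 = p[3], p22 = p[4],
      n_hap = as.integer(nh), loglik = trace[length(trace)],
      converged = converged, iterations = iters, loglik_trace = trace
    ),
    class = "hap_freqs"
  )
}

#' @export
print.hap_freqs <- function(x, digits = 4, ...) {
  cat("Pseudohaplotype frequencies (", x$n_hap, " haplotypes, ",
      x$iterations, " EM iterations",
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  print(round(c(p11 = x$p11, p12 = x$p12, p21 = x$p21, p22 = x$p22), digits))
  invisible(x)
}

#' @rdname em_haplotype_frequencies
#' @param x A `hap_freqs` object.
#' @param ... Unused.
#' @method tidy hap_freqs
#' @export
tidy.hap_freqs <- function(x, ...) {
  tibble::tibble(
    haplotype = c("G1H1", "G1H2", "G2H1", "G2H2"),
    frequency = c(x$p11, x$p12, x$p21, x$p22)
  )
}

# Coerce hap_freqs / named or plain length-4 numeric into the (p11, p12,
# p21, p22) vector the arithmetic uses.
as_hap_probs <- function(x) {
  if (inherits(x, "hap_freqs")) {
    p <- c(x$p11, x$p12, x$p21, x$p22)
  } else if (is.numeric(x) && length(x) == 4) {
    p <- unname(x)
  } else {
    stop("expected a `hap_freqs` object or a numeric vector of length 4",
         call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop("haplotype frequencies must be nonnegative and sum to 1",
         call. = FALSE)
  }
  p
}

#' Linkage-disequilibrium coefficient of a haplotype distribution
#'
#' Computes `D = p11 - (p11 + p12) * (p11 + p21)`, the deviation of the
#' G1H1 haplotype frequency from the product of its marginal allele
#' frequencies. `D` lies in `[-0.25, 0.25]` and is zero exactly when the two
#' loci are in linkage equilibrium.
#'
#' @param freqs A `hap_freqs` object or a numeric vector
#'   `(p11, p12, p21, p22)`.
#' @return The scalar disequilibrium coefficient.
#' @examples
#' ld_coefficient(c(0.5, 0, 0, 0.5))
#' @export
ld_coefficient <- function(freqs) {
  p <- as_hap_probs(freqs)
  p[1] - (p[1] + p[2]) * (p[1] + p[3])
}
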