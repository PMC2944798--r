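# Pairwise genome-scan machinery: pair enumeration, streaming scan with a
# p-value storage threshold, BH-FDR, QQ diagnostics and replication logic.

#' Number of unordered SNP pairs
#'
#' @param m Number of SNPs.
#' @return `m * (m - 1) / 2`, as a double (exact for panels far beyond
#'   genome scale).
#' @examples
#' pair_count(50327)
#' @export
pair_count <- function(m) {
  m <- as.numeric(m)
  stopifnot(m >= 0)
  m * (m - 1) / 2
}

# Canonical SNP ordering: chromosome, position, then identifier.  SNPs with
# missing coordinates sort by id.  Returns a permutation of seq_along ids.
canonical_snp_order <- function(meta) {
  order(meta$chrom, meta$pos, meta$id, na.last = TRUE, method = "radix")
}

#' Enumerate unordered SNP pairs in canonical order
#'
#' Emits each unordered pair exactly once with `snp1` preceding `snp2` in
#' the canonical ordering (chromosome, position, then identifier; plain
#' identifier order when no metadata is given).
#'
#' @param snp_ids Character vector of unique SNP identifiers, or a
#'   `genotype_panel`.
#' @param source `"all"` (every pair, the default) or `"pair-file"`
#'   (restrict to `pairs`).
#' @param pairs For `source = "pair-file"`: a two-column data frame of SNP
#'   id pairs.
#' @return A tibble (`snp1`, `snp2`) with the total pair count of the
#'   source in `attr(, "total")`.
#' @export
enumerate_pairs <- function(snp_ids, source = c("all", "pair-file"),
                            pairs = NULL) {
  source <- match.arg(source)
  if (inherits(snp_ids, "genotype_panel")) {
    ord <- canonical_snp_order(snp_ids$meta)
    snp_ids <- snp_ids$meta$id[ord]
  } else {
    snp_ids <- sort(as.character(snp_ids), method = "radix")
  }
  if (anyDuplicated(snp_ids)) {
    stop("SNP identifiers must be unique", call. = FALSE)
  }
  m <- length(snp_ids)
  if (source == "all") {
    idx <- pair_indices(m)
    out <- tibble::tibble(snp1 = snp_ids[idx$i], snp2 = snp_ids[idx$j])
    attr(out, "total") <- pair_count(m)
  } else {
    stopifnot(is.data.frame(pairs), ncol(pairs) >= 2)
    bad <- !(pairs[[1]] %in% snp_ids) | !(pairs[[2]] %in% snp_ids)
    if (any(bad)) {
      stop("pair file names unknown SNP id: ",
           paste(unique(unlist(pairs[bad, 1:2])), collapse = ", "),
           call. = FALSE)
    }
    r1 <- match(pairs[[1]], snp_ids)
    r2 <- match(pairs[[2]], snp_ids)
    out <- tibble::tibble(
      snp1 = snp_ids[pmin(r1, r2)],
      snp2 = snp_ids[pmax(r1, r2)]
    )
    out <- dplyr::distinct(out[out$snp1 != out$snp2, ])
    out <- dplyr::arrange(out, .data$snp1, .data$snp2)
    attr(out, "total") <- nrow(out)
  }
  out
}

# All (i, j) index pairs with i < j for m items, in row-major order.
pair_indices <- function(m) {
  if (m < 2) return(list(i = integer(0), j = integer(0)))
  i <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
  j <- sequence((m - 1L):1L) + i
  list(i = i, j = j)
}

#' Pairwise interaction scan over a genotype panel
#'
#' Applies the chosen interaction test to every SNP pair of the panel,
#' streaming over pairs in chunks, and emits only results with
#' `p_value <= store_threshold` (genome-scale scans cannot store every
#' result; the default threshold 1e-4 matches QQ diagnostics that start at
#' 4 on the -log10 scale). Pairs are keyed canonically (snp1 before snp2 by
#' chromosome, position, id) and output is sorted by that key, so results
#' are invariant to chunk size and to the input order of SNPs.
#'
#' @param panel A `genotype_panel` with case-control status, or a list with
#'   elements `case` and `ctrl` holding dosage matrices with identical
#'   column names.
#' @param method `"tih"`, `"fast"` or `"logistic"` (additive coding; use
#'   `logistic_coding` to change).
#' @param store_threshold Retain only results with p at or below this value.
#' @param chunk_size Number of pairs evaluated per chunk.
#' @param logistic_coding Genotype coding for `method = "logistic"`.
#' @return A tibble (`snp1`, `snp2`, `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `method`, `statistic`, `p_value`, `flags`) sorted by pair key, with
#'   attributes `m_pairs` (total pairs tested, the FDR denominator) and
#'   `failures` (tibble of non-evaluable pairs with reasons).
#' @export
scan_pairs <- function(panel, method = c("tih", "fast", "logistic"),
                       store_threshold = 1e-4, chunk_size = 10000L,
                       logistic_coding = "additive") {
  method <- match.arg(method)
  if (inherits(panel, "genotype_panel")) {
    if (all(is.na(panel$status))) {
      stop("panel has no case-control status", call. = FALSE)
    }
    ord <- canonical_snp_order(panel$meta)
    meta <- panel$meta[ord, , drop = FALSE]
    case <- panel$genotypes[!is.na(panel$status) & panel$status == 1L, ord,
                            drop = FALSE]
    ctrl <- panel$genotypes[!is.na(panel$status) & panel$status == 0L, ord,
                            drop = FALSE]
  } else {
    case <- panel$case
    ctrl <- panel$ctrl
    stopifnot(identical(colnames(case), colnames(ctrl)))
    meta <- tibble::tibble(id = colnames(case), chrom = NA_character_,
                           pos = NA_integer_)
    ord <- canonical_snp_order(meta)
    meta <- meta[ord, , drop = FALSE]
    case <- case[, ord, drop = FALSE]
    ctrl <- ctrl[, ord, drop = FALSE]
  }
  m <- ncol(case)
  idx <- pair_indices(m)
  total <- pair_count(m)
  kept <- list()
  failures <- list()
  n_pairs <- length(idx$i)
  starts <- seq(1L, max(n_pairs, 1L), by = chunk_size)
  for (s in starts) {
    if (n_pairs == 0L) break
    rng <- s:min(s + chunk_size - 1L, n_pairs)
    ii <- idx$i[rng]
    jj <- idx$j[rng]
    Ncase <- t(vapply(seq_along(rng), function(k) {
      .count_cells(case[, ii[k]], case[, jj[k]])
    }, integer(9)))
    Nctrl <- t(vapply(seq_along(rng), function(k) {
      .count_cells(ctrl[, ii[k]], ctrl[, jj[k]])
    }, integer(9)))
    empty <- rowSums(Ncase) == 0 | rowSums(Nctrl) == 0
    if (method == "tih") {
      res <- .tih_stat_vec(pmax(Ncase, 0L), pmax(Nctrl, 0L))
      stat <- res$statistic; pv <- res$p_value
      flags <- ifelse(res$corrected, "corrected", "")
    } else if (method == "fast") {
      res <- .fast_stat_vec(Ncase, Nctrl)
      stat <- res$statistic; pv <- res$p_value
      flags <- ifelse(res$corrected, "corrected", "")
    } else {
      xg <- mode_score(CELL_ORDER[, "i"], logistic_coding)
      yh <- mode_score(CELL_ORDER[, "j"], logistic_coding)
      stat <- pv <- rep(NA_real_, length(rng))
      for (k in seq_along(rng)) {
        if (empty[k]) next
        yy <- cbind(Ncase[k, ], Nctrl[k, ])
        fit <- tryCatch(
          suppressWarnings(stats::glm(yy ~ xg * yh,
                                      family = stats::binomial())),
          error = function(e) NULL
        )
        if (is.null(fit) || is.na(stats::coef(fit)["xg:yh"])) next
        b <- stats::coef(fit)["xg:yh"]
        stat[k] <- b^2 / stats::vcov(fit)["xg:yh", "xg:yh"]
        pv[k] <- stats::pchisq(stat[k], 1, lower.tail = FALSE)
      }
      flags <- rep("", length(rng))
    }
    bad <- empty | !is.finite(pv)
    if (any(bad)) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        snp1 = meta$id[ii[bad]], snp2 = meta$id[jj[bad]],
        reason = ifelse(empty[bad], "no complete genotype pairs",
                        "test not evaluable")
      )
    }
    sel <- !bad & pv <= store_threshold
    if (any(sel)) {
      kept[[length(kept) + 1L]] <- tibble::tibble(
        snp1 = meta$id[ii[sel]], snp2 = meta$id[jj[sel]],
        chrom1 = meta$chrom[ii[sel]], pos1 = meta$pos[ii[sel]],
        chrom2 = meta$chrom[jj[sel]], pos2 = meta$pos[jj[sel]],
        method = method, statistic = stat[sel], p_value = pv[sel],
        flags = flags[sel]
      )
    }
  }
  out <- if (length(kept)) dplyr::bind_rows(kept) else tibble::tibble(
    snp1 = character(), snp2 = character(), chrom1 = character(),
    pos1 = integer(), chrom2 = character(), pos2 = integer(),
    method = character(), statistic = numeric(), p_value = numeric(),
    flags = character()
  )
  out <- dplyr::arrange(out, .data$snp1, .data$snp2)
  attr(out, "m_pairs") <- total
  attr(out, "failures") <- if (length(failures)) dplyr::bind_rows(failures)
    else tibble::tibble(snp1 = character(), snp2 = character(),
                        reason = character())
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR q-values `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1
#' and mapped back to input order. When results were stored only below a
#' p-value threshold, pass the total number of tests as `m` so the
#' denominator is not distorted.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param m Total number of tests (default `length(p)`).
#' @return The q-values, in input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= length(p))
  stats::p.adjust(p, method = "BH", n = m)
}

#' Attach q-values to a scan result
#'
#' Convenience wrapper adding a `q_value` column via [bh_fdr()] with the
#' scan's total pair count (`m_pairs` attribute) as the FDR denominator.
#'
#' @param results A [scan_pairs()] tibble.
#' @return The tibble with a `q_value` column; attributes preserved.
#' @export
add_fdr <- function(results) {
  m <- attr(results, "m_pairs")
  if (is.null(m)) m <- nrow(results)
  results$q_value <- bh_fdr(results$p_value, m = max(m, nrow(results)))
  results
}

#' Two-stage Bonferroni replication across two datasets
#'
#' Stage 1 declares discovery-set significance at `alpha / m1_pairs`
#' (Bonferroni over all pairs tested in dataset 1); stage 2 re-tests only
#' the selected pairs in dataset 2 at `alpha / n_selected` and reports the
#' pairs surviving both stages.
#'
#' @param results1 Tibble with `snp1`, `snp2`, `p_value` from dataset 1.
#' @param m1_pairs Total number of pairs tested in dataset 1.
#' @param dataset2 Either a tibble with `snp1`, `snp2`, `p_value` from
#'   dataset 2, or a function taking the selected-pair tibble and returning
#'   their dataset-2 p-values.
#' @param alpha Family-wise level (default 0.05).
#' @return A `replication_report`: stage thresholds, selection count, and
#'   the tibble of replicated pairs with both p-values. Zero stage-1
#'   selections yield an empty report.
#' @export
two_stage_bonferroni_replication <- function(results1, m1_pairs, dataset2,
                                             alpha = 0.05) {
  stopifnot(m1_pairs >= 1)
  thr1 <- alpha / m1_pairs
  sel <- results1[results1$p_value <= thr1, , drop = FALSE]
  n_sel <- nrow(sel)
  if (n_sel == 0) {
    rep_tbl <- tibble::tibble(snp1 = character(), snp2 = character(),
                              p1 = numeric(), p2 = numeric())
    thr2 <- NA_real_
  } else {
    thr2 <- alpha / n_sel
    p2 <- if (is.function(dataset2)) {
      dataset2(sel)
    } else {
      key <- paste(sel$snp1, sel$snp2)
      dataset2$p_value[match(key, paste(dataset2$snp1, dataset2$snp2))]
    }
    rep_tbl <- tibble::tibble(snp1 = sel$snp1, snp2 = sel$snp2,
                              p1 = sel$p_value, p2 = p2)
    rep_tbl <- rep_tbl[!is.na(rep_tbl$p2) & rep_tbl$p2 <= thr2, ,
                       drop = FALSE]
  }
  structure(
    list(stage1_threshold = thr1, n_selected = n_sel,
         stage2_threshold = thr2, replicated = rep_tbl, alpha = alpha),
    class = "replication_report"
  )
}

#' @export
print.replication_report <- function(x, ...) {
  cat("Two-stage Bonferroni replication (alpha =", x$alpha, ")\n")
  cat("  stage-1 threshold:", format(x$stage1_threshold, digits = 4),
      "->", x$n_selected, "pairs selected\n")
  cat("  stage-2 threshold:", format(x$stage2_threshold, digits = 4),
      "->", nrow(x$replicated), "pairs replicated\n")
  invisible(x)
}

#' Intersect FDR-significant pairs of two scans
#'
#' @param results1,results2 Scan tibbles with `snp1`, `snp2`, `q_value`
#'   (see [add_fdr()]).
#' @param fdr_threshold Significance threshold applied to both datasets.
#' @return Tibble of pairs with `q <= fdr_threshold` in both datasets,
#'   carrying both q-values.
#' @export
replication_intersect <- function(results1, results2, fdr_threshold) {
  s1 <- results1[!is.na(results1$q_value) &
                   results1$q_value <= fdr_threshold, , drop = FALSE]
  s2 <- results2[!is.na(results2$q_value) &
                   results2$q_value <= fdr_threshold, , drop = FALSE]
  dplyr::inner_join(
    dplyr::select(s1, "snp1", "snp2", q1 = "q_value"),
    dplyr::select(s2, "snp1", "snp2", q2 = "q_value"),
    by = c("snp1", "snp2")
  )
}

#' Expected-versus-observed points for a QQ plot of p-values
#'
#' Sorted observed `-log10` p-values against their expected values under
#' uniformity, `-log10(rank / (m + 1))`. When only p-values below a storage
#' threshold were kept, set `min_neg_log10` to the threshold's `-log10`
#' scale so the truncated plot starts there.
#'
#' @param p P-values in `(0, 1]`; exact zeros are clamped to the smallest
#'   positive double and flagged.
#' @param min_neg_log10 Keep only points with observed `-log10 p` at or
#'   above this value (default 0, no truncation).
#' @return A tibble (`expected`, `observed`, `clamped`) sorted by
#'   significance.
#' @export
qq_points <- function(p, min_neg_log10 = 0) {
  stopifnot(all(p >= 0 & p <= 1))
  clamped <- p == 0
  p[clamped] <- .Machine$double.xmin
  ord <- order(p)
  m <- length(p)
  out <- tibble::tibble(
    expected = -log10(seq_len(m) / (m + 1)),
    observed = -log10(p[ord]),
    clamped = clamped[ord]
  )
  out[out$observed >= min_neg_log10, , drop = FALSE]
}
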