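make_tiny_panel <- function(dir) {
  # 3 individuals x 2 SNPs, hand-written PLINK text fixture
  writeLines(c(
    "1\trs1\t0\t1000",
    "1\trs2\t0\t2000"
  ), file.path(dir, "tiny.map"))
  writeLines(c(
    "FAM ind1 0 0 1 2 A A G T",
    "FAM ind2 0 0 1 1 A C T T",
    "FAM ind3 0 0 2 -9 C C G G"
  ), file.path(dir, "tiny.ped"))
  file.path(dir, "tiny")
}

test_that("PLINK text fixtures parse to the expected dosage matrix", {
  dir <- withr::local_tempdir()
  prefix <- make_tiny_panel(dir)
  panel <- read_genotypes(prefix, "ped")
  # rs1: alleles A (ind1 AA, ind2 AC, ind3 CC) -> C is minor? counts: A=3, C=3
  # tie keeps first sorted allele as allele1 = "A"
  expect_equal(unname(panel$genotypes[, "rs1"]), c(2L, 1L, 0L))
  # rs2: G T with ind1 GT, ind2 TT, ind3 GG -> equal counts, allele1 = "G"
  expect_equal(unname(panel$genotypes[, "rs2"]), c(1L, 0L, 2L))
  expect_equal(panel$status, c(1L, 0L, NA))
  expect_equal(panel$meta$pos, c(1000L, 2000L))
})

test_that("binary PLINK round-trips the same data as text", {
  dir <- withr::local_tempdir()
  prefix <- make_tiny_panel(dir)
  panel <- read_genotypes(prefix, "ped")
  write_plink(panel, file.path(dir, "bin"), format = "bed")
  back <- read_genotypes(file.path(dir, "bin"), "bed")
  expect_equal(unname(back$genotypes), unname(panel$genotypes))
  expect_equal(back$status, panel$status)
  expect_equal(back$meta$id, panel$meta$id)
  # larger random panel round-trip, including missing genotypes
  set.seed(33)
  g <- matrix(sample(c(0:2, NA), 25 * 7, TRUE), 25, 7)
  meta <- tibble::tibble(id = paste0("rs", 1:7), chrom = "2",
                         pos = 1:7 * 100L, allele1 = "A", allele2 = "B")
  p <- hapint:::new_genotype_panel(g, meta,
                                   rep(c(1L, 0L, NA), length.out = 25),
                                   sprintf("s%02d", 1:25))
  write_plink(p, file.path(dir, "rt"), format = "bed")
  rt <- read_genotypes(file.path(dir, "rt"), "bed")
  expect_equal(unname(rt$genotypes), unname(g))
  write_plink(p, file.path(dir, "rt2"), format = "ped")
  rt2 <- read_genotypes(file.path(dir, "rt2"), "ped")
  # text reader re-infers minor alleles, so compare up to allele flips
  for (k in 1:7) {
    col <- rt2$genotypes[, k]
    expect_true(identical(unname(col), unname(g[, k])) ||
                  identical(unname(col), unname(2L - g[, k])))
  }

  bad <- file.path(dir, "bad")
  writeBin(as.raw(c(0x00, 0x01, 0x01)), paste0(bad, ".bed"))
  file.copy(file.path(dir, "bin.bim"), paste0(bad, ".bim"))
  file.copy(file.path(dir, "bin.fam"), paste0(bad, ".fam"))
  expect_error(read_genotypes(bad, "bed"), "magic")
})

test_that("dosage tables parse and reject bad entries", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "dos.tsv")
  writeLines(c("iid\tstatus\trsA\trsB",
               "i1\t2\t0\t2",
               "i2\t1\t1\tNA",
               "i3\t-9\t2\t0"), path)
  panel <- read_genotypes(path, "dosage")
  expect_equal(unname(panel$genotypes[, "rsA"]), c(0L, 1L, 2L))
  expect_equal(panel$status, c(1L, 0L, NA))
  writeLines(c("iid\tstatus\trsA", "i1\t2\t5"), path)
  expect_error(read_genotypes(path, "dosage"), "0, 1, 2 or NA")
})

test_that("QC removes SNPs for missingness, MAF, HWE and duplication", {
  set.seed(44)
  n <- 200
  g_ok <- rbinom(n, 2, 0.3)
  g_rare <- rbinom(n, 2, 0.005)          # MAF below threshold
  g_miss <- g_ok; g_miss[1:13] <- NA     # 6.5% missing
  g_hwe <- c(rep(0L, 100), rep(2L, 100)) # no hets at 50/50 -> HWE fails
  geno <- cbind(g_ok, g_rare, g_miss, g_hwe, g_ok)
  meta <- tibble::tibble(id = c("ok", "rare", "miss", "hwe", "ok"),
                         chrom = "1", pos = 1:5 * 10L,
                         allele1 = "A", allele2 = "B")
  panel <- hapint:::new_genotype_panel(geno, meta,
                                       rep(c(1L, 0L), n / 2),
                                       sprintf("i%03d", 1:n))
  qc <- qc_filter(panel)
  expect_equal(sort(qc$log$reason),
               sort(c("maf", "missing", "hwe", "duplicate")))
  expect_equal(colnames(qc$panel$genotypes), "ok")
  # chi-squared HWE oracle for the no-het SNP
  ct <- c(100, 0, 100)
  e <- 200 * c(0.25, 0.5, 0.25)
  p_orc <- pchisq(sum((ct - e)^2 / e), 1, lower.tail = FALSE)
  expect_equal(hwe_test(g_hwe), p_orc)
  expect_lt(p_orc, 1e-4)
})

test_that("exact HWE test agrees with the chi-squared test at moderate
           counts and is exact for tiny ones", {
  set.seed(45)
  g <- rbinom(500, 2, 0.4)
  expect_equal(hwe_test(g, "exact"), hwe_test(g, "chisq"), tolerance = 0.05)
  # enumerated oracle for n = 5, 3 copies of the minor allele
  g_small <- c(1L, 1L, 1L, 0L, 0L)
  probs <- sapply(c(1, 3), function(h) {
    nr <- (3 - h) / 2
    exp(lchoose(5, h) + lchoose(5 - h, nr) + h * log(2) - lchoose(10, 3))
  })
  probs <- probs / sum(probs)
  expect_equal(hwe_test(g_small, "exact"),
               sum(probs[probs <= probs[2] * (1 + 1e-12)]),
               tolerance = 1e-10)
})

test_that("pair enumeration reproduces the combinatorial totals", {
  expect_equal(pair_count(50327), 1266378301)
  expect_equal(pair_count(49876), 1243782750)
  expect_equal(pair_count(2), 1)
  set.seed(46)
  for (m in sample(2:2000, 20)) {
    expect_equal(pair_count(m), choose(m, 2))
  }
  pairs <- enumerate_pairs(c("rs3", "rs1", "rs2"))
  expect_equal(nrow(pairs), 3)
  expect_true(all(pairs$snp1 < pairs$snp2))
  expect_equal(attr(pairs, "total"), 3)
  expect_error(enumerate_pairs(c("a", "a")), "unique")
  expect_error(
    enumerate_pairs(c("a", "b"), "pair-file",
                    pairs = data.frame(s1 = "a", s2 = "zzz")),
    "unknown SNP id"
  )
})

test_that("scan stores all pairs at threshold 1, nearly none under the null
           threshold, and is chunking-invariant", {
  panel <- planted_panel(8, 150, 150, lambda3 = 1, seed = 47)
  full <- scan_pairs(panel, store_threshold = 1)
  expect_equal(nrow(full), choose(10, 2))
  expect_equal(attr(full, "m_pairs"), choose(10, 2))
  chunked <- scan_pairs(panel, store_threshold = 1, chunk_size = 7)
  expect_equal(as.data.frame(chunked), as.data.frame(full))
  # column-permuted panel gives the same canonical results
  perm <- sample(ncol(panel$genotypes))
  panel2 <- hapint:::new_genotype_panel(
    panel$genotypes[, perm], panel$meta[perm, ], panel$status,
    panel$sample_id
  )
  full2 <- scan_pairs(panel2, store_threshold = 1)
  expect_equal(as.data.frame(full2), as.data.frame(full))
  # null panel at the default storage threshold: almost surely nothing kept
  sparse <- scan_pairs(panel, store_threshold = 1e-4)
  expect_lte(nrow(sparse), 1)
})

test_that("BH q-values match the brute-force step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(48)
  for (k in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    m <- length(p) + sample(0:50, 1)
    expect_equal(bh_fdr(p, m = m), oracle_bh(p, m = m), tolerance = 1e-12)
  }
})

test_that("two-stage Bonferroni replication thresholds and selection logic", {
  expect_equal(0.05 / pair_count(50327), 3.948268e-11, tolerance = 1e-6)
  r1 <- tibble::tibble(snp1 = c("a", "b", "c"), snp2 = c("x", "y", "z"),
                       p_value = c(1e-9, 0.2, 0.5))
  r2 <- tibble::tibble(snp1 = c("a", "b"), snp2 = c("x", "y"),
                       p_value = c(0.01, 0.9))
  rep <- two_stage_bonferroni_replication(r1, m1_pairs = 1e6, r2)
  expect_equal(rep$stage1_threshold, 5e-8)
  expect_equal(rep$n_selected, 1)
  expect_equal(rep$stage2_threshold, 0.05)   # one selected pair
  expect_equal(rep$replicated$snp1, "a")
  none <- two_stage_bonferroni_replication(
    tibble::tibble(snp1 = "a", snp2 = "b", p_value = 0.5), 100, r2)
  expect_equal(none$n_selected, 0)
  expect_equal(nrow(none$replicated), 0)
})

test_that("FDR replication intersects significant pairs of both datasets", {
  r1 <- tibble::tibble(snp1 = c("a", "b"), snp2 = c("x", "y"),
                       q_value = c(0.0005, 0.5))
  r2 <- tibble::tibble(snp1 = c("a", "c"), snp2 = c("x", "z"),
                       q_value = c(0.0002, 0.0001))
  hit <- replication_intersect(r1, r2, 0.001)
  expect_equal(hit$snp1, "a")
  expect_equal(nrow(replication_intersect(r1, r2, 1e-6)), 0)
  both <- replication_intersect(r2, r2, 0.001)
  expect_equal(nrow(both), 2)
})

test_that("qq_points follow the uniform order statistics and truncate", {
  m <- 99
  p <- seq_len(m) / (m + 1)
  pts <- qq_points(p)
  expect_equal(pts$observed, pts$expected, tolerance = 1e-12)
  set.seed(49)
  u <- runif(10000)
  pts_u <- qq_points(u)
  inner <- pts_u[pts_u$expected < 3, ]
  expect_lt(max(abs(inner$observed - inner$expected)), 0.3)
  trunc <- qq_points(c(1e-6, 1e-5, 0.5, 0.9), min_neg_log10 = 4)
  expect_equal(nrow(trunc), 2)
  clamped <- qq_points(c(0, 0.5))
  expect_true(clamped$clamped[1])
  expect_true(all(is.finite(clamped$observed)))
})

test_that("a planted strong interaction tops the scan and survives
           replication", {
  top_hits <- 0
  seeds <- 1:10
  for (s in seeds) {
    panel <- planted_panel(20, 1000, 1000, lambda3 = 4, seed = 600 + s)
    res <- scan_pairs(panel, store_threshold = 1)
    best <- res[which.min(res$p_value), ]
    if (best$snp1 == "rs_planted_1" && best$snp2 == "rs_planted_2") {
      top_hits <- top_hits + 1
    }
  }
  expect_gte(top_hits, 9)

  # end-to-end: two independent datasets, planted pair passes the two-stage
  # Bonferroni procedure and the FDR intersection; null pairs do not
  panel1 <- planted_panel(20, 1500, 1500, lambda3 = 4, seed = 701)
  panel2 <- planted_panel(20, 1500, 1500, lambda3 = 4, seed = 702)
  res1 <- add_fdr(scan_pairs(panel1, store_threshold = 1))
  res2 <- add_fdr(scan_pairs(panel2, store_threshold = 1))
  rep <- two_stage_bonferroni_replication(res1, attr(res1, "m_pairs"), res2)
  expect_equal(rep$replicated$snp1, "rs_planted_1")
  expect_equal(rep$replicated$snp2, "rs_planted_2")
  hits <- replication_intersect(res1, res2, 0.001)
  expect_true(any(hits$snp1 == "rs_planted_1" & hits$snp2 == "rs_planted_2"))
  expect_lte(nrow(hits), 2)
})

test_that("plot helpers return ggplot objects", {
  set.seed(50)
  expect_s3_class(plot_qq(runif(100)), "ggplot")
  r <- estimate_type1_error(population_spec(0.5, 0.5), 100, reps = 50,
                            seed = 1)
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
  pw <- estimate_power(population_spec(0.5, 0.5, 0.1),
                       disease_model("dominant", f0 = 0.1),
                       lambda3 = c(1, 3), tests = "T_IH",
                       n_per_group = 100, reps = 20, seed = 2)
  expect_s3_class(ggplot2::autoplot(pw), "ggplot")
})
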