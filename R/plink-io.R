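# PLINK text (.ped/.map) and binary (.bed/.bim/.fam) readers plus a plain
# dosage-table format.  Dosages count copies of allele_1 (the A1 allele of
# .bim, or the minor allele inferred from .ped data); coordinates are 1-based
# as in .map/.bim.

new_genotype_panel <- function(genotypes, meta, status, sample_id) {
  stopifnot(ncol(genotypes) == nrow(meta), nrow(genotypes) == length(status))
  dimnames(genotypes) <- list(sample_id, meta$id)
  structure(
    list(genotypes = genotypes, meta = meta, status = status,
         sample_id = sample_id),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel: ", nrow(x$genotypes), " individuals x ",
      ncol(x$genotypes), " SNPs (", sum(x$status == 1L, na.rm = TRUE),
      " cases, ", sum(x$status == 0L, na.rm = TRUE), " controls)\n", sep = "")
  invisible(x)
}

#' Read case-control genotypes
#'
#' Reads a genotype panel from PLINK text (`.ped`/`.map`), PLINK 1 binary
#' (`.bed`/`.bim`/`.fam`, SNP-major), or a tab-separated dosage table with a
#' header (`iid`, `status`, then one 0/1/2 column per SNP; `NA` for
#' missing). Dosages count copies of allele 1 — the A1 column of `.bim`, or
#' the minor allele inferred from the data for `.ped`. Phenotypes follow the
#' PLINK convention: 2 = case, 1 = control, 0 or -9 = missing.
#'
#' @param path File path; for PLINK formats the prefix (without extension)
#'   or any one of the component files.
#' @param format `"auto"` (default, inferred from the files present),
#'   `"ped"`, `"bed"` or `"dosage"`.
#' @return A `genotype_panel`: integer dosage matrix `genotypes`
#'   (individuals x SNPs, `NA` = missing), SNP metadata tibble `meta`
#'   (`id`, `chrom`, `pos`, `allele1`, `allele2`), case-control `status`
#'   (1/0/`NA`), and `sample_id`.
#' @export
read_genotypes <- function(path, format = c("auto", "ped", "bed", "dosage")) {
  format <- match.arg(format)
  prefix <- sub("\\.(ped|map|bed|bim|fam|tsv|txt)$", "", path)
  if (format == "auto") {
    format <- if (file.exists(paste0(prefix, ".bed"))) "bed"
      else if (file.exists(paste0(prefix, ".ped"))) "ped"
      else "dosage"
  }
  switch(format,
    ped = read_ped(prefix),
    bed = read_bed(prefix),
    dosage = read_dosage_table(path)
  )
}

read_map_like <- function(path, alleles = FALSE) {
  cols <- if (alleles) {
    c("chrom", "id", "cm", "pos", "allele1", "allele2")
  } else {
    c("chrom", "id", "cm", "pos")
  }
  df <- utils::read.table(path, header = FALSE, col.names = cols,
                          colClasses = c("character", "character", "numeric",
                                         "integer",
                                         if (alleles) rep("character", 2)))
  meta <- tibble::tibble(
    id = df$id, chrom = df$chrom, pos = df$pos,
    allele1 = if (alleles) df$allele1 else NA_character_,
    allele2 = if (alleles) df$allele2 else NA_character_
  )
  meta
}

status_from_pheno <- function(pheno) {
  s <- rep(NA_integer_, length(pheno))
  s[pheno == "2"] <- 1L
  s[pheno == "1"] <- 0L
  s
}

read_ped <- function(prefix) {
  meta <- read_map_like(paste0(prefix, ".map"))
  ped <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                           colClasses = "character")
  m <- nrow(meta)
  if (ncol(ped) != 6 + 2 * m) {
    stop("column count of .ped does not match .map SNP count", call. = FALSE)
  }
  n <- nrow(ped)
  status <- status_from_pheno(ped[[6]])
  geno <- matrix(NA_integer_, n, m)
  a1 <- character(m)
  a2 <- character(m)
  for (k in seq_len(m)) {
    x <- ped[[5 + 2 * k]]
    y <- ped[[6 + 2 * k]]
    miss <- x == "0" | y == "0"
    alleles <- sort(unique(c(x[!miss], y[!miss])))
    if (length(alleles) > 2) {
      stop("SNP ", meta$id[k], " has more than two alleles", call. = FALSE)
    }
    if (length(alleles) == 0) alleles <- c("0", "0")
    if (length(alleles) == 1) alleles <- c(alleles, alleles)
    # allele1 = minor allele (PLINK A1 convention for text input)
    cnt1 <- sum(x[!miss] == alleles[1]) + sum(y[!miss] == alleles[1])
    cnt2 <- sum(x[!miss] == alleles[2]) + sum(y[!miss] == alleles[2])
    if (cnt1 > cnt2) alleles <- rev(alleles)
    a1[k] <- alleles[1]
    a2[k] <- alleles[2]
    d <- (x == alleles[1]) + (y == alleles[1])
    d[miss] <- NA_integer_
    geno[, k] <- as.integer(d)
  }
  meta$allele1 <- a1
  meta$allele2 <- a2
  new_genotype_panel(geno, meta, status, sample_id = ped[[2]])
}

read_fam <- function(path) {
  fam <- utils::read.table(path, header = FALSE, colClasses = "character")
  list(sample_id = fam[[2]], status = status_from_pheno(fam[[6]]))
}

# PLINK 1 .bed: magic bytes 0x6c 0x1b, mode byte 0x01 (SNP-major); each SNP
# packs 4 individuals per byte, low bits first: 00 = hom A1, 01 = missing,
# 10 = het, 11 = hom A2.
read_bed <- function(prefix) {
  meta <- read_map_like(paste0(prefix, ".bim"), alleles = TRUE)
  fam <- read_fam(paste0(prefix, ".fam"))
  n <- length(fam$sample_id)
  m <- nrow(meta)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (length(magic) < 3 || magic[1] != as.raw(0x6c) || magic[2] != as.raw(0x1b)) {
    stop("not a PLINK 1 .bed file (bad magic bytes)", call. = FALSE)
  }
  if (magic[3] != as.raw(0x01)) {
    stop("only SNP-major .bed files are supported", call. = FALSE)
  }
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_snp * m)
  if (length(raw) != bytes_per_snp * m) {
    stop(".bed size does not match .bim/.fam dimensions", call. = FALSE)
  }
  ints <- as.integer(raw)
  # unpack 2-bit codes, individuals within byte from the low bits up
  codes <- rbind(
    ints %% 4L,
    (ints %/% 4L) %% 4L,
    (ints %/% 16L) %% 4L,
    ints %/% 64L
  )
  codes <- matrix(as.vector(codes), nrow = 4L * bytes_per_snp)[seq_len(n), ,
                                                               drop = FALSE]
  lookup <- c(2L, NA_integer_, 1L, 0L)  # code 0,1,2,3 -> dosage of A1
  geno <- matrix(lookup[codes + 1L], nrow = n)
  new_genotype_panel(geno, meta, fam$status, sample_id = fam$sample_id)
}

read_dosage_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("iid", "status") %in% names(df))) {
    stop("dosage table must have `iid` and `status` columns", call. = FALSE)
  }
  snp_cols <- setdiff(names(df), c("iid", "status"))
  geno <- vapply(snp_cols, function(cn) {
    suppressWarnings(as.integer(df[[cn]]))
  }, integer(nrow(df)))
  geno <- matrix(geno, nrow = nrow(df),
                 dimnames = list(NULL, snp_cols))
  if (any(!is.na(geno) & !(geno %in% 0:2))) {
    stop("dosage table entries must be 0, 1, 2 or NA", call. = FALSE)
  }
  meta <- tibble::tibble(id = snp_cols, chrom = NA_character_,
                         pos = NA_integer_, allele1 = NA_character_,
                         allele2 = NA_character_)
  new_genotype_panel(geno, meta, status_from_pheno(df$status),
                     sample_id = df$iid)
}

#' Write a genotype panel in PLINK format
#'
#' Writes `.ped`/`.map` or `.bed`/`.bim`/`.fam` (SNP-major) files, e.g. to
#' export simulated panels for external tools. Dosages are written as
#' counts of `allele1`; missing alleles become `0` (text) or the missing
#' code (binary).
#'
#' @param panel A `genotype_panel` (see [read_genotypes()]).
#' @param prefix Output path prefix.
#' @param format `"ped"` or `"bed"`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix, format = c("ped", "bed")) {
  format <- match.arg(format)
  geno <- panel$genotypes
  meta <- panel$meta
  a1 <- ifelse(is.na(meta$allele1), "A", meta$allele1)
  a2 <- ifelse(is.na(meta$allele2), "B", meta$allele2)
  pheno <- ifelse(is.na(panel$status), "-9",
                  ifelse(panel$status == 1L, "2", "1"))
  if (format == "ped") {
    utils::write.table(
      data.frame(meta$chrom, meta$id, 0, meta$pos),
      paste0(prefix, ".map"), quote = FALSE, sep = "\t",
      row.names = FALSE, col.names = FALSE
    )
    al <- matrix("0", nrow(geno), 2 * ncol(geno))
    for (k in seq_len(ncol(geno))) {
      d <- geno[, k]
      al[, 2 * k - 1] <- ifelse(is.na(d), "0", ifelse(d >= 1, a1[k], a2[k]))
      al[, 2 * k] <- ifelse(is.na(d), "0", ifelse(d == 2, a1[k], a2[k]))
    }
    ped <- cbind("FAM", panel$sample_id, "0", "0", "0", pheno, al)
    utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                       sep = " ", row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(
      data.frame(meta$chrom, meta$id, 0, meta$pos, a1, a2),
      paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
      row.names = FALSE, col.names = FALSE
    )
    utils::write.table(
      data.frame("FAM", panel$sample_id, 0, 0, 0, pheno),
      paste0(prefix, ".fam"), quote = FALSE, sep = " ",
      row.names = FALSE, col.names = FALSE
    )
    n <- nrow(geno)
    bytes_per_snp <- ceiling(n / 4)
    code_of <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    for (k in seq_len(ncol(geno))) {
      codes <- c(code_of(geno[, k]), rep.int(0L, 4 * bytes_per_snp - n))
      cm <- matrix(codes, nrow = 4)
      bytes <- cm[1, ] + 4L * cm[2, ] + 16L * cm[3, ] + 64L * cm[4, ]
      writeBin(as.raw(bytes), con)
    }
  }
  invisible(prefix)
}
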