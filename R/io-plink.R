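#' Genotype matrix container
#'
#' Holds raw biallelic allele counts for `N` samples by `M` variants together
#' with sample identifiers and per-variant records. Counts are counts of
#' **allele1** (the bim A1 allele): 0, 1, 2 or `NA` for a missing call. The
#' sign of any downstream effect estimate is relative to allele1, so the
#' counted-allele convention matters and is fixed here.
#'
#' @param counts integer matrix, samples in rows, variants in columns; entries
#'   in \{0, 1, 2, NA\}.
#' @param sample_ids character vector, one id per row of `counts`.
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `allele1`,
#'   `allele2`, one row per column of `counts`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(counts, sample_ids, variants) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  stopifnot(nrow(counts) == length(sample_ids),
            ncol(counts) == nrow(variants))
  ok <- counts %in% c(0L, 1L, 2L, NA)
  if (!all(ok)) stop("genotype counts must be 0, 1, 2 or NA")
  validate_variant_records(variants)
  structure(list(counts = counts,
                 sample_ids = as.character(sample_ids),
                 variants = variants),
            class = "genotype_matrix")
}

validate_variant_records <- function(v) {
  need <- c("chrom", "pos", "id", "allele1", "allele2")
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("variant table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(v$pos < 1)) stop("variant positions are 1-based and must be >= 1")
  if (any(!nzchar(v$id))) stop("variant ids must be non-empty")
  if (any(v$allele1 == v$allele2)) stop("allele1 must differ from allele2")
  invisible(v)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d missing calls)\n",
              nrow(x$counts), ncol(x$counts), sum(is.na(x$counts))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

# 256 x 4 decode table: byte value -> allele1 counts of the 4 packed samples.
# 2-bit codes, least-significant pair first: 00 = hom allele1 (2 copies),
# 01 = missing, 10 = het (1 copy), 11 = hom allele2 (0 copies).
bed_decode_table <- function() {
  code_to_count <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  tab <- matrix(NA_integer_, nrow = 256L, ncol = 4L)
  for (b in 0:255) {
    codes <- bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L)
    tab[b + 1L, ] <- code_to_count[as.character(codes)]
  }
  tab
}

#' Read a PLINK binary fileset
#'
#' Reads `prefix.bed` / `prefix.bim` / `prefix.fam` into a [genotype_matrix].
#' Only SNP-major bed files (magic bytes `6c 1b 01`) are supported. Genotypes
#' are decoded as counts of the bim allele1 (A1) allele; missing calls become
#' `NA`. Mean imputation of missing calls is deliberately left to the GRM
#' layer, never done here.
#'
#' @param prefix path prefix; `.bed`, `.bim`, `.fam` extensions are appended.
#' @return A [genotype_matrix].
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("missing PLINK file: ", p)

  fam <- data.table::fread(fam_path, header = FALSE, data.table = FALSE)
  bim <- data.table::fread(bim_path, header = FALSE, data.table = FALSE,
                           colClasses = list(character = c(1, 2, 5, 6)))
  if (ncol(fam) < 2) stop("fam file needs at least 2 columns")
  if (ncol(bim) < 6) stop("bim file needs 6 columns")
  names(bim)[1:6] <- c("chrom", "id", "cM", "pos", "allele1", "allele2")
  n <- nrow(fam); m <- nrow(bim)

  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic bytes): ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed files are supported: ", bed_path)
  bpv <- ceiling(n / 4)          # bytes per variant
  if (length(raw) - 3L != bpv * m)
    stop(sprintf("bed size mismatch: %d data bytes, expected %d (N=%d, M=%d)",
                 length(raw) - 3L, bpv * m, n, m))

  tab <- bed_decode_table()
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
  # decode all variants at once: each byte expands to 4 sample slots
  counts <- matrix(t(tab[body + 1L, , drop = FALSE]), nrow = 4L * bpv, ncol = m)
  counts <- counts[seq_len(n), , drop = FALSE]

  variants <- bim[, c("chrom", "pos", "id", "allele1", "allele2")]
  variants$chrom <- as.character(variants$chrom)
  genotype_matrix(counts, as.character(fam[[2]]), variants)
}

#' Write a PLINK binary fileset
#'
#' Inverse of [read_plink()]; encodes allele1 counts into the 2-bit SNP-major
#' bed layout. Used by the simulator and for round-trip testing.
#'
#' @param geno a [genotype_matrix].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  counts <- geno$counts
  n <- nrow(counts); m <- ncol(counts)
  # count -> 2-bit code (see bed_decode_table)
  code <- matrix(3L, nrow = n, ncol = m)
  code[counts == 2L] <- 0L
  code[counts == 1L] <- 2L
  code[counts == 0L] <- 3L
  code[is.na(counts)] <- 1L
  bpv <- ceiling(n / 4)
  pad <- 4L * bpv - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  idx <- rep(seq_len(bpv), each = 4L)
  shifted <- code * rep(c(1L, 4L, 16L, 64L), bpv)
  bytes <- rowsum(shifted, group = idx)   # bpv x m, one byte per 4 samples
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)

  v <- geno$variants
  bim <- data.frame(v$chrom, v$id, 0, v$pos, v$allele1, v$allele2)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE)
  fam <- data.frame(geno$sample_ids, geno$sample_ids, 0, 0, 0, -9)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE)
  invisible(prefix)
}
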