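#' Drop monomorphic and all-missing variants
#'
#' Variants with minor-allele count < 1 among non-missing calls (including
#' all-missing columns) carry no information for the GRM and would break the
#' Hardy-Weinberg standardization; they are removed with a message.
#'
#' @param geno a [genotype_matrix].
#' @return A [genotype_matrix] containing only polymorphic variants.
#' @export
drop_monomorphic <- function(geno) {
  cnt <- geno$counts
  n_called <- colSums(!is.na(cnt))
  ac <- colSums(cnt, na.rm = TRUE)
  mac <- pmin(ac, 2 * n_called - ac)
  keep <- n_called > 0 & mac >= 1
  if (!all(keep))
    message(sum(!keep), " monomorphic/all-missing variants dropped, ",
            sum(keep), " retained")
  genotype_matrix(cnt[, keep, drop = FALSE], geno$sample_ids,
                  geno$variants[keep, , drop = FALSE])
}

#' Standardize genotypes for the implicit GRM
#'
#' Builds the standardized matrix `A` behind the GRM \eqn{\psi = A A^T / M}:
#' column j is \eqn{(g_j - 2 p_j) / \sqrt{2 p_j (1 - p_j)}} with the allele
#' frequency \eqn{p_j} computed from non-missing calls and missing entries
#' imputed to the mean \eqn{2 p_j} (hence exactly 0 after centering). The
#' Hardy-Weinberg scaling makes \eqn{\psi} a correlation-like kinship
#' estimator.
#'
#' @param geno a [genotype_matrix] with monomorphic variants already removed
#'   (see [drop_monomorphic()]).
#' @return An object of class `std_genotypes` with elements `A` (N x M dense
#'   standardized matrix), `p` (allele1 frequencies), `N`, `M`, `sample_ids`.
#' @export
standardize_genotypes <- function(geno) {
  cnt <- geno$counts
  n_called <- colSums(!is.na(cnt))
  p <- colSums(cnt, na.rm = TRUE) / (2 * n_called)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("monomorphic or all-missing variant reached standardization; ",
         "call drop_monomorphic() first")
  A <- sweep(ifelse(is.na(cnt), rep(2 * p, each = nrow(cnt)), cnt),
             2, 2 * p, `-`)
  A <- sweep(A, 2, sqrt(2 * p * (1 - p)), `/`)
  structure(list(A = A, p = p, N = nrow(A), M = ncol(A),
                 sample_ids = geno$sample_ids,
                 diag = rowSums(A^2) / ncol(A)),
            class = "std_genotypes")
}

#' @export
print.std_genotypes <- function(x, ...) {
  cat(sprintf("std_genotypes: %d samples x %d variants (implicit GRM)\n",
              x$N, x$M))
  invisible(x)
}

#' Implicit GRM-vector product
#'
#' Computes \eqn{\psi v = A (A^T v) / M} with two matrix-vector products,
#' never forming the N x N GRM: O(MN) time, O(N + M) extra space.
#'
#' @param gstd a `std_genotypes` object.
#' @param v numeric vector of length N.
#' @return Numeric vector \eqn{\psi v} of length N.
#' @export
grm_matvec <- function(gstd, v) {
  if (length(v) != gstd$N) stop("v must have length N = ", gstd$N)
  if (any(!is.finite(v))) stop("v must be finite")
  drop(gstd$A %*% crossprod(gstd$A, v)) / gstd$M
}

#' Diagonal of the implicit GRM
#'
#' Entry i is \eqn{\sum_j a_{ij}^2 / M}; needed by the Jacobi preconditioner.
#' Cached at standardization time since the preconditioner asks for it on
#' every solve.
#'
#' @param gstd a `std_genotypes` object.
#' @return Nonnegative numeric vector of length N.
#' @export
grm_diag <- function(gstd) {
  if (!is.null(gstd$diag)) gstd$diag else rowSums(gstd$A^2) / gstd$M
}

#' Column partition plan
#'
#' Splits the M variant columns into `n_workers` contiguous, disjoint,
#' covering ranges (half-open, 0-based), mirroring how the genotype matrix is
#' column-partitioned across devices in distributed deployments.
#'
#' @param M number of variant columns.
#' @param n_workers number of partitions (clamped to at most M).
#' @return An object of class `partition_plan`: list of `ranges` (k x 2 matrix
#'   of \[start, end) pairs) plus `n_workers`, `M`.
#' @export
partition_plan <- function(M, n_workers) {
  stopifnot(M >= 1, n_workers >= 1)
  k <- min(n_workers, M)
  bounds <- round(seq(0, M, length.out = k + 1))
  ranges <- cbind(start = bounds[-(k + 1)], end = bounds[-1])
  validate_partition_plan(
    structure(list(ranges = ranges, n_workers = k, M = M),
              class = "partition_plan"))
}

validate_partition_plan <- function(plan) {
  r <- plan$ranges
  if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 1)
    stop("partition plan needs a k x 2 range matrix")
  if (any(r[, 2] <= r[, 1])) stop("empty partition range")
  ord <- order(r[, 1])
  r <- r[ord, , drop = FALSE]
  if (r[1, 1] != 0 || r[nrow(r), 2] != plan$M ||
      (nrow(r) > 1 && any(r[-1, 1] != r[-nrow(r), 2])))
    stop("partition ranges must be disjoint and cover [0, M) exactly")
  plan
}

#' Partitioned GRM-vector product
#'
#' Computes \eqn{\psi v = \sum_i A_{:,s_i:e_i} (A_{:,s_i:e_i}^T v) / M}:
#' independent partial products per column block, then a deterministic
#' reduction in ascending partition order. Algebraically identical to
#' [grm_matvec()]; floating-point reassociation across blocks bounds the
#' agreement at about 1e-8 relative.
#'
#' @param gstd a `std_genotypes` object.
#' @param v numeric vector of length N.
#' @param plan a `partition_plan` covering `gstd$M` columns.
#' @return Numeric vector \eqn{\psi v} of length N.
#' @export
grm_matvec_partitioned <- function(gstd, v, plan) {
  validate_partition_plan(plan)
  if (plan$M != gstd$M) stop("plan covers ", plan$M, " columns, matrix has ",
                             gstd$M)
  if (length(v) != gstd$N) stop("v must have length N = ", gstd$N)
  out <- numeric(gstd$N)
  r <- plan$ranges[order(plan$ranges[, 1]), , drop = FALSE]
  for (i in seq_len(nrow(r))) {
    cols <- (r[i, 1] + 1L):r[i, 2]          # 0-based half-open -> 1-based
    blk <- gstd$A[, cols, drop = FALSE]
    out <- out + drop(blk %*% crossprod(blk, v))
  }
  out / gstd$M
}

#' GPU capacity planner
#'
#' Number of devices needed to hold the single-precision standardized genotype
#' matrix: \eqn{\lceil 4 M N / (\mathrm{mem\_gb} \times 10^9) \rceil}, at
#' least 1. Four bytes per value; decimal gigabytes (16 GB = 16e9 bytes).
#'
#' @param n_variants M, number of variants.
#' @param n_samples N, number of samples.
#' @param mem_gb per-device memory in decimal GB.
#' @return Integer device count >= 1.
#' @export
plan_gpus <- function(n_variants, n_samples, mem_gb) {
  stopifnot(n_variants >= 1, n_samples >= 1, mem_gb > 0)
  max(1L, as.integer(ceiling(4 * n_variants * n_samples / (mem_gb * 1e9))))
}
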