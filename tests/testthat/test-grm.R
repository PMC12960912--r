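test_that("standardization matches hand arithmetic on a (0,1,2) column", {
  v <- data.frame(chrom = "1", pos = 1L, id = "v", allele1 = "A",
                  allele2 = "G")
  g <- genotype_matrix(matrix(c(0L, 1L, 2L), 3, 1), c("a", "b", "c"), v)
  s <- standardize_genotypes(g)
  expect_equal(s$p, 0.5)
  expect_equal(s$A[, 1], c(-1, 0, 1) / sqrt(0.5))   # (-sqrt2, 0, +sqrt2)
})

test_that("all-het column centers to zero; missing entries impute to zero", {
  v <- data.frame(chrom = "1", pos = 1L, id = "v", allele1 = "A",
                  allele2 = "G")
  g <- genotype_matrix(matrix(1L, 4, 1), paste0("s", 1:4), v)
  s <- standardize_genotypes(g)
  expect_equal(s$p, 0.5)
  expect_equal(s$A[, 1], rep(0, 4))

  g2 <- genotype_matrix(matrix(c(0L, 1L, 2L, NA), 4, 1), paste0("s", 1:4), v)
  s2 <- standardize_genotypes(g2)
  expect_equal(s2$A[4, 1], 0)              # imputed to mean, centered away
  expect_equal(mean(s2$A[, 1]), 0, tolerance = 1e-12)
})

test_that("monomorphic columns are dropped and rejected past the filter", {
  v <- data.frame(chrom = "1", pos = 1:2, id = c("v1", "v2"),
                  allele1 = "A", allele2 = "G")
  g <- genotype_matrix(cbind(c(0L, 1L, 2L), c(0L, 0L, 0L)),
                       c("a", "b", "c"), v)
  expect_message(gf <- drop_monomorphic(g), "dropped")
  expect_equal(ncol(gf$counts), 1L)
  expect_error(standardize_genotypes(g), "drop_monomorphic")
})

test_that("grm_matvec equals the dense GRM product on random instances", {
  for (seed in 1:6) {
    gstd <- std_fixture(12, 7, seed, miss_rate = if (seed > 3) 0.1 else 0)
    psi <- dense_grm(gstd)
    set.seed(seed + 100)
    v <- rnorm(gstd$N)
    expect_equal(grm_matvec(gstd, v), drop(psi %*% v), tolerance = 1e-10)
  }
  gstd <- std_fixture(12, 7, 1)
  expect_equal(grm_matvec(gstd, numeric(12)), numeric(12))  # linearity at 0
  expect_error(grm_matvec(gstd, numeric(5)), "length")
})

test_that("single-column GRM reduces to the rank-1 identity", {
  v <- data.frame(chrom = "1", pos = 1L, id = "v", allele1 = "A",
                  allele2 = "G")
  g <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L), 4, 1), paste0("s", 1:4), v)
  s <- standardize_genotypes(g)
  a <- s$A[, 1]
  set.seed(3); vv <- rnorm(4)
  expect_equal(grm_matvec(s, vv), a * sum(a * vv), tolerance = 1e-12)
})

test_that("grm_diag matches the dense GRM diagonal and degenerate cases", {
  gstd <- std_fixture(10, 6, 5)
  expect_equal(grm_diag(gstd), diag(dense_grm(gstd)), tolerance = 1e-12)
  zero <- gstd; zero$A[] <- 0; zero$diag <- NULL
  expect_equal(grm_diag(zero), numeric(10))
})

test_that("partitioned matvec is partition-invariant and validates plans", {
  gstd <- std_fixture(25, 50, 8)
  psi <- dense_grm(gstd)
  set.seed(9); v <- rnorm(gstd$N)
  ref <- drop(psi %*% v)

  # k = 1 is bitwise-identical to the unpartitioned operator
  expect_identical(grm_matvec_partitioned(gstd, v, partition_plan(50, 1)),
                   grm_matvec(gstd, v))
  # one column per partition
  expect_equal(grm_matvec_partitioned(gstd, v, partition_plan(50, 50)),
               ref, tolerance = 1e-8)
  # >= 20 random ragged plans
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(2:9, 1)
    cuts <- sort(sample(1:49, k - 1))
    plan <- structure(list(ranges = cbind(c(0, cuts), c(cuts, 50)),
                           n_workers = k, M = 50L),
                      class = "partition_plan")
    expect_equal(grm_matvec_partitioned(gstd, v, plan), ref,
                 tolerance = 1e-8)
  }

  bad <- structure(list(ranges = cbind(c(0, 30), c(20, 50)),
                        n_workers = 2, M = 50L), class = "partition_plan")
  expect_error(grm_matvec_partitioned(gstd, v, bad), "cover")
})

test_that("the implicit GRM is symmetric and positive semidefinite", {
  gstd <- std_fixture(30, 40, 12)
  for (seed in 1:10) {
    set.seed(seed)
    u <- rnorm(30); v <- rnorm(30)
    lhs <- sum(u * grm_matvec(gstd, v))
    rhs <- sum(v * grm_matvec(gstd, u))
    expect_equal(lhs, rhs, tolerance = 1e-8)
    expect_gte(sum(v * grm_matvec(gstd, v)), -1e-10)
  }
})

test_that("plan_gpus reproduces the published capacity relationship", {
  # fixed variant count from the scaling figure, N = 100k, 16 GB devices:
  # 4 * 123826 * 1e5 / 16e9 = 3.0957 -> 4 devices
  expect_identical(plan_gpus(123826, 100000, 16), 4L)
  expect_identical(plan_gpus(100, 100, 16), 1L)       # minimum clamp
  # doubling memory exactly halves the pre-ceiling count: 3.0957 -> 1.548 -> 2
  expect_identical(plan_gpus(123826, 100000, 32), 2L)
})

test_that("plan_gpus equals the brute-force ceiling and is monotone", {
  set.seed(77)
  for (i in 1:1000) {
    M <- sample(1:5e6, 1); N <- sample(1:1e6, 1)
    mem <- runif(1, 1, 128)
    expect_identical(plan_gpus(M, N, mem),
                     max(1L, as.integer(ceiling(4 * M * N / (mem * 1e9)))))
  }
  for (i in 1:50) {
    M <- sample(1e4:1e6, 1); N <- sample(1e4:1e6, 1)
    mem <- runif(1, 4, 64)
    expect_lte(plan_gpus(M, N, mem), plan_gpus(M + 1000, N, mem))
    expect_lte(plan_gpus(M, N, mem), plan_gpus(M, N + 1000, mem))
    expect_gte(plan_gpus(M, N, mem), plan_gpus(M, N, mem * 2))
  }
  expect_error(plan_gpus(0, 10, 16))
})
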