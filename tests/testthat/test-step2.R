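make_step2_fixture <- function(seed = 91, n = 300, m = 400,
                               prevalence = 0.3) {
  cfg <- sim_config(n_samples = n, n_variants = m, seed = seed,
                    family_structure = "sib_pairs", tau_true = 0.5,
                    prevalence = prevalence)
  sim <- simulate_cohort(cfg)
  fit <- fit_null_glmm(sim$pheno, sim$geno,
                       control = glmm_control(max_outer = 50))
  fit$variance_ratio <- estimate_variance_ratio(fit, seed = seed)
  list(sim = sim, fit = fit)
}

test_that("chunked and parallel runs are byte-identical to the serial run", {
  fx <- make_step2_fixture()
  dir <- withr::local_tempdir()
  serial <- run_assoc(fx$fit, fx$sim$geno, chunks = 1, workers = 1)
  chunked <- run_assoc(fx$fit, fx$sim$geno, chunks = 8, workers = 4)
  expect_identical(serial, chunked)

  p1 <- file.path(dir, "serial.tsv"); p2 <- file.path(dir, "chunked.tsv")
  write_results(serial, p1); write_results(chunked, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("a one-trait manifest reproduces the direct invocation", {
  fx <- make_step2_fixture(seed = 93)
  dir <- withr::local_tempdir()
  model <- file.path(dir, "t1.model.json")
  vr <- file.path(dir, "t1.vr.json")
  out <- file.path(dir, "t1.out.tsv")
  write_null_model(fx$fit, model)
  write_variance_ratio(fx$fit$variance_ratio, vr)
  mpath <- file.path(dir, "manifest.tsv")
  writeLines(c("trait_id\tnull_model\tvariance_ratio\toutput",
               paste("t1", model, vr, out, sep = "\t")), mpath)
  run_step2_batch(read_manifest(mpath), fx$sim$geno, chunks = 3)

  direct <- file.path(dir, "direct.tsv")
  write_results(run_assoc(fx$fit, fx$sim$geno), direct)
  expect_identical(readLines(out), readLines(direct))
})

test_that("a two-trait batch writes both outputs and checks sample sets", {
  fx1 <- make_step2_fixture(seed = 95)
  fx2 <- make_step2_fixture(seed = 95, prevalence = 0.15)
  dir <- withr::local_tempdir()
  paths <- list()
  for (t in c("a", "b")) {
    fx <- if (t == "a") fx1 else fx2
    write_null_model(fx$fit, file.path(dir, paste0(t, ".model.json")))
    write_variance_ratio(fx$fit$variance_ratio,
                         file.path(dir, paste0(t, ".vr.json")))
  }
  mpath <- file.path(dir, "manifest.tsv")
  rows <- vapply(c("a", "b"), function(t)
    paste(t, file.path(dir, paste0(t, ".model.json")),
          file.path(dir, paste0(t, ".vr.json")),
          file.path(dir, paste0(t, ".out.tsv")), sep = "\t"), "")
  writeLines(c("trait_id\tnull_model\tvariance_ratio\toutput", rows), mpath)
  run_step2_batch(read_manifest(mpath), fx1$sim$geno, chunks = 2)
  expect_true(all(file.exists(file.path(dir, c("a.out.tsv", "b.out.tsv")))))
  ra <- read_results(file.path(dir, "a.out.tsv"))
  expect_equal(nrow(ra), 400L)

  # sample-id mismatch names the offending trait
  other <- make_step2_fixture(seed = 97, n = 200)
  expect_error(run_step2_batch(read_manifest(mpath), other$sim$geno),
               "trait 'a'")
})

test_that("logged SPA counts equal a recount from the output table", {
  fx <- make_step2_fixture(seed = 99, n = 500, m = 300, prevalence = 0.05)
  msgs <- capture_messages(res <- run_assoc(fx$fit, fx$sim$geno))
  logged <- as.integer(sub(".*spa_applied=(\\d+).*", "\\1",
                           grep("spa_applied=", msgs, value = TRUE)))
  z <- abs(res$Tstat) / sqrt(res$var)
  expect_identical(logged, sum(res$testable & z > 2))
  expect_identical(logged, sum(res$spa_applied))
  # the audit column keeps the uncorrected normal p
  expect_true(all(res$p_value_NA[res$testable] ==
                    2 * pnorm(-z[res$testable])))
})

test_that("dosage input follows the same path as hard calls", {
  fx <- make_step2_fixture(seed = 101, n = 150, m = 60)
  dir <- withr::local_tempdir()
  g <- fx$sim$geno
  path <- file.path(dir, "dose.tsv")
  D <- g$counts
  tab <- cbind(g$variants[, c("chrom", "pos", "id")],
               a1 = g$variants$allele1, a2 = g$variants$allele2,
               as.data.frame(t(D)))
  names(tab)[6:ncol(tab)] <- g$sample_ids
  data.table::fwrite(tab, path, sep = "\t")
  res_dose <- run_assoc(fx$fit, read_dosage(path))
  res_hard <- run_assoc(fx$fit, g)
  expect_equal(res_dose$p_value, res_hard$p_value, tolerance = 1e-12)
})
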