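test_that("with tau fixed at 0 the binary fit matches an independent IRLS oracle", {
  cfg <- sim_config(n_samples = 500, n_variants = 50, seed = 31,
                    prevalence = 0.35, tau_true = 0)
  sim <- simulate_cohort(cfg)
  fit <- fit_null_glmm(sim$pheno,
                       control = glmm_control(fix_tau = 0, tol = 1e-8))
  oracle <- irls_logistic(sim$pheno$X, sim$pheno$Y)
  expect_lt(max(abs(fit$alpha - oracle)), 1e-6)
  expect_equal(fit$tau, 0)
  # score equation for the intercept: residuals sum to ~0
  expect_lt(abs(sum(fit$residuals)), 1e-6 * length(fit$residuals))
})

test_that("intercept-only balanced binary fit returns alpha0 = logit(0.5) = 0", {
  n <- 200
  ph <- phenotype_table(paste0("s", 1:n), rep(c(0, 1), n / 2),
                        trait_type = "binary")
  fit <- fit_null_glmm(ph, control = glmm_control(fix_tau = 0, tol = 1e-10))
  expect_equal(unname(fit$alpha[1]), 0, tolerance = 1e-8)
  expect_equal(fit$mu, rep(0.5, n), tolerance = 1e-8)
})

test_that("gaussian tau estimate matches a dense REML oracle within 2%", {
  cfg <- sim_config(n_samples = 300, n_variants = 500, seed = 33,
                    family_structure = "sib_quads", tau_true = 1,
                    trait_type = "quantitative")
  sim <- simulate_cohort(cfg)
  fit <- fit_null_glmm(sim$pheno, sim$geno,
                       control = glmm_control(tol = 1e-6, max_outer = 60))
  gstd <- standardize_genotypes(drop_monomorphic(sim$geno))
  oracle <- reml_oracle_gaussian(sim$pheno$Y, sim$pheno$X, dense_grm(gstd))
  expect_lt(abs(fit$tau - oracle$tau) / oracle$tau, 0.02)
  expect_lt(abs(fit$phi - oracle$phi) / oracle$phi, 0.02)
})

test_that("tau estimated on unrelated samples converges to near zero", {
  cfg <- sim_config(n_samples = 1000, n_variants = 800, seed = 35,
                    family_structure = "unrelated", tau_true = 0,
                    trait_type = "quantitative")
  sim <- simulate_cohort(cfg)
  fit <- fit_null_glmm(sim$pheno, sim$geno)
  expect_lt(fit$tau, 0.05)
})

test_that("Hutchinson trace agrees with the exact trace within 5%", {
  gstd <- std_fixture(300, 400, seed = 37)
  set.seed(37)
  W <- runif(300, 0.1, 0.25)
  tau <- 0.8
  ctrl_exact <- glmm_control()                      # N=300 <= exact cutoff
  ctrl_hutch <- glmm_control(exact_trace_n = 10, n_probes = 30, seed = 99)
  env_e <- mmgwas:::make_trace_env(gstd, ctrl_exact, gaussian = FALSE)
  env_h <- mmgwas:::make_trace_env(gstd, ctrl_hutch, gaussian = FALSE)
  tr_e <- mmgwas:::trace_sigma_inv(W, tau, gstd, env_e, ctrl_exact)
  tr_h <- mmgwas:::trace_sigma_inv(W, tau, gstd, env_h, ctrl_hutch)
  expect_lt(abs(tr_h["tr_psi"] - tr_e["tr_psi"]) / tr_e["tr_psi"], 0.05)
})

test_that("the REML score at the true tau averages to zero across seeds", {
  scores <- vapply(1:12, function(seed) {
    cfg <- sim_config(n_samples = 250, n_variants = 400, seed = 400 + seed,
                      family_structure = "sib_quads", tau_true = 1,
                      trait_type = "quantitative", alpha_true = numeric(0))
    sim <- simulate_cohort(cfg)
    gstd <- standardize_genotypes(drop_monomorphic(sim$geno))
    st <- ai_reml_step(sim$pheno$Y, sim$pheno$X, rep(1, 250), tau = 1,
                       gstd = gstd, phi = 1)
    st$score[["psi"]]
  }, numeric(1))
  # mean score ~ 0 within Monte-Carlo error of the mean
  expect_lt(abs(mean(scores)), 3 * sd(scores) / sqrt(length(scores)))
})

test_that("non-convergence raises an error carrying the last iterate", {
  cfg <- sim_config(n_samples = 200, n_variants = 300, seed = 39,
                    family_structure = "sib_quads", tau_true = 1,
                    trait_type = "quantitative")
  sim <- simulate_cohort(cfg)
  err <- tryCatch(
    fit_null_glmm(sim$pheno, sim$geno,
                  control = glmm_control(tol = 1e-12, max_outer = 2)),
    mmgwas_nonconvergence = function(e) e)
  expect_s3_class(err, "mmgwas_nonconvergence")
  expect_false(err$fit$converged)
  expect_true(is.finite(err$fit$tau))
})

test_that("PCG iteration growth with N is sublinear on matched simulations", {
  iters <- vapply(c(200L, 3200L), function(n) {
    cfg <- sim_config(n_samples = n, n_variants = 2L * n, seed = 41,
                      family_structure = "sib_quads", tau_true = 1,
                      prevalence = 0.3)
    sim <- simulate_genotypes(cfg)
    gstd <- standardize_genotypes(drop_monomorphic(sim$geno))
    set.seed(42)
    W <- runif(gstd$N, 0.1, 0.25)     # binary-like weights
    b <- rnorm(gstd$N)
    pcg_solve(W, 1, gstd, b, tol = 1e-6)$iterations
  }, integer(1))
  expect_lt(iters[2] / iters[1], 4)
})
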