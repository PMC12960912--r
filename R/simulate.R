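#' Simulation configuration
#'
#' Describes a synthetic cohort: biallelic genotypes with a uniform MAF
#' spectrum, optional family blocks built by Mendelian transmission, and
#' phenotypes drawn exactly from the mixed model — a latent polygenic effect
#' \eqn{b \sim N(0, \tau\psi)} with \eqn{\psi} the realized GRM of the
#' simulated markers, passed through the logistic link (binary, with the
#' intercept solved to hit a target prevalence) or added to gaussian noise
#' (quantitative).
#'
#' @param n_samples number of samples (rounded down to a multiple of the
#'   family size for related designs).
#' @param n_variants number of independent biallelic markers.
#' @param maf_range uniform range for the allele frequencies, within (0, 0.5\].
#' @param family_structure `"unrelated"`, `"sib_pairs"` (2 sibs per family)
#'   or `"sib_quads"` (4 sibs per family); sibs share two simulated parents,
#'   giving expected kinship 1/4 (GRM expectation 1/2).
#' @param tau_true variance component of the polygenic effect.
#' @param alpha_true fixed effects for the generated covariates (a standard
#'   normal and a Bernoulli(0.5) covariate by default); use `numeric(0)` for
#'   an intercept-only model.
#' @param prevalence target case fraction for binary traits (the intercept is
#'   solved numerically); ignored for quantitative traits.
#' @param n_cases,n_controls optional case-control ascertainment: simulate a
#'   larger pool at `prevalence` and keep exactly this many cases and
#'   controls, e.g. to construct extreme 1:99 imbalance.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param seed single integer seeding all randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1000, n_variants = 2000,
                       maf_range = c(0.05, 0.5),
                       family_structure = c("unrelated", "sib_pairs",
                                            "sib_quads"),
                       tau_true = 1, alpha_true = c(0.2, 0.3),
                       prevalence = 0.5, n_cases = NULL, n_controls = NULL,
                       trait_type = c("binary", "quantitative"), seed = 1) {
  family_structure <- match.arg(family_structure)
  trait_type <- match.arg(trait_type)
  stopifnot(maf_range[1] > 0, maf_range[1] < maf_range[2],
            maf_range[2] <= 0.5, tau_true >= 0,
            prevalence > 0, prevalence < 1)
  structure(list(n_samples = n_samples, n_variants = n_variants,
                 maf_range = maf_range, family_structure = family_structure,
                 tau_true = tau_true, alpha_true = alpha_true,
                 prevalence = prevalence, n_cases = n_cases,
                 n_controls = n_controls, trait_type = trait_type,
                 seed = seed),
            class = "sim_config")
}

# Mendelian transmission: each child receives one allele from each parent's
# stored haplotype pair, independently per marker (no linkage).
sample_offspring <- function(pat_hap, mat_hap) {
  m <- ncol(pat_hap[[1]])
  n <- nrow(pat_hap[[1]])
  from_pat <- matrix(stats::runif(n * m) < 0.5, n, m)
  from_mat <- matrix(stats::runif(n * m) < 0.5, n, m)
  a1 <- ifelse(from_pat, pat_hap[[1]], pat_hap[[2]])
  a2 <- ifelse(from_mat, mat_hap[[1]], mat_hap[[2]])
  a1 + a2
}

#' Simulate genotypes with known relatedness
#'
#' Founder haplotypes carry allele1 with probability \eqn{p_j \sim
#' U(\mathrm{maf\_range})}; offspring genotypes are built by Mendelian
#' transmission from stored parental haplotypes, so sib-sib GRM entries have
#' expectation 1/2 and unrelated pairs 0.
#'
#' @param cfg a [sim_config()].
#' @return list with `geno` (a [genotype_matrix]) and `family_id` (integer
#'   pedigree labels; 0 marks unrelated singletons).
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  m <- cfg$n_variants
  p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  fam_size <- switch(cfg$family_structure,
                     unrelated = 1L, sib_pairs = 2L, sib_quads = 4L)
  n <- (cfg$n_samples %/% fam_size) * fam_size
  if (n < cfg$n_samples)
    message("n_samples truncated to ", n, " (multiple of family size ",
            fam_size, ")")
  if (fam_size == 1L) {
    counts <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    family_id <- integer(n)
  } else {
    n_fam <- n %/% fam_size
    hap <- function() matrix(stats::runif(n_fam * m) < rep(p, each = n_fam),
                             n_fam, m) + 0L
    pat <- list(hap(), hap()); mat <- list(hap(), hap())
    kids <- lapply(seq_len(fam_size), function(k) sample_offspring(pat, mat))
    counts <- matrix(0L, n, m)
    for (k in seq_len(fam_size))
      counts[seq(k, n, by = fam_size), ] <- kids[[k]]
    family_id <- rep(seq_len(n_fam), each = fam_size)
  }
  variants <- data.frame(chrom = "1", pos = seq_len(m),
                         id = sprintf("snp%06d", seq_len(m)),
                         allele1 = "A", allele2 = "C")
  geno <- genotype_matrix(counts, sprintf("sample%06d", seq_len(n)), variants)
  list(geno = geno, family_id = family_id)
}

#' Simulate phenotypes from the mixed model
#'
#' Draws \eqn{b \sim N(0, \tau\psi)} exactly from the realized GRM of the
#' supplied markers, using the standardized genotype matrix itself as the
#' symmetric factor (\eqn{\psi = AA^T/M}, so \eqn{b = \sqrt{\tau/M}\,Az},
#' \eqn{z \sim N(0, I_M)}), then generates
#' \eqn{Y \sim \mathrm{Bernoulli}(\mathrm{expit}(\alpha_0 + X\alpha + b))}
#' with \eqn{\alpha_0} solved so the expected case fraction equals the target
#' prevalence, or \eqn{Y = X\alpha + b + \varepsilon},
#' \eqn{\varepsilon \sim N(0,1)} for quantitative traits. With ascertainment
#' requested, a pool is simulated and exactly `n_cases` + `n_controls`
#' samples are kept (genotype rows subset accordingly).
#'
#' @param sim output of [simulate_genotypes()].
#' @param cfg the same [sim_config()].
#' @return list with `pheno` (a [phenotype_table()]), `geno` (possibly
#'   subset under ascertainment), `b` (the latent polygenic draw), and
#'   `alpha0` (the solved intercept).
#' @export
simulate_phenotype <- function(sim, cfg) {
  geno <- sim$geno
  n <- nrow(geno$counts)
  set.seed(cfg$seed + 1L)
  gstd <- standardize_genotypes(drop_monomorphic(geno))
  # exact draw from N(0, tau psi): psi = A A^T / M, so A/sqrt(M) is a
  # symmetric-factor square root and b = sqrt(tau/M) A z has covariance
  # tau psi exactly, with no dense N x N matrix
  b <- if (cfg$tau_true > 0) {
    sqrt(cfg$tau_true / gstd$M) * drop(gstd$A %*% stats::rnorm(gstd$M))
  } else numeric(n)

  k <- length(cfg$alpha_true)
  X <- if (k == 0) matrix(numeric(0), n, 0) else {
    X0 <- matrix(stats::rnorm(n * k), n, k)
    if (k >= 2) X0[, 2] <- stats::rbinom(n, 1, 0.5)
    colnames(X0) <- paste0("covar", seq_len(k))
    X0
  }
  lin <- drop(if (k) X %*% cfg$alpha_true else numeric(n)) + b

  if (cfg$trait_type == "quantitative") {
    Y <- lin + stats::rnorm(n)
    alpha0 <- 0
  } else {
    alpha0 <- stats::uniroot(function(a) mean(stats::plogis(a + lin)) -
                               cfg$prevalence,
                             interval = c(-40, 40), tol = 1e-10)$root
    Y <- stats::rbinom(n, 1, stats::plogis(alpha0 + lin))
    if (all(Y == 0) || all(Y == 1)) {   # reseed once, then give up
      set.seed(cfg$seed + 2L)
      Y <- stats::rbinom(n, 1, stats::plogis(alpha0 + lin))
      if (all(Y == 0) || all(Y == 1))
        stop("unattainable prevalence: simulated phenotype is constant")
    }
    if (!is.null(cfg$n_cases) && !is.null(cfg$n_controls)) {
      cases <- which(Y == 1); controls <- which(Y == 0)
      if (length(cases) < cfg$n_cases || length(controls) < cfg$n_controls)
        stop("pool too small for requested case-control ascertainment: ",
             length(cases), " cases, ", length(controls), " controls drawn")
      keep <- sort(c(sample(cases, cfg$n_cases),
                     sample(controls, cfg$n_controls)))
      Y <- Y[keep]; X <- X[keep, , drop = FALSE]; b <- b[keep]
      geno <- genotype_matrix(geno$counts[keep, , drop = FALSE],
                              geno$sample_ids[keep], geno$variants)
      n <- length(keep)
    }
  }
  pheno <- phenotype_table(geno$sample_ids, Y, X, trait_type = cfg$trait_type)
  list(pheno = pheno, geno = geno, b = b, alpha0 = alpha0)
}

#' Simulate a full cohort
#'
#' Convenience wrapper: [simulate_genotypes()] then [simulate_phenotype()].
#'
#' @param cfg a [sim_config()].
#' @return list with `geno`, `pheno`, `family_id`, `b`, `alpha0`.
#' @export
simulate_cohort <- function(cfg) {
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim, cfg)
  list(geno = ph$geno, pheno = ph$pheno, family_id = sim$family_id,
       b = ph$b, alpha0 = ph$alpha0)
}
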