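# Stable Bernoulli-mixture CGF machinery for the saddlepoint correction.
# S = sum_i g_i Y_i with Y_i ~ Bernoulli(mu_i); K(t) = sum log(1 - mu + mu e^{g t}).
spa_cgf <- function(g, mu) {
  K <- function(t) {
    x <- g * t
    # log(1 - mu + mu e^x), written to avoid overflow for large |x|
    sum(ifelse(x > 0, x + log(mu + (1 - mu) * exp(-pmin(x, 745))),
               log(1 - mu + mu * exp(pmax(x, -745)))))
  }
  pi_t <- function(t) {
    ex <- exp(pmin(pmax(-g * t, -745), 745))
    mu / (mu + (1 - mu) * ex)
  }
  K1 <- function(t) { p <- pi_t(t); sum(g * p) }
  K2 <- function(t) { p <- pi_t(t); sum(g^2 * p * (1 - p)) }
  list(K = K, K1 = K1, K2 = K2,
       mean = sum(g * mu), var = sum(g^2 * mu * (1 - mu)),
       smin = sum(pmin(g, 0)), smax = sum(pmax(g, 0)))
}

# Solve K'(zeta) = s by safeguarded Newton with a bisection fallback.
spa_root <- function(cgf, s, maxit = 100, tol = 1e-10) {
  lo <- -1; hi <- 1
  while (cgf$K1(lo) > s && lo > -500) lo <- lo * 2
  while (cgf$K1(hi) < s && hi < 500) hi <- hi * 2
  if (cgf$K1(lo) > s || cgf$K1(hi) < s)
    return(list(zeta = NA_real_, converged = FALSE))
  zeta <- 0
  for (i in seq_len(maxit)) {
    f <- cgf$K1(zeta) - s
    if (abs(f) <= tol * (abs(s) + 1)) return(list(zeta = zeta, converged = TRUE))
    if (f > 0) hi <- min(hi, zeta) else lo <- max(lo, zeta)
    step <- f / cgf$K2(zeta)
    zeta_new <- zeta - step
    if (!is.finite(zeta_new) || zeta_new <= lo || zeta_new >= hi)
      zeta_new <- (lo + hi) / 2
    zeta <- zeta_new
  }
  list(zeta = zeta, converged = abs(cgf$K1(zeta) - s) <= 1e-6 * (abs(s) + 1))
}

# Barndorff-Nielsen tail P(S >= s) (upper) or P(S <= s) (lower) at the
# saddlepoint; falls back to the normal tail near the mean (|zeta| tiny),
# where the saddlepoint expression degenerates but the normal is accurate.
spa_tail <- function(cgf, s, upper) {
  if (upper && s >= cgf$smax) return(list(p = 0, converged = TRUE))
  if (!upper && s <= cgf$smin) return(list(p = 0, converged = TRUE))
  root <- spa_root(cgf, s)
  if (!root$converged) {
    p <- stats::pnorm(s, cgf$mean, sqrt(cgf$var), lower.tail = !upper)
    return(list(p = p, converged = FALSE))
  }
  zeta <- root$zeta
  if (abs(zeta) < 1e-4) {
    p <- stats::pnorm(s, cgf$mean, sqrt(cgf$var), lower.tail = !upper)
    return(list(p = p, converged = TRUE))
  }
  w <- sign(zeta) * sqrt(2 * (zeta * s - cgf$K(zeta)))
  v <- zeta * sqrt(cgf$K2(zeta))
  wstar <- w + log(v / w) / w
  p <- stats::pnorm(wstar, lower.tail = !upper)
  list(p = p, converged = TRUE)
}

#' Saddlepoint-corrected score-test p-value
#'
#' Computes a two-sided tail probability for the score
#' \eqn{S = \sum_i \tilde g_i Y_i} of a binary trait from the exact cumulant
#' generating function of the Bernoulli mixture, instead of the normal
#' approximation that fails in the far tails under extreme case-control
#' imbalance. The two tails are evaluated separately at
#' \eqn{K'(0) \pm |q - K'(0)|/\sqrt{r}} and summed, where `r` is the
#' variance-ratio calibration. Near the mean the normal p-value is returned
#' (the saddlepoint expression degenerates there and the normal is accurate).
#'
#' @param g covariate-adjusted genotype vector \eqn{\tilde g}.
#' @param mu fitted null probabilities.
#' @param q observed score \eqn{\sum_i \tilde g_i Y_i}.
#' @param r variance-ratio calibration factor (default 1).
#' @return list with `p` (two-sided, in (0, 1\]) and `converged`.
#' @export
spa_pvalue <- function(g, mu, q, r = 1) {
  cgf <- spa_cgf(g, mu)
  if (cgf$var <= 0) stop("degenerate score distribution: K''(0) <= 0")
  delta <- abs(q - cgf$mean) / sqrt(r)
  up <- spa_tail(cgf, cgf$mean + delta, upper = TRUE)
  lo <- spa_tail(cgf, cgf$mean - delta, upper = FALSE)
  p <- min(1, up$p + lo$p)
  list(p = max(p, .Machine$double.xmin),
       converged = up$converged && lo$converged)
}

#' Firth penalized logistic effect estimate
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' \eqn{\ell(\theta) + \frac12 \log\det I(\theta)} for the model
#' `Y ~ X + g` by Newton iteration with step-halving. The penalty keeps the
#' estimate finite under complete separation and reduces small-sample bias.
#'
#' @param g genotype/dosage vector (the tested term; its coefficient is
#'   returned).
#' @param X covariate matrix including the intercept.
#' @param y binary 0/1 response.
#' @param maxit Newton iteration cap.
#' @param tol convergence tolerance on the penalized score.
#' @return list with `beta`, `se` (penalized-information), `converged`,
#'   `coefficients` (all terms), `iterations`.
#' @export
firth_effect <- function(g, X, y, maxit = 50, tol = 1e-6) {
  if (!all(y %in% c(0, 1))) stop("Firth correction requires a binary 0/1 response")
  Z <- cbind(X, g = g)
  k <- ncol(Z)
  beta <- numeric(k)
  penll <- function(b) {
    eta <- drop(Z %*% b)
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-12)
    sum(y * eta - log1p(exp(pmin(eta, 700))) - pmax(eta - 700, 0)) +
      0.5 * determinant(crossprod(Z, Z * W), logarithm = TRUE)$modulus
  }
  ll <- penll(beta)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-12)
    XWX <- crossprod(Z, Z * W)
    XWXinv <- solve(XWX)
    h <- W * rowSums((Z %*% XWXinv) * Z)       # leverages of the W-weighted fit
    U <- drop(crossprod(Z, y - mu + h * (0.5 - mu)))
    if (max(abs(U)) < tol) { converged <- TRUE; break }
    delta <- drop(XWXinv %*% U)
    step <- 1
    repeat {
      cand <- beta + step * delta
      llc <- penll(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) { beta <- cand; ll <- llc; break }
      step <- step / 2
      if (step < 1e-8) break
    }
    if (step < 1e-8) break
  }
  eta <- drop(Z %*% beta)
  W <- pmax(stats::plogis(eta) * (1 - stats::plogis(eta)), 1e-12)
  se_all <- sqrt(diag(solve(crossprod(Z, Z * W))))
  list(beta = unname(beta[k]), se = unname(se_all[k]),
       converged = converged, coefficients = beta, iterations = it)
}

# Normalize a genotype source (genotype_matrix or read_dosage() output) to a
# dense dosage matrix plus variant records, imputing missing hard calls to
# the variant mean.
as_dosage_source <- function(geno) {
  if (inherits(geno, "genotype_matrix")) {
    D <- geno$counts
    storage.mode(D) <- "double"
    if (anyNA(D)) {
      mns <- colMeans(D, na.rm = TRUE)
      idx <- which(is.na(D), arr.ind = TRUE)
      D[idx] <- mns[idx[, 2]]
      D[is.na(D)] <- 0   # all-missing columns; flagged untestable downstream
    }
    list(variants = geno$variants, dosages = D, sample_ids = geno$sample_ids)
  } else if (is.list(geno) && !is.null(geno$dosages)) {
    list(variants = geno$variants, dosages = geno$dosages,
         sample_ids = rownames(geno$dosages))
  } else stop("genotype source must be a genotype_matrix or a dosage list")
}

# Vectorized score tests for one block of variants (columns of D).
score_test_block <- function(D, variants, fit, spa_trigger, firth,
                             firth_p_cutoff) {
  X <- fit$X; W <- fit$W; resid <- fit$residuals
  r <- fit$variance_ratio
  n <- nrow(D); m <- ncol(D)
  proj <- solve(crossprod(X, X * W), t(X * W))   # (X'WX)^{-1} X'W
  # residualize column by column: per-variant arithmetic must not depend on
  # how variants are blocked, so chunked runs stay bitwise-identical
  Gt <- D
  for (j in seq_len(m)) Gt[, j] <- D[, j] - X %*% (proj %*% D[, j])
  # score uses Sigma^{-1}-weighted residuals: for binary W = mu(1-mu) this is
  # G'(Y - mu); for gaussian W = 1/phi the residuals carry the 1/phi factor
  resid_w <- if (fit$trait_type == "quantitative") W * resid else resid
  Tstat <- colSums(Gt * resid_w)
  v_no <- colSums(W * Gt^2)
  testable <- v_no > 1e-12 * n
  v <- r * v_no
  z <- ifelse(testable, Tstat / sqrt(v), NA_real_)
  p_norm <- 2 * stats::pnorm(-abs(z))
  p <- p_norm
  spa_applied <- rep(FALSE, m)
  spa_conv <- rep(TRUE, m)
  if (fit$trait_type == "binary") {
    for (j in which(testable & abs(z) > spa_trigger)) {
      sp <- spa_pvalue(Gt[, j], fit$mu, q = Tstat[j] + sum(Gt[, j] * fit$mu),
                       r = r)
      p[j] <- sp$p
      spa_applied[j] <- TRUE
      spa_conv[j] <- sp$converged
    }
  }
  beta <- ifelse(testable, Tstat / v, NA_real_)
  se <- ifelse(testable, 1 / sqrt(v), NA_real_)
  if (firth && fit$trait_type == "binary") {
    for (j in which(testable & p < firth_p_cutoff)) {
      fe <- firth_effect(D[, j], X, fit$Y)
      if (fe$converged) { beta[j] <- fe$beta; se[j] <- fe$se }
    }
  }
  data.frame(chrom = variants$chrom, pos = variants$pos, id = variants$id,
             allele1 = variants$allele1, allele2 = variants$allele2,
             af = colMeans(D) / 2, n = n, beta = beta, se = se,
             Tstat = Tstat, var = v,
             p_value = ifelse(testable, p, NA_real_),
             p_value_NA = ifelse(testable, p_norm, NA_real_),
             is_SPA_converged = spa_conv, spa_applied = spa_applied,
             testable = testable)
}

#' Score test for a single variant
#'
#' Tests one dosage vector against a fitted null model: the variant is
#' residualized against the covariates under the null weights, the score
#' \eqn{T = \tilde G^T (Y - \mu)} and its variance-ratio-calibrated variance
#' \eqn{r \tilde G^T W \tilde G} are formed, and the p-value is taken from
#' the normal approximation or, when the standardized score exceeds
#' `spa_trigger` for a binary trait, from the saddlepoint approximation.
#'
#' @param g dosage/count vector of length N (allele1 scale, values in
#'   \[0, 2\]).
#' @param fit a converged `null_model_fit` (with `variance_ratio` set).
#' @param spa_trigger standardized-score threshold beyond which the SPA
#'   replaces the normal p-value (default 2).
#' @param variant optional one-row variant record for labeling.
#' @return one-row data.frame (see [run_assoc()] for columns).
#' @export
score_test <- function(g, fit, spa_trigger = 2, variant = NULL) {
  if (is.null(variant))
    variant <- data.frame(chrom = "0", pos = 1L, id = "variant",
                          allele1 = "A", allele2 = "B")
  if (length(g) != length(fit$Y)) stop("dosage length does not match the model")
  score_test_block(matrix(as.numeric(g), ncol = 1), variant, fit,
                   spa_trigger = spa_trigger, firth = FALSE,
                   firth_p_cutoff = 0.05)
}

#' Run Step-2 association tests for one trait
#'
#' Partitions the variants into `chunks` equal contiguous blocks, tests each
#' block independently (optionally across `workers` processes), and
#' concatenates results in the original variant order. Per-variant results
#' are pure functions of the inputs, so the output is identical for any
#' chunk/worker configuration.
#'
#' @param fit a converged `null_model_fit` with its `variance_ratio` set.
#' @param geno genotype source: a [genotype_matrix] or [read_dosage()] output.
#' @param chunks number of contiguous variant blocks.
#' @param workers processes for [parallel::mclapply()] over blocks.
#' @param spa_trigger see [score_test()].
#' @param firth apply Firth penalized effect re-estimation to variants with
#'   p below `firth_p_cutoff`.
#' @param firth_p_cutoff p-value threshold gating the Firth refit.
#' @return data.frame, one row per variant in input order, with columns
#'   `chrom, pos, id, allele1, allele2, af, n, beta, se, Tstat, var,
#'   p_value, p_value_NA, is_SPA_converged, spa_applied, testable`.
#' @export
run_assoc <- function(fit, geno, chunks = 1, workers = 1, spa_trigger = 2,
                      firth = FALSE, firth_p_cutoff = 0.05) {
  src <- as_dosage_source(geno)
  if (!is.null(src$sample_ids) &&
      !identical(as.character(src$sample_ids), as.character(fit$sample_ids)))
    stop("sample ids of the genotype source do not match the null model")
  m <- ncol(src$dosages)
  if (m == 0)
    return(score_test_block(src$dosages, src$variants, fit, spa_trigger,
                            firth, firth_p_cutoff))
  bounds <- round(seq(0, m, length.out = min(chunks, m) + 1))
  blocks <- lapply(seq_len(length(bounds) - 1),
                   function(i) (bounds[i] + 1L):bounds[i + 1L])
  worker <- function(cols)
    score_test_block(src$dosages[, cols, drop = FALSE],
                     src$variants[cols, , drop = FALSE], fit,
                     spa_trigger, firth, firth_p_cutoff)
  parts <- if (workers > 1)
    parallel::mclapply(blocks, worker, mc.cores = workers)
  else lapply(blocks, worker)
  err <- vapply(parts, inherits, logical(1), "try-error")
  if (any(err)) stop("association worker failed: ", parts[[which(err)[1]]])
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  message(sprintf("variants=%d tested=%d dropped=%d spa_applied=%d",
                  m, sum(out$testable), sum(!out$testable),
                  sum(out$spa_applied)))
  out
}

#' Batched Step 2 over a trait manifest
#'
#' For every manifest row, loads the serialized null model and variance
#' ratio, checks the sample set against the genotype source, runs
#' [run_assoc()] and writes the results TSV to the row's output path.
#'
#' @param manifest a `trait_manifest` from [read_manifest()].
#' @param geno shared genotype source for all traits.
#' @param chunks,workers,spa_trigger,firth passed to [run_assoc()].
#' @return invisible character vector of output paths, in manifest order.
#' @export
run_step2_batch <- function(manifest, geno, chunks = 1, workers = 1,
                            spa_trigger = 2, firth = FALSE) {
  stopifnot(inherits(manifest, "trait_manifest"))
  src <- as_dosage_source(geno)
  outs <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    trait <- manifest$trait_id[i]
    fit <- read_null_model(manifest$null_model[i])
    fit$variance_ratio <- read_variance_ratio(manifest$variance_ratio[i])
    if (!identical(as.character(src$sample_ids),
                   as.character(fit$sample_ids)))
      stop("trait '", trait,
           "': null-model samples do not match the genotype source")
    res <- run_assoc(fit, src, chunks = chunks, workers = workers,
                     spa_trigger = spa_trigger, firth = firth)
    write_results(res, manifest$output[i])
    message(sprintf("trait=%s output=%s", trait, manifest$output[i]))
    outs[i] <- manifest$output[i]
  }
  invisible(outs)
}
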