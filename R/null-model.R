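#' Control parameters for the null GLMM fit
#'
#' @param tol outer-loop relative-change tolerance on the fixed effects and
#'   variance components.
#' @param max_outer maximum outer (PQL / AI-REML) iterations.
#' @param pcg_tol,pcg_maxit tolerances of the inner [pcg_solve()] calls.
#' @param exact_trace_n sample-size cutoff below which \eqn{tr(P\psi)} is
#'   computed exactly from the dense GRM; above it a seeded Hutchinson
#'   Rademacher-probe estimator is used.
#' @param n_probes number of Hutchinson probe vectors.
#' @param tau_init starting value for the variance component.
#' @param fix_tau `NULL` to estimate tau, or a nonnegative value to hold it
#'   fixed (0 reduces the model to an ordinary GLM fitted by the same solver).
#' @param weight_floor lower bound on binary working weights, guarding
#'   against quasi-separation driving \eqn{\mu \to 0/1}.
#' @param seed seed for the Hutchinson probes.
#' @param verbose print one `key=value` line per outer iteration.
#' @return list of class `glmm_control`.
#' @export
glmm_control <- function(tol = 1e-4, max_outer = 30, pcg_tol = 1e-5,
                         pcg_maxit = 5000, exact_trace_n = 2000,
                         n_probes = 30, tau_init = 0.1, fix_tau = NULL,
                         weight_floor = 1e-10, seed = 1, verbose = FALSE) {
  structure(list(tol = tol, max_outer = max_outer, pcg_tol = pcg_tol,
                 pcg_maxit = pcg_maxit, exact_trace_n = exact_trace_n,
                 n_probes = n_probes, tau_init = tau_init, fix_tau = fix_tau,
                 weight_floor = weight_floor, seed = seed, verbose = verbose),
            class = "glmm_control")
}

# Per-fit workspace for trace computations. Holds the dense GRM (exact path)
# or the Rademacher probe matrix (Hutchinson path), built once per fit.
make_trace_env <- function(gstd, control, gaussian) {
  env <- new.env(parent = emptyenv())
  env$exact <- !is.null(gstd) && gstd$N <= control$exact_trace_n
  if (is.null(gstd)) return(env)
  if (env$exact) {
    env$psi <- tcrossprod(gstd$A) / gstd$M
    if (gaussian)   # Sigma = phi I + tau psi shares psi's eigenbasis
      env$lambda <- eigen(env$psi, symmetric = TRUE, only.values = TRUE)$values
  } else {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(control$seed)
    env$Z <- matrix(sample(c(-1, 1), gstd$N * control$n_probes,
                           replace = TRUE), gstd$N, control$n_probes)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  env
}

# tr(Sigma^{-1}) and tr(Sigma^{-1} psi) for Sigma = diag(1/W) + tau psi.
# Exact from the dense GRM when available, else Hutchinson probes (each probe
# costs one PCG solve). Returns c(tr_I, tr_psi); tr_I only needed for
# gaussian fits.
trace_sigma_inv <- function(W, tau, gstd, env, control) {
  n <- length(W)
  if (env$exact) {
    if (!is.null(env$lambda) && length(unique(W)) == 1L) {
      phi <- 1 / W[1]
      d <- phi + tau * env$lambda
      return(c(tr_I = sum(1 / d), tr_psi = sum(env$lambda / d)))
    }
    Sigma <- tau * env$psi
    diag(Sigma) <- diag(Sigma) + 1 / W
    Sinv <- chol2inv(chol(Sigma))
    return(c(tr_I = sum(diag(Sinv)), tr_psi = sum(Sinv * env$psi)))
  }
  tr_I <- 0; tr_psi <- 0
  for (j in seq_len(ncol(env$Z))) {
    z <- env$Z[, j]
    sz <- pcg_solve(W, tau, gstd, z, tol = control$pcg_tol,
                    maxit = control$pcg_maxit)$x
    tr_I <- tr_I + sum(sz * z)
    tr_psi <- tr_psi + sum(sz * grm_matvec(gstd, z))
  }
  c(tr_I = tr_I / ncol(env$Z), tr_psi = tr_psi / ncol(env$Z))
}

# Apply the REML projection P = Sigma^{-1} - Sigma^{-1} X B^{-1} X' Sigma^{-1}
# to a vector, given precomputed Sigma^{-1} X and B = X' Sigma^{-1} X.
apply_projection <- function(SigmaInv_v, X, SigmaInvX, B) {
  SigmaInv_v - SigmaInvX %*% solve(B, crossprod(X, SigmaInv_v))
}

#' One average-information REML update of the variance component(s)
#'
#' Computes the REML score \eqn{\frac12(\tilde y^T P V_k P \tilde y -
#' tr(P V_k))} and average information \eqn{\frac12 \tilde y^T P V_k P V_l P
#' \tilde y} for each variance component, and takes one Newton step. For
#' binary traits the single component is the GRM (\eqn{V = \psi}); for
#' gaussian traits the dispersion and the GRM component
#' (\eqn{V_1 = I, V_2 = \psi}) are updated jointly. Traces use the dense GRM
#' exactly below `exact_trace_n` samples and seeded Hutchinson probes above.
#' If the AI matrix is not positive definite the tau update falls back to
#' bounded bisection on the sign of the score.
#'
#' @param y_work working response vector (the PQL working response for binary
#'   traits; the phenotype itself for gaussian).
#' @param X fixed-effect design matrix (with intercept).
#' @param W diagonal weights defining \eqn{\Sigma = W^{-1} + \tau\psi}.
#' @param tau current variance component.
#' @param gstd `std_genotypes` backing the GRM.
#' @param phi current gaussian dispersion, or `NULL` for binary traits.
#' @param control a [glmm_control()].
#' @param env internal trace workspace (rebuilt if missing).
#' @param precomp optional list with `SigmaInvX` and `SigmaInvy`, the current
#'   \eqn{\Sigma^{-1}X} and \eqn{\Sigma^{-1}\tilde y} solves, so a caller
#'   that has just performed them (the PQL loop) need not repeat them.
#' @return list with updated `tau` (and `phi`), the `score` vector and `AI`
#'   matrix, and `Py` (the projected working response, reusable by callers).
#' @export
ai_reml_step <- function(y_work, X, W, tau, gstd, phi = NULL,
                         control = glmm_control(), env = NULL,
                         precomp = NULL) {
  if (is.null(env)) env <- make_trace_env(gstd, control, !is.null(phi))
  n <- length(y_work)
  gaussian <- !is.null(phi)

  solve1 <- function(b, x0 = NULL)
    pcg_solve(W, tau, gstd, b, tol = control$pcg_tol,
              maxit = control$pcg_maxit, x0 = x0)$x
  SigmaInvX <- if (!is.null(precomp)) precomp$SigmaInvX
               else apply(X, 2, solve1)
  B <- crossprod(X, SigmaInvX)
  SigmaInvy <- if (!is.null(precomp)) precomp$SigmaInvy else solve1(y_work)
  Py <- apply_projection(SigmaInvy, X, SigmaInvX, B)

  tr <- trace_sigma_inv(W, tau, gstd, env, control)
  # correction term tr(B^{-1} X' Sigma^{-1} V Sigma^{-1} X) per component
  corr_psi <- sum(diag(solve(B, crossprod(SigmaInvX,
                                          apply(SigmaInvX, 2, function(col)
                                            grm_matvec(gstd, col))))))
  trP_psi <- unname(tr["tr_psi"]) - corr_psi
  u_psi <- grm_matvec(gstd, Py)
  Pu_psi <- apply_projection(solve1(u_psi), X, SigmaInvX, B)
  score_psi <- 0.5 * (sum(Py * u_psi) - trP_psi)
  ai_pp <- 0.5 * sum(u_psi * Pu_psi)

  if (!gaussian) {
    new_tau <- tau + score_psi / ai_pp
    if (!is.finite(new_tau) || ai_pp <= 0)
      new_tau <- bisect_tau(y_work, X, W, tau, gstd, control, env)
    new_tau <- max(0, min(new_tau, 5 * (tau + 1)))  # safeguard huge steps
    return(list(tau = new_tau, phi = NULL,
                score = c(psi = score_psi), AI = matrix(ai_pp, 1, 1),
                Py = drop(Py), SigmaInvX = SigmaInvX, B = B))
  }

  corr_I <- sum(diag(solve(B, crossprod(SigmaInvX, SigmaInvX))))
  trP_I <- unname(tr["tr_I"]) - corr_I
  PPy <- apply_projection(solve1(Py), X, SigmaInvX, B)   # V = I component
  score_I <- 0.5 * (sum(Py * Py) - trP_I)
  AI <- 0.5 * matrix(c(sum(Py * PPy), sum(Py * Pu_psi),
                       sum(u_psi * PPy), sum(u_psi * Pu_psi)), 2, 2)
  theta <- c(phi, tau)
  step <- tryCatch(drop(solve(AI, c(score_I, score_psi))),
                   error = function(e) c(NA_real_, NA_real_))
  if (any(!is.finite(step)))
    step <- c(score_I, score_psi) / pmax(diag(AI), 1e-8)
  # keep the dispersion positive by step-halving toward the current iterate
  h <- 1
  while ((theta + h * step)[1] <= 0 && h > 1e-3) h <- h / 2
  new <- theta + h * step
  if (new[1] <= 0) new[1] <- theta[1] / 2
  new[2] <- max(0, min(new[2], 5 * (tau + 1)))
  list(tau = new[2], phi = new[1],
       score = c(I = score_I, psi = score_psi), AI = AI,
       Py = drop(Py), SigmaInvX = SigmaInvX, B = B)
}

# Bounded bisection on the sign of the REML score in tau; fallback when the
# average information is nonpositive.
bisect_tau <- function(y_work, X, W, tau, gstd, control, env) {
  score_at <- function(t) {
    solve1 <- function(b) pcg_solve(W, t, gstd, b, tol = control$pcg_tol,
                                    maxit = control$pcg_maxit)$x
    SigmaInvX <- apply(X, 2, solve1)
    B <- crossprod(X, SigmaInvX)
    Py <- apply_projection(solve1(y_work), X, SigmaInvX, B)
    tr <- trace_sigma_inv(W, t, gstd, env, control)
    corr <- sum(diag(solve(B, crossprod(SigmaInvX,
                                        apply(SigmaInvX, 2, function(col)
                                          grm_matvec(gstd, col))))))
    0.5 * (sum(Py * grm_matvec(gstd, Py)) - (tr["tr_psi"] - corr))
  }
  lo <- 0; hi <- max(1, 5 * tau)
  s_lo <- score_at(lo)
  if (s_lo <= 0) return(0)
  s_hi <- score_at(hi)
  tries <- 0
  while (s_hi > 0 && tries < 6) { hi <- hi * 2; s_hi <- score_at(hi); tries <- tries + 1 }
  if (s_hi > 0) return(hi)
  for (i in 1:25) {
    mid <- (lo + hi) / 2
    if (score_at(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Fit the null generalized linear mixed model
#'
#' Fits \eqn{g(\mu) = X\alpha + b}, \eqn{b \sim N(0, \tau\psi)}, with the
#' per-variant genetic effect fixed at zero — the Step-1 null fit of
#' mixed-model association testing. Binary traits use the logistic link and
#' penalized quasi-likelihood: each outer iteration builds the working
#' response \eqn{z = \eta + (Y-\mu)/W}, solves the mixed-model system by
#' matrix-free PCG to update \eqn{(\alpha, \hat b, \mu)}, then takes one
#' AI-REML Newton step on \eqn{\tau}. Gaussian traits use the identity link
#' with the dispersion and \eqn{\tau} updated jointly. The GRM is never
#' materialized for solves; it enters only through [grm_matvec()].
#'
#' @param pheno a [phenotype_table()].
#' @param geno a [genotype_matrix] or `std_genotypes` holding the Step-1
#'   (typically LD-pruned, hard-called) markers; may be `NULL` when
#'   `control$fix_tau == 0`.
#' @param control a [glmm_control()].
#' @return `null_model_fit`: list with `alpha`, `tau`, `phi` (gaussian
#'   dispersion, 1 for binary), `mu`, `W`, `residuals` (= Y - mu), `bhat`,
#'   `variance_ratio` (1 until calibrated), `X`, `Y`, `sample_ids`,
#'   `trait_type`, `converged`, `n_iterations`, `history` (per-iteration tau
#'   and PCG iteration counts), and `gstd` (the standardized markers, kept
#'   for calibration; not serialized).
#' @export
fit_null_glmm <- function(pheno, geno = NULL, control = glmm_control()) {
  stopifnot(inherits(pheno, "phenotype_table"))
  # inner solves must be an order tighter than the outer tolerance, or the
  # outer iteration stalls at the solver noise floor
  control$pcg_tol <- min(control$pcg_tol, control$tol / 10)
  Y <- pheno$Y; X <- pheno$X; n <- length(Y)
  binary <- pheno$trait_type == "binary"
  if (binary && (all(Y == 0) || all(Y == 1)))
    stop("binary trait must contain both cases and controls")

  fixed_tau <- control$fix_tau
  gstd <- NULL
  if (!is.null(geno)) {
    gstd <- if (inherits(geno, "std_genotypes")) geno
            else standardize_genotypes(drop_monomorphic(geno))
    if (gstd$N != n) stop("genotype/phenotype sample-count mismatch")
  } else if (is.null(fixed_tau) || fixed_tau > 0) {
    stop("genotypes are required unless tau is fixed at 0")
  }
  tau <- if (!is.null(fixed_tau)) fixed_tau else control$tau_init
  env <- make_trace_env(gstd, control, gaussian = !binary)

  # fixed-effects-only initialization
  if (binary) {
    fit0 <- stats::glm.fit(X, Y, family = stats::binomial())
    alpha <- fit0$coefficients
    phi <- 1
  } else {
    fit0 <- stats::lm.fit(X, Y)
    alpha <- fit0$coefficients
    phi <- sum(fit0$residuals^2) / (n - ncol(X))
  }
  eta <- drop(X %*% alpha); bhat <- numeric(n)
  mu <- if (binary) stats::plogis(eta) else eta
  history <- list()
  converged <- FALSE
  floored <- FALSE

  for (iter in seq_len(control$max_outer)) {
    if (binary) {
      W <- mu * (1 - mu)
      if (any(W < control$weight_floor)) floored <- TRUE
      W <- pmax(W, control$weight_floor)
      zw <- eta + (Y - mu) / W
    } else {
      W <- rep(1 / phi, n)
      zw <- Y
    }

    pcg_iters <- 0L
    solve1 <- function(b, x0 = NULL) {
      s <- pcg_solve(W, tau, gstd, b, tol = control$pcg_tol,
                     maxit = control$pcg_maxit, x0 = x0)
      pcg_iters <<- pcg_iters + s$iterations
      if (!s$converged)
        warning("inner PCG hit maxit (relative residual ",
                signif(s$final_relative_residual, 3), ")")
      s$x
    }
    # warm-start from the previous outer iteration's solves
    SigmaInvX <- vapply(seq_len(ncol(X)), function(j)
      solve1(X[, j], x0 = if (iter > 1) SigmaInvX[, j]), numeric(n))
    SigmaInvz <- solve1(zw, x0 = if (iter > 1) SigmaInvz)
    B <- crossprod(X, SigmaInvX)
    alpha_new <- drop(solve(B, crossprod(X, SigmaInvz)))
    Pz <- drop(apply_projection(SigmaInvz, X, SigmaInvX, B))
    bhat <- if (tau > 0) tau * grm_matvec(gstd, Pz) else numeric(n)
    eta <- drop(X %*% alpha_new) + bhat
    mu <- if (binary) stats::plogis(eta) else eta

    tau_old <- tau; phi_old <- phi
    if (is.null(fixed_tau)) {
      up <- ai_reml_step(zw, X, W, tau, gstd,
                         phi = if (binary) NULL else phi,
                         control = control, env = env,
                         precomp = list(SigmaInvX = SigmaInvX,
                                        SigmaInvy = SigmaInvz))
      tau <- up$tau
      if (!binary) phi <- up$phi
    } else if (!binary) {
      mres <- Y - eta
      phi <- drop(crossprod(mres, pcg_solve(rep(1, n), tau, gstd, mres,
                                            tol = control$pcg_tol,
                                            maxit = control$pcg_maxit)$x)) /
             (n - ncol(X))
    }

    old <- c(alpha, tau_old, if (!binary) phi_old)
    new <- c(alpha_new, tau, if (!binary) phi)
    delta <- max(abs(new - old) / (abs(old) + 1e-4))
    alpha <- alpha_new
    history[[iter]] <- data.frame(iter = iter, tau = tau, phi = phi,
                                  pcg_iterations = pcg_iters, delta = delta)
    if (control$verbose)
      message(sprintf("outer=%d tau=%.6g phi=%.6g pcg_iters=%d delta=%.3g",
                      iter, tau, phi, pcg_iters, delta))
    if (delta < control$tol) { converged <- TRUE; break }
  }
  if (floored)
    warning("binary working weights hit the floor; possible quasi-separation")

  fit <- structure(list(
    alpha = stats::setNames(alpha, colnames(X)), tau = tau,
    phi = if (binary) 1 else phi, mu = mu, W = W,
    residuals = Y - mu, bhat = bhat, variance_ratio = 1,
    X = X, Y = Y, sample_ids = pheno$sample_ids,
    trait_type = pheno$trait_type, converged = converged,
    n_iterations = iter, history = do.call(rbind, history), gstd = gstd),
    class = "null_model_fit")
  if (!converged) {
    cond <- structure(class = c("mmgwas_nonconvergence", "error", "condition"),
                      list(message = paste0("null GLMM did not converge in ",
                                            control$max_outer,
                                            " outer iterations"),
                           call = sys.call(), fit = fit))
    stop(cond)
  }
  fit
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf("null_model_fit (%s): N=%d, tau=%.4g, phi=%.4g, r=%.4g, %s in %d iterations\n",
              x$trait_type, length(x$Y), x$tau, x$phi, x$variance_ratio,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  print(x$alpha)
  invisible(x)
}

#' Estimate the variance-ratio calibration factor
#'
#' For a random subset of markers, compares the exact score-test variance
#' under the full model, \eqn{\tilde G^T P \tilde G} with
#' \eqn{P = \Sigma^{-1} - \Sigma^{-1}X(X^T\Sigma^{-1}X)^{-1}X^T\Sigma^{-1}}
#' applied matrix-free, against the cheap no-GRM variance
#' \eqn{\tilde G^T W \tilde G} (\eqn{\tilde G} is the marker residualized
#' against the covariates under weights `W`). The mean ratio calibrates every
#' Step-2 test without a per-variant PCG solve. When \eqn{\tau = 0} the two
#' variances coincide and the ratio is 1.
#'
#' @param fit a converged `null_model_fit` (must retain its `gstd` markers).
#' @param n_markers number of markers to average over (default 30).
#' @param mac_min minimum minor-allele count for an eligible marker.
#' @param seed seed for the marker draw.
#' @param control a [glmm_control()] supplying the inner PCG tolerances.
#' @param geno optional [genotype_matrix] to draw markers from; defaults to
#'   the markers the model was fitted on.
#' @return Positive scalar ratio.
#' @export
estimate_variance_ratio <- function(fit, n_markers = 30, mac_min = 20,
                                    seed = 1, geno = NULL,
                                    control = glmm_control()) {
  stopifnot(inherits(fit, "null_model_fit"), fit$converged)
  gstd <- fit$gstd
  if (is.null(gstd) && is.null(geno))
    stop("no markers available: fit has no genotypes and none supplied")
  if (!is.null(geno)) {
    cnt <- geno$counts
  } else {
    # reconstruct raw-scale dosages from the standardized view
    cnt <- sweep(sweep(gstd$A, 2, sqrt(2 * gstd$p * (1 - gstd$p)), `*`),
                 2, 2 * gstd$p, `+`)
  }
  n <- length(fit$Y)
  p <- colMeans(cnt, na.rm = TRUE) / 2
  mac <- pmin(colSums(cnt, na.rm = TRUE),
              2 * colSums(!is.na(cnt)) - colSums(cnt, na.rm = TRUE))
  eligible <- which(mac >= mac_min & p > 0 & p < 1)
  if (!length(eligible)) stop("no markers with MAC >= ", mac_min)
  if (length(eligible) < n_markers) {
    warning("only ", length(eligible), " markers with MAC >= ", mac_min,
            "; using all")
    pick <- eligible
  } else {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    pick <- sample(eligible, n_markers)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  X <- fit$X; W <- fit$W
  XtWX <- crossprod(X, X * W)
  solve1 <- function(b) pcg_solve(W, fit$tau, gstd, b, tol = control$pcg_tol,
                                  maxit = control$pcg_maxit)$x
  SigmaInvX <- apply(X, 2, solve1)
  B <- crossprod(X, SigmaInvX)
  ratios <- vapply(pick, function(j) {
    g <- cnt[, j]
    g[is.na(g)] <- 2 * p[j]
    gt <- g - drop(X %*% solve(XtWX, crossprod(X, W * g)))
    v_no <- sum(W * gt^2)
    Pg <- apply_projection(solve1(gt), X, SigmaInvX, B)
    v_full <- sum(gt * Pg)
    v_full / v_no
  }, numeric(1))
  mean(ratios)
}
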