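# Independent oracles used across the suite. Each one deliberately takes the
# naive dense / brute-force route so it shares no code with the package paths
# it checks.

# small random genotype fixture with optional missingness
random_geno <- function(n, m, seed, miss_rate = 0) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  counts <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  if (miss_rate > 0)
    counts[matrix(runif(n * m) < miss_rate, n, m)] <- NA
  variants <- data.frame(chrom = "1", pos = seq_len(m),
                         id = paste0("v", seq_len(m)),
                         allele1 = "A", allele2 = "C")
  genotype_matrix(counts, paste0("s", seq_len(n)), variants)
}

std_fixture <- function(n, m, seed, miss_rate = 0) {
  standardize_genotypes(drop_monomorphic(random_geno(n, m, seed, miss_rate)))
}

# dense GRM formed explicitly
dense_grm <- function(gstd) tcrossprod(gstd$A) / gstd$M

# independent Newton-Raphson IRLS for plain logistic regression
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    step <- solve(crossprod(X, X * w), crossprod(X, y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Cochran-Armitage trend chi-square from the 2x3 genotype contingency table
trend_chi2 <- function(g, y) {
  stopifnot(all(g %in% 0:2), all(y %in% 0:1))
  n <- length(y)
  tab <- table(factor(y, levels = 0:1), factor(g, levels = 0:2))
  scores <- 0:2
  r1 <- sum(tab[2, ])                      # cases
  num <- sum(scores * (tab[2, ] - r1 * colSums(tab) / n))
  pbar <- r1 / n
  s2 <- sum(scores^2 * colSums(tab)) / n - (sum(scores * colSums(tab)) / n)^2
  num^2 / (pbar * (1 - pbar) * n * s2)
}

# exact REML for y ~ N(X alpha, phi I + tau psi), dense algebra + optim
reml_oracle_gaussian <- function(y, X, psi) {
  n <- length(y); p <- ncol(X)
  negloglik <- function(par) {
    phi <- exp(par[1]); tau <- exp(par[2])
    V <- phi * diag(n) + tau * psi
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi <- chol2inv(ch)
    B <- crossprod(X, Vi %*% X)
    alpha <- solve(B, crossprod(X, Vi %*% y))
    r <- y - X %*% alpha
    0.5 * (2 * sum(log(diag(ch))) + determinant(B)$modulus +
             drop(crossprod(r, Vi %*% r)))
  }
  fit <- optim(c(0, 0), negloglik, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(phi = exp(fit$par[1]), tau = exp(fit$par[2]), value = fit$value)
}

# Exact distribution of S = sum_i c_i Y_i, Y_i ~ Bernoulli(mu_i), by
# dynamic-programming convolution on a fine grid. Each contribution c_i is
# split linearly between its two neighboring grid points, which preserves the
# mean exactly and smears each atom by at most one grid step.
dp_score_dist <- function(c, mu, grid = 1e-4) {
  pos <- sum(pmax(c, 0)); neg <- sum(pmin(c, 0))
  n_neg <- ceiling(-neg / grid) + length(c) + 1
  n_pos <- ceiling(pos / grid) + length(c) + 1
  nb <- n_neg + n_pos + 1
  p <- numeric(nb)
  p[n_neg + 1] <- 1
  for (i in seq_along(c)) {
    x <- c[i] / grid
    k <- floor(x); f <- x - k
    shifted <- numeric(nb)
    if (k >= 0) {
      if (k < nb) shifted[(k + 1):nb] <- (1 - f) * p[1:(nb - k)]
      if (k + 1 < nb) shifted[(k + 2):nb] <- shifted[(k + 2):nb] +
          f * p[1:(nb - k - 1)]
    } else {
      shifted[1:(nb + k)] <- (1 - f) * p[(1 - k):nb]
      shifted[1:(nb + k + 1)] <- shifted[1:(nb + k + 1)] +
        f * p[(-k):nb]
    }
    p <- (1 - mu[i]) * p + mu[i] * shifted
  }
  list(s = ((seq_len(nb)) - n_neg - 1) * grid, p = p)
}

dp_two_sided <- function(dist, center, delta) {
  min(1, sum(dist$p[dist$s >= center + delta - 1e-9]) +
        sum(dist$p[dist$s <= center - delta + 1e-9]))
}

# brute-force Firth: directly optimize the Jeffreys-penalized log-likelihood
firth_brute <- function(g, X, y) {
  Z <- cbind(X, g)
  negpen <- function(b) {
    eta <- drop(Z %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    -(sum(y * eta - log(1 + exp(eta))) +
        0.5 * determinant(crossprod(Z, Z * w))$modulus)
  }
  fit <- optim(numeric(ncol(Z)), negpen, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$par[ncol(Z)]
}
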