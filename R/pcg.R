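#' Matrix-free preconditioned conjugate gradient for the mixed-model system
#'
#' Solves \eqn{\Sigma x = b} with \eqn{\Sigma = W^{-1} + \tau \psi}, applying
#' \eqn{\Sigma} only through elementwise division by `W` and the implicit
#' GRM product [grm_matvec()]. The preconditioner is Jacobi:
#' \eqn{\mathrm{diag}(\Sigma)_i = 1/W_i + \tau \psi_{ii}}. Empirically the
#' iteration count grows like \eqn{O(\sqrt N)} on genotype-derived systems,
#' which is what makes the matrix-free formulation practical at biobank scale.
#'
#' @param W strictly positive diagonal weights (length N, or scalar recycled).
#' @param tau nonnegative variance component multiplying the GRM.
#' @param gstd `std_genotypes` backing the implicit GRM; may be `NULL` when
#'   `tau == 0`.
#' @param b right-hand side vector.
#' @param tol relative-residual tolerance on \eqn{\|\Sigma x - b\| / \|b\|}.
#' @param maxit iteration cap; exceeding it returns `converged = FALSE`
#'   rather than an error so the caller decides.
#' @param precondition use the Jacobi preconditioner (TRUE) or plain CG.
#' @param x0 optional warm start.
#' @return list with `x` (solution), `iterations`, `final_relative_residual`,
#'   `converged`.
#' @export
pcg_solve <- function(W, tau, gstd, b, tol = 1e-5, maxit = 5000,
                      precondition = TRUE, x0 = NULL) {
  n <- length(b)
  W <- rep_len(as.numeric(W), n)
  if (any(W <= 0)) stop("weights must be strictly positive")
  if (tau < 0) stop("tau must be nonnegative")
  if (tau > 0 && is.null(gstd)) stop("gstd required when tau > 0")
  if (tau > 0 && gstd$N != n) stop("dimension mismatch: gstd has N = ",
                                   gstd$N, ", b has length ", n)

  apply_sigma <- function(x) {
    if (tau > 0) x / W + tau * grm_matvec(gstd, x) else x / W
  }
  d <- 1 / W + if (tau > 0) tau * grm_diag(gstd) else 0
  minv <- if (precondition) 1 / d else rep(1, n)

  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0)
    return(list(x = numeric(n), iterations = 0L,
                final_relative_residual = 0, converged = TRUE))

  x <- if (is.null(x0)) numeric(n) else x0
  r <- b - if (is.null(x0)) 0 else apply_sigma(x)
  z <- minv * r
  p <- z
  rz <- sum(r * z)
  it <- 0L
  repeat {
    if (sqrt(sum(r^2)) / bnorm <= tol || it >= maxit) break
    Ap <- apply_sigma(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    it <- it + 1L
  }
  final <- sqrt(sum((apply_sigma(x) - b)^2)) / bnorm
  list(x = x, iterations = it, final_relative_residual = final,
       converged = final <= tol)
}
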