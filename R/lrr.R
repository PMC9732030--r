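#' Singular value thresholding
#'
#' Closed-form proximal operator of the nuclear norm: the minimizer of
#' `tau * ||J||_* + 1/2 ||J - M||_F^2`, obtained by soft-thresholding
#' the singular values of `M` by `tau` (flooring at zero).
#'
#' @param M numeric matrix.
#' @param tau non-negative threshold.
#' @return matrix of the same shape.
#' @export
svt <- function(M, tau) {
  stopifnot(tau >= 0)
  if (length(M) == 0) return(M)
  s <- svd(M)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  s$u[, keep, drop = FALSE] %*%
    (d[keep] * t(s$v[, keep, drop = FALSE]))
}

#' Column-wise L2,1 shrinkage
#'
#' Closed-form proximal operator of the L2,1 norm (sum of column
#' Euclidean norms): column `j` of the minimizer of
#' `tau * ||E||_{2,1} + 1/2 ||E - M||_F^2` is
#' `max(0, 1 - tau / ||M_j||_2) * M_j`; columns with norm at most `tau`
#' shrink to zero.
#'
#' @param M numeric matrix.
#' @param tau non-negative threshold.
#' @return matrix of the same shape.
#' @export
l21_shrink <- function(M, tau) {
  stopifnot(tau >= 0)
  if (length(M) == 0) return(M)
  nrm <- sqrt(colSums(M^2))
  scale <- ifelse(nrm > tau, 1 - tau / nrm, 0)
  scale[nrm == 0] <- 0
  sweep(M, 2, scale, `*`)
}

#' Configuration of the inexact augmented Lagrange multiplier solver
#'
#' @param alpha balance between the nuclear norm on the coefficient
#'   matrix and the L2,1 norm on the noise matrix (default 0.1).
#' @param mu0 initial penalty parameter (default 1e-4).
#' @param mu_max penalty cap (default 1e10).
#' @param rho penalty growth factor per iteration, > 1 (default 1.1).
#' @param tol stopping tolerance on both infinity-norm residuals
#'   (default 1e-7).
#' @param max_iter iteration cap (default 500).
#' @return list of class `smma_ialm_config`.
#' @export
ialm_config <- function(alpha = 0.1, mu0 = 1e-4, mu_max = 1e10,
                        rho = 1.1, tol = 1e-7, max_iter = 500L) {
  stopifnot(alpha > 0, mu0 > 0, mu0 < mu_max, rho > 1, tol > 0, max_iter >= 1)
  structure(list(alpha = alpha, mu0 = mu0, mu_max = mu_max, rho = rho,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "smma_ialm_config")
}

#' Low-rank representation by inexact augmented Lagrange multipliers
#'
#' Solves `min ||X||_* + alpha ||E||_{2,1}  s.t.  A = A X + E` by
#' alternating proximal updates with a growing penalty `mu` and two
#' Lagrange multiplier matrices.  Per iteration:
#' the auxiliary nuclear-norm variable `J` is updated by [svt()] with
#' threshold `1/mu` on `X + Y2/mu`; `X` solves the penalized least
#' squares `(I + A'A)^{-1} (A'A - A'E + J + (A'Y1 - Y2)/mu)` through a
#' Cholesky factorization of `I + A'A` cached across iterations; `E` is
#' updated by [l21_shrink()] with threshold `alpha/mu` on
#' `A - A X + Y1/mu`; the multipliers absorb the scaled residuals and
#' `mu` grows by `rho` up to `mu_max`.  Iteration stops when both
#' infinity-norm residuals `||A - AX - E||` and `||X - J||` drop below
#' `tol`.
#'
#' @param A numeric matrix (not empty).
#' @param cfg an [ialm_config()].
#' @return list of class `smma_lrr` with elements `X` (coefficient
#'   matrix, `ncol(A)` square), `E` (noise), `n_iter`, `converged`, and
#'   `residuals` (a two-column matrix of per-iteration infinity-norm
#'   residuals).  Non-convergence within `max_iter` iterations returns
#'   the last iterate with `converged = FALSE` and a warning.
#' @export
ialm_solve <- function(A, cfg = ialm_config()) {
  stopifnot(inherits(cfg, "smma_ialm_config"), length(A) > 0)
  A <- as.matrix(A)
  n <- ncol(A)
  X <- J <- Y2 <- matrix(0, n, n)
  E <- Y1 <- matrix(0, nrow(A), n)
  mu <- cfg$mu0
  AtA <- crossprod(A)
  R <- chol(diag(n) + AtA)   # cached; I + A'A is SPD
  res <- matrix(NA_real_, cfg$max_iter, 2,
                dimnames = list(NULL, c("feasibility", "coupling")))
  converged <- FALSE
  it <- 0L
  while (it < cfg$max_iter) {
    it <- it + 1L
    J <- svt(X + Y2 / mu, 1 / mu)
    rhs <- AtA - crossprod(A, E) + J + (crossprod(A, Y1) - Y2) / mu
    X <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
    E <- l21_shrink(A - A %*% X + Y1 / mu, cfg$alpha / mu)
    R1 <- A - A %*% X - E
    R2 <- X - J
    Y1 <- Y1 + mu * R1
    Y2 <- Y2 + mu * R2
    mu <- min(cfg$rho * mu, cfg$mu_max)
    res[it, ] <- c(max(abs(R1)), max(abs(R2)))
    if (res[it, 1] < cfg$tol && res[it, 2] < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("IALM did not converge in ", cfg$max_iter, " iterations ",
            "(residuals ", signif(res[it, 1], 3), ", ", signif(res[it, 2], 3), ")")
  structure(list(X = X, E = E, n_iter = it, converged = converged,
                 residuals = res[seq_len(it), , drop = FALSE]),
            class = "smma_lrr")
}

#' Denoise an association matrix by low-rank representation
#'
#' Runs [ialm_solve()] on the binary association matrix and forms the
#' denoised real-valued association matrix `A* = A X*`.  With
#' `side = "mirna"` (default) the coefficient matrix is
#' miRNA-by-miRNA (the decomposition is run on `A` as stored, SMs on
#' rows); with `side = "sm"` it is SM-by-SM (run on the transpose) and
#' `A* = t(X*) A`.
#'
#' @param data an [association_data()] object.
#' @param cfg an [ialm_config()].
#' @param side `"mirna"` or `"sm"`.
#' @return list of class `smma_denoised`: `A_star` (real-valued, same
#'   shape and dimnames as `data$A`), `X`, `E`, `n_iter`, `converged`,
#'   `residuals`, `side`, plus the identifier lists.
#' @export
denoise_associations <- function(data, cfg = ialm_config(),
                                 side = c("mirna", "sm")) {
  stopifnot(inherits(data, "smma_association"))
  side <- match.arg(side)
  fit <- if (side == "mirna") ialm_solve(data$A, cfg)
         else ialm_solve(t(data$A), cfg)
  A_star <- if (side == "mirna") data$A %*% fit$X else t(fit$X) %*% data$A
  dimnames(A_star) <- dimnames(data$A)
  structure(c(list(A_star = A_star, side = side,
                   sm_ids = data$sm_ids, mirna_ids = data$mirna_ids),
              unclass(fit)),
            class = "smma_denoised")
}
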