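# Pure-R adaptive Gauss-Hermite quadrature backend. Written independently
# of the compiled Laplace kernel so it can serve as a brute-force oracle:
# it builds the marginal covariance itself, locates the mode with nlminb,
# takes a finite-difference Hessian, and integrates the log-baseline
# deviations on an adaptive product grid. Feasible for units with at most
# a handful of lesions; the default Laplace backend has no such limit.

# Nodes/weights for weight function exp(-x^2) via the Golub-Welsch
# eigendecomposition of the Hermite Jacobi matrix.
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# marginal covariance of one unit given the slope-effect SDs (R-side build)
r_unit_cov <- function(x1u, x2u, block_start, block_end, sds) {
  n <- length(x1u)
  V <- diag(sds$sd_e^2, n)
  if (sds$sd_pd > 0) V <- V + sds$sd_pd^2 * tcrossprod(x1u)
  if (sds$sd_pg > 0) V <- V + sds$sd_pg^2 * tcrossprod(x2u)
  for (j in seq_along(block_start)) {
    idx <- block_start[j]:block_end[j]
    if (sds$sd_ld > 0)
      V[idx, idx] <- V[idx, idx] + sds$sd_ld^2 * tcrossprod(x1u[idx])
    if (sds$sd_lg > 0)
      V[idx, idx] <- V[idx, idx] + sds$sd_lg^2 * tcrossprod(x2u[idx])
  }
  V
}

ldmvnorm_chol <- function(r, U) {
  # U: upper Cholesky of the covariance
  z <- backsolve(U, r, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(U))) - 0.5 * length(r) * log(2 * pi)
}

fd_hessian <- function(f, x, eps = 1e-4) {
  m <- length(x)
  H <- matrix(NA_real_, m, m)
  hstep <- eps * (1 + abs(x))
  for (i in seq_len(m)) {
    for (j in i:m) {
      ei <- ej <- numeric(m); ei[i] <- hstep[i]; ej[j] <- hstep[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hstep[i] * hstep[j])
    }
  }
  H
}

# Adaptive GH marginal log-likelihood of one unit.
ghq_unit_loglik <- function(yu, x1u, x2u, block_start, block_end,
                            sds, n_points) {
  m <- length(block_start)
  if (m > 4L)
    stop("quadrature backend limited to units with <= 4 lesions (", m,
         " requested); use the Laplace backend")
  A <- matrix(0, length(yu), m)
  for (j in seq_len(m)) A[block_start[j]:block_end[j], j] <- 1
  V <- r_unit_cov(x1u, x2u, block_start, block_end, sds)
  U <- chol(V)
  y_adj <- yu - sds$d_pop * x1u - sds$g_pop * x2u

  f <- function(b) {
    ldmvnorm_chol(y_adj - A %*% exp(sds$beta0 + b), U) +
      sum(dnorm(b, 0, sds$sd_b, log = TRUE))
  }
  if (sds$sd_b <= 0)
    return(ldmvnorm_chol(y_adj - A %*% rep(exp(sds$beta0), m), U))

  opt <- stats::nlminb(rep(0, m), function(b) -f(b),
                       control = list(abs.tol = 1e-14, rel.tol = 1e-12))
  mode <- opt$par
  H <- fd_hessian(function(b) -f(b), mode)
  Sig <- solve((H + t(H)) / 2)
  Ls <- t(chol((Sig + t(Sig)) / 2))

  gh <- gauss_hermite(n_points)
  grid <- as.matrix(do.call(expand.grid,
                            rep(list(seq_len(n_points)), m)))
  terms <- apply(grid, 1L, function(qq) {
    z <- gh$nodes[qq]
    b <- mode + sqrt(2) * drop(Ls %*% z)
    f(b) + sum(z^2) + sum(log(gh$weights[qq]))
  })
  (m / 2) * log(2) + sum(log(diag(Ls))) + logsumexp(terms)
}

ghq_loglik <- function(pd, sds, n_points) {
  lp <- pd$lesion_ptr; up <- pd$unit_les_ptr
  total <- 0
  unit_ll <- numeric(pd$n_units)
  for (i in seq_len(pd$n_units)) {
    l0 <- up[i] + 1L; l1 <- up[i + 1L]
    o0 <- lp[l0] + 1L; o1 <- lp[l1 + 1L]
    bs <- lp[l0:l1] + 1L - (o0 - 1L)
    be <- lp[(l0:l1) + 1L] - (o0 - 1L)
    unit_ll[i] <- ghq_unit_loglik(pd$y[o0:o1], pd$x1[o0:o1], pd$x2[o0:o1],
                                  bs, be, sds, n_points)
  }
  list(loglik = sum(unit_ll), unit_loglik = unit_ll)
}
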