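#' Symmetric FastICA with tanh contrast
#'
#' Deterministic (seeded) fixed-point independent component analysis used by
#' the ocular-artifact removal step. Data are centered and whitened by PCA,
#' then unmixed by the symmetric FastICA iteration with the tanh
#' nonlinearity and symmetric decorrelation.
#'
#' @param x channels x samples matrix.
#' @param n_comp number of components (default: number of channels).
#' @param tol convergence tolerance on the unmixing update.
#' @param max_iter maximum iterations.
#' @param seed RNG seed for the orthonormal initialization (local; caller's
#'   RNG state is restored).
#' @return list with `S` (components x samples), `A` (mixing matrix,
#'   channels x components, in original units), `W` (unmixing so that
#'   `S = W %*% (x - center)`), `center` (channel means).
#' @export
fast_ica <- function(x, n_comp = nrow(x), tol = 1e-6, max_iter = 200L,
                     seed = 1L) {
  n <- nrow(x); m <- ncol(x)
  if (m < n) stopf("more channels than samples")
  center <- rowMeans(x)
  xc <- x - center
  cv <- tcrossprod(xc) / (m - 1)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[n] < max(eg$values) * 1e-10 || eg$values[n] <= 0)
    stopf("decomposition failure: data are rank deficient; check for flat or duplicated channels")
  K <- diag(1 / sqrt(eg$values[seq_len(n_comp)])) %*%
       t(eg$vectors[, seq_len(n_comp), drop = FALSE])
  z <- K %*% xc                                 # whitened, identity covariance

  sym_decorrelate <- function(W) {
    sw <- W %*% t(W)
    es <- eigen(sw, symmetric = TRUE)
    es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors) %*% W
  }
  W <- with_seed(seed,
                 matrix(stats::rnorm(n_comp * n_comp), n_comp, n_comp))
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W1 <- g %*% t(z) / m - diag(rowMeans(gp)) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% z
  W_full <- W %*% K
  A <- MASS_ginv(W_full)
  list(S = S, A = A, W = W_full, center = center)
}

## Moore-Penrose pseudoinverse via SVD (avoids a MASS dependency)
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
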