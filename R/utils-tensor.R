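# Three-way array primitives shared by the Tucker3 and NPLS engines.
# Unfolding convention: mode-n unfolding has the remaining modes as columns
# with the *earlier* original mode varying fastest, so the mode-1 unfolding
# of an I x J x K array is I x (J*K) with column index j + (k-1)*J. Under
# this convention X_(1) = A G_(1) (C \otimes B)' for a Tucker model
# (A, B, C) with core G.

unfoldTensor <- function(X, mode) {
  d <- dim(X)
  stopifnot(length(d) == 3L, mode %in% 1:3)
  perm <- switch(mode, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  matrix(aperm(X, perm), nrow = d[mode])
}

refoldTensor <- function(M, mode, dims) {
  perm <- switch(mode, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  back <- order(perm)
  aperm(array(M, dim = dims[perm]), back)
}

# tensor-times-matrix along one mode: result has dim[mode] = nrow(M)
ttm <- function(X, M, mode) {
  d <- dim(X)
  out <- M %*% unfoldTensor(X, mode)
  d[mode] <- nrow(M)
  refoldTensor(out, mode, d)
}

# contraction of an I x J x K tensor with a feature vector (J) and a time
# vector (K): returns the length-I score vector sum_jk x_ijk wj_j wk_k
contractModes23 <- function(X, wj, wk) {
  as.vector(unfoldTensor(X, 1L) %*% as.vector(outer(wj, wk)))
}

sumsq <- function(x) sum(x * x)

# Ledoit-Wolf style covariance shrinkage toward the diagonal target with
# the analytic intensity of Schafer & Strimmer (2005). Returns the shrunk
# covariance; lambda = 0 reproduces the sample covariance.
shrinkCovariance <- function(X, lambda = NULL) {
  n <- nrow(X); p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / (n - 1)
  if (is.null(lambda)) {
    # Var-hat of each off-diagonal covariance entry from the per-sample
    # cross products w_tij = x_ti * x_tj
    varS <- matrix(0, p, p)
    wbar <- S * (n - 1) / n
    for (j in seq_len(p)) {
      W <- Xc * Xc[, j]
      varS[, j] <- n / ((n - 1)^3) * colSums((W - matrix(wbar[, j], n, p,
                                                        byrow = TRUE))^2)
    }
    off <- upper.tri(S) | lower.tri(S)
    denom <- sum(S[off]^2)
    lambda <- if (denom <= 0) 1 else min(1, max(0, sum(varS[off]) / denom))
  }
  Sig <- (1 - lambda) * S
  diag(Sig) <- diag(S)
  attr(Sig, "lambda") <- lambda
  Sig
}

`%||%` <- function(a, b) if (is.null(a)) b else a
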