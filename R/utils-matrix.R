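#' Clamp a symmetric matrix to the nearest positive semi-definite matrix
#'
#' Eigenvalue truncation: negative eigenvalues are set to zero and the matrix
#' reassembled symmetrically. This is the PSD repair used throughout for
#' estimated covariance matrices, which can be indefinite in finite samples.
#'
#' @param S symmetric numeric matrix.
#' @param tol symmetry tolerance (maximum absolute asymmetry allowed).
#' @return a symmetric PSD matrix of the same dimension, with dimnames kept.
#' @export
clamp_psd <- function(S, tol = 1e-10) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("matrix must be square")
  asym <- max(abs(S - t(S)))
  if (asym > max(tol, tol * max(abs(S), 1))) {
    stop(sprintf("matrix is not symmetric (max asymmetry %.3g)", asym))
  }
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= 0)) return(S)
  lam <- pmax(e$values, 0)
  out <- e$vectors %*% (lam * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(S)
  out
}

is_psd <- function(S, tol = 1e-8) {
  min(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values) >= -tol
}

check_symmetric <- function(S, name = "matrix", tol = 1e-8) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop(name, " must be a square matrix")
  if (max(abs(S - t(S))) > tol * max(1, max(abs(S)))) {
    stop(name, " must be symmetric")
  }
  (S + t(S)) / 2
}

#' Draw multivariate normal deviates
#'
#' Zero-mean MVN sampler based on the eigendecomposition of the covariance,
#' tolerant of positive semi-definite (rank-deficient) covariances.
#'
#' @param n number of draws.
#' @param Sigma covariance matrix (PSD).
#' @param mean optional mean vector (default zero).
#' @return an `n x d` matrix of draws.
#' @export
rmvn <- function(n, Sigma, mean = NULL) {
  Sigma <- check_symmetric(as.matrix(Sigma), "Sigma")
  d <- nrow(Sigma)
  e <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (min(e$values) < -1e-6 * max(lam, 1)) stop("Sigma is not positive semi-definite")
  Z <- matrix(stats::rnorm(n * d), n, d)
  X <- Z %*% (t(e$vectors) * sqrt(lam))
  if (!is.null(mean)) X <- sweep(X, 2, mean, "+")
  colnames(X) <- colnames(Sigma)
  X
}

## solve with a pseudo-inverse fallback for rank-deficient systems;
## rank deficiency is reported because downstream index coefficients are then
## only determined on the observed span.
solve_maybe_pinv <- function(A, b, label = "matrix", tol = 1e-10) {
  A <- as.matrix(A)
  sv <- svd(A)
  pos <- sv$d > tol * sv$d[1]
  if (!all(pos)) {
    message(sprintf("%s is rank-deficient (rank %d of %d); using pseudo-inverse",
                    label, sum(pos), ncol(A)))
  }
  di <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (di * (t(sv$u) %*% b))
}

condition_number <- function(A) {
  sv <- svd(as.matrix(A))$d
  sv[1] / sv[length(sv)]
}
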