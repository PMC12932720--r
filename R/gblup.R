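#' Fit multi-trait GBLUP marker effects
#'
#' Per-trait ridge regression of genotype entry means on standardized markers:
#' `beta_t = (X'X + lambda_t I)^-1 X' y_t`. Because the stacked multi-trait
#' design is block diagonal over traits, per-trait solving is exact for the
#' multi-trait GBLUP; cross-trait information enters the indices through the
#' genomic covariance `Gamma` estimated from the resulting GEBV matrix. The
#' dual (kernel) form `beta = X'(XX' + lambda I)^-1 y` is used automatically
#' when markers outnumber genotypes; the two forms are algebraically
#' identical.
#'
#' The default shrinkage ties `lambda` to the entry-mean heritability:
#' `lambda_t = c (1 - h2_t)/h2_t` with `c = 2 sum p(1-p)`, which makes the
#' ridge equivalent to the GRM mixed-model equations with variance ratio
#' `sigma2_e(entry)/sigma2_g`.
#'
#' @param panel a [trait_panel()]; genotype ids must match `rownames` of the
#'   marker codes.
#' @param markers a [standardize_markers()] result for the training set.
#' @param lambda optional per-trait shrinkage (length t or scalar); if
#'   omitted, derived from [estimate_P_G()] heritabilities.
#' @return object of class `marker_effects`: `beta` (m x t), `lambda`,
#'   `intercept` (trait means of entry means), `freqs`, `gebv_train` (n x t
#'   fitted GEBVs, centered scale).
#' @export
fit_gblup <- function(panel, markers, lambda = NULL) {
  stopifnot(inherits(panel, "trait_panel"), inherits(markers, "marker_matrix"))
  ym <- entry_means(panel)
  X <- markers$M
  if (is.null(rownames(X))) {
    if (nrow(X) != nrow(ym)) stop("markers lack rownames and row count differs from genotype count")
    rownames(X) <- rownames(ym)
  }
  miss <- setdiff(rownames(ym), rownames(X))
  if (length(miss)) stop("genotypes missing from marker matrix: ", paste(utils::head(miss, 5), collapse = ", "))
  X <- X[rownames(ym), , drop = FALSE]

  t <- ncol(ym)
  if (is.null(lambda)) {
    covs <- estimate_P_G(panel)
    cc <- 2 * sum(markers$freqs * (1 - markers$freqs))
    lambda <- cc * (1 - covs$h2) / pmax(covs$h2, 1e-6)
  }
  lambda <- rep_len(as.numeric(lambda), t)
  if (any(lambda < 0)) stop("lambda must be non-negative")

  n <- nrow(X); m <- ncol(X)
  mu <- colMeans(ym)
  Yc <- sweep(ym, 2, mu)
  beta <- matrix(0, m, t, dimnames = list(colnames(X), colnames(ym)))
  for (k in seq_len(t)) {
    lam <- lambda[k]
    if (lam == 0 && m > n) {
      stop("singular system: lambda = 0 with more markers than genotypes; supply lambda > 0")
    }
    if (m <= n) {
      A <- crossprod(X) + diag(lam, m)
      beta[, k] <- tryCatch(solve(A, crossprod(X, Yc[, k])),
                            error = function(e) stop("singular ridge system; supply lambda > 0"))
    } else {
      A <- tcrossprod(X) + diag(lam, n)
      beta[, k] <- crossprod(X, solve(A, Yc[, k]))
    }
  }
  gebv <- X %*% beta
  structure(list(beta = beta, lambda = lambda, intercept = mu,
                 freqs = markers$freqs, markers = colnames(X),
                 gebv_train = gebv),
            class = "marker_effects")
}

#' @export
print.marker_effects <- function(x, ...) {
  cat(sprintf("marker_effects: %d markers x %d trait(s), lambda = %s\n",
              nrow(x$beta), ncol(x$beta),
              paste(signif(x$lambda, 3), collapse = ", ")))
  invisible(x)
}

#' Predict GEBVs for a (test) population from fitted marker effects
#'
#' `gebv = M beta` per trait, where `M` must be standardized with the
#' training-set allele frequencies (pass `freqs = effects$freqs` to
#' [standardize_markers()]).
#'
#' @param effects a [fit_gblup()] result.
#' @param markers_test a `marker_matrix` over the same markers, in the same
#'   order, standardized with the training frequencies.
#' @return n x t GEBV matrix (centered scale: deviations from the training
#'   trait means).
#' @export
predict_gebv <- function(effects, markers_test) {
  stopifnot(inherits(effects, "marker_effects"), inherits(markers_test, "marker_matrix"))
  if (ncol(markers_test$M) != nrow(effects$beta)) {
    stop(sprintf("marker count mismatch: model has %d, test set has %d",
                 nrow(effects$beta), ncol(markers_test$M)))
  }
  markers_test$M %*% effects$beta
}
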