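#' Index model container
#'
#' An index model scores candidates as
#' `I(x) = linear'x + x'Q x + offset` where `x` is a row of mean-centered
#' phenotype entry means (phenotypic kinds) or GEBVs (genomic kinds). Linear
#' kinds (LPSI, LGSI) have `Q = 0`.
#'
#' @param kind one of "LPSI", "LGSI", "QPSI", "QGSI".
#' @param linear length-t coefficient vector (`b` for phenotypic indices,
#'   `theta` for genomic).
#' @param quad t x t symmetric matrix (`B` for QPSI, `D` for QGSI); zero for
#'   linear kinds.
#' @param offset scalar constant absorbing the expectation of the quadratic
#'   terms under the centering convention.
#' @return object of class `index_model`.
#' @export
index_model <- function(kind, linear, quad = NULL, offset = 0) {
  kind <- match.arg(kind, c("LPSI", "LGSI", "QPSI", "QGSI"))
  linear <- as.numeric(linear)
  t <- length(linear)
  if (is.null(quad)) quad <- matrix(0, t, t)
  quad <- check_symmetric(as.matrix(quad), "quad", tol = 1e-6)
  if (kind %in% c("LPSI", "LGSI") && any(quad != 0)) {
    stop("linear index kinds must have a zero quadratic matrix")
  }
  if (!all(is.finite(linear)) || !all(is.finite(quad)) || !is.finite(offset)) {
    stop("index coefficients must be finite")
  }
  structure(list(kind = kind, linear = linear, quad = quad, offset = offset),
            class = "index_model")
}

#' @export
print.index_model <- function(x, ...) {
  cat(sprintf("index_model %s: linear = [%s]%s\n", x$kind,
              paste(signif(x$linear, 4), collapse = ", "),
              if (any(x$quad != 0)) sprintf(", quadratic matrix (|Q|max %.3g), offset %.4g",
                                            max(abs(x$quad)), x$offset) else ""))
  invisible(x)
}

is_linear_kind <- function(model) all(model$quad == 0)

#' Smith-Hazel linear phenotypic selection index coefficients
#'
#' `b = P^-1 G w`, the coefficients maximizing the correlation between the
#' phenotypic index `b'y` and the linear net merit `w'g`.
#'
#' @param covs a [covariance_set()] with `P` and `G`.
#' @param weights an [economic_weights()] (only `w` is used).
#' @return an `index_model` of kind "LPSI".
#' @export
lpsi_coefficients <- function(covs, weights) {
  P <- as.matrix(covs$P); G <- as.matrix(covs$G)
  kappa <- condition_number(P)
  if (!is.finite(kappa) || kappa > 1e12) {
    stop(sprintf("P is singular or near-singular (condition number %.3g)", kappa))
  }
  b <- drop(solve(P, G %*% weights$w))
  index_model("LPSI", b)
}

#' Quadratic phenotypic selection index coefficients
#'
#' The conditional-expectation (minimum-MSPE) predictor of the quadratic
#' merit `H_q = w'g + g'Wg` given centered phenotypes `y`, under joint
#' normality with `Cov(g) = G`, `Cov(y) = P`, `Cov(g, y) = G`:
#' `E[H_q | y] = b'y + y'B y + offset` with
#' `b = P^-1 G w`, `B = P^-1 G W G P^-1`, and
#' `offset = tr(W (G - G P^-1 G))` (the conditional-variance trace carried by
#' the quadratic merit). With `W = 0` this reduces exactly to the LPSI.
#'
#' @inheritParams lpsi_coefficients
#' @return an `index_model` of kind "QPSI" (or the LPSI model when `W = 0`).
#' @export
qpsi_coefficients <- function(covs, weights) {
  P <- as.matrix(covs$P); G <- as.matrix(covs$G)
  W <- weights$W
  lin <- lpsi_coefficients(covs, weights)
  if (all(W == 0)) return(lin)
  PiG <- solve(P, G)                       # P^-1 G
  B <- PiG %*% W %*% t(PiG)                # P^-1 G W G P^-1
  off <- sum(diag(W %*% (G - t(PiG) %*% G)))
  index_model("QPSI", lin$linear, quad = B, offset = off)
}

#' Linear genomic selection index
#'
#' The LGSI scores GEBVs directly with the economic weights: `I = w'gebv`.
#'
#' @param weights an [economic_weights()].
#' @return an `index_model` of kind "LGSI".
#' @export
lgsi_model <- function(weights) {
  index_model("LGSI", weights$w)
}

#' Quadratic genomic selection index
#'
#' Under the classical genomic-index assumption
#' `Cov(gebv) = Cov(gebv, g) = Gamma`, the minimum-MSPE quadratic predictor
#' of `H_q` from centered GEBVs takes the economic weights directly:
#' `I_qg = w'gebv + gebv' W gebv` (theta = w, D = W). The offset is zero by
#' convention; centering of the quadratic mean is handled by
#' [index_moments()].
#'
#' @param covs a [covariance_set()] with a PSD `Gamma` (used for validation).
#' @param weights an [economic_weights()].
#' @return an `index_model` of kind "QGSI" (or the LGSI model when `W = 0`).
#' @export
qgsi_model <- function(covs, weights) {
  if (is.null(covs$Gamma)) stop("Gamma is required for the QGSI")
  if (!is_psd(covs$Gamma, tol = 1e-6 * max(1, max(abs(covs$Gamma))))) {
    stop("Gamma must be positive semi-definite")
  }
  if (all(weights$W == 0)) return(lgsi_model(weights))
  index_model("QGSI", weights$w, quad = weights$W)
}

#' Evaluate an index on a score matrix
#'
#' `score_i = linear'x_i + x_i' Q x_i + offset`. By the package's centering
#' convention, columns are mean-centered before evaluation (the closed-form
#' moments assume zero-mean inputs); pass `center = FALSE` for raw scoring.
#'
#' @param model an `index_model`.
#' @param x n x t matrix of phenotype entry means or GEBVs, columns in the
#'   model's trait order.
#' @param center mean-center columns first (default TRUE).
#' @return length-n numeric score vector (named if `x` has rownames).
#' @export
evaluate_index <- function(model, x, center = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$linear)) {
    stop(sprintf("dimension mismatch: model has %d traits, input has %d columns",
                 length(model$linear), ncol(x)))
  }
  if (center) x <- sweep(x, 2, colMeans(x))
  s <- drop(x %*% model$linear) + model$offset
  if (!is_linear_kind(model)) s <- s + rowSums((x %*% model$quad) * x)
  names(s) <- rownames(x)
  s
}

#' Mean and variance of an index score under normality
#'
#' For a zero-mean normal scored variable `x ~ N(0, Sigma)`:
#' `E[I] = tr(Q Sigma) + offset` and
#' `Var[I] = linear' Sigma linear + 2 tr(Q Sigma Q Sigma)`
#' (standard quadratic-form moment identities; the linear and quadratic parts
#' are uncorrelated because odd moments vanish).
#'
#' @param model an `index_model`.
#' @param Sigma t x t PSD covariance of the scored variable (P for phenotypic
#'   kinds, Gamma for genomic kinds).
#' @return named numeric vector `c(mean, variance)`.
#' @export
index_moments <- function(model, Sigma) {
  Sigma <- check_symmetric(as.matrix(Sigma), "Sigma", tol = 1e-8)
  QS <- model$quad %*% Sigma
  m <- sum(diag(QS)) + model$offset
  v <- drop(t(model$linear) %*% Sigma %*% model$linear) + 2 * sum(QS * t(QS))
  c(mean = m, variance = v)
}

#' Quadratic net genetic merit
#'
#' `H_q,i = w'g_i + g_i' W g_i` for each row of true genetic values; the
#' ground truth against which indices are evaluated in simulation.
#'
#' @param g n x t matrix of true genetic values.
#' @param weights an [economic_weights()].
#' @return length-n numeric vector.
#' @export
merit_hq <- function(g, weights) {
  g <- as.matrix(g)
  s <- drop(g %*% weights$w)
  if (any(weights$W != 0)) s <- s + rowSums((g %*% weights$W) * g)
  names(s) <- rownames(g)
  s
}
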