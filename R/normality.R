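#' @name normality
#' @title Normality tests for index-theory assumptions
#'
#' @description
#' The closed-form index moments, responses and gains assume (multivariate)
#' normality of traits, GEBVs and the pair (merit, index). These tests report
#' the evidence against that assumption: univariate Shapiro-Wilk, Mardia's
#' multivariate skewness and kurtosis (two-sided), the Henze-Zirkler
#' statistic (one-sided, log-normal approximation), and a generalized
#' multivariate Shapiro-Wilk on standardized principal scores. Each returns
#' one or more rows of a report data.frame: `dataset`, `test`, `statistic`,
#' `p_value`, `n`, `d`.
NULL

normality_report <- function(dataset, test, statistic, p_value, n, d) {
  data.frame(dataset = dataset, test = test, statistic = statistic,
             p_value = p_value, n = n, d = d, stringsAsFactors = FALSE)
}

center_and_invcov <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n <= d) stop("need more observations than dimensions")
  Z <- sweep(X, 2, colMeans(X))
  S <- crossprod(Z) / n                     # biased covariance (Mardia/HZ convention)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 1e-12 * max(ev$values)) stop("singular sample covariance")
  Sinv <- ev$vectors %*% (t(ev$vectors) / ev$values)
  list(Z = Z, S = S, Sinv = Sinv, n = n, d = d,
       Sinv_half = ev$vectors %*% (t(ev$vectors) / sqrt(ev$values)))
}

#' Mardia's multivariate skewness and kurtosis tests
#'
#' Skewness: `b1 = mean over pairs of (z_i' S^-1 z_j)^3`, with
#' `n b1 / 6 ~ chi^2` on `d(d+1)(d+2)/6` degrees of freedom. Kurtosis:
#' `b2 = mean((z_i' S^-1 z_i)^2)` with asymptotic reference
#' `N(d(d+2), 8 d(d+2)/n)`; the kurtosis p-value is two-sided.
#'
#' @param X n x d numeric matrix, `n > d`, nonsingular sample covariance.
#' @param dataset label for the report.
#' @return two-row report data.frame (`mardia_skewness`, `mardia_kurtosis`).
#' @export
mardia_test <- function(X, dataset = "data") {
  cs <- center_and_invcov(X)
  D <- cs$Z %*% cs$Sinv %*% t(cs$Z)
  b1 <- sum(D^3) / cs$n^2
  b2 <- mean(diag(D)^2)
  d <- cs$d; n <- cs$n
  stat1 <- n * b1 / 6
  df1 <- d * (d + 1) * (d + 2) / 6
  p1 <- stats::pchisq(stat1, df1, lower.tail = FALSE)
  z2 <- (b2 - d * (d + 2)) / sqrt(8 * d * (d + 2) / n)
  p2 <- 2 * stats::pnorm(abs(z2), lower.tail = FALSE)
  rbind(normality_report(dataset, "mardia_skewness", stat1, p1, n, d),
        normality_report(dataset, "mardia_kurtosis", z2, p2, n, d))
}

#' Henze-Zirkler test of multivariate normality
#'
#' The HZ statistic with the standard smoothing parameter
#' `beta = ((n (2d + 1))/4)^(1/(d+4)) / sqrt(2)` and the usual log-normal
#' approximation for the null distribution (one-sided: large values reject).
#'
#' @inheritParams mardia_test
#' @return one-row report data.frame.
#' @export
henze_zirkler_test <- function(X, dataset = "data") {
  cs <- center_and_invcov(X)
  n <- cs$n; d <- cs$d
  b <- ((n * (2 * d + 1)) / 4)^(1 / (d + 4)) / sqrt(2)
  D <- cs$Z %*% cs$Sinv %*% t(cs$Z)
  Di <- diag(D)
  Dij <- outer(Di, Di, "+") - 2 * D        # pairwise Mahalanobis distances
  hz <- n * (sum(exp(-b^2 / 2 * Dij)) / n^2 -
               2 * (1 + b^2)^(-d / 2) * mean(exp(-b^2 / (2 * (1 + b^2)) * Di)) +
               (1 + 2 * b^2)^(-d / 2))
  a <- 1 + 2 * b^2
  wb <- (1 + b^2) * (1 + 3 * b^2)
  mu <- 1 - a^(-d / 2) * (1 + d * b^2 / a + d * (d + 2) * b^4 / (2 * a^2))
  s2 <- 2 * (1 + 4 * b^2)^(-d / 2) +
    2 * a^(-d) * (1 + 2 * d * b^4 / a^2 + 3 * d * (d + 2) * b^8 / (4 * a^4)) -
    4 * wb^(-d / 2) * (1 + 3 * d * b^4 / (2 * wb) + d * (d + 2) * b^8 / (2 * wb^2))
  pmu <- log(sqrt(mu^4 / (s2 + mu^2)))
  psi <- sqrt(log((s2 + mu^2) / mu^2))
  p <- stats::plnorm(hz, pmu, psi, lower.tail = FALSE)
  normality_report(dataset, "henze_zirkler", hz, p, n, d)
}

#' Univariate Shapiro-Wilk test
#'
#' Wraps [stats::shapiro.test()] (the contract is agreement with the
#' published reference values of the W statistic).
#'
#' @param x numeric vector, 3 <= n <= 5000.
#' @param dataset label for the report.
#' @return one-row report data.frame.
#' @export
shapiro_univariate <- function(x, dataset = "data") {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("Shapiro-Wilk requires at least 3 observations")
  if (stats::sd(x) == 0) stop("Shapiro-Wilk undefined for a constant vector")
  sw <- stats::shapiro.test(x)
  normality_report(dataset, "shapiro_wilk", unname(sw$statistic), sw$p.value,
                   length(x), 1L)
}

#' Generalized multivariate Shapiro-Wilk test
#'
#' Applies the univariate Shapiro-Wilk to each standardized principal score
#' (coordinates of `S^-1/2 (x - xbar)`, which are uncorrelated under the
#' null) and combines the per-coordinate p-values by Fisher's method. The
#' statistic reported is the mean W. This is an approximation to the exact
#' multivariate Shapiro-Wilk; coordinates are only asymptotically
#' independent because the covariance is estimated.
#'
#' @inheritParams mardia_test
#' @return one-row report data.frame (`shapiro_wilk_mv`).
#' @export
shapiro_multivariate <- function(X, dataset = "data") {
  cs <- center_and_invcov(X)
  U <- cs$Z %*% cs$Sinv_half
  ws <- apply(U, 2, function(u) unlist(stats::shapiro.test(u)[c("statistic", "p.value")]))
  fisher <- -2 * sum(log(pmax(ws[2, ], 1e-300)))
  p <- stats::pchisq(fisher, df = 2 * cs$d, lower.tail = FALSE)
  normality_report(dataset, "shapiro_wilk_mv", mean(ws[1, ]), p, cs$n, cs$d)
}

#' Joint bivariate normality of merit and index scores
#'
#' Runs Mardia's tests and Henze-Zirkler on the n x 2 matrix
#' `(H_q, I)`. The null hypothesis is that the merit and its index predictor
#' are jointly bivariate normal — the assumption under which the closed-form
#' selection response is exact. p-values measure the credibility of that
#' hypothesis; no accept/reject decision is imposed.
#'
#' @param hq true (or estimated) quadratic merit vector.
#' @param index_scores index scores aligned with `hq`.
#' @param dataset label for the report.
#' @return three-row report data.frame.
#' @export
bivariate_merit_normality <- function(hq, index_scores, dataset = "merit-index") {
  if (length(hq) != length(index_scores)) stop("hq and index_scores must be aligned")
  X <- cbind(H_q = hq, index = index_scores)
  rbind(mardia_test(X, dataset), henze_zirkler_test(X, dataset))
}
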