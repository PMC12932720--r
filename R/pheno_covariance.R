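#' Covariance set for selection-index construction
#'
#' Bundles the three covariance matrices that drive index theory: the
#' phenotypic covariance `P` of genotype entry means, the genotypic covariance
#' `G`, and the genomic covariance `Gamma` of GEBVs, together with per-trait
#' broad-sense heritabilities on the entry-mean basis.
#'
#' @param P,G,Gamma t x t symmetric matrices (any may be NULL if not yet
#'   estimated).
#' @param h2 length-t heritability vector in `[0, 1]`, or NULL.
#' @param n_reps replicate count (harmonic mean for unbalanced designs) used
#'   in estimation, or NA.
#' @param traits character vector of trait names.
#' @return an object of class `covariance_set`.
#' @export
covariance_set <- function(P = NULL, G = NULL, Gamma = NULL, h2 = NULL,
                           n_reps = NA_real_, traits = NULL) {
  for (nm in c("P", "G", "Gamma")) {
    M <- get(nm)
    if (!is.null(M)) check_symmetric(as.matrix(M), nm, tol = 1e-6)
  }
  if (!is.null(h2) && any(h2 < -1e-8 | h2 > 1 + 1e-8)) {
    stop("h2 entries must lie in [0, 1]")
  }
  structure(list(P = P, G = G, Gamma = Gamma,
                 h2 = if (is.null(h2)) NULL else pmin(pmax(h2, 0), 1),
                 n_reps = n_reps, traits = traits),
            class = "covariance_set")
}

#' @export
print.covariance_set <- function(x, ...) {
  cat("covariance_set:",
      paste(Filter(function(nm) !is.null(x[[nm]]), c("P", "G", "Gamma")),
            collapse = ", "),
      sprintf("(%d trait(s), n_reps = %s)\n",
              length(x$traits), format(x$n_reps)))
  if (!is.null(x$h2)) cat("h2:", paste(sprintf("%.3f", x$h2), collapse = " "), "\n")
  invisible(x)
}

#' Estimate phenotypic and genotypic covariance matrices from a trait panel
#'
#' Multivariate method-of-moments (MANOVA cross-products) for the two-way
#' model `value = trait mean + genotype effect + residual`. On the genotype
#' entry-mean basis, `P` is the sample covariance of entry means and
#' `G = P - E/(df * r)` where `E` is the residual cross-product matrix and `r`
#' the (harmonic-mean) replicate count; for balanced designs this coincides
#' with the ML/ANOVA estimator `G = (MSB - MSE)/r` rescaled to entry means.
#' Both matrices are clamped to the PSD cone (eigenvalue truncation), jointly
#' so that `P - G` stays PSD. Broad-sense heritability per trait is the
#' univariate ratio `h2 = s2_g / (s2_g + s2_e / r)`.
#'
#' Missing phenotype cells are dropped pairwise per trait pair, with a
#' warning; no imputation is done.
#'
#' @param panel a [trait_panel()] with at least two genotypes and at least
#'   some genotypes replicated.
#' @return a [covariance_set()] with `P`, `G`, `h2` and `n_reps` filled.
#' @examples
#' set.seed(1)
#' g <- matrix(rnorm(200 * 2), 200, 2)
#' panel <- trait_panel(rep(1:200, each = 3), rep(1:3, 200),
#'                      g[rep(1:200, each = 3), ] + matrix(rnorm(1200), 600, 2))
#' estimate_P_G(panel)
#' @export
estimate_P_G <- function(panel) {
  stopifnot(inherits(panel, "trait_panel"))
  Y <- trait_matrix(panel)
  g <- factor(panel$genotype)
  tn <- colnames(Y)
  t <- ncol(Y)
  if (nlevels(g) < 2) stop("at least 2 genotypes are required")
  if (max(table(g)) < 2) stop("genotypic covariance not estimable: every genotype has a single replicate")
  if (anyNA(Y)) {
    warning(sprintf("%d missing phenotype cells dropped pairwise", sum(is.na(Y))))
  }

  ## residuals around per-genotype trait means (trait-wise available reps)
  gm <- entry_means(panel)
  R <- Y - gm[as.character(g), , drop = FALSE]

  ## pairwise residual mean cross-products with pairwise degrees of freedom
  Ecp <- matrix(0, t, t, dimnames = list(tn, tn))
  for (a in seq_len(t)) {
    for (b in a:t) {
      ok <- !is.na(R[, a]) & !is.na(R[, b])
      df <- sum(tapply(ok, g, function(z) max(sum(z) - 1, 0)))
      Ecp[a, b] <- Ecp[b, a] <-
        if (df > 0) sum(R[ok, a] * R[ok, b]) / df else 0
    }
  }

  r_i <- table(g)
  r_bar <- length(r_i) / sum(1 / as.numeric(r_i))  # harmonic mean

  P_raw <- stats::cov(gm, use = "pairwise.complete.obs")
  P_raw[is.na(P_raw)] <- 0
  G_raw <- P_raw - Ecp / r_bar

  ## joint PSD repair keeping P - G PSD
  P <- clamp_psd(P_raw)
  G <- clamp_psd(G_raw)
  for (it in 1:20) {
    D <- clamp_psd(P - G)
    G2 <- clamp_psd(P - D)
    if (max(abs(G2 - G)) < 1e-12) { G <- G2; break }
    G <- G2
  }

  s2g <- pmax(diag(P_raw) - diag(Ecp) / r_bar, 0)
  denom <- s2g + diag(Ecp) / r_bar
  h2 <- ifelse(denom > 0, s2g / denom, 0)

  covariance_set(P = P, G = G, h2 = as.numeric(h2), n_reps = r_bar, traits = tn)
}

#' Estimate the genomic covariance matrix of GEBVs
#'
#' Sample covariance of the GEBV matrix across individuals, clamped to the
#' PSD cone. This is the `Gamma` consumed by the genomic indices.
#'
#' @param gebvs n x t matrix of GEBVs (n >= 2 individuals).
#' @return a t x t symmetric PSD matrix.
#' @export
estimate_Gamma <- function(gebvs) {
  gebvs <- as.matrix(gebvs)
  if (nrow(gebvs) < 2) stop("at least 2 individuals are required to estimate Gamma")
  clamp_psd(stats::cov(gebvs))
}

#' Heritability of a linear selection index
#'
#' For a linear index `I = b'y` the broad-sense index heritability is
#' `b'Gb / b'Pb`, in `[0, 1]` whenever `P - G` is PSD.
#'
#' @param P,G t x t phenotypic and genotypic covariance matrices.
#' @param b length-t index coefficient vector (not all zero).
#' @return scalar heritability.
#' @export
index_heritability <- function(P, G, b) {
  b <- as.numeric(b)
  if (all(b == 0)) stop("b must not be the zero vector")
  den <- drop(t(b) %*% P %*% b)
  if (den <= 0) stop("b'Pb is zero: index has no phenotypic variance")
  drop(t(b) %*% G %*% b) / den
}
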