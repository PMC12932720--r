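#' Selection intensity under normal truncation
#'
#' For a selected proportion `p`, the standardized mean deviation of the
#' selected fraction of a normal distribution is `k = phi(z_p)/p` where `z_p`
#' is the upper-p standard-normal quantile. Strictly decreasing in `p`;
#' `k(0.10) = 1.755`.
#'
#' @param p selected proportion in (0, 1).
#' @return scalar selection intensity `k`.
#' @examples
#' selection_intensity(0.10)  # 1.755
#' @export
selection_intensity <- function(p) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) stop("p must lie strictly between 0 and 1")
  z <- stats::qnorm(1 - p)
  stats::dnorm(z) / p
}

#' Selection configuration
#'
#' @param proportion selected fraction in (0, 1).
#' @param intensity optional selection intensity `k`; derived from
#'   `proportion` when absent.
#' @param seed integer seed for stochastic oracles.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(proportion, intensity = NULL, seed = NULL) {
  if (proportion <= 0 || proportion >= 1) stop("proportion must lie in (0, 1)")
  k <- if (is.null(intensity)) selection_intensity(proportion) else intensity
  if (k <= 0) stop("selection intensity must be positive")
  structure(list(proportion = proportion, intensity = k, seed = seed),
            class = "selection_config")
}

#' Truncation selection of the top-scoring candidates
#'
#' Returns the identifiers of the `ceiling(n * p)` highest scores. Ties are
#' broken deterministically by ascending identifier.
#'
#' @param scores numeric vector, named with candidate ids (unnamed vectors
#'   use indices "1", "2", ... as ids).
#' @param p selected proportion; `n * p >= 1` required.
#' @return character vector of selected ids, in rank order.
#' @export
truncation_select <- function(scores, p) {
  n <- length(scores)
  if (n == 0) stop("scores must be non-empty")
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  n_sel <- ceiling(n * p)
  if (n_sel < 1) stop("n * p must be at least 1")
  ord <- order(-scores, ids)
  ids[ord[seq_len(n_sel)]]
}

## joint second moments of (H_q, I): the scored variable x has covariance
## Sigma_x and cross-covariance C = Cov(g, x); both parts centered.
index_merit_moments <- function(model, weights, G, Sigma_x, C) {
  a <- model$linear; Q <- model$quad
  w <- weights$w; W <- weights$W
  WG <- W %*% G
  var_H <- drop(t(w) %*% G %*% w) + 2 * sum(WG * t(WG))
  QS <- Q %*% Sigma_x
  var_I <- drop(t(a) %*% Sigma_x %*% a) + 2 * sum(QS * t(QS))
  CQ <- C %*% Q %*% t(C)
  cov_HI <- drop(t(w) %*% C %*% a) + 2 * sum(W * CQ)
  gamma_gI <- drop(C %*% a)     # Cov(g_j, I): the quadratic term contributes 0
  list(var_H = var_H, var_I = var_I, cov_HI = cov_HI, gamma_gI = gamma_gI)
}

make_summary <- function(cycle, kind, R, scor, sr_mspe, gains, traits = NULL) {
  if (is.null(traits)) traits <- paste0("T", seq_along(gains))
  out <- data.frame(cycle = cycle, index = kind, R = R, scor = scor,
                    sr_mspe = sr_mspe, stringsAsFactors = FALSE)
  gm <- matrix(gains, nrow = 1, dimnames = list(NULL, paste0("gain_", traits)))
  cbind(out, as.data.frame(gm))
}

#' Expected selection response and per-trait genetic gains of an index
#'
#' Computes the quantities of a per-cycle summary row: selection response
#' `R`, squared correlation with the quadratic merit (`scor`), the square
#' root of the minimized prediction error (`sr_mspe`), and per-trait expected
#' gains, under truncation selection at the configured proportion.
#'
#' The scored variable is phenotypic (covariance `P`, cross-covariance `G`
#' with the genetic values) for LPSI/QPSI and genomic (`Gamma` for both, the
#' classical genomic-index assumption) for LGSI/QGSI. All second moments of
#' `(H_q, I)` use exact quadratic-form identities. For `R`:
#' * linear index kinds have an exact closed form even under quadratic merit,
#'   `R = k w'c/sigma_I + z_p k c'Wc/sigma_I^2` with `c = Cov(g, I)` and
#'   `z_p` the truncation point (the second term uses the truncated-normal
#'   second moment);
#' * quadratic index kinds (a quadratic form is not normal, so no elementary
#'   closed form exists) are evaluated by the seeded high-precision
#'   truncation oracle [mc_truncation_oracle()] and flagged
#'   `method_R = "mc"` in the attributes, with a Monte-Carlo standard error.
#'
#' Per-trait gains always use the closed form `k * Cov(g, I_lin)/sd(I_lin)`
#' built on the index's linear kernel: the quadratic term has zero covariance
#' with every individual trait under zero-mean normality, so matched linear
#' and quadratic indices print identical per-trait gains.
#'
#' @param model an [index_model()].
#' @param covs a [covariance_set()]; `P`, `G` needed for phenotypic kinds,
#'   `Gamma` (and `G` for merit moments) for genomic kinds.
#' @param weights an [economic_weights()].
#' @param sel a [selection_config()]; a seed is required when the oracle path
#'   is used.
#' @param n_draws oracle draws for quadratic kinds (default 1e6).
#' @return one-row data.frame (`cycle`, `index`, `R`, `scor`, `sr_mspe`,
#'   `gain_*`) with attributes `method_R` ("closed" or "mc") and `mc_se`.
#' @export
response_and_gains <- function(model, covs, weights, sel, n_draws = 1e6) {
  stopifnot(inherits(model, "index_model"), inherits(sel, "selection_config"))
  phen <- model$kind %in% c("LPSI", "QPSI")
  G <- as.matrix(if (!is.null(covs$G)) covs$G else covs$Gamma)
  if (phen) {
    Sigma_x <- as.matrix(covs$P); C <- G
    traits <- colnames(covs$P)
  } else {
    Sigma_x <- as.matrix(covs$Gamma); C <- as.matrix(covs$Gamma)
    traits <- colnames(covs$Gamma)
  }
  mo <- index_merit_moments(model, weights, G, Sigma_x, C)
  if (mo$var_I <= 0) stop("index variance is zero")
  k <- sel$intensity
  sd_I <- sqrt(mo$var_I)

  scor <- mo$cov_HI^2 / (mo$var_H * mo$var_I)
  sr_mspe <- sqrt(max(mo$var_H - mo$cov_HI^2 / mo$var_I, 0))

  a <- model$linear
  sd_lin <- sqrt(drop(t(a) %*% Sigma_x %*% a))
  gains <- if (sd_lin > 0) k * drop(C %*% a) / sd_lin else rep(0, length(a))

  method_R <- "closed"; mc_se <- NA_real_
  if (is_linear_kind(model)) {
    z_p <- stats::qnorm(1 - sel$proportion)
    cvec <- mo$gamma_gI
    R <- k * drop(t(weights$w) %*% cvec) / sd_I +
      z_p * k * drop(t(cvec) %*% weights$W %*% cvec) / mo$var_I
  } else {
    if (is.null(sel$seed)) stop("a seed is required in selection_config for the quadratic-index oracle")
    orc <- mc_truncation_oracle(model, covs, weights, sel, n_draws = n_draws)
    R <- orc$R
    method_R <- "mc"; mc_se <- attr(orc, "se")["R"]
  }

  out <- make_summary(NA_integer_, model$kind, R, scor, sr_mspe, gains, traits)
  attr(out, "method_R") <- method_R
  attr(out, "mc_se") <- mc_se
  attr(out, "k") <- k
  out
}

#' Monte-Carlo truncation-selection oracle
#'
#' Draws `(g, x)` from the assumed joint multivariate normal (phenotypic
#' kinds: `g ~ N(0, G)`, `x = g + e`, `e ~ N(0, P - G)`; genomic kinds:
#' `x ~ N(0, Gamma)`, `g = x + eps`, `eps ~ N(0, G - Gamma)`), scores `x`
#' with the index, truncates at proportion `p`, and returns the empirical
#' selection response, per-trait selected-mean gains, squared correlation and
#' offset-aligned root MSE. Reproducible under the seed in `sel`.
#'
#' @inheritParams response_and_gains
#' @param n_draws number of Monte-Carlo draws (>= 1e5).
#' @return a list with `R`, `gains`, `scor`, `sr_mspe`, plus attribute `se`
#'   (approximate Monte-Carlo standard errors for `R`, `gains`, `scor`).
#' @export
mc_truncation_oracle <- function(model, covs, weights, sel, n_draws = 1e6) {
  if (is.null(sel$seed)) stop("selection_config must carry a seed for the oracle")
  if (n_draws < 1e5) stop("n_draws must be at least 1e5")
  set.seed(as.integer(sel$seed))
  phen <- model$kind %in% c("LPSI", "QPSI")
  G <- as.matrix(if (!is.null(covs$G)) covs$G else covs$Gamma)
  if (phen) {
    E <- clamp_psd(as.matrix(covs$P) - G)
    g <- rmvn(n_draws, G)
    x <- g + rmvn(n_draws, E)
  } else {
    Gamma <- as.matrix(covs$Gamma)
    Eps <- clamp_psd(G - Gamma)
    x <- rmvn(n_draws, Gamma)
    g <- x + rmvn(n_draws, Eps)
  }
  hq <- merit_hq(g, weights)
  I <- evaluate_index(model, x, center = FALSE)
  n_sel <- ceiling(n_draws * sel$proportion)
  sel_idx <- order(-I)[seq_len(n_sel)]

  R <- mean(hq[sel_idx]) - mean(hq)
  gains <- colMeans(g[sel_idx, , drop = FALSE]) - colMeans(g)
  r <- stats::cor(hq, I)
  hc <- hq - mean(hq); ic <- I - mean(I)
  out <- list(R = R, gains = gains, scor = r^2,
              sr_mspe = sqrt(mean((hc - ic)^2)))
  se_R <- stats::sd(hq[sel_idx]) / sqrt(n_sel)
  se_g <- apply(g[sel_idx, , drop = FALSE], 2, stats::sd) / sqrt(n_sel)
  se_scor <- 2 * abs(r) * (1 - r^2) / sqrt(n_draws)
  attr(out, "se") <- c(R = se_R, scor = se_scor, gains = se_g)
  out
}

#' Realized per-cycle selection summary from a finite population
#'
#' The empirical counterpart of [response_and_gains()] for an actual
#' population: realized response `R` (selected-minus-population mean of the
#' quadratic merit), squared Pearson correlation of index scores with the
#' merit, offset-aligned root mean squared prediction error, and realized
#' per-trait selection differentials (selected-minus-population trait means,
#' unscaled; the nominal intensity `k` and the realized intensity are
#' recorded as attributes).
#'
#' @param scores index scores (named by candidate id).
#' @param hq true quadratic merit, aligned with `scores`.
#' @param traits_or_gebvs n x t matrix whose selected-vs-population mean
#'   differences are reported as gains (true genetic values in simulation).
#' @param sel a [selection_config()].
#' @param cycle optional cycle number for the summary row.
#' @param kind index kind label.
#' @return one-row summary data.frame as in [response_and_gains()].
#' @export
empirical_summary <- function(scores, hq, traits_or_gebvs, sel,
                              cycle = NA_integer_, kind = "LPSI") {
  n <- length(scores)
  if (length(hq) != n || nrow(traits_or_gebvs) != n) stop("length mismatch between scores, hq and trait matrix")
  ids <- names(scores)
  if (is.null(ids)) { ids <- as.character(seq_len(n)); names(scores) <- ids }
  sel_ids <- truncation_select(scores, sel$proportion)
  idx <- match(sel_ids, ids)

  R <- mean(hq[idx]) - mean(hq)
  scor <- stats::cor(scores, hq)^2
  d <- hq - scores
  sr_mspe <- sqrt(mean((d - mean(d))^2))
  gains <- colMeans(traits_or_gebvs[idx, , drop = FALSE]) - colMeans(traits_or_gebvs)
  out <- make_summary(cycle, kind, R, scor, sr_mspe, gains, colnames(traits_or_gebvs))
  attr(out, "k") <- sel$intensity
  attr(out, "realized_intensity") <-
    (mean(scores[idx]) - mean(scores)) / stats::sd(scores)
  attr(out, "selected") <- sel_ids
  out
}
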