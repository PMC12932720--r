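#' Genome configuration for the breeding-cycle simulator
#'
#' Describes the simulated genome: uniformly placed markers, randomly placed
#' pleiotropic QTL, per-trait QTL counts, and the target genetic correlation
#' structure the QTL effects are calibrated to.
#'
#' @param n_chromosomes number of chromosomes.
#' @param n_markers total marker count (split as evenly as possible across
#'   chromosomes, equally spaced within each).
#' @param n_qtl total QTL count (positions uniform-random).
#' @param qtl_per_trait length-t integer vector; entries must not exceed
#'   `n_qtl`.
#' @param target_genetic_corr t x t correlation matrix (PSD, unit diagonal)
#'   for the founder genetic values.
#' @param target_h2 length-t per-plot heritability targets used by
#'   [sim_phenotype()].
#' @param chromosome_length_cM map length per chromosome (default 100 cM).
#' @param target_genetic_var length-t founder genetic variances (default 1).
#' @param founder_freq founder allele frequency at every locus (default 0.5).
#' @return object of class `genome_config`.
#' @export
genome_config <- function(n_chromosomes, n_markers, n_qtl, qtl_per_trait,
                          target_genetic_corr, target_h2 = NULL,
                          chromosome_length_cM = 100,
                          target_genetic_var = NULL, founder_freq = 0.5) {
  t <- length(qtl_per_trait)
  R <- as.matrix(target_genetic_corr)
  if (!all(dim(R) == t)) stop("target_genetic_corr must be t x t")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("target_genetic_corr must have unit diagonal")
  check_symmetric(R, "target_genetic_corr")
  if (!is_psd(R)) stop("target_genetic_corr must be positive semi-definite")
  if (any(qtl_per_trait > n_qtl)) stop("qtl_per_trait entries must not exceed n_qtl")
  if (any(qtl_per_trait < 1)) stop("each trait needs at least one QTL")
  if (is.null(target_h2)) target_h2 <- rep(0.5, t)
  if (is.null(target_genetic_var)) target_genetic_var <- rep(1, t)
  if (founder_freq <= 0 || founder_freq >= 1) stop("founder_freq must lie in (0,1)")
  structure(list(n_chromosomes = n_chromosomes, n_markers = n_markers,
                 n_qtl = n_qtl, qtl_per_trait = as.integer(qtl_per_trait),
                 target_genetic_corr = R, target_h2 = target_h2,
                 chromosome_length_cM = chromosome_length_cM,
                 target_genetic_var = target_genetic_var,
                 founder_freq = founder_freq, n_traits = t),
            class = "genome_config")
}

#' The simulated-maize genome configuration
#'
#' Convenience constructor for the simulated maize recurrent-selection
#' design: 10 chromosomes, 2806 uniformly spaced markers, 315 randomly
#' placed QTL with per-trait counts 300/100/60/40, and target genotypic
#' correlations (T1,T2) = -0.5, (T1,T3) = 0.4, (T1,T4) = 0.3, (T2,T3) =
#' -0.3, (T2,T4) = -0.2, (T3,T4) = 0.1. Heritabilities default to 0.5 per
#' trait and chromosome length to 100 cM.
#'
#' @param target_h2 per-trait heritabilities (default 0.5 each).
#' @return a [genome_config()].
#' @export
simulated_maize_config <- function(target_h2 = rep(0.5, 4)) {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- -0.5
  R[1, 3] <- R[3, 1] <- 0.4
  R[1, 4] <- R[4, 1] <- 0.3
  R[2, 3] <- R[3, 2] <- -0.3
  R[2, 4] <- R[4, 2] <- -0.2
  R[3, 4] <- R[4, 3] <- 0.1
  dimnames(R) <- list(paste0("T", 1:4), paste0("T", 1:4))
  genome_config(n_chromosomes = 10, n_markers = 2806, n_qtl = 315,
                qtl_per_trait = c(300, 100, 60, 40),
                target_genetic_corr = R, target_h2 = target_h2)
}

## sign vector sigma with sigma_i sigma_j = sign(R_ij) when the sign pattern
## is one-factor consistent; falls back to +1s otherwise (the numerical
## calibration then does the work).
corr_sign_vector <- function(R) {
  t <- nrow(R)
  s <- rep(1, t)
  if (t > 1) for (j in 2:t) if (R[1, j] != 0) s[j] <- sign(R[1, j])
  s
}

#' Build a simulated genome with calibrated pleiotropic QTL effects
#'
#' Markers are equally spaced per chromosome; QTL positions are
#' uniform-random. Each trait is assigned a random subset of QTL of the
#' configured size, so traits share QTL (pleiotropy). Effect sizes are then
#' calibrated so that the expected founder genetic covariance
#' `2 p (1-p) A'A` matches the target correlation/variance structure: the
#' masked effect matrix is initialized sign-consistently and refined by
#' quasi-Newton minimization of the squared Frobenius gap. If the achieved
#' founder correlation matrix is farther than `tol` from the target the
#' function errors, reporting the achieved matrix.
#'
#' @param config a [genome_config()].
#' @param seed integer seed (QTL placement, support masks, initialization).
#' @param tol acceptance tolerance on the achieved correlations
#'   (elementwise, default 0.05).
#' @param max_iter optimizer iteration cap per restart.
#' @return object of class `genome`: `map` (data.frame: chrom, pos_cM, type,
#'   index), `effects` (n_qtl x t, zero off-support), `achieved_corr`,
#'   `config`.
#' @export
build_genome <- function(config, seed, tol = 0.05, max_iter = 500) {
  stopifnot(inherits(config, "genome_config"))
  set.seed(as.integer(seed))
  nc <- config$n_chromosomes
  len <- config$chromosome_length_cM
  t <- config$n_traits

  per_chr_m <- diff(round(seq(0, config$n_markers, length.out = nc + 1)))
  marker_map <- do.call(rbind, lapply(seq_len(nc), function(cc) {
    m <- per_chr_m[cc]
    data.frame(chrom = cc, pos_cM = seq(0, len, length.out = m + 2)[2:(m + 1)],
               type = "marker")
  }))
  qtl_chr <- sample.int(nc, config$n_qtl, replace = TRUE)
  qtl_map <- data.frame(chrom = qtl_chr, pos_cM = stats::runif(config$n_qtl, 0, len),
                        type = "qtl")
  map <- rbind(marker_map, qtl_map)
  map <- map[order(map$chrom, map$pos_cM), ]
  map$index <- seq_len(nrow(map))
  rownames(map) <- NULL

  ## trait-support masks: random subsets of QTL per trait
  mask <- matrix(FALSE, config$n_qtl, t,
                 dimnames = list(NULL, colnames(config$target_genetic_corr)))
  for (k in seq_len(t)) mask[sample.int(config$n_qtl, config$qtl_per_trait[k]), k] <- TRUE
  ## every QTL affects at least one trait; re-draw orphans into trait 1's slots
  orphan <- which(rowSums(mask) == 0)
  if (length(orphan)) {
    donor <- which(mask[, 1] & rowSums(mask) > 1)
    swap <- donor[seq_len(min(length(orphan), length(donor)))]
    mask[swap, 1] <- FALSE
    mask[orphan[seq_along(swap)], 1] <- TRUE
  }

  vfac <- 2 * config$founder_freq * (1 - config$founder_freq)
  sdv_t <- diag(sqrt(config$target_genetic_var), t)
  Ctar <- sdv_t %*% config$target_genetic_corr %*% sdv_t
  Ttar <- Ctar / vfac                     # target A'A

  sgn <- corr_sign_vector(config$target_genetic_corr)
  eps <- sample(c(-1, 1), config$n_qtl, replace = TRUE)
  A0 <- mask * outer(eps, sgn * sqrt(diag(Ttar) / config$qtl_per_trait))

  idx <- which(mask)
  obj <- function(par) {
    A <- matrix(0, config$n_qtl, t); A[idx] <- par
    sum((crossprod(A) - Ttar)^2)
  }
  grad <- function(par) {
    A <- matrix(0, config$n_qtl, t); A[idx] <- par
    Gm <- 4 * A %*% (crossprod(A) - Ttar)
    Gm[idx]
  }
  fit <- stats::optim(A0[idx], obj, grad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  A <- matrix(0, config$n_qtl, t); A[idx] <- fit$par
  colnames(A) <- colnames(config$target_genetic_corr)

  Cach <- vfac * crossprod(A)
  sdv <- sqrt(pmax(diag(Cach), .Machine$double.eps))
  Rach <- Cach / tcrossprod(sdv)
  err <- max(abs(Rach - config$target_genetic_corr))
  if (err > tol) {
    stop(sprintf(paste0("QTL effect calibration failed: achieved correlations deviate ",
                        "by up to %.3f (> %.3f).\nAchieved matrix:\n%s"),
                 err, tol, paste(utils::capture.output(print(round(Rach, 3))), collapse = "\n")))
  }

  structure(list(map = map, effects = A, mask = mask,
                 achieved_corr = Rach, config = config, seed = seed),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("genome: %d chromosomes, %d markers, %d QTL, %d trait(s)\n",
              cfg$n_chromosomes, cfg$n_markers, cfg$n_qtl, cfg$n_traits))
  cat("achieved founder genetic correlations:\n")
  print(round(x$achieved_corr, 3))
  invisible(x)
}
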