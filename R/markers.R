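#' Standardize biallelic marker genotypes
#'
#' Builds the standardized marker matrix `M` used by GBLUP and the genomic
#' relationship matrix. Allele counts 2/1/0 (genotypes AA/Aa/aa, counting
#' allele A) are centered by twice the allele-A frequency, so that the coded
#' values are `2-2p`, `1-2p` and `-2p`. Frequencies are computed from the
#' training set and must be reused for any test set (pass `freqs`), which
#' matters in recurrent selection where frequencies drift after cycle 0.
#'
#' Missing codes are imputed to the column mean before centering (so imputed
#' cells standardize to 0 when `freqs` come from the same data). Monomorphic
#' columns (p of 0 or 1 in the training data) are excluded with a warning.
#'
#' @param codes n x m matrix of allele counts in \{0, 1, 2\} (NA allowed).
#' @param freqs optional length-m vector of training allele-A frequencies; if
#'   omitted they are computed from `codes`.
#' @return an object of class `marker_matrix`: list with `codes` (possibly
#'   column-reduced), `freqs`, and the standardized matrix `M`.
#' @examples
#' cm <- matrix(c(2, 1, 0, 0, 1, 2), 3, 2)
#' standardize_markers(cm)$M
#' @export
standardize_markers <- function(codes, freqs = NULL) {
  codes <- as.matrix(codes)
  if (any(!(codes %in% c(0, 1, 2)) & !is.na(codes))) {
    stop("marker codes must be 0, 1, 2 or NA")
  }
  if (any(colSums(!is.na(codes)) == 0)) stop("marker column with all values missing")
  if (is.null(colnames(codes))) colnames(codes) <- paste0("M", seq_len(ncol(codes)))

  own_freqs <- is.null(freqs)
  if (own_freqs) freqs <- colMeans(codes, na.rm = TRUE) / 2
  if (length(freqs) != ncol(codes)) stop("freqs length must match marker count")

  poly <- freqs > 0 & freqs < 1
  if (!any(poly)) stop("no polymorphic markers")
  if (any(!poly)) {
    warning(sprintf("%d monomorphic marker(s) excluded", sum(!poly)))
    codes <- codes[, poly, drop = FALSE]
    freqs <- freqs[poly]
  }

  filled <- codes
  if (anyNA(filled)) {
    cm <- colMeans(filled, na.rm = TRUE)
    idx <- which(is.na(filled), arr.ind = TRUE)
    filled[idx] <- cm[idx[, 2]]
  }
  M <- sweep(filled, 2, 2 * freqs, "-")
  structure(list(codes = codes, freqs = as.numeric(freqs), M = M),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d genotypes x %d polymorphic markers\n",
              nrow(x$M), ncol(x$M)))
  invisible(x)
}

#' Genomic relationship matrix
#'
#' VanRaden-type GRM from standardized markers:
#' `Phi = M M' / c` with `c = 2 * sum(p * (1 - p))` over the training allele
#' frequencies. Symmetric and PSD by construction.
#'
#' @param markers a [standardize_markers()] result.
#' @return an object of class `kernel` with fields `values` (n x n), `kind =
#'   "GRM"` and `bandwidth = NA`.
#' @export
grm <- function(markers) {
  stopifnot(inherits(markers, "marker_matrix"))
  p <- markers$freqs
  cc <- 2 * sum(p * (1 - p))
  if (cc <= 0) stop("no polymorphic markers")
  K <- tcrossprod(markers$M) / cc
  structure(list(values = (K + t(K)) / 2, kind = "GRM", bandwidth = NA_real_),
            class = "kernel")
}

#' Gaussian (RKHS) kernel from standardized markers
#'
#' `K_ij = exp(-d2_ij / (h * q))` where `d2` is the squared Euclidean distance
#' between standardized marker rows and `q` scales the distances; by the
#' median heuristic `q` is the median nonzero `d2`. The kernel has unit
#' diagonal and is PSD (Gaussian kernels are positive definite).
#'
#' @param markers a [standardize_markers()] result (training), or for
#'   prediction purposes any marker_matrix.
#' @param bandwidth positive scalar `h`, or the string "median" to take
#'   `h = 1` with the median-distance scaling (default).
#' @return a `kernel` object with `kind = "Gaussian"`.
#' @export
gaussian_kernel <- function(markers, bandwidth = "median") {
  stopifnot(inherits(markers, "marker_matrix"))
  M <- markers$M
  sq <- rowSums(M^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(M), 0)
  nz <- D2[upper.tri(D2)]
  nz <- nz[nz > 0]
  if (identical(bandwidth, "median")) {
    if (length(nz) == 0) stop("median bandwidth heuristic undefined: all marker rows identical")
    h <- 1
    q <- stats::median(nz)
  } else {
    h <- as.numeric(bandwidth)
    if (!is.finite(h) || h <= 0) stop("bandwidth must be a positive scalar or \"median\"")
    q <- if (length(nz)) stats::median(nz) else 1
  }
  K <- exp(-D2 / (h * q))
  diag(K) <- 1
  structure(list(values = (K + t(K)) / 2, kind = "Gaussian", bandwidth = h),
            class = "kernel")
}

#' @export
print.kernel <- function(x, ...) {
  cat(sprintf("%s kernel, %d x %d%s\n", x$kind, nrow(x$values), ncol(x$values),
              if (is.finite(x$bandwidth)) sprintf(", bandwidth %.3g", x$bandwidth) else ""))
  invisible(x)
}
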