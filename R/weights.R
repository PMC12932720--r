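#' Economic weights for net genetic merit
#'
#' The quadratic net genetic merit is `H_q = w'g + g'Wg`: `w` converts trait
#' units into merit units linearly, while the symmetric matrix `W` weights
#' squared and cross-product trait terms (interactions / nonlinear merit).
#' `W` is symmetrized on input as `(W + W')/2`.
#'
#' Because published experiments typically state only `w`, three constructors
#' are offered for `W`: `"zero"` (pure linear merit, the default), `"rank1"`
#' (`W = w w'/2`, a scaled outer product emphasizing the same direction as
#' `w`), or an explicit matrix.
#'
#' @param w length-t numeric vector of linear weights.
#' @param W `"zero"`, `"rank1"`, or a t x t symmetric matrix.
#' @return object of class `economic_weights` with fields `w`, `W`, and
#'   `W_kind` recording which constructor was used.
#' @examples
#' economic_weights(c(5, -0.3, -0.3, -1))
#' economic_weights(c(1, -1), W = "rank1")
#' @export
economic_weights <- function(w, W = "zero") {
  w <- as.numeric(w)
  t <- length(w)
  if (t < 1) stop("w must have at least one entry")
  if (is.character(W)) {
    W_kind <- match.arg(W, c("zero", "rank1"))
    Wm <- switch(W_kind, zero = matrix(0, t, t), rank1 = tcrossprod(w) / 2)
  } else {
    Wm <- as.matrix(W)
    if (!all(dim(Wm) == t)) stop("W must be a t x t matrix")
    Wm <- (Wm + t(Wm)) / 2
    W_kind <- "matrix"
  }
  structure(list(w = w, W = Wm, W_kind = W_kind), class = "economic_weights")
}

#' @export
print.economic_weights <- function(x, ...) {
  cat("economic_weights: w =", paste(signif(x$w, 4), collapse = ", "),
      sprintf("| W: %s\n", x$W_kind))
  invisible(x)
}
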