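#' Construct a replicated multi-trait phenotype panel
#'
#' A trait panel holds replicated phenotypic records for a set of genotypes in
#' long format: one row per (genotype, replicate), one column per trait. It is
#' the phenotypic input for covariance estimation, GBLUP training and index
#' scoring.
#'
#' @param genotype vector of genotype identifiers (coerced to character).
#' @param rep replicate numbers (positive integers).
#' @param traits data frame or matrix of trait measurements, one column per
#'   trait, in the trait units of the experiment (e.g. grain yield in t/ha,
#'   plant height in cm).
#' @return an object of class `trait_panel` (a data.frame with columns
#'   `genotype`, `rep`, then the traits).
#' @examples
#' tp <- trait_panel(rep(c("g1", "g2"), each = 2), rep(1:2, 2),
#'                   data.frame(GY = c(5, 6, 4, 5), PH = c(180, 185, 170, 172)))
#' entry_means(tp)
#' @export
trait_panel <- function(genotype, rep, traits) {
  traits <- as.data.frame(traits)
  if (nrow(traits) != length(genotype) || length(rep) != length(genotype)) {
    stop("genotype, rep and traits must have matching lengths")
  }
  if (ncol(traits) < 1) stop("at least one trait is required")
  if (any(!vapply(traits, is.numeric, TRUE))) stop("trait columns must be numeric")
  rep <- as.integer(rep)
  if (any(is.na(rep)) || any(rep < 1)) stop("replicate numbers must be positive integers")
  if (is.null(colnames(traits))) colnames(traits) <- paste0("T", seq_len(ncol(traits)))
  out <- data.frame(genotype = as.character(genotype), rep = rep, traits,
                    stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("trait_panel", "data.frame")
  out
}

#' @export
print.trait_panel <- function(x, ...) {
  cat(sprintf("trait_panel: %d records, %d genotypes, %d trait(s): %s\n",
              nrow(x), length(unique(x$genotype)), length(trait_names(x)),
              paste(trait_names(x), collapse = ", ")))
  NextMethod()
}

trait_names <- function(panel) setdiff(colnames(panel), c("genotype", "rep"))

trait_matrix <- function(panel) {
  as.matrix(as.data.frame(panel)[, trait_names(panel), drop = FALSE])
}

#' Genotype entry means of a trait panel
#'
#' Means over replicates per genotype; the analysis basis on which P is
#' defined and indices are scored. Missing cells are dropped per trait.
#'
#' @param panel a [trait_panel()].
#' @return a genotype x trait matrix with genotype ids as row names, rows
#'   ordered by genotype id.
#' @export
entry_means <- function(panel) {
  Y <- trait_matrix(panel)
  g <- factor(panel$genotype)
  out <- apply(Y, 2, function(col) tapply(col, g, mean, na.rm = TRUE))
  out <- matrix(out, nrow = nlevels(g),
                dimnames = list(levels(g), colnames(Y)))
  out
}

rep_counts <- function(panel) {
  tab <- table(panel$genotype)
  as.integer(tab)[order(names(tab))]
}
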