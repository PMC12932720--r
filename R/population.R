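#' Found a base population on a simulated genome
#'
#' Founder haplotypes are drawn with independent loci at the configured
#' founder allele frequency (no ancestral linkage disequilibrium; LD then
#' accrues through selection and drift). True genetic values are QTL dosages,
#' centered at the founder expectation, times the calibrated effects.
#'
#' @param genome a [build_genome()] result.
#' @param n population size (>= 2).
#' @param seed integer seed.
#' @return object of class `population`: haplotype matrices `hapA`, `hapB`
#'   (n x L over all mapped loci), `genetic_values` (n x t), `ids`, `cycle`,
#'   and the genome.
#' @export
found_population <- function(genome, n, seed) {
  stopifnot(inherits(genome, "genome"))
  if (n < 2) stop("population size must be at least 2")
  set.seed(as.integer(seed))
  L <- nrow(genome$map)
  p <- genome$config$founder_freq
  hapA <- matrix(stats::rbinom(n * L, 1L, p), n, L)
  hapB <- matrix(stats::rbinom(n * L, 1L, p), n, L)
  ids <- sprintf("G%05d", seq_len(n))
  rownames(hapA) <- rownames(hapB) <- ids
  pop <- structure(list(hapA = hapA, hapB = hapB, ids = ids, cycle = 0L,
                        genome = genome, genetic_values = NULL),
                   class = "population")
  pop$genetic_values <- true_genetic_values(pop)
  pop
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population: %d individuals, cycle %d, %d loci\n",
              length(x$ids), x$cycle, ncol(x$hapA)))
  invisible(x)
}

#' True genetic values of a population
#'
#' `g = (dosage_qtl - 2 p0) %*% effects`, centered at the founder allele
#' frequency `p0` so founder means are near zero.
#'
#' @param pop a `population`.
#' @return n x t matrix with individual ids as rownames.
#' @export
true_genetic_values <- function(pop) {
  qtl <- pop$genome$map$index[pop$genome$map$type == "qtl"]
  D <- pop$hapA[, qtl, drop = FALSE] + pop$hapB[, qtl, drop = FALSE]
  g <- (D - 2 * pop$genome$config$founder_freq) %*% pop$genome$effects
  rownames(g) <- pop$ids
  g
}

#' Marker genotype codes of a population
#'
#' @param pop a `population`.
#' @return n x m allele-count matrix (0/1/2) over the marker loci, ids as
#'   rownames.
#' @export
marker_codes <- function(pop) {
  mk <- pop$genome$map$index[pop$genome$map$type == "marker"]
  D <- pop$hapA[, mk, drop = FALSE] + pop$hapB[, mk, drop = FALSE]
  rownames(D) <- pop$ids
  colnames(D) <- paste0("M", seq_along(mk))
  D
}

#' Simulate replicated phenotypes for a population
#'
#' Each replicate value is the true genetic value plus an independent normal
#' error with variance `s2_g (1 - h2) / h2` per trait, where `s2_g` is the
#' realized genetic variance of the current population (so refitting the
#' variance components recovers `h2` on average). Errors are independent
#' across traits and replicates.
#'
#' @param pop a `population`.
#' @param h2 per-trait plot heritabilities in (0, 1]; defaults to the genome
#'   config targets.
#' @param n_reps replicates per genotype.
#' @param seed integer seed.
#' @return a [trait_panel()].
#' @export
sim_phenotype <- function(pop, h2 = NULL, n_reps = 4, seed) {
  if (is.null(h2)) h2 <- pop$genome$config$target_h2
  if (any(h2 <= 0)) stop("h2 must be strictly positive (h2 = 0 leaves no genetic signal)")
  if (any(h2 > 1)) stop("h2 must not exceed 1")
  set.seed(as.integer(seed))
  g <- pop$genetic_values
  n <- nrow(g); t <- ncol(g)
  s2g <- apply(g, 2, stats::var)
  s2e <- s2g * (1 - h2) / h2
  G <- g[rep(seq_len(n), each = n_reps), , drop = FALSE]
  E <- matrix(stats::rnorm(n * n_reps * t, sd = rep(sqrt(s2e), each = n * n_reps)),
              n * n_reps, t)
  traits <- G + E
  colnames(traits) <- colnames(g)
  trait_panel(rep(pop$ids, each = n_reps), rep(seq_len(n_reps), n), traits)
}

## one gamete per row of `parents`: recombination is simulated per adjacent
## locus interval with Haldane switch probability r = (1 - exp(-2d/100))/2,
## equivalent to Poisson crossover counts with uniform positions (no
## interference); returns list(gametes, n_switches per gamete)
make_gametes <- function(pop, parents) {
  map <- pop$genome$map
  ng <- length(parents)
  L <- ncol(pop$hapA)
  gam <- matrix(0L, ng, L)
  nsw <- numeric(ng)
  for (cc in unique(map$chrom)) {
    loci <- map$index[map$chrom == cc]
    Lc <- length(loci)
    d <- diff(map$pos_cM[map$chrom == cc])
    r <- (1 - exp(-2 * d / 100)) / 2
    src <- matrix(0L, ng, Lc)
    src[, 1] <- stats::rbinom(ng, 1L, 0.5)
    if (Lc > 1) {
      SW <- matrix(stats::rbinom(ng * (Lc - 1), 1L, rep(r, each = ng)), ng, Lc - 1)
      nsw <- nsw + rowSums(SW)
      for (j in 2:Lc) src[, j] <- (src[, j - 1] + SW[, j - 1]) %% 2L
    }
    A <- pop$hapA[parents, loci, drop = FALSE]
    B <- pop$hapB[parents, loci, drop = FALSE]
    gam[, loci] <- A * (1L - src) + B * src
  }
  list(gametes = gam, n_switches = nsw)
}

#' Advance a population one selection cycle
#'
#' The next generation (same size) is produced by random pairing of the
#' selected parents: each offspring draws two distinct parents at random,
#' each contributing one recombinant gamete under the Haldane model (no
#' crossover interference). True genetic values are recomputed and the cycle
#' counter incremented.
#'
#' @param pop a `population`.
#' @param selected_ids ids of the selected parents (>= 2).
#' @param seed integer seed.
#' @return the next-generation `population`.
#' @export
advance_cycle <- function(pop, selected_ids, seed) {
  idx <- match(selected_ids, pop$ids)
  if (anyNA(idx)) stop("unknown ids: ", paste(selected_ids[is.na(idx)], collapse = ", "))
  if (length(idx) < 2) stop("at least 2 selected parents are required")
  set.seed(as.integer(seed))
  n <- length(pop$ids)
  p1 <- idx[sample.int(length(idx), n, replace = TRUE)]
  shift <- sample.int(length(idx) - 1, n, replace = TRUE)
  p2 <- idx[(match(p1, idx) + shift - 1) %% length(idx) + 1]  # distinct from p1
  g1 <- make_gametes(pop, p1)
  g2 <- make_gametes(pop, p2)
  out <- pop
  out$hapA <- g1$gametes
  out$hapB <- g2$gametes
  out$cycle <- pop$cycle + 1L
  out$ids <- sprintf("G%05d", seq_len(n))
  rownames(out$hapA) <- rownames(out$hapB) <- out$ids
  out$genetic_values <- true_genetic_values(out)
  out
}

#' Paired draws of true genetic values and phenotypes from (G, P)
#'
#' Unit-test generator for the index and response oracles:
#' `g ~ N(0, G)`, `y = g + e`, `e ~ N(0, P - G)`.
#'
#' @param G,P t x t genotypic and phenotypic covariance matrices with
#'   `P - G` PSD.
#' @param n number of draws.
#' @param seed integer seed.
#' @return list with matrices `g` and `y` (n x t).
#' @export
mvn_generator <- function(G, P, n, seed) {
  E <- as.matrix(P) - as.matrix(G)
  if (!is_psd(E, tol = 1e-8 * max(1, max(abs(P))))) {
    stop("P - G must be positive semi-definite")
  }
  set.seed(as.integer(seed))
  g <- rmvn(n, G)
  y <- g + rmvn(n, clamp_psd(E))
  list(g = g, y = y)
}
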