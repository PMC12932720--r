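## shared fixture builders (everything generated in code; no stored data)

## random symmetric PSD matrix with unit-order scale
rand_psd <- function(t, scale = 1) {
  A <- matrix(rnorm(t * t), t)
  clamp_psd(crossprod(A) / t * scale)
}

## random (G, P) pair with P - G PSD
rand_G_P <- function(t, noise = 0.8) {
  G <- rand_psd(t)
  P <- G + rand_psd(t, noise)
  list(G = G, P = P)
}

## simulate a replicated panel from g ~ N(0, G0), e ~ N(0, E0)
sim_panel <- function(n_geno, n_reps, G0, E0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- nrow(G0)
  g <- rmvn(n_geno, G0)
  ids <- sprintf("g%05d", seq_len(n_geno))
  y <- g[rep(seq_len(n_geno), each = n_reps), , drop = FALSE] +
    rmvn(n_geno * n_reps, E0)
  colnames(y) <- paste0("T", seq_len(t))
  list(panel = trait_panel(rep(ids, each = n_reps), rep(seq_len(n_reps), n_geno), y),
       g = g, ids = ids)
}

## random marker codes with rownames
rand_codes <- function(n, m, seed = NULL, p = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rbinom(n * m, 2, p), n, m,
         dimnames = list(sprintf("g%03d", seq_len(n)), paste0("M", seq_len(m))))
}

## tiny genome config for fast simulator tests
tiny_config <- function(t = 2, corr = diag(t), n_markers = 60, n_qtl = 20,
                        qtl_per_trait = rep(15, t)) {
  genome_config(n_chromosomes = 2, n_markers = n_markers, n_qtl = n_qtl,
                qtl_per_trait = qtl_per_trait, target_genetic_corr = corr)
}

## random symmetric (not necessarily PSD) weight matrix
rand_W <- function(t, scale = 0.4) {
  M <- matrix(rnorm(t * t) * scale, t)
  (M + t(M)) / 2
}

## mean within-genotype (residual) variance per trait of a panel
trait_panel_resid_var <- function(panel) {
  Y <- as.matrix(as.data.frame(panel)[, setdiff(colnames(panel), c("genotype", "rep"))])
  g <- factor(panel$genotype)
  apply(Y, 2, function(col) mean(tapply(col, g, var)))
}
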