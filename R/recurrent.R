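#' Run a recurrent-selection experiment
#'
#' Emulates a multi-cycle truncation-selection program on a simulated
#' genome. Phenotypic index kinds (LPSI, QPSI) are re-phenotyped and
#' re-estimated every cycle. Genomic kinds (LGSI, QGSI) are trained once at
#' cycle 0 (phenotypes + markers -> GBLUP marker effects, or an RKHS fit)
#' and then run phenotype-free: GEBVs in later cycles come from the frozen
#' cycle-0 marker effects and cycle-0 allele frequencies, while the genomic
#' covariance `Gamma` is re-estimated from the current GEBV matrix each
#' cycle.
#'
#' Each cycle scores the candidates, records the realized selection summary
#' against the true quadratic merit, selects the top fraction and advances
#' the population by random mating with recombination.
#'
#' @param config a [genome_config()].
#' @param index_kind one of "LPSI", "QPSI", "LGSI", "QGSI".
#' @param weights an [economic_weights()].
#' @param cycles number of selection cycles.
#' @param seed integer master seed; all per-cycle seeds derive from it.
#' @param engine "gblup" or "rkhs" (genomic kinds only).
#' @param n population size per cycle (default 500).
#' @param n_reps phenotype replicates (default 4).
#' @param proportion selected fraction (default 0.10).
#' @param rkhs_opts list of options for [fit_rkhs_multitrait()] when
#'   `engine = "rkhs"` (iters, burnin, thin).
#' @return object of class `recurrent_run`: `summaries` (one row per cycle:
#'   cycle, index, R, scor, sr_mspe), `gains` (per-cycle per-trait realized
#'   gains), `config`, and the final `population`.
#' @export
run_recurrent_selection <- function(config, index_kind, weights, cycles, seed,
                                    engine = c("gblup", "rkhs"), n = 500,
                                    n_reps = 4, proportion = 0.10,
                                    rkhs_opts = list(iters = 2000, burnin = 500, thin = 5)) {
  engine <- match.arg(engine)
  index_kind <- match.arg(index_kind, c("LPSI", "QPSI", "LGSI", "QGSI"))
  genomic <- index_kind %in% c("LGSI", "QGSI")
  sel <- selection_config(proportion, seed = seed)
  seed <- as.integer(seed)

  genome <- build_genome(config, seed = seed)
  pop <- found_population(genome, n = n, seed = seed + 1L)

  fit <- NULL; frozen_freqs <- NULL; rkhs_state <- NULL
  rows <- vector("list", cycles)

  for (cyc in seq_len(cycles)) {
    cs <- seed + 100L * cyc
    if (!genomic || cyc == 1L) {
      panel <- sim_phenotype(pop, n_reps = n_reps, seed = cs + 1L)
      covs <- estimate_P_G(panel)
    }

    if (!genomic) {
      model <- if (index_kind == "LPSI") lpsi_coefficients(covs, weights)
               else qpsi_coefficients(covs, weights)
      scores <- evaluate_index(model, entry_means(panel))
    } else {
      if (cyc == 1L) {
        std <- standardize_markers(marker_codes(pop))
        frozen_freqs <- std$freqs
        frozen_cols <- colnames(std$codes)
        if (engine == "gblup") {
          lam <- 2 * sum(std$freqs * (1 - std$freqs)) *
            (1 - covs$h2) / pmax(covs$h2, 1e-6)
          fit <- fit_gblup(panel, std, lambda = lam)
          gebv <- fit$gebv_train
        } else {
          K <- gaussian_kernel(std)
          rk <- fit_rkhs_multitrait(panel, K, iters = rkhs_opts$iters,
                                    burnin = rkhs_opts$burnin,
                                    thin = rkhs_opts$thin, seed = cs + 2L)
          gebv <- rk$gebv
          Kv <- K$values + diag(1e-6, nrow(K$values))
          rkhs_state <- list(M_train = std$M, q = attr_median_d2(std$M),
                             alpha = solve(Kv, rk$gebv))
        }
      } else {
        std <- standardize_markers(marker_codes(pop)[, frozen_cols, drop = FALSE],
                                   freqs = frozen_freqs)
        gebv <- if (engine == "gblup") predict_gebv(fit, std)
                else rkhs_cross_predict(rkhs_state, std$M)
      }
      covs <- covariance_set(G = covs$G, Gamma = estimate_Gamma(gebv),
                             h2 = covs$h2, n_reps = covs$n_reps, traits = covs$traits)
      model <- if (index_kind == "LGSI") lgsi_model(weights)
               else qgsi_model(covs, weights)
      scores <- evaluate_index(model, gebv)
    }

    ## genetic values are expressed as deviations from the current population
    ## mean (breeding values are deviations by definition), matching the
    ## centered scoring convention of the indices
    g <- sweep(pop$genetic_values, 2, colMeans(pop$genetic_values))
    hq <- merit_hq(g, weights)
    summ <- empirical_summary(scores, hq, g, sel, cycle = cyc, kind = index_kind)
    rows[[cyc]] <- summ
    pop <- advance_cycle(pop, attr(summ, "selected"), seed = cs + 3L)
  }

  summaries <- do.call(rbind, rows)
  gain_cols <- grep("^gain_", colnames(summaries), value = TRUE)
  structure(list(summaries = summaries[, c("cycle", "index", "R", "scor", "sr_mspe")],
                 gains = summaries[, c("cycle", "index", gain_cols)],
                 weights = weights, config = config, seed = seed,
                 population = pop),
            class = "recurrent_run")
}

attr_median_d2 <- function(M) {
  sq <- rowSums(M^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(M), 0)
  nz <- D2[upper.tri(D2)]
  stats::median(nz[nz > 0])
}

## kernel regression prediction for new genotypes: K_new,train alpha with the
## training bandwidth scaling
rkhs_cross_predict <- function(state, M_new) {
  sqn <- rowSums(M_new^2)
  sqt <- rowSums(state$M_train^2)
  D2 <- pmax(outer(sqn, sqt, "+") - 2 * tcrossprod(M_new, state$M_train), 0)
  K <- exp(-D2 / state$q)
  K %*% state$alpha
}

#' @export
print.recurrent_run <- function(x, ...) {
  cat(sprintf("recurrent_run: %s, %d cycle(s)\n", x$summaries$index[1], nrow(x$summaries)))
  print(x$summaries, row.names = FALSE)
  invisible(x)
}
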