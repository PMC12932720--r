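test_that("the simulated-maize genome builds and calibrates to its targets", {
  cfg <- simulated_maize_config()
  gen <- build_genome(cfg, seed = 1)
  expect_equal(sum(gen$map$type == "marker"), 2806)
  expect_equal(sum(gen$map$type == "qtl"), 315)
  expect_equal(colSums(gen$mask), c(T1 = 300, T2 = 100, T3 = 60, T4 = 40))
  expect_lt(max(abs(gen$achieved_corr - cfg$target_genetic_corr)), 0.05)
  ## markers equally spaced within chromosomes
  m1 <- gen$map[gen$map$chrom == 1 & gen$map$type == "marker", ]
  expect_lt(diff(range(diff(m1$pos_cM))), 1e-8)
})

test_that("disjoint QTL sets with an identity target give near-zero correlations", {
  cfg <- genome_config(n_chromosomes = 2, n_markers = 50, n_qtl = 30,
                       qtl_per_trait = c(15, 15), target_genetic_corr = diag(2))
  ## force disjoint supports by construction: counts sum to n_qtl
  gen <- build_genome(cfg, seed = 2)
  pop <- found_population(gen, 2000, seed = 3)
  expect_lt(abs(cor(pop$genetic_values)[1, 2]), 0.05)
})

test_that("a single-QTL trait has founder variance 2 p (1-p) effect^2", {
  cfg <- genome_config(n_chromosomes = 1, n_markers = 10, n_qtl = 1,
                       qtl_per_trait = 1, target_genetic_corr = matrix(1),
                       target_genetic_var = 4)
  gen <- build_genome(cfg, seed = 4)
  a <- gen$effects[1, 1]
  expect_equal(0.5 * a^2, 4, tolerance = 1e-6)
  pop <- found_population(gen, 20000, seed = 5)
  expect_equal(var(pop$genetic_values[, 1]), 0.5 * a^2, tolerance = 0.15)
})

test_that("infeasible correlation targets error with the achieved matrix", {
  R <- matrix(c(1, 0.9, 0.9, 1), 2)
  cfg <- genome_config(n_chromosomes = 1, n_markers = 10, n_qtl = 2,
                       qtl_per_trait = c(1, 1), target_genetic_corr = R)
  ## single-QTL traits can only realize correlations of 0 or +-1
  expect_error(build_genome(cfg, seed = 6), "Achieved matrix")
})

test_that("founder construction matches its sampling assumptions", {
  gen <- build_genome(tiny_config(), seed = 7)
  pop <- found_population(gen, 2000, seed = 8)
  freqs <- colMeans(marker_codes(pop)) / 2
  expect_lt(max(abs(freqs - 0.5)), 0.05)
  ## zero effects give zero genetic values
  gen0 <- gen; gen0$effects[] <- 0
  pop0 <- found_population(gen0, 50, seed = 9)
  expect_equal(max(abs(pop0$genetic_values)), 0)
  expect_error(found_population(gen, 1, seed = 1), "at least 2")
})

test_that("phenotypes respect the heritability construction", {
  gen <- build_genome(tiny_config(), seed = 10)
  pop <- found_population(gen, 500, seed = 11)
  ## h2 = 1: replicates equal genetic values
  panel1 <- sim_phenotype(pop, h2 = c(1, 1), n_reps = 2, seed = 12)
  em <- entry_means(panel1)
  gv <- pop$genetic_values[order(pop$ids), ]
  expect_equal(unname(em), unname(gv[rownames(em), ]), tolerance = 1e-12)

  ## round trip: refitting recovers h2 within 0.05 at 500 x 4
  panel <- sim_phenotype(pop, h2 = c(0.5, 0.7), n_reps = 4, seed = 13)
  cs <- estimate_P_G(panel)
  ## h2 on the entry-mean basis: h2_em = r h2 / (1 + (r-1) h2)
  expect_lt(abs(cs$h2[1] - 4 * 0.5 / (1 + 3 * 0.5)), 0.05)
  expect_lt(abs(cs$h2[2] - 4 * 0.7 / (1 + 3 * 0.7)), 0.05)

  ## error variance doubles when h2 drops from 0.5 to 1/3
  set.seed(14)
  p5 <- sim_phenotype(pop, h2 = c(0.5, 0.5), n_reps = 50, seed = 15)
  p3 <- sim_phenotype(pop, h2 = c(1 / 3, 1 / 3), n_reps = 50, seed = 16)
  r5 <- trait_panel_resid_var(p5); r3 <- trait_panel_resid_var(p3)
  expect_equal(unname(r3 / r5), c(2, 2), tolerance = 0.15)

  expect_error(sim_phenotype(pop, h2 = c(0, 0.5), n_reps = 2, seed = 1), "positive")
})

test_that("meiosis conserves parental alleles and the map switch rate", {
  gen <- build_genome(tiny_config(), seed = 17)
  pop <- found_population(gen, 100, seed = 18)
  set.seed(19)
  gm <- quadindex:::make_gametes(pop, rep(1L, 5000))
  ## every gamete allele copies one of the two parental haplotypes
  A <- pop$hapA[1, ]; B <- pop$hapB[1, ]
  ok <- apply(gm$gametes, 1, function(g) all(g == A | g == B))
  expect_true(all(ok))
  ## expected switch count: sum of Haldane interval probabilities
  d <- unlist(tapply(gen$map$pos_cM, gen$map$chrom, diff))
  exp_sw <- sum((1 - exp(-2 * d / 100)) / 2)
  expect_equal(mean(gm$n_switches), exp_sw, tolerance = 0.05)
  ## close to total map length / 100 Morgans for a dense map
  expect_equal(exp_sw, sum(d) / 100, tolerance = 0.1)
})

test_that("directional selection raises the selected trait; no selection drifts", {
  cfg <- tiny_config(t = 2, n_markers = 40, n_qtl = 20, qtl_per_trait = c(15, 15))
  ups <- logical(6)
  for (s in 1:6) {
    gen <- build_genome(cfg, seed = 20 + s)
    pop <- found_population(gen, 200, seed = 40 + s)
    m0 <- mean(pop$genetic_values[, 1])
    for (cyc in 1:3) {
      sc <- pop$genetic_values[, 1]; names(sc) <- pop$ids
      keep <- truncation_select(sc, 0.2)
      pop <- advance_cycle(pop, keep, seed = 60 + 10 * s + cyc)
    }
    ups[s] <- mean(pop$genetic_values[, 1]) > m0
  }
  expect_gte(sum(ups), 4)  # majority of seeds

  ## neutrality: selecting everyone leaves only drift
  gen <- build_genome(cfg, seed = 99)
  pop <- found_population(gen, 400, seed = 100)
  pop2 <- advance_cycle(pop, pop$ids, seed = 101)
  drift_se <- sqrt(2 * var(pop$genetic_values[, 1]) / 400)
  expect_lt(abs(mean(pop2$genetic_values[, 1]) - mean(pop$genetic_values[, 1])),
            4 * drift_se)
  expect_error(advance_cycle(pop, pop$ids[1], seed = 1), "at least 2")
})

test_that("populations and runs are bit-identical under a fixed seed", {
  cfg <- tiny_config()
  g1 <- build_genome(cfg, seed = 30); g2 <- build_genome(cfg, seed = 30)
  expect_identical(g1$effects, g2$effects)
  p1 <- found_population(g1, 100, seed = 31)
  p2 <- found_population(g2, 100, seed = 31)
  expect_identical(p1$hapA, p2$hapA)
  w <- economic_weights(c(1, -1))
  r1 <- run_recurrent_selection(cfg, "LPSI", w, cycles = 2, seed = 32, n = 100, n_reps = 2)
  r2 <- run_recurrent_selection(cfg, "LPSI", w, cycles = 2, seed = 32, n = 100, n_reps = 2)
  expect_identical(r1$summaries, r2$summaries)
})

test_that("QGSI with W = 0 reproduces the LGSI run line for line", {
  cfg <- tiny_config()
  w0 <- economic_weights(c(1, -1), W = "zero")
  rq <- run_recurrent_selection(cfg, "QGSI", w0, cycles = 3, seed = 33, n = 120, n_reps = 2)
  rl <- run_recurrent_selection(cfg, "LGSI", w0, cycles = 3, seed = 33, n = 120, n_reps = 2)
  expect_equal(rq$summaries[, c("R", "scor", "sr_mspe")],
               rl$summaries[, c("R", "scor", "sr_mspe")], tolerance = 1e-12)
})

test_that("a multi-cycle run emits per-cycle rows and an Average row", {
  cfg <- tiny_config()
  w <- economic_weights(c(1, -1), W = "rank1")
  run <- run_recurrent_selection(cfg, "QGSI", w, cycles = 3, seed = 34, n = 120, n_reps = 2)
  expect_equal(nrow(run$summaries), 3)
  full <- cbind(run$summaries, run$gains[, -(1:2), drop = FALSE])
  out <- write_summary_tables(full, file.path(tempdir(), "run"))
  expect_equal(out$response$cycle[4], "Average")
  expect_equal(out$response$R[4], round(mean(run$summaries$R), 1))
})

test_that("the MVN generator matches its moments", {
  G <- matrix(c(1, 0.5, 0.5, 1), 2)
  P <- G + diag(2)
  d <- mvn_generator(G, P, 2e5, seed = 35)
  expect_lt(max(abs(cov(d$y) - P)), 3 * sqrt(2 / 2e5) * 2 + 0.02)
  for (k in 1:2) {
    expect_lt(abs(cor(d$g[, k], d$y[, k]) - sqrt(G[k, k] / P[k, k])), 0.01)
  }
  d2 <- mvn_generator(G, G, 100, seed = 36)
  expect_equal(d2$g, d2$y)
  expect_error(mvn_generator(diag(2) * 2, diag(2), 10, seed = 1), "PSD|semi-definite")
})

test_that("the RKHS engine runs a short genomic cycle experiment", {
  cfg <- tiny_config()
  w <- economic_weights(c(1, -1))
  run <- run_recurrent_selection(cfg, "LGSI", w, cycles = 2, seed = 37, n = 80,
                                 n_reps = 2, engine = "rkhs",
                                 rkhs_opts = list(iters = 600, burnin = 200, thin = 2))
  expect_equal(nrow(run$summaries), 2)
  expect_true(all(is.finite(run$summaries$R)))
})
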