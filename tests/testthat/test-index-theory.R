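test_that("LPSI coefficients solve the Smith-Hazel system", {
  ## hand-inverted 2x2 system
  covs <- covariance_set(P = diag(c(2, 2)), G = matrix(c(1, 0.5, 0.5, 1), 2))
  m <- lpsi_coefficients(covs, economic_weights(c(1, -1)))
  expect_equal(m$linear, drop(solve(diag(c(2, 2)), matrix(c(1, 0.5, 0.5, 1), 2) %*% c(1, -1))))
  expect_equal(m$linear, c(0.25, -0.25))

  ## G = P gives b = w
  covs2 <- covariance_set(P = diag(3) + 0.2, G = diag(3) + 0.2)
  w <- c(2, -1, 0.5)
  expect_equal(lpsi_coefficients(covs2, economic_weights(w))$linear, w)

  expect_error(lpsi_coefficients(covariance_set(P = matrix(0, 2, 2), G = diag(2)),
                                 economic_weights(c(1, 1))), "condition number")
})

test_that("LPSI maximizes correlation with the linear merit over random candidates", {
  set.seed(11)
  for (i in 1:3) {
    gp <- rand_G_P(3)
    w <- rnorm(3)
    covs <- covariance_set(P = gp$P, G = gp$G)
    b <- lpsi_coefficients(covs, economic_weights(w))$linear
    corr2 <- function(bb) {
      drop(t(bb) %*% gp$G %*% w)^2 /
        (drop(t(bb) %*% gp$P %*% bb) * drop(t(w) %*% gp$G %*% w))
    }
    cand <- matrix(rnorm(3 * 1e4), 1e4, 3)
    best_rand <- max(apply(cand, 1, corr2))
    expect_gte(corr2(b) + 1e-12, best_rand)
  }
})

test_that("QPSI nests LPSI and matches the closed substitution case", {
  gp <- rand_G_P(3)
  covs <- covariance_set(P = gp$P, G = gp$G)
  w <- c(1, -1, 0.5)
  m0 <- qpsi_coefficients(covs, economic_weights(w, W = "zero"))
  expect_identical(m0$kind, "LPSI")
  expect_equal(m0$linear, lpsi_coefficients(covs, economic_weights(w))$linear)

  ## G = P, W = I: quad = I, linear = w, offset = 0
  S <- clamp_psd(rand_psd(2) + diag(2))
  covs2 <- covariance_set(P = S, G = S)
  m1 <- qpsi_coefficients(covs2, economic_weights(c(1, 2), W = diag(2)))
  expect_equal(m1$linear, c(1, 2))
  expect_equal(m1$quad, diag(2), tolerance = 1e-10)
  expect_equal(m1$offset, 0, tolerance = 1e-10)
})

test_that("QPSI equals the conditional expectation E[H_q | y] (univariate integration)", {
  G <- matrix(2); P <- matrix(3)
  w <- 1.5; W <- matrix(0.7)
  covs <- covariance_set(P = P, G = G)
  m <- qpsi_coefficients(covs, economic_weights(w, W))
  for (y in c(-2, -0.5, 0, 1, 2.5)) {
    mu_g <- 2 / 3 * y
    v_g <- 2 - 4 / 3
    num <- integrate(function(g) (w * g + W[1] * g^2) * dnorm(g, mu_g, sqrt(v_g)),
                     -Inf, Inf, rel.tol = 1e-10)$value
    pred <- m$linear * y + drop(m$quad) * y^2 + m$offset
    expect_equal(pred, num, tolerance = 1e-6)
  }
})

test_that("QPSI/QGSI analytic coefficients minimize empirical MSPE", {
  set.seed(12)
  Gamma <- rand_psd(3) + diag(3) * 0.1
  G <- Gamma + rand_psd(3, 0.3)
  P <- G + rand_psd(3, 0.6)
  w <- rnorm(3); W <- rand_W(3)
  ew <- economic_weights(w, W)
  covs <- covariance_set(P = P, G = G, Gamma = Gamma)

  draws <- mvn_generator(G, P, 2e5, seed = 13)
  hq <- merit_hq(draws$g, ew)
  m <- qpsi_coefficients(covs, ew)
  err_base <- (hq - evaluate_index(m, draws$y, center = FALSE))^2
  for (j in 1:30) {
    pm <- m
    pm$linear <- m$linear + rnorm(3, sd = 0.1)
    pm$quad <- m$quad + rand_W(3, 0.05)
    pm$offset <- m$offset + rnorm(1, sd = 0.1)
    err_p <- (hq - evaluate_index(pm, draws$y, center = FALSE))^2
    se_dd <- sd(err_p - err_base) / sqrt(2e5)
    expect_gte(mean(err_p) - mean(err_base), -3 * se_dd)
  }

  ## genomic: gebv ~ N(0, Gamma), g = gebv + eps
  set.seed(14)
  gebv <- rmvn(2e5, Gamma)
  g2 <- gebv + rmvn(2e5, G - Gamma)
  hq <- merit_hq(g2, ew)
  mq <- qgsi_model(covs, ew)
  off <- sum(diag(ew$W %*% (G - Gamma)))
  err_base <- (hq - evaluate_index(mq, gebv, center = FALSE) - off)^2
  for (j in 1:30) {
    pm <- mq
    pm$linear <- mq$linear + rnorm(3, sd = 0.1)
    pm$quad <- mq$quad + rand_W(3, 0.05)
    err_p <- (hq - evaluate_index(pm, gebv, center = FALSE) - off)^2
    se_dd <- sd(err_p - err_base) / sqrt(2e5)
    expect_gte(mean(err_p) - mean(err_base), -3 * se_dd)
  }
})

test_that("QGSI reduces to LGSI at W = 0 and evaluates Eq-style scores", {
  covs <- covariance_set(Gamma = diag(2))
  w <- c(1, 1)
  m0 <- qgsi_model(covs, economic_weights(w, "zero"))
  expect_identical(m0$kind, "LGSI")
  m1 <- qgsi_model(covs, economic_weights(w, diag(2)))
  ## hand case: gebv = (1, 2) -> 1 + 2 + 1 + 4 = 8
  expect_equal(unname(evaluate_index(m1, rbind(c(1, 2)), center = FALSE)), 8)
  badG <- diag(2); badG[1, 1] <- -1
  covs_bad <- covariance_set(Gamma = NULL)
  covs_bad$Gamma <- badG
  expect_error(qgsi_model(covs_bad, economic_weights(w, diag(2))), "semi-definite")
})

test_that("index evaluation is linear for linear kinds and handles hand cases", {
  m <- index_model("LPSI", c(2, -1))
  X <- matrix(rnorm(20), 10, 2)
  s1 <- evaluate_index(m, X, center = FALSE)
  expect_equal(evaluate_index(m, 2 * X, center = FALSE), 2 * s1)

  mq <- index_model("QGSI", c(1, 0), quad = matrix(c(1, 0.5, 0.5, -1), 2), offset = 3)
  expect_equal(unname(evaluate_index(mq, rbind(c(0, 0)), center = FALSE)), 3)
  x <- c(1, 2)
  expect_equal(unname(evaluate_index(mq, rbind(x), center = FALSE)),
               1 + (1 * 1 + 0.5 * 2 * 2 - 1 * 4) + 3)
  expect_error(evaluate_index(mq, matrix(0, 2, 3)), "mismatch")
})

test_that("index moments match the quadratic-form identities and Monte-Carlo", {
  ## trace arithmetic: quad = I, Sigma = diag(2, 3), linear = 0
  m <- index_model("QGSI", c(0, 0), quad = diag(2))
  mo <- index_moments(m, diag(c(2, 3)))
  expect_equal(unname(mo), c(5, 2 * (4 + 9)))
  ## chi-square variance identity
  m2 <- index_model("QGSI", c(0, 0), quad = diag(2))
  expect_equal(unname(index_moments(m2, diag(2))["variance"]), 4)
  m3 <- index_model("LPSI", c(1, 0))
  expect_equal(unname(index_moments(m3, diag(2))), c(0, 1))

  set.seed(15)
  S <- rand_psd(4) + diag(4) * 0.5
  mq <- index_model("QGSI", rnorm(4), quad = rand_W(4), offset = 0.3)
  mo <- index_moments(mq, S)
  X <- rmvn(1e6, S)
  sc <- evaluate_index(mq, X, center = FALSE)
  se_mean <- sd(sc) / 1e3
  expect_lt(abs(mean(sc) - mo["mean"]), 3 * se_mean)
  se_var <- sqrt((mean((sc - mean(sc))^4) - var(sc)^2) / 1e6)
  expect_lt(abs(var(sc) - mo["variance"]), 3 * se_var)
})

test_that("quadratic merit evaluates hand cases and degenerate inputs", {
  ew <- economic_weights(c(1, -1), matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(unname(merit_hq(rbind(c(2, 1)), ew)), 2 - 1 + 2 * 0.5 * 2 * 1)
  expect_equal(unname(merit_hq(rbind(c(0, 0)), ew)), 0)
  ew0 <- economic_weights(c(2, 3))
  g <- matrix(rnorm(10), 5, 2)
  expect_equal(merit_hq(g, ew0), drop(g %*% c(2, 3)))
})
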