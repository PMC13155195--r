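test_that("tree-binomial log-likelihood matches hand arithmetic", {
  tr <- ltn_tree("(a,b);")
  X <- matrix(c(1L, 1L), 1, dimnames = list(NULL, c("a", "b")))
  nct <- aggregate_node_counts(X, tr)
  # single node, y = 2, y_l = 1, psi = 0: log C(2,1) + 2 log 0.5 = log 0.5
  expect_equal(ltn_loglik(nct, 0, tr), log(0.5), tolerance = 1e-12)
})

test_that("empty samples contribute zero log-likelihood", {
  tr <- random_tree(6, seed = 31)
  X <- matrix(0L, 3, 6, dimnames = list(NULL, tr$leaves))
  nct <- aggregate_node_counts(X, tr)
  psi <- matrix(rnorm(3 * 5), 3, 5)
  expect_equal(ltn_loglik(nct, psi, tr), 0)
})

test_that("multinomial and tree-binomial log-likelihoods differ by a psi-free constant", {
  set.seed(32)
  for (rep in 1:10) {
    K <- sample(4:8, 1)
    tr <- ltn_tree(ape::rtree(K))
    X <- matrix(rpois(K, 5), 1, dimnames = list(NULL, tr$leaves))
    nct <- aggregate_node_counts(X, tr)
    diffs <- replicate(10, {
      psi <- rnorm(K - 1)
      p <- tlr_inverse(psi, tr)
      dmultinom(X[1, ], prob = p, log = TRUE) -
        ltn_loglik(nct, psi, tr)
    })
    expect_lt(var(diffs), 1e-16)
  }
})

test_that("a degenerate Gaussian reproduces the mean composition", {
  tr <- balanced4()
  X <- sample_ltn_counts(ltn_params(rep(0, 3), diag(1e-12, 3)), tr,
                         totals = 4e6, seed = 33)
  phat <- X[1, ] / sum(X)
  # multinomial MC sd of each component
  mc_sd <- sqrt(0.25 * 0.75 / 4e6)
  expect_true(all(abs(phat - 0.25) < 3 * mc_sd))
})

test_that("zero totals give all-zero rows and seeds give identical output", {
  tr <- random_tree(6, seed = 34)
  prm <- ltn_params(rnorm(5), diag(5))
  X <- sample_ltn_counts(prm, tr, totals = c(0, 100, 0), seed = 35)
  expect_true(all(X[c(1, 3), ] == 0))
  expect_equal(sum(X[2, ]), 100)
  X2 <- sample_ltn_counts(prm, tr, totals = c(0, 100, 0), seed = 35)
  expect_identical(X, X2)
  expect_error(sample_ltn_counts(ltn_params(rep(0, 5), -diag(5)), tr, 10),
               "positive definite")
})

test_that("multinomial and binomial-cascade sampling paths agree in distribution", {
  tr <- random_tree(5, seed = 36)
  prm <- ltn_params(rnorm(4, 0, 0.5), diag(0.3, 4))
  Xa <- sample_ltn_counts(prm, tr, totals = rep(500, 400), seed = 37,
                          method = "multinomial")
  Xb <- sample_ltn_counts(prm, tr, totals = rep(500, 400), seed = 38,
                          method = "binomial")
  pa <- colMeans(Xa / 500)
  pb <- colMeans(Xb / 500)
  se <- sqrt(apply(Xa / 500, 2, var) / 400 + apply(Xb / 500, 2, var) / 400)
  expect_true(all(abs(pa - pb) < 4 * se))
})

test_that("the Gibbs sampler recovers parameters on a small LTN simulation", {
  tr <- random_tree(6, seed = 39)
  mu0 <- c(0.5, -0.5, 1, 0, -1)
  X <- sample_ltn_counts(ltn_params(mu0, diag(0.4, 5)), tr,
                         totals = rep(1000, 150), seed = 40)
  fit <- gibbs_fit_ltn(X, tr, iters = 800, burn = 400, seed = 41)
  psd <- apply(fit$mu, 2, sd)
  expect_true(all(abs(fit$mu_hat - mu0) < 4 * psd))
  # every retained Omega draw positive definite
  pd <- apply(fit$Omega, 3, function(O) {
    all(eigen(O, symmetric = TRUE, only.values = TRUE)$values > 0)
  })
  expect_true(all(pd))
  expect_equal(dim(fit$mu), c(400L, 5L))
})

test_that("the sampler transition kernel preserves the prior (Geweke check)", {
  tr <- ltn_tree("((a,b),(c,d));")
  Om <- diag(3)
  gw <- ltnbayes:::geweke_chain_ltn(tr, rep(30, 20), Om, tau2 = 1,
                                    iters = 5000, seed = 42)
  set.seed(43)
  nf <- 5000
  muf <- matrix(rnorm(nf * 3), nf)
  psif <- muf + matrix(rnorm(nf * 3), nf)
  bm_se <- function(x, nb = 50) {
    b <- colMeans(matrix(x, ncol = nb))
    sd(b) / sqrt(nb)
  }
  for (j in 1:3) {
    z_mu <- (mean(gw$mu[, j]) - mean(muf[, j])) /
      sqrt(bm_se(gw$mu[, j])^2 + var(muf[, j]) / nf)
    z_mu2 <- (mean(gw$mu[, j]^2) - mean(muf[, j]^2)) /
      sqrt(bm_se(gw$mu[, j]^2)^2 + var(muf[, j]^2) / nf)
    z_psi <- (mean(gw$psi[, j]) - mean(psif[, j])) /
      sqrt(bm_se(gw$psi[, j])^2 + var(psif[, j]) / nf)
    expect_lt(max(abs(c(z_mu, z_mu2, z_psi))), 5)
  }
})

test_that("induced clr covariance is near zero for a degenerate model", {
  tr <- random_tree(6, seed = 44)
  cc <- induced_clr_covariance(ltn_params(rnorm(5), diag(1e-12, 5)), tr,
                               n_mc = 2000, seed = 45)
  expect_lt(max(abs(cc)), 1e-6)
})

test_that("induced clr correlation is symmetric with unit diagonal and MC-stable", {
  tr <- random_tree(8, seed = 46)
  prm <- ltn_params(rnorm(7), diag(0.5, 7))
  r1 <- induced_clr_correlation(prm, tr, n_mc = 8000, seed = 47)
  expect_equal(r1, t(r1))
  expect_equal(unname(diag(r1)), rep(1, 8))
  expect_true(all(abs(r1) <= 1 + 1e-12))
  r2 <- induced_clr_correlation(prm, tr, n_mc = 16000, seed = 48)
  # doubling the MC size moves entries by no more than a few MC sds
  expect_lt(max(abs(r1 - r2)), 3 * 3 / sqrt(8000))
})
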