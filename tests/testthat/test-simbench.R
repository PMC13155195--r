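test_that("generated precision matrices are positive definite for all models", {
  for (model in c("hub", "block", "sparse")) {
    for (s in 1:5) {
      Om <- gen_precision(30, model, seed = 100 + s)
      ev <- eigen(Om, symmetric = TRUE, only.values = TRUE)$values
      expect_true(all(ev > 0))
      expect_equal(Om, t(Om))
    }
  }
})

test_that("hub-model edge frequencies match their probabilities", {
  d <- 99
  hub_hits <- 0; hub_tot <- 0; non_hits <- 0; non_tot <- 0
  for (s in 1:30) {
    set.seed(200 + s)
    hubs <- sample.int(d, 3)  # same draw order as the generator
    Om <- gen_precision(d, "hub", seed = 200 + s)
    A <- (Om != 0) & upper.tri(Om)
    is_hub <- seq_len(d) %in% hubs
    hub_pair <- outer(is_hub, is_hub, `|`) & upper.tri(Om)
    hub_hits <- hub_hits + sum(A & hub_pair)
    hub_tot <- hub_tot + sum(hub_pair)
    non_hits <- non_hits + sum(A & !hub_pair & upper.tri(Om))
    non_tot <- non_tot + sum(!hub_pair & upper.tri(Om))
  }
  expect_lt(abs(hub_hits / hub_tot - 0.7), 3 * sqrt(0.7 * 0.3 / hub_tot))
  expect_lt(abs(non_hits / non_tot - 0.2), 3 * sqrt(0.2 * 0.8 / non_tot))
})

test_that("block-model edge frequencies match within and between blocks", {
  d <- 100
  blocks <- sort(rep_len(1:10, d))
  within_pair <- outer(blocks, blocks, `==`) & upper.tri(diag(d))
  win <- c(0, 0); btw <- c(0, 0)
  for (s in 1:20) {
    Om <- gen_precision(d, "block", seed = 300 + s)
    A <- (Om != 0) & upper.tri(Om)
    win <- win + c(sum(A & within_pair), sum(within_pair))
    btw <- btw + c(sum(A & !within_pair & upper.tri(Om)),
                   sum(!within_pair & upper.tri(Om)))
  }
  expect_lt(abs(win[1] / win[2] - 0.5), 3 * sqrt(0.25 / win[2]))
  expect_lt(abs(btw[1] / btw[2] - 0.2), 3 * sqrt(0.16 / btw[2]))
  # nonzero hub/block entries are +/- 0.3
  Om <- gen_precision(50, "block", seed = 321)
  off <- Om[upper.tri(Om)]
  expect_true(all(off %in% c(0, 0.3, -0.3)))
})

test_that("logistic-normal benchmark data are seed-deterministic and calibrated", {
  tr <- random_tree(20, seed = 400)
  Om0 <- diag(19)
  a <- simulate_ln_dataset(tr, Om0, n = 50, total = 1e4, seed = 401,
                           n_mc_truth = 2000)
  b <- simulate_ln_dataset(tr, Om0, n = 50, total = 1e4, seed = 401,
                           n_mc_truth = 2000)
  expect_identical(a$X, b$X)
  expect_equal(a$m, b$m)
  # with identity precision and zero mean, the ilr balances of the observed
  # proportions have near-identity covariance at large depth
  big <- simulate_ln_dataset(tr, Om0, n = 400, total = 1e5, m = rep(0, 19),
                             seed = 402, n_mc_truth = 2000)
  phat <- big$X / rowSums(big$X)
  eta_hat <- ilr(pmax(phat, 1e-12) / rowSums(pmax(phat, 1e-12)), tr)
  C <- cov(eta_hat)
  expect_lt(max(abs(C - diag(19))), 0.35)
  expect_lt(mean(abs(C - diag(19))), 0.05)
})

test_that("Dirichlet-tree data concentrate and match their Beta means", {
  tr <- balanced4()
  X <- simulate_dtm_dataset(tr, mu_A = 0.5, nu_A = 1e6, n = 20,
                            total = 1e6, seed = 403)
  phat <- colMeans(X / rowSums(X))
  expect_lt(max(abs(phat - 0.25)), 0.01)
  # empirical branch frequencies track mu(A)
  mu_A <- c(0.3, 0.6, 0.5)
  X2 <- simulate_dtm_dataset(tr, mu_A = mu_A, nu_A = 20, n = 2000,
                             total = 500, seed = 404)
  nct <- aggregate_node_counts(X2, tr)
  theta_hat <- colSums(nct$y_left) / colSums(nct$y)
  se <- sqrt(mu_A * (1 - mu_A) / (21 * 2000)) * 3  # Beta sampling error bound
  expect_true(all(abs(theta_hat - mu_A) < pmax(3 * se, 0.02)))
})

test_that("signal injection multiplies and rounds only group-1 counts", {
  set.seed(405)
  X <- matrix(rpois(200, 20), 20, 10,
              dimnames = list(NULL, paste0("t", 1:10)))
  g <- rep(c(0L, 1L), 10)
  null_inj <- inject_signal(X, g, K_star = 3, a_star = 0, seed = 406)
  expect_identical(null_inj$X, X)
  inj <- inject_signal(X, g, K_star = 3, a_star = 0.5, seed = 407)
  expect_identical(inj$X[g == 0L, ], X[g == 0L, ])
  expect_equal(unname(inj$X[g == 1L, inj$taxa]),
               unname(round(X[g == 1L, inj$taxa] * 1.5)),
               ignore_attr = TRUE)
  expect_identical(inj$X[g == 1L, -inj$taxa], X[g == 1L, -inj$taxa])
  expect_equal(which(inj$truth), inj$taxa)
  expect_equal(round(10 * 1.5), 15)
  expect_error(inject_signal(X, g, K_star = 50, a_star = 1), "exceeds")
  expect_error(inject_signal(X, rep(0L, 20), 1, 1), "non-empty")
  # the benchmark grid of effect sizes runs cleanly
  for (spec in list(c(1, 0.5), c(1, 2), c(1, 4),
                    c(8, 0.5), c(8, 0.75), c(8, 1))) {
    out <- inject_signal(X, g, K_star = spec[1], a_star = spec[2])
    expect_true(all(out$X == round(out$X)))
    expect_length(out$taxa, spec[1])
  }
})

test_that("matrix losses match hand linear algebra and are symmetric", {
  I2 <- diag(2)
  z <- loss_suite(I2, I2)
  expect_equal(unclass(z)[c("frobenius", "l1", "linf", "spectral")],
               list(frobenius = 0, l1 = 0, linf = 0, spectral = 0))
  est <- matrix(c(1, 0.3, 0.3, 1), 2)
  ls <- loss_suite(est, I2)
  expect_equal(ls$frobenius, sqrt(2 * 0.09), tolerance = 1e-12)
  expect_equal(ls$l1, 0.3, tolerance = 1e-12)
  expect_equal(ls$linf, 0.3)
  expect_equal(ls$spectral, 0.3, tolerance = 1e-12)
  rev <- loss_suite(I2, est)
  expect_equal(unclass(ls), unclass(rev))
  expect_error(loss_suite(diag(2), diag(3)), "dimensions")
})

test_that("zero-proportion statistics count zeros along both axes", {
  X <- matrix(c(0, 2, 1, 0), 2)
  zp <- zero_proportion_stats(X)
  expect_equal(zp$per_otu, c(0.5, 0.5))
  expect_equal(zp$per_sample, c(0.5, 0.5))
  full <- zero_proportion_stats(matrix(1:6, 2))
  expect_true(all(full$per_otu == 0) && all(full$per_sample == 0))
  expect_equal(ks_distance(zp$per_otu, zp$per_otu), 0)
  set.seed(408)
  expect_lte(ks_distance(runif(40), runif(40) + 2), 1)
})

test_that("zero proportions respond monotonically to mean and variance scales", {
  tr <- random_tree(30, seed = 409)
  set.seed(410)
  mu0 <- rnorm(29, 0, 1.2)
  Sig0 <- diag(0.8, 29)
  sw <- sparsity_sweep(mu0, Sig0, mean_scales = c(0.5, 1, 2, 4),
                       var_scales = c(0.5, 1, 2, 4), tree = tr,
                       totals = rep(2000, 60), seed = 411)
  mz <- sw$median_zero_otu[sw$type == "mean"]
  vz <- sw$median_zero_sample[sw$type == "variance"]
  expect_gt(mz[4], mz[1])
  expect_gt(vz[4], vz[1])
  expect_true(all(diff(mz) > -0.05))
  expect_true(all(diff(vz) > -0.05))
})

test_that("the induced node contrast is zero without injection and tracks its sign", {
  tr <- balanced4()
  p0 <- c(0.4, 0.2, 0.3, 0.1)
  expect_equal(unname(induced_node_contrast(tr, p0, taxa = 1, a_star = 0)),
               rep(0, 3))
  dd <- induced_node_contrast(tr, p0, taxa = "u1", a_star = 1)
  expect_gt(dd[1], 0)  # left subtree of the root gains mass
  expect_gt(dd[2], 0)  # u1 gains within its pair
  expect_equal(unname(dd[3]), 0, tolerance = 1e-12)  # u3:u4 ratio unchanged
})

test_that("the synthetic cohort generator is reproducible with balanced groups", {
  tr <- random_tree(12, seed = 412)
  a <- simulate_da_cohort(tr, G = 6, samples_per_subject = 4, seed = 413)
  b <- simulate_da_cohort(tr, G = 6, samples_per_subject = 4, seed = 413)
  expect_identical(a$X, b$X)
  expect_equal(sum(a$design$s), 12L)
  expect_equal(a$design$G, 6L)
  expect_equal(dim(a$X), c(24L, 12L))
})
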