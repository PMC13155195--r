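test_that("global-null prior calibration inverts correctly", {
  expect_equal(select_m_for_global_null(2, 0.5), 0.5)
  set.seed(51)
  for (r in 1:20) {
    K <- sample(2:500, 1)
    p0 <- runif(1, 0.01, 0.99)
    m <- select_m_for_global_null(K, p0)
    expect_equal((1 - m)^(K - 1), p0, tolerance = 1e-12)
  }
  expect_error(select_m_for_global_null(1, 0.5))
  expect_error(select_m_for_global_null(10, 1.2))
})

test_that("PMAP and PJAP count alternative draws", {
  draws <- rbind(c(1, 0), c(0, 0), c(1, 1), c(0, 1))
  expect_equal(compute_pmap(draws), c(0.5, 0.5))
  expect_equal(compute_pjap(draws), 0.75)
  expect_equal(compute_pmap(matrix(0, 5, 3)), rep(0, 3))
  expect_equal(compute_pjap(matrix(0, 5, 3)), 0)
  set.seed(52)
  rnd <- matrix(rbinom(200, 1, 0.3) * rnorm(200), 40, 5)
  expect_gte(compute_pjap(rnd), max(compute_pmap(rnd)))
})

test_that("FDR selection matches hand-enumerated examples", {
  sel <- fdr_select(c(0.99, 0.98, 0.90, 0.60), c = 0.05)
  expect_equal(sel$selected, 1:3)
  expect_equal(sel$threshold, 0.90)
  expect_equal(sel$expected_fdr, (0.01 + 0.02 + 0.10) / 3, tolerance = 1e-12)
  all1 <- fdr_select(rep(1, 6), c = 0.05)
  expect_equal(all1$selected, 1:6)
  expect_equal(all1$expected_fdr, 0)
  none <- fdr_select(0.5, c = 0.05)
  expect_length(none$selected, 0L)
  expect_true(is.na(none$threshold))
})

test_that("nodes tied with the threshold are selected together", {
  pm <- c(0.98, 0.93, 0.93, 0.2)
  sel <- fdr_select(pm, c = 0.06)
  expect_equal(sel$selected, 1:3)
  expect_equal(sel$expected_fdr, mean(1 - pm[1:3]), tolerance = 1e-12)
})

test_that("spike-and-slab inclusion matches direct numerical integration", {
  set.seed(53)
  n <- 30
  s <- rep(c(0L, 1L), each = 15)
  sigma2 <- 0.5
  phi <- 1
  pi_a <- 0.3
  r <- rnorm(n, 0.4 * s, sqrt(sigma2))
  # likelihood ratio slab/spike by quadrature, scaled by the spike
  # likelihood so the integrand is O(1)
  lr <- integrate(function(a) {
    sapply(a, function(ai) {
      exp(sum(dnorm(r, ai * s, sqrt(sigma2), log = TRUE)) -
            sum(dnorm(r, 0, sqrt(sigma2), log = TRUE))) *
        dnorm(ai, 0, 1 / sqrt(phi))
    })
  }, -10, 10, rel.tol = 1e-10)$value
  p_true <- pi_a * lr / (pi_a * lr + (1 - pi_a))
  upd <- ltnbayes:::spike_slab_update(r, s, sigma2, phi, pi_a)
  expect_equal(upd$p_incl, p_true, tolerance = 1e-6)
  inc <- replicate(5000, ltnbayes:::spike_slab_update(r, s, sigma2, phi, pi_a)$incl)
  expect_lt(abs(mean(inc) - p_true), 4 * sqrt(p_true * (1 - p_true) / 5000))
})

test_that("the design constructor validates and inserts an intercept", {
  d <- da_design(c(0, 1, 0, 1), Z = cbind(x = c(1, 2, 3, 4)),
                 g = c("a", "a", "b", "b"))
  expect_equal(d$q, 2L)
  expect_equal(unname(d$Z[, 1]), rep(1, 4))
  expect_equal(d$G, 2L)
  expect_error(da_design(c(0, 2)), "0/1")
  expect_error(da_design(c(0, 1), Z = cbind(a = c(1, 2), b = c(2, 4))),
               "singular")
})

test_that("a strongly differential node reaches high PMAP", {
  tr <- random_tree(8, seed = 54)
  alpha0 <- c(2, rep(0, 6))
  sim <- simulate_da_cohort(tr, G = 20, samples_per_subject = 10,
                            alpha = alpha0, seed = 55)
  fit <- gibbs_fit_da(sim$X, tr, sim$design, m = 0.05,
                      iters = 1000, burn = 500, seed = 56)
  pm <- compute_pmap(fit)
  expect_gt(pm[1], 0.95)
  expect_equal(dim(fit$alpha), c(500L, 7L))
})

test_that("null cohorts keep the PJAP low under global-null calibration", {
  tr <- random_tree(8, seed = 57)
  m0 <- select_m_for_global_null(8, 0.5)
  low <- logical(10)
  for (r in 1:10) {
    sim <- simulate_da_cohort(tr, G = 15, samples_per_subject = 6,
                              seed = 580 + r)
    fit <- gibbs_fit_da(sim$X, tr, sim$design, m = m0,
                        iters = 600, burn = 300, seed = 680 + r)
    low[r] <- compute_pjap(fit) < 0.5
  }
  expect_gte(sum(low), 9L)
})

test_that("a single-subject design warns about weak identification", {
  tr <- ltn_tree("(a,(b,c));")
  set.seed(59)
  X <- matrix(rpois(30, 30), 10, 3, dimnames = list(NULL, tr$leaves))
  des <- da_design(rep(c(0L, 1L), 5))
  expect_warning(
    gibbs_fit_da(X, tr, des, iters = 30, burn = 10, seed = 60),
    "weakly identified")
})

test_that("posterior predictive replicates behave at the degenerate edges", {
  tr <- random_tree(12, seed = 61)
  # shallow sequencing so the tables actually contain zeros
  sim <- simulate_da_cohort(tr, G = 5, samples_per_subject = 4,
                            total_meanlog = log(150), seed = 62)
  fit <- gibbs_fit_da(sim$X, tr, sim$design, iters = 100, burn = 50, seed = 63)
  ppc0 <- posterior_predictive_counts(fit, sim$design,
                                      totals = rep(0, sim$design$n), tr,
                                      n_rep = 5, seed = 64)
  expect_true(all(ppc0$per_otu == 1))
  expect_true(all(ppc0$per_sample == 1))
  # envelope estimates stabilize as replicates accumulate: the seed-to-seed
  # wobble of the envelope limits shrinks with n_rep
  wobble <- function(n_rep, s1, s2) {
    e1 <- posterior_predictive_counts(fit, sim$design, sim$totals, tr,
                                      n_rep = n_rep, seed = s1)$envelope_otu
    e2 <- posterior_predictive_counts(fit, sim$design, sim$totals, tr,
                                      n_rep = n_rep, seed = s2)$envelope_otu
    mean(abs(e1 - e2))
  }
  expect_lt(wobble(300, 65, 66), wobble(15, 67, 68))
})
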