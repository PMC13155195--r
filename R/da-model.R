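#' Design for the mixed-effects differential-abundance model
#'
#' Collects the sample-level design: a binary group indicator `s`, a
#' covariate matrix `Z` (an intercept column is inserted if absent, so the
#' global node means are absorbed into the fixed effects and the group
#' contrast `alpha` is identifiable), and a subject/grouping label `g` for
#' the random effects.
#'
#' @param s Group indicator in `{0, 1}`, length `n`.
#' @param Z Optional `n x q` numeric covariate matrix (or data.frame).
#' @param g Optional subject labels (factor, character or integer), length
#'   `n`; if omitted, all samples share one subject (the random-effect
#'   variance is then weakly identified and a warning is raised at fit
#'   time).
#' @return An object of class `da_design`.
#' @export
da_design <- function(s, Z = NULL, g = NULL) {
  s <- as.integer(s)
  if (!all(s %in% c(0L, 1L))) stop("s must be 0/1", call. = FALSE)
  n <- length(s)
  if (is.null(Z)) {
    Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    Z <- as.matrix(Z)
    storage.mode(Z) <- "double"
    if (nrow(Z) != n) stop("Z must have length(s) rows", call. = FALSE)
    has_intercept <- any(apply(Z, 2L, function(col) all(col == col[1L] & col[1L] != 0)))
    if (!has_intercept) {
      Z <- cbind(`(Intercept)` = 1, Z)
    }
  }
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  ZtZ <- crossprod(Z)
  if (rcond(ZtZ) < 1e-12) {
    stop("Z'Z is (numerically) singular", call. = FALSE)
  }
  if (is.null(g)) g <- rep(1L, n)
  g <- as.integer(factor(g))
  if (length(g) != n) stop("g must have length(s) entries", call. = FALSE)
  structure(list(s = s, Z = Z, g = g, G = max(g), n = n, q = ncol(Z)),
            class = "da_design")
}

#' Prior inclusion probability calibrated to the global null
#'
#' With independent Beta(m, 1 - m) priors on the per-node inclusion
#' probabilities, the prior probability that all `K - 1` node-level nulls
#' hold simultaneously is `(1 - m)^(K-1)`. This returns the `m` that sets
#' that prior global-null probability to `p0_null`:
#' `m = 1 - p0_null^(1/(K-1))`.
#'
#' @param K Number of taxa (so `K - 1` interior-node hypotheses).
#' @param p0_null Desired prior probability of the global null, in (0, 1).
#' @return The scalar `m`.
#' @examples
#' select_m_for_global_null(100, 0.5)  # 0.006977 to 4 s.f.
#' @export
select_m_for_global_null <- function(K, p0_null = 0.5) {
  if (!(K >= 2)) stop("K must be >= 2", call. = FALSE)
  if (!(p0_null > 0 && p0_null < 1)) {
    stop("p0_null must lie in (0, 1)", call. = FALSE)
  }
  1 - p0_null^(1 / (K - 1))
}

# closed-form spike-and-slab update for one node's group contrast.
# residuals r_i ~ N(alpha * s_i, sigma2); slab N(0, 1/phi); returns the
# inclusion probability and a draw of alpha.
spike_slab_update <- function(r, s, sigma2, phi, pi_a) {
  idx <- s == 1L
  n1 <- sum(idx)
  b <- sum(r[idx]) / sigma2
  A <- n1 / sigma2 + phi
  log_odds <- log(pi_a) - log1p(-pi_a) + 0.5 * (log(phi) - log(A)) +
    0.5 * b^2 / A
  p_incl <- stats::plogis(log_odds)
  incl <- stats::runif(1) < p_incl
  alpha <- if (incl) stats::rnorm(1, b / A, sqrt(1 / A)) else 0
  list(alpha = alpha, incl = incl, p_incl = p_incl)
}

#' Fit the LTN mixed-effects differential-abundance model
#'
#' Gibbs sampling for the node-level linear model
#' `psi_i = alpha s_i + beta' z_i + gamma_{g_i} + eps_i`, where `alpha` is
#' the group contrast under a spike-and-slab prior
#' `alpha(A) ~ (1 - pi(A)) delta_0 + pi(A) N(0, 1/phi_alpha)` with
#' `pi(A) ~ Beta(m, 1 - m)` and `phi_alpha ~ Gamma(t, u)`; `beta` has the
#' g-prior-style `N(0, c n (Z'Z)^{-1})` per node; subject random effects
#' `gamma_g ~ MVN(0, Omega_re^{-1})` with a graphical-lasso prior on
#' `Omega_re` (or diagonal when `diagonal_re = TRUE`); and independent node
#' noise `eps_i(A) ~ N(0, sigma2_eps(A))` with inverse-gamma priors. The
#' binomial likelihood is linked to `psi` through Polya-Gamma augmentation
#' exactly as in [gibbs_fit_ltn()].
#'
#' @param X `n x K` count matrix or `node_counts`.
#' @param tree An [ltn_tree()].
#' @param design A [da_design()].
#' @param m Prior inclusion probability per node (e.g. 0.05, or
#'   [select_m_for_global_null()] for global-null testing).
#' @param t,u Gamma(t, u) hyperparameters of the slab precision
#'   `phi_alpha` (defaults 2, 1).
#' @param c_beta Scale of the fixed-effect prior variance `c n (Z'Z)^{-1}`
#'   (default 50).
#' @param lambda Graphical-lasso rate for `Omega_re` (default 10).
#' @param sigma2_shape,sigma2_rate Inverse-gamma hyperparameters of the node
#'   noise variances (defaults 2, 1).
#' @param iters,burn,thin As in [gibbs_fit_ltn()].
#' @param diagonal_re Restrict the random-effect precision to be diagonal.
#' @param keep_psi Store latent `psi` draws.
#' @param seed Optional integer seed.
#' @param verbose Print progress.
#' @return An object of class `ltn_da_fit` holding kept draws of `alpha`
#'   (kept x d), `beta` (q x d x kept), `gamma` (G x d x kept), `sigma2`
#'   (kept x d), `pi`, `phi_alpha`, the posterior mean `Omega_re_hat`, and
#'   `meta`.
#' @export
gibbs_fit_da <- function(X, tree, design, m = 0.05, t = 2, u = 1,
                         c_beta = 50, lambda = 10,
                         sigma2_shape = 2, sigma2_rate = 1,
                         iters = 10000, burn = floor(iters / 2), thin = 1L,
                         diagonal_re = FALSE, keep_psi = FALSE,
                         seed = NULL, verbose = FALSE) {
  stopifnot(inherits(tree, "ltn_tree"), inherits(design, "da_design"))
  if (!(iters > burn && burn >= 0)) stop("need iters > burn >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nct <- if (inherits(X, "node_counts")) X else aggregate_node_counts(X, tree)
  y <- unname(nct$y)
  yl <- unname(nct$y_left)
  n <- nrow(y)
  d <- tree$d
  if (design$n != n) stop("design does not match the count table", call. = FALSE)
  if (design$G == 1L) {
    warning("single subject: random-effect variance is weakly identified")
  }
  s <- design$s
  Z <- design$Z
  g <- design$g
  G <- design$G
  q <- design$q
  kappa <- yl - y / 2
  n_g <- tabulate(g, G)
  ZtZinv <- chol2inv(chol(crossprod(Z)))
  H <- ZtZinv %*% t(Z)               # q x n hat-matrix factor
  Lz <- t(chol(ZtZinv))              # lower Cholesky of (Z'Z)^{-1}
  cn <- c_beta * n

  # initial state
  psi <- qlogis_shrunk(yl, y)
  alpha <- numeric(d)
  incl <- logical(d)
  beta <- matrix(0, q, d)
  gam <- matrix(0, G, d)
  sigma2 <- rep(1, d)
  Omega_re <- diag(d)
  pi_a <- rep(m, d)
  phi <- t / u
  s_col <- matrix(s, n, d)

  keep <- seq.int(burn + 1L, iters, by = thin)
  n_keep <- length(keep)
  alpha_draws <- matrix(NA_real_, n_keep, d)
  beta_draws <- array(NA_real_, c(q, d, n_keep))
  gamma_draws <- array(NA_real_, c(G, d, n_keep))
  sigma2_draws <- matrix(NA_real_, n_keep, d)
  pi_draws <- matrix(NA_real_, n_keep, d)
  phi_draws <- numeric(n_keep)
  psi_draws <- if (keep_psi) array(NA_real_, c(n, d, n_keep)) else NULL
  Omega_re_sum <- matrix(0, d, d)
  k <- 0L
  idx1 <- which(s == 1L)
  n1 <- length(idx1)

  for (it in seq_len(iters)) {
    # (1) PG weights
    w <- .rpg_mat(y, psi)
    # (2) psi | rest: diagonal Gaussian per entry
    mean_lin <- s_col * rep(alpha, each = n) + Z %*% beta + gam[g, , drop = FALSE]
    prec <- w + rep(1 / sigma2, each = n)
    v <- 1 / prec
    psi <- matrix(stats::rnorm(n * d,
                               mean = v * (kappa + mean_lin / rep(sigma2, each = n)),
                               sd = sqrt(v)), n, d)
    # (3) spike-and-slab alpha, vectorized over nodes
    R_a <- psi - Z %*% beta - gam[g, , drop = FALSE]
    b_vec <- colSums(R_a[idx1, , drop = FALSE]) / sigma2
    A_vec <- n1 / sigma2 + phi
    log_odds <- log(pi_a) - log1p(-pi_a) +
      0.5 * (log(phi) - log(A_vec)) + 0.5 * b_vec^2 / A_vec
    incl <- stats::runif(d) < stats::plogis(log_odds)
    alpha <- ifelse(incl,
                    stats::rnorm(d, b_vec / A_vec, sqrt(1 / A_vec)),
                    0)
    # (4) pi(A) | inclusion
    pi_a <- stats::rbeta(d, m + incl, (1 - m) + (!incl))
    # (5) slab precision
    phi <- stats::rgamma(1, t + sum(incl) / 2, rate = u + sum(alpha^2) / 2)
    # (6) beta columns: conjugate Gaussian with prior var c n (Z'Z)^{-1}
    R_b <- psi - s_col * rep(alpha, each = n) - gam[g, , drop = FALSE]
    ols <- H %*% R_b                                    # q x d
    prec_s <- 1 / sigma2 + 1 / cn
    shrink <- (1 / sigma2) / prec_s
    beta <- ols * rep(shrink, each = q) +
      (Lz %*% matrix(stats::rnorm(q * d), q, d)) * rep(1 / sqrt(prec_s), each = q)
    # (7) random effects
    R_g <- psi - s_col * rep(alpha, each = n) - Z %*% beta
    rsum <- rowsum(R_g, g)
    gam <- .gamma_update(Omega_re, sigma2, rsum, n_g)
    # (8) random-effect precision
    S_re <- crossprod(gam)
    Omega_re <- if (diagonal_re) {
      update_omega_diagonal(S_re, G, lambda)
    } else {
      update_omega_glasso(Omega_re, S_re, G, lambda)
    }
    # (9) node noise variances
    E <- R_g - gam[g, , drop = FALSE]
    sigma2 <- 1 / stats::rgamma(d, sigma2_shape + n / 2,
                                rate = sigma2_rate + colSums(E^2) / 2)
    if (it > burn && ((it - burn - 1L) %% thin == 0L)) {
      k <- k + 1L
      alpha_draws[k, ] <- alpha
      beta_draws[, , k] <- beta
      gamma_draws[, , k] <- gam
      sigma2_draws[k, ] <- sigma2
      pi_draws[k, ] <- pi_a
      phi_draws[k] <- phi
      Omega_re_sum <- Omega_re_sum + Omega_re
      if (keep_psi) psi_draws[, , k] <- psi
    }
    if (verbose && it %% max(1L, iters %/% 10L) == 0L) {
      message("iteration ", it, "/", iters)
    }
  }
  structure(
    list(
      alpha = alpha_draws, beta = beta_draws, gamma = gamma_draws,
      sigma2 = sigma2_draws, pi = pi_draws, phi_alpha = phi_draws,
      Omega_re_hat = Omega_re_sum / n_keep, psi = psi_draws,
      node_labels = tree$node_labels,
      meta = list(m = m, t = t, u = u, c_beta = c_beta, lambda = lambda,
                  iters = iters, burn = burn, thin = thin, seed = seed,
                  n = n, d = d, q = q, G = G,
                  diagonal_re = diagonal_re)
    ),
    class = "ltn_da_fit"
  )
}

#' @export
print.ltn_da_fit <- function(x, ...) {
  m <- x$meta
  cat("LTN mixed-effects DA fit:", m$n, "samples,", m$d, "nodes,",
      m$G, "subjects,", m$q, "covariates;", nrow(x$alpha), "kept draws\n")
  cat("  PJAP =", format(compute_pjap(x), digits = 4),
      "; max PMAP =", format(max(compute_pmap(x)), digits = 4), "\n")
  invisible(x)
}

#' Posterior marginal and joint alternative probabilities
#'
#' `compute_pmap()` returns, for each interior node, the posterior
#' probability that its group contrast is nonzero (the fraction of kept
#' draws with `alpha(A) != 0`); `compute_pjap()` returns the posterior
#' probability that any node is differential (the fraction of draws with at
#' least one nonzero `alpha(A)`). PJAP is always at least the largest PMAP.
#'
#' @param fit An `ltn_da_fit` from [gibbs_fit_da()], or a matrix of `alpha`
#'   draws (kept x d).
#' @return `compute_pmap()`: a named `d`-vector; `compute_pjap()`: a scalar.
#' @export
compute_pmap <- function(fit) {
  a <- alpha_draw_matrix(fit)
  pm <- colMeans(a != 0)
  if (inherits(fit, "ltn_da_fit")) names(pm) <- fit$node_labels
  pm
}

#' @rdname compute_pmap
#' @export
compute_pjap <- function(fit) {
  a <- alpha_draw_matrix(fit)
  mean(rowSums(a != 0) > 0)
}

alpha_draw_matrix <- function(fit) {
  a <- if (inherits(fit, "ltn_da_fit")) fit$alpha else as.matrix(fit)
  if (nrow(a) < 1L) stop("need at least one retained draw", call. = FALSE)
  a
}

#' Select differential nodes by posterior expected FDR
#'
#' Thresholds the PMAPs so that the posterior expected false discovery rate
#' — the average of `1 - PMAP` over the reported nodes — is at most `c`.
#' All thresholds of the form "report every node with PMAP >= t" are
#' scanned and the largest feasible reported set is returned (ties with the
#' threshold are always reported together). With distinct PMAPs this is the
#' usual rule: sort `p_1 >= ... >= p_d` and take
#' `k = max{k : (1/k) sum_{i<=k} (1 - p_i) <= c}`.
#'
#' @param pmap Vector of posterior marginal alternative probabilities.
#' @param c Target posterior expected FDR, in (0, 1).
#' @return An object of class `da_selection`: `selected` (indices into
#'   `pmap`), `threshold` (the PMAP cutoff, `NA` if nothing is selectable),
#'   `expected_fdr` (the attained posterior expected FDR), `target_fdr`,
#'   and the input `pmap`.
#' @examples
#' fdr_select(c(0.99, 0.98, 0.90, 0.60), c = 0.05)  # selects the top 3
#' @export
fdr_select <- function(pmap, c = 0.05) {
  if (!(c > 0 && c < 1)) stop("c must lie in (0, 1)", call. = FALSE)
  if (any(pmap < 0 | pmap > 1)) stop("pmap must lie in [0, 1]", call. = FALSE)
  thr <- sort(unique(pmap), decreasing = TRUE)
  best <- NULL
  for (t in thr) {
    sel <- which(pmap >= t)
    efdr <- mean(1 - pmap[sel])
    if (efdr <= c && (is.null(best) || length(sel) > length(best$sel))) {
      best <- list(sel = sel, thr = t, efdr = efdr)
    }
  }
  structure(
    list(
      selected = if (is.null(best)) integer(0) else best$sel,
      threshold = if (is.null(best)) NA_real_ else best$thr,
      expected_fdr = if (is.null(best)) NA_real_ else best$efdr,
      target_fdr = c,
      pmap = pmap
    ),
    class = "da_selection"
  )
}

#' @export
print.da_selection <- function(x, ...) {
  cat("posterior expected FDR selection at c =", x$target_fdr, "\n")
  if (length(x$selected) == 0L) {
    cat("  no nodes selected\n")
  } else {
    cat("  ", length(x$selected), "nodes selected (PMAP >=",
        format(x$threshold, digits = 4), "), attained expected FDR",
        format(x$expected_fdr, digits = 4), "\n")
  }
  invisible(x)
}

#' Summarize a differential-abundance fit
#'
#' Per-node table (node label, descendant-leaf count, PMAP, posterior mean
#' of `alpha` and its sign: "+" means the left child gained relative
#' abundance in group 1) plus the PJAP and the FDR-selected node set.
#'
#' @param object An `ltn_da_fit`.
#' @param tree The [ltn_tree()] used for the fit.
#' @param target_fdr Posterior expected FDR level for node selection.
#' @param ... Unused.
#' @return A list of class `da_summary`: `nodes` (data.frame), `pjap`,
#'   `selection` (a `da_selection`).
#' @export
summary.ltn_da_fit <- function(object, tree = NULL, target_fdr = 0.05, ...) {
  pmap <- compute_pmap(object)
  sel <- fdr_select(pmap, target_fdr)
  amean <- colMeans(object$alpha)
  nodes <- data.frame(
    node = object$node_labels,
    n_leaves = if (!is.null(tree)) colSums(tree$in_leaf) else NA_integer_,
    pmap = as.numeric(pmap),
    alpha_mean = amean,
    sign = ifelse(amean > 0, "+", ifelse(amean < 0, "-", "")),
    selected = seq_along(pmap) %in% sel$selected
  )
  structure(list(nodes = nodes, pjap = compute_pjap(object), selection = sel),
            class = "da_summary")
}

#' @export
print.da_summary <- function(x, ...) {
  cat("PJAP:", format(x$pjap, digits = 4), "\n")
  print(x$selection)
  top <- x$nodes[order(-x$nodes$pmap), ][seq_len(min(10L, nrow(x$nodes))), ]
  cat("top nodes by PMAP:\n")
  print(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Posterior predictive count replicates and zero-proportion envelopes
#'
#' Generates `n_rep` replicated count tables from the posterior predictive
#' distribution of a fitted mixed-effects model: for each replicate a
#' retained draw is selected, node log-odds are formed as
#' `alpha s_i + beta' z_i + gamma_{g_i}` plus fresh `N(0, sigma2_eps)`
#' noise, mapped through [tlr_inverse()], and counts drawn as multinomials
#' with the observed per-sample totals. Returns 95% envelopes for the
#' per-OTU and per-sample zero proportions, and, when the observed table is
#' supplied, the fraction of observed zero proportions covered.
#'
#' @param fit An `ltn_da_fit`.
#' @param design The [da_design()] used for the fit.
#' @param totals Per-sample totals to condition on.
#' @param tree The [ltn_tree()].
#' @param n_rep Number of posterior predictive replicates (default 500).
#' @param seed Optional integer seed.
#' @param X_obs Optional observed count matrix for coverage assessment.
#' @return A list of class `ltn_ppc`: `per_otu` and `per_sample`
#'   (`n_rep x K` / `n_rep x n` zero-proportion matrices), the 95%
#'   `envelope_otu` / `envelope_sample` (2-row matrices of limits), and
#'   `coverage_otu` / `coverage_sample` if `X_obs` was given.
#' @export
posterior_predictive_counts <- function(fit, design, totals, tree,
                                        n_rep = 500, seed = NULL,
                                        X_obs = NULL) {
  stopifnot(inherits(fit, "ltn_da_fit"), inherits(design, "da_design"),
            n_rep >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- design$n
  d <- fit$meta$d
  n_keep <- nrow(fit$alpha)
  zp_otu <- matrix(NA_real_, n_rep, tree$K)
  zp_sample <- matrix(NA_real_, n_rep, n)
  s_col <- matrix(design$s, n, d)
  for (r in seq_len(n_rep)) {
    kdraw <- sample.int(n_keep, 1L)
    beta_k <- matrix(fit$beta[, , kdraw], nrow = fit$meta$q)
    gamma_k <- matrix(fit$gamma[, , kdraw], nrow = fit$meta$G)
    mean_lin <- s_col * rep(fit$alpha[kdraw, ], each = n) +
      design$Z %*% beta_k +
      gamma_k[design$g, , drop = FALSE]
    psi <- mean_lin + matrix(stats::rnorm(n * d,
                                          sd = rep(sqrt(fit$sigma2[kdraw, ]), each = n)),
                             n, d)
    p <- tlr_inverse(psi, tree)
    if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
    Xr <- matrix(0L, n, tree$K)
    for (i in seq_len(n)) {
      if (totals[i] > 0) Xr[i, ] <- stats::rmultinom(1L, totals[i], p[i, ])
    }
    zp_otu[r, ] <- colMeans(Xr == 0)
    zp_sample[r, ] <- rowMeans(Xr == 0)
  }
  env_otu <- apply(zp_otu, 2L, stats::quantile, probs = c(0.025, 0.975))
  env_sample <- apply(zp_sample, 2L, stats::quantile, probs = c(0.025, 0.975))
  out <- list(per_otu = zp_otu, per_sample = zp_sample,
              envelope_otu = env_otu, envelope_sample = env_sample)
  if (!is.null(X_obs)) {
    X_obs <- as_count_matrix(X_obs, tree)
    obs_otu <- colMeans(X_obs == 0)
    obs_sample <- rowMeans(X_obs == 0)
    out$coverage_otu <- mean(obs_otu >= env_otu[1L, ] & obs_otu <= env_otu[2L, ])
    out$coverage_sample <- mean(obs_sample >= env_sample[1L, ] &
                                  obs_sample <= env_sample[2L, ])
    out$observed_otu <- obs_otu
    out$observed_sample <- obs_sample
  }
  structure(out, class = "ltn_ppc")
}

#' @export
print.ltn_ppc <- function(x, ...) {
  cat("posterior predictive zero-proportion check,", nrow(x$per_otu),
      "replicates\n")
  if (!is.null(x$coverage_otu)) {
    cat("  95% envelope coverage: per-OTU", format(x$coverage_otu, digits = 3),
        ", per-sample", format(x$coverage_sample, digits = 3), "\n")
  }
  invisible(x)
}
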