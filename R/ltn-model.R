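#' Logistic-tree normal model parameters
#'
#' Bundles the latent-Gaussian parameters of an LTN(mu, Sigma) model: the
#' mean and covariance of the `d = K - 1` node log-odds `psi`.
#'
#' @param mu Mean `d`-vector of the node log-odds.
#' @param Sigma `d x d` symmetric positive definite covariance matrix.
#' @return An object of class `ltn_params`.
#' @export
ltn_params <- function(mu, Sigma) {
  mu <- as.numeric(mu)
  Sigma <- as.matrix(Sigma)
  d <- length(mu)
  if (!all(dim(Sigma) == d)) {
    stop("Sigma must be ", d, " x ", d, call. = FALSE)
  }
  if (max(abs(Sigma - t(Sigma))) > 1e-8) {
    stop("Sigma must be symmetric", call. = FALSE)
  }
  structure(list(mu = mu, Sigma = Sigma), class = "ltn_params")
}

#' Simulate count tables from an LTN model
#'
#' For each sample, draws node log-odds `psi ~ MVN(mu, Sigma)`, maps them to
#' a composition with [tlr_inverse()], and draws counts. Two equivalent
#' sampling paths are provided: a single multinomial draw given the
#' composition, or sequential binomial splitting down the tree
#' (`y(A_l) | y(A) ~ Bin(y(A), theta(A))`); they generate from the same
#' distribution.
#'
#' @param params An [ltn_params()] object.
#' @param tree An [ltn_tree()].
#' @param totals Integer vector of per-sample sequencing depths `N_i`.
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @param method `"multinomial"` or `"binomial"` sampling path.
#' @return An `n x K` count matrix with taxon column names.
#' @export
sample_ltn_counts <- function(params, tree, totals, seed = NULL,
                              method = c("multinomial", "binomial")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(params, "ltn_params"), inherits(tree, "ltn_tree"))
  if (length(params$mu) != tree$d) {
    stop("params dimension does not match tree", call. = FALSE)
  }
  totals <- as.numeric(totals)
  if (any(totals < 0) || any(abs(totals - round(totals)) > 1e-8)) {
    stop("totals must be non-negative integers", call. = FALSE)
  }
  n <- length(totals)
  psi <- rmvnorm_chol(n, params$mu, params$Sigma)
  if (method == "multinomial") {
    p <- tlr_inverse(psi, tree)
    if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
    X <- matrix(0L, n, tree$K)
    for (i in seq_len(n)) {
      if (totals[i] > 0) X[i, ] <- stats::rmultinom(1L, totals[i], p[i, ])
    }
  } else {
    X <- binomial_cascade(psi, tree, totals)
  }
  colnames(X) <- tree$leaves
  X
}

# sequential binomial splitting in node preorder: parents precede children,
# so y(A) is known before A is split
binomial_cascade <- function(psi, tree, totals) {
  if (!is.matrix(psi)) psi <- matrix(psi, nrow = 1L)
  n <- nrow(psi)
  theta <- stats::plogis(psi)
  ynode <- matrix(0, n, tree$d)
  X <- matrix(0L, n, tree$K)
  ynode[, 1L] <- totals
  for (a in seq_len(tree$d)) {
    yl <- stats::rbinom(n, ynode[, a], theta[, a])
    yr <- ynode[, a] - yl
    cl <- tree$child_left[a]
    cr <- tree$child_right[a]
    if (cl > 0) ynode[, cl] <- yl else X[, -cl] <- yl
    if (cr > 0) ynode[, cr] <- yr else X[, -cr] <- yr
  }
  X
}

rmvnorm_chol <- function(n, mu, Sigma) {
  d <- length(mu)
  R <- tryCatch(chol(Sigma), error = function(e) {
    stop("Sigma is not positive definite", call. = FALSE)
  })
  matrix(stats::rnorm(n * d), n, d) %*% R +
    matrix(mu, n, d, byrow = TRUE)
}

#' Tree-factorized binomial log-likelihood
#'
#' The log-likelihood of node log-odds under the binomial decomposition of
#' the multinomial: `sum_i sum_A log Bin(y_i(A_l) | y_i(A),
#' plogis(psi_i(A)))`. It differs from the multinomial log-pmf only by the
#' log ratio of the multinomial to the product-binomial coefficients, a
#' constant in `psi`. Nodes with `y_i(A) = 0` contribute exactly zero.
#'
#' @param nct A `node_counts` object from [aggregate_node_counts()].
#' @param psi An `n x d` matrix (or `d`-vector for a single sample) of node
#'   log-odds.
#' @param tree An [ltn_tree()].
#' @return The scalar log-likelihood.
#' @export
ltn_loglik <- function(nct, psi, tree) {
  stopifnot(inherits(nct, "node_counts"))
  Psi <- as_node_matrix(psi, tree)
  if (!all(dim(Psi) == dim(nct$y))) {
    stop("psi and node counts have mismatched shapes", call. = FALSE)
  }
  sum(stats::dbinom(nct$y_left, nct$y, stats::plogis(Psi), log = TRUE))
}

#' Fit the base LTN model by blocked Gibbs sampling
#'
#' Posterior sampling for LTN(mu, Sigma) with a graphical-lasso prior on the
#' precision matrix `Omega = Sigma^{-1}` (double-exponential rate `lambda`
#' off the diagonal, exponential rate `lambda/2` on it) and an
#' MVN(0, tau2 I) prior on `mu`. Conjugacy is restored by Polya-Gamma
#' augmentation: each Gibbs cycle draws (1) the PG weights
#' `w_i(A) | psi ~ PG(y_i(A), psi_i(A))`; (2) `psi_i | rest`, a
#' d-dimensional Gaussian with precision `Omega + diag(w_i)` and linear term
#' `Omega mu + kappa_i` where `kappa_i(A) = y_i(A_l) - y_i(A)/2`; (3)
#' `mu | rest`, conjugate Gaussian; (4) `Omega | psi` by column-wise blocked
#' Gibbs for the graphical lasso (or a gamma draw per diagonal entry when
#' `diagonal_precision = TRUE`, the proxy for the Dirichlet-tree
#' multinomial's independence assumption). Nodes with `y_i(A) = 0` carry no
#' likelihood (`PG(0, .)` is a point mass at zero) and the corresponding
#' `psi_i(A)` is drawn from its conditional Gaussian prior.
#'
#' @param X `n x K` count matrix (columns named by taxon, matching the
#'   tree), or a `node_counts` object.
#' @param tree An [ltn_tree()].
#' @param lambda Graphical-lasso rate; default 10.
#' @param iters,burn Total Gibbs iterations and burn-in discarded
#'   (defaults 10000 / 5000).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param tau2 Prior variance of each component of `mu` (default 100).
#' @param diagonal_precision If `TRUE`, restrict `Omega` to be diagonal.
#' @param fix_omega Optional known precision matrix; when given, `Omega` is
#'   held fixed at this value and only `mu` and the latent `psi` are
#'   sampled.
#' @param keep_psi If `TRUE`, store the latent `psi` draws (memory guard:
#'   `n x d x` kept iterations).
#' @param seed Optional integer seed.
#' @param verbose Print progress every 10% of iterations.
#' @return An object of class `ltn_fit` with elements `mu` (kept x d draws),
#'   `Omega` (d x d x kept array), optional `psi`, posterior means
#'   `mu_hat`/`Sigma_hat`, and a `meta` list (lambda, iters, burn, thin,
#'   seed, dimensions).
#' @export
gibbs_fit_ltn <- function(X, tree, lambda = 10, iters = 10000,
                          burn = floor(iters / 2), thin = 1L, tau2 = 100,
                          diagonal_precision = FALSE, fix_omega = NULL,
                          keep_psi = FALSE,
                          seed = NULL, verbose = FALSE) {
  stopifnot(inherits(tree, "ltn_tree"))
  if (!(iters > burn && burn >= 0)) {
    stop("need iters > burn >= 0", call. = FALSE)
  }
  if (tree$d < 1L) stop("tree has no interior nodes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nct <- if (inherits(X, "node_counts")) X else aggregate_node_counts(X, tree)
  y <- unname(nct$y)
  yl <- unname(nct$y_left)
  n <- nrow(y)
  d <- tree$d
  kappa <- yl - y / 2

  # initialize at empirical log-odds
  psi <- qlogis_shrunk(yl, y)
  mu <- colMeans(psi)
  Omega <- if (is.null(fix_omega)) diag(d) else as.matrix(fix_omega)
  keep <- seq.int(burn + 1L, iters, by = thin)
  n_keep <- length(keep)
  mu_draws <- matrix(NA_real_, n_keep, d)
  Omega_draws <- array(NA_real_, c(d, d, n_keep))
  psi_draws <- if (keep_psi) array(NA_real_, c(n, d, n_keep)) else NULL
  Sigma_sum <- matrix(0, d, d)
  k <- 0L
  for (it in seq_len(iters)) {
    w <- .rpg_mat(y, psi)
    psi <- .psi_update_dense(Omega, mu, kappa, w)
    mu <- update_mu(psi, Omega, tau2)
    if (is.null(fix_omega)) {
      S <- crossprod(sweep(psi, 2L, mu))
      Omega <- if (diagonal_precision) {
        update_omega_diagonal(S, n, lambda)
      } else {
        update_omega_glasso(Omega, S, n, lambda)
      }
    }
    if (it > burn && ((it - burn - 1L) %% thin == 0L)) {
      k <- k + 1L
      mu_draws[k, ] <- mu
      Omega_draws[, , k] <- Omega
      Sigma_sum <- Sigma_sum + chol2inv(chol(Omega))
      if (keep_psi) psi_draws[, , k] <- psi
    }
    if (verbose && it %% max(1L, iters %/% 10L) == 0L) {
      message("iteration ", it, "/", iters)
    }
  }
  structure(
    list(
      mu = mu_draws, Omega = Omega_draws, psi = psi_draws,
      mu_hat = colMeans(mu_draws), Sigma_hat = Sigma_sum / n_keep,
      node_labels = tree$node_labels,
      meta = list(lambda = lambda, iters = iters, burn = burn, thin = thin,
                  tau2 = tau2, seed = seed, n = n, d = d,
                  diagonal_precision = diagonal_precision)
    ),
    class = "ltn_fit"
  )
}

#' @export
print.ltn_fit <- function(x, ...) {
  m <- x$meta
  cat("LTN fit:", m$n, "samples,", m$d, "nodes;",
      nrow(x$mu), "kept draws (", m$iters, "iterations,", m$burn,
      "burn-in ), lambda =", m$lambda, "\n")
  invisible(x)
}

# empirical logit with a half-count shrink; defined even when y = 0
qlogis_shrunk <- function(yl, y) {
  stats::qlogis((yl + 0.5) / (y + 1))
}

# mu | psi, Omega: precision n Omega + I/tau2, linear term Omega colSums(psi)
update_mu <- function(psi, Omega, tau2) {
  n <- nrow(psi)
  d <- ncol(psi)
  P_mu <- n * Omega + diag(1 / tau2, d)
  h_mu <- Omega %*% colSums(psi)
  R <- chol(P_mu)
  m <- backsolve(R, forwardsolve(t(R), h_mu))
  drop(m + backsolve(R, stats::rnorm(d)))
}

# Geweke-style successive-conditional simulator for the fixed-Omega LTN
# sampler: alternates the sampler's own parameter updates with re-simulation
# of the counts given the current latent log-odds. If the transition kernel
# is correct, the chain's marginal law of (mu, psi) equals the forward
# (prior-predictive) law.
geweke_chain_ltn <- function(tree, totals, Omega, tau2, iters, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- tree$d
  n <- length(totals)
  Sigma <- chol2inv(chol(Omega))
  mu <- stats::rnorm(d, 0, sqrt(tau2))
  psi <- rmvnorm_chol(n, mu, Sigma)
  mu_draws <- matrix(NA_real_, iters, d)
  psi_draws <- matrix(NA_real_, iters, d)  # first sample's psi row
  for (it in seq_len(iters)) {
    X <- binomial_cascade(psi, tree, totals)
    colnames(X) <- tree$leaves
    nct <- aggregate_node_counts(X, tree)
    y <- unname(nct$y)
    kappa <- unname(nct$y_left) - y / 2
    w <- .rpg_mat(y, psi)
    psi <- .psi_update_dense(Omega, mu, kappa, w)
    mu <- update_mu(psi, Omega, tau2)
    mu_draws[it, ] <- mu
    psi_draws[it, ] <- psi[1L, ]
  }
  list(mu = mu_draws, psi = psi_draws)
}

#' Induced clr correlation matrix of an LTN model
#'
#' The LTN model is generative, so the correlation structure it induces on
#' any other log-ratio coordinate system can be computed by Monte Carlo:
#' draw latent log-odds `psi ~ MVN(mu, Sigma)`, apply the inverse tlr
#' transform to obtain compositions, apply the clr transform, and take the
#' sample correlation. For an `ltn_fit`, the posterior means `mu_hat` and
#' `Sigma_hat` are used as the generative parameters.
#'
#' @param object An [ltn_params()] or `ltn_fit`.
#' @param tree An [ltn_tree()].
#' @param n_mc Number of Monte Carlo draws (default 10000).
#' @param seed Optional integer seed.
#' @return A symmetric `K x K` correlation matrix with unit diagonal.
#' @export
induced_clr_correlation <- function(object, tree, n_mc = 10000, seed = NULL) {
  stopifnot(inherits(tree, "ltn_tree"), n_mc >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(object, "ltn_fit")) {
    mu <- object$mu_hat
    Sigma <- object$Sigma_hat
  } else if (inherits(object, "ltn_params")) {
    mu <- object$mu
    Sigma <- object$Sigma
  } else {
    stop("object must be an ltn_params or ltn_fit", call. = FALSE)
  }
  psi <- rmvnorm_chol(n_mc, mu, Sigma)
  p <- tlr_inverse(psi, tree)
  z <- clr(p)
  cc <- stats::cov(z)
  # degenerate covariance (e.g. Sigma ~ 0) would make cov2cor blow up
  sd0 <- sqrt(diag(cc)) < 1e-12
  if (any(sd0)) {
    cr <- diag(1, tree$K)
    ok <- !sd0
    cr[ok, ok] <- stats::cov2cor(cc[ok, ok, drop = FALSE])
  } else {
    cr <- stats::cov2cor(cc)
  }
  dimnames(cr) <- list(tree$leaves, tree$leaves)
  cr
}

#' Induced clr covariance matrix (Monte Carlo)
#'
#' Same Monte Carlo scheme as [induced_clr_correlation()] but returning the
#' covariance rather than the correlation.
#'
#' @inheritParams induced_clr_correlation
#' @return A symmetric `K x K` covariance matrix.
#' @export
induced_clr_covariance <- function(object, tree, n_mc = 10000, seed = NULL) {
  stopifnot(inherits(tree, "ltn_tree"), n_mc >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(object, "ltn_fit")) {
    mu <- object$mu_hat
    Sigma <- object$Sigma_hat
  } else {
    mu <- object$mu
    Sigma <- object$Sigma
  }
  psi <- rmvnorm_chol(n_mc, mu, Sigma)
  stats::cov(clr(tlr_inverse(psi, tree)))
}
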