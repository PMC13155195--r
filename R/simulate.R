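#' Generate sparse ground-truth precision matrices
#'
#' Random symmetric positive definite precision matrices under three sparse
#' network models commonly used to emulate microbiome covariance:
#' \describe{
#'   \item{hub}{`hub_count` randomly chosen hub coordinates connect to each
#'     other coordinate with probability `p_hub` (default 0.7); non-hub
#'     pairs connect with probability `p_nonhub` (0.2). Nonzero entries are
#'     `+edge_mag` or `-edge_mag` with equal probability.}
#'   \item{block}{coordinates are split into `block_count` (near-)equal
#'     blocks; within-block pairs connect with probability `p_within`
#'     (0.5), between-block pairs with `p_between` (0.2); entries again
#'     `+/- edge_mag`.}
#'   \item{sparse}{a dense-corner model: the leading `p1` coordinates get a
#'     symmetric matrix with entries `U 1{V < sparse_thresh}`,
#'     `U ~ Unif([-1,-0.5] U [0.5,1])`, `V ~ Unif(0,1)`; the remaining
#'     `d - p1` coordinates are an identity block.}
#' }
#' Positive definiteness is enforced by strict diagonal dominance: each
#' diagonal entry is the row sum of absolute off-diagonals plus `diag_pad`.
#'
#' @param d Dimension (number of tree nodes the Gaussian lives on).
#' @param model One of `"hub"`, `"block"`, `"sparse"`.
#' @param seed Optional integer seed.
#' @param edge_mag Magnitude of hub/block nonzero entries (default 0.3).
#' @param hub_count,p_hub,p_nonhub Hub-model parameters.
#' @param block_count,p_within,p_between Block-model parameters.
#' @param sparse_p1,sparse_thresh Sparse-model parameters; `sparse_p1`
#'   defaults to `floor(3 * sqrt(d))`.
#' @param diag_pad Slack added to the dominant diagonal (default 0.1).
#' @return A `d x d` symmetric positive definite matrix.
#' @export
gen_precision <- function(d, model = c("hub", "block", "sparse"),
                          seed = NULL, edge_mag = 0.3,
                          hub_count = 3, p_hub = 0.7, p_nonhub = 0.2,
                          block_count = 10, p_within = 0.5, p_between = 0.2,
                          sparse_p1 = floor(3 * sqrt(d)), sparse_thresh = 0.3,
                          diag_pad = 0.1) {
  model <- match.arg(model)
  if (d < 2) stop("d must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Omega <- matrix(0, d, d)
  if (model == "hub") {
    hubs <- sample.int(d, hub_count)
    is_hub <- seq_len(d) %in% hubs
    for (j in seq_len(d - 1)) {
      for (k in seq.int(j + 1, d)) {
        pr <- if (is_hub[j] || is_hub[k]) p_hub else p_nonhub
        if (stats::runif(1) < pr) {
          Omega[j, k] <- Omega[k, j] <- sample(c(-1, 1), 1) * edge_mag
        }
      }
    }
  } else if (model == "block") {
    blocks <- sort(rep_len(seq_len(block_count), d))
    for (j in seq_len(d - 1)) {
      for (k in seq.int(j + 1, d)) {
        pr <- if (blocks[j] == blocks[k]) p_within else p_between
        if (stats::runif(1) < pr) {
          Omega[j, k] <- Omega[k, j] <- sample(c(-1, 1), 1) * edge_mag
        }
      }
    }
  } else {
    p1 <- min(max(2L, as.integer(sparse_p1)), d)
    for (j in seq_len(p1 - 1)) {
      for (k in seq.int(j + 1, p1)) {
        if (stats::runif(1) < sparse_thresh) {
          Omega[j, k] <- Omega[k, j] <-
            sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1)
        }
      }
    }
    if (p1 < d) diag(Omega)[seq.int(p1 + 1, d)] <- 1 - diag_pad  # identity block
  }
  diag(Omega) <- rowSums(abs(Omega)) - abs(diag(Omega)) + diag_pad +
    diag(Omega)
  Omega
}

#' Simulate logistic-normal multinomial benchmark data
#'
#' Draws `n` samples from the ilr-based logistic-normal model: balances
#' `eta_i ~ MVN(m, Omega0^{-1})`, compositions `p_i = ilr_inverse(eta_i)`,
#' counts `X_i ~ Multinomial(total, p_i)`. The components of `m` default to
#' independent `N(0, 16)` draws. The clr correlation matrix induced by the
#' generating law is computed by a large Monte Carlo sample and returned as
#' the ground truth for loss evaluation.
#'
#' @param tree An [ltn_tree()].
#' @param Omega0 `d x d` positive definite precision matrix of the
#'   balances (e.g. from [gen_precision()]).
#' @param n Number of samples (default 200).
#' @param total Sequencing depth per sample (default `1e5`).
#' @param m Optional mean `d`-vector; drawn as `N(0, 16)` if `NULL`.
#' @param seed Optional integer seed.
#' @param n_mc_truth Monte Carlo size for the ground-truth clr correlation.
#' @return A list: `X` (counts), `m`, `Omega0`, `clr_cor_true`.
#' @export
simulate_ln_dataset <- function(tree, Omega0, n = 200, total = 1e5,
                                m = NULL, seed = NULL, n_mc_truth = 2e4) {
  stopifnot(inherits(tree, "ltn_tree"))
  if (!is.null(seed)) set.seed(seed)
  d <- tree$d
  if (!all(dim(Omega0) == d)) stop("Omega0 must be d x d", call. = FALSE)
  if (is.null(m)) m <- stats::rnorm(d, 0, 4)
  Sigma0 <- chol2inv(chol(Omega0))
  Sigma0 <- (Sigma0 + t(Sigma0)) / 2
  eta <- rmvnorm_chol(n, m, Sigma0)
  p <- ilr_inverse(eta, tree)
  if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
  X <- matrix(0L, n, tree$K)
  for (i in seq_len(n)) X[i, ] <- stats::rmultinom(1L, total, p[i, ])
  colnames(X) <- tree$leaves
  eta_mc <- rmvnorm_chol(n_mc_truth, m, Sigma0)
  clr_true <- stats::cov2cor(stats::cov(clr(ilr_inverse(eta_mc, tree))))
  list(X = X, m = m, Omega0 = Omega0, clr_cor_true = clr_true)
}

#' Simulate Dirichlet-tree multinomial benchmark data
#'
#' Each sample draws independent Beta branch probabilities
#' `theta(A) ~ Beta(mu(A) nu(A), (1 - mu(A)) nu(A))` at every interior
#' node, forms the composition as the product of branch probabilities down
#' the tree, and draws multinomial counts. The independence of the branch
#' draws is the restrictive covariance assumption that the logistic-tree
#' normal model relaxes; this generator serves as a misspecification
#' stressor.
#'
#' @param tree An [ltn_tree()].
#' @param mu_A Beta mean `d`-vector with entries in (0, 1).
#' @param nu_A Concentration `d`-vector, positive.
#' @param n Number of samples.
#' @param total Sequencing depth per sample.
#' @param seed Optional integer seed.
#' @return An `n x K` count matrix.
#' @export
simulate_dtm_dataset <- function(tree, mu_A, nu_A, n, total, seed = NULL) {
  stopifnot(inherits(tree, "ltn_tree"))
  if (!is.null(seed)) set.seed(seed)
  d <- tree$d
  mu_A <- rep_len(mu_A, d)
  nu_A <- rep_len(nu_A, d)
  if (any(mu_A <= 0 | mu_A >= 1)) stop("mu_A must lie in (0, 1)", call. = FALSE)
  if (any(nu_A <= 0)) stop("nu_A must be positive", call. = FALSE)
  theta <- matrix(stats::rbeta(n * d, rep(mu_A * nu_A, each = n),
                               rep((1 - mu_A) * nu_A, each = n)), n, d)
  theta <- pmin(pmax(theta, 1e-12), 1 - 1e-12)
  psi <- stats::qlogis(theta)
  p <- tlr_inverse(psi, tree)
  if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
  X <- matrix(0L, n, tree$K)
  for (i in seq_len(n)) X[i, ] <- stats::rmultinom(1L, total, p[i, ])
  colnames(X) <- tree$leaves
  X
}

#' Inject differential-abundance signal into a count table
#'
#' Multiplies the counts of `K_star` randomly chosen candidate taxa by
#' `(1 + a_star)` in the rows of group 1, rounding to the nearest integer;
#' group-0 rows are untouched. By default the candidate pool is the 20 taxa
#' with the highest average per-sample relative abundance.
#'
#' @param X `n x K` count matrix.
#' @param groups 0/1 group labels, length `n`; group 1 receives the signal.
#' @param K_star Number of taxa to perturb.
#' @param a_star Effect size (multiplier is `1 + a_star`); `a_star = 0`
#'   leaves `X` unchanged.
#' @param candidate_taxa Optional candidate column indices or names;
#'   defaults to the top 20 by mean relative abundance.
#' @param seed Optional integer seed.
#' @return A list: `X` (modified counts), `taxa` (chosen column indices),
#'   `truth` (logical `K`-vector marking injected taxa).
#' @export
inject_signal <- function(X, groups, K_star, a_star, candidate_taxa = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- as.integer(groups)
  if (length(groups) != nrow(X)) stop("groups must match rows of X", call. = FALSE)
  if (!any(groups == 1L) || !any(groups == 0L)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (a_star < 0) stop("a_star must be >= 0", call. = FALSE)
  if (is.null(candidate_taxa)) {
    rel <- X / pmax(rowSums(X), 1)
    candidate_taxa <- order(colMeans(rel), decreasing = TRUE)[
      seq_len(min(20L, ncol(X)))]
  } else if (is.character(candidate_taxa)) {
    candidate_taxa <- match(candidate_taxa, colnames(X))
  }
  if (K_star > length(candidate_taxa)) {
    stop("K_star exceeds the number of candidate taxa", call. = FALSE)
  }
  taxa <- sample(candidate_taxa, K_star)
  X2 <- X
  X2[groups == 1L, taxa] <- round(X[groups == 1L, taxa, drop = FALSE] *
                                    (1 + a_star))
  if (is.integer(X)) storage.mode(X2) <- "integer"
  truth <- rep(FALSE, ncol(X))
  truth[taxa] <- TRUE
  list(X = X2, taxa = sort(taxa), truth = truth)
}

#' Simulate a longitudinal cohort from the LTN mixed-effects model
#'
#' A self-contained synthetic stand-in for a longitudinal 16S cohort:
#' `G` subjects each contribute `samples_per_subject` samples; node
#' log-odds follow `psi_i = mu + alpha s_i + gamma_{g_i} + eps_i` with
#' subject effects `gamma_g ~ MVN(0, sigma_re^2 I)` and node noise
#' `eps_i(A) ~ N(0, sigma_eps^2)`; per-sample totals are log-normal; counts
#' are multinomial. With `alpha = NULL` the cohort is null (no group
#' effect) and groups are assigned by a balanced random split of the
#' samples, matching the benchmark protocol in which signal is injected
#' into a null base dataset afterwards.
#'
#' @param tree An [ltn_tree()].
#' @param G Number of subjects (default 33).
#' @param samples_per_subject Samples per subject (default 10).
#' @param mu Baseline node log-odds; drawn once as `N(0, 1.5^2)` per node if
#'   `NULL`.
#' @param alpha Optional group-contrast `d`-vector (zero vector when `NULL`).
#' @param sigma_re Between-subject standard deviation of node log-odds
#'   (default 0.7).
#' @param sigma_eps Within-subject node noise standard deviation
#'   (default 0.7).
#' @param total_meanlog,total_sdlog Log-normal parameters of the per-sample
#'   sequencing depths (defaults `log(2e4)` and 0.7).
#' @param seed Optional integer seed.
#' @return A list: `X` (counts), `design` (a [da_design()]), `mu`,
#'   `alpha`, `totals`.
#' @export
simulate_da_cohort <- function(tree, G = 33, samples_per_subject = 10,
                               mu = NULL, alpha = NULL,
                               sigma_re = 0.7, sigma_eps = 0.7,
                               total_meanlog = log(2e4), total_sdlog = 0.7,
                               seed = NULL) {
  stopifnot(inherits(tree, "ltn_tree"))
  if (!is.null(seed)) set.seed(seed)
  d <- tree$d
  n <- G * samples_per_subject
  if (is.null(mu)) mu <- stats::rnorm(d, 0, 1.5)
  if (is.null(alpha)) alpha <- numeric(d)
  g <- rep(seq_len(G), each = samples_per_subject)
  s <- sample(rep_len(c(0L, 1L), n))  # balanced random split of samples
  gam <- matrix(stats::rnorm(G * d, 0, sigma_re), G, d)
  psi <- matrix(mu, n, d, byrow = TRUE) +
    outer(s, alpha) + gam[g, , drop = FALSE] +
    matrix(stats::rnorm(n * d, 0, sigma_eps), n, d)
  totals <- round(stats::rlnorm(n, total_meanlog, total_sdlog))
  p <- tlr_inverse(psi, tree)
  if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
  X <- matrix(0L, n, tree$K)
  for (i in seq_len(n)) {
    if (totals[i] > 0) X[i, ] <- stats::rmultinom(1L, totals[i], p[i, ])
  }
  colnames(X) <- tree$leaves
  list(X = X, design = da_design(s, g = g), mu = mu, alpha = alpha,
       totals = totals)
}

#' True node-level contrast induced by a signal injection
#'
#' Multiplying the relative abundance of a taxon set by `(1 + a_star)` in
#' one group shifts the log-odds at every node whose split separates
#' perturbed from unperturbed mass. This computes that shift exactly for a
#' baseline composition: the per-node difference in tlr coordinates between
#' the perturbed (renormalized) and baseline compositions, i.e. the true
#' group contrast `alpha(A)` that the injection induces at the level of the
#' mean composition. Nodes with a (near-)zero induced contrast are truly
#' null for the node-level test even when they are ancestors of injected
#' taxa.
#'
#' @param tree An [ltn_tree()].
#' @param p0 Baseline composition (strictly positive `K`-vector).
#' @param taxa Indices or names of the injected taxa.
#' @param a_star Effect size (multiplier `1 + a_star`).
#' @return A `d`-vector of induced log-odds shifts, in node preorder.
#' @export
induced_node_contrast <- function(tree, p0, taxa, a_star) {
  if (is.character(taxa)) taxa <- match(taxa, tree$leaves)
  p0 <- as.numeric(p0) / sum(p0)
  p1 <- p0
  p1[taxa] <- p1[taxa] * (1 + a_star)
  p1 <- p1 / sum(p1)
  tlr(p1, tree) - tlr(p0, tree)
}

#' Zero-proportion sweep over mean and variance scalings
#'
#' Emulates the two routes by which the LTN model generates sparsity:
#' scaling the absolute node means inflates per-OTU (within-taxon) zeros,
#' while scaling the marginal variances of the node log-odds — with the
#' correlation structure held fixed — inflates per-sample (within-sample)
#' zeros. For each scale the function simulates a count table and records
#' the zero-proportion distributions.
#'
#' @param mu_hat Baseline node mean `d`-vector.
#' @param Sigma_hat Baseline `d x d` covariance.
#' @param mean_scales,var_scales Positive multipliers applied to `mu_hat`
#'   and to the marginal variances, respectively.
#' @param tree An [ltn_tree()].
#' @param totals Per-sample totals for each simulated dataset.
#' @param seed Optional integer seed.
#' @return A data.frame with one row per (type, scale): median per-OTU and
#'   per-sample zero proportions, plus list-columns holding the full
#'   distributions.
#' @export
sparsity_sweep <- function(mu_hat, Sigma_hat, mean_scales = 1,
                           var_scales = 1, tree, totals, seed = NULL) {
  if (any(c(mean_scales, var_scales) <= 0)) {
    stop("scales must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  run1 <- function(mu, Sigma, type, scale) {
    X <- sample_ltn_counts(ltn_params(mu, Sigma), tree, totals)
    zp <- zero_proportion_stats(X)
    data.frame(type = type, scale = scale,
               median_zero_otu = stats::median(zp$per_otu),
               median_zero_sample = stats::median(zp$per_sample),
               per_otu = I(list(zp$per_otu)),
               per_sample = I(list(zp$per_sample)))
  }
  for (sc in mean_scales) {
    rows[[length(rows) + 1L]] <- run1(mu_hat * sc, Sigma_hat, "mean", sc)
  }
  for (sc in var_scales) {
    rows[[length(rows) + 1L]] <- run1(mu_hat, Sigma_hat * sc, "variance", sc)
  }
  do.call(rbind, rows)
}
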