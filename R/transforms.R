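#' Tree-based log-ratio (tlr) transform
#'
#' Maps a composition `p` on the `K`-simplex to the `d = K - 1` vector of
#' node log-odds `psi(A) = logit(theta(A))`, where `theta(A)` is the
#' probability mass of the left subtree of `A` relative to `A` itself. This
#' is the coordinate system in which the logistic-tree normal model places
#' its multivariate Gaussian.
#'
#' @param p A strictly positive composition (`K`-vector summing to 1) or an
#'   `n x K` matrix of compositions (one per row). Column names, if present,
#'   must match the tree leaves.
#' @param tree An [ltn_tree()].
#' @param pseudo_mass If `TRUE`, a pseudo-mass of `1e-10` of the total is
#'   added to every component before transforming, so that compositions with
#'   zero entries can be mapped; by default zero subtree mass is an error.
#' @return A `d`-vector (or `n x d` matrix) of log-odds in node preorder.
#' @examples
#' tr <- ltn_tree("((u1,u2),(u3,u4));")
#' tlr(c(0.4, 0.2, 0.3, 0.1), tr)  # log(1.5), log(2), log(3)
#' @export
tlr <- function(p, tree, pseudo_mass = FALSE) {
  P <- as_composition(p, tree, allow_zero = pseudo_mass)
  if (pseudo_mass) {
    P <- P + 1e-10
    P <- P / rowSums(P)
  }
  mass <- P %*% tree$in_leaf
  mass_l <- P %*% tree$left_leaf
  if (any(mass_l <= 0) || any(mass - mass_l <= 0)) {
    stop("zero subtree mass; use pseudo_mass = TRUE to add a pseudo-mass",
         call. = FALSE)
  }
  psi <- log(mass_l) - log(mass - mass_l)
  colnames(psi) <- tree$node_labels
  drop_if_vector(psi, p)
}

#' Inverse tlr transform
#'
#' Reconstructs the composition from node log-odds: each leaf probability is
#' the product, over its ancestors, of the left-branch probability
#' `theta(A) = plogis(psi(A))` or its complement `1 - theta(A)`.
#'
#' @param psi A finite `d`-vector of node log-odds, or an `n x d` matrix.
#' @inheritParams tlr
#' @return A composition `K`-vector (or `n x K` matrix) on the simplex.
#' @export
tlr_inverse <- function(psi, tree) {
  Psi <- as_node_matrix(psi, tree)
  if (any(!is.finite(Psi))) stop("psi must be finite", call. = FALSE)
  # log p = log(theta) LEFT' + log(1 - theta) RIGHT'
  log_th <- stats::plogis(Psi, log.p = TRUE)
  log_1mth <- stats::plogis(-Psi, log.p = TRUE)
  right_leaf <- tree$in_leaf - tree$left_leaf
  logp <- log_th %*% t(tree$left_leaf) + log_1mth %*% t(right_leaf)
  p <- exp(logp)
  p <- p / rowSums(p)  # guard against rounding drift
  colnames(p) <- tree$leaves
  drop_if_vector(p, psi)
}

#' Isometric log-ratio (ilr) balances and their inverse
#'
#' `ilr()` maps a strictly positive composition to the tree's `d` balances
#' `eta(A) = sqrt(|A_l||A_r| / (|A_l| + |A_r|)) *
#' log( g(p(A_l)) / g(p(A_r)) )`, where `g()` is the geometric mean over the
#' leaves of a subtree; `ilr_inverse()` maps balances back to the simplex.
#' The two are mutual inverses on the interior of the simplex.
#'
#' @inheritParams tlr
#' @return `ilr()`: a `d`-vector (or `n x d` matrix) of balances;
#'   `ilr_inverse()`: a composition.
#' @export
ilr <- function(p, tree) {
  P <- as_composition(p, tree, allow_zero = FALSE)
  eta <- log(P) %*% tree$ilr_basis
  colnames(eta) <- tree$node_labels
  drop_if_vector(eta, p)
}

#' @param eta A finite `d`-vector of balances, or an `n x d` matrix.
#' @rdname ilr
#' @export
ilr_inverse <- function(eta, tree) {
  E <- as_node_matrix(eta, tree)
  if (any(!is.finite(E))) stop("eta must be finite", call. = FALSE)
  z <- E %*% t(tree$ilr_basis)
  z <- z - apply(z, 1L, max)  # softmax, stabilized
  p <- exp(z)
  p <- p / rowSums(p)
  colnames(p) <- tree$leaves
  drop_if_vector(p, eta)
}

#' Centred log-ratio (clr) transform
#'
#' `clr(p) = log(p_j / g(p))` with `g(p)` the geometric mean of the
#' composition; the output sums to zero. Scale-invariant: any positive
#' rescaling of `p` gives the same result.
#'
#' @param p A strictly positive vector (need not be normalized) or matrix
#'   with one composition per row.
#' @return A zero-sum vector (or matrix with zero-sum rows).
#' @export
clr <- function(p) {
  P <- if (is.matrix(p)) p else matrix(p, nrow = 1L)
  if (any(P <= 0)) stop("clr requires strictly positive entries", call. = FALSE)
  lp <- log(P)
  out <- lp - rowMeans(lp)
  drop_if_vector(out, p)
}

as_composition <- function(p, tree, allow_zero = FALSE) {
  P <- if (is.matrix(p)) p else matrix(p, nrow = 1L, dimnames = list(NULL, names(p)))
  if (ncol(P) != tree$K) {
    stop("composition has ", ncol(P), " components but tree has ", tree$K,
         " leaves", call. = FALSE)
  }
  if (!is.null(colnames(P))) {
    if (!setequal(colnames(P), tree$leaves)) {
      stop("composition names do not match tree leaves", call. = FALSE)
    }
    P <- P[, tree$leaves, drop = FALSE]
  }
  if (any(P < 0)) stop("composition entries must be non-negative", call. = FALSE)
  if (!allow_zero && any(P == 0)) {
    stop("composition has zero entries; strictly positive input required",
         call. = FALSE)
  }
  s <- rowSums(P)
  if (any(abs(s - 1) > 1e-6)) P <- P / s
  P
}

as_node_matrix <- function(x, tree) {
  M <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(M) != tree$d) {
    stop("expected ", tree$d, " node coordinates, got ", ncol(M),
         call. = FALSE)
  }
  M
}

drop_if_vector <- function(out, input) {
  if (is.matrix(input)) out else drop(out)
}
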