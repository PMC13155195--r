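#' Matrix-loss suite for estimated clr correlation matrices
#'
#' The four losses used to score an estimated clr correlation (or
#' covariance) matrix against the truth: the Frobenius norm, the operator
#' L1 norm (maximum absolute column sum), the entry-wise L-infinity norm,
#' and the spectral norm of the difference. All are symmetric in their
#' arguments and zero iff the matrices are equal.
#'
#' @param est,truth Square matrices of equal dimension.
#' @return A list of class `loss_report` with elements `frobenius`, `l1`,
#'   `linf`, `spectral`.
#' @examples
#' loss_suite(diag(2), diag(2))  # all zeros
#' @export
loss_suite <- function(est, truth) {
  est <- as.matrix(est)
  truth <- as.matrix(truth)
  if (!all(dim(est) == dim(truth))) {
    stop("est and truth must have the same dimensions", call. = FALSE)
  }
  diff <- est - truth
  structure(
    list(
      frobenius = norm(diff, type = "F"),
      l1 = norm(diff, type = "O"),
      linf = max(abs(diff)),
      spectral = norm(diff, type = "2")
    ),
    class = "loss_report"
  )
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("frobenius %.4g | L1 %.4g | Linf %.4g | spectral %.4g\n",
              x$frobenius, x$l1, x$linf, x$spectral))
  invisible(x)
}

#' Zero-proportion summaries of a count table
#'
#' Per-taxon (column) and per-sample (row) fractions of zero counts — the
#' two axes of sparsity in microbiome tables.
#'
#' @param X Non-negative integer count matrix.
#' @return A list: `per_otu` (length `K`), `per_sample` (length `n`).
#' @export
zero_proportion_stats <- function(X) {
  X <- as_count_matrix(X)
  list(per_otu = colMeans(X == 0), per_sample = rowMeans(X == 0))
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' The KS statistic (supremum distance between empirical CDFs) between two
#' numeric samples, e.g. the per-taxon zero-proportion distributions of a
#' generated and an observed count table.
#'
#' @param a,b Numeric vectors.
#' @return The KS distance in `[0, 1]`.
#' @export
ks_distance <- function(a, b) {
  unname(suppressWarnings(stats::ks.test(a, b))$statistic)
}
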