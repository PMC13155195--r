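# Precision-matrix updates shared by the samplers.
#
# The graphical-lasso prior puts independent double-exponential densities
# with rate `lambda` on the off-diagonal precision entries and exponential
# densities with rate `lambda/2` on the diagonal, restricted to the positive
# definite cone. Conditional on the latent scale matrix Tau of the
# double-exponential scale-mixture representation, the precision matrix is
# updated one column at a time from its conjugate conditional (a Gaussian
# for the off-diagonal block and a gamma for the Schur complement), which
# keeps every draw positive definite by construction.

update_omega_glasso <- function(Omega, S, ns, lambda) {
  Tau <- .glasso_tau_update(Omega, lambda)
  .glasso_sweep(Omega, S, Tau, lambda, as.integer(ns))
}

# Diagonal-precision variant (independent node log-odds): each omega_jj has
# an exponential(lambda/2) prior, so omega_jj | psi ~ Gamma(ns/2 + 1,
# rate = (S_jj + lambda)/2). Used as the proxy for the Dirichlet-tree
# multinomial's independence assumption.
update_omega_diagonal <- function(S, ns, lambda) {
  d <- nrow(S)
  diag(stats::rgamma(d, shape = ns / 2 + 1, rate = (diag(S) + lambda) / 2),
       nrow = d)
}
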