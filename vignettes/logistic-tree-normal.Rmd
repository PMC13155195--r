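---
title: "The logistic-tree normal model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The logistic-tree normal model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Microbiome OTU/ASV count tables are compositional, high-dimensional, very
sparse, and strongly heterogeneous across samples. The logistic-tree normal
(LTN) model addresses all four features with one construction. Given a
rooted full binary tree over the $K$ taxa, the multinomial sampling model
for a count vector $X$ with depth $N$ is decomposed into independent
binomials at the $d = K-1$ interior nodes,

$$y(A_l) \mid y(A), \theta(A) \sim \mathrm{Binomial}(y(A), \theta(A)),$$

where $y(A)$ is the total count in the subtree rooted at $A$ and
$\theta(A)$ is the relative abundance of $A$'s left subtree within $A$.
The node log-odds $\psi(A) = \mathrm{logit}\,\theta(A)$ — the tree-based
log-ratio (tlr) coordinates of the composition — are modelled jointly as

$$\psi \sim \mathrm{MVN}(\mu, \Sigma).$$

Unlike the Dirichlet-tree multinomial (DTM), which forces the branch
probabilities to be independent Betas and so spends only $K-1$ scalars on a
$(K-1)\times(K-1)$ covariance, the multivariate Gaussian leaves the
covariance of the log-odds unconstrained. Unlike logistic-normal models in
clr/alr/ilr coordinates, the binomial decomposition restores conjugacy:
with Pólya-Gamma (PG) auxiliary variables
$w_i(A) \mid y_i(A), \psi_i(A) \sim \mathrm{PG}(y_i(A), \psi_i(A))$,
every full conditional in the Gibbs sampler is a standard distribution.

Zeros arise without any zero-inflation component. A large $|\mu(A)|$ on an
ancestor node starves the taxa below one branch, producing per-taxon
(within-OTU) zeros; large marginal variances of $\psi(A)$ produce wildly
varying compositions and hence per-sample (within-sample) zeros. Both
mechanisms leave the correlation structure untouched, which is what makes
the induced taxa correlations identifiable. `sparsity_sweep()` reproduces
both monotone effects.

## Samplers

`gibbs_fit_ltn()` implements the base model with a Bayesian graphical
lasso prior on the precision matrix $\Omega = \Sigma^{-1}$: independent
double-exponential densities with rate $\lambda$ on off-diagonal entries
and exponential densities with rate $\lambda/2$ on the diagonal,
restricted to the positive definite cone. One Gibbs cycle draws

1. $w_i(A) \sim \mathrm{PG}(y_i(A), \psi_i(A))$ — exactly zero when
   $y_i(A) = 0$, so empty subtrees carry no likelihood and the
   corresponding $\psi_i(A)$ is drawn from its conditional Gaussian prior
   (no pseudo-counts anywhere);
2. $\psi_i \mid \cdot \sim \mathrm{MVN}$ with precision
   $\Omega + \mathrm{diag}(w_i)$ and linear term $\Omega\mu + \kappa_i$,
   $\kappa_i(A) = y_i(A_l) - y_i(A)/2$;
3. $\mu \mid \cdot$, conjugate Gaussian under a proper
   $\mathrm{MVN}(0, \tau^2 I)$ hyperprior — $\tau^2 = 100$ by default, a
   flat-ish choice we state explicitly rather than leaving improper;
4. $\Omega \mid \psi$ by the column-wise blocked Gibbs scan for the
   graphical lasso (a Gaussian for each off-diagonal block, a gamma for
   each Schur complement), which keeps every draw positive definite by
   construction. `diagonal_precision = TRUE` replaces this with
   independent gamma draws on the diagonal — the proxy for DTM's
   independence assumption.

`gibbs_fit_da()` extends the model for differential abundance testing
between two groups with the node-level mixed-effects regression

$$\psi_i = \alpha s_i + \beta^T z_i + \gamma_{g_i} + \epsilon_i,$$

with group indicator $s_i$, covariates $z_i$ (an intercept column is
required and inserted if absent, so that baseline node means are absorbed
into $\beta$ and $\alpha$ is identified as a pure group contrast), subject
random effects $\gamma_g \sim \mathrm{MVN}(0, \Omega_{re}^{-1})$ under the
same graphical-lasso prior, and independent node noise
$\epsilon_i(A) \sim N(0, \sigma^2_\epsilon(A))$ with inverse-gamma priors.
The group contrast gets a spike-and-slab prior

$$\alpha(A) \sim (1-\pi(A))\,\delta_0 + \pi(A)\, N(0, 1/\phi_\alpha),
\qquad \pi(A) \sim \mathrm{Beta}(m, 1-m), \qquad
\phi_\alpha \sim \mathrm{Gamma}(t, u).$$

We read the slab as a proper two-component mixture (the two weights must
sum to one). The inclusion indicator is drawn from its closed-form odds —
the slab is Gaussian, so it marginalizes analytically against the
pseudo-Gaussian likelihood of the node residuals — and $\pi(A)$ is updated
explicitly from its conjugate Beta conditional rather than collapsed. The
fixed effects use the g-prior-style scale
$\beta_{\cdot A} \sim N(0, c\,n\,(Z^TZ)^{-1})$, reading the prior scale as
the scalar $c$ times the sample size $n$; $c = 50$ by default. The
$\mathrm{Gamma}(t,u)$ hyperparameters of the slab precision are not pinned
down by any external constraint; we default to $t = 2, u = 1$ (prior mean
2, proper) and expose both.

Testing is decision-theoretic: the per-node PMAP
$\Pr(\alpha(A) \neq 0 \mid Y)$ and the global PJAP
$\Pr(\alpha \neq 0 \mid Y)$ are MCMC frequencies of nonzero draws.
`select_m_for_global_null(K, p0)` sets $m = 1 - p_0^{1/(K-1)}$ so the
prior global-null probability is $p_0$; with $K = 100$ taxa and
$p_0 = 1/2$ this gives $m \approx 0.006977$. `fdr_select()` thresholds
PMAPs so the posterior expected FDR — the mean of $1-\mathrm{PMAP}$ over
reported nodes — stays below the target $c$. We implement the rule as a
scan over all achievable thresholds and keep the largest feasible reported
set; with distinct PMAPs this coincides with the usual sorted
$k = \max\{k: \frac{1}{k}\sum_{i\le k}(1-p_i) \le c\}$ rule, and nodes
tied with the threshold are always reported together (a tie never splits),
which also keeps the attained expected FDR of the reported set below $c$
by construction.

## Numerical choices

**Pólya-Gamma draws.** No exact PG sampler was available to build on, and
the PG device is the computational heart of the model, so the package
implements the Devroye-type rejection sampler for $\mathrm{PG}(1, c)$ in
C++ (alternating-series accept/reject on a truncated inverse-Gaussian /
exponential mixture), with R's RNG throughout so `set.seed()` governs
every draw. Integer shapes up to `max_exact = 30` are drawn as exact sums
of $\mathrm{PG}(1,c)$ variates. Above the cutoff the b-fold convolution is
drawn from a gamma matched to the exact mean $\tfrac{b}{2c}\tanh(c/2)$ and
variance. We chose the gamma (over a Gaussian) because it preserves
positivity and the right skew of the convolution: a Geweke-style
successive-conditional check of the sampler is clean under the gamma tail
at node counts around the cutoff, while a Gaussian tail leaves a small but
detectable bias. The approximation error decays as $b$ grows; counts below
the cutoff — including every regime the moment tests probe — use the exact
path only.

**Trees.** Multifurcations are resolved deterministically by
left-laddering (the first two children in stored Newick order are joined
under a new node, repeatedly), singleton interior nodes are collapsed, and
the result is recorded in the tree object so reruns are reproducible.
Interior nodes are indexed in depth-first preorder; the left child is the
first child in Newick order and $\theta(A)$ is always the left-branch
probability. Branch lengths are ignored — the model uses topology only.
Node-level outputs are labelled `n<preorder index>.<lexicographically
smallest descendant leaf>` so reports stay readable across tree versions.

**Zero subtree mass.** `tlr()` refuses compositions with zero subtree mass
by default; an explicit `pseudo_mass` flag adds $10^{-10}$ of the total
instead. The samplers never need this: they operate on the counts
$y(A)$, not on transformed proportions.

**Degenerate inputs.** `PG(0, c)` is a point mass at zero, all-zero
samples contribute zero likelihood, zero totals produce all-zero rows, and
a single-subject design triggers a warning (the random-effect variance is
weakly identified) rather than an error.

## The synthetic-data generators

`simulate_ln_dataset()` and `simulate_dtm_dataset()` reproduce the two
benchmark generators for covariance estimation: an ilr-based
logistic-normal with hub/block/sparse precision matrices
(`gen_precision()`; nonzero entries $\pm 0.3$ for hub/block, hub edge
probability 0.7, non-hub 0.2, ten blocks with 0.5 within / 0.2 between,
means drawn from $N(0,16)$, $n = 200$ samples of depth $10^5$ by default)
and a Dirichlet-tree multinomial. Neither matches the tlr-Gaussian form of
the fitted model, which is deliberate: they act as misspecification
stressors. In the sparse model the published construction is garbled in
the source text; we use $\Omega_0 = \mathrm{blockdiag}(A_1, I_{p_2})$ with
$p_1 = \lfloor 3\sqrt{d}\rfloor$ as the most plausible reading and expose
both constants. Positive definiteness in all three models is enforced by
strict diagonal dominance (diagonal = row sum of absolute off-diagonals
plus 0.1), a deterministic rule stated here because the source only asks
for diagonals "large enough".

`simulate_da_cohort()` is the package's self-contained stand-in for a real
longitudinal 16S cohort in the differential-abundance experiments, which
in the original setting resample a real infant cohort: 33 subjects, 10
samples each, log-normal sequencing depths (median $2\times10^4$), node
means drawn once from $N(0, 1.5^2)$ (giving realistic per-taxon sparsity),
between-subject and residual log-odds standard deviations of 0.7 each —
magnitudes we consider typical of the between-subject and within-subject
variation in infant-gut log-odds coordinates. Groups are a balanced random
split of samples and signal is injected afterwards with
`inject_signal()`: the counts of $K^*$ taxa drawn from the 20 most
abundant (mean per-sample relative abundance) are multiplied by
$(1+a^*)$ in group 1 and rounded, the grid being $K^*=1$ with
$a^* \in \{0.5, 2, 4\}$ and $K^*=8$ with $a^* \in \{0.5, 0.75, 1\}$.
Injection rounds to the nearest integer, so $a^* = 0.5$ on odd counts
rounds half-up counts; truth labels are returned alongside.

What the generator does *not* emulate: real phylogenetic signal in the
covariance (the tree is random), overdispersion beyond the logistic-normal
law, batch effects, and longitudinal within-subject trends (samples within
a subject are exchangeable). Tests passing on these generators therefore
demonstrate correctness of the machinery and calibration under the model's
own assumptions and under the LN/DTM misspecifications above — not
performance on any particular real cohort.

Because the injection acts on taxa while testing acts on tree nodes,
benchmark truth at the node level is defined by
`induced_node_contrast()`: the exact log-odds shift the injection induces
at each node of the mean composition. Nodes whose induced shift is
essentially zero (for instance a node both of whose children lie entirely
inside, or entirely outside, the injected set) are genuinely null for the
node-level test even when they are ancestors of injected taxa; ranking
evaluations label nodes with $|\Delta\psi| > 0.1$ as signal and
$|\Delta\psi| < 0.01$ as null, leaving the sliver in between out of both
classes.

## Problem sizes used in the test suite

The shipped checks run the full pipeline at reduced scale, chosen so the
suite completes comfortably on a single CPU while still exercising every
moving part: transform and selection-rule properties at up to $K = 25$
with thousands of random cases; recovery of $(\mu, \Sigma)$ at $d = 7$
with 4000 Gibbs iterations and $n \in \{50, 200\}$; differential-abundance
power at $K = 50$ with the full synthetic cohort ($n = 330$) and 2000
iterations; null calibration over 20 replicates at $n = 100$; the
covariance-loss experiment at $K = 50$ with 10 replicates and 2000
iterations (the samplers' own defaults remain at full scale: 10,000
iterations with half discarded as burn-in, suitable for $K$ around 100);
generative-fit checks at $n = 189$ samples. The acceptance script reports
the deterministic prior-calibration constant, which is exact at any scale.

## Known limitations

- The latent-factor extension of the noise term (low-rank residual
  covariance) is not implemented; the precision prior is pluggable in
  principle but only graphical-lasso and diagonal variants ship.
- Interaction terms between the group indicator and covariates are not
  supported.
- PG shapes above the cutoff use the matched-gamma tail described above;
  users who want fully exact augmentation at large counts can raise
  `max_exact` at a proportional cost in time.
- The graphical-lasso rate $\lambda$ is fixed by the user (default 10),
  not learned.
- Trees must be rooted; unrooted inputs should be rooted upstream
  (e.g. with `ape::root()`) since the binomial decomposition depends on
  the root.
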