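---
title: "Birth-death symmetries, incomplete sampling, and what a tree can identify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Birth-death symmetries, incomplete sampling, and what a tree can identify}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdswap)
```

## The model

`bdswap` implements the constant-rate linear birth-death process used
throughout phylodynamics and macroevolution: every lineage independently
speciates (gives birth) at rate $\lambda$ and goes extinct (dies) at rate
$\mu$, both per lineage per unit time and constant through time. At the
present, each surviving individual is included in the data independently
with a sampling probability $\rho \in (0, 1]$; pruning all extinct and
unsampled lineages leaves the *reconstructed tree*, an ultrametric tree on
the $n$ sampled tips with branching times $t_1 > t_2 > \dots > t_{n-1}$
measured backwards from the present. The process may be rooted at the stem
age $t_0$ (one starting lineage) or at the crown age $t_1$ (two lineages).

Two facts organize the package.

**Rate-interchange symmetry.** The scaled transition probabilities
$\tilde p_{n,m}(t \mid \lambda, \mu) = \lambda^n \mu^m p_{n,m}(t \mid
\lambda, \mu)$ are invariant under swapping $\lambda$ and $\mu$; in
particular $p_{1,1}$ and every diagonal $p_{n,n}$ are themselves symmetric.
The mechanism is a time-reversal argument: run a population-size path
backwards and every birth becomes a death, with identical waiting-time and
event-probability factors when the rates are interchanged
(`trajectory_log_density()` and `reverse_trajectory()` expose the pathwise
version of this identity for paths with equal start and end size).

**Two identifiable parameters, not three.** With incomplete sampling, all
conditioned reconstructed-tree densities depend on
$(\lambda, \mu, \rho)$ only through the canonical pair
$$\lambda' = \rho\lambda, \qquad \mu' = \mu - \lambda(1 - \rho),$$
which preserves the net diversification rate ($\lambda' - \mu' =
\lambda - \mu$) and can make the "death rate" $\mu'$ negative (for example
$\lambda = 4\mu$, $\rho = 1/2$ gives $\mu' = -\mu$). Each $(\lambda',
\mu')$ corresponds to a one-dimensional family of triplets; the sampling
probabilities that back-transform to a proper process are $\rho \in (0,1]$
when $\mu' \ge 0$ and $\rho \in (0, 1/(1 - \mu'/\lambda')]$ when
$\mu' < 0$ (`feasible_rho_interval()`). Consequences implemented here: the
three-parameter likelihood surface is a perfect ridge
(`ridge_profile()`), maximum likelihood should be performed over
$(\lambda', \mu')$ (`fit_canonical_mle()`), uniform-$\rho$ priors are
distorted once $\mu'$ can go negative (`effective_prior_pushforward()`),
and a likelihood comparison of complete against incomplete sampling is
meaningless because every complete-sampling model has equal-likelihood
incompletely sampled twins but not vice versa
(`complete_sampling_equivalent()`).

## Probability building blocks

The single-lineage no-sampling law is geometric, with
$\alpha = \mu(e^{rt}-1)/(\lambda e^{rt}-\mu)$,
$\beta = \lambda(e^{rt}-1)/(\lambda e^{rt}-\mu)$, $r = \lambda - \mu$:
$p_{1,0} = \alpha$ and $p_{1,m} = (1-\alpha)(1-\beta)\beta^{m-1}$. A start
of $n$ lineages composes this law $n$-fold
(`transition_probability()`). The sampled process replaces these with
$p_n(t \mid \lambda, \mu, \rho)$ (`sampled_count_probability()`) and the
auxiliary $q(t)$ (`q_function()`), which satisfies $dq/dt = p_1$ - the
identity behind several normalization checks below. Dividing by $\rho$
yields the tilde functions $\tilde p_0, \tilde p_1, \tilde p_n, \tilde q$
that depend only on $(\lambda', \mu')$ (`canonical_p0()` and friends); a
negative $\mu'$ is a first-class input to all of them and the closed forms
remain positive and finite.

The seven reconstructed-tree densities (`tree_log_density()`,
`tree_log_density_canonical()`) cover stem and crown starts, no
conditioning, conditioning on survival, on the exact sampled tip count, and
on the tip count with a uniform (improper) origin-age prior. Only the two
unconditioned rows see $\rho$ itself; the five conditioned rows are pure
functions of $(\lambda', \mu')$, and the canonical interface refuses a
`rho` argument for them precisely because supplying one would feign a third
identifiable parameter.

## Numerical choices

* **Branch selection, not cancellation.** All probability kernels are
  evaluated in log scale on the branch determined by the sign of
  $r = \lambda - \mu$, so $e^{rt}$ never overflows; rates of order 100
  (exercised in the tests) are safe.
* **Critical switch.** The $\lambda = \mu$ limits ($\alpha = \beta =
  \lambda t/(1+\lambda t)$, $\tilde q = t/(1+\lambda' t)$, ...) are used
  when $|\lambda-\mu|\,t < 10^{-9}(1 + \lambda t)$. The threshold is
  relative to the elapsed-time scale so the generic and critical branches
  agree to well under $10^{-5}$ across the switch (tested at a perturbation
  of $10^{-7}$).
* **Feasibility boundary.** Back-transforming at the upper end of the
  feasible $\rho$ interval must give $\mu = 0$ exactly; float dust of
  magnitude below $10^{-12}\max(1, \lambda)$ is collapsed to zero, and
  $\rho$ comparisons against the bound carry an absolute slack of
  $10^{-12}$.
* **Oracle.** `transition_oracle()` exponentiates the truncated generator;
  state spaces up to 400 use dense Pade exponentiation from `Matrix`, and
  larger truncations evaluate the same exponential by the uniformized
  Poisson series (touching only the needed row), which keeps the
  heavy-tailed supercritical grid cells affordable. An explicit tail-mass
  check (< $10^{-12}$) guards the truncation in both regimes.
* **Infeasibility as a value.** `equivalent_triplet()` returns a typed
  `bd_infeasible` marker carrying the violated bound instead of throwing,
  because grid enumeration over $\hat\rho$ expects partial feasibility.
* **Ties.** Tied branching times are measure-zero under the model;
  simulated or parsed ties are broken by an ulp-scale jitter with a
  warning rather than rejected.

Two published renderings of the crown-conditioned density rows disagree
about whether the normalizing $q$ is evaluated at the stem or the crown
age. Since those rows condition on the crown age $t_1$ and carry products
starting at $i = 2$, this package evaluates every crown-row normalizer at
$t_1$; the choice is validated by the internal-consistency checks (the
survival/exact-$n$ ratio identity and the $n = 2$ normalization of the
uniform-origin row integrate correctly under this reading and not under
the alternative). Similarly, the swap identities of the tilde functions
are only asserted for $\mu' \ge 0$ - the swapped pair $(\mu', \lambda')$
needs a positive first argument - and at $\mu' = 0$ the swapped side is
evaluated by its limiting closed forms ($\tilde p_0 \to e^{-\lambda' t}$,
$\tilde q \to (1 - e^{-\lambda' t})/\lambda'$), under which the identities
hold trivially (both sides of the first one vanish).

## Simulation

`simulate_trajectory()` and `simulate_genealogy()` are plain Gillespie
samplers: exponential waiting times at total rate $n(\lambda+\mu)$ and a
birth with probability $\lambda/(\lambda+\mu)$ per event.
`sample_present()` retains each extant tip with probability $\rho$ and
prunes; `simulate_reconstructed_tree()` wraps the pair in a rejection loop
for the survival and exact-$n$ conditionings and reports the number of
rejections so callers can budget replicates. Every stochastic entry point
accepts a seed; a fixed seed reproduces results bit for bit (the rejection
loop consumes the same stream, which is documented rather than isolated
into substreams - a simpler protocol than counter-based generators, chosen
because R's global RNG is what the surrounding ecosystem, e.g. `ape` and
`TreeSim`-style workflows, already uses).

Rejection sampling cannot reach trees conditioned on hundreds of tips (the
acceptance probability of an exact large $n$ is vanishing), so the package
also exposes `sample_branching_times()`: under the exact-$n$ conditionings
the non-root branching times are iid with density
$\tilde p_1(t)/\tilde q(\text{age})$, whose CDF is
$\tilde q(t)/\tilde q(\text{age})$ and inverts in closed form. This exact
sampler is cross-checked against the rejection simulator (two-sample and
binned goodness-of-fit tests) and drives the large-$n$ parameter-recovery
experiments. In those experiments the crown age is drawn by a count-level
first-passage simulation to the target tip number, which produces a
realistic spread of crown ages without affecting consistency (the
likelihood conditions on the crown age).

**What the generator emulates - and does not.** Default experiment
settings follow the stated worlds of the checks: rate grids
$\lambda, \mu \in \{0.3, 1, 2.5\}$ with times up to 2 for the algebraic
identities; $(\lambda, \mu, \rho) = (1, 0.5, 0.8)$ for fixture trees;
$(\lambda', \mu') = (1, 0.5)$ with $n = 200$ tips and 200 replicates for
recovery. The generator produces exactly the model's world - constant
rates, independent lineages, one-shot present-day sampling. It does not
emulate rate variation through time or among lineages, serial (fossil)
sampling, or diversity dependence, so a green suite establishes internal
correctness of this model family, not adequacy of the model for any
empirical tree.

## Inference

`fit_canonical_mle()` maximizes the conditioned log-density over
$(\log\lambda', \mu')$ with Nelder-Mead from four starts seeded by a
pure-birth estimate $\lambda'_0 = (n-2)/\sum t_i$ (with $\pm\lambda'_0/2$
as $\mu'$ guesses), a relative tolerance of $10^{-10}$ and a 2000-evaluation
budget. Standard errors come from the finite-difference Hessian and are
reported only when it is negative-definite; trees too small to identify two
parameters (a single branching time, or flat curvature) are flagged
`ridge_degenerate` instead of erroring. For the exact-$n$ stem and crown
conditionings the likelihood is invariant under swapping
$(\lambda', \mu') \to (\mu', \lambda')$ whenever $\mu' > 0$, so the fit has
twin optima and any analysis must declare which rate is larger; the
package reports the estimate found and the tests verify the twin attains
the same likelihood.

The model-selection corollary is deliberately *not* packaged as a test
statistic: `ridge_profile()` demonstrates that every feasible $\rho$ row
has identical log-likelihood, which is exactly why a
"$\rho = 1$ versus $\rho < 1$" comparison carries no information.

## Known limitations

* Constant rates only; no serial sampling, no multi-type or
  density-dependent extensions.
* Densities are over ordered branching-time vectors with the conventional
  combinatorial constants; topology/ranking probabilities are out of
  scope (`write_newick()` draws a random ranked topology only to emit
  valid Newick).
* The rejection simulator is practical for small target tip counts; use
  the exact conditioned sampler for large ones.
* The uniform-origin conditioning (`n_uniform_t0`) has an improper prior
  and is supported in density evaluation but not in simulation.
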