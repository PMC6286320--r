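---
title: "Birth-death chronospecies models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Birth-death chronospecies models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdchrono)
```

## The model

Speciation and extinction rates estimated from an extant timetree and from
fossil stratigraphic ranges measure different things. A timetree records
*branching* events (rate $\lambda$) and *lineage terminations* (rate
$\mu$). The fossil record instead counts originations and extinctions of
*morphospecies*, which also arise without branching. The birth-death
chronospecies (BDC) process makes the link explicit with two extra
parameters: at each branching event the ancestor is replaced by two new
species with probability $\beta$ (bifurcation) and survives with
probability $1 - \beta$ (budding), and species are replaced along branches
by anagenesis at rate $\lambda_a$ per lineage per time unit. The
morphospecies origination and extinction rates estimable from ranges are
then

$$\lambda^* = \lambda(1-\beta) + 2\lambda\beta + \lambda_a, \qquad
  \mu^* = \lambda\beta + \lambda_a + \mu,$$

so that $\lambda^* \ge \lambda$, $\mu^* \ge \mu$, and net diversification
is conserved: $\lambda^* - \mu^* = \lambda - \mu$. Conversely, given
estimated $(\lambda, \mu, \lambda^*, \mu^*)$ exactly three situations can
occur: the rates are *equal* ($\lambda^* = \lambda$, $\mu^* = \mu$; pure
budding), *compatible* ($\lambda^* - \lambda = \mu^* - \mu > 0$; some
bifurcation and/or anagenesis), or *incompatible* (anything else; the data
cannot have come from one BDC process). Because the linear system linking
$(\beta, \lambda_a)$ to the rate gap is rank-deficient, only the interval
$\lambda_a \in [\max(0, \lambda^* - 2\lambda),\ \lambda^* - \lambda]$ is
identifiable, never the point; the sign of $\lambda^* - 2\lambda$ still
tells whether anagenesis outweighs budding (`mode_prevalence()`).

```{r algebra}
fossil_rates_from_bdc(lambda = 0.2, mu = 0.16, beta = 0.7, lambda_a = 0.16)
lambda_a_interval(lambda = 0.2, lambda_star = 0.5)
```

## Likelihoods

The two data blocks are modelled independently, and the joint likelihood
is their product. For a timetree with branching ages
$t_1 \ge \dots \ge t_{n-1}$, origin age $t_0$ and sampling fraction
$\rho$, the reconstructed-process density is

$$f(\mathcal{T} \mid t_0) = \frac{p_1(t_0)}{1 - p_0(t_0)}
  \prod_{i=1}^{n-1} \lambda\, p_1(t_i),$$

with $p_0(t)$, $p_1(t)$ the probabilities that a lineage of age $t$ leaves
zero or exactly one sampled descendant (`bd_p0()`, `bd_log_p1()`). When
the origin age is unknown (empirical trees) the process is instead
conditioned on the crown age, with both crown lineages conditioned on
leaving sampled descendants; that standard form is adopted here and
squares the $p_1/(1-p_0)$ factor. For ranges, the likelihood depends on
the data only through the number of birth events $B$, death events $D$
and the summed durations $S$:
$\log P(\mathcal{R}) = B\log\lambda^* + D\log\mu^* -
(\lambda^*+\mu^*)S$, maximised in closed form at $(B/S,\, D/S)$.

The skyline variants let the rates differ across predefined age bins. The
range term simply decomposes by bin. For the timetree term, $p_0$ and
$p_1$ are propagated across bin boundaries from the present backwards;
internally both are read off a fractional-linear (Moebius) representation
of the single-lineage descendant-count generating function, composed
across intervals, which is exact for piecewise-constant rates. The test
suite cross-checks this propagation against direct numerical integration
of the corresponding differential equations, and against the closed-form
constant-rate expressions (agreement to 1e-10 with one bin).

## Model testing

Three nested models are fitted by joint maximum likelihood: *equal* (two
free rates, shared by both blocks), *compatible* ($\lambda, \mu$ and a
common non-negative offset $c = \lambda^* - \lambda = \mu^* - \mu$) and
*incompatible* (four free rates; the range part is closed-form). The
likelihood-ratio cascade then selects the simplest non-rejected model.
Because the equal model sits on the boundary $c = 0$ of the compatible
model, the LR statistic follows a 50:50 mixture of a point mass at zero
and $\chi^2_1$; equal rates are therefore rejected at level $\alpha$ when
the $\chi^2_1$ tail probability of the LR falls below $2\alpha$ — at
$\alpha = 0.05$ the threshold is $2.71$. Compatible vs incompatible uses
$\chi^2_1$ (only the constraint on $\mu^*$ is counted, which makes the
test slightly conservative against the compatible model), and equal vs
incompatible uses $\chi^2_2$. Ties at a threshold resolve to the simpler
model. Optimisation uses Nelder-Mead on log-transformed parameters with
the positive-diversification constraint enforced by the
reparameterisation $d = \lambda - \mu > 10^{-8}$, five random restarts
(initial rates log-uniform in $[0.01, 2]$), plus one warm start from the
best fit of the model nested inside, which enforces the nesting
inequality of the maximised likelihoods up to optimiser tolerance.

## The simulator

`simulate_tree()` draws complete trees (extinct lineages included)
conditioned on the number of extant tips with the general sampling
algorithm: the process is simulated forward far beyond $n$ lineages, every
time span during which a present placed there would leave exactly $n$
survivors is recorded, and one span is sampled with probability
proportional to its duration. Sampling spans only *within* one run
underweights runs that spend more time in qualifying states, so whole
runs are additionally accepted in proportion to their total span weight
(the bound is calibrated from 25 pilot runs on a private random stream
and cached); with that correction the sampled origin-age distribution
matches the analytic conditional law (the uniform-origin-prior posterior
$\propto P(N(0) = n \mid t_0)$) — the simulator's means at the study
conditions (about 108, 52 and 32 time units for $\mu$ = 0.16, 0.1, 0.02
at $\lambda = 0.2$, $n = 200$) are recomputed in the acceptance tests.

Rate schedules are anchored to the present, which makes conditioning on
$n$ non-trivial: the shift ages are fixed relative to the present being
sampled. Above the oldest shift age the process is homogeneous, so the
span machinery applies there with span weights
$\text{duration} \times P(N(0) = n \mid m \text{ lineages at the
boundary})$, computed exactly from the zero-modified geometric descendant
law of the linear birth-death process; the recent window is then
completed forward by rejection until exactly $n$ tips survive. Origins
falling *inside* the window are handled as a second mixture component
whose exact mass is obtained by integrating the same descendant law; a
property test verifies that a split schedule with identical rates is
distributionally indistinguishable from the constant-rate sampler
(two-sample Kolmogorov-Smirnov, $\alpha = 0.01$, 500 trees each).

Runs are bounded by a cap of $10^6$ events; exhausting all retries raises
an error rather than returning a silently truncated tree. `lambda = mu`
is allowed in simulation (the decline scenario uses it) even though
estimation requires `lambda > mu`.

## Chronospecies mapping and fossil degradation

`assign_chronospecies()` overlays species boundaries on a complete tree.
At a budding event the continuing daughter is chosen uniformly — the
choice is symmetric and leaves all range statistics invariant. Cryptic
events (probability $\kappa$, applied to every speciation mode) give the
new species its ancestor's morphospecies label; a merged morphospecies is
recorded as the union interval from its earliest origination to its
latest extinction, because an observer of the fossil record would see one
continuous taxon. `range_statistics()` counts $B = (\text{ranges}) - 1$,
treating the oldest range as the process start; on complete data this
equals counting non-root origin modes, and it remains well defined after
ranges have been dropped.

Degradation mimics real fossil data: whole ranges are removed uniformly
or conditionally on extinction status (`subsample_ranges()`), or
occurrences are drawn as a Poisson process at rate $\psi$ within each
range (`sample_occurrences()`), with extant species given a present-day
record by default (their status is taken as known, configurable).
First/last appearances underestimate durations, biasing $B/S$ upwards —
asserted as a directional property in the tests. `estimate_ranges_hpp()`
is a deliberately simple homogeneous-Poisson endpoint estimator
(Metropolis-Hastings over endpoints and $\psi$, conjugate Gibbs draws for
the range rates, each taxon conditioned on being found at least once);
epoch-variable preservation is out of scope.

## Bayesian samplers

`mcmc_sample()` targets the product of the two likelihoods and
Gamma(1.1, 1.1) priors on every rate, via log-scale random-walk
Metropolis-Hastings tuned during burn-in to an acceptance rate near 0.3
(default burn-in 25%, no thinning — draws are cheap). The constrained
variants move on the constraint surfaces (two shared rates, or
$(\lambda, \mu, c \ge 0)$). Positive net diversification is treated as a
likelihood-domain constraint, so prior-only runs recover the untruncated
gamma prior (checked by Kolmogorov-Smirnov at $\alpha = 0.01$). The
posterior model check mirrors the credible-interval rules: equal if 0
lies in the intervals of both $\lambda^* - \lambda$ and $\mu^* - \mu$;
otherwise compatible if 0 lies in the interval of their difference and
$P(\lambda^* \ge \lambda) > 1 - \text{level}$ (one-sided, as stated);
otherwise incompatible. The skyline sampler uses independent per-bin
priors with no smoothing; bins without range data are flagged as
prior-dominated. Desk-scale chains default to $2\times10^4$ iterations —
posterior means on data of the sizes used here stabilise well below that,
and the determinism contract (fixed seed, bit-identical chains) is
tested.

## Problem sizes and what the tests show

The acceptance-level checks run at the design's study conditions: 200
trees per origin-age check, 100 replicates per model-selection study at
$n = 200$ tips, 60 replicates (tree set shared across the three
speciation-mode settings) for the estimator-recovery check, and
$6\times10^4$ prior-only / $2\times10^4$ posterior MCMC iterations.
Smaller unit and property tests use trees of 10-150 tips.

The generator emulates clean chronospecies data: completely known true
ranges (unless explicitly degraded), correct species identifications,
constant rates within intervals, no trait evolution, geography or
lineage-specific rates. Passing tests therefore demonstrate internal
consistency and statistical calibration of the estimators and tests under
the BDC process itself — not robustness to taxonomic error, non-uniform
preservation, or rate heterogeneity beyond the piecewise scenarios
exercised.

## Known limitations

* `(beta, lambda_a)` are interval-, not point-identified; the package
  reports intervals and the $\lambda^* - 2\lambda$ statistic only.
* The joint likelihood treats tree and ranges as independent although
  both derive from the same realisation; this is the standard
  approximation and slightly miscalibrates the tests when both blocks are
  small.
* No fossilized-birth-death tree likelihood, no joint occurrence-level
  inference with the tree, no reversible-jump shift detection, no
  AIC/BIC-based selection.
* The one-lineage pendant tree (`n_extant = 1`) cannot be converted to an
  `ape::phylo` object.
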