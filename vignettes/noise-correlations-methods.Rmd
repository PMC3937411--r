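---
title: "Noise correlations and population-coding fidelity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise correlations and population-coding fidelity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisecorr)
```

## The question

Sensory neurons respond variably to repeated presentations of the same
stimulus, and this trial-to-trial "noise" is correlated across cells.
`noisecorr` studies a deliberately abstract version of the resulting
question: with tuning curves and single-neuron noise variances held fixed,
how does encoded stimulus information change as the $N(N-1)/2$ pairwise
noise correlations $\rho_{ij}$ vary over everything that is mathematically
possible?

A coding problem is summarized by its sufficient statistics
(`population_stats()`): the local tuning sensitivities $f'$ ($N \times K$),
the response–stimulus cross-covariance $L$, the covariance of the mean
response $C^\mu$, the noise variances $\sigma_i^2$, and the stimulus
covariance $C^s$.  The noise covariance is assembled from the fixed
variances and the free correlations, $C^n_{ij} = \rho_{ij}\sigma_i\sigma_j$
(`noise_cov_from()`).

## The three information measures

* **Linear Fisher information** $I_F = \mathrm{tr}\,[f'^\top (C^n)^{-1} f']$
  — the accuracy of a locally linear unbiased discriminator near one
  stimulus value.  Requires $C^n \succ 0$.
* **OLE information** $I_{OLE} = \mathrm{tr}\,[L^\top (C^n + C^\mu)^{-1} L]$
  — the quantity subtracted from the stimulus variance to give the mean
  squared error of the optimal linear estimator, a *global* measure over the
  whole stimulus ensemble.  The optimal readout is
  $A = (C^n + C^\mu)^{-1} L$ (`ole_solution()`).
* **Gaussian mutual information**
  $I_{mut} = \tfrac12 [\log\det(C^n + C^\mu) - \log\det C^n]$ (nats) — valid
  when stimulus and response are jointly Gaussian, which imposes the
  consistency constraint $C^\mu = L (C^s)^{-1} L^\top$; the implementation
  checks this (relative spectral-norm tolerance $10^{-6}$) and errors
  otherwise rather than returning a number with no meaning.  A singular but
  PSD $C^n$ gives `+Inf` with a warning.

For $K$-dimensional stimuli the matrix forms are retained and the scalar
summary is the trace.

## The sign rule and its gradient

Signal correlations $\xi_{ij}$ measure tuning similarity through normalized
per-neuron sensitivity vectors: the rows of $f'$ for Fisher, of
$(D + C^\mu)^{-1}L$ for OLE, and of $D^{-1} L (C^s + L^\top D^{-1}
L)^{-1/2}$ for mutual information ($D = \mathrm{diag}(\sigma_i^2)$).  These
choices are not arbitrary: they are exactly the vectors for which the
gradient of the measure at independent noise factorizes entrywise as

$$ G_{ij} \;=\; -\,w_{ij}\,\xi_{ij}, \qquad w_{ij} > 0 , $$

which is the content of the sign rule: moving the noise correlations
opposite in sign to the signal correlations is uphill for information, and
by convexity (next section) this improvement persists globally along the
whole feasible ray, not just locally.  `info_gradient()` implements the
closed forms at arbitrary correlation points, `rescaling_weights()` returns
the $w_{ij}$, and the identity above is asserted to machine precision in
the tests — it is the oracle that pins the OLE/mutual sensitivity-vector
definitions.

Every closed form in this package is validated against an independent
oracle rather than trusted as transcribed: central finite differences for
every gradient, tolerance-free bisection for boundary steps, Monte-Carlo
simulation for the OLE error, and SVD ranks for solution-set dimensions.
Where a constant is a package choice rather than a derived quantity, that
choice is flagged explicitly below.

## Geometry: the spectrahedron and boundary optima

Admissible correlation patterns are those whose correlation matrix is
positive semidefinite — a bounded convex spectrahedron in
$\mathbb{R}^{N(N-1)/2}$.  All three measures are convex functions of the
correlations, so any maximizer that improves on independence lies on the
boundary of the feasible region (the PSD wall, or a norm cap when one is
imposed).  `classify_corr()` performs membership/boundary classification,
`max_step()` computes the exact exit point of a ray (symmetric
eigenproblem from interior points; tolerance-free bisection from boundary
points), and `random_admissible()` samples Gram matrices of random unit
vectors with controllable rank — rank-deficient draws are boundary points,
which is how the scans of the admissible set are generated (any dense
sampler serves; this one gives direct rank control).

Numerical tolerances: eigenvalues $\ge -10^{-9}\lambda_{max}$ count as PSD,
$< 10^{-12}\lambda_{max}$ as singular for inversion, and the boundary is
declared at $|\lambda_{min}| \le 10^{-8}\lambda_{max}$.  The theory assumes
exact definiteness; finite precision needs the explicit cutoffs.

## Optimization

Maximizing a convex function is a boundary-seeking, non-convex problem, so
`maximize_info()` uses projected multi-start gradient ascent: analytic
gradients, backtracking line search, and a Dykstra nearest-correlation
projection as the feasibility map, with starts at independence, at a scaled
sign-rule point, at user-supplied candidates, and at random admissible
points of mixed rank (20 by default, seeded).  Radial scaling toward the
independent point implements norm caps exactly, since the feasible set is
convex and contains the origin.  For Fisher and mutual information the
iterates are kept $10^{-8}$ above singularity and an optimum pinned at that
floor is flagged `divergent` — those measures genuinely diverge on the
boundary — rather than reported as overflow.

`penalty_sweep()` traces the strength–information frontier by maximizing
info $- \lambda \sum_{i<j}\rho_{ij}^2$ for a descending $\lambda$ grid with
warm starts; the Lagrange argument makes each solution optimal among points
up to its achieved norm.  The strength-targeted prefactor
$\lambda(c) = \lVert G\rVert_2/(2c)$ (from setting the penalized gradient
to zero near independence) targets a strength $c$ directly
(`penalty_for_strength()`); the generic grid is the default since the two
are equivalent by that same argument.  `sr_curve()` evaluates the measure
along the unit gradient direction and reports strengths beyond
`max_step()` as infeasible — the sign-rule prescription simply ceases to
exist past a critical strength, while optimized correlations continue.

## Noise cancellation

For a scalar stimulus with noise-free readout $A = (C^\mu)^{-1}L$, a noise
covariance attains the noise-free OLE bound
$\mathrm{tr}[L^\top (C^\mu)^{-1} L]$ exactly when $C^n A = 0$.  Writing
$q_i = \sigma_i |A_i|$, such correlations exist iff the polygon condition
$2\max_i q_i \le \sum_i q_i$ holds (`cancel_feasibility()`): the
construction needs $N$ vectors of lengths $q_i$ closing into a loop.
`closing_polygon()` builds them deterministically — lengths sorted
descending, the two smallest repeatedly merged into a virtual length chosen
at the midpoint of its feasible open interval, the base triangle resolved
by the law of cosines, each merge unfolded in a fresh standard-basis
dimension.  The proof allows any valid choice; determinism buys regression
tests.  The resulting direction Gram matrix, sign-flipped by the readout
signs, is the canceling correlation matrix (`construct_canceling()`);
neurons with $q_i = 0$ join as an uncorrelated identity block, and the
equality case collapses to the unique collinear solution (for two identical
neurons: perfect anti-correlation).

The set of all canceling correlations is convex and flat; its dimension
(`canceling_set_dimension()`) is the number of pair unknowns minus the rank
of the linear system $C^nA = 0$ — $N(N-1)/2 - N$ for generic all-nonzero
$q$ (170 at $N = 20$) — and $N_0(N_0+1)/2$ in the equality case with $N_0$
zeros, where the PSD constraint pins the nonzero block to a rank-one
matrix.  The equality-case formula was derived from the block-matrix
argument (the free PSD block of the zero-coordinate neurons plus their
couplings along the rank-one direction); the SVD rank oracle and explicit
two-sided perturbation tests arbitrate it in the test suite.  Because
$C^n A = 0$ with $A \ne 0$ forces singularity, every canceling solution
lies on the spectrahedron boundary.

`feasibility_probability()` estimates $P(2\max q \le \sum q)$ for i.i.d.
lengths by Monte-Carlo with a Wilson interval; for three Uniform(0,1)
lengths this is the classic triangle probability $1/2$, and it approaches
one in large populations — failure requires a single neuron to outweigh all
others combined.  For multidimensional stimuli the polygon theory does not
apply; `cancel_feasible_numeric()` decides feasibility by alternating
projections between the affine constraint set and the spectrahedron, and a
certified canceling point doubles as an optimizer start, so the computed
frontier provably saturates at the bound whenever cancellation is feasible.

## Sensitivity

The local condition number of a measure (relative change in information per
relative spectral-norm change of an input) is bounded by
$\lambda_{max}/\lambda_{min}$ of $C^n$ (Fisher) or of $C^n + C^\mu$ (OLE)
for covariance perturbations, and by
$2\sqrt{K}(\lambda_{max}/\lambda_{min})\lVert L\rVert_2/\min_k\lVert
L_k\rVert$ for tuning perturbations (`condition_bound()`).  These are the
standard first-order bounds; the empirical-ratio-below-bound property is
the contract (`empirical_kappa()`), with the "local" regime operationalized
as relative perturbations of at most $10^{-3}$.  The OLE bound is finite
even at singular $C^n$ — total covariance rules — which is why
noise-canceling solutions, despite sitting on the boundary, are robust in
the OLE sense, while near-singular Fisher optima are genuinely fragile.

## The synthetic population generator

`sample_population()` emulates a heterogeneously tuned direction-coding
population: von Mises tuning curves
$f_i(\theta) = \alpha_i \exp[\kappa_i(\cos(\theta - \phi_i) - 1)]$ with
peak rates $\alpha_i \sim \tfrac{19}{3}\chi^2_3$ (mean 19 spikes/s), widths
$\kappa_i$ log-normal with `meanlog = 2`, `sdlog = 2` ("mean 2, standard
deviation 2" are parameters of the underlying normal), preferred directions
equally spaced, and Poisson spike counts in a window so count variance
equals mean count.  The stimulus is the 2-D unit vector
$(\cos\theta, \sin\theta)$, $\theta$ uniform, so $C^s = I/2$ and $K = 2$;
`population_moments()` computes $L$ and $C^\mu$ by quadrature on a uniform
periodic grid (512 points by default; trapezoid and rectangle rules
coincide on a closed periodic grid) rather than by Monte-Carlo, for
reproducibility.

Two generator constants are package choices, made once: the count window
(100 ms, a standard counting window for such simulations) and the numeric
entries of the 3-neuron examples.  `fixture_population()` ships *synthetic*
examples, labelled as such in their documentation and return value, each
constructed to exhibit one regime of interest — the four correlation
regimes of the discrimination example (independent / anti-sign-rule /
sign-rule / sign-rule-violating-but-better), the convex two-parameter slice
$\rho_{13}=\rho_{23}$, and the pair of 3-neuron problems on either side of
the cancellation condition.  Seeds are always explicit, so any larger-scale
reproduction is statistical, never bit-exact.

What a green test on these synthetic worlds does establish: every
structural claim — sign rule, convexity, boundary optima, cancellation
construction and dimension, frontier saturation, sensitivity bounds — on
populations drawn from the stated distributions.  What it does not: any
claim about a particular recorded dataset, real spike trains,
stimulus-dependent noise covariances, higher-order correlations, or
nonlinear decoders, all of which are out of scope.

## Numerical and design choices worth knowing

* Pair vectors are lexicographic over $(i, j)$, $i<j$, 1-based — the
  ordering is a package convention, fixed in `pair_index()`.
* The rescaling-weight identity is implemented as $G = -w\circ\xi$ with
  positive $w$; a definition with $w\circ\xi = G$ and positive weights
  would contradict the sign rule itself.
* `ole_mse()` is `trace(C^s)` minus the OLE information and is only
  guaranteed nonnegative for realizable statistics;
  `random_population_stats()` generates realizable instances by
  construction ($C^\mu \succeq L (C^s)^{-1} L^\top$).
* The optimizer is a local method on a problem whose global optima may be
  disconnected; multi-start plus the analytic candidate points (sign-rule
  point, canceling point) is a practical, not certified, strategy.  No
  global-optimality certificates are attempted.
* Degenerate inputs are first-class: zero readout ($L = 0$) reports a flat
  objective rather than a canceling set; zero-norm sensitivity vectors make
  the affected signal correlations `NA` with a warning, never silently 0.

## A worked example

```{r example, eval = FALSE}
library(noisecorr)
ens <- sample_population(10, seed = 11)
st  <- population_moments(ens)
noise_free_bound(st)
feas <- cancel_feasible_numeric(st)
sw <- penalty_sweep(st, "ole", lambdas = c(2000, 100, 5, 0.2, 0),
                    restarts = 4, seed = 11,
                    extra_starts = if (feas$feasible) list(feas$corr))
sw$frontier
```

With this seed the population admits noise cancellation and the frontier's
last row reaches the noise-free bound exactly; the README shows the printed
numbers.
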