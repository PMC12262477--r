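---
title: "Integrated effective connectivity: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated effective connectivity: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

```{r}
library(iecflow)
```

## The problem

Resting-state fMRI gives an undirected picture of brain communication:
correlation (functional connectivity, FC) is symmetric by construction.
Effective connectivity (EC) asks the directed question — how strongly, and
with what sign, does region *j* drive region *i*?  Many estimators answer
it under different assumptions, and none dominates.  This package
implements a battery of complementary estimators, a principled way to
combine them into a single **integrated EC (iEC)** — a weighted sum whose
weights are optimized against a validation target — and the downstream
analyses a directed, signed connectome makes possible: signal-flow
mapping, a data-driven cortical hierarchy, and state contrasts.

Everything below uses one orientation convention: **rows are targets,
columns are sources** (`W[i, j]` is the edge `j -> i`).  Much of the
graphical-model literature uses the transpose; every estimator in this
package emits the rows-as-targets form and every consumer assumes it.

## The estimator battery

* **`estimate_var_l2()`** — lag-1 vector autoregression,
  `x(t+1) = A x(t) + e`, solved in closed form with an L2 (ridge) penalty
  `lambda` on the normal equations.  Lag 1 is the default and the tested
  configuration: at fMRI's temporal resolution higher lags add little.
  `lambda` defaults to 0.01 and is worth cross-validating on training
  data when a ground-truth target exists.  Signs are preserved — they
  carry the excitatory/suppressive semantics the hierarchy analyses need.
* **`estimate_mvgc()`** — Granger causality on the same lag-1 model: for
  each ordered pair, an F-test of the target's own history plus the
  source's history against the target's history alone; edge weight is the
  F statistic where significant, zero elsewhere.  MVGC is implemented for
  completeness but not included in the default integration battery: its
  estimates are the most sensitive to regional hemodynamic variation.
* **`estimate_direct_lingam()`** — DirectLiNGAM.  Assumes linear
  relations, acyclicity and non-Gaussian noise; finds a causal order by
  repeatedly extracting the most exogenous variable (scored by a
  mutual-information difference built from a maximum-entropy
  approximation with `log cosh` and Gaussian-derivative contrasts — a
  form valid for both sub- and super-Gaussian noise) and estimates signed
  coefficients by least squares along that order.  On Gaussian data the
  direction of an edge is provably unidentifiable; the package's tests
  treat chance-level orientation there as correct behavior.  The
  quadratic pair sweep is compiled (RcppArmadillo) and scores at most
  `order_samples` (default 1024) evenly spaced samples per step.
* **`estimate_patel_tau()`** — a pairwise measure on binarized
  activations.  Each region is binarized at its `q`-quantile (default
  0.75) and the asymmetry of the conditional activation probabilities
  P(Y|X) vs P(X|Y) gives a directionality index in [-1, 1].  An
  important structural fact, documented on the function: with quantile
  binarization every strictly continuous signal is active exactly
  `1 - q` of the time, the two conditional probabilities coincide, and
  tau is ~0.  Patel's tau therefore only orients **event-like**
  (zero-inflated) signals, and the package's planted orientation fixture
  (`synth_burst_pair()`) is built that way.  The sign convention is
  tau > 0 when P(Y|X) > P(X|Y) — the source's bursts are reliably
  followed by target activation while the target also activates on its
  own — which is the only convention that orients a linear forward model
  source-to-target under quantile binarization.
* **`estimate_skew_graph()`** — a two-step adjacency + orientation
  estimator in the spirit of fast adjacency-skewness search: adjacency by
  partial correlation given all other regions (thresholded and tested at
  level `alpha`), orientation by the left-right rule comparing the
  *uncentered* conditional second moments given positivity of each
  member.  Centering within the conditioned subsample would remove
  exactly the skewness the rule exploits, and empirically inverts the
  orientation; the uncentered statistic is the correct one and is what
  the package uses.  Fidelity to the reference Tetrad implementation is
  not claimed; externally computed matrices can be injected through
  `register_external_ec()`.

`ensemble_subsample()` stabilizes the graphical estimators by averaging
signed edge indicators over random half-length subsamples (default 100),
yielding weights in [-1, 1] interpretable as signed edge frequencies.
Subsampling destroys temporal order, which the targeted estimators treat
as irrelevant (i.i.d. samples); the VAR and MVGC never run subsampled,
and Patel's tau is conventionally applied without subsampling.

## Integration

`integrate_ec()` computes `iEC = sum_n beta_n EC_n` after dividing each
estimate's entries by the population standard deviation of its
off-diagonal cells (`standardize_ec()`).  No centering is applied: zeros
stay zero and signs survive.  Standardization is a package decision —
raw estimator scales differ by orders of magnitude, which would make the
beta coefficients uninterpretable.  An estimate with no edges at all
contributes a zero matrix rather than an error.

`optimize_weights()` maximizes the Pearson correlation between the
off-diagonal entries of the iEC and a target matrix (tracer-style
targets may carry NaN for unmeasured pairs; those cells are skipped), or
any user objective such as a composite simulation fit.  Weights are
bounded to [0, 1]: negative weights would silently invert an estimator's
sign semantics.  The optimizer is a Latin-hypercube exploration design
followed by box-constrained quasi-Newton polishing of the best design
points, repeated over restarts with the elementwise **median** beta as
the headline estimate.  The working contract — verified in the test
suite — is that on 3-dimensional problems the optimized objective is
within 1% of a 10,000-point random-search oracle.  A Gaussian-process
surrogate optimizer satisfies the same contract and can be substituted
where available; the correlation objective is smooth and low-dimensional
enough that the simpler global strategy is not the bottleneck.

For composite-fit objectives, evaluate each candidate beta with a fixed
simulation seed (so the optimizer sees a deterministic function) and
report the final fit with fresh seeds.

`crossval_integration()` implements the train/test protocol: betas are
optimized per training session, aggregated as the elementwise median
across sessions, and the fixed median beta is applied unchanged to every
test session, with per-session scores reported for each individual
estimator and the iEC.

## Synthetic ground truth

Directed ground truth for validation is planted in three steps:

1. **`generate_synthetic_sc()`** builds a symmetric weighted connectome
   stand-in: modular topology (default 5 communities whose within-module
   connection propensity follows a 0.35–0.95 gradient, adjacent-module
   bridges, sparse long-range background), heavy-tailed weights
   (lognormal by default, Pareto optionally), and weight–topology
   coupling (within-module edges boosted, between-module edges damped).
   The modular, weight-coupled design matters: the across-node
   correlation of clustering coefficients before vs after rewiring — a
   fingerprint the validation checks — is a property of *heterogeneous*
   local structure.  A homogeneous random graph would shuffle its (flat)
   clustering profile into noise under the same rewiring, telling us
   nothing about the procedure.
2. **`rewire_directed()`** plants directionality: directed edge swaps
   (`a->b, c->d` to `a->d, c->b`) that preserve binary in- and
   out-degree sequences exactly, reject self-loops and duplicates, carry
   each weight with its source stub, and roll back any batch of 10 swaps
   that disconnects the graph.  Swaps continue until the requested
   fraction (default 20%) of edges has been reassigned.  Because binary
   degrees are invariant by construction, the "degree distribution"
   fingerprint is checked on node *strengths* (weighted degrees), which
   do change as weights travel.  Rewiring operates on the weighted
   graph — the weights are needed downstream as Hopf coupling.
3. **`simulate_hopf()`** generates signals from the directed network
   (below), closing the loop: estimators see only the signals and are
   scored against the planted network.

`plant_hierarchy_network()` is the analogous fixture for the hierarchy
estimator: edge weights are exactly `beta_i - beta_j` plus Gaussian
noise, the estimator's own generative model.  `synth_burst_pair()` is
the two-node orientation fixture: a sparse positive-burst source
(Bernoulli(0.2) x Exp(1) — an event-like activation profile) with a
linear, noisy readout.

## The Hopf simulator

Each region is a Stuart-Landau oscillator near its bifurcation:

$$\dot x_i = (a_i - x_i^2 - y_i^2) x_i - \omega_i y_i
  + G \textstyle\sum_j C_{ij} (x_j - x_i) + \epsilon \eta_i(t)$$

with the rotated counterpart for $y_i$, integrated by Euler–Maruyama
(noise scaled by $\sqrt{dt}$).  Defaults: $a = -0.01$ (just below the
bifurcation, noise-driven oscillations), $\epsilon = 0.02$, $dt = 0.1$,
burn-in 20% of the integrated steps.  Two sign conventions in circulation
are both implemented: the default couples diffusively through
$(x_j - x_i)$ and rotates with $-\omega y$ in $\dot x$ / $+\omega x$ in
$\dot y$ (the standard normal form); `coupling_sign` and `rotation_sign`
flip either for sensitivity checks.  Model time units are mapped
one-to-one to seconds, so $dt = 0.1$ s and intrinsic frequencies in the
0.01–0.1 Hz BOLD band; this mapping is a documented package convention,
not an estimate.  `estimate_peak_frequencies()` supplies per-region
$\omega$ from data via a Welch periodogram, falling back to the band
midpoint (with a warning) when no peak stands out of the band's mean
level by a factor of 3.

In the validation study (`simulate_validation_session()`), coupling
matrices are scaled to unit maximum and $G = 3$: strong enough that the
signals carry recoverable connectivity information, comfortably inside
the Euler stability margin ($dt \cdot G \cdot \max_i \sum_j C_{ij} < 2$),
and below the synchronization regime.  Intrinsic frequencies are drawn
uniformly from 0.04–0.07 Hz — a homogeneous-$\omega$ network
synchronizes globally and becomes nearly uninformative about its own
coupling.

## Validation metrics

* `static_fc()` — Pearson correlation matrix.
* `fcd_distribution()` — sliding-window FC (default window 30 samples,
  step 3 — conventional values; the windowing is not prescribed by any
  ground truth and is config-exposed), then the correlation between
  vectorized upper-triangular window-FCs for every window pair; the
  upper triangle of that matrix is the FCD distribution.
* `ks_distance()` — sup-norm distance between empirical CDFs.
* `composite_fit()` — `fit = r - KS`, the FC correlation minus the FCD
  distance; 1 for a perfect match, invariant under common positive
  affine rescaling.
* `time_delay_projection()` — per-pair lagged cross-covariance extrema
  (default `max_lag` 10 samples) refined by parabolic interpolation,
  edge-pinned extrema censored; a region's value is its mean lag, with
  leaders negative.
* `f1_directionality()` — binarize the estimate at a retention sparsity
  (15% and 30% are the conventional operating points), binarize the
  truth at nonzero (an absent tracer projection is a structural zero),
  and score directed edge labels.

## Profiling and hierarchy

`signed_degree_profile()` computes weighted in-/out-strengths (row and
column sums) and signed-edge ratios with denominator **N**, the matrix
dimension, matching the defining formulas of the profile (not N-1, even
though the diagonal is structurally zero).  `tail_index()` is a Hill
estimator on the top fraction (default 10%) of positive weights; values
below 2 indicate a heavy tail.  `pathway_sign_profile()` splits edges at
a tracer threshold (default 0.5) into feedforward/feedback classes and
reports sign proportions within each; exact ties are dropped.

`estimate_hierarchy()` regresses every retained edge value on the
hierarchy difference of its endpoints, `E[EC_ij] = beta_i - beta_j`
(identity link), after keeping the top 15% of absolute weights by
default (ties at the cutoff are all kept — determinism beats exact
count).  The incidence system is solved by minimum-norm least squares
via the pseudoinverse of the incidence Gram matrix (a graph Laplacian),
and levels are anchored to mean zero per weakly connected component;
levels from different components are not comparable and a warning says
so.  Reversing all edges negates the levels exactly; adding a constant
to the planted levels changes nothing; negative edges genuinely move
the estimate (the signed EC carries information a positive-only EC does
not).

`normalize_stable()` rescales a signed EC into a decaying linear system,
`W / (lambda_max + c) - I` with `c = 1`, where `lambda_max` is the
**largest real part** among the eigenvalues — the only reading that
guarantees stability for signed matrices (a spectral-radius variant
would too, but more conservatively; the real-part reading is the
default).  All eigenvalues of the result have strictly negative real
part, always.

`propagate_impulse()` reads out the **time-integrated** impulse
response: analytically $-W^{-1} x_0$, or over a finite horizon via the
matrix exponential.  The integral is the package's definition of "signal
flow strength": the underlying dynamics `x' = W x` describe a decaying
trajectory, and the integral is the canonical scalar summary that makes
the trivial cases exact (for `W = -I`, a unit impulse integrates to
exactly 1 at the seeded region).  A fixed-time readout is available by
passing a finite horizon.  `module_flow()` seeds one module at a time
(unit mass split uniformly over the module's regions — per-region
seeding is available by calling `propagate_impulse()` directly) and
accumulates responses by target module, keeping positive and negative
parts separate: excitatory and suppressive streams are interpreted
separately throughout.

`compare_states()` contrasts two flow graphs per module and per stream
(positive/negative outflow separately — the streams are z-scored
separately, matching their separate interpretation), flagging modules at
|z| >= 1.645 and |z| >= 1.96.

## Numerical choices and degenerate inputs

* TSV round-trips are lossless to <= 1e-12 relative error (17
  significant digits written).
* Estimators reject degenerate inputs loudly: too few samples, constant
  regions (Patel), more regions than samples (partial correlation),
  singular designs at `lambda = 0`.
* Duplicated signals give zero Granger edges (the F-test numerator
  collapses), not a crash.
* `ks_distance()` evaluates both empirical CDFs on the pooled sample —
  exact, no interpolation.
* All stochastic operations take explicit seeds and are bit-reproducible
  under them; the ensemble and the optimizer derive per-restart seeds
  from the master seed.

## Scales used by the validation suite

The packaged validation study runs at desk scale, chosen to finish on a
single CPU while preserving the regime of interest: connectomes of 100
regions at density 0.15; 20% edge reassignment; Hopf sessions of 1200
output samples at `dt = 0.1`; 10 training and 10 test sessions for the
cross-validated integration; 100-replicate orientation checks at 5000
samples; 20-seed hierarchy recovery at 50 regions.  These sizes are
stated here as the package's reference configuration so results are
comparable across machines.

## What the synthetic tests do and do not show

The generators emulate the *structural* properties that matter for the
methods — modular heavy-tailed connectomes, genuinely directed ground
truth with preserved topology, oscillatory signals driven through known
coupling, event-like activations for pairwise orientation.  They do not
emulate hemodynamic convolution and its regional variability, scanner
noise and motion, spatial autocorrelation of parcellated signals, or
subject heterogeneity.  A passing suite therefore demonstrates that the
estimators and the integration machinery recover what they claim under
their own assumptions at realistic scale — not that any particular
empirical dataset will yield the same accuracy.  MVGC's exclusion from
the default battery, and the caution that Patel's tau is uninformative
on strictly continuous signals, are the two places where the package
hard-codes lessons about robustness rather than leaving them to the
user.
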