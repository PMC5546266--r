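---
title: "Constructing and diagnosing effective time priors from fossil calibrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and diagnosing effective time priors from fossil calibrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timeprior)
```

## The problem

Bayesian molecular clock dating needs a joint prior over the ages of all
interior nodes of a rooted species tree — the *time prior*.  In practice a
paleontologist supplies minimum and/or maximum age bounds for a handful of
clades, and the dating program turns those bounds into a full
multidimensional distribution.  Two things happen along the way that users
rarely see:

1. **Truncation.** Calibration densities are specified per node, but the
   prior must respect the constraint that every ancestor is older than its
   descendants.  The program renormalizes the product of calibration
   densities on that feasible region, which can reshape the marginals
   drastically.
2. **Combination with a branching process.** Uncalibrated nodes need a
   density too, supplied by a birth–death-sampling (BDS) process, and
   programs differ in how they glue it to the calibrations.

The distribution the sampler actually uses — the *effective prior* — can
therefore differ sharply from what the user wrote down.  This package
makes that machinery explicit and inspectable: it evaluates the joint
densities, samples them without any sequence data, and reports how far
each effective marginal has drifted from its calibration density.

## Calibration densities

Three families are implemented (`cal_uniform()`, `cal_offset_exp()`,
`cal_cauchy_min()`), covering the conventions of the major dating
programs.  Ages are in arbitrary time units — the shipped fixtures use Ma
— and densities are per time unit.

* `cal_uniform(tL, tU, pL, pU)`: joint bounds as a uniform density, with
  *soft* tails carrying probability `pL` below `tL` and `pU` above `tU`
  (defaults 0.01 and 0.05).  A maximum-only bound is `tL = 0, pL = 0`;
  `hard = TRUE` zeroes both tails.
* `cal_offset_exp(tL, theta)`: a minimum bound decaying exponentially
  above `tL`, mean `tL + 1/theta`.  The default `theta = 10/tL` puts the
  mean at `1.1 tL`; the analytic five-species example instead uses
  `theta = 1/tL` (mean `2 tL`), set per fixture and never implicitly.
* `cal_cauchy_min(tL, p, c, pL)`: a heavy-tailed minimum bound whose mode
  is `(1 + p) tL` and whose scale is `c tL` (defaults `p = c = 0.1`);
  smaller `p` and `c` concentrate mass near the minimum.

The exact functional form of the soft tails is a design choice (programs
document their semantics, not their formulas).  We use a power density
`f(t) = f(tL) (t/tL)^(a-1)` below the minimum and an exponential tail
above the maximum, with the free parameter in each chosen so the tail is
continuous at the bound and carries exactly the stated mass.  Every
testable property — total mass, tail masses, continuity, mode location —
is independent of this choice, and the acceptance-grade quantities never
depend on tail shape.  The truncated-Cauchy body is a Cauchy with
location `(1+p) tL` and scale `c tL` restricted to `(tL, ∞)` and
renormalized to mass `1 - pL`; its mean is infinite, which is why the
truncation report carries median-based as well as mean-based shifts.

## Strategies and constructions

`propagate_calibrations()` implements the three calibration strategies:
**st1** uses bounds as given; **st2** gives every *calibration* node joint
bounds, inheriting a missing minimum from the oldest calibrated
descendant and a missing maximum from the youngest calibrated ancestor;
**st3** does the same for *every* interior node, with minimum 0 where no
fossil sits below.  Two readings of the inheritance rule are possible
when several candidates exist; we take the largest descendant minimum and
the smallest ancestral maximum, the only choices that keep the propagated
bounds simultaneously informative and feasible.  Propagation is a single
pass over the original bounds — inherited bounds do not cascade — and is
therefore idempotent, which the test suite asserts.  The root must carry
a maximum under st2/st3, else nothing could propagate.

Two constructions combine the calibrations with the BDS kernel
(`joint_log_prior()`):

* the **conditional construction**,
  `f(t) = f_cal(t_C) · f_BDS(t_C̄ | t_C)`: the truncated calibration
  product times the BDS density of the uncalibrated ages *conditioned* on
  the calibrated ones;
* the **multiplicative construction**,
  `f(t) ∝ f_cal(t_C) · f_BDS(t_C, t_C̄)`: the calibration product times
  the *full* BDS density, so calibrated ages are double-counted.  This is
  mathematically incoherent but is what some widely used programs do, so
  it is implemented exactly as defined.

Only the uniform BDS kernel is supported (`lambda = mu`, `rho -> 0`):
given the root age `t1`, the non-root ages are order statistics of
i.i.d. `U(0, t1)` draws, density `(s-2)!/t1^(s-2)`.  General
`(lambda, mu, rho)` kernels are out of scope; constructors reject them.

### Exact conditional densities via order-polytope volumes

Under the uniform kernel, the conditional density of the free ages given
the calibrated ones is uniform on the *section* of the tree's order
polytope cut by the fixed ages, so the conditional factor is the
reciprocal of that section's volume.  `order_polytope_volume()` computes
it exactly: the free nodes decompose into connected components, and
within each component a postorder recursion
`F_v(a) = ∫_{L_v}^{a} ∏_c F_c(t) dt` builds piecewise polynomials with
breakpoints at the fixed ages.  Two closed-form fast paths (a free
subtree with no interior fossils below, and a chain with a single fossil
at its bottom, volume `(A - L)^m / m!`) cover the common cases.  The DP
is validated in the tests against Monte-Carlo hit-fraction estimates and
against the known `2/(t1 - t4)^2` factor of the five-species ladder.

## The analytic five-species example

For the ladder with a minimum bound at `tL = 10` on the youngest interior
node and a maximum `tU = 100` on the root, all six strategy ×
construction combinations are tractable after integrating out the two
middle ages.  `analytic_normalizer()` evaluates each normalizing constant
by adaptive nested quadrature (relative tolerance 1e-10, which also keeps
the *absolute* error far below the smallest constant, ~1.6e-5);
`analytic_marginal_pdf()` and `analytic_marginal_cdf()` derive the
effective marginals of `t1` and `t4` by quadrature of the reduced joint.
We deliberately derive marginals numerically rather than transcribing the
printed closed forms: the published multiplicative-construction marginal
formulas mix up the `t1`/`t4` labels in places, and quadrature of the
joint is unambiguous.  Where the closed forms are recognizable (the st1
conditional marginals, the st2/st3 order-statistic marginals, and the
corrected multiplicative forms) the tests assert pointwise agreement.

## Prior-only sampling

`sample_time_prior()` samples any tree/strategy/construction combination
by Metropolis-within-Gibbs, mirroring the "run the program without data"
procedure:

* uncalibrated nodes are drawn *exactly* from their conditionals, which
  under the uniform kernel are uniform on (max child age, parent age);
* calibrated nodes whose update does not touch a free-component volume
  are likewise drawn exactly, by quantile inversion of their calibration
  density truncated to the feasible interval;
* the remaining calibrated nodes alternate reflected sliding-window
  proposals (windows tuned to ~30% acceptance during burn-in, then
  frozen) with independence proposals from the calibration density,
  whose density cancels in the Hastings ratio;
* a whole-tree age-scaling move and several random-clade scaling moves
  per sweep decorrelate deep nodes, whose ages otherwise diffuse slowly
  through chains of nested constraints.

Initial ages are built by recursive midpointing: each node starts a fixed
fraction of the remaining headroom above the larger of its floor (its own
and its descendants' minima) and its children's ages, guaranteeing
feasibility whenever the bounds admit any feasible vector.  Two chains
run by default; their per-node means are compared in units of the pooled
Monte-Carlo standard error, and per-node effective sample sizes (Geyer
initial positive sequence) and 95% equal-tail and HPD intervals are
reported by `summarize_prior()`.

`rejection_sample_prior()` is an independent exact sampler used to
cross-validate the MCMC on small trees.  For the conditional construction
it draws calibration ages from their densities, accepts iff they respect
the partial order — making the acceptance rate an unbiased estimate of
the truncation normalizer, ~0.80 in the five-species st1 example — and
then fills each free component sequentially from the top, sampling each
node from its exact conditional (proportional to the product of its
children's volume polynomials) by envelope rejection.  For the
multiplicative construction it draws the root from its calibration, all
other ages from the uniform kernel, and reweights by the non-root
calibration densities against their suprema.  Acceptance is guarded
(default floor 1e-4) with an error directing users to the MCMC sampler.

## Synthetic data

`simulate_timetree()` generates random rooted binary trees with true node
ages by recursive splitting (each node's age a random fraction of its
parent's), plus a ladder option reproducing the five-species topology.
`simulate_calibrations()` places bounds that straddle the true ages, so a
feasible age vector always exists and propagated sets are always
satisfiable.  The generator emulates exactly what the prior machinery
needs — partial-order structure, bound nesting, mixtures of joint and
minimum-only calibrations — and nothing else: no fossil preservation
model, no sequence evolution, no realistic diversification dynamics.
Passing tests on synthetic trees therefore certify the *prior
arithmetic*, not any claim about real fossil records.

## Problem sizes and numerical choices

The test suite runs the five-species oracle comparison with two chains of
175,000 sweeps per combination (≥10,000 effective samples per reported
node), cross-validates MCMC against rejection sampling on twenty trees of
5–10 tips, and samples the primate (10 tips, 9 calibrations) and
seed-plant (48 tips, 15 calibrations) fixtures with two chains of
8,000–12,000 post-burn-in sweeps — enough that the directional contrasts
it asserts (tens of Myr) exceed their Monte-Carlo errors by an order of
magnitude.  Quadrature tolerances are 1e-10 (normalizers) and 1e-8
(marginal masses); the overlap coefficient uses a fixed 512-bin histogram
so reports are deterministic given the samples; Kolmogorov–Smirnov
distances are computed against exact calibration cdfs.  Degenerate inputs
fail fast with named errors: empty calibration sets reject the
conditional construction, contradictory bounds abort initialization and
propagation, and infeasible age vectors evaluate to `-Inf` rather than
raising.

## Fixtures and naming

The primate fixture's nine calibrations resolve by most-recent-common-
ancestor of the defining taxon pairs; its node ids (11–19) coincide with
the published numbering.  One clade label in the source table
("Ponginae" for the Gorilla–Pan/Human pair) conflicts with standard
nomenclature; the fixture follows the taxon pair, not the label.  The
48-taxon seed-plant topology is *synthetic*: only the 15 calibrated
clades are authoritative, and the remaining resolution follows standard
seed-plant relationships.  All calibrated comparisons (e.g. the Proteales
and monocot stem nodes aging in the order st1 < st2 < st3) are keyed to
clades, never to node numbers.

A caveat worth spelling out: *strategy contrasts are topology-sensitive*.
Under the conditional construction the marginal prior of a calibrated
node is the truncated product of the calibration densities alone (the
uncalibrated nodes' conditional integrates to one), so moving from st2
to st3 can raise a calibrated node only through the order-statistics
stack of its own newly bounded subtree, while the extra bounded nodes
inserted *above* it strictly tighten its ceiling.  A calibrated clade
with only two sampled taxa has no internal stack, and on this synthetic
topology its prior mean drops slightly from st2 to st3 even though
richer clades (the monocots) rise, and roots rise strongly.  Conclusions
about particular nodes on a tree whose full resolution is not known
should therefore be drawn only for clades whose internal sampling is
known.

## Limitations

* Only the uniform BDS kernel is implemented; conclusions about priors
  under informative birth–death settings are out of reach.
* The multiplicative construction is implemented as defined; the package
  does not emulate any particular program's internals, and known
  unexplained discrepancies between programs and the analytic form are
  out of scope.
* Posterior inference with sequence data is deliberately absent: the
  package characterizes priors, which is exactly the part of a dating
  analysis users are urged to inspect and most often skip.
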