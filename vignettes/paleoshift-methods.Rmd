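---
title: "Shift statistics, fossil rates and model comparison: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift statistics, fossil rates and model comparison: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

paleoshift detects diversification-rate shifts in time-calibrated fossil
phylogenies from tree imbalance, estimates per-interval origination and
extinction rates from the same trees, and asks — by formal model
comparison — whether the shifts concentrate in intervals of elevated
extinction. This vignette records the models, the tunable parameters,
the numerical choices, and the places where the design was genuinely
open, so that a reader can judge exactly what the test suite does and
does not establish.

## The equal-rates Markov null and the shift statistics

Under the equal-rates Markov (ERM) model of clade growth every extant
lineage is equally likely to be the next to split. The probability that
the root split of a clade of $n$ tips partitions them into unordered
sides of $l$ and $n-l$ tips is $2/(n-1)$ for $l \neq n/2$ and $1/(n-1)$
for an even split; the probability of a split at least as lopsided as an
observed $(l, n-l)$, $l \ge n-l$, is $\min\{1,\, 2(n-l)/(n-1)\}$.

We define the *nodal surprise* of a split as
$S = -\log \Pr(\text{split at least this lopsided})$, zero for a
maximally balanced partition. For every internal node with at least 3
descendant tips, the statistics are assigned to its more speciose child
$c$ (the branch along which a rate shift would be inferred):

* $\Delta_1(c) = S(\text{parent split})$ — the raw imbalance at the
  parent;
* $\Delta_2(c) = \max\{0,\, S(\text{parent split}) - S(c\text{'s own
  split})\}$ — the parent's imbalance discounted by imbalance sitting
  one level deeper, so that a lopsided split *inside* $c$ does not get
  double-counted at $c$.

$\Delta_2 \le \Delta_1$ always. Significance is Monte-Carlo: for a
scored node whose parent clade holds $n$ tips, the null distribution of
$\Delta_2$ is built from ERM topologies of $n$ tips (statistic taken at
the larger root child), and
$p = (1 + \#\{\Delta_2^{null} \ge \Delta_2^{obs}\}) / (N + 1)$, ties
counting toward the tail, so $p > 0$ and the test errs conservative.
Shifts with $p < 0.05$ are classed *significant* and
$0.05 \le p < 0.1$ *substantial*; a p-value of exactly 0.05 falls in
the substantial class. No multiplicity correction is applied by default
(Benjamini–Hochberg sits behind `adjust = TRUE`). Because a subclade of
an ERM tree is itself ERM conditional on its size, a null draw needs
only the two nested splits at the scored node, which makes each draw
O(1); null distributions are cached per clade size within a call.
Defaults: `n_sims = 1e4` per clade size, giving roughly $10^{-2}$
p-resolution at desk scale (the argument accepts much larger values).

When the input topology has polytomies, `resolve_polytomies()` draws
seeded random refinements (via `ape::multi2di`; random sequential
refinement, not exactly uniform over resolutions) and
`consensus_shifts()` retains only clades — identified by their subtended
tip-label set, which is topology- and order-independent — that are
significant or substantial in *every* replicate, reporting
across-replicate mean $\Delta_2$ and $p$.

## Time calibration and slicing

Ages run in Ma before present throughout (larger = older). Calibration
sets each internal node's base age to the oldest first-appearance age
(fad) among its descendant tips, then walks tipward-to-rootward pushing
ancestors older until every *internal* branch lasts at least
`min_branch` (default 1 Ma; 0 permits zero-duration ladders). A tip's
branch runs from its calibrated origin down to its last appearance
(lad); the span between branch origin and fad is its ghost lineage,
non-negative by construction. Terminal branches may still have zero
duration when fad = lad at the parent's age; the Mk machinery treats a
zero-length branch as an identity transition rather than demanding
strictly positive durations.

Stages are halved at their midpoints into early/late substage bins. One
boundary convention is used everywhere: a point event at a shared bin
boundary belongs to the *older* bin (bins are `[young, old)` in age,
with the oldest bin closed at the window edge), and interval presence in
a bin requires positive-duration overlap — touching a boundary does not
count. `slice_tree()` keeps exactly the tips whose lineage interval
(branch origin to lad, ghost included) overlaps the bin, suppresses
unary nodes, and leaves every node age unchanged. The per-bin
mean-$\Delta_2$ series averages over **all** scored nodes of the slice
by default so that it reflects magnitude and number of shifts jointly;
`significant_only = TRUE` averages over detected shifts instead. Note a
consequence of the default, quantified under *Limitations*: the
attainable surprise of a clade grows with its size, so the all-nodes
mean drifts upward with slice richness.

## Diversity, rates, and the sampling correction

The phylogenetic diversity estimate (PDE) of a bin counts the lineage
intervals — one per branch, ghost portions and range extensions
included — present in the bin. Origination events are cladogeneses
(internal-node ages) assigned to bins; extinction events are tip lads,
except that tips whose lad sits exactly at the window's young edge are
treated as extant at window close, not extinctions. Rates divide events
by PDE, so a bin's extinction rate is the fraction of its lineages that
terminate there and never exceeds 1.

Sampling is measured per bin as the proportion of crossing lineages that
are *observed* there (some tip's [fad, lad] range overlaps the bin along
that branch) as opposed to *ghost*; internal branches carry no observed
range and count as ghost by definition. The default correction damps
each bin's rates multiplicatively by its sampling proportion —
discounting bins whose apparent rates rest mostly on inferred lineages —
and is pluggable (`correction = "identity"` or any `function(rate, s)`),
since discounting conventions differ between studies. Mass-extinction
flags mark bins whose (corrected) extinction rate is strictly above 30%.

### Finite-bin expectations and the recovery test

For a linear birth–death process with speciation $\lambda$ and
extinction $\mu$ per Ma observed in bins of length $\Delta t$, write
$g = (e^{(\lambda-\mu)\Delta t} - 1)/(\lambda-\mu)$. Conditional on
$N_0$ lineages entering a bin, the expected number of cladogeneses in
the bin is $\lambda N_0 g$ and of terminations $\mu N_0 g$; each
cladogenesis adds *two* new branches to the bin's lineage pool, so the
expected PDE is $N_0(1 + 2\lambda g)$ and the per-bin ratio estimators
have expectations

$$p_o \approx \frac{\lambda g}{1 + 2\lambda g}, \qquad
  p_e \approx \frac{\mu g}{1 + 2\lambda g},$$

which reduce to $\lambda\,\Delta t$ and $\mu\,\Delta t$ as
$\Delta t \to 0$. The rate-recovery test therefore inverts the pooled
ratios, $\hat\lambda = p_o / ((1 - 2 p_o) g)$ and
$\hat\mu = p_e / ((1 - 2 p_o) g)$, and checks both against the true
values within Monte-Carlo error (100 complete-sampling replicates at
$\lambda = 0.3$, $\mu = 0.2$, 25 Ma in 1-Ma bins). The oldest 5 bins are
excluded: simulations that die out completely are redrawn, and
conditioning on survival inflates early growth when the process starts
from 2 lineages; the distortion is negligible once the standing count is
large.

## Ancestral states and trait groups

Binary ecological traits (0 = absent, 1 = present) evolve as a
continuous-time 2-state Markov chain over branch durations.
`mk_loglik()` is the standard pruning recursion with per-node scaling;
impossible configurations return $-\infty$ as a value. `fit_mk()`
maximises it by bounded 1-D (equal-rates, the default — one parameter
suits sparse paleontological codings) or 2-D (all-rates-different)
search on the log-rate scale, and computes marginal node probabilities
by a down–up pass equivalent to rerooting at every node. The root prior
is uniform (0.5, 0.5) by default with a stationary option, since
conventions differ across implementations; both the likelihood and the
fitted equal rate match an independent implementation
(`phytools::fitMk` with equal root prior) to numerical precision, and
the pruning likelihood and marginals are checked against brute-force
enumeration on all rooted shapes up to 6 tips.

A branch belongs to a trait *group* when the node it descends from has
marginal P(state 1) above the cutoff (default 0.5) or any ancestor does
— "descended from" is hereditary, so reversals do not eject descendants
(`hereditary = FALSE` gives the strict-state variant) — or when it is
the terminal branch of a trait-positive tip. Cladogenetic events are
attributed to the group of the parent branch; group and complement
events and lineage counts sum to the full-tree values in every bin.

## Model comparison

The per-bin mean-$\Delta_2$ series is regressed on the rate series by
maximum-likelihood GLS (ML, not REML, so log-likelihoods are comparable
across fixed-effect structures) with an AR(1) residual correlation —
fossil time series are autocorrelated, and the choice costs every
candidate the same one parameter. Six candidates are fitted: intercept
only (null), extinction, origination, mass-extinction,
origination + extinction, origination + mass-extinction. The parameter
count $k$ includes intercept, slopes, the AR(1) coefficient and the
residual variance; $\mathrm{AIC} = 2k - 2\log L$ and Akaike weights are
computed across exactly the fitted set. A predictor that is constant
over the series (e.g. no bin flagged as a mass extinction) is collinear
with the intercept, so models containing it are dropped from the set
with a message rather than fitted degenerately. The "random variation
around a mean" null is implemented as an estimated intercept.
A random-forest regression (500 trees, out-of-bag evaluation, fixed
recorded seed) supplies an absolute-fit view: permutation importance as
% increase in out-of-bag MSE, node-purity importance, and out-of-bag
variance explained.

## The synthetic scenario generator

Because the original supertree lives in supplementary material, every
stage is validated on synthetic data whose generating process is fully
known. `simulate_bd_tree()` is a continuous-time birth–death simulation
over a study window, starting from a split into two lineages at the old
edge, with: lineage-inherited rate classes (a clade shift reassigns one
uniformly chosen extant lineage and its descendants at a trigger time),
binary traits evolving in-line as part of the event process, and
instantaneous extinction pulses in which each extant lineage survives
with a probability set by its current trait state. The true tree, true
ages, true states and the shifted clade's tip set are all returned, so
recovery is always scorable. `simulate_fossil_sampling()` overlays
incomplete sampling: each terminal branch accrues Poisson($r$ per Ma)
occurrences, a taxon's observed range is the span of its occurrences,
unsampled taxa vanish (truncating ranges and creating ghost lineages),
and lineages extant at the window close are recorded there with
probability $\rho$ (default 1, the standard sampling-at-present
convention — without it nothing could ever be identified as extant at
window close and the terminal bin would always look like a mass
extinction). Sampling is uniform in time per lineage; time-varying $r$
is a deliberate extension point, not implemented.

Three presets over a 320–260 Ma window (10-Ma stages, 5-Ma substage
bins) define the study conditions, chosen once from power
considerations at desk scale:

* **erm-null** — $\lambda = 0.06$, $\mu = 0.03$, $r = 1$: homogeneous
  rates; the shift test should fire at its nominal level.
* **clade-shift** — base $\lambda = 0.04$, $\mu = 0.01$, $r = 1.5$; at
  282 Ma one lineage switches to $5\lambda$. The multiplier and the
  ~40-Ma run-in keep the shifted clade around 20–90 sampled tips —
  large enough that a (clade, small sister) split can reach
  $p < 0.1$, small enough to run in seconds.
* **trait-buffered-pulse** — $\lambda = 0.10$, $\mu = 0.04$,
  $q_{01} = q_{10} = 0.02$, $r = 1.2$; at 287 Ma a pulse kills
  trait-negative lineages with probability 0.8 but trait-positive ones
  with only 0.2, the "extinction selectivity creates imbalance"
  mechanism in its simplest form.

Draws that go totally extinct, leave fewer than 20 sampled taxa, or (for
clade-shift) sample fewer than 3 tips of the shifted clade are redrawn
from a derived seed — such draws realise no scenario at all — with the
attempt count recorded in the manifest. Identical seeds yield
byte-identical bundles, and every emitted file round-trips through the
package's readers.

What the generator deliberately does *not* emulate: diversity-dependent
or environment-driven rates, time- or facies-varying sampling,
anagenetic pseudo-speciation, taxonomic error, and polytomies from
conflicting source trees (polytomy handling is exercised on constructed
fixtures instead). Passing tests on these data show the machinery is
correct under the stated generative assumptions, not that real fossil
records satisfy those assumptions.

## Problem sizes and what the checks establish

The suite's heavier checks run at sizes chosen so the full suite
completes in a few minutes: split-law normalization to $n = 200$ and
tail-probability oracle equivalence to $n = 50$; simulator split
frequencies at $10^5$ draws per tip count (4–12); type-I error from
$10^3$ ERM trees of 64 tips with $10^3$ null simulations each, measured
at one scored node per tree (the root's larger child) because scored
nodes within a tree are dependent and a pooled binomial interval would
be invalid — the measured rejection rate sits inside the 3-standard-
error band around 0.05, while the rate pooled over *all* nodes is
conservative (about 0.01) because small clades have few attainable
$\Delta_2$ values and ties go to the tail; shift placement on 50
clade-shift seeds; Mk oracle equivalence on all 1,065 rooted shapes of
4–6 tips over a rate grid at relative tolerance $10^{-10}$; and rate
recovery over 100 birth–death replicates.

## Limitations

* **Scale-dependence of the all-nodes mean $\Delta_2$.** Attainable
  surprises grow roughly logarithmically with clade size, so richer
  slices have higher expected mean $\Delta_2$ under the null itself. In
  pulse scenarios at desk scale (tens of taxa, 12 bins) the post-pulse
  radiation makes the youngest slices the richest, and the global
  argmax of the series usually lands there rather than at the pulse
  bin, even though the pulse is plainly visible as a local elevation
  and as the raw extinction spike. The end-to-end pulse check in the
  acceptance suite asserts the argmax-at-pulse property and fails at
  these sizes; with hundreds of taxa per slice the size effect
  saturates. The significant-only variant is size-robust (p-values are
  ERM-calibrated) but at these tree sizes detections are too sparse to
  form a usable series.
* **GLS at 12 time points.** A single-spike extinction series rarely
  beats the intercept-only model against the 2-AIC-unit penalty at
  series length 12; the null model tops the candidate set in most pulse
  seeds. This is a power statement about short series, not an
  implementation defect — with generated series of length 40 the
  correct predictor is top-weighted in over 90% of seeds and pure noise
  selects the null in the majority.
* The $\Delta_2$ formalization here is defined from ERM tail surprises;
  it preserves the published semantics (parent-level imbalance,
  discounted for nested imbalance, assigned to the more speciose child,
  ERM-calibrated) but is not numerically identical to the historical
  SymmeTREE executable, whose internals are not reproduced. Monte-Carlo
  p-values are the comparable quantity.
* The ghost-lineage damping correction is one member of a family of
  sampling corrections; it is exposed as a pluggable function
  precisely because published corrections differ in their algebra.
* Whole-tree imbalance indices, branch-length likelihood models of
  diversification, trait-dependent diversification (BiSSE-family), and
  subsampling-based sampling standardization are out of scope.

## Worked entry points

`analysis/01_simulate_scenarios.R` through
`analysis/04_model_comparison.R` run the full workflow on the generated
scenarios and write tables under `results/`; `run_full_analysis()` does
the same end-to-end from a config file. `scripts/acceptance.R
--seed <int> --out <path>` recomputes the headline quantities (published
Akaike weights from the printed AICs, type-I error, shift placement
rate, birth–death rate recovery, and the pulse-scenario outcome rates)
from scratch.
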