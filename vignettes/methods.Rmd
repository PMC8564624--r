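---
title: "Dating population splits and linking them to rapid climate change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating population splits and linking them to rapid climate change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`glacialsplit` implements an inference chain for asking *when* populations
of a species split from one another and *whether* those splits coincided
with episodes of rapid climate change. The chain has four analysis stages
and a synthetic-data module that makes every stage testable against known
ground truth without any external data:

1. **Allele frequencies from genotype likelihoods** (`estimate_maf`,
   `polymorphism_test`, `apply_site_filters`, `build_joint_sfs`): per-site
   minor-allele frequencies estimated directly from genotype likelihoods,
   never from hard genotype calls, followed by coverage/p-value/MAF
   filters and construction of joint site frequency spectra (SFS).
2. **Demographic inference** (`expected_sfs`, `fit_model`,
   `convert_units`): expected joint SFS under split-with-migration models,
   Poisson composite-likelihood fitting with multi-start optimization, and
   conversion of the fitted diffusion-unit parameters to years and
   individuals through a directly estimated mutation rate.
3. **Climate rate-of-change analysis** (`rate_of_change`,
   `smooth_series`, `detect_episodes`, `interval_episode_overlap`):
   percent temperature change per millennium, loess-style smoothing,
   detection of rapid-change episodes, and a permutation test for overlap
   between split-time intervals and those episodes.
4. **Species distribution modelling** (`fit_learner`, `cross_evaluate`,
   `build_ensemble`, `mess`, `project_time_slices`,
   `detect_range_collapse`): a TSS-gated median ensemble calibrated on
   current occurrences, projected across past climate time slices, with
   multivariate environmental similarity surfaces (MESS) flagging
   extrapolation and an area series from which range collapses are read.

The motivating system is a migratory forest bird (the pied flycatcher,
*Ficedula hypoleuca*) whose Spanish, British and central/north European
lineages split during glacial–interglacial transitions, but every
component is generic.

# The demographic model and its units

All demographic quantities are dimensionless, scaled by a reference
diploid size $N_{ref}$: sizes $\nu = N/N_{ref}$, times in units of
$2N_{ref}$ generations, migration $M_{ij} = 2N_{ref} m_{ij}$ with
$m_{ij}$ the per-generation fraction of population $i$ replaced by
migrants from $j$, and $\theta = 4 N_{ref} \mu L$ for a sequence of
effective length $L$.

The two-population model is: an ancestral population at size 1 changes to
$\nu_{anc}$, persists for $t_{anc}$, then splits into daughters $\nu_1,
\nu_2$ that exchange migrants ($M_{12}, M_{21}$) for $t_{split}$ until the
present. The three-population variant adds a second split
($t_{split2} < t_{split}$) of the second daughter, matching the observed
chronology in which the most divergent lineage (Spain) separates first
and the British lineage separates from the central/north European group
much later.

## The expected-SFS engine

The expectation of the joint SFS is computed by a moment system: the
expected count $\Phi_n(i)$ of sites with derived-allele count $i$ in a
sample of $n$ obeys, under drift in a population of relative size $\nu$,

$$\frac{d\Phi_n(i)}{dT} = \frac{1}{2\nu}\Big[(i{-}1)(n{-}i{+}1)\Phi_n(i{-}1)
 - 2i(n{-}i)\Phi_n(i) + (i{+}1)(n{-}i{-}1)\Phi_n(i{+}1)\Big],$$

with mutation entering the singleton class at rate $\theta n/2$. This
system is closed and exact; its stationary state is exactly $\theta/i$,
which is why the equilibrium test in the suite passes at machine
precision. Migration couples the population axes and raises the required
sample size in the source population by one; we close the hierarchy with
a local-quadratic jackknife (the underlying frequency density is treated
as locally quadratic, making the order-$(n{+}1)$ spectrum a precomputable
linear image of the order-$n$ spectrum). Within an epoch all coefficients
are constant, so the affine system is integrated *exactly* by the action
of a matrix exponential (a scaled, truncated Taylor expansion on the
sparse generator); splits redistribute the spectrum hypergeometrically.

Because the jackknife is the only approximation, accuracy is controlled
by one knob: `extra`, the number of additional working samples per axis
before the final hypergeometric projection (the same role grid refinement
plays in diffusion-PDE solvers). With no migration the computation is
exact up to round-off for any `extra`. At the default `extra = 4`, the
two-population expectation at $n = (6,6)$, $t_{split} = 0.2$, $M = 2$
differs from a 1.8-million-site coalescent simulation by a
total-variation distance of about 0.005, within the Monte-Carlo noise of
the acceptance-scale simulations. Raising `extra` to 8–14 reduces the
closure error roughly in proportion to the square of the working size;
the cubic cost of the exponential is the trade-off. The engine supports
up to 40 haploids per population, which covers spectra from the sample
sizes this kind of reduced-representation study uses (6–15 individuals
per population).

Correctness is pinned to independent oracles rather than to any existing
solver binary: the closed-form equilibrium, the hypergeometric
redistribution identity at $t_{split} \to 0$, and the package's own
structured-coalescent simulator (an entirely independent code path).

## Fitting and uncertainty

`composite_loglik` treats unmasked SFS cells as independent Poisson
counts; $\theta$ is profiled analytically ($\hat\theta = \sum n_c / \sum
e_c$), which is exact and removes one optimization dimension.
`fit_model` runs Nelder–Mead from multiply perturbed starts, in log space
for sizes and times (bounds $\nu \in [10^{-3}, 10^2]$, $t \in [10^{-4},
10]$) and in linear space for migration ($M \in [0, 20]$, so $M = 0$ is
attainable); each run restarts its simplex at the incumbent until the
relative log-likelihood change falls below $10^{-8}$. Summaries (median
and 25–75% quantiles, linear interpolation) are computed across converged
runs.

A caveat documented here deliberately: on a single dataset a well-behaved
multi-start optimizer usually drives every run to the same optimum, so the
across-run interquartile range measures optimization reproducibility, not
sampling uncertainty. When we validate parameter recovery on simulated
data we therefore pool optima across independently simulated datasets, so
that the reported interval reflects sampling variability — the quantity a
reader would want such an interval to mean. For real data, resampled
(bootstrap) spectra would play that role; bootstrap machinery is out of
scope here.

When sites enter the spectrum through a strict MAF filter, the
low-frequency cells are unobservable by construction. `mask_low_maf`
masks every cell whose total minor-allele count corresponds to a
frequency at or below the cutoff, and `fit_model` evaluates the expected
spectrum under the same mask. Fitting a MAF-truncated spectrum without
this mask drives split times toward zero as the model tries to explain
the missing singletons — an ascertainment artifact, not a property of the
data.

## Real units

With the directly estimated mutation rate $\mu = 2.3\times10^{-9}$ per
site per year, a generation time of 2 years and an effective length $L$
(from `estimate_L`: callable length scaled by the retained fraction of
segregating sites), `convert_units` recovers $N_{ref} =
\hat\theta/(4\mu g L)$ and converts times as $t \cdot 2 N_{ref} g$ years
and migration as $M/(2N_{ref})$ per generation. The conversion and its
inverse are exact; mixing per-year and per-generation rates silently
would change dates by the generation time, which is why the unit chain is
a single, tested code path.

# Climate rates of change

`rate_of_change` implements percent change per resampling interval,
$(T_t - T_{t-1})/T_{t-1} \times 100$, with the lag pointing at the
previous, older sample of a series resampled to 1000-year spacing. On
anomaly series the lagged denominator crosses zero; such points are
returned as `NA` and counted, never silently propagated, and an
absolute-difference mode (°C per interval) is provided as a labelled
alternative with no zero-crossing pathology. "Rapid" is operationalized
scale-free as exceeding a quantile (default 0.90) of $|ROC|$; flagged
runs separated by at most one lattice step are merged into episodes.
The overlap statistic between a split-time interval and the episode set
is the covered fraction of the interval; its null distribution comes from
circular shifts of the episode pattern along the time axis, which
preserves episode number, widths and spacings.

The smoother is local linear regression with tricube weights over the
span-fraction nearest neighbours (span 0.05 by default). It reproduces
constant and linear series exactly and is tested against an independently
coded weighted-least-squares implementation; exact equivalence with any
particular statistical package's loess is not claimed.

# The SDM ensemble

Occurrences are thinned to one record per 50 km cell; background points
are drawn uniformly from the study region. Two transparent learner
families implement the ensemble contract: a ridge-penalized logistic
regression on linear and quadratic terms of the four climate variables,
and a percentile range-envelope. Members are cross-evaluated by repeated
70/30 resampling (twice by default) with max-TSS scoring over a 101-point
threshold grid; final members are refit on all occurrences, and only
members with cross-evaluation TSS at or above 0.8 enter the cell-wise
median ensemble — if none passes, that is an explicit error. Binary range
maps use the mean of the member max-TSS thresholds; the suitable-cell
count is the area proxy (cells are treated as equal-area at this fixture
scale; spherical weighting is a documented omission). MESS surfaces
follow the canonical percentile formula with the reference sample taken
at the occurrence cells; negative values flag extrapolation. A range
collapse is any run of slices whose area falls below half the series
median.

# What the synthetic data emulate — and what they do not

The generators define the study conditions under which the package is
validated:

* `simulate_coalescent`: Hudson-style structured coalescent with
  piecewise-constant sizes, continuous migration, splits, and
  infinite-sites mutation — the same model family the inference assumes,
  so it is a *calibration* oracle, not a robustness test. No
  recombination, no selection, no RAD-locus dropout.
* `simulate_genotype_likelihoods`: Poisson depth (default emulating
  moderate-coverage RAD data), independent per-read errors with the
  GATK-style two-allele likelihood. Real base-quality variation, mapping
  error and allelic bias are not modelled.
* `simulate_climate`: piecewise-linear baseline, stadial/interstadial
  style jump events with linear ramps (amplitudes up to the 16 °C swings
  reported for glacial transitions), AR(1) noise. Real ice-core series
  have chronology error and multi-scale variability the AR(1) term only
  caricatures.
* `simulate_landscape`: Gaussian-smoothed white-noise rasters
  (correlation length 3 cells), a logistic niche whose default
  coefficients `c(-16, 8, -6, 6, -4)` produce a strongly
  climate-delimited range occupying roughly 9% of the grid — sharp enough
  that the logistic learner clears the 0.8 TSS gate, as the real
  ensemble did; the envelope learner typically does not, exercising the
  gate's exclusion path. Presences are sampled proportional to true
  suitability.

Passing tests therefore demonstrate internal correctness and calibration
under the assumed models, not robustness to the many ways real data
violate them.

# Numerical choices and degenerate inputs

* EM for per-site frequencies is run from a ladder of five starting
  frequencies (the per-site likelihood can be bimodal) and finished with
  a bracketed golden-section polish; the likelihood trace is
  non-decreasing within each EM run and the final estimate matches an
  exhaustive $10^{-5}$-step grid search to $10^{-4}$.
* The polymorphism test's null lies on the parameter boundary; the
  $\chi^2_1$ upper tail is used, which is conservative, matching the
  convention of the standard genotype-likelihood tools.
* A flat likelihood triple is "no data": excluded from the coverage
  count and from the estimate. All-missing sites are unestimable and are
  dropped by the coverage filter.
* Exact frequency ties at 0.5 break lexicographically by allele label
  and are flagged.
* Spectrum corners (sites variant nowhere or everywhere) are always
  masked; folding merges complements onto the canonical half-lattice,
  halving the mid-frequency diagonal so counts are conserved and folding
  is idempotent.
* Degenerate observed spectra (e.g. all mass in one cell) either
  converge or flag non-convergence with per-run diagnostics; they never
  crash.
* MESS with a degenerate (zero-range) reference variable scores 0 at the
  reference value and decreases linearly away from it, with a warning.

# Problem sizes used in the validation suite

The shipped tests run at desk scale, chosen to make Monte-Carlo error
bars meaningful while keeping the whole suite in the minutes range:
equilibrium checks at $n \le 20$; coalescent-oracle comparisons at
$10^5$ independent genealogies; parameter recovery on three simulated
datasets of about $1.5\times10^5$ segregating sites each ($n = 8+8$
haploids, five optimization starts); episode recovery over five climate
seeds; the permutation-null calibration at 1000 trials; and the
end-to-end determinism check on a reduced pipeline configuration. The
pipeline's own defaults (`default_config()`) are modest for the same
reason and are meant to be scaled up for real use.

# Known limitations

* The migration closure is approximate; at very high migration rates
  ($M \gtrsim 10$) and small `extra` the expected spectrum's
  boundary-adjacent cells carry percent-level bias. Raise `extra` when
  precision there matters.
* Composite-likelihood values are valid for point estimation and model
  comparison heuristics, not for likelihood-ratio confidence intervals
  (SFS cells are not independent in the presence of linkage).
* The three-population model is implemented and oracle-tested, but
  fitting its 16 parameters is practical only with many parameters held
  fixed.
* The SDM stage treats grid cells as equal-area and ignores dispersal
  limitation; projections are climate-only.
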