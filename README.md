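# glacialsplit

Dating population splits from genotype-likelihood data and linking them to
episodes of rapid climate change.

Reduced-representation sequencing of wild populations (for example ddRAD
data from pied flycatchers sampled across western Europe) yields genotype
*likelihoods*, not reliable genotypes. This package implements the full
inference chain from such data to dated population splits and their
climatic context, for population geneticists and molecular ecologists:

* **Allele frequencies without genotype calls.** Per-site minor-allele
  frequencies are estimated by maximizing
  `l(f) = sum_i log sum_g GL_i(g) C(2,g) f^g (1-f)^(2-g)` via EM, with a
  likelihood-ratio polymorphism test (chi-squared 1 df, conservative at
  the boundary) and the production filter chain (data in >= 2/3 of
  individuals, p < 1e-6, MAF > 0.05), plus BED-mask exclusion of
  coding/conserved/CpG regions.
* **Joint site frequency spectra and demographic fits.** 1-3 population
  SFS built from the likelihoods (posterior binning or a joint-EM
  estimator), expected spectra under split-with-migration models
  (sizes nu = N/N_ref, times in 2 N_ref generations, migration
  M = 2 N_ref m) computed by a moment-system engine, Poisson
  composite-likelihood fitting with multi-start Nelder-Mead, and exact
  conversion to years and individuals through the directly estimated
  mutation rate mu = 2.3e-9 per site per year, a 2-year generation time
  and the effective length `L = L_unfiltered * seg_filtered /
  seg_unfiltered`.
* **Climate rates of change.** `ROC_t = (T_t - T_{t-1}) / T_{t-1} * 100`
  on a series resampled every 1000 years, loess-style smoothing
  (span 0.05), quantile-based detection of rapid-change episodes, and a
  circular-shift permutation test for overlap between split-time
  intervals and episodes.
* **Species distribution modelling.** Occurrence thinning (one record
  per 50 km cell), uniform background sampling, repeated 70/30
  cross-evaluation with max-TSS scoring, a TSS >= 0.8 gated median
  ensemble, projection across paleoclimate time slices, MESS
  extrapolation surfaces (negative = at least one variable outside its
  reference range), and range-collapse detection on the suitable-area
  series.
* **Synthetic data with known truth** for every stage: a structured
  coalescent simulator (Rcpp), a GATK-style read/error model for genotype
  likelihoods, a climate simulator with engineered stadial/interstadial
  jumps, and spatially autocorrelated landscapes with a known logistic
  niche.

## Worked example

Simulate two populations that split 0.1 time units ago with symmetric
migration, build the spectrum, fit the model and convert to years:

```r
library(glacialsplit)

truth <- two_pop_model(nu_anc = 2, t_anc = 0.3, t_split = 0.1,
                       m12 = 1, m21 = 1)
sim <- simulate_coalescent(truth, c(8, 8), n_sites = 3e5,
                           theta_per_site = 0.1, seed = 1)
sim$n_seg
#> [1] 130337

fit <- fit_model(sim$sfs, "two_pop_sizechange_split_mig",
                 n_starts = 5, seed = 100, maxit = 400)
median(fit$runs$t_split[fit$runs$converged])
#> [1] 0.1070715

units <- unit_system(mu_site_year = 2.3e-9, generation_years = 2,
                     L = estimate_L(1e7, 35686, 79918))
summarize_split_times(fit, units)
#>   median_kya  q25_kya  q75_kya n_runs
#> 1   156.3038 156.3008 156.3373      5
```

The fitted split time (0.107 in diffusion units) lands within 7% of the
simulated truth (0.1); `summarize_split_times` reports the median and
25-75% range of the converted split times in thousands of years, where
the absolute scale is set by the profiled theta and the mutation-rate
unit chain (here through an illustrative 10 Mb callable length scaled by
the retained-site fraction). The whole pipeline
(simulate -> genotype likelihoods -> filters -> SFS -> fit -> climate
linkage -> SDM projection) runs behind one call:

```r
run_pipeline(list(seed = 1), out_dir = "demo_run")
```

which writes per-stage outputs (Beagle GLs, dadi-style `.fs` spectra, fit
JSON, episode tables, area series) plus a manifest echoing the resolved
configuration. A thin CLI wrapper is installed at
`inst/cli/glacialsplit.R`.

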