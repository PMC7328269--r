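---
title: "Quantifying false positives induced by empirical-Bayes batch correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying false positives induced by empirical-Bayes batch correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methbatchsim)
```

## The problem

Illumina methylation BeadChips measure 8 samples per chip at fixed row
positions, with 12 chips per sample plate. Samples processed on the same
chip, row position or plate share systematic measurement offsets — batch
effects — and when those technical factors are confounded with the
case/control variable, uncorrected batch effects masquerade as biology.
The standard remedy is ComBat, a parametric empirical-Bayes location/scale
adjustment, usually applied through integrated pipelines that pass the
outcome-of-interest variable to the correction as a covariate.

`methbatchsim` turns the corrective step itself into the object of study.
It simulates beta-value matrices that *cannot* contain any real signal,
pushes them through batch correction and a moderated-t differential
methylation analysis, and measures what the correction alone does to the
test statistics. Because the input is pure noise, every "significant" probe
is a false positive by construction. The package reimplements both the
correction and the test from scratch so that every arithmetic step is
inspectable; the widely used sva and limma implementations serve as
independent references in the test suite, where agreement is asserted to
1e-6 and 1e-8 respectively.

## The generative model

Each probe $j$ has a mean $\mu_j \in [0,1]$ and standard deviation
$\sigma_j$ on the beta scale. Null data are drawn independently as
$\beta_{ij} \sim N(\mu_j, \sigma_j^2)$ and clamped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 0.001$. The clamp keeps
the logit transform $M = \log_2 \beta/(1-\beta)$ finite; corrections run on
the M-value scale by default (a `on_mvalues = FALSE` switch corrects betas
directly, since published analyses exist on both scales).

When no measured per-probe parameter table is supplied,
`emulate_parameter_profile()` synthesises one: probe means come from a
three-component beta mixture — an unmethylated mode (Beta(2.5, 22.5), mean
0.1), a methylated mode (Beta(22.5, 2.5), mean 0.9) and a minority
intermediate component (Beta(5, 5)) with weights 0.42/0.42/0.16 — and probe
SDs from a log-normal with median 0.03 (sdlog 0.55), truncated to
(0, 0.5]. These values encode the familiar bimodal landscape of array
methylomes: most CpGs sit near fully unmethylated or fully methylated with
small technical spread, a minority is intermediate and more variable. The
emulator reproduces the *shape* of a real profile, not any particular
cohort: it has no probe-probe correlation, no type-I/type-II intensity
shift (the carried `design_type` column is descriptive only), and its
exact mean/SD joint distribution is stylised. Conclusions that depend only
on calibration (mean p, $\lambda$) transfer well; absolute significance
counts depend on the profile and on the probe count, so the package
reports them both raw and as per-probe rates.

Platform comparisons subsample the profile uniformly without replacement
(`subsample_platform()`), mirroring how 27K/450K-sized data can be derived
from an EPIC-sized profile. Platform sizes are configuration with defaults
27,000 / 450,000 / 758,289 — the last being the EPIC probe count used
throughout as the full-scale reference.

## Layouts and batch factors

`build_layout()` fills chips (8 rows) and plates (12 chips) sequentially.
Three group assignments span the confounding spectrum:

* **balanced** — every chip carries 4 cases and 4 controls, with the
  case/control phase alternating between chips so each row position hosts
  each group equally often. Group is orthogonal to both batch factors.
* **random** — a uniform permutation of $n/2$ labels each; the realistic
  default.
* **unbalanced** — cases fill the first chips contiguously, with the two
  samples adjacent to the group boundary exchanged. The exchange is a
  deliberate design choice: under *perfect* confounding the combined
  design of batch indicators and group is singular, and a correction that
  includes the outcome covariate cannot be fitted at all (the reference
  implementation stops with an error). Any completed outcome-model
  correction of an "unbalanced" study therefore implies at least minimal
  crossing, and the single boundary swap is the most extreme such design.
  Perfectly confounded layouts remain constructible by hand; `combat_fit()`
  then drops the confounded covariate with a loud warning and flags the
  fit, so the run proceeds as a covariate-free correction.

Because the swap leaves one crossing sample per group, the group effect in
the standardization model is estimated from almost no information; this
makes the unbalanced + outcome-model cell *more* extreme here than in a
layout with several crossings. Reported inflation magnitudes for that cell
should be read as an upper envelope of the near-confounded family, while
directions and orderings across cells are stable.

## The correction under test

`combat_fit()`/`combat_apply()` implement parametric empirical-Bayes batch
adjustment: per-probe least-squares standardization against batch
indicators plus optional covariates; per-batch location/scale estimates
$(\hat\gamma_{ij}, \hat\delta^2_{ij})$ on the standardized data; a normal
prior on locations and an inverse-gamma prior on scales, both fitted
across probes by method of moments; and a fixed-point iteration for the
conditional posteriors $(\gamma^*_{ij}, \delta^{*2}_{ij})$, run to
relative tolerance 1e-4 with a 500-iteration cap (unconverged probes are
flagged, not fatal). One numerical subtlety is intentional: the
convergence criterion divides the location change by the *signed* previous
value, exactly as the canonical implementation does, so that the two
implementations agree elementwise rather than merely approximately.
Degenerate inputs are handled explicitly — a single batch level yields an
identity fit, zero-variance probes are floored at machine precision, and
any non-finite adjusted value aborts with a diagnostic. The nonparametric
pathway is deliberately unimplemented and errors loudly.

Multi-factor correction (`sequential_correct()`) loops over the ordered
factor list — `c("row", "chip")` by default — feeding each pass's output to
the next, as integrated pipelines do; ComBat itself is single-factor. The
three usage variants under study are `"with_outcome_model"` (group
indicator passed as covariate, the integrated-pipeline behaviour),
`"no_model"` (batch indicators only) and `"none"`.

## The readout

`fit_dmp()` fits the two-group linear model per probe on the beta scale
and moderates residual variances with the standard empirical-Bayes
squeeze: hyperparameters $(d_0, s_0^2)$ from the moments of
$\log s^2_j$ across probes (with the trigamma inversion solved by Newton
iteration), $\tilde s^2_j = (d_0 s_0^2 + d\, s^2_j)/(d_0 + d)$, and a t
reference on $\min(d + d_0, m\,d)$ degrees of freedom. When the observed
variances show no excess spread beyond chi-square sampling noise the prior
df is infinite and all probes share the pooled prior variance.

Run-level metrics follow the study design: the mean p-value across probes
(0.5 under a calibrated null), the genomic inflation factor
$\lambda = \mathrm{median}\,\chi^2_{obs} / \mathrm{median}\,\chi^2_{null}$
with the observed statistics obtained as $\chi^2_1$ quantiles of $1-p$
(so $\lambda = 1$ under uniformity), and counts of probes passing
Benjamini–Hochberg $q < 0.05$ and Bonferroni $p < 0.05$ (both through
`stats::p.adjust`; $\alpha = 0.05$ throughout). Q-Q plots use
$(i - 0.5)/m$ plotting positions. Mean p is computed over all probes with
no filtering.

## Perturbations

Two perturbations can be layered onto the null:

* **Batch offsets** (`inject_batch_effects()`): one offset per factor
  level, drawn Uniform($-a$, $+a$) with $a = 0.01$ (a ±1% "brightness"
  shift), added as a constant to every probe of the affected samples and
  redrawn independently each repetition. Uniformity is an assumption — the
  magnitude range is the modelled quantity — and the offset is
  probe-constant by design; probe-correlated or type-specific batch
  structure is out of scope.
* **Spike-ins** (`spike_group_effects()`): 2000 probes receive a true
  case-group shift calibrated through the pooled-variance t quantile so
  that the expected two-sided p equals a target on the ladder
  $10^{-1} \ldots 10^{-20}$, 100 probes per rung, using each probe's own
  profile SD. Shifts are always positive; detection metrics are
  sign-blind. Spiking precedes injection, and detection is scored on the
  truth mask at $q < 0.05$.

## Orchestration, seeds and scale

`scenario_config()` + `replicate_scenario()` run the
design × variant × perturbation grid with any repetition count; the sweep
functions grow one knob at a time (levels of one synthetic factor, number
of two-level factors, sample size in chip multiples, platform size).
Every stage of every repetition derives its own substream from one master
seed via `sample.int` under `withr::with_seed`, so a whole result table is
a pure function of (profile, config) and the global RNG state is never
touched. Identical configs reproduce byte-identical tables.

Default analysis scale is a 20,000-probe profile: mean p and $\lambda$ are
probe-count-free in expectation, so the study's calibration conclusions
hold at this scale, while FDR/Bonferroni counts scale roughly linearly
with probe count and are interpreted as rates. The built-in suite runs the
headline grid at m = 20,000 with 10–100 repetitions, the null guardrail at
m = 50,000, and the factor-level and sample-size sweeps at m = 20,000 with
10 and 1–3 repetitions per cell; these sizes are the package's chosen
trade-off between Monte-Carlo stability and a test suite that runs in
minutes. Two caveats at reduced scale are documented rather than hidden:
the level count at which the first FDR hit appears depends on the probe
count (at full EPIC scale it lands near 7; at m = 20,000 the expected
count crosses 1 only around 10–12 levels), and the random-design
sample-size trend bottoms out at a floor of a few probes where rank
correlations drown in Poisson noise.

## What a clean pipeline should show

Running `variant = "none"` on uninjected null data is the built-in
guardrail: mean p within a percent of 0.5 and $\lambda$ within a few
percent of 1. Any analysis pipeline can be audited the same way — feed it
signal-free data and check that nothing comes out. The package's central
finding mirrors its motivating literature: outcome-model correction
inflates the statistics on *every* design (including the fully balanced
one), covariate-free correction of a near-confounded design deflates them
(a false-negative risk), and only the random design with covariate-free
correction stays near calibration.

## Known limitations

Probe-probe correlation, spatial within-plate gradients, hybridization
date effects, missing values, dye/type-specific batch structure and
region-level (DMR) analysis are all out of scope; the batch model is
deliberately minimal. Absolute false-positive counts from the emulated
profile are indicative, not calibrated to any cohort; the loader accepts a
measured per-probe table (`load_parameter_table()`) whenever one is
available, and its column mapping is configurable because published
parameter tables vary in schema.
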