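---
title: "Quantifying crossover interference from focus data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying crossover interference from focus data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meicoc)
```

## The measurement problem

At pachytene, crossover-designated recombination sites can be scored as
immunostained foci (e.g. Zip3) along the synaptonemal-complex axis of a
chromosome, with the axis itself traced from Zip1 or Rec8 lines. The
data unit is therefore one chromosome: an axis length in micrometres
and an ordered list of focus positions measured from a marked end.
From a few hundred such chromosomes per strain, two classical summaries
of crossover interference are computed, and `meicoc` implements both
together with the surrounding bookkeeping (per-nucleus counts and
densities, obligatory-crossover frequencies, tetrad missegregation
scoring, immunofluorescence quantification).

## The coefficient of coincidence

Each chromosome is normalised to unit length and cut into `n_intervals`
equal bins (default 30 — on a ~3 μm yeast chromosome XV axis this is
roughly 0.1 μm per bin). For each interval the CO frequency is the
fraction of chromosomes bearing *at least one* focus there: presence,
not multiplicity, so two foci falling in one bin count once. For an
interval pair the observed double-CO frequency is the fraction of
chromosomes with foci in both bins; the predicted frequency under
independence is the product of the two marginal frequencies; and their
ratio is the coefficient of coincidence. Averaging CoC over all pairs
sharing the same midpoint-to-midpoint distance gives the CoC curve.
Interference shows up as CoC ≈ 0 at short distances rising to ~1 at
long distances; a no-interference (Poisson) process fluctuates around 1
everywhere.

Numerical conventions, chosen here because the procedure itself does
not fix them:

- **Bin edges.** Bins are half-open, `[k/n, (k+1)/n)`, with the top
  edge closed so a focus at exactly the chromosome end is kept in the
  last bin rather than lost.
- **Undefined pairs.** A pair with a zero marginal frequency has
  predicted DCO = 0 and no defined CoC; such pairs are flagged,
  excluded from curve averaging, and counted in the curve's
  `n_undefined_pairs` attribute rather than silently dropped.
- **Replicates.** If the input table carries an `experiment` column,
  curves are computed per experiment and averaged, with the SE across
  experiments; otherwise a single pooled curve is returned. Grouping by
  distance is exact because distances are integer multiples of `1/n`.

`coc_pairs()` is verified in the test suite against an independent
brute-force enumeration over chromosomes and interval pairs on small
random datasets, and against hand-computed examples.

## Gamma-distribution interference strength

The second summary fits the pooled inter-adjacent focus distances
(consecutive gaps within a chromosome; chromosomes with fewer than two
foci contribute none) with a two-parameter gamma distribution by
maximum likelihood. The shape ν measures interference: ν = 1 is
exponential gaps (Poisson placement, no interference), larger ν means
more regular spacing.

- **Units.** Gaps are pooled in normalised axis units (fraction of each
  chromosome's own length) by default, matching the per-chromosome
  normalisation of the CoC analysis; `normalized = FALSE` pools raw
  micrometres. Both are exposed because the choice is not dictated by
  the procedure; for a fixed axis length they differ only by scale,
  which leaves the shape untouched.
- **Algorithm.** With the scale profiled out as `mean(x)/shape`, the
  shape solves `log(k) − digamma(k) = log(mean(x)) − mean(log(x))`.
  This score equation is solved by safeguarded Newton iteration (steps
  halved until they stay on the positive half-line) from the standard
  closed-form starting value, to a tolerance of 1e−10 on the score. The
  implementation is cross-checked in the tests against
  `MASS::fitdistr` and, for the two-observation edge case, against a
  dense grid maximisation of the likelihood.
- **Confidence interval.** The 95% CI for the shape is a seeded
  percentile parametric bootstrap (default 1 000 resamples drawn from
  the fitted gamma), vectorised over resamples. Degenerate inputs — no
  gaps, or all gaps identical, for which the likelihood is unbounded in
  ν — raise estimation errors rather than returning a number.

### What recovery tests do and do not show

On simulated datasets of 2 000 chromosomes the fitted shape recovers
the generating ν ∈ {1, 2, 5} within 10%, and bootstrap CIs cover the
true shape in ≥ 90% of 100 replicates when the data are i.i.d. gamma
(the fitted model's own sampling situation), which is the setting in
which a parametric bootstrap makes a coverage promise.

One bias is inherent to the method and worth stating: on a finite
chromosome, a gap of length *g* can only be observed if it fits inside
the axis, so observed gaps are size-biased against long gaps in
proportion to roughly the mean-spacing-to-axis-length ratio μ/L. Plain
gamma MLE on pooled gaps — the field's standard procedure, kept here —
therefore carries a small upward bias in the shape (a few percent at
μ/L ≈ 0.17, shrinking as chromosomes get longer relative to the
spacing). The 10% recovery tolerance absorbs it; analyses comparing
strains at similar focus densities are unaffected because the bias is
shared. For the same reason the CI-calibration check is run under the
fitted model rather than under renewal sampling, where any nonzero bias
would dominate coverage at large *n* regardless of the interval method.

## The synthetic-data generator

`simulate_focus_dataset()` places foci by a *stationary* gamma-renewal
process: gaps are i.i.d. Gamma(ν, μ/ν), and the first event is drawn
from the equilibrium forward-recurrence distribution — sampled exactly
as *U* × (length-biased gap), where the length-biased version of
Gamma(ν, θ) is Gamma(ν + 1, θ). Stationarity makes interval occupancy
position-homogeneous, avoiding edge artifacts that would distort CoC
near chromosome ends; for ν = 1 this convention coincides with simply
drawing the first gap from the origin, and the tests exercise that
sub-case through the Poisson reductions. Events beyond the axis end are
discarded; zero-focus chromosomes are kept (the obligatory-CO analysis
needs them), with an optional `obligate_co` redraw flag, default off.

Per-nucleus axis lengths are lognormal, parameterised by arithmetic
mean and CV — a positive-support law chosen as the simulation's
modelling convention, not a claim about any particular dataset. The
defaults (3 μm mean, CV 0.15, 200 nuclei) are in the range a yeast
chromosome XV spread experiment produces; analyses that need other
regimes set them explicitly.

**RNG contract.** One root seed; nucleus *i* draws from a child stream
seeded deterministically as `(seed + 9973·i) mod (2³¹ − 1)`. Identical
config therefore gives bit-identical datasets, and — tested explicitly
— the first *k* nuclei of a larger run equal a smaller run with the
same seed, so datasets are reproducible under partial regeneration.

What the generator does *not* emulate: DSB formation and CO
homeostasis, two-pathway (interfering plus non-interfering) CO
mixtures, measurement error in focus positions, chromosome-specific
focus-density differences, and optical blurring of nearby foci.
Passing tests therefore validate the analysis code's statistics, not
any biological claim about real spreads.

`simulate_tetrads()` emits 2Y/2R tetrads, aberrant fluorescent patterns
at a set missegregation rate, and all-dark tetrads at an independent
blank rate. `simulate_nucleus_image()` builds uniform background plus
Gaussian spots plus Gaussian noise, clipped at zero, and returns the
exact integrated spot signal as ground truth.

## Focus metrics and tests of significance

Per-nucleus summaries sum foci and axis length over a nucleus's
chromosomes (duplicate chromosome records are a hard data error);
zero-focus frequencies are reported per chromosome and per nucleus.
The double-mutant independence expectation is the product of the two
single-mutant fractions of wild type; overlap and conditional fractions
are exact count arithmetic, with display rounding separated from the
stored value.

Missegregation scoring: tetrads with exactly two yellow and two red
spores are faithful; any other pattern with at least one fluorescent
spore is one missegregation event (MI/MII sub-typing is out of scope);
all-dark tetrads never enter numerator or denominator.

Two significance tests are provided: a *t*-test of means — Welch by
default, since equal variances between mutant strains is rarely
defensible, with `pooled = TRUE` for the classical Student form — and
the pooled two-proportion *z*-test for frequencies, both two-sided,
with stars at 0.05/0.01/0.001. The *z* implementation is cross-checked
in the tests against `prop.test(correct = FALSE)` via z² = χ².

## Immunofluorescence quantification

The background for a nucleus is estimated from three line profiles
drawn perpendicular to randomly chosen chromosome fragments: each
profile is a bump over a flat floor, and the floor is "where the curve
flattens". That criterion is operationalised as: smooth with a
3-sample moving average, mark slopes below 2% of the profile's dynamic
range (`slope_frac`, configurable), and take the maximal flat runs
anchored at the two profile ends, requiring at least 3 samples per
side — profiles without such tails (too short a line, or a monotone
ramp) raise an error advising a longer line. The background is the mean
raw intensity over both tails, and the per-nucleus value is the mean of
the three profiles.

Integration then counts mask pixels *strictly above* background (ties
at exactly background are excluded, which keeps every counted pixel's
contribution positive when the background equals the true floor), sums
them into the raw total, and corrects by background × count. On
simulated nuclei with spot amplitudes ≫ noise the corrected total
recovers the known signal within 5%; the residual error is the balance
of two small opposing terms (noise pixels just above threshold, spot
tail pixels below it), both proportional to mask area × noise SD, which
is why quantification assumes bright signal over modest noise — as the
mixed-slide same-exposure comparison design provides.

## Problem sizes and runtime choices

The validation suite uses 2 000-chromosome simulations for CoC and
shape-recovery checks (sampling error ~2% on the relevant summaries),
50 000 chromosomes for the analytic zero-class comparison, 100
replicates × 1 000 bootstrap resamples for CI calibration, and
10 000-tetrad batches for rate recovery — sizes at which the 3-SE test
bands are tight enough to be meaningful while the whole suite runs in
about a minute on one core. The bootstrap and the simulator's child
streams make every number in the suite and in
`scripts/acceptance.R` a pure function of the declared seeds.

## Known limitations

- CoC is computed within chromosomes only; inter-chromosomal pairs and
  two-pathway mixture models are out of scope.
- The gamma shape inherits the window-censoring bias discussed above;
  no finite-axis correction is applied, by design, to keep the
  estimator identical to the field's standard procedure.
- Fragment/line selection for background estimation is user-supplied;
  nothing is segmented automatically.
- Axis-length law and tetrad aberrant-pattern mixture in the simulator
  are conventions; they match the downstream analyses' assumptions, not
  measured distributions.
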