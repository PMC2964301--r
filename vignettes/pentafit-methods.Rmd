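---
title: "Inferring pentamer stoichiometry from reporter-mutation EC50 shifts"
author: "pentafit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring pentamer stoichiometry from reporter-mutation EC50 shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentafit)
```

## The scientific problem

Heteromeric pentameric ligand-gated channels such as the α3β4 nicotinic
acetylcholine receptor can assemble with either two or three copies of the α
subunit (the β subunit making up the remainder to five). The two stoichiometries
are pharmacologically and biophysically distinct, but cannot be counted
directly from macroscopic recordings. `pentafit` implements the quantitative
chain of inference that identifies the stoichiometry from whole-cell and
single-channel electrophysiology:

1. **Hill fits** of single-cell concentration–response curves, after
   correcting for rundown using interleaved standard-agonist applications;
2. **parallel (equal-slope) fits** of pooled normalized curves, yielding
   mutant/wild-type dose ratios with 2.01-unit profile-likelihood intervals;
3. **per-copy shift arithmetic**: a 9′ Leu→Thr reporter mutation in a pore-lining
   M2 position multiplies agonist potency by approximately the same factor *r*
   for every mutant copy in the pentamer, so a receptor with *n* mutant copies
   shifts its EC50 by *r*ⁿ-fold; comparing the shifts produced by mutating
   the α versus the β subunit identifies which subunit is present in three
   copies;
4. **partial-curve potency ratios** for agonist panels, from parallel
   power-law fits at the foot of the curve with Fieller confidence bounds;
5. **Zn²⁺ modulation fits** that classify a receptor population as
   potentiation-plus-inhibition (biphasic; a two-α signature) or
   inhibition-only (three-α);
6. **single-channel burst analysis**: amplitude mixtures, chord conductances
   and per-conductance-class burst durations distinguishing the
   low-conductance/long-burst form from the high-conductance/short-burst form.

A seeded synthetic-data generator stands in for the oocyte/HEK recordings, so
that every stage is testable end to end without laboratory data.

## Dose–response machinery

### The Hill equation and per-cell fits

Responses are peak inward currents, recorded as magnitudes. The Hill model is

$$I(A) = I_{max}\,\frac{A^{n_H}}{A^{n_H} + EC_{50}^{n_H}},$$

with concentration *A* in µM throughout; all log transforms are base 10.
`fit_hill()` performs equal-weight least squares per cell
(Levenberg–Marquardt, four deterministic starts with the EC50 initialized at
the concentration nearest half the maximal observed response and the slope
at 1.5). Parameters live on the natural scale with positivity bounds; a fit
whose optimum lands on a bound is reported as failed rather than clipped.
Standard errors come from the approximate covariance at the optimum.

### Rundown correction

A standard (~EC20) application of the reference agonist every third response
tracks the preparation's drift. `rundown_correct()` interpolates the standard
response linearly in application index and rescales every response by
(first standard)/(interpolated standard). The linear-in-index interpolation
is this package's documented rule; the correction used with the original
recordings was described only in earlier work. The construct-then-invert
test (scale a known curve by a known decline, correct, recover the curve to
machine precision) pins the implementation.

### Parallel fits and 2.01-unit likelihood intervals

Cells are normalized to their own fitted maxima and pooled per receptor set
(`normalize_pool()`), then `parallel_fit()` fits all curves simultaneously
with one shared Hill slope, each curve's EC50 parameterized as
`reference_ec50 × dose_ratio`. The potency ratio is the reciprocal of the
dose ratio. A free-slope refit provides a lack-of-parallelism
extra-sum-of-squares F test, mirroring the caveat that very shallow mutant
curves distort parallel fits.

Interval estimation uses the Gaussian profile log-likelihood with the noise
variance profiled out, so the profile for a parameter θ is
$-\tfrac{n}{2}\log RSS(\theta)$ up to a constant, with all other parameters
re-optimized at every θ. The interval is bounded where the profile falls
2.01 units below its maximum — equivalent to about ±2 standard deviations for
a Gaussian parameter, since $z = \sqrt{2\delta} \approx 2.005$. The search
steps monotonically outward from the estimate and finishes with root
bracketing; a side that never crosses is returned as an open (infinite)
bound. A dense grid-search profile serves as the oracle in the test suite
(endpoint agreement well under 0.5%).

Calibration: with two pooled-normalized curves of six cells each and 5%
multiplicative noise, the 2.01-unit interval covers the true dose ratio in
about 94–95% of replicates. Two caveats are worth recording. First, the
2.01-unit rule is asymptotic: with a single 8-point cell per curve the exact
small-sample coverage drops to roughly 0.87–0.90, which is why pooling
several cells per curve (as the original protocol did) matters. Second,
rundown correction divides all responses by noisily-interpolated standards;
this injects noise shared across points that the iid-residual profile
likelihood does not model, and in simulations it lowers coverage by a few
points (to ~0.90–0.92 at 2% rundown per application). The calibration test
therefore isolates the interval machinery under its stated noise-only
conditions, and the rundown operation is verified separately by its exact
inversion test.

## Potency ratios from partial curves

At concentrations giving less than ~10% of the maximal response the Hill
curve is a power law, so log response is linear in log concentration with
slope tending to *n~H~*. `fit_parallel_powerlaw()` regresses
log₁₀(response) on log₁₀(concentration) jointly over all agonists of one
cell with a common slope *s* and per-agonist intercepts; the potency ratio
of agonist *a* versus the standard is $10^{(c_a - c_{std})/s}$. Fieller's
theorem gives the confidence bounds for the intercept-difference/slope
ratio, using the t quantile at the cell's residual degrees of freedom; when
$g = t^2\,\mathrm{var}(s)/s^2 \ge 1$ the interval is flagged unbounded
rather than raised as an error. A 10⁵-draw parametric bootstrap on a toy
joint-normal problem is the oracle for the bounds. Per-cell ratios are
combined as unweighted mean ± SEM, with the per-cell Fieller intervals
pooled as their range; how the original analysis combined per-cell intervals
was not stated, so both are reported side by side without asserting
equivalence. Non-positive responses are excluded before the log transform
with a logged count.

## The per-copy shift model

`per_copy_shift()` takes the *n*-th root of a mutant/wild-type potency ratio
(*n* ∈ {1, 2, 3} mutant copies); interval endpoints transform through the
same monotone map. `fit_copy_line()` regresses log₁₀ EC50 on copy number —
the unitary model predicts a straight line of slope −log₁₀ *r*.
`infer_stoichiometry()` scores the two admissible pentamer assignments,
(α, β) = (2, 3) and (3, 2), by the log-scale discrepancy
$|\log r_\alpha - \log r_\beta|$ between the per-copy factors implied by the
α-mutant and β-mutant ratios, and picks the more consistent one; exact ties
are flagged ambiguous rather than broken arbitrarily. The log scale is the
natural one because the shifts are multiplicative (equal free-energy
increments per copy). Only the two pentameric assignments are admitted;
other copy numbers are outside the model's hypothesis space and rejected at
input. When likelihood intervals for the ratios are supplied, the
transformed per-copy intervals are compared for overlap as a qualitative
confidence note — no formal test is invented. `equal_efficacy_ec50()` is the
convenience extrapolation EC50 = reference EC50 / potency ratio, valid only
under the stated equal-efficacy assumption.

## Zn²⁺ modulation

The biphasic model is a sum of two base-10 logistics in
$x = \log_{10}[\mathrm{Zn}^{2+}]$:

$$I(x) = 1 + w\,(Max - 1)\,L(x; EC_{50}, n_{H1}) + (1 - w)\,Min\,L(x; IC_{50}, n_{H2}),
\qquad L(x; c, n) = \frac{1}{1 + 10^{\,n(\log_{10} c - x)}},$$

anchored at the control response 1 at low zinc, with *w* ∈ [0, 1] weighting
the enhancement component. The printed source for this equation is an
illegible image, so this algebra is a reconstruction that satisfies every
stated constraint (parameter names and ranges, the log-concentration
independent variable, the control anchor); it is deliberately isolated
behind `biphasic_response()` so it can be swapped. An important consequence:
only the two amplitude products $w(Max-1)$ and $(1-w)Min$ are identifiable
from a curve, so the fit estimates the amplitudes and reports a canonical
(w, Max, Min); recovery tests assert the identifiable quantities (the
amplitudes, the two c50s and slopes, and the realized peak enhancement).
Published values of w/Max/Min from other software are not comparable and are
not asserted anywhere.

`fit_biphasic()` also fits the nested single-Hill inhibition-only model
$I = 1 - a\,L(x; IC_{50}, n_H)$ (free amplitude *a*).
`classify_modulation()` calls a curve biphasic only if the biphasic model
wins an extra-sum-of-squares F test at α = 0.05 **and** its fitted peak
enhancement exceeds control by more than 10%; both thresholds are
configurable. On noiseless data the F statistic degenerates (zero residual);
the classifier then falls back to a direct residual comparison.

## Single-channel analysis

Openings enter amplitude analysis only if they outlast twice the filter rise
time $T_r = 0.3321/f_c$ (the Gaussian-response constant; an 8-pole Bessel is
close enough at this precision, and the constant is configurable). Excluded
openings stay in the event sequence for burst segmentation. Amplitude
mixtures are fitted by maximum likelihood (`mclust`, k ∈ {1, 2, 3} by BIC,
floor of 100 openings) rather than binned-histogram least squares — the
statistically cleaner equivalent of fitting the displayed histograms. Chord
conductance assumes a 0 mV reversal potential with no junction-potential
correction and uses the magnitude of the driving force.

`segment_bursts()` groups openings separated by shut times shorter than a
critical duration t~crit~; burst duration runs from first opening start to
last opening end. Total open time and opening count are conserved exactly
for every t~crit~, and burst count is non-increasing in t~crit~ — both are
property tests. The default t~crit~ of 5 ms was chosen once: it sits well
between the sub-millisecond within-burst gaps implied by ~14 ms bursts of
several openings and the ≥100 ms separations between bursts; the original
analysis did not state its value, so t~crit~ is always recorded in output
and overridable. Bursts are assigned to the mixture component with the
highest posterior density at the burst's mean amplitude; a burst further
than 4 SDs from every component is left unassigned. Because the two
amplitude classes overlap (2.6 ± 0.5 vs 3.9 ± 0.4 pA), some
individual-burst misassignment is unavoidable; the per-class burst-duration
summaries remain well separated in simulation. Direct open-level transitions
between classes are counted as a diagnostic, not assumed absent.

## The synthetic-data generator

`simulate_dose_response()` emulates the recording protocol: descending test
concentrations, a standard ~EC20 application every third response (opening
and closing the protocol so correction can bracket every test response),
geometric rundown per application, and multiplicative mean-one lognormal
noise — peak currents are positive and heteroscedastic, which additive
Gaussian noise would misrepresent. Defaults are the wild-type whole-cell
conditions (EC50 91.1 µM, slope 1.65, maximum 6.67 nA, 6 cells, 8 half-log
concentrations, 5% noise, 2% rundown per application).
`simulate_mutation_panel()` derives mutant EC50s from the per-copy model.
`simulate_zinc_curve()` draws from either zinc model;
`simulate_single_channel()` draws bursts from a class mix with exponential
open/shut durations and Gaussian amplitudes, then imposes the stated
resolution by merging unresolvable events (merged openings carry
duration-weighted amplitudes; durations never become non-positive). Every
generator returns a ground-truth sidecar, and recovery tests read truth only
from the sidecar.

What the generator does **not** emulate: desensitization and agonist
self-block (the protocol avoided them with low concentrations and peak
measurements), calcium-dependent conductance effects, multi-exponential
burst kinetics, correlated rundown between cells, and series-resistance
artefacts. Passing recovery tests therefore show that the analysis correctly
inverts its own assumed data-generating process at realistic noise — not
that those assumptions hold for any particular recording.

## Numerical choices and problem sizes

* Equal weights in all least squares, matching the stated fitting protocol.
* Optimizers: Levenberg–Marquardt from several deterministic starts; Hill
  fits are effectively unimodal unless the data are degenerate, and the
  multi-start guards the biphasic zinc model's broader landscape.
* Profile search: outward doubling from the estimate, then `uniroot` at
  tolerance 1e-8 on the RSS crossing.
* Tie-break in `infer_stoichiometry`: exact score ties are reported
  ambiguous, never resolved by ordering.
* Degenerate inputs: zero-variance zinc curves classify as inhibition-only
  with a zero-effect note; records with no openings give empty burst sets;
  empty concentration lists and non-positive concentrations are rejected at
  construction.
* Simulation sizes used by the test suite (chosen to estimate each quantity
  to well inside its tolerance): 100 replicates for Hill-recovery bias, 200
  replicate parallel fits (six cells per curve) for interval coverage, 40
  pooled five-cell curves for zinc recovery, 30 replicates for mixture
  recovery, and 500 replicates for the end-to-end stoichiometry recovery
  rate.

## Known limitations

* The 2.01-unit interval is an asymptotic construction; see the calibration
  discussion above for small samples and for the extra variance injected by
  rundown correction.
* The biphasic zinc parameterization is a documented reconstruction, and
  (w, Max, Min) are reported under a stated convention, not identified
  individually.
* Potency pooling reports mean ± SEM across cells alongside the range of
  per-cell Fieller intervals; the two summarize different uncertainties.
* Burst-class assignment is pointwise-optimal but ignores burst-length
  information that could sharpen classification when amplitude classes
  overlap.
* The per-copy model assumes a constant *r* across copies and contexts; the
  wild-type EC50 itself differs between stoichiometries, so each
  injection-ratio context is fitted separately and never merged.
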