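---
title: "Methods: spICP-MS data reduction and its uncertainty budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spICP-MS data reduction and its uncertainty budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spicpms)
```

## The measurement

Single-particle ICP-MS introduces a dilute nanoparticle dispersion into a
plasma while the detector is read out in short dwell intervals (milliseconds).
Dissolved analyte and instrument noise produce a continuous background;
each nanoparticle produces a discrete ion plume, read as an intensity pulse.
Two proportionalities carry all the quantitative content: pulse intensity is
proportional to particle mass, and pulse frequency is proportional to the
particle number concentration. This package implements the data-reduction
chain from raw dwell-indexed intensities to particle sizes, concentrations,
and a defensible measurement uncertainty, with silver nanoparticles (AgNP)
in the food additive E174 and in confectionery as the motivating use case.

## Particle detection: iterative mean + n·sigma

`detect_particles()` classifies dwells. Starting from "everything is
background", it computes the plain sample mean µ and standard deviation σ of
the background-classified dwells, moves every dwell strictly above
µ + n·σ into the particle class, and repeats until the classification is
stable (or `max_iter = 100`, with a warning). Plain moments rather than
robust estimators are used deliberately: that is how the thresholding
algorithm is defined in the spICP-MS literature this implements. Ties sit at
the threshold, not above it, so they remain background.

Two properties follow from the construction and are enforced by tests:
removing high readings can only lower µ + n·σ, so the background set shrinks
monotonically and the iteration lands on the *largest* thresholding-stable
partition; and raising `n_sigma` never increases the event count.

The multiplier n is an integer, 4 or 5 depending on the sample.
`choose_n_sigma()` automates the choice: keep n = 5 when it already finds at
least 200 events (the lower edge of the dilution-acceptance window) or when
relaxing to n = 4 finds nothing extra; drop to n = 4 only for low-count
samples where it materially recovers events. A particle-free trace therefore
reports n = 5 with zero events rather than relaxing the threshold for
nothing. The decision, with both candidate counts, is attached to the result
and logged — threshold choice is a recognized source of between-day
variation in complex samples, so auditability matters.

An ion plume that straddles two consecutive dwells appears as two adjacent
above-threshold readings. `merge_split_events()` offers the three defensible
dispositions — sum them into one event (default), discard them, keep them —
because operator practice varies; the mode is recorded in the object. The
merge default recovers the full pulse intensity and, on simulated traces
with a 30% split probability, restores the no-split per-event mass
distribution (verified by a Kolmogorov–Smirnov test in the suite).

## Calibration

Two constants convert counts to mass. The *transport efficiency* η — the
fraction of nebulized sample that reaches the plasma — comes from the
particle frequency method (`transport_efficiency_frequency()`): detected
particle count divided by the count delivered, the latter derived from a
monodisperse gold reference dispersion (e.g. certificate diameter 27.6 nm,
density 19.3 g/cm³, 12.5 ng/L) via the sphere mass
(`reference_number_concentration()`). A result above 1 is a hard error.

The *response slope* comes from dissolved standards
(`ionic_calibration()`): ordinary least squares of mean intensity against
the analyte mass reaching the plasma per dwell, concentration × flow ×
dwell time × η. The slope is then in counts per gram per dwell and applies
directly to a particle pulse, whose whole mass arrives within one dwell.
The intercept is retained in the model and represents the blank response of
the trace baseline. One consequence deserves emphasis: detected event
intensities are *net* of the trace background µ, which already contains the
blank, so pipelines converting µ-subtracted nets should use an
intercept-zero model (or blank-corrected standard intensities). The
threshold-to-size conversion below, by contrast, starts from a *raw*
intensity and does subtract the intercept.

`event_mass()` is then `(net − intercept)/slope`, with non-positive masses
dropped and counted; `esd_from_mass()` is the exact sphere inverse
`d = (6m/πρ)^{1/3}`, so mass ↔ diameter round-trips to numerical precision
for any density.

## Size LOQ, distributions, concentrations

`size_loq()` reports the equivalent spherical diameter of a particle whose
pulse sits exactly at the detection threshold: the practical size
quantification limit. No 3×/10× multiplier is applied by default (the term
is used loosely in practice; a `multiplier` argument exists). Under the
high-background additive preset the LOQ lands at ~13 nm, inside the
11–23 nm range typical for AgNP analyses.

`distribution_summary()` reports the sample median plus a mode and half
width at half maximum read off a Gaussian kernel density estimate with
Silverman's rule-of-thumb bandwidth, the HWHM as half the distance between
the two half-maximum crossings. The estimator choice is ours (none is
canonical); with 10⁵ draws from a normal population it recovers mode and
HWHM to better than 0.1 nm, the HWHM of a normal being √(2 ln 2)·sd. Below
50 particles only the median is reported (with a warning): a KDE mode on a
handful of events is noise.

`concentrations()` scales the event count and the summed event masses back
to the original sample: C_p = N × dilution / (η × flow × duration ×
sample-mass ratio), C_m likewise, which preserves the identity
C_m = (mean event mass) × C_p. The 200–2200 detected-particle window is a
QC flag, not a hard stop. `dilution_proportionality()` encodes the paired
dilution check — back-calculated concentrations within 20%, median size
within 5% — which characteristically *fails* for high-background low-count
additive samples, as it should.

Because particles below the size LOQ are invisible to the instrument,
normalized number-based size distributions can be corrected with an
externally determined below-LOQ number fraction (from electron microscopy
of the same sample): `number_recovery_correction()` reweights the observed
distribution to carry 1 − fraction of the total. The fraction is always an
input, never computed internally — the package has no access to the
independent method that provides it.

## The uncertainty framework

`anova_precision()` decomposes a day × replicate study by one-way ANOVA:
s_r = √MSW, s_d = √((MSB − MSW)/n), s_ip = √(s_r² + s_d²), relative values
by the grand mean. Negative between-day estimates floor at zero with a
flag. For unbalanced designs n is the harmonic mean of the per-day counts
(with a warning); with a single day, s_d is refused. The hand-written sums
of squares are verified against `stats::aov()` over a thousand random
designs.

Bias uncertainty: for sizes, `u_Δ = √((s_t/√n_t)² + u_ref²)` combines the
trueness-experiment scatter with the reference (TEM) uncertainty of the
matching size measurand; for concentrations, where no reference method
exists, only `s_t/√n_t` enters.

`routine_budget()` forms the routine-conditions budget: u_r = s_r/√n,
u_d = s_d/√d, u_c = √(u_r² + u_d² + u_Δ²), U = k·u_c with k = 2 (~95%
coverage). Reported values are rounded to 2 significant figures, half away
from zero (`signif_away()`), matching the usual table convention; all test
comparisons against printed values tolerate one unit in the last printed
digit, since the printed inputs are themselves rounded.

`decompose_uncertainty()` inverts the quadrature composition
u_c² = u²_sample preparation + u²_analysis (and its three-term extension
with a data-interpretation component): given a total and the known
components, the remainder is √(u_total² − Σu²_known), with a hard error
when the components exceed the total. `theoretical_concentration()` builds
the expected C_m and C_p of a characterized dispersion from total analyte
content, ionic fraction, per-particle mass, and the undetectable number
fraction; the mass fraction of the undetectable particles (~1.5%) is
reported but not subtracted by default — it is inside the rounding of the
other inputs — and `recovery()` is the plain percentage against the
theoretical value. The high-dilution ionic fraction (22%) is the
appropriate input at single-particle working dilutions; the low-dilution
value (3–4%) is also accepted.

## The synthetic-data generator

`simulate_trace()` is the package's ground-truth instrument. Per dwell it
draws a Poisson counting background whose mean is the instrument background
plus the dissolved-analyte flux (slope × dissolved concentration × flow ×
dwell × η), optionally widened by Gaussian flicker; particle arrivals are
per-dwell Poisson with rate C_p·q·η·t_dwell/dilution; each arrival draws a
diameter, converts to sphere mass, and contributes Poisson-distributed
counts with mean slope × mass. With probability `split_prob` (default 0.1,
a rise time of ~10% of the dwell) a pulse is partitioned between two
consecutive dwells by a uniform fraction. Coincidence is allowed and sums;
above 0.1 expected arrivals per dwell a warning flags the regime. All
randomness flows from one seed through fixed per-component sub-streams, so
a trace is reproducible regardless of what else was drawn first.

Three presets define the study conditions: `nm300k` (normal diameters,
mode 15.4 nm, HWHM 2.6 nm ⇒ sd 2.208 nm, silver density 10.49 g/cm³,
negligible dissolved silver), `e174` (log-normal, median 18.7 nm,
sdlog 0.35, dissolved silver dominating the background at ~97% of total
analyte mass, ~250 detected events), and `product` (log-normal, median
22.5 nm, sdlog 0.30, low background, ~800 events). Instrument constants are
configuration with documented defaults — dwell 3 ms, 60 000 dwells (a
3-minute run), uptake 5.8 × 10⁻³ g/s (~0.35 mL/min), η = 0.05, response
2 × 10¹⁹ counts/g/dwell so a 15.4 nm AgNP yields a ~400-count pulse —
chosen once as realistic operating points for a quadrupole instrument; they
are not measured values of any particular instrument. The colloidal
preset's instrument background of 50 counts/dwell keeps the discrete
Poisson tail above both the 4σ and 5σ thresholds negligible, so the n = 4
and n = 5 event counts agree within 2% on clean traces, as they should for
a well-separated distribution.

What the generator emulates: counting statistics, dissolved background,
split events, coincidence, dilution. What it does not: electronic drift,
plasma fluctuations beyond white flicker, isotopic structure, matrix
effects on ionization, particle agglomeration, or adsorption losses during
sample preparation. A pipeline that passes the round-trip tests is
therefore verified as an *algorithm*; accuracy on real samples still rests
on the calibration materials and the sample preparation.

`simulate_validation_study()` generates day × replicate tables as
true_value × (1 + bias + day effect + replicate effect), day effects shared
within a day — exactly the additive model under which the ANOVA components
are defined, so recovery of (s_r, s_d) = (0.9%, 2.8%) over 10³ simulated
5 × 3 studies is a sharp test with analytic Monte-Carlo bands.

## Numerical choices and degenerate inputs

Convergence of detection is *identical classification* on two successive
passes; a constant trace gives σ = 0 and zero events; an empty trace and
n_sigma < 1 are rejected. The detector's error branch "no background
identifiable" guards a state the shrinking iteration cannot normally reach
(the smallest reading always stays background) but is kept as a defensive
invariant. Report rounding is half-away-from-zero because half-to-even
(`signif()`) produces 12 where uncertainty tables print 13. Problem sizes
in the test suite — 60 000-dwell traces, 10⁶-dwell false-positive traces,
10³ simulated studies — were chosen as the smallest sizes at which the
Monte-Carlo bands are decisive.

## Known limitations

- Microsecond (sub-dwell) acquisition and pulse-shape processing are out of
  scope; dwell-quantized counting is assumed throughout.
- Only the particle-frequency transport-efficiency estimator is provided.
- One calibration model per run group: mixing traces across calibration
  days without an explicit new model is the caller's responsibility.
- The additive presets make the paired-dilution QC fail by construction in
  some seeds — that mirrors the measurement reality of high-background,
  low-count samples and is not a defect of the check.
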