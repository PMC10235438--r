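---
title: "Models and methods behind patchkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind patchkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchkit)
```

patchkit quantifies cellular neurophysiology experiments on cultured
neurons: current-clamp excitability, voltage-clamp subthreshold
conductances, miniature EPSCs, population calcium synchrony, nuclear
versus cytoplasmic marker distribution, and the normality-gated
statistics used to compare experimental groups. Because raw patch-clamp
and imaging recordings of this kind are rarely shareable, every analysis
ships with a synthetic-data generator whose ground truth is recorded, so
each stage of the package can be verified end to end without external
data. This vignette explains the underlying models, the measurement
conventions, the tunable parameters, and what the verification does and
does not establish about real recordings.

## The synthetic neuron

`neuron_params()` parameterizes a single-compartment conductance-based
model with eight state variables: membrane voltage, the classic fast-Na
and delayed-rectifier-K gates (Hodgkin-Huxley kinetics, squid-type rate
functions), a slow adaptation K gate, a first-order HCN gate, and fast
activation/inactivation gates for an A-type K current. An instantaneous
Boltzmann-rectified Kir conductance needs no state. A full waveform model
(rather than an integrate-and-fire caricature) is required because the
analysis measures spike shape: amplitude, half width, and the
afterhyperpolarization all depend on the upstroke and repolarization
trajectory.

Defaults describe a small cultured hippocampal neuron: 30 pF capacitance,
1.5 nS leak around -65 mV, resting near -74 mV (the model's zero-current
fixed point, solved exactly with `true_resting_potential()`), and a
rheobase of several tens of pA under 1 s steps — the order of magnitude
one records in dissociated hippocampal cultures. The `na_shift` parameter
translates the Na-gate kinetics along the voltage axis; it is the cleanest
way to move the spike threshold, and the demo pipeline uses it to plant a
cohort difference.

Integration is fixed-step classical Runge-Kutta (RK4) in compiled code at
a default step of 20 microseconds (at most 25 microseconds; coarser steps
are refused). Two properties make the integrator checkable in closed
form: with all active conductances at zero the model is an RC cell whose
steady-state deflection is exactly `dI / g_leak`, and the fixed point of
the discrete scheme coincides with the continuous one, so the simulated
resting potential can be compared against the root of the steady-state
current. Ground-truth spike times are the upward 0 mV crossings of the
deterministic trajectory; measurement noise (band-limited Gaussian,
default 0.2 mV s.d. filtered at the 10 kHz acquisition cutoff) is added
after integration and therefore never perturbs the truth. Band-limiting
matters: white noise at a 50 kHz sampling rate would make the sample-to-
sample derivative explode and no dV/dt criterion could work on it, which
mirrors why real rigs low-pass filter at acquisition.

The voltage-clamp generator is deliberately simpler: each sweep is the
closed-form sum of a capacitive transient (single exponential, time
constant 1 ms), ohmic leak, instantaneous Kir, exponentially relaxing HCN
(tau = 200 ms), an A-type current whose activation (tau = 2 ms) and
inactivation (tau = 25 ms) product peaks about 5 ms after a depolarizing
step, and white current noise (default 2 pA). Because gating relaxes
between exact steady states, the "instantaneous versus steady-state"
separation that the conductance analysis relies on is exact in the model.
Ground-truth conductances are defined the same way the estimators are —
slope contrasts of the definitional current components on a dense 1 mV
grid — so recovery tests compare an estimate from noisy, protocol-sampled
sweeps against the model-implied value of the same functional, not
against a loosely related parameter.

The event-level generators follow the same pattern. mEPSCs are a
homogeneous Poisson train of biexponential inward deflections (rise
0.5 ms, decay 5 ms) normalized to unit peak so the drawn amplitude is the
true baseline-to-peak amplitude. The calcium field gives each of 15-30
ROIs a baseline, per-cell amplitude scaling (s.d. 0.2 of the mean),
per-cell onset jitter (s.d. 0.1 s), and a shared event train convolved
with a calcium kernel (0.25 s rise, 1 s exponential decay, unit peak); a
trailing segment carries one large reference transient emulating the
first transient after bicuculline. The kernel rise constant is chosen so
that 2 Hz sampling attenuates sampled peaks by at most a few percent;
with an instant-rise kernel the attenuation would depend strongly on
frame phase. The image generator draws a two-channel cell — marker
intensity on a nuclear disk and cytoplasmic annulus, nuclear stain on the
nucleus — plus pixel noise. The Ct-table generator plants a nuclear
proportion per gene and draws replicate Ct values consistent with
perfect-doubling amplification.

The study conditions the generators default to — 1 s depolarizing steps
in 5 or 10 pA increments, hyperpolarizing families from -60 to -130 mV in
10 mV increments, 500 ms depolarizing steps from -100 mV in 5 mV
increments, 250 kHz/10 kHz current-clamp and 20 kHz/2 kHz voltage-clamp
acquisition, 2 Hz calcium imaging for 10 min, at least 200 mEPSC events —
follow the experimental design this package quantifies. Noise levels and
cell-to-cell variability are not reported for such data and are stated
choices here, not inferences.

## Spike detection and waveform features

`detect_aps()` implements the dV/dt criterion: an AP begins where the
first derivative of the voltage trace first exceeds 20 mV/ms (upward
crossing, interpolated linearly between the bracketing samples), and its
peak is the voltage maximum reached before the derivative returns below
zero. The derivative is a central difference on the raw,
acquisition-filtered trace; no additional analysis-side smoothing is
applied, because filtering belongs to acquisition. Two exclusion rules
match standard practice: detections whose threshold precedes the analysis
window are spontaneous APs and are dropped, and detections within 5 ms of
the injection onset are dropped as onset-coincident (the exclusion is
standard; the 5 ms width of the blanking window is this package's
choice). A peak floor of -10 mV separates APs from subthreshold
depolarizations and from band-limited noise ripples that can
transiently push the derivative over threshold near rest; the floor is
not part of the textbook definition but is required by any automated
implementation, and it leaves detection invariant under the 10 mV
junction correction since healthy AP peaks sit far above it.

`ap_features()` measures everything relative to the interpolated
threshold: amplitude is peak minus threshold, half width is the
interpolated trace width at threshold plus half amplitude, and the AHP is
the minimum between the peak and the next AP's threshold (or the window
end), with its amplitude referenced to threshold and its delay to the
threshold-crossing time. When the trace is still falling at the search
boundary the AHP is reported missing rather than guessed. The AHP delay
endpoint is ambiguous in common usage (trough time relative to threshold
versus relative to peak); it is measured from threshold here, consistent
with referencing all AP quantities to threshold.

`rheobase_analysis()` takes the lowest step level with at least one valid
detection; ties are impossible because protocols enforce strictly
monotone step levels. The accommodation index is the interval between the
last pair of APs divided by the interval between the first pair, computed
on the lowest sweep with at least six APs. Both orderings of that ratio
are defensible readings of the verbal definition; the last-over-first
ordering is used (values above 1 mean adaptation) and the reciprocal is
reported alongside (`accommodation_index_inverse`), as is the same ratio
at the strongest injection (`accommodation_index_top`), which is the more
stable quantity for cohort comparisons because every cell contributes at
the same drive.

## Passive properties

The amplifier reports passive values online in a real experiment; here
they are recomputed from the data so they can be verified. Input
resistance is the least-squares slope of steady-state voltage deflection
against injected current over subthreshold hyperpolarizing steps
(depolarizing or spiking sweeps are excluded automatically). Whole-cell
capacitance uses the charge-integral method on a voltage-clamp test
pulse: after subtracting the steady leak current, the integral of the
transient equals `C * dV`. The transient end is detected as the first
point where the current stays within three noise standard deviations of
the steady level for 1 ms. "Stabilized" values across repeated test
pulses are summarized by the median. Access resistance is estimated from
the peak of the test-pulse transient (`Ra = dV / I_peak`) and fed to the
QC gate, which fails recordings above 25 MOhm (or without a recorded
value).

## Subthreshold conductances

`measure_step_currents()` reads two currents per sweep: the instantaneous
current, averaged over a 5 ms window placed directly after the detected
end of the capacitive transient, and the steady-state current, averaged
over the final 100 ms of the step (window widths are this package's
choices; the measurement logic — directly after the transient, and at the
end of the step — is the field's). Transient-end detection compares the
smoothed |dI/dt| against a floor set by the larger of the
noise-derivative scale and 0.2% of the transient's own peak slope; the
second term stops slow ionic relaxation (HCN) from holding the window
open on clean data.

The three conductances are slope contrasts:

* **Kir** — instantaneous slope conductance over -130..-110 mV minus that
  over -90..-70 mV. The subtraction order is chosen so inward rectifiers
  give positive values; only the magnitude is meaningful and the
  convention is stated in the documentation.
* **HCN** — slope of the steady-minus-instantaneous difference current
  over -130..-110 mV. Leak and Kir are instantaneous and cancel exactly
  in the difference.
* **A-type** — control and 4-AP-blocked families are subtracted sweep by
  sweep (paired by command level, not sweep order), the difference
  current must peak 3-13 ms after the depolarizing step, and the
  conductance is the slope of peak current against voltage over
  -20..+35 mV. Sweeps peaking outside the latency window are flagged and
  excluded — but only when their peak rises above an extreme-value-scaled
  noise floor, so that a null difference (blocked = control) cleanly fits
  a zero slope instead of erroring on noise peaks at random latencies.

All fits are unconstrained least squares; nothing forces them through a
reversal point. Slope estimates are exact on exact lines and immune to
constant current offsets.

## Miniature EPSCs

`detect_minis()` replaces interactive template software with a
deterministic rule set: the trace is smoothed (1 ms boxcar), a running
median (50 ms) provides the baseline, and candidate events are upward
crossings of the deflection's rising slope through a slope threshold
(default: the amplitude threshold per millisecond). The slope gate is
what distinguishes a new event from noise ripples riding the decay of the
previous one — a pure amplitude criterion double-counts decays. Each
candidate is paired with the subsequent deflection maximum (within 5 ms),
must exceed the 5 pA amplitude threshold, and must have an onset-to-peak
rise time within 0.3-5 ms; amplitude is read from a lightly smoothed
(0.25 ms) trace around the peak. Onset is the last baseline crossing
before the peak, or the inter-event minimum for summated events. Events
less than 10 ms after their predecessor are flagged as summated: excluded
from amplitude statistics but never from counts or frequency
(`mark_summation()` exposes the rule as a pure function). `mini_summary()`
reports frequency from all events (span-based, `(n-1)` over the first-to-
last onset interval), amplitude statistics from included events only, and
a sufficiency flag at 200 events. Visual verification is replaced by the
machine-checkable rise-time and amplitude QC fields.

## Calcium synchrony

`dff()` computes `(F - F0)/F0` on background-subtracted fluorescence with
F0 estimated as a rolling 10th percentile over a trailing 60 s window by
default (F0 estimation is never specified in descriptions of such
experiments; a rolling low percentile tracks slow drift while ignoring
sparse transients). A percentile baseline leaves a small positive offset
in the resulting dF/F, so transient peaks are always measured
baseline-to-peak after removing the segment median.

Synchrony is defined against a stimulation reference: `reference_peak()`
takes the population-mean dF/F peak of the first transient after the
marker (bicuculline addition), and `detect_synchronous_events()` accepts
candidate peaks of the across-ROI mean trace — at least 2 s apart, the
minimum separation preventing double-counting of multi-peaked bursts —
when they reach at least 1/10 of that reference. "Mean peak across all
cells" is read as the peak of the across-ROI mean trace rather than the
mean of per-cell peaks; the across-ROI mean is what the 1/10 rule is
applied to here, and per-ROI dF/F (rather than raw intensity) is the
scale on which both sides of the criterion are computed, making the rule
invariant to uniform rescaling of the raw fluorescence. Frequency is
accepted events per minute of the unstimulated segment, which must be at
least 60 s long.

## Nuclear/cytoplasmic ratio

`nuc_cyto_ratio()` segments the nucleus on the nuclear-stain channel by
Otsu threshold, fills holes, and keeps the largest connected component;
the cytoplasm is the soma region minus the nucleus. When no soma mask is
supplied the soma is approximated by a fixed-radius dilation of the
nucleus (10 px by default). The dilation radius trades coverage against
contamination: too large and background pixels dilute the cytoplasmic
mean, biasing the ratio upward. The default keeps the automatic region
inside the soma for the synthetic geometry (8 px nucleus, 20 px soma);
for real images a measured soma mask is preferable and is accepted
directly. The ratio of mean marker intensities over the two masks is
invariant to rescaling the marker channel.

## qPCR compartment proportions

With cDNA synthesized from proportionally equal volumes of the nuclear
and cytoplasmic fractions and amplification efficiency fixed at perfect
doubling (no efficiency correction is attempted), relative abundance is
proportional to `2^-Ct` and the nuclear proportion is
`2^-ct_nuc / (2^-ct_nuc + 2^-ct_cyt)`; proportions are computed per
primer pair, assuming equal efficiency across compartments. Proportions
are summarized on the arcsine-square-root scale (mean and SD) and
back-transformed for presentation; the transform round-trips to machine
precision. `relative_expression()` provides the standard `2^-ddCt`
normalization against a reference gene for expression-level analyses.

## Statistical reporting

`normality_gate()` runs Shapiro-Wilk on every group and declares the
comparison nonparametric as soon as any group rejects at 0.05 — from then
on summaries are median with interquartile range and the two-group test
is the two-sample Kolmogorov-Smirnov; otherwise Student's t (pooled
variance, two-tailed) with mean and SEM. Groups smaller than three leave
the gate indeterminate and the caller must choose. A zero-variance group
is treated as rejecting normality: the test statistic is untestable and
a constant sample is not plausibly Gaussian. The ratio paired t test is
a one-sample t on log ratios of paired positive values; all-equal ratios
return a zero statistic rather than 0/0.

`adjust_p()` implements Benjamini-Hochberg (step-up), Holm and Holm-Sidak
(step-down), and Bonferroni adjustments directly, with monotonicity
enforcement and capping; these adjustments are part of the package's own
reporting contract, and the test suite checks them against brute-force
recomputations from the definitions (and against `p.adjust` where the
method exists there). Adjusted values never fall below raw ones.

`anova_factorial()` covers the two designs used in this kind of study:
between-subjects two-way ANOVA (with Tukey HSD post hoc) and a split-plot
design with one between- and one within-subjects factor. For the
repeated design the within-subject effects carry a Greenhouse-Geisser
sphericity correction — epsilon from the pooled within-group covariance
of the subject-by-level matrix under orthonormalized contrasts — giving
the fractional corrected degrees of freedom that repeated-measures
reports display; per-within-level group comparisons with BH adjustment
are available as the post hoc. The epsilon computation is cross-checked
against `car::Anova`'s multivariate machinery in the tests.

Type-I error of the full gated pipeline is verified on null simulations
(both groups identical, normal and lognormal, n = 15 per group, 10 000
replicates per family) and held to 5% within one percentage point.

## The demo pipeline

`run_pipeline()` wires the stages together: it simulates a control cohort
and a "shifted-excitability" cohort (Na activation shifted 2 mV
hyperpolarized — lower threshold, more spikes — plus a stronger
adaptation conductance), with seeded lognormal cell-to-cell variability
(s.d. 0.1 on the log scale) on the main conductances; extracts per-cell
excitability features; and compares the cohorts on total AP count, AP
threshold, and the top-injection accommodation index through the gated
test selection. The run is deterministic given the config seed, every
row carries provenance (cohort, cell seed, package version), and the
planted direction of all three differences is recovered reliably at four
to six cells per cohort. The demo mirrors the structure of a
virus-versus-control comparison without claiming any measured values.

## Verification scale and limitations

The test suite and the acceptance script run everything at sizes chosen
for a single CPU: 100 sweeps for detector-oracle equivalence, 50 neurons
against the dense 1 pA rheobase oracle in the tests (25 in the script),
100 random conductance triples (30 in the script), a few hundred seconds
of mEPSC recording, 50 calcium fields, 100 synthetic cells for the image
ratio, 10 000 null replicates per distribution family for the type-I
check, and 8 pipeline replicates at the default six cells per cohort.

One statistical property deserves an explicit caveat: at fifteen samples
per group the exact two-sample Kolmogorov-Smirnov null distribution is
discrete, and its attainable p-values jump from about 0.026 to 0.076.
Any KS-based procedure at this sample size therefore rejects a true null
at roughly 2-3%, not 5% — the gated pipeline is conservative, never
anti-conservative, whenever the gate routes data to the nonparametric
branch. The type-I verification reflects this: the parametric (normal)
branch sits inside 4-6%, while the lognormal case, which mostly routes
to KS, sits near 3%.

What passing these checks shows is internal consistency at simulated
conditions: the estimators recover what the generative models planted,
the detectors agree with independent brute-force oracles on the same
samples, and the statistical layer holds its nominal error rate. What it
cannot show is robustness to everything real recordings add — seal
instability and access-resistance drift, electrode offset drift,
non-Gaussian and correlated noise, overlapping mEPSC bursts beyond
simple summation, photobleaching and motion in imaging, out-of-focus
light in the nuclear/cytoplasmic quantification, and amplification
efficiencies below 2 in qPCR. Those effects are exactly why the QC
gates, the flag columns, and the explicit parameter knobs exist; on real
data they should be inspected, not assumed.
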