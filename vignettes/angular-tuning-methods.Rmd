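---
title: "Angular tuning of spike trains: models, statistics, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angular tuning of spike trains: models, statistics, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skytuner)
```

## The measurement problem

A neuron suspected of carrying sky-compass information is probed by
rotating a stimulus through full 360° turns — a zenithal polarizer whose
E-vector orientation is the angle of polarization (AoP), or an unpolarized
light spot circling the head at fixed elevation — while its spikes are
recorded. Three quantities summarize the response: the stimulus angle of
maximal excitation Φ~max~, the mean vector length *r* measuring how
concentrated spiking is around Φ~max~, and the fraction R² of per-bin
firing-rate variability explained by the stimulus angle. The AoP is
defined only modulo 180°: a polarizer at 10° and at 190° present the same
E-vector. All polarizer statistics are therefore *axial*: angles are
doubled, ordinary circular statistics are applied, and the resulting
direction is halved. Azimuthal (light-spot) tuning uses the ordinary
360° statistics.

## From spike times to angles

A protocol is a list of rotation segments (stimulus kind, direction,
angular velocity, start time and angle, number of turns), stimulus-off
intervals, and stationary lights-on intervals. Within a segment the
presented angle is linear in time: clockwise rotation increases the angle
(0°→360°), counterclockwise decreases it, and angles are reduced to
[0°, 360°). Each full turn is one trial; trial windows are half-open
`[t_start, t_end)`, and so are angular bins `[a, a + width)`, anchored at
0°, so no spike is ever counted twice and a spike exactly at a boundary
belongs to the upper window/bin.

The first presented rotation of each stimulus kind is excluded by default:
stimulus onset commonly evokes a phasic transient unrelated to angular
tuning, and the exclusion is applied once per stimulus kind (not per
segment), because it is the onset of that stimulus — not of each rotation
block — that produces the transient.

Stationary lights-on periods are excluded from both the tuning analysis
and background estimation; background activity is the mean ± SD of spike
counts in consecutive complete 1-s bins inside stimulus-off intervals
(partial trailing bins discarded, at least 2 complete bins required).

## Statistics

**Φ~max~ and r.** By default each spike contributes one unit vector at its
presented angle, pooled over all retained trials of the group (cw, ccw, or
both); Φ~max~ and r come from the resultant (doubled/halved for axial
stimuli). The finest-grained use of the angular conversion is the
individual spike; an alternative (`phi_from = "bins"`) uses bin centers
weighted by mean rate, which matters only when bins are very coarse. A
vanishing resultant raises a typed "no preferred angle" condition that the
pipeline reports as a non-significant outcome rather than inventing an
arbitrary direction.

**Dispersion.** The circular SD is the mean angular deviation
$(180/\pi)\sqrt{2(1-r)}$ (0 at $r = 1$, ≈81.03° at $r = 0$); the
alternative $(180/\pi)\sqrt{-2\ln r}$ is available via `sd_convention`.

**Confidence arc.** The 95% confidence arc of the mean direction uses the
two-regime analytic formula with $\chi^2_{0.05,1} = 3.841$ and $R = nr$:
for $r \le 0.9$,
$d = \arccos\!\big(\sqrt{2n(2R^2 - n\chi^2)/(4n - \chi^2)}/R\big)$,
otherwise
$d = \arccos\!\big(\sqrt{n^2 - (n^2 - R^2)e^{\chi^2/n}}/R\big)$.
When the arccos argument leaves [−1, 1] the sample is too dispersed and
the arc is reported as undefined (`NA`). For axial data the arc is
computed in doubled-angle space and halved. Because the literature for
this analysis cites the arc only by name, the formula choice was open; the
analytic arc is the default and a percentile-bootstrap alternative
(`circ_ci_bootstrap()`) is provided and cross-checked against it in the
test suite (agreement within 2° at n = 100, r ≈ 0.8).

**Significance gate.** Tuning significance is tested by linear–circular
correlation of the per-bin mean firing rates against the bin-center
angles (doubled for axial stimuli): $n R^2$ is $\chi^2$-distributed with
2 df under the null. The sample size *n* of the test is the number of
bins (24 at 15° width), matching the convention that all statistical
descriptions use per-bin samples. R² is withheld whenever p ≥ 0.05, so
serialized results never carry an R² for a non-significant tuning. The
gate is fixed at α = 0.05 with no multiple-testing correction, matching
standard practice for per-neuron reporting. R² is numerically clipped to
[0, 1]; the p-value uses the unclipped statistic.

**Binning and pairing.** Counts become rates through the dwell time of
the stimulus in one bin, `bin_width / angular_velocity` of that trial, so
trials at different velocities are comparable. Mean ± SD per bin is taken
across cw/ccw trial pairs, paired in presentation order; leftover
unpaired trials (e.g. a cw-only group) enter as singleton pairs, and the
SD is undefined (NA) when only one pair exists. Mixed velocities across
segments are allowed; each trial keeps its own dwell time.

**Opponency and direction mismatch.** A response is *opponent* when the
tuning curve exceeds background mean + SD at Φ~max~ and falls below
background mean − SD at the anti-preferred angle Φ~min~ = Φ~max~ +
periodicity/2 (for axial stimuli both presentations of each axial class
are averaged); excitation without the trough is `excitation_only`. The
cw/ccw mismatch is the smallest angular distance between group-wise
Φ~max~ estimates under the shared periodicity — the axial distance for
the polarizer, so 5° vs 175° is a 10° mismatch.

## The generative model

The simulator exists so that every stage of the analysis can be validated
against known ground truth; its defaults emulate the standard recording
conditions (three consecutive rotations per direction at 30–60°/s,
30-s off intervals, background rates and preferred angles of documented
response classes).

The instantaneous intensity is

$$\lambda(t) = \max\!\big(0,\; b + A\cos(k(\varphi(t) - \Phi + s\delta)\tfrac{\pi}{180})\big) + \text{transients}(t)$$

with background rate $b$, modulation amplitude $A$, harmonic $k$ (2 for
axial polarization tuning — two peaks per 360° turn — and 1 for azimuthal
tuning), presented angle $\varphi(t)$, direction sign $s$ (+1 cw, −1 ccw)
and anticipatory shift $\delta \ge 0$. The sign convention places the
measured cw peak at $\Phi - \delta$ and the ccw peak at $\Phi + \delta$ —
a shift *against* the rotation direction, as observed for
polarization-sensitive neurons at low rotation velocities — so the cw/ccw
mismatch is $2\delta$. Opponent neurons use the full cosine, clipped at
zero (the trough falls below background, to complete inhibition when
$A \ge b$); non-opponent neurons half-wave rectify the modulation at
background. Lights-on edges add an exponential transient
$a_{on}e^{-(t-t_{on})/\tau}$; lights-off edges optionally add a phasic or
inhibitory transient. Cosine tuning is the minimal model reproducing the
unimodal/bimodal circular histograms seen in recordings; it is a
first/second-harmonic approximation, not a mechanistic receptor model.

Spike trains are drawn by Poisson thinning against the envelope
$\lambda_{max} = b + A + a_{on}$: candidate events from a homogeneous
process at $\lambda_{max}$ are accepted with probability
$\lambda(t)/\lambda_{max}$. A single integer seed governs the whole
simulation through R's default RNG, making every train reproducible.

`scenario_library()` provides presets spanning the documented response
classes — strongly opponent axial tuning at 51.8° on a 9 imp/s background,
azimuthal tuning at 94.3° with complete inhibition opposite the preferred
azimuth on a 30.7 imp/s background, an anticipatory-shift neuron
(δ = 23.3°, giving a 46.6° cw/ccw mismatch), an untuned control at
17.3 imp/s, a 1 imp/s sparse responder, and an opponent azimuthal
green-spot responder. Published characterizations of such neurons report
background rates and preferred angles but not modulation amplitudes, so
preset amplitudes were chosen once to reproduce the qualitative response
class (an opponent trough reaching zero requires $A \ge b$) and are not
fitted quantities.

### What the simulator does and does not emulate

It reproduces the statistical structure the analysis assumes: Poisson
spiking, stationary background, cosine angular modulation locked to the
stimulus, onset transients, opponency, anticipatory shift. It does not
model membrane dynamics, bursting, adaptation beyond the exponential
transient, velocity-dependent gain, or the orthogonal cw/ccw tuning seen
in rare neurons with strong phasic dynamics. Passing the validation suite
therefore demonstrates correctness of the pipeline under these
assumptions — not that real recordings satisfy them; in particular,
slow non-stationarities in real background activity can inflate the
false-positive rate of any per-bin correlation test.

## Numerical and design choices

- Half-open conventions everywhere (time windows, angular bins) with bin
  edges anchored at 0°; ties resolve upward.
- Φ~max~ from pooled spikes by default (`phi_from` option for per-bin).
- Degenerate inputs (zero resultant, constant rates, insufficient trials
  or baseline) raise typed conditions (`skytuner_no_preferred_angle`,
  `skytuner_undefined_statistic`, `skytuner_insufficient_data`, ...) so
  callers can report "n.s." outcomes without string matching.
- Serialized artifacts use degrees and impulses/s exclusively; spike CSVs
  are written at full double precision so a write→read→analyze round trip
  reproduces the in-memory results exactly.
- Whether cw and ccw turns are presented as alternating single turns or
  as blocks is protocol-dependent in practice; the protocol format
  supports both, and `make_protocol()` builds blocks.

## Validation problem sizes

The test suite validates the statistics against an independent
brute-force unit-vector oracle (1,000 random instances, agreement to
1e−9), exact trigonometric identities (noiseless cosine over n equally
spaced bins gives R² = 1 and p = e^(−n/2)), the empirical type-I error of
the significance gate (2,000 simulated unmodulated neurons; nominal 0.05,
accepted within [0.035, 0.065]), recovery of a known axial preferred
angle (200 simulations at 2 cw + 2 ccw retained rotations, ≥95% within
5° and significant), the anticipation law (δ ∈ {10°, 20°, 30°}, 100
simulations each, median mismatch within 2δ ± 5°), monotonicity of r̂ in
modulation amplitude (20 levels × 50 seeds, Spearman ρ > 0.9), and a χ²
goodness-of-fit check of the thinning sampler (100 runs, 1-s bins,
p > 0.01 in ≥98%). These sizes keep the full suite under a minute on one
CPU while leaving the binomial acceptance bands comfortably wider than
the Monte-Carlo error.

## Known limitations

- The analytic confidence arc assumes an approximately von Mises-shaped
  sample; for very small n or near-uniform samples it is undefined, and
  the bootstrap arc is the more honest alternative.
- The χ²(2) null of the linear–circular correlation is asymptotic in the
  number of bins; at 24 bins with moderate counts the empirical type-I
  error is within a few thousandths of nominal (validated), but very low
  firing rates make per-bin rates skewed and the gate slightly
  conservative.
- Opponency classification compares single bins (or axial bin pairs)
  against a background mean ± SD band; it is a phenomenological label,
  not a hypothesis test.
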