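# skytuner

Angular tuning analysis of neuronal spike trains recorded during rotating
sky-compass stimuli, with a matched spike-train simulator for validation.

Insect neurons involved in celestial compass orientation are typically
characterized by rotating a stimulus — a zenithal linear polarizer, or an
unpolarized light spot circling the head — through 360° in clockwise (cw)
and counterclockwise (ccw) direction while recording intracellularly. The
question for each neuron is whether its firing rate is locked to the
presented angle, and if so, at which angle it fires most. `skytuner`
implements that analysis chain as a tested, reusable pipeline:

1. **Stimulus model** — reconstructs the presented angle at any time from a
   machine-readable protocol (rotation segments with direction, angular
   velocity, start time/angle; stimulus-off and stationary intervals), and
   converts spike times in each retained rotation (the first rotation of
   each stimulus is excluded by default, because stimulus onset evokes a
   phasic transient) to angular values in [0°, 360°).
2. **Circular statistics** — the preferred angle Φ<sub>max</sub> and mean
   vector length *r* from the resultant of unit vectors at spike angles;
   the polarizer's angle of polarization is axial (180°-periodic), so its
   statistics are computed on doubled angles and halved at the end. The
   circular SD is the mean angular deviation (180/π)·√(2(1−r)), the 95%
   confidence arc uses the two-regime analytic formula for a circular mean
   (χ²₀.₀₅,₁ = 3.841), and significance of tuning is tested by
   linear–circular correlation of per-bin firing rates against bin-center
   angles: with r<sub>xc</sub> = cor(x, cos φ), r<sub>xs</sub> = cor(x, sin φ),
   r<sub>cs</sub> = cor(cos φ, sin φ),

   R² = (r<sub>xc</sub>² + r<sub>xs</sub>² − 2 r<sub>xc</sub> r<sub>xs</sub> r<sub>cs</sub>) / (1 − r<sub>cs</sub>²),

   and n·R² ~ χ²(2 df) under the null. R² is reported only when p < 0.05.
3. **Tuning pipeline** — background activity from 1-s bins of stimulus-off
   periods, per-trial angular histograms (10/15/20° bins, firing rates via
   the stimulus dwell time per bin), across-trial-pair means ± SD,
   opponency classification (excitation at Φ<sub>max</sub> plus inhibition
   below background at Φ<sub>min</sub>), and the cw/ccw mismatch of
   Φ<sub>max</sub>.
4. **Simulator** — inhomogeneous-Poisson spike trains (thinning) from
   parametric neuron models: background rate *b*, cosine modulation of
   amplitude *A* with harmonic *k* (1 = azimuthal, 2 = axial), true
   preferred angle, onset/offset transients, opponent inhibition, and an
   anticipatory shift δ of the peak against rotation direction (so the
   cw/ccw mismatch equals 2δ).

## Worked example

Simulate a strongly polarization-opponent neuron (axial tuning at 51.8°,
background 9 imp/s) through a standard protocol of three cw and three ccw
polarizer rotations at 30°/s, then analyze it:

```r
library(skytuner)

protocol <- make_protocol("polarizer_blue", velocities = 30, n_turns = 3)
spikes   <- simulate_spike_train(scenario_library()$PC4, protocol, seed = 1)
spikes
#> <spike_train 'PC4': 1196 spikes, 0.075-131.894 s>

result <- compute_tuning(spikes, protocol, bin_width = 15)
result
#> <tuning 'PC4' polarizer_blue/both: Phi_max = 53.9 deg, r = 0.60, R2 = 0.98 (p = 8.3e-06, n = 5 rotations)>
result$background
#> <background: 9.55 +/- 3.43 imp/s (n = 60 1-s bins)>
result$opponency
#> [1] "opponent"
```

The estimate Φ̂<sub>max</sub> = 53.9° recovers the generative preferred
angle of 51.8° to about 2°; the five retained rotations (first cw rotation
excluded) give a mean vector length r = 0.60 and a significant
linear–circular correlation (R² = 0.98: 98% of the per-bin rate
variability is explained by the polarization angle). The background
estimate 9.55 ± 3.43 imp/s recovers the generative 9 imp/s, and the
trough below background at Φ<sub>min</sub> classifies the response as
opponent. Direction-wise analysis quantifies the cw/ccw tuning mismatch:

```r
cw  <- compute_tuning(spikes, protocol, group = "cw")
ccw <- compute_tuning(spikes, protocol, group = "ccw")
direction_mismatch(cw, ccw)
#> [1] 6.6   # degrees (axial); ~0 expected for delta = 0, estimation noise only
```

File-based runs use `run_analysis()` (spike-time CSV with a `time_s`
column, protocol YAML; writes tuning-result JSON, binned-curve and
polar-plot CSVs, a summary table and a run manifest), or the thin CLI in
`inst/cli/skytuner` (`simulate`, `analyze`, `report`). Example protocol
configs and a small synthetic recording ship in `inst/extdata/`.

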