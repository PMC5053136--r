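# iecsaxs

Background correction and analysis for **ion-exchange chromatography
coupled SAXS** (IEC–SAXS) frame series.

## The problem

In chromatography-coupled BioSAXS, scattering frames are recorded
continuously (here 1 Hz) while the eluent flows through the beam. With
ion-exchange columns the protein is eluted by increasing the NaCl
concentration — a linear gradient or programmed steps — and the salt
itself scatters, so the buffer background changes *during* the run and is
time-shifted between the sample run and a blank run of the same
gradient. Subtracting same-index frames produces systematic under- or
over-subtraction that corrupts the structural parameters.

`iecsaxs` is for beamline scientists and SAXS users reducing such runs.
It provides:

* **Linear gradients** — `scan_shifts()`: shift the blank run against
  the sample run (default −100…+300 frames, step 5), score each shift by
  the flatness of the low-q/mid-q intensity ratio across the elution
  peak (a constant ratio ⇔ one species, correct background; concave ⇔
  under-subtraction, convex ⇔ over-subtraction), and subtract at the
  best shift. `flag_heterogeneous_peak()` reports when *no* shift gives
  a constant ratio — a co-eluting contaminant.
* **Salt steps** — `fit_transition()`: model the delayed buffer response
  after a step as II − (II − I)·exp[−(N − N₀)/N′] on the mean scattering
  above 4.5 nm⁻¹, then subtract a per-frame interpolated buffer
  (`framewise_subtract_step()`), with explicit over/under-subtraction
  bounds (`mis_subtraction_bounds()`).
* **Irregular backgrounds** — `match_buffer()`: average the peak and
  choose the background from a measured salt series by the mean
  scattering in 4.25–4.75 nm⁻¹, bracketing with the neighbouring salt
  steps (`bracket_buffers()`).
* **Analysis** — automatic Guinier fit (qRg ≤ 1.3 window search),
  Porod volume with fitted flat-background removal
  (Vp = 2π²I₀/Q; protein mass ≈ Vp/1.7 nm³ kDa⁻¹), correlated-volume
  mass (Vc = I₀/∫qI dq, M = Vc²/Rg/0.1231), concentration from forward
  scattering (I₀ = c·M on the calibrated scale, 1 a.u. = 8.03×10⁻⁴
  cm⁻¹), an exact longest-run (CORMAP-style) frame-similarity test, and
  stable-region selection for averaging.
* **Synthetic runs** — `simulate_run()`: seeded sample + blank runs with
  Gaussian elution peaks of spherical species, a salt-tracking
  background with capillary term, exponential gradient dispersion, a
  known sample/blank clock offset and Poisson-like noise — with a full
  ground-truth record, so the whole pipeline is testable without
  beamline data.

## Worked example

Simulate a BSA-like linear-gradient run (Rg 2.74 nm, 66.5 kDa, peak
concentration 1.75 mg/ml, 130-frame offset between sample and blank
clocks) and reduce it:

```r
library(iecsaxs)

cfg  <- sim_config_linear_bsa(seed = 42)
run  <- simulate_run(cfg)

scan <- scan_shifts(run$sample, run$buffer)
scan
#> <shift_scan: best shift 130 +/- 5 frames, flatness 0.932, 41 shifts tested>
frames_to_volume(scan$best_shift, 1, 1)   # 1 Hz, 1 ml/min
#> [1] 2.166667                              # ~2.2 ml of elution volume

flag_heterogeneous_peak(scan)$report
#> roi frames 702..958: min constancy 0.9323 <= threshold 2 -> single-species peak

sr  <- stable_region(scan$subtracted)
sr$report
#> stable region: frames 724..958 (235 of 257 candidates), reference 830,
#> min adjusted p in region 0.481

avg <- average_frames(scan$subtracted, sr$frames)
auto_guinier(avg)
#> <guinier: Rg = 2.773 +/- 0.001 nm, I0 = 70.53 +/- 0.011, qRg 0.09-1.06 (points 1-73)>
porod_volume(avg, auto_guinier(avg))
#> <porod: Vp = 184.7 nm^3 (Q = 7.539, B = -0.000559, extrapolated 0.0% + 6.1%)>
```

Reading the output: the scan recovers the generator's 130-frame offset
exactly (≈2.2 ml at this flow rate); the reduced flatness ≈ 0.93 means
the ratio trace is flat to within noise, so one species elutes across the
double peak; 235 frames pass the CORMAP and ratio stability tests and are
averaged. The fitted Rg of 2.77 nm sits 1.5% above the generating 2.74 nm
(the known small bias of a Guinier window pushed to qRg ≈ 1.3 for a
sphere at this noise level), and the Porod volume 184.7 nm³ is within 1%
of the generating sphere volume (4/3)πR³ = 185.5 nm³. The concentration
estimate `concentration_from_forward(70.53, 66.5)` gives 1.06 mg/ml, the
mean over the averaged region of the generator's concentration profile.

The same pipeline is scriptable from a shell via
`inst/scripts/iecsaxs.R` (`simulate`, `subtract`, `analyze`
subcommands), with YAML run configs and tab-separated reports.

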