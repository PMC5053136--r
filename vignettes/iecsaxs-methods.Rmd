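---
title: "Background correction for ion-exchange chromatography coupled SAXS"
author: "iecsaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background correction for ion-exchange chromatography coupled SAXS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In chromatography-coupled BioSAXS a detector records one scattering frame
per second while the eluent flows through the beam, giving a time-ordered
series of 1D curves $I_N(q)$. With size-exclusion columns the mobile phase
is constant, so any protein-free stretch of the run supplies the
background. Ion-exchange chromatography (IEC) separates by surface charge
and elutes with an increasing NaCl concentration, either a linear gradient
or programmed steps. Salt scatters: the buffer background now *changes
during the run*, roughly linearly with NaCl concentration at high $q$, and
the background recorded in a blank (no-sample) run of the same gradient is
shifted in time relative to the sample run (pump/acquisition
synchronisation, ions co-eluting from the column). Subtracting the frame
with the same index is therefore wrong, and the error is systematic: it
grows with the local slope of the gradient.

`iecsaxs` implements three correction strategies, the diagnostics that
decide between them, the downstream single-curve analysis
(Guinier, Porod volume, correlated-volume mass, concentration), a
longest-run (CORMAP-style) frame-similarity test used to choose which
frames to average, and a synthetic run generator that produces sample and
blank runs with complete ground truth so that every stage can be verified
numerically.

## Data model and conventions

A `saxs_curve` holds $(q, I, \sigma)$ with $q$ in nm$^{-1}$ strictly
increasing; Å$^{-1}$ input is converted by exactly 10 on I/O. A
`frame_series` stores all frames of a run on one shared $q$ grid (matrix
layout, one column per frame) together with the frame rate (Hz) and flow
rate (ml/min), which convert frame counts to elution volumes:
$V = n / f / 60 \cdot \dot v$. Curve arithmetic never resamples
implicitly; grids must agree to a relative $10^{-9}$ per point, and an
explicit linear-interpolation utility exists for the rare case where they
do not. Band reductions (`band_mean`) use unweighted means over inclusive
band edges. The standard diagnostic bands are low $q$ (0.11–0.5
nm$^{-1}$), mid $q$ (1.5–2.5 nm$^{-1}$), the buffer-dominated transition
band (4.5 nm$^{-1}$ up to the grid maximum) and the buffer-match band
(4.25–4.75 nm$^{-1}$).

A `gradient_program` maps frame number to the buffer-B fraction $f$ and
salt concentration $c = c_A + f\,(c_B - c_A)$. Step schedules are
right-continuous: the new fraction holds from its start frame inclusive,
so frame → salt is a function and "the step at frame 1290" means frame
1290 is already on the new plateau.

## Linear gradients: the shift scan

For a linear gradient the background change between nearby frames is
small and smooth, so the blank run can be aligned to the sample run by a
pure integer shift: sample frame $N$ is paired with buffer frame
$N - s$, positive $s$ meaning the sample run's background arrives late.
The quality of a candidate $s$ is judged on the per-frame ratio of low-$q$
to mid-$q$ scattering across the elution peak. For a single species with
correct background this ratio is constant; residual background makes it
curve, concave (downward) for under-subtraction and convex for
over-subtraction, because the residual is a constant offset while the
protein signal follows the concentration profile.

Numerically the package fits the *inverse* ratio (mid/low). Across a peak
the low-$q$ band carries strong protein signal while the mid-$q$ band is
weak, so dividing by the mid band means dividing by a noisy, near-zero
quantity at the peak flanks; mid/low is well conditioned everywhere in
the region of interest, a background mismatch enters it linearly, and to
first order around a flat trace the two orientations differ only in the
sign of the deviations. The reported curvature is mapped back to the
conventional low/mid sign.

Two scalar metrics are computed per shift from the normalized trace:

* **flatness** — residual about a weighted straight-line fit in frame
  number. A sloped but straight line is tolerated; this is the shift
  selection criterion.
* **constancy** — residual about the weighted mean. A drift is *not*
  tolerated; this is the heterogeneity criterion, because a co-eluting
  second species produces exactly a smooth composition drift that a line
  would absorb.

Both are computed as reduced quantities, each residual divided by the
propagated standard error of its point, so their expectation is ~1 for a
perfect subtraction regardless of where the noise is large. This
weighting is load-bearing: an unweighted metric systematically rewards
under-subtraction (a larger mid-band denominator shrinks the apparent
ratio noise) and biases the recovered shift by tens of frames at
realistic noise levels. For noise-free input the metrics fall back to
plain RMS residuals.

`scan_shifts` evaluates a grid of shifts (default −100…+300 in steps of
5 frames), picks the flatness minimum (ties toward smaller $|s|$),
reports the uncertainty as the half-width of the contiguous run of shifts
within one standard error of the minimum (floored at the grid step), and
classifies each shift as `under`/`over`/`acceptable` from its curvature:
acceptable when $|a_2| \cdot w^2 < 2\,\mathrm{RMS}$, with $a_2$ the
quadratic coefficient, $w$ the half-width of the region of interest and
RMS the line residual in trace units — curvature must be invisible
relative to the residual scatter. Because band means are linear in
intensity, the scan differences per-frame band means of the two runs
rather than subtracting full curves, which makes the grid search
essentially free. The region of interest defaults to the largest
contiguous block of frames whose low-band signal (at shift 0) exceeds
10% of the peak maximum.

`flag_heterogeneous_peak` raises a flag when no shift achieves constancy
below a threshold (default 2, i.e. drift at least as large as the noise).
A refinement pass of the scan at step 1 is available but off by default;
the 5-frame grid with the ±(grid-derived) uncertainty matches what the
data support.

## Stepwise gradients: the exponential transition

After a programmed salt step the background at the measurement position
does not jump: dispersion in the flow path, co-elution of small ions and
new salt-binding sites on the column smear the step into a saturating
rise. The buffer-dominated trace $y(N)$ — the mean scattering above 4.5
nm$^{-1}$ — is modelled as

$$ y(N) = \mathrm{II} - (\mathrm{II} - \mathrm{I})\,
   e^{-(N - N_0)/N'} \quad (N \ge N_0), \qquad y(N) = \mathrm{I} \quad
   (N < N_0), $$

where I and II are the band means of the averaged buffer regions before
and after the peak. I and II are held fixed from those averages rather
than refit: this reduces the fit to two parameters $(N_0, N')$ and keeps
the $q$-resolved interpolation consistent with the scalar fit. The model
is non-convex in $N_0$, so the fit runs a coarse $N_0$ grid (every 5
frames between the regions) with the smooth 1-D profile over $N'$ solved
by `optimize` at each node, then refines $N_0$ by golden-section around
the best node. On self-generated noise-free traces this recovers the
generating parameters to better than $10^{-6}$ relative. $\chi^2$ is the
mean squared residual divided by the mean trace variance; a fitted
$N' < 0.5$ frames is flagged as a hard step.

The per-frame background is then the point-wise interpolation
$b_N(q) = \mathrm{II}(q) - [\mathrm{II}(q) - \mathrm{I}(q)]\,
e^{-(N - N_0)/N'}$ with the same $(N_0, N')$ at every $q$ (a
$q$-dependent rate is unsupported by a single scalar trace), which is
bounded between the two buffers and monotone in $N$. Default buffer
regions: 60 frames ending 20 frames before the programmed step, and 60
frames starting five half-lives ($t_{1/2} = N' \ln 2$) after the fitted
onset, recomputed once after a first pass. Subtraction quality is
re-checked with the same ratio diagnostics as in the linear case, and
`mis_subtraction_bounds` brackets the result by deliberately
over-subtracting (buffer II directly) and under-subtracting (the mean of
buffers I and II); above 1 nm$^{-1}$ the bracketing error is an
approximately constant offset, below it the report carries the maximum
relative deviation.

## Irregular backgrounds: averaged-curve buffer matching

When ions co-elute discontinuously the high-$q$ background can overshoot
transiently and no frame-wise model applies. The fallback averages the
peak frames and picks the background from a salt series (buffer mixtures
measured before the run) whose mean scattering in 4.25–4.75 nm$^{-1}$ is
closest to the averaged sample's, ties broken toward lower salt. The
neighbouring salt steps provide under/over-subtraction bounds
(`bracket_buffers`). The pipeline recommends this path whenever the
exponential fit's $\chi^2$ exceeds 5. Note that matching the band level
of the *averaged sample* deliberately absorbs any co-eluted-ion
contribution into the chosen buffer — that is the point of the method,
and it is why the matched label can sit above the programmed salt step
when an overshoot is present.

## Curve analysis

**Guinier.** Weighted linear regression of $\ln I$ on $q^2$ with weights
$(I/\sigma)^2$; $R_g = \sqrt{-3\,\mathrm{slope}}$, errors from the
regression covariance. The automatic window search grows a window from
each candidate start point while (a) $q R_g \le 1.3$ for the refitted
window and (b) the reduced $\chi^2$ against the stated uncertainties
stays below 3; the longest admissible window wins, ties to the lowest
starting $q$. The $\chi^2$ rule matters for precise data: the true
Guinier region of a compact particle ends well before $qR_g = 1.3$, and
for a sphere a fit pushed to the nominal limit overestimates $R_g$ by
1–2% (the $x^4$ term of $\ln P$); with tight uncertainties the window
stops where the law actually holds. With 1%-level per-point noise the
window typically reaches the nominal limit and the small bias is hidden
in the noise, which is the regime the qRg ≤ 1.3 convention comes from.

**Porod volume.** $V_p = 2\pi^2 I_0 / Q$ with
$Q = \int q^2 (I - B)\,dq$. The flat residual $B$ is fitted by linear
regression of $q^4 I$ on $q^4$ over 3.5–4.9 nm$^{-1}$ (slope $B$,
intercept the Porod constant $K$) — background subtraction residuals
above 1 nm$^{-1}$ are constant offsets, so $B$ is fitted rather than
assumed zero, and $V_p$ is invariant under adding a flat background. The
invariant integral uses the trapezoid rule over the measured range, the
Guinier form below $q_{\min}$ and the $K/q_{\max}$ tail above
$q_{\max}$; both extrapolated fractions are reported. Protein mass
follows as $V_p / 1.7$ nm$^3$ kDa$^{-1}$. An over-flattening guard
rejects $B$ exceeding the band's mean intensity.

**Correlated-volume mass.** $V_c = I_0 / \int q I\,dq$ in Å units,
$Q_R = V_c^2 / R_g$, protein mass $= Q_R / 0.1231$ Da. The integral runs
to a fixed 3 nm$^{-1}$ cap with a Guinier head correction; convergence is
declared when the contribution per unit $q$ at the cap falls below 0.1%
per nm$^{-1}$, otherwise the value is returned with a warning. An early
stopping rule based on the per-grid-point increment was rejected: it is
grid-spacing dependent and truncates the integral mid-rise on a
1000-point grid. The estimator is exactly scale-invariant in intensity
and constant across a single-species peak, but its constant is an
empirical calibration on real protein scattering: applied to the form
factor of a homogeneous sphere (which lacks a protein's internal high-$q$
structure, so $\int qI$ is smaller and $V_c$ larger) it overestimates the
mass by roughly 40%. The per-frame mass trace is therefore a
*constancy* diagnostic on synthetic data, not an absolute one.

**Concentration.** On the calibrated scale where forward scattering
equals concentration (mg/ml) × molar mass (kDa), $c = I_0 / M$; the
absolute-unit conversion is 1 a.u. $= 8.03\times10^{-4}$ cm$^{-1}$.

**Frame similarity.** The longest-run statistic: differences $a_i - b_i$
are reduced to signs, $C$ is the longest run of one sign, and the exact
null (two statistically identical noisy curves, fair-coin signs) gives
$p = \Pr(\text{longest run} \ge C)$. The distribution comes from the
composition-counting recurrence, evaluated through the deficit
$t(k) = 1/2 - r(k)$, $t(k) = 2^{-C} + \sum_{j<C} t(k-j)/2^j$, $p = 2t(n)$:
all terms positive, so counts enumerable in doubles are exact and tiny
p-values suffer no $1 - (1-\varepsilon)$ cancellation. Exact zero
differences carry no sign and break runs; all-zero input short-circuits
to an "identical curves" result ($C = n$, $p = 1$) — zeros only occur in
synthetic or duplicated data. Multiple comparisons are
Bonferroni-adjusted by default (any `p.adjust` method can be swapped
in).

**Stable region.** The frames averaged for the final curve are the
largest contiguous run around the peak maximum in which every frame (i)
passes the CORMAP test against the reference frame at adjusted
$p \ge \alpha$ (default 0.01) after being scaled to the reference by a
weighted least-squares factor over the comparison range ($q \le 2.5$
nm$^{-1}$), and (ii) keeps its low/mid ratio within a noise-aware band
(4 combined standard errors, floored at 5%) of the reference frame's
ratio. The scale factor must come from the full comparison range: a
factor estimated from a narrow band is noisy enough to shift all
differences coherently by about one standard deviation, which inflates
run lengths and collapses the region. Comparing ratios to the reference
frame rather than to the region mean keeps contaminated flanks from
dragging the criterion.

## The synthetic generator

`simulate_run` builds a sample and a blank run from one configuration:

* **Species** are homogeneous spheres; $P(q)$ is the analytic sphere form
  factor (series-expanded below $qR = 0.05$ where the closed form cancels
  catastrophically), so the true $R_g = \sqrt{3/5}\,R$, volume
  $\tfrac{4}{3}\pi R^3$ and mass are known exactly. Intensities are on
  the calibrated scale, so forward scattering equals
  concentration × mass by construction.
* **Elution** is a sum of Gaussian peaks (centre, width, peak
  concentration), optionally assigning components to a second species for
  contaminated-peak scenarios.
* **Background** is $b_0 + a_\text{salt}\,c_\text{NaCl} + $ a capillary
  term $\propto q^{-3}$ confined below 0.2 nm$^{-1}$ (continuous at the
  cut). The linear salt dependence mirrors the observed linear rise of
  high-angle scattering along a linear gradient.
* **Dispersion**: the programmed schedule reaches the measurement
  position delayed by $N_0^{\text{disp}}$ frames and smeared through an
  exponential response of time constant $N'$; linear gradients pass
  through with the delay only. Refitting the generated trace recovers
  these parameters exactly in the noise-free case, which is the round-trip
  identity the transition fit is tested against.
* **Clock offset**: the sample run's background is evaluated at
  $N - s_\text{true}$, the ground truth for the shift scan.
* **Noise** is Gaussian with $\sigma(q) = \lambda \sqrt{I(q)}$
  (Poisson-like, default $\lambda = 0.05$, i.e. ~1% relative at a
  background of 20 a.u., representative of 1-s frames at a high-flux
  beamline). The $\sigma$ columns are exact and the residual signs are
  symmetric, as the CORMAP null assumes. True Poisson counts are
  available behind a flag. A fixed seed gives byte-identical output, and
  the RNG state of the session is restored afterwards.
* **Overshoot** (optional): an additive transient at $q \ge 2.5$
  nm$^{-1}$ after each salt step, emulating co-eluting ions, used to
  drive the exponential model's $\chi^2$ above the threshold and exercise
  the buffer-matching path.

The defaults describe a BSA-like experiment: $R_g$ 2.74 nm, 66.5 kDa,
1.75 mg/ml at the peak, 1 Hz, 1 ml/min, a 25→1000 mM linear program
reaching 35% B, a 130-frame clock offset, and a step preset with the
onset at frame 1289 and $N' = 17$ frames (plateau at 142 mM). What the
generator does **not** emulate: inter-particle structure factors at high
concentration, radiation damage, detector artefacts, real protein form
factors (sphere curves have deep minima and a too-clean Porod tail — one
consequence is the $V_c$ bias above, another is that the generator's
"Porod volume" ground truth is the geometric sphere volume, not the
1.7-ratio protein value), drifts in the blank run, or $q$-dependent salt
contrast. Passing tests on synthetic runs therefore demonstrate the
correctness of the algorithms under the stated model, not their
performance on any particular beamline's data.

## Problem sizes and numerical choices

The test suite exercises full-size runs (2400 frames × 1000 $q$ points)
where the claim is about the full acquisition-scale conditions — shift
recovery to
±10 frames over 20 seeded runs, transition-parameter recovery to ±2/±3
frames — and reduced runs (500–600 frames × 250 points; 120 × 120 for
the command-layer round trips) everywhere the claim is
scale-independent. Grid-equality tolerance is $10^{-9}$ relative per
point; the shift grid default is −100…+300 step 5; ties in the shift scan
break toward smaller $|s|$, in the Guinier search toward lower
$q_{\min}$, in buffer matching toward lower salt. Degenerate inputs have
defined outcomes rather than surprises: identical curves short-circuit
the CORMAP test, a vanishing mid-band mean is an explicit undefined-ratio
error, a hard salt step pins $N'$ at its bound and is flagged, and an
empty stable region is a reported diagnosis, not a crash.

## File formats

Curves travel as whitespace-separated three-column text (`q I sigma`,
`#` headers carrying `key: value` metadata including units and
subtraction provenance; 12 significant digits). Series are a directory of
per-frame `.dat` files plus a CSV manifest whose `#` header stores frame
rate and flow rate (authoritative for conversions; the manifest time
column is informational). Gradient programs, simulation configs and run
configs are YAML. Two-column `.dat` files are accepted with
$\sigma = \sqrt{|I|}$ and flagged as synthetic.

## Known limitations

The shift is integer-valued (no sub-frame interpolation; the underlying
data do not support it). The exponential transition assumes a single
dominant relaxation; multi-step schedules are handled step by step in the
generator but the fit addresses one transition at a time. The
heterogeneity flag tests constancy of one scalar ratio and can miss a
contaminant whose low/mid ratio matches the main species. Absolute-scale
calibration against water scattering is out of scope; the
arbitrary-units-to-cm$^{-1}$ constant is carried as metadata only.
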