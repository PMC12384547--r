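---
title: "Simulating CT-gantry/tumor-motion interplay for SBRT image guidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating CT-gantry/tumor-motion interplay for SBRT image guidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctinterplay)
```

## The physical problem

A helical CT scanner images anatomy by sweeping the table (or gantry)
longitudinally while the tube rotates. A thoracic tumor breathes along
the same axis. When a fast diagnostic protocol crosses a 3 cm target in a
second or two — a fraction of a breathing period — the reconstructed
target is essentially a snapshot of the tumor at whatever breathing phase
the sweep happened to catch, displaced from the time-average position
that treatment planning uses as its reference. When a slow, low-pitch
protocol takes a minute for the same range, each target position is
averaged over several breathing cycles and the apparent (blurred) target
centers near the mean position. The alignment error of daily image
guidance therefore depends jointly on motion amplitude, breathing rate,
and scan speed. `ctinterplay` models exactly this interaction and its
downstream consequences for PTV margins and protocol choice.

## Breathing waveforms

`breathing_waveform()` provides two shapes, both strictly periodic with
period $T = 60/\mathrm{BPM}$ s and both centered to zero time-average so
that the mean position — the analytic stand-in for the average-intensity
4DCT reference image — is identically 0:

* **sinusoid**: $z(t) = \tfrac{A}{2}\cos(2\pi t/T)$;
* **exhale-weighted** (Lujan-type): $z(t) = A\,(c_n - \cos^{2n}(\pi t/T))$
  with $c_n = \binom{2n}{n}/4^n$, default $n = 2$. The profile has a flat
  exhale top (the positive extreme) and brief inhale troughs, matching
  the flat-topped exhale-dominant traces programmed into respiratory
  phantoms. For $n \ge 2$ it spends more than half of each period above
  its mean; at $n = 1$ the $\cos^2$ profile splits the period exactly in
  half, so only $n \ge 2$ gives a true exhale dwell.

$A$ is the **peak-to-peak** excursion by default. Published motion
settings for the phantom platform we emulate (5, 10, 15 mm) follow the
peak-to-peak convention; an `amplitude_convention = "peak"` switch is
available because some of the literature quotes half-excursions, and the
two readings differ by a factor of two in every downstream error.

A useful closed form: for the sinusoid the time-average of
$|z|$ is $A/\pi$. In the fast-scan limit under a uniformly random start
phase the expected absolute alignment error converges to exactly this
value, which anchors the simulator's validation.

## The acquisition model

`acquire()` implements a deliberately minimal 1-D plane-sweep model:

* Reconstructed slice centers sit at $z_k = (k - \tfrac12)\,\Delta z$
  with $\Delta z = 2.5$ mm across the scan length; a head-to-feet scan
  acquires them in descending order, feet-to-head ascending, at
  $t_k = d_k / v$ where $d_k$ is the distance from the scan start and
  $v = \text{scan length}/\text{scan time}$.
* Slice $k$'s occupancy is the cross-sectional area
  $\pi\,(r^2 - (z_k - c(t))^2)_+$ of the sphere at its displaced center
  $c(t) = \mu + z_w(t + \phi)$, averaged over the **beam dwell window**
  (below) by supersampling (11 samples by default).
* `apparent_center()` reduces occupancy to one position: the midpoint of
  the occupied extent (default; the analog of a therapist manually
  centering the GTV contour inside the iGTV envelope) or the
  occupancy-weighted centroid (the analog of intensity-based
  registration). The signed alignment error is this center minus the true
  mean position, optionally quantized to a 1 mm readout granularity —
  clinical couch shifts are recorded to the millimetre.

Full sinogram formation, reconstruction filters, noise, HU calibration
and 2-D/3-D image synthesis are intentionally out of scope: the interplay
mechanism lives entirely in *when* each plane is acquired relative to the
breathing cycle, and that is what the model captures.

### The dwell window

The temporal width a slice integrates over is **not** the rotation time:
a table position stays inside the collimated beam for
$\text{collimation}/v = \text{rotation time}/\text{pitch}$. For the
standard protocol (rotation 0.5 s, pitch 1.75) that is 0.29 s — sharper
than one rotation — while for the slow protocol (rotation 1 s, pitch
0.562) each position is irradiated across 1.78 s, almost two rotations.
Using the rotation time alone understates the slow protocol's intrinsic
temporal averaging and overstates the standard protocol's. With the
dwell window, the simulated slow-protocol scan-to-scan variability drops
below the standard protocol's in essentially every condition, which is
the clinically observed behavior this package studies.

### Scan geometry

The two built-in protocols print their rotation time, pitch and scan
time, but not the scan length. The printed quantities fix it up to the
collimation width $c$: $v_{std} = 3.5c$, $v_{slow} = 0.562c$, and the two
scan times (9.9 s, 59.5 s) are mutually consistent at a common length
$L \approx 34.5c$. A standard 10 mm collimation ($16 \times 0.625$ mm)
gives $L \approx 345$ mm — a realistic thoracic coverage — and
$v_{std} \approx 34.8$ mm/s, which is the package default. The default
matters: at substantially lower table speeds the standard protocol's
sphere-crossing time approaches the 28 BPM breathing period and the
simulator enters an aliasing regime in which mean error *rises* again at
high breathing rates, contrary to the measured phantom behavior. 345 mm
(rather than 346) also places the default sphere center $L/2$
symmetrically on the slice grid, so a static sphere reconstructs with
exactly zero error — a convenient exactness anchor for testing. Both the
length and the sphere position are configurable.

## The factorial experiment

`run_phantom_experiment()` sweeps 2 protocols × {5, 10, 15} mm ×
{8, 20, 28} BPM × 10 repeats = 180 scans, alternating scan direction on
successive repeats (head-to-feet first, so 10 repeats split 5/5) and
drawing each scan's breathing start phase uniformly over one period from
a seeded generator. `generate_phantom_dataset()` adds an optional
zero-mean manual-alignment jitter (default SD 0.3 mm, well below the
1 mm readout quantum) before quantization, emulating the human in the
loop.

Simulated errors at the defaults behave like the physical measurements
do qualitatively: mean absolute error grows with amplitude and falls
with breathing rate for the standard protocol, and the slow protocol's
SDs are consistently at or below the standard protocol's. The phantom's
*numerical* Table-style values are physical measurements of a specific
scanner and are not claimed to be reproduced; the published summary
statistics ship separately as `quasar_phantom_summaries()` and drive the
margin and statistics modules directly.

## Margins

`summarize_condition()` reduces each condition to
$\Sigma = \operatorname{mean}|e_i|$ (systematic, since the interplay
displaces the apparent target coherently within a scan) and
$\sigma = \operatorname{sd}(|e_i|)$ with the $n-1$ denominator (random).
The absolute-value convention matches how the reference summaries are
tabulated (all-positive means); a signed mode is retained for
sensitivity analysis.

Two margin recipes are first-class:

* `eq1_margin()`: $2.5\sqrt{b^2 + \Sigma^2} + 0.7\sigma - o$ with
  $b = 2$ mm (system-related systematic uncertainty — table, image
  resolution — combined in quadrature) and $o = 3$ mm. Applied to the
  published summaries it reproduces all 18 published margin cells to the
  printed 0.1 mm.
* `van_herk_margin()`: the linear $2.5\Sigma + 0.7\sigma - o$; with
  $\Sigma = 2.64$ mm, $\sigma = 2$ mm, $o = 3$ mm it gives exactly
  5.0 mm, the worked justification for the common 5 mm thoracic SBRT
  margin.

Reported margins round **half-up** to 0.1 mm (base R's round-half-even
would turn 5.25 into 5.2 where the clinical tables print 5.3). The $-3$
offset is inherited as printed; its provenance is not derivable from the
recipe itself, so it is exposed as an explicit parameter rather than
hard-coded.

## Protocol statistics

`welch_from_summary()` implements the two-sided Welch test from
$(\bar x, s, n)$ per arm with Welch–Satterthwaite degrees of freedom —
the form needed when only summary tables are available. Degenerate
inputs are defined rather than fatal: equal means with both SDs zero
give $t = 0, p = 1$; unequal means with both SDs zero give $p = 0$ with
a warning. `welch_from_samples()` is definitionally the same test on
sample summaries, and the test suite pins both against `stats::t.test`
on samples constructed to have exactly the target moments. Applied to
the published summaries (n = 10 per arm), exactly three conditions are
significant at $\alpha = 0.05$: (8 BPM, 10 mm), (8 BPM, 15 mm), and
(20 BPM, 15 mm). No multiple-testing correction is applied — the
comparisons are reported per-condition, as is conventional for this kind
of protocol audit — and the results table records that choice.

## Clinical decision rules

`select_guidance()` encodes the modality flow chart with the stated
threshold semantics taken literally: amplitude $\le 5$ mm inclusive
chooses CTOR; amplitude $< 10$ mm strict with rate $\ge 20$ BPM
inclusive chooses CTOR; everything else goes to the MR linac.

`imaging_decision()` encodes the first-day re-imaging cascade. One
ambiguity required a design choice: the prose rule for proceeding after
a second image ("consistently less than 5 mm between the first and
second images") cannot mean that *both* images pass the bone-vs-GTV
check, because a second image exists only when the first failed it. We
read it as: proceed when the **second** image is stable *and* the two
images' longitudinal alignments agree within 5 mm — i.e., the alignment
is reproducible and currently acceptable. A third image is the last
permitted; failing it escalates with no treatment value. On proceeding,
CBCT uses the most recent image's longitudinal value while CTOR averages
all images: CTOR snapshots sit at random breathing phases, so averaging
estimates the mean position, which is also why the package recommends an
even number of alternating-direction scans.

## Synthetic patient cohort

`generate_cohort()` draws per-fraction longitudinal bone-minus-GTV
differences from $\mathcal N(-1.9, 1.7^2)$ mm — the observed cohort drift
of the clinical population this emulates — with zero-mean lateral and
vertical nuisance components (SD 1.5 mm). Two optional layers are off by
default: a patient-level random intercept (the real variance split
between patients and fractions is unknown; all variance sits at the
fraction level unless requested) and a uniform outlier component spanning
the clinically observed extremes ($-11.4$ to $+2.8$ mm), which a pure
normal at these parameters would essentially never reach. The generator
emulates the *distributional* summary of a cohort, not its longitudinal
structure: real target drift can trend over a treatment course, differ
between patients with different tumor sites, and correlate across
directions, none of which is modelled. Passing recovery tests therefore
demonstrates statistical correctness of the generator and audit chain,
not fidelity to any particular patient population.

## Numerical choices and problem sizes

* Dwell-window supersampling: 11 equally spaced samples; occupancy uses
  exact sphere cross-sections, so the only discretizations are the slice
  grid and the time samples.
* Zero-amplitude scans yield *exactly* zero error at the default
  geometry (grid symmetry), and the test suite asserts identity, not
  tolerance.
* Closed-form limit checks run on purpose-built geometries: a 0.05 s
  "snapshot" protocol with 0.5 mm slices and the area-weighted centroid
  (the limit is a continuum statement; midpoint centering at 2.5 mm
  granularity adds avoidable discretization bias), and a 120 s "crawl"
  whose sphere crossing spans ~19 breathing periods. Monte-Carlo sizes:
  $10^4$ uniform phases for the limit checks (standard error well below
  the 2% comparison band), $10^3$ repeats per condition for the trend
  checks, $10^4$ fractions for cohort parameter recovery (within 3
  standard errors). These sizes make the full suite complete in well
  under a minute on a single core.
* All experiment-level randomness flows through one seeded generator per
  call; every CSV written embeds the seed and generator version in `#`
  header comments, and reruns under the same seed are bit-identical.

## Known limitations

* Motion is longitudinal only — the axis shared with the table sweep,
  where the interplay lives. Lateral/AP motion, hysteresis, irregular
  breathing and baseline drift within a scan are not modelled.
* The target is a homogeneous sphere; real tumors have irregular shapes
  and fuzzy boundaries, which chiefly affect the midpoint-centering
  analog of manual alignment.
* The acquisition model is 1-D: no reconstruction physics, no image
  noise, no contrast. Conclusions about *visibility* (which drives the
  CTOR-vs-CBCT choice clinically) are outside the model.
* The simulated error magnitudes depend on the assumed table speeds;
  only scan-time ratios, not absolute collimation, are printed for the
  protocols we emulate, so absolute comparability with any specific
  scanner's measurements is approximate by construction.
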