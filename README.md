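# ctinterplay

Helical CT–respiratory motion interplay simulation and PTV margin
estimation for thoracic SBRT image guidance.

## The problem

During image guidance of thoracic stereotactic body radiation therapy
(SBRT) with an in-room CT such as CT-on-rail (CTOR), the scanner table
sweeps along the same longitudinal axis the tumor breathes along. The two
motions interfere — the *interplay effect* — so the imaged target appears
displaced or distorted relative to its true time-average position, and the
daily soft-tissue alignment inherits that error. A slow, low-pitch scan
protocol averages the target over many breathing cycles (like a CBCT does)
and suppresses the interplay at the cost of blur; a fast diagnostic
protocol catches the tumor in a near-snapshot at a random breathing phase.

`ctinterplay` is for medical physicists and methodologists who want to
study this trade-off in silico: it simulates helical acquisition of a
breathing spherical target, summarizes alignment errors into systematic
(Σ) and random (σ) components, converts them to planning target volume
(PTV) margins, compares protocols statistically, and encodes the clinical
decision rules for choosing an image-guidance modality.

## The models at the core

**Breathing motion.** Periodic longitudinal displacement, mean-centered so
the time-average (the 4DCT "average image" reference) is zero: a sinusoid,
or an exhale-weighted Lujan-type profile
`z(t) = A (c_n − cos^{2n}(πt/T))`, `c_n = C(2n,n)/4^n`, which dwells at
exhale. Amplitudes are peak-to-peak by default.

**Helical acquisition.** A 1-D plane sweep: slice k at position
`z_k = (k − ½)·Δz` is acquired at `t_k = (distance from scan start)/v`
with `v = scan_length / scan_time`; its occupancy is the sphere's
cross-sectional area at the displaced center `c(t_k)`, averaged over the
beam dwell window `rotation_time / pitch`. The apparent center (midpoint
of the occupied extent, emulating manual GTV-in-iGTV centering, or the
area-weighted centroid) minus the true mean position is the longitudinal
alignment error.

**Margins.** Two recipes, both with the 2.5/0.7 weighting of systematic
and random uncertainty:

    PTV = 2.5·sqrt(b² + Σ²) + 0.7·σ − o        (quadrature baseline b = 2 mm, offset o = 3 mm)
    PTV = 2.5·Σ + 0.7·σ − o                    (linear van Herk form)

**Protocol comparison.** Two-sided Welch t-tests, computable directly
from summary statistics (mean, SD, n per arm) with Welch–Satterthwaite
degrees of freedom.

**Clinical rules.** Modality selection (CTOR if amplitude ≤ 5 mm, or
< 10 mm with rate ≥ 20 BPM; otherwise MR linac), the bone-vs-GTV 5 mm
stability check, and the 1–2–3-image re-imaging cascade.

## Worked example

Margins and protocol comparison from the published phantom summary
statistics that ship with the package:

```r
library(ctinterplay)
mt <- margin_table(quasar_phantom_summaries())
cat(render_margin_report(mt), sep = "\n")
```

```
Estimated PTV margins, mm
Amplitude  Protocol     28 BPM   20 BPM    8 BPM
5 mm       standard        2.8      4.5      4.4
5 mm       slow            2.6      3.8      3.6
10 mm      standard        3.5      5.8     10.3
10 mm      slow            3.0      4.0      5.3
15 mm      standard        5.4      7.9     12.3
15 mm      slow            4.0      3.4      4.6

Per-protocol maximum margin: slow 5.3 mm, standard 12.3 mm
```

The standard protocol needs a 10.3 mm margin at 10 mm motion / 8 BPM and
12.3 mm at 15 mm / 8 BPM, while the slow protocol never needs more than
5.3 mm — the case for slow CT when breathing is slow or motion is large.

```r
significance_pattern(quasar_phantom_summaries())
#>   rate_bpm amplitude_mm
#> 1        8           10
#> 2        8           15
#> 3       20           15
```

Exactly three conditions show a significant standard-vs-slow difference
in mean absolute alignment error at α = 0.05.

Simulating the factorial phantom experiment (2 protocols × 3 amplitudes ×
3 rates × 10 repeats, alternating scan directions, random start phases):

```r
rec <- run_phantom_experiment(default_run_config(seed = 1))
nrow(rec)                      # 180 simulated scans
summarize_alignments(rec)      # per-condition Sigma / sigma
```

Synthetic patient cohort and the drift audit:

```r
cohort_drift_summary(generate_cohort(seed = 1))
#> Longitudinal bone-GTV drift over 124 fractions: -1.71 +/- 1.49 mm (range 2.18 to -5.66 mm)
select_guidance(8, 22)
#> Guidance: CTOR for amplitude 8 mm at 22 BPM (rule: amplitude < 10 mm and rate >= 20 BPM)
```

A thin command-line wrapper over the same drivers is at
`inst/cli/ctinterplay.R` (subcommands `simulate`, `margins`, `stats`,
`generate-cohort`, `patient-audit`, `select-guidance`).

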