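# stapetrack

Automated detection of electrically evoked stapedius reflexes (eSR) in
grayscale video of the middle ear recorded through a surgical microscope
during cochlear implantation.

## Why

Intraoperative eSR measurements give an objective proxy for the
loudness-discomfort level used to fit cochlear implants — critical for
small children and patients who cannot report loudness. The reflex is a
tiny twitch of the stapedius tendon, visible under the microscope but
easy to miss: it rides on heartbeat and respiration motion of the whole
field, and the human verdict depends on the observer's experience.
`stapetrack` detects the twitch automatically and estimates the reflex
threshold (eSRT) from stimulation-level sweeps.

## Method

For each recording the pipeline

1. stabilizes every frame against a reference patch on the cochlear
   promontory (normalized cross-correlation, sub-pixel refinement),
2. seeds markers on the stapedius tendon from maximally stable extremal
   regions (MSER) summarized by their moment ellipses,
3. tracks the markers with a pyramidal Kanade–Lucas–Tomasi solver
   anchored to each marker's birth-frame template (forward–backward
   validated),
4. smooths the trajectories with a Savitzky–Golay filter and collapses
   them into a scalar displacement signal *s(t)*: the signed projection
   of the median displacement vector onto the tendon's motion axis,
5. declares a stimulus an eSR when the post-stimulus peak exceeds

   *s*<sub>peak</sub> &gt; *k* · 1.4826 · MAD(baseline), *k* = 3,

   with the robust noise floor pooled over the pre-stimulus baselines
   of the whole run, and
6. estimates the eSRT as the lowest stimulation level with a detected
   reflex.

A ground-truthed synthetic scene generator (textured middle-ear scene,
heartbeat/respiration/jitter nuisance motion, logistic
amplitude-vs-level twitch model) drives the validation studies, and a
statistics layer reproduces the rater comparisons used to evaluate the
method clinically (pairwise 2×2 chi-square with Bonferroni correction,
Pearson intensity–amplitude correlations).

## Worked example

```r
library(stapetrack)

# render a synthetic recording: 4 stimuli, two above reflex threshold
scene <- scene_spec()
sched <- stimulus_schedule(onsets_s = 0.8 + 1.2 * (0:3),
                           levels = c(40, 5, 40, 5))
sim <- synthesize_sequence(scene, sched, seed = 21)

ana <- analyze_sequence(sim$sequence, tendon_roi(scene),
                        reference_roi(scene), sched,
                        search_radius_px = 8)
ana
#> <esr_analysis> 4 stimuli, 2 detected (50.0%)
#>   markers: 6 | median noise floor: 0.011 px | shift RMS: 2.26 px

round(ana$detections[, c("level", "detected",
                         "motion_vector_length_px", "latency_s")], 3)
#>   level detected motion_vector_length_px latency_s
#> 1    40        1                   2.826      0.16
#> 2     5        0                   0.001      0.10
#> 3    40        1                   2.833      0.16
#> 4     5        0                   0.000      0.20
```

The two level-40 stimuli (true twitch amplitude 3 px) are detected with
motion-vector lengths within ~6% of the rendered amplitude and latencies
close to the modelled twitch peak (140 ms); the two level-5 stimuli
(amplitude ≈ 0.002 px) stay far below threshold. The shift RMS of
2.26 px is the recovered global nuisance motion (mostly respiration)
that stabilization removed.

The statistics layer runs without any video, from bundled per-patient
counts of a six-patient clinical evaluation (387 stimuli):

```r
rater_stats(load_rater_counts())
#> Detection rates:
#>   software       226/387 (58.4%)
#>   experienced    179/387 (46.3%)
#>   intermediate   146/387 (37.7%)
#>   unexperienced  161/387 (41.6%)
#> Pairwise chi-square (Bonferroni-adjusted):
#>   software       vs experienced    X2 =  11.44  p = 0.00072  p_adj = 0.0043
#>   software       vs intermediate   X2 =  33.12  p = 8.6e-09  p_adj = 5.2e-08
#>   software       vs unexperienced  X2 =  21.83  p = 3e-06  p_adj = 1.8e-05
#>   experienced    vs intermediate   X2 =   5.78  p = 0.016  p_adj = 0.097
#>   experienced    vs unexperienced  X2 =   1.70  p = 0.19  p_adj = 1
#>   intermediate   vs unexperienced  X2 =   1.21  p = 0.27  p_adj = 1
```

## Command line

A thin wrapper over the same functions:

```sh
inst/scripts/stapetrack simulate --config sim.yaml --seed 7
inst/scripts/stapetrack detect   --config run.yaml
inst/scripts/stapetrack stats    --config stats.yaml
```

Exit codes: 0 success, 2 usage/config error, 3 pipeline failure.

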