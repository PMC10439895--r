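# sdwave

Noninvasive detection and tracking of spreading depolarizations (SDs) in
low-density scalp EEG.

## The problem

Spreading depolarizations are slowly propagating (0.5-8 mm/min) waves of
neuronal depolarization that silence cortical activity as they pass; they
are a biomarker and a treatable mechanism of worsening brain injury after
severe TBI. The clinical standard for detecting them is an invasive
subdural electrode strip. In patients who underwent decompressive
hemicraniectomy (DHC), the missing skull no longer blurs the ipsilateral
EEG, and an SD appears on the scalp as a slow power depression travelling
across the electrodes of a standard 10-20 montage. `sdwave` is an R
implementation of an automated detector for these travelling depressions,
together with its evaluation framework and a synthetic SD-EEG simulator.
It is aimed at researchers in neurocritical-care signal processing who
want to study, extend, or stress-test this class of detector without
access to clinical recordings.

## The method

For each 240-min epoch of band-passed (default Delta, [0.5, 4] Hz),
64 Hz, impedance- and outlier-masked EEG, each channel is normalized,
squared, and reduced to an RMS power envelope over 5-min windows. The
envelope is cross-correlated with an odd first-derivative kernel so that
depression onsets (falling edges) become positive peaks, rectified, and
projected onto a cylindrical map of the upper hemisphere; Gaussian
interpolation (sigma = 2.62 cm) and a three-stage threshold produce
binary wavefront images every 30 s. Dense Horn-Schunck optical flow on
these images is mapped to physical scalp velocities on a 75-mm sphere,

    Vx(phi, theta) = r * dphi * Vx2D * cos(theta)
    Vy(phi, theta) = r * dtheta * Vy2D

and each connected component becomes a bounding box whose flows define an
effective propagation measure

    EPM = sqrt( mean(|V| cos a)^2 + mean(|V| sin a)^2 ),

zero for pop-up/fade (radially symmetric) transitions and maximal for
coherent translation. Boxes below an EPM threshold are dropped; the rest
are split by prominent 45-degree orientation bins, gated to physiological
speeds (0.5-8 mm/min), scored by the number of same-direction neighbours
within 7 cm and +/- 2 min, zeroed when too few neighbourhood frames
contribute, and stitched into a binary detection trace `T_out`.

Detection quality is scored on sliding 2-min windows (step 30 s,
matching tolerance 1 h, windows with fewer than 6 of 11 unmasked
ipsilateral electrodes excluded):

    TPR = detected SD windows / SD windows
    FPR = false-alarm windows / (false-alarm + true-negative windows)
    PPV = detected SD windows / (detected + false-alarm windows)

with weighted bootstrap confidence intervals, leave-2-out
cross-validation over patients (threshold-averaged ROC curves, operating
point minimizing `eps_CV = sqrt((1-TPR)^2 + (1-PPV)^2)` subject to
PPV >= 0.5), and an SD-burden analysis that prunes and stitches `T_out`
at a 4-h scale inside 30-h windows and fits `y = a sqrt(x) + b` by least
squares, inverted as `xhat = ((y - b)/a)^2`.

## Worked example

Simulate a 90-min DHC recording with one SD starting at Fp2 45 min in
(80% power depression, 3 mm/min, anterior-to-posterior path), run the
detector, and compare against the annotation:

```r
library(sdwave)

montage <- montage_1020()
cfg <- sim_config(duration_s = 5400, seed = 42,
                  events = sd_event_schedule(onset_s = 2700))
sim <- simulate_recording(cfg, montage)
run <- run_detect(sim$recording)
run$detection
#> <sd_detection> 180 frames, 4 detection run(s), 14.5 min detected

run$detection$runs
#> # A tibble: 4 x 3
#>   start_s end_s mean_speed_mm_min
#>     <dbl> <dbl>             <dbl>
#> 1    1050  1320              3.92
#> 2    2430  2520              2.24
#> 3    3060  3180              5.98
#> 4    4230  4620              3.21

ev <- run_evaluate(run, sim$annotations$onset_s)
ev$perf
#> <sd_perf> TPR 1.0000 (4/4), FPR 0.0000 (0/0), PPV 1.0000
```

The depression troughs of the planted wave reach the three path
electrodes at 3150, 4094 and 5176 s; the last three detection runs track
its onset and passage with mean optical-flow speeds near the planted
3 mm/min. The first run, half an hour before the onset, is a false alarm
of the kind the method's published false-positive rate reflects - with a
1-h matching tolerance in a 90-min scene it still lands within tolerance
of the event, so every SD window counts as detected and no window
qualifies as a false alarm or true negative here. On long recordings, `run_frequency()` turns
the same trace into 30-h SD counts via the square-root regression, and
`autoplot()` methods draw the trace, the ROC curve and the regression.

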