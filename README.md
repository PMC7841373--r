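# swimseg

Macro–micro analysis of swimming training sessions from body-worn inertial
sensors (IMUs), for sports scientists and engineers building swimming
monitoring tools.

A swimmer wearing 6-axis IMUs (3D accelerometer in g, 3D gyroscope in °/s,
500 Hz) on the sacrum (SA), head (HE), wrists (RW/LW) and shanks (RS/LS)
produces location-specific signatures for every element of a training
session. `swimseg` implements a rule-based two-level analysis:

- **Macro level** — detect swimming *bouts* (periods of swimming bounded by
  the abrupt posture change between upright rest and horizontal swimming,
  found by sharp-change detection on the longitudinal acceleration:
  `t = SC(Acc_y, 0.3 × max|d/dt Acc_y|)`, derivative troughs → approximate
  starts, peaks → approximate ends); separate *laps* by locating the
  approximate turn (the dominant wall-contact peak on the anterior
  acceleration and |Acc_yz|); and identify the *technique* of each lap
  (front crawl, breaststroke, butterfly, backstroke) from PCA of the
  angular velocity (trunk rolling vs. pitching), the gravity sign of the
  anterior acceleration (supine backstroke), and thresholded spectral
  magnitude of the stroke harmonic (butterfly vs. breaststroke).
- **Micro level** — segment each lap into its five phases by detecting the
  beginning of wall push-off (Push_B), glide (Glid_B), strokes preparation
  (StPr_B), swimming (Swim_B) and turn (Turn_B), per sensor location and
  technique, using extremum detection `[A, t] = EXT(s, TH)`, threshold
  crossings, empirical mode decomposition and Hilbert–Huang instantaneous
  energy. Phase durations follow ΔPush = Glid_B − Push_B and so on, with
  ΔTurn ending at the next lap's Push_B.

The package also provides the validation machinery (sensitivity /
precision / accuracy with true negatives fixed at zero, signed event-error
statistics in ms, phase-duration errors absolute and relative,
Bland–Altman limits of agreement, and a ±10% threshold-sensitivity sweep)
and a synthetic-session simulator that emits multi-location IMU signals
containing every detector trigger together with exact ground truth, so the
whole pipeline is testable without any recorded data.

## Worked example

```r
library(swimseg)

sim <- simulate_session(default_study_config(), seed = 42)
sim$session
#> <session_recording> simulated: SA, HE, RW, LW, RS, LS; 253.9 s @ 500 Hz, pool 25 m

rep <- run_full_analysis(sim$session, location = "SA", truth = sim$truth)
rep
#> <analysis_report> SA: 4 bout(s)
#>   bout 1: [9.6, 51.1] s, 2 lap(s) (2 segmented), front_crawl/front_crawl
#>   bout 2: [80.4, 115.4] s, 2 lap(s) (2 segmented), breaststroke/breaststroke
#>   bout 3: [144.7, 182.7] s, 2 lap(s) (2 segmented), butterfly/butterfly
#>   bout 4: [212.1, 244.2] s, 2 lap(s) (2 segmented), backstroke/backstroke
```

The default simulator configuration builds four bouts of two 25-m laps —
one bout per technique — with phase durations drawn from the validated
study statistics (ΔPush 218 ± 29 ms, ΔGlid 880 ± 476 ms, ΔStPr
2673 ± 1268 ms, ΔSwim 12423 ± 1905 ms, ΔTurn 1223 ± 166 ms) and sensor
noise of 0.05 g / 5 °/s. Supplying `truth` embeds validation metrics in
the report:

```r
v <- rep$validation
#> bout sensitivity 1.00, precision 1.00; technique accuracy 1.00
#> Push_B 0 +/- 2 ms | Glid_B 2 +/- 8 ms | Turn_B -0 +/- 2 ms (n = 8 laps)
```

All four bouts, all turns and all eight techniques are recovered, and the
sacrum phase-begin events land within a few milliseconds of the simulated
ground truth. Each number means: a bout/turn counts as detected when it
falls within the matching tolerance of a true event; event errors are
signed detected − truth times (negative = early).

The same analysis runs per location; wrist and shank micro detectors can be
anchored on the sacrum macro outputs
(`run_full_analysis(..., location = "RW", anchor_location = "SA")`),
because the wrist's own bout detection only begins with the first strokes.

A thin command-line front end ships in `inst/cli/swimseg`:

```sh
Rscript inst/cli/swimseg simulate --seed 42 --out session_dir --truth gt.json
Rscript inst/cli/swimseg run session_dir --location SA --truth gt.json --out report.json
Rscript inst/cli/swimseg validate --events detected.json --truth gt.json --report report.csv
```

Sessions are stored as one CSV per location
(`t,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z` with `# fs=...` comment headers;
m/s² and rad/s inputs are converted on read), annotations as versioned
JSON (`swimseg-gt-1`).

## Vignette

`vignettes/swim-phase-segmentation.Rmd` documents the detection rules, the
thresholds and their units, the simulator's design and its limits, and the
numerical choices (zero-phase filtering, EMD mode selection, window
placement, tie-breaking).
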