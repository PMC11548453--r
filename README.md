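# solestep

Step counting from a single six-axis IMU (200 Hz, ±16 g, ±2000 °/s)
embedded in the sole of a shoe, under the heel — for movement scientists and
wearable-device engineers who need accurate step counts in *multi-activity*
conditions (walking at several speeds, running, stomping, high knees, butt
kicks, stair descent), where simple peak-counting pedometers degrade.

The method detects the **foot-flat** phase of each step — the part of stance
in which the sole is stationary relative to the ground (sole angle < 3°) —
with a windowed many-to-one LSTM classifier, then converts the binary
foot-flat stream into step events with a refractory **rest delay** (RD)
rule:

- classifier: P(foot flat at *t*) from the last `w` samples of the retained
  channels (default: 125 ms window, 2 LSTM layers × 32 units, dropout 0.2,
  tanh, Adam at 10⁻², batch 1024), trained on video-annotated foot-status
  labels with binary cross-entropy;
- channel selection: Pearson correlation of each channel with the foot
  status, keep |r| ≥ 0.1 (on the reference cohort: gyroscope norm,
  acceleration norm, vertical acceleration);
- counting: a step is registered at each 0→1 transition of the thresholded
  stream; further onsets within RD ms are suppressed. RD is chosen by
  sweeping 25–1000 ms in 25 ms steps against ground-truth counts;
- errors: `MAPE_DL = |n_flat,pred − n_flat,obs| / n_flat,obs` (flat-labeled
  samples) and `MAPE_G = |n_steps,pred − n_steps,obs| / n_steps,obs`
  (step counts), evaluated subject-wise (7 folds × 3 subjects).

Because the motivating 21-participant dataset is not public, the package
includes a first-class synthetic cohort generator (`simulate_cohort()`)
calibrated to the study's statistical structure: ~191 steps per subject over
the multi-activity track, a 3-heel-strike synchronization prelude (third
impact = time 0), 60 fps annotations with ~9.7% undetermined frames, and
channel/foot-status correlations of ≈ 0.64 (gyro norm), 0.41 (acc norm),
0.16 (vertical acc) with all single gyro axes below 0.1.

## Worked example

```r
library(solestep)

# simulate a cohort, preprocess, rank channels
cohort   <- simulate_cohort(21, seed = 1)
enriched <- enrich_cohort(cohort)                  # sync + fuse, 11 columns
truth    <- vapply(cohort, function(s) s$truth$n_steps, numeric(1))

ranking <- select_channels(enriched, threshold = 0.1)
as.data.frame(ranking)[1:4, c("channel", "r", "abs_r", "retained")]
#>     channel      r abs_r retained
#> 1 gyro_norm -0.643 0.643     TRUE
#> 2  acc_norm -0.408 0.408     TRUE
#> 3     acc_z  0.159 0.159     TRUE
#> 4    gyro_y -0.008 0.008    FALSE

# train on 18 subjects, evaluate per-sample on 3 held-out subjects,
# sweep the rest delay on the 25-1000 ms grid
ids <- withr::with_seed(1, sample(1:21))
res <- evaluate_split(enriched, truth, model_config(seed = 1),
                      train_ids = ids[4:21], test_ids = ids[1:3],
                      channels = retained_channels(ranking)[1:3],
                      train_stride = 4L)
round(100 * c(mape_dl = res$mape_dl, mape_g = res$mape_g), 2)
#> mape_dl  mape_g
#>    0.23    0.18
```

The gyroscope norm dominates (foot quiescent when flat, hence the negative
sign; selection is on |r|), the classifier misassigns ≈ 0.2% of foot-flat
samples, and after the rest-delay sweep the held-out step counts are off by
about one step in 550. A rest delay of 1000 ms instead inflates `MAPE_G` to ~25%:
fast activities step more than once per second, so an over-long refractory
period swallows real steps.

A single YAML-configurable entry point runs everything
(`run_pipeline(run_config(...))`), and `inst/cli/solestep.R` exposes the
stages as shell verbs (`simulate`, `preprocess`, `select`, `count`, `run`).

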