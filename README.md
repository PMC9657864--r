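# fallsafe

Fall prediction from skeleton key-point kinematics with LSTM
classifiers.

Video is the least intrusive way to watch over people at risk of
falling: nothing is strapped to the person, and a pose estimator can
track body landmarks in every frame. `fallsafe` takes such key-point
streams — the **nose (N)**, **left shoulder (LSh)** and **left hip
(LH)** in image coordinates, with the y-axis pointing down towards the
floor — and decides, second by second, whether the person is falling or
performing an ordinary activity of daily living (ADL). It is aimed at
researchers in human-movement analysis and digital health who want a
complete, reproducible, dependency-light pipeline: feature extraction,
windowing, class balancing, training, evaluation, and a synthetic
motion simulator so everything runs without video data.

## The model

Per frame, three kinematic quantities are computed for the tracked key
points $i \in \{N, LSh, LH\}$:

* angle to the image origin: $A_i = \arctan(Y_i / X_i)$ (radians);
* angular rate between consecutive frames:
  $dw_i = \Delta A_i / \Delta t_i$ (rad/s), first frame 0 by
  convention;
* nose-to-hip height ratio: $R = N_y / LH_y$ — with y pointing down,
  $R > 1$ means the head is at or below hip height.

Streams of these features are cut into non-overlapping 18-frame
windows (~1 s at 18 Hz) and classified by a two-layer LSTM
(100 units per layer, dropout 0.3, one sigmoid output neuron; Adam,
learning rate 0.001, binary cross entropy, batch 64, 50 epochs). Three
variants differ only in their inputs: **4p** $(N_x, N_y, dw_N, R)$,
**5p** $(N_x, N_y, dw_N, dw_{LSh}, dw_{LH})$ and **6p** (all six).
Falls are the positive class; reports carry the confusion counts,
precision, recall, F1 and accuracy in percent, and the base-2 cross
entropy in bits.

## Worked example

Simulate a noiseless forward fall and look at the features (the trunk
pitches from vertical past horizontal at a peak rate of 3.5 rad/s;
frames after the impact are dropped by the frame filters):

```r
library(fallsafe)
trial <- simulateTrial("fall_forward", simulationConfig(noiseSd = 0), seed = 1)
f <- computeFeatures(applyFrameFilters(trial))
f[c(1, 6, 11, 16, 19), c("t", "N_x", "N_y", "dw_N", "dw_LSh", "dw_LH", "R")]
#>      t   N_x   N_y   dw_N dw_LSh dw_LH     R
#>  0.000 0.450 0.200  0.000  0.000 0.000 0.323
#>  0.278 0.466 0.202 -0.155 -0.144 0.020 0.325
#>  0.556 0.720 0.328  0.519  0.164 0.098 0.505
#>  0.833 0.870 0.702  0.911  0.646 0.079 1.022
#>  1.000 0.848 0.833  0.383  0.285 0.030 1.192
```

The nose accelerates ($dw_N$ spikes), descends ($N_y$ grows) and passes
hip height ($R$ crosses 1 around $t = 0.8$ s) — the signature that
separates falls from bends and recovered stumbles, where $R$ stays
below 1.

Run the whole pipeline — simulate the default synthetic study (40
trials of each of 7 scenarios), featurize, balance, window, split
69/31 without shuffling, train all three variants and evaluate on the
held-out tail:

```r
res <- runEndToEnd(seed = 7)
res$reports[["6p"]]
#> EvalReport on 41 windows (positive class: fall)
#>   TP 27  FN 0
#>   FP 0  TN 14
#>   precision 100.00%  recall 100.00%  F1 100.00%  accuracy 100.00%
#>   cross entropy 0.0000 bits
round(res$accuracy, 2)
#>  4p  5p  6p
#> 100 100 100
```

On this clean synthetic study all three variants separate the classes
perfectly; on real video the published ranking (6p strongest, 4p
weakest) is the expected regime. A shell interface wraps the same
functions:

```sh
Rscript inst/cli/safe.R simulate  --out data.csv --seed 7
Rscript inst/cli/safe.R featurize --in data.csv --out features.csv
Rscript inst/cli/safe.R train     --in features.csv --model 6p --out ckpt/
Rscript inst/cli/safe.R evaluate  --checkpoint ckpt/ --in features.csv --out report.json
```

Every command writes a JSON manifest (config snapshot, seed, package
version, timestamps) next to its outputs.

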