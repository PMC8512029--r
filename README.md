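# imubehave

Supervised behavior classification for fish carrying multi-sensor
bio-logging tags. The package implements the full analysis chain for
9-channel inertial measurement unit (IMU) recordings — tri-axial
accelerometer (50 or 200 Hz), gyroscope and magnetometer (50 Hz), plus
pressure and temperature (1 Hz) — labeled against a 13-class ethogram
developed from animal-borne video, and compares three classifiers on the
resulting 1-s epochs:

* a **random forest** (200 bagged, un-pruned trees, `\sqrt{p}` predictors
  per split) and a **Gaussian radial-kernel SVM** (one-vs-one), both fed a
  pinned set of 187 handcrafted features per epoch: ten time-domain
  statistics on each of the nine axes and on overall dynamic body
  acceleration (ODBA), signal magnitude area, per-sensor vector norms
  `q = \sqrt{x^2+y^2+z^2}` with circular variances of inclination and
  azimuth, accelerometer axis correlations, vertical velocity from the
  pressure channel, and eight spectral statistics per axis plus ODBA
  spectral energy;
* a **frequency-domain CNN** fed the absolute FFT (NFFT = 512) of each
  channel as a 256 × 9 input, with three conv(3 × 1) + ReLU +
  maxpool(2 × 1, stride 2) stages of 32/64/128 kernels, a 500-node fully
  connected layer with dropout 0.25, and a 9-class softmax — 36,864
  activations enter the fully connected layer. The network, its
  backpropagation and its Adam optimizer are implemented in base R on
  BLAS matrix products.

ODBA uses the standard static/dynamic split: the gravitational component
is a centered 3-s running mean of total acceleration and ODBA is the
per-sample sum of absolute dynamic axis values. Simultaneous behaviors
(a fish booming while it swims forward) are resolved by a labeling
hierarchy in which booming outranks forward swimming. Minority classes
can be grown with three seeded time-domain augmentation operators
(Gaussian jitter, global magnitude scaling, cubic-spline magnitude
warping). Evaluation reports per-class and overall sensitivity,
specificity, F1, Matthews correlation and Cohen's kappa, including the
class-summed overall-kappa procedure and the usual qualitative kappa
bands (0.81–1 "almost perfect").

Because field recordings from tagged animals are available only on
request, the package ships a seeded synthetic IMU simulator
(`simulate_deployment()`, `benchmark_dataset()`) whose per-class
kinematic signatures (tail-beat sway tones, gravity-dominated resting,
boom transients, broadband shaking, sustained-yaw turning, sub-45°
listing, …) make every pipeline stage testable end to end.

## Worked example

```r
library(imubehave)

bundle <- run_experiment(run_config(
  seed = 1, models = c("rf", "svm"), n_per_class = 40))
print(bundle)
```

```
experiment_bundle: rf, svm on 288 train / 72 test epochs
 model sensitivity specificity f1 mcc kappa kappa_agreement
    rf           1           1  1   1     1  almost-perfect
   svm           1           1  1   1     1  almost-perfect
```

On the balanced synthetic benchmark the classes are separable by
construction, so both conventional models reach perfect scores: the
synthetic sensitivity/kappa of 1 validates the pipeline plumbing, not
any field result. The per-class breakdown, random-forest feature
importances and class budget live in the bundle:

```r
head(bundle$importance, 3)
```

```
             feature importance
69      mag_x_invcov   5.234394
171 mag_y_spec_power   4.989107
128   acc_y_spec_max   4.920276
```

Heading-sensitive magnetometer statistics and the lateral-acceleration
spectral peak rank highest here — the synthetic signatures separate
largely on heading dynamics (turning) and the tail-beat sway tone. A command-line
front-end over the same function is installed at
`inst/cli/imubehave.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/imubehave.R", package="imubehave"))')" \
  --seed 1 --model rf,svm --out-dir results/run1
```

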