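# bcgsq — signal-quality assessment for wearable arm ballistocardiograms

The arm ballistocardiogram (BCG) is the body's recoil from each cardiac
ejection, measured by a wearable accelerometer in the head-to-foot
direction. Its dominant peak, the **J wave**, is timed close to aortic
valve opening, which makes the BCG a proximal timing reference for
cuff-less blood-pressure estimation — but the signal is only a few tens
of milli-gravity and is easily swamped by motion. Estimators that
ingest corrupted beats fail silently, so a per-beat *quality gate* is
needed.

`bcgsq` implements such a gate for synchronized ECG/PPG/BCG recordings
sampled at 1 kHz, for researchers working on wearable cardiovascular
monitoring:

1. **Preprocessing** — zero-phase Butterworth filtering (ECG 0.5–100 Hz,
   PPG/BCG 0.5–20 Hz), R-wave gating with a refractory period, fixed
   448-ms beat windows starting at each R wave, and PPG-foot detection
   by the intersecting tangent method.
2. **Rule-based labeling** — a beat is *high-quality* iff a J-wave
   candidate exists before the PPG foot, its amplitude exceeds 3 mg,
   and its full width at half amplitude is under 100 ms
   (strict boundaries; ties are low-quality), followed by class
   balancing.
3. **Time-series imaging** — each 448-sample BCG beat becomes a square
   grayscale image: recurrence plot `R[i,j] = |x_i − x_j|` (m = 1,
   τ = 1, continuous), Gramian angular fields
   `GASF[i,j] = cos(φ_i + φ_j)`, `GADF[i,j] = sin(φ_i − φ_j)` with
   `φ = arccos(x̃)` on the min–max rescaled series, or Markov transition
   field `M[k,l] = Ŵ[bin(x_k), bin(x_l)]` from row-normalized
   quantile-bin transition counts (Q = 8). Optional PAA shortens the
   series first.
4. **CNN model zoo** — LeNet-Tanh / LeNet-ReLU (classic LeNet-5 behind
   two prepended stride-2 conv/pool pairs), ResNet-18, DenseNet-121,
   SqueezeNet v1.0, and a 1-D FCN baseline (kernels {8, 5, 3}, filters
   {128, 256, 128}, global average pooling). Layers (im2col + BLAS
   convolution, pooling, batch norm, Adam/SGD/RMSprop) are implemented
   in the package's compiled code.
5. **Evaluation protocol** — five independent seeded stratified
   50/20/30 splits (for the canonical 9626-beat balanced design:
   4812/1926/2888), per-repeat hyperparameter selection on validation
   accuracy, pooled confusion matrices (5 × 2888 = 14,440), and
   equal-variance t-tests between models.

Because the kind of clinical dataset this targets is rarely shareable,
the package ships a seeded **synthetic-beat generator** with known
ground-truth fiducials (J amplitude/width/latency, PPG foot, motion
artifacts), so every stage is testable end to end. See
`vignette("bcg-signal-quality")` for the methods account.

## Worked example

```r
library(bcgsq)
# simulate 400 annotated beats, half high-quality
beats <- synth_dataset(400, high_fraction = 0.5, difficulty = "separable",
                       seed = 42)
# rule-based labels vs ground truth
labels <- label_beats(beats)
table(truth = ground_truth_labels(beats), rule = labels)
#>       rule
#> truth  high low
#>   high  200   0
#>   low     3 197

# inspect one beat's J-wave candidate
print(attr(labels, "details")[[1]])
#> <quality label> high (rule1 TRUE, rule2 TRUE, rule3 TRUE)

# encode as 64 x 64 GADF images and train SqueezeNet v1.0 over
# 5 stratified 50/20/30 repeats
x <- encode_beats(beats, imaging_config("GADF", paa_output_len = 64))
cfg <- experiment_config(optimizers = "adam", learning_rates = 3e-4,
                         batch_size = 16, epochs = 10, n_repeats = 5,
                         seed = 1, early_stop_train_acc = 0.995)
res <- train_and_evaluate(x, ground_truth_labels(beats), "SqueezeNetV1",
                          cfg, method = "GADF")
print(res)
#> <bcg_experiment_result> SqueezeNetV1 + GADF
#>   accuracy: 0.985 +/- 0.009 over 5 repeats
#>   pooled confusion (rows = true, cols = predicted):
#>       predicted
#> true   low high
#>   low  295    5
#>   high   4  296
```

The rule engine recovers the generator's ground truth on 397/400 beats
(the three misses are motion-artifact beats whose corrupted J region
still passes the literal rules), and the image classifier separates the
two quality classes at 98.5% ± 0.9% mean test accuracy over five
repeats, with the pooled confusion matrix counting 5 × 120 test beats.

A thin command-line front end covers the same pipeline:

```sh
inst/cli/bcgsq synth --n 1000 --high-frac 0.5 --difficulty separable --seed 42 --out beats.csv
inst/cli/bcgsq label --in beats.csv --out labels.csv
inst/cli/bcgsq image --method GADF --paa 64 --in beats.csv --out imgs/
inst/cli/bcgsq train --method GADF --model SqueezeNetV1 --in beats.csv --out results.json
```

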