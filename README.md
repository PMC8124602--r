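# pigdepth

Fully automatic estimation of pig body weight and body size from overhead
depth images of the pig back.

On commercial farms, weighing and measuring pigs by hand is slow and
stressful for the animals. A depth camera mounted above a weighing platform
(here 1650 mm above a 1.5 m × 0.5 m platform) sees the pig back as a
height field, and a convolutional network can regress body weight and the
standard body-size traits directly from that single image. `pigdepth`
implements the complete software side of such a system in R:

- **Capture trigger** — the scale is read every 0.2 s; when 4 consecutive
  readings lie in the population weight range and their spread is < 0.2 kg,
  the pig is standing quietly and an image is captured.
- **Preprocessing** — each depth pixel `P_o` (mm from the camera) is
  inverted to a height, `P_i = 1650 − P_o`, scaled linearly to 0–255 gray
  (lighter = higher) and resized to the square model input (299 × 299 or
  224 × 224).
- **Model factory** — a classification CNN backbone (DenseNet201,
  ResNet152 V2, Xception, MobileNet V2, or the package's own desk-scale
  `tinycnn`) is truncated after global average pooling and six parallel
  single-node linear dense heads are attached, one per target, in the order
  **BW** (kg), **SW**, **SH**, **HW**, **HH**, **BL** (cm): body weight,
  shoulder width, shoulder height, hip width, hip height, body length.
- **Training** — mini-batch Adam (lr 0.001, batch 16) on the summed
  per-target mean squared error

  `MSE = MSE_BW + MSE_SW + MSE_SH + MSE_HW + MSE_HH + MSE_BL`,
  `MSE_V = (1/M) Σ_m (y_m^V − ŷ_m^V)²`,

  with a shuffled 7:3 train/validation split and retention of the
  parameters of the best validation epoch.
- **Evaluation** — per-target RMSE, MAE, MRE (percent, relative to the
  measured value), R², the aggregate total MSE, and mean estimation time.
- **Synthetic scene simulator** — the original farm datasets are not
  released, so the package ships a parametric generator: pig bodies are
  lofted solids of half-elliptical cross-sections on the platform, with
  allometric trait sampling, a weight law `BW = density × volume × noise`,
  posture variation (yaw, offset, head pitch, spine bend) and sensor noise.
  Every rendered image has analytically known labels and volume, so the
  whole pipeline is testable end to end on a desktop CPU.

Depth images are 16-bit grayscale PNGs holding millimetre distances; the
codec, the CNN engine (im2col + BLAS convolutions with full backward
support for the sequential `tinycnn` backbone) and all components above are
implemented in R/Rcpp with no deep-learning framework dependency.

## Worked example

Simulate 600 labelled scenes at 64 × 64, train the desk-scale backbone for
30 epochs with the reference hyper-parameters, and evaluate on the held-out
30 %:

```r
library(pigdepth)
cfg  <- scene_config(image_height_px = 64, image_width_px = 64)
data <- preprocess_dataset(generate_dataset(600, cfg, seed = 42), 64)

model <- build_regressor(model_spec("tinycnn", input_size = 64))
fit   <- train(model, data, train_config(epochs = 30, shuffle_seed = 42))
print(fit)
#> <train_result> 30 epochs, best epoch 29, best validation loss 79.8041

held_out <- split_dataset(data, 0.7, seed = 42)$validation
evaluate(fit$model, held_out)
#> <metrics_report> n = 180
#>  target unit  rmse   mae   mre r_squared
#>      BW   kg 6.763 3.947 6.00%    0.9474
#>      SW   cm 1.125 0.790 3.77%    0.9104
#>      SH   cm 2.941 2.123 4.97%    0.8826
#>      HW   cm 0.970 0.688 3.60%    0.9197
#>      HH   cm 2.314 1.609 3.68%    0.9126
#>      BL   cm 4.226 3.049 3.83%    0.9117
#> total MSE (kg^2): 79.804   mean estimation time: 3.12 ms/image
```

The network recovers the generator's weight and body-size parameters from
rendered depth maps alone: R² ≈ 0.95 for body weight and ≥ 0.91 for the
length/width traits after half an hour of simulated farm data and ~1 minute
of CPU training. SH is the hardest target because head movement displaces
the apparent shoulder apex (by up to ±4 cm here), exactly the error
structure reported for real drinking pigs.

Building a full-size backbone and counting its parameters (the published
totals for all four backbones are reproduced exactly; see
`tests/testthat/test-acceptance.R`):

```r
count_parameters(build_regressor("xception"))
#> parameters: total 20,873,774, trainable 20,819,246
```

## Command line

```sh
Rscript -e 'pigdepth::pigdepth_cli()' simulate --n 100 --seed 1 --out scenes/
Rscript -e 'pigdepth::pigdepth_cli()' preprocess --in scenes/ --out gray/ --size 224
Rscript -e 'pigdepth::pigdepth_cli()' train --in scenes/ --out fit/ --backbone tinycnn --size 64 --epochs 30
Rscript -e 'pigdepth::pigdepth_cli()' evaluate --model fit/checkpoint.rds --in scenes/ --out metrics/
Rscript -e 'pigdepth::pigdepth_cli()' trigger-demo --in readings.csv --out events/
```

Every command takes `--config file.json` plus flag overrides and records
the seed, resolved configuration, its CRC-32 hash and package version in
`run.json`.

## Documentation

The methods vignette (`vignettes/pigdepth-methods.Rmd`) describes the
simulator geometry and its assumptions, the preprocessing and counting
conventions, the training design choices, and what the synthetic benchmark
does and does not establish.
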