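# fetalage

Attention-guided dual-branch convolutional regression of gestational age
from fetal brain MRI — with a synthetic phantom generator that makes the
whole pipeline testable on a laptop, no scanner data required.

## What it does, and for whom

Estimating gestational age (GA) in the second half of pregnancy matters
for prenatal care and delivery planning, and the fetal brain's rapidly
changing size and cortical folding make it a natural imaging clock. This
package is for researchers in medical image analysis who want a fully
inspectable R implementation of an attention-guided GA regressor:

- a **global branch** regresses age (days) from the whole multi-slice,
  multi-plane T2-weighted-like input;
- an **attention heatmap** is read off the global branch's last
  convolutional layer as the channel-wise maximum of absolute
  activations, `H_g(x,y) = max_k |f_k(x,y)|`, upsampled bilinearly,
  normalized to [0, 1] by a truncated ReLU, and re-weighted by a
  unit-peak 2D Gaussian encoding the prior that the fetal brain sits
  near the image center;
- a **local branch** regresses age from the input multiplied by that
  heatmap, suppressing maternal background;
- branch outputs are averaged, and per-plane (axial/coronal/sagittal)
  predictions are averaged again.

Training minimizes the summed per-branch, per-plane MSE with Adam; the
attention pipeline is differentiable, so the whole model trains end to
end (the test suite verifies the gradient through the mask against
finite differences). A fine-tuning protocol adapts a trained model to an
external site using 20% of that site's subjects with early stopping.

Evaluation reports everything a GA-regression study needs: R², MAE in
days, Lin's concordance correlation coefficient
`rho_c = 2·cov(y, ŷ) / (var(y) + var(ŷ) + (ȳ − ŷ̄)²)` with 95% CI and
McBride agreement class, and modified Bland–Altman quantile curves
(15-point windows, 95% overlap, Gaussian smoothing).

The convolutional stack — forward, backprop, Adam — is implemented in
the package itself with Rcpp/Armadillo kernels, so every numerical claim
is testable down to the layer level.

## Worked example

Generate a 400-subject phantom cohort (ages 133–273 days), split it
70/10/20, train the tiny three-plane dual-branch model at desk scale,
and evaluate on the held-out test set:

```r
library(fetalage)

cfg      <- phantom_config()                      # 64 px, 3 planes, 9 slices
manifest <- generate_cohort(cfg, 400, seed = 1)
splits   <- split_dataset(manifest, seed = 1)     # 70 / 10 / 20

prep <- function(part) {
  ids <- splits$subject_id[splits$partition == part]
  prepare_dataset(manifest[manifest$subject_id %in% ids, ],
                  n_slices = 3, size = 64, seed = 1)
}

model <- build_multiplane_model(
  backbone_spec("tiny", in_channels = 3, input_size = 64), seed = 1)
ck <- train_model(model, prep("train"),
                  train_config("desk", iterations = 500),
                  val_data = prep("val"))

pred <- multiplane_predict(ck$model, prep("test"))
report <- evaluate_predictions(pred)
report
#> Gestational-age regression evaluation (n = 80)
#>   R^2 = 0.955 | MAE = 6.55 days
#>   Lin's CCC = 0.975 [0.963-0.983], substantial agreement
```

`glance(report)` returns the same numbers as a one-row tibble,
`autoplot(report)` draws the prediction scatter, and
`autoplot(report, "bland_altman")` the quantile agreement curves. The
meaning: on phantoms whose object size and texture encode age, the
trained model recovers held-out age to about a week over a 140-day
range, with substantial concordance — the mechanism works; no claim
about clinical images is implied.

A thin command-line wrapper covers the same pipeline
(`exec/fetalage generate|train|predict|finetune|evaluate`); see
`?ga_cli`.

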