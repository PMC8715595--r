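# hybridreg

Hybrid-supervised deformable registration of brain CT volumes in R.

## The problem

Intersubject registration of head CT — aligning one patient's anatomy to
another's — underpins template-based reading of stroke imaging: once a
moving image is registered to a reference, regional labels such as the
middle-cerebral-artery (MCA) supply territory can be transported between
subjects. Learning-based registration is attractive for its speed, but
two obstacles stand out: dense gold-standard deformation fields between
real subjects cannot be annotated, and anatomical differences across
individuals can be large.

`hybridreg` implements a hybrid-supervised answer for researchers in
medical image analysis:

* a **deformation-field simulator** draws random multiscale affine +
  elastic displacement fields `F_g` (with a configurable fraction of
  large deformations) and warps a real moving image `M` into a synthetic
  reference `I⁰ = M ∘ (id + F_g)` — so `F_g` is an *exact* gold standard
  for that pair;
* a **dilated encoder–decoder network** maps a (moving, reference) pair
  to a dense displacement field under the backward-warping convention
  `output(x) = input(x + u(x))`;
* training minimizes the **hybrid loss**

  ```
  L = α·L_F + β·L_M0 + γ·L_M1,     α = 1/13, β = γ = 0.4
  ```

  where `L_F` is the mean L2 deviation (mm) between predicted and gold
  fields on the supervised pair, and `L_M0`, `L_M1` are negative mean
  squared windowed normalized cross-correlations for the supervised and
  self-supervised (real pair) images;
* an **evaluation battery** computes sparse-landmark endpoint error (EPE,
  mm), normalized mutual information (NMI), territory Dice and paired
  t-tests over a test cohort.

Because clinical head-CT cohorts with territory annotations are private,
the package ships a **phantom generator**: skull-bearing, CT-like heads
with ventricles, an MCA-territory-like label and exact feature landmarks,
with controllable intersubject variation. The full pipeline — phantoms,
skull stripping + Z-score preprocessing, simulator, training, evaluation —
runs on a single CPU at desk scale (2D 64×64 cohorts). The network,
backpropagation and Adam optimizer are implemented in the package itself
(Rcpp/RcppArmadillo); no external deep-learning framework is required.

## Worked example

```r
library(hybridreg)

# 14 phantom subjects, 2D desk scale, preprocessed
spec   <- phantom_spec(grid_shape = c(64, 64, 1))
cohort <- lapply(generate_cohort(spec, 14, seed = 65078), preprocess_subject)

# train the registration network (8 train / 2 val), ~9 min on one CPU
fit <- hybridreg(cohort[1:8], cohort[9:10],
                 train_config(steps = 2000, seed = 1))
fit
#> Hybrid-supervised deformable registration fit
#>   network: 2D, 4 levels, 16 base channels, 487,170 parameters
#>   trained: 2000 steps on 8 subjects (batch size 1)
#>   loss weights: alpha = 0.07692, beta = 0.4, gamma = 0.4
#>   final losses: field 7.551 mm, sim0 -0.06157, sim1 -0.2549 (total 0.4543)
#>   best validation EPE: 2.228 mm at step 2000

# evaluate on held-out subjects: simulated test pairs with exact gold
# landmark vectors, vs the unregistered (identity) baseline
evaluate_cohort(fit, cohort[11:14], pairing_seed = 1)
#> Registration evaluation (simulated pairing, 8 cases)
#>   EPE (mm): 3.352 +/- 2.768
#>   NMI:      0.344 +/- 0.040
#>   Dice:     0.861 +/- 0.068
#>   Time (s): 0.036 +/- 0.002
evaluate_cohort("identity", cohort[11:14], pairing_seed = 1)
#> Registration evaluation (simulated pairing, 8 cases)
#>   EPE (mm): 11.887 +/- 5.005
#>   NMI:      0.117 +/- 0.037
#>   Dice:     0.440 +/- 0.203
#>   Time (s): 0.002 +/- 0.000

# register one pair and inspect the field
res <- predict(fit, cohort[[11]]$volume, cohort[[12]]$volume, what = "both")
res$field
#> <hr_field 64x64x1, max |u| 3.74 mm>
```

Read: registration cuts the mean landmark endpoint error from 11.9 mm
(unregistered) to 3.4 mm — a 72% reduction — while territory overlap
(Dice) rises from 0.44 to 0.86 and image similarity (NMI) from 0.12 to
0.34. The `final losses` line shows the three weighted hybrid-loss parts
at the last step; `field` is the supervised mean field deviation in mm on
that step's (fresh, random) training pair. A shell interface with
`phantom / preprocess / simulate / train / register / apply-field /
evaluate` subcommands is installed at `inst/cli/hybridreg`.

## Package tour

| Area | Functions |
| --- | --- |
| Phantoms | `phantom_spec`, `generate_phantom`, `generate_subject`, `generate_cohort` |
| Preprocessing | `strip_skull`, `zscore`, `pad_to_multiple`/`unpad`, `preprocess_subject` |
| Simulator | `simulator_config`, `sample_affine`, `affine_to_field`, `sample_elastic`, `compose_fields`, `sample_deformation` |
| Warping | `warp_volume`, `warp_mask`, `transform_points`, `field_voxels_to_mm` |
| Losses | `loss_weights`, `similarity_window`, `field_loss`, `local_sq_ncc_loss`, `hybrid_loss` |
| Network | `network_spec`, `build_network`, `predict_field` |
| Training | `train_config`, `hybridreg` (+ `predict`, `plot`, `summary`, `coef`, `simulate` methods), `train_network`, `make_supervised_pair`, `make_eval_pair`, `validate` |
| Evaluation | `landmark_epe`, `nmi`, `dice`, `paired_ttest`, `evaluate_cohort` |
| I/O | `read_volume`/`write_volume`, `read_field`/`write_field`, `read_landmarks`/`write_landmarks`, `read_run_config` |

See `vignettes/hybrid-supervised-registration.Rmd` for the model, its
assumptions, the numerical conventions and known limitations.
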