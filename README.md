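# bgcnn: rotation-invariant convolutional networks on the sphere for voxel-wise diffusion MRI classification

A single-shell diffusion-weighted MRI (DWI) voxel is a function on the unit
sphere — one attenuation value per gradient direction — and tissue classes
differ in its *angular pattern*, which can appear at any orientation.
`bgcnn` implements a three-layer geodesic convolutional network that learns
such patterns up to rotation, with so few parameters (164 for a two-class
model) that a single annotated scan, or a fraction of one, suffices for
training. It is aimed at researchers doing voxel-wise DWI tissue
classification and at anyone who needs rotation-invariant features of
sampled spherical signals.

## The model

The sphere is discretised by the 12 vertices of a regular icosahedron, and
the measured directions are interpolated onto tangent-plane sample points
with an antipodally symmetric Watson kernel,
w(q, g) ∝ exp(κ (qᵀg)²), row-normalised. Three layers follow:

1. **Lifting** — a tangent-plane kernel k (5 rays × 2 radii + centre,
   radius 0.6 rad) is correlated with the signal at every discrete tangent
   rotation: (k ⋆ f)(S) = Σᵢ ∫ kᵢ(S⁻¹v) fᵢ,ₓ(v) dv, discretised so that the
   rotated kernel is an exact index permutation of the 11-point grid;
2. **Group correlation** — correlation over the cyclic group of 5 tangent
   rotations, (F ⋆ K)(S) = Σᵢ ∫ Fᵢ(R) Kᵢ(S⁻¹R) dR, the Haar integral
   becoming a uniform 5-term sum;
3. **Projection** — a per-vertex maximum over the rotations,
   f(x) = max_R F(x, R), which removes the dependence on how the kernels
   were transported (the holonomy ambiguity of a curved space).

A single dense layer maps the flattened 12 × 5 projected features to class
probabilities. Training minimises the focal loss
FL(p_t) = −α_t (1 − p_t)^γ log p_t with Adam and analytic, hand-derived
gradients (finite-difference-checked in the tests); γ = 0 with unit α is
cross-entropy, used for balanced tasks.

Everything runs in plain R — no deep-learning framework is required.

## Worked example

The package bundles the synthetic rotation benchmark: 90 directions on a
hemisphere, per-class Gaussian values, and every sample an independent
uniform rotation of its class's function — so the *only* usable class
signal is the angular pattern. Train the 286-parameter four-class model:

```r
library(bgcnn)
res <- run_synth_experiment(n_classes = 4, model = "gcnn", seed = 1)
res
#> # A tibble: 1 × 4
#>   model n_classes n_parameters test_accuracy
#>   <chr>     <int>        <int>         <dbl>
#> 1 gcnn          4          286         0.981

attr(res, "reports")$gcnn
#> Overall accuracy: 0.9808
#> # A tibble: 4 × 5
#>   class n_true recall  dice undefined
#>   <int>  <dbl>  <dbl> <dbl> <lgl>
#> 1     0   1000  1     0.975 FALSE
#> 2     1   1000  0.975 0.987 FALSE
#> 3     2   1000  0.948 0.961 FALSE
#> 4     3   1000  1     1     FALSE
```

A model classifying 4000 unseen random rotations at 98% accuracy with 286
trainable scalars: `n_parameters` counts every weight and bias (11 + 1
lift, 25 + 5 group kernel, 240 + 4 dense head), `test_accuracy` is the
proportion of the 4 × 1000 held-out rotated samples recovered, and the
per-class table gives recall and Dice from the confusion matrix. For real
data, `run_dwi_experiment()` takes a 4D NIfTI volume with FSL `bval`/`bvec`
tables and a co-registered label volume, extracts one shell, normalises by
the voxel-wise mean b0, trains on labelled voxels (optionally a per-class
subsample) and writes a predicted label volume.

A command-line front end is installed with the package:

```sh
bgcnn synth-generate --classes 2 --seed 1 --out synth
bgcnn train --classes 2 --model gcnn --seed 1 --out run/
bgcnn predict-volume --dwi scan.nii --bval scan.bval --bvec scan.bvec \
      --labels labels.nii --b-target 1000 --alpha 0.25,0.75 --out dwi_run/
```

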