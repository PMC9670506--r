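---
title: "Rotation-invariant convolution on the sphere: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation-invariant convolution on the sphere: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcnn)
```

## The problem

A single-shell diffusion-weighted MRI (DWI) voxel is a sampled function on
the unit sphere: one scalar attenuation per gradient direction, with the
physical symmetry $f(g) = f(-g)$. Tissue classes differ in the *angular
pattern* of that function, and the pattern appears at arbitrary
orientations. `bgcnn` implements a small convolutional network whose
features are, by construction, invariant to how the tangent-plane kernels
are oriented — the discrete counterpart of learning spherical patterns up
to rotation — and trains it voxel-by-voxel, so a single annotated scan (or
a fraction of one) suffices as training data.

## The three layers

Let $M = S^2$ and let $f \in L^2(M, \mathbb{R}^{N_c})$ be the (interpolated)
signal. Three layers are composed:

1. **Lifting.** A *pointed kernel* $k$ lives on the tangent plane at a base
   point, supported in a ball of radius $r$. Parallel transport $P_\gamma$
   along a chosen path family carries it to every point $x$. The lift
   correlates kernel and signal at every tangent rotation
   $S \in SO(T_xM)$:
   $$(k \star_\gamma f)(S) \;=\; \sum_{i=1}^{N_c} \int_{T_xM}
     k_i(S^{-1}v)\, f_{i,x}(v)\, dv,
     \qquad f_{i,x} = f_i \circ \mathrm{Exp}_x ,$$
   producing a function on the bundle of tangent rotations.
2. **Group correlation.** On each fibre $SO(T_xM) \cong SO(2)$, the lifted
   feature is correlated with a rotation kernel $K$ under the Haar measure:
   $(F \star K)(S) = \sum_i \int F_i(R)\, K_i(S^{-1}R)\, dR$.
3. **Projection.** $f^{out}(x) = \max_{R \in SO(T_xM)} F(x, R)$. Because
   two path choices differ fibre-wise by a fixed rotation and the Haar
   measure is bi-invariant, the maximum is independent of the base point
   and the transport paths — this is what removes the arbitrariness that
   holonomy introduces on a curved space.

Biases are added per kernel and ReLU follows the lifting and the group
correlation (without the nonlinearities the first two layers would collapse
into a single lifting, which the test suite verifies by exhibiting the
equivalent single kernel).

## Discretisation

* **Vertices.** The sphere is discretised by the 12 vertices of a regular
  icosahedron (vertex 1 rotated to the north pole; adjacent vertices
  subtend $\arccos(1/\sqrt5) \approx 63.4^\circ$).
* **Kernel grid.** Tangent kernels are sampled on a polar grid: 5 rays,
  2 samples per ray at radii $0.3$ and $0.6$, plus the centre — 11 points
  within radius $0.6$ rad. Two adjacent kernels overlap, since
  $2 \times 0.6 > \arccos(1/\sqrt5) \approx 1.107$. The centre sample is
  included because it is what reconciles the "5 rays, 2 samples per ray"
  layout with the model's parameter totals (164/286/408; see below).
* **Rotations.** The fibre $SO(2)$ is discretised by the 5 rotations
  $2\pi k/5$ that map the grid onto itself, so rotating the kernel is an
  exact permutation of grid indices (the centre is fixed) and the Haar
  integral becomes the uniform sum over the 5 slots.
* **Frames.** Each vertex needs a tangent frame to lay the grid down.
  By default ray 0 points along the geodesic to the vertex's first
  (lowest-index) neighbor: at an icosahedron vertex the five neighbor
  directions are *exactly* $2\pi/5$ apart (the vertex figure is a regular
  pentagon), so with this anchoring the rays point at the five neighbors
  and the sampling pattern is identical at every vertex up to rotation.
  Any frame field is the parallel transport of the base frame along *some*
  path family (holonomy on $S^2$ generates all of $SO(2)$), so this choice
  sits squarely inside the construction above. The alternative
  `frames = "transport"` builds the frames by transporting the base frame
  along minimizing geodesics (with a fixed two-leg path through the first
  neighbor for the antipodal vertex, where the minimizing geodesic is not
  unique); those frames carry arbitrary holonomy offsets relative to the
  local neighbor grids. Both are provided; the network default is the
  neighbor anchoring because it makes the per-vertex feature extractor
  identical across vertices, which measurably helps the dense read-out
  generalise across rotations.
* **Invariance, exactly and approximately.** With 5 discrete rotations the
  composed lift–correlate–project map is *exactly* invariant under
  re-anchoring any vertex's frame by multiples of $2\pi/5$, and under
  changing the base vertex once the frames are realigned to the induced
  5-fold grid (`realign_frames()` snaps a chart's frames to a reference
  chart's grid). Re-anchoring by arbitrary angles changes where the signal
  is sampled, so it is only approximately neutral; the residual is the
  error of discretising $SO(2)$ by 5 rotations and shrinks with smoother
  signals. The test suite asserts the exact invariances at $10^{-6}$ and
  bounds the approximate one.

## Interpolation

Scanner directions rarely coincide with the 132 chart sample points
(12 vertices × 11 grid points), so values are interpolated with a Watson
kernel: the weight of data direction $g$ at query $q$ is proportional to
$\exp(\kappa (q^\top g)^2)$, row-normalised to a partition of unity (the
Watson normalising constant cancels, and constants are reproduced
exactly). The kernel is antipodally symmetric, matching DWI physics; it is
kept for the synthetic hemisphere data too, one formula everywhere.
$\kappa$ trades smoothing against peak preservation: 10 for the tissue
tasks, 5 for the synthetic benchmark. Because the chart is fixed, one
weight matrix per acquisition scheme maps raw signals to all 132 sample
points; the whole front end is a fixed linear resampling followed by
learned layers.

## The classifier and its size

The voxel model is lift → ReLU → group correlation → ReLU → projection →
dense → softmax, with 1 lift channel, 5 correlation channels, and a single
dense layer from the flattened $12 \times 5$ manifold features
(vertex-major, channel fastest). Parameters including biases:

$$\underbrace{11 + 1}_{\text{lift}} +
  \underbrace{1 \cdot 5 \cdot 5 + 5}_{\text{corr}} +
  \underbrace{12 \cdot 5 \cdot n + n}_{\text{dense}}
  \;=\; 164,\ 286,\ 408 \quad (n = 2, 4, 6).$$

The dense baseline is FC(90)–ReLU–FC(50)–ReLU–FC(30)–ReLU–FC($n$) on the
values interpolated back onto the 90 fixed acquisition directions. Its
printed parameter totals exceed plain dense-stack arithmetic by exactly
$2(50+30) = 160$, which matches a per-unit scale-and-shift normalisation on
the two hidden layers; `mlp_config(hidden_norm = TRUE)` (the default)
implements that as layer normalisation with learnable gain and shift and
reproduces the totals (6302/6364/6426, and 5802 for the 80-direction
variant). Neither setting is treated as ground truth; the flag exposes
both.

## Training

Training minimises the focal loss
$\mathrm{FL}(p_t) = -\alpha_t (1-p_t)^\gamma \log p_t$ (probabilities
clamped below at $10^{-8}$; $\gamma = 0$ with unit weights is
cross-entropy) with Adam at default moments — the optimiser is this
package's choice, recorded in the training config. Gradients are
analytic, hand-derived for every layer, and validated against central
finite differences at $10^{-4}$ relative error in the test suite. Batch
size defaults to 32; minibatch shuffling, initialization and the data
generator all draw from explicit seeds, so a run is a pure function of its
configuration. For the imbalanced tissue tasks the settings follow the
class weights $\alpha$ given per task ($\gamma = 2$); the balanced
synthetic benchmark trains with cross-entropy ($\gamma = 0$), since focal
weighting exists to counter imbalance. Early stopping (optional) monitors
one class's validation accuracy with a patience of 5 epochs — the patience
is this package's choice where "stops rising" is otherwise unquantified.

Weight initialization is fan-in-scaled uniform (He-style) from a seed kept
in the model config. The tiny classifier is sensitive to initialization:
an occasional run settles in a visibly poor optimum (final *training*
accuracy well below 1). `run_synth_experiment()` therefore trains
`n_restarts = 3` seeded initializations and keeps the run with the lowest
final training loss — a standard multi-start policy that never looks at
test data.

## The synthetic rotation benchmark

`generate_dataset()` reproduces the benchmark that isolates rotational
invariance: 90 directions sampled area-uniformly on the upper hemisphere
($z \sim U(0,1)$, azimuth uniform) are shared by all classes; each class
draws 90 i.i.d. $N(0,1)$ values (same distribution for every class, so the
classes share scale); each sample is an independently Haar-uniform rotated
copy (unit-quaternion construction) of its class's function — 50 training
and 1000 test samples per class for 2/4/6 classes. Train and test are
disjoint with probability one by independence of the rotations. Where the
benchmark's description leaves freedom we chose: standard normal values,
Haar-uniform rotations per sample, one seeded stream split by position.

What the generator emulates is exactly this rotation task — it makes no
attempt at DWI physics (no tensors, no fibre crossings, no Rician noise),
so passing it demonstrates rotational robustness of the architecture, not
tissue-contrast realism; the NIfTI fixture generator
(`write_dwi_fixture()`) covers the volume pipeline with tensor-profile
blocks instead.

One property of this construction deserves emphasis. With i.i.d. values
the *sample mean* of a class's 90 values differs between classes by
sampling noise ($\mathrm{sd} \approx 1/\sqrt{90}$), and the mean survives
both rotation and Watson smoothing. It is therefore a rotation-invariant
scalar cue available to *any* model — a logistic regression on that single
number separates two classes almost perfectly on typical seeds. Our
Adam-trained dense baseline reliably finds it (test accuracy far above
chance), unlike the chance-level baseline the benchmark is usually quoted
with; removing the cue by standardising each class's values makes the
baseline nearly honest but measurably hardens the main task as well. We
keep the generator literal (i.i.d. values) and report the baseline as our
implementation measures it.

## Numerical choices

* Antipodal `log_map` input is an explicit error (cut locus); the
  antipodal *vertex* in frame transport takes the fixed two-leg path.
* Watson weights subtract the row maximum before exponentiation, so large
  $\kappa$ cannot overflow.
* `project_max` breaks ties toward the lowest rotation slot; its
  subgradient routes to that slot.
* Focal-loss gradients use the clamped probability; the $\gamma = 0$
  branch avoids the $0 \cdot \infty$ form at $p_t = 1$.
* b0 normalisation masks voxels with non-positive mean b0 (reported, not
  silently dropped); the b0 threshold defaults to 50 s/mm².
* Checkpoints store doubles as `%.17g` strings inside JSON, which
  round-trips IEEE-754 exactly.

## Problem sizes used in the checks

The bundled tests train the full benchmark (50/1000 per class, 200 epochs)
for 2, 4 and 6 classes over three seeds, and the acceptance script averages
five independent repetitions per setting; the volume pipeline is exercised
on a generated 6×6×6×14 two-tissue scan, where per-class Dice reaches ~1
after ~100 epochs. Property tests run on randomly generated kernels and
signals under fixed seeds.

## Known limitations

* The chart is the fixed 12-vertex icosahedron: adequate for single-shell
  voxel signals, not a general mesh framework; no icosphere refinement.
* Exact invariance holds only for the $2\pi/5$ subgroup; arbitrary
  re-orientations of the *input signal* are handled statistically (the
  network sees many rotations in training), not by construction.
* Spatial context is ignored — voxels are classified independently.
* Label volumes must share the DWI grid (or be nearest-neighbor resampled
  beforehand); no registration is performed.
* The synthetic benchmark's i.i.d. values leak a weak rotation-invariant
  moment cue (see above); comparisons of non-geometric baselines on it
  should be read with that in mind.
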