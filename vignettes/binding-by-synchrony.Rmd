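---
title: "Binding by synchrony: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding by synchrony: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`phasebind` simulates a two-variable neural oscillator network on top of
a convolutional feature representation of an image. Each neuron at grid
position $(x, y)$ coding feature $k$ carries an **activation** $g_{x,y,k}
\ge 0$, computed once from the image by a feedforward stage and then held
fixed, and a **phase** $\varphi_{x,y,k} \in [0, 2\pi)$, evolved by a
Kuramoto-type equation

$$\frac{d\varphi_{x,y,k}}{dt} \;=\; -\frac{1}{\tau} \sum_{e}
g_{x,y,k}\, w_e\, g_{x-\delta x, y-\delta y, j}\,
\sin\!\big(\varphi_{x,y,k} - \varphi_{x-\delta x, y-\delta y, j}\big),$$

where the sum runs over a sparse, translation-invariant set of signed
tangential connections $e = (\delta x, \delta y, j, k, w_e)$ with $w_e =
+1$ (synchronizing) or $-1$ (desynchronizing). Because all oscillators
share one natural frequency, the common rotation is transformed away and
$\varphi$ represents only phase *offsets*; the hypothesis under study is
that neurons coding parts of the same object align these offsets —
binding by synchrony — while desynchronizing connections keep unrelated
parts apart. The separation into a rate-like activation and a relational
phase reflects the physiological picture of feature coding by firing
rate and contextual grouping by spike timing.

Assumptions worth keeping in mind: activations are constant during a
phase run (stimulus fixed over the fast oscillatory timescale); the
interaction is purely sinusoidal; the model is deterministic — all
desynchronization comes from the learned negative connections, not from
noise; and there is no feedback from phases to activations, so gaps in a
stimulus are never "filled in".

## Pipeline stages and their parameters

**Preprocessing** (`preprocess_image`). Images are resized
(area-averaging, anti-aliased by construction — the reference scale is
400×300 from 2560×1920, a 6.4× downscale), per-channel mean-subtracted,
and whitened with a smoothed zero-phase (ZCA) transform $U D U^\top$
with $D_{ii} = 1/\sqrt{\lambda_i + 0.1}$. The regularizer 0.1 keeps the
transform from amplifying noise in near-null directions; the whitening
matrix is estimated on image patches (default 12×12, the receptive-field
extent) and truncated to its center row, giving a small center-surround
convolution kernel. Estimating on patches and applying convolutionally
is our choice for realizing the transform "as a filter"; the covariance
extent is the one genuinely free parameter and is exposed as
`patch_extent`.

**Feature stages** (`build_gabor_bank`, `train_autoencoder`). The
designed bank uses three-lobe monophasic Gaussian-derivative profiles
$g_{2\sigma}(y)\,(-5 g_\sigma(x+\sigma) + 10.1 g_\sigma(x) - 5
g_\sigma(x-\sigma))$ with $\sigma = 1.5$ px, rotated to 8 orientations in
22.5° steps, applied per RGB channel and duplicated with opposite sign
(on/off opponent pairs): 48 channels, 12×12 px, stride 2. The sigmoid
that maps the linear drive to $(0,1)$ has unspecified provenance for its
gain; we use the unit-gain logistic and expose `gain`. `color = FALSE`
collapses the color axis into luminance filters (2 × orientations
channels), the configuration the desk-scale recipes use. The learned
alternative is a convolutional sparse autoencoder (12×12 filters, stride
2, linear decoder, valid-only convolutions during training) minimizing
reconstruction error + a KL sparseness penalty toward mean activation
0.035 (weight β = 90) + L2 weight decay (0.3), by L-BFGS (delegated to
`stats::optim`, 500 iterations cap) with backpropagated gradients that
are finite-difference-checked in the test suite.

**Activation regularization** (`regularize_activations`). At every
position the mean activation over features is subtracted, negative
residues are clipped (half-wave rectification; roughly half of the
neurons inactivate, which is the stated intent of this stage), and the
rest is normalized to unit sum. One printed formulation of this step
subtracts the per-position *sum* rather than the mean; with sigmoid
outputs that would inactivate nearly every neuron, contradicting both
the stated intent and the normalization that follows, so this package
subtracts the mean. Inactive positions ($g \equiv 0$) are flagged and
take no part in the dynamics. A consequence used by the evaluation: the
per-position activation mass is uniform (0 or 1) across the image.

**Connectivity** (`correlation_tensor`, `fdr_significance_mask`,
`sample_connections`). Pearson correlations between feature $k$ at a
position and feature $m$ at spatial offset $(\delta x, \delta y)$ are
pooled over positions and images, for offsets up to `max_offset`
(default 18 grid units = three receptive-field extents at stride 2; the
desk recipes use 6). Entries are masked by a
Benjamini–Hochberg–Yekutieli step-up at FDR 0.05 under arbitrary
dependence, with two-sided p-values from the t approximation $t = \rho
\sqrt{(n-2)/(1-\rho^2)}$ — the t approximation is our choice; only the
BHY procedure itself is prescribed. For each efferent feature,
`eta_plus` synchronizing connections are drawn with probability
proportional to $\max(0, \rho)$ and `eta_minus` desynchronizing ones
proportional to $\max(0, -\rho)$ (self-pairs excluded). Because the
per-feature counts are fixed, sampling must be without replacement; we
use systematic probability-proportional-to-size sampling, whose
inclusion probabilities equal the capped proportional shares — the
natural without-replacement realization of the stated marginal
probabilities (verified empirically against the closed-form
probabilities in the tests). Reference scale is 200+200 per neuron
(sparsity 0.014% of full signed connectivity at 200×150×48); the desk
recipes use 50+50.

**Dynamics** (`simulate_phases`). One "iteration" is one classical RK4
step of unit step size; $\tau$ absorbs all physical time units. Initial
phases are i.i.d. uniform, drawn feature-major from the seed. Phases are
stored wrapped to $[0, 2\pi)$ and all differences are computed wrapped
to $(-\pi, \pi]$. The step-size sanity rule (`check_step_criterion`): a
run is trustworthy when at most 1% of neurons move more than $\pi/2$ per
iteration. $\tau = 1/3$ is the reference value for Gabor activations and
$1/30$ for autoencoder activations; both pass the criterion on the scene
fixtures. In the uniform-activation pinwheel demonstration every neuron
has $g = 1$, so the interaction scales with the raw connection count and
the same criterion leads to $\tau$ of the order of that count — the
recipe sets $\tau$ = (number of afferent connections). Grid borders
absorb (outside sources contribute nothing); the pinwheel demo uses the
optional toroidal mode to avoid boundary pinning.

**Evaluation** (`mean_phase_map`, `population_synchrony`,
`local_synchrony`, `segmentation_index`, `boundary_phase_difference`,
`boundary_angle_error`). Synchrony of a population is its
activation-weighted mean resultant length. The segmentation index
$\kappa$ compares mean synchrony over 100 random 1000-neuron subsets of
a segment against subsets of its neighborhood, grown by diamond
dilations until it holds twice the segment's neurons; subsets are drawn
without replacement when the pool suffices, with replacement otherwise
(small segments × few features can undershoot 1000). Matching runs are
paired against non-matching runs (same masks applied to a cyclically
deranged scene list) because compact regions score positive $\kappa$
generically — spatial synchrony decays with distance — and only the
paired difference isolates genuine binding. Boundary metrics: at
sampled boundary cells the local tangent is the principal axis of
nearby boundary cells (radius 10); the semicircle contrast splits the
disc along that tangent, picks the inner half as the one containing
more of the segment, and takes the absolute wrapped difference of the
two halves' weighted circular means. The orientation estimator builds
the local phase variance $\vartheta$ (1 minus the normalized resultant
of the five-point phasor stencil summed over features; border stencils
drop missing neighbors and shrink the normalizer), takes central
differences, forms the Gaussian-windowed (σ = 3) structure tensor, and
reads the boundary direction from the eigenvector of the *smaller*
eigenvalue — the gradient of $\vartheta$ points across a boundary, so
the minor axis runs along it. Errors are folded to [0°, 90°]; a uniform
random estimate scores 45° on average, the chance level every run is
compared against. Confidence intervals are normal-approximation
mean ± 1.96 SEM, over segments for paired $\kappa$ and over sampled
boundary locations for the angle error.

## The synthetic scene generator

Real evaluations in this line of work use hand-labeled photographs;
those are large, external downloads, so the package ships a generator
(`make_synthetic_scene`) whose scenes stand in for them: a colored
background carrying smooth low-amplitude texture, and non-overlapping
smooth blob-like polygonal segments (16 vertices, low-order Fourier
radius modulation) whose color differs from the background by at least
`contrast` per channel (one shared sign, so segments also differ in
luminance) and which carry stronger oriented band-limited texture
(wavelength 4–10 px, amplitude 0.12, phase-jittered). Segment radii are
drawn so that every mask, after stride-2 downsampling, lands inside the
evaluated size range (36–15000 grid cells). The same seed reproduces
the scene bit-identically.

The oriented textures and smoothly curved outlines are not decoration:
the connectivity is learned from activation correlations, and what
natural images teach such a learner is precisely (a) collinear
continuation of oriented structure and (b) slow rotation of orientation
along object contours. An isotropic-noise generator produces neither,
and with it the learned connections carry no segment-binding signal.
What the generator does *not* emulate: occlusion and overlapping masks,
part–whole label hierarchies, broad 1/f spatial spectra, perspective
and shading gradients, and the size statistics of real labeled objects
(real label sets are dominated by many small segments). A green
scene-study test therefore establishes that the mechanism binds
ground-truth regions under natural-like low-level statistics — not that
it reproduces photograph-level numbers.

Desk-scale defaults for the end-to-end recipes: 128×128 px images
(64×64 neuron grid), 16 luminance feature channels, 50+50 connections
per neuron, correlation offsets up to 6, 20 iterations (the
dashed-circle demonstration integrates 100: its binding must propagate
multi-hop around the contour; the collinear bars are bridged directly).

## Numerical choices and degenerate inputs

- Constant images whiten to exactly zero (nothing to decorrelate);
  degenerate zero-area images and non-RGB inputs are rejected.
- Zero-variance features yield undefined correlations; they are stored
  as `NA` and masked out before sampling. The sampler refuses (with an
  informative error) when a feature lacks enough strictly positive or
  negative candidates for the requested counts.
- Antipodal equal-weight phasors have zero resultant: such positions are
  flagged invalid in phase maps rather than assigned an arbitrary angle.
- Eigen-decompositions use the symmetric path (`eigen(symmetric =
  TRUE)`); the structure tensor's orientation is undefined when the
  tensor vanishes — such locations are excluded and counted.
- The shortest-path statistics of the translation-invariant connection
  graph are computed by breadth-first search over (feature, offset)
  states. An infinite graph has no canonical search bound; we bound
  offsets at three times the largest sampled connection length and cap
  hops at 8, excluding (with a warning) pairs not reached — at the
  realized densities path lengths are 2–3 hops, far from the bound. The
  random baseline keeps every connection's Euclidean length but
  re-draws its orientation and feature pair, averaged over ≥10
  randomizations.
- The non-matching pairing is a deterministic cyclic shift of the scene
  list, so the baseline is reproducible and every scene appears exactly
  once in each role.

## Known limitations

- The dashed-circle demonstration rarely reaches one globally coherent
  phase at desk scale; it typically forms a continuous phase progression
  or a few clusters around the contour (a failure mode that also exists
  at full scale, where it is the exception rather than the rule). The
  recipe reports the coherent-case count; the robust property — the
  stimulus synchronizes above a stimulus-plus-background reference — is
  what the tests assert.
- Photograph-scale reference numbers (median kurtosis tables,
  small-world coefficients, segmentation-index curves, full-scale
  boundary-angle errors) require a real labeled-image corpus and full
  200×150×48+ simulations; the package asserts the
  directions and desk-scale analogues only, and `run_recipe` exposes
  full-scale parameters for users who supply real data via
  `read_image`/`load_masks`.
- The autoencoder's learned filters at desk-scale training budgets are
  serviceable but not the crisp oriented patches a 500-iteration,
  625,000-sample run produces; tests exercise the loss, gradients and
  training loop on tiny instances.
- Videos, eye movements, feedback from phase to activation, conduction
  delays and multi-band oscillations are out of scope.
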