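# phasebind

Binding by synchrony in coupled neural phase oscillator networks.

`phasebind` is for computational neuroscientists who want to test, on
images with ground-truth segmentations, the hypothesis that the visual
cortex groups features of one object by *synchronizing their oscillation
phases*. The package implements the whole chain:

1. **Preprocessing** — resize, per-channel mean subtraction, smoothed
   zero-phase (ZCA) whitening applied as a center-surround convolution
   kernel (`preprocess_image`, `build_zca_kernel`).
2. **Feedforward features** — a Gaussian-derivative (Gabor-like) bank
   (8 orientations × 3 colors × 2 opponent signs = 48 channels, 12×12 px,
   stride 2; `build_gabor_bank`) or a convolutional sparse autoencoder
   trained by L-BFGS (`train_autoencoder`), followed by mean
   subtraction, half-wave rectification and unit-sum normalization
   (`regularize_activations`).
3. **Unsupervised connectivity** — Pearson cross-correlations of the
   induced activations over spatial offsets (`correlation_tensor`),
   Benjamini–Hochberg–Yekutieli FDR masking, and sampling of sparse
   signed tangential connections, `eta` synchronizing (+1) and
   desynchronizing (−1) per neuron (`sample_connections`). Each
   connection is a 5-tuple (δx, δy, afferent feature, efferent feature,
   sign), applied at every grid position.
4. **Dynamics** — the activation-weighted Kuramoto network

   dφ<sub>x,y,k</sub>/dt = −(1/τ) Σ<sub>e</sub> g<sub>x,y,k</sub> · w<sub>e</sub> ·
   g<sub>x−δx,y−δy,j</sub> · sin(φ<sub>x,y,k</sub> − φ<sub>x−δx,y−δy,j</sub>),

   integrated with classical 4th-order Runge–Kutta at unit steps
   (`simulate_phases`), with a step-size sanity criterion
   (`check_step_criterion`).
5. **Evaluation** — circular-mean phase maps, activation-weighted
   synchrony, a segmentation index κ (segment vs. doubled diamond-grown
   neighborhood, with a matching vs. non-matching baseline), semicircle
   boundary phase contrast, and structure-tensor boundary-angle
   estimation against the 45° chance level.

A seeded generator of natural-like scenes with ground-truth masks
(`make_synthetic_scene`), artificial Gestalt stimuli
(`make_artificial_stimulus`), LabelMe-style XML / label-raster mask
ingestion (`load_masks`), and end-to-end recipes (`run_recipe`:
`pinwheel`, `gestalt`, `scene_study`) are included. See the vignette
`vignettes/binding-by-synchrony.Rmd` for the model, parameter and design
notes.

## Worked example

Learn connectivity from four synthetic scenes, simulate the phase
network on one of them, and score a ground-truth segment:

```r
library(phasebind)

bank <- build_gabor_bank(color = FALSE)         # 16 luminance channels
scenes <- lapply(1:4, function(i) make_synthetic_scene(100 + i, extent = 128))
learned <- learn_connectivity(lapply(scenes, `[[`, "image"), bank,
                              eta_plus = 50, eta_minus = 50,
                              max_offset = 6, seed = 1)
learned$conns
#> <connection_set: 1600 records (800 sync, 800 desync), K = 16>
graph_metrics(learned$conns, "sync", seed = 1)
#> <graph_metrics [sync]: mu = 11.58%, gamma = 0.03049 (rand 0.01192), lambda = 2.61 (rand 2.36), sigma_sw = 2.31>

g <- learned$g_blocks[[1]]
traj <- simulate_phases(g, learned$conns,
                        sim_config(tau = 1/3, n_iterations = 20, seed = 1))
check_step_criterion(traj)$pass
#> [1] TRUE

phi <- final_phases(traj)
Q <- filter_masks(scenes[[1]]$masks)[[1]]
kappa <- segmentation_index(phi, g, Q, seed = 1)
cat(sprintf("segmentation index kappa = %.3f\n", kappa))
#> segmentation index kappa = 0.060
ang <- boundary_angle_error(phi, Q, seed = 1)
cat(sprintf("boundary angle error = %.1f deg (chance 45)\n", ang$mean_error_deg))
#> boundary angle error = 37.5 deg (chance 45)
```

What the numbers mean: the sampled synchronizing subgraph is
small-world (σ<sub>sw</sub> = 2.31 > 1: clustered like the learned
correlations but with random-graph path lengths); the simulation passes
the step-size criterion (no neuron population moves violently within an
iteration); κ = 0.060 > 0 means random neuron subsets inside the
labeled segment are more phase-synchronous than subsets of its grown
neighborhood; and the phase map's discontinuities predict the segment's
boundary orientation with 37.5° mean error, clearly below the 45°
chance level. Meaningful κ values are established against the
non-matching baseline — `run_recipe("scene_study", seed = 1)` runs the
full paired design.

A thin command-line front-end over the recipes is provided at
`inst/cli/phasebind.R`:

```sh
Rscript inst/cli/phasebind.R scene_study --seed 1 --scenes 10 --out study.json
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — generating scenes, learning connectivity, simulating the
oscillator network and evaluating the segmentation metrics — and writes
a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
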