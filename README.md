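# voxflex

Voxel-level protein flexibility prediction from cryo-EM density maps and
fitted atomic models.

## What it does

Cryo-EM reconstructions average many instantaneous conformations of a
molecule, so flexible regions appear blurred; the fitted atomic model is
close to the mean structure and encodes the topology that determines
flexibility. `voxflex` combines the two to predict the root-mean-square
fluctuation

RMSF_i = sqrt( (1/T) * sum_t || x_i(t) - x̃_i ||² )

of every atom-occupied map voxel and every residue, in Angstrom — the
standard flexibility index otherwise obtained from long molecular-dynamics
simulations.

The pipeline: resample the map to 1.5 A voxels → render a simulated density
from the model (mass-weighted Gaussians, sd = 0.225 × resolution) → cut both
grids into 40³ boxes (stride 10), keep boxes whose central 10³ subbox
contains atoms, normalise each box to [0, 1] → run a 3D nested-Unet
(Unet++, three down-samplings, dense skip pathways) that regresses RMSF on
the central subbox → merge the subboxes back into an RMSF map and average
per residue. Training uses masked mean-squared error on ensemble-derived
labels, Adam (lr 0.004, batch 32), validation-driven halving/early-stopping
and eightfold flip augmentation. Input variants share the backbone: map
only (`cryo`), simulated map only (`pdb`), its 3σ one-hot encoding
(`pdb01`), both (`dual` — the flagship), plus a two-stage route
(`occ2rmsf`) through a per-voxel structure-occupancy classifier trained
with class-weighted cross-entropy (0.05:0.95).

Because MD-labelled training data cannot ship with a package, `voxflex`
includes a synthetic study system with closed-form ground truth:
globular pseudo-proteins (self-avoiding 3.8 A walks), fluctuation ensembles
with known per-atom amplitudes σ_i (expected RMSF = σ_i √3), and
heterogeneity-blurred noisy maps. Every stage of the pipeline is tested
against these closed forms. The neural network itself is implemented from
scratch in RcppArmadillo (single precision, im2col + SGEMM convolutions,
batch norm, trilinear upsampling, Adam) with finite-difference-verified
gradients; for the regression variants it evaluates exactly the receptive
field of the central subbox, which makes CPU training practical.

## Worked example

Train on a small synthetic dataset and predict a held-out entry:

```r
library(voxflex)

ds <- make_dataset(10, synthetic_spec(), seed = 1)      # ~300-atom entries
samples <- lapply(ds$entries, prepare_samples, variant = "dual")
fit <- train_network(
  build_rmsf_network(network_config("dual", base_channels = 8, seed = 1)),
  train_samples = unlist(samples[1:6], recursive = FALSE),
  val_samples   = unlist(samples[7:8], recursive = FALSE),
  train_config(epochs = 12, batch = 32, lr = 0.004, seed = 1,
               augment = FALSE))

ccs <- sapply(9:10, function(i) {                        # held out
  entry <- ds$entries[[i]]
  pred <- predict_rmsf_map(fit$model, entry$map, entry$model, resolution = 5)
  evaluate_entry(pred, entry)$voxel_cc
})
mean(ccs)
```

On this configuration (about ten minutes on one CPU) the run prints a
falling loss curve and the held-out evaluation returns

```
[1] 0.7522507
```

— the mean Pearson correlation between predicted and ground-truth RMSF over
the labelled voxels of the two held-out maps. (With one pseudo-residue per
atom and a minimum atom distance larger than the voxel diagonal, atoms never
share a voxel, so the residue-level correlation from `evaluate_entry()`
coincides with the voxel-level one on this synthetic system.) Values near
0.75 on clean synthetic data mean the network has learned the blur/topology
→ flexibility relationship end to end; the exact number varies a little
with the training seed. `pred$rmsf_map` is a
masked RMSF map you can write with `write_density_map()`;
`write_model_bfactor()` puts the per-atom predictions in a PDB B-factor
column for colouring in a molecular viewer.

A command-line interface wrapping the same functions ships in
`inst/cli/voxflex` (subcommands `synth`, `train`, `predict`, `evaluate`).

## Scope

Proteins only (no nucleic acids, ligands or membranes); the synthetic
system demonstrates pipeline correctness and learnability, not transfer to
experimental EMDB maps — for that, train on real maps with MD-derived
labels. See the methods vignette (`vignettes/voxflex-methods.Rmd`) for the
model, its assumptions and the design decisions.
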