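---
title: "voxflex: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxflex: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A cryo-EM reconstruction averages hundreds of thousands of particle images.
Regions of the protein that fluctuate across the imaged ensemble are blurred
in the reconstructed density — lower, broader peaks — so the map carries a
physical signal about local flexibility. The fitted atomic model, in turn,
is close to the *mean* structure of the fluctuating molecule and encodes the
topological determinants of flexibility (burial, packing, chain ends).
`voxflex` combines both sources to predict per-voxel and per-residue
root-mean-square fluctuation (RMSF),

$$\mathrm{RMSF}_i = \sqrt{\tfrac{1}{T}\sum_{t=1}^{T}\lVert x_i(t) -
\tilde{x}_i\rVert^2},$$

the time-averaged deviation of atom $i$ from its mean position
$\tilde{x}_i$ — the standard flexibility index of molecular-dynamics
analysis, in Angstrom.

## Pipeline

1. **Resampling.** The experimental map is brought to an isotropic
   1.5 A voxel size (about one heavy atom per voxel) by cubic B-spline
   interpolation with the standard recursive prefilter
   (`resample_to_voxel_size()`). Output voxel centre $i$ samples input
   coordinate $i \cdot \mathrm{target}/\mathrm{source}$; the world origin is
   preserved and boundary evaluation uses mirror reflection, which pairs
   with the prefilter's boundary assumption and reproduces knot values
   exactly (constants are preserved to machine precision).
2. **Simulated density.** The atomic model is rendered as a density map on
   the same grid (`simulate_density()`): each atom contributes an isotropic
   Gaussian with standard deviation $0.225 \times \mathrm{resolution}$ and
   peak amplitude proportional to its atomic mass, truncated at 4 standard
   deviations — the molmap convention. The simulation resolution should be
   the map's reported resolution (synthetic default 5 A).
3. **Boxing.** Both grids are zero-padded by 15 voxels per side (plus
   padding up to a stride multiple) and cut into 40^3-voxel boxes at a
   stride of 10, so the central 10^3 subboxes tile the original grid exactly
   once. Boxes whose central subbox contains no atom-occupied voxel are
   screened out; the surviving boxes are normalised per channel (negatives
   clamped to zero, then divided by the box maximum). The zero-padding rule
   is ours: it makes the merge step exact and overlap-free, with every
   original voxel covered by exactly one retained or discarded subbox.
4. **Network.** A 3D Unet++ with three down-samplings (channels
   $b, 2b, 4b, 8b$; 3^3 convolutions, batch normalisation, ReLU; max-pool
   down, trilinear up; dense nested skip pathways) followed by two 1-kernel
   convolutions and a centre crop to the 10^3 subbox. Input variants share
   the backbone and differ only in input channels: `cryo` (1, map only),
   `pdb` (1, simulated map only), `pdb01` (2, one-hot of the simulated map
   thresholded at $3\sigma$, where $\sigma$ is the population standard
   deviation of the simulated density about its mean), and `dual` (2,
   map + simulated map), the flagship configuration.
5. **Merging.** Predicted subboxes are written back at their recorded tile
   positions; since the stride equals the subbox edge no voxel is written
   twice, and `merge(segment(x))` is bit-exact on labelled voxels (a master
   property test). Per-atom values are read at each atom's nearest voxel
   and averaged per residue.

## Ground truth from ensembles

Training labels come from conformational ensembles
(`ensemble_rmsf()`): all frames are aligned to the first frame by Kabsch
superposition (proper rotations only, via SVD of the cross-covariance), the
heavy-atom mean structure is computed, frames are re-aligned to the mean and
the mean recomputed — twice, which stabilises the reference without
convergence machinery — and RMSF follows from the closed form above.
Per-atom values are deposited in nearest voxels (collisions averaged;
the mean is unbiased and order-independent) to form the masked `RMSFMap`
used by the masked mean-squared-error loss. Labels are raw RMSF in
Angstrom: the normalisation (z-scores over the model, population standard
deviation) is used only for visualisation and residue profiles, and Pearson
evaluation is scale-free.

## The occupancy route

To expose what a map-only predictor must learn, the two-step variant first
predicts per-voxel structure occupancy. `build_occ_network()` mirrors the
regression backbone but keeps the full 40^3 output with a 2-class softmax
head; ground truth marks a voxel occupied iff some heavy atom's nearest
voxel is that voxel. The loss is class-weighted cross-entropy with weights
0.05 : 0.95 (unoccupied : occupied) against the heavy class imbalance, and
precision/recall/F1 of the occupied class are reported at thresholds 0.3 to
0.8. In `compose_occ2rmsf()` the trained classifier is frozen and its
two-channel probability field feeds a fresh 2-channel regression head.

A caveat specific to the synthetic study system: at its default 5 A map
resolution, exact nearest-voxel occupancy is information-limited. Each atom's
Gaussian footprint (sd 1.125 A, about 0.75 voxel, further broadened by up to
1.2 A of heterogeneity blur) spreads over many voxels while the truth marks a
single one, and with 0.05 : 0.95 weights on a ~400:1 class imbalance the
weighted class ratio is still ~21:1 — so a well-trained classifier converges
to soft posteriors that rarely clear high probability thresholds. On this
system the classifier's F1 at threshold 0.7 is accordingly poor even as its
weighted cross-entropy keeps improving, in contrast to the sharper 2-4 A
experimental regime; the two-stage regression route is unaffected, since its
second stage consumes the soft probability fields themselves.

## Training

Adam at learning rate 0.004, batch 32, up to 100 epochs, Kaiming
initialisation. If the validation loss does not strictly improve for 10
consecutive epochs the learning rate is halved (so two halvings are possible
before stopping); after 30 stagnant epochs training stops and the
parameters with minimum validation loss are restored. "Improvement" means
strictly lower epoch validation loss, for determinism. Flip augmentation
applies the 8 axis-mirror combinations identically to channels, labels and
masks (offline eightfold expansion); each transform is an involution, and a
flip-equivariant predictor has exactly invariant loss on the expanded set —
both are property-tested. Splits are made at entry (map) level, never at
box level, with a 3:1 train:validation ratio inside each cross-validation
fold; one seed governs shuffling, batching and initialisation, and repeated
runs are bit-identical.

## Implementation notes on the network

No deep-learning framework is used: the network is implemented in
C++ (RcppArmadillo) in single precision, with im2col + SGEMM convolutions.
Two choices matter for reproducing it:

* **Receptive-field-exact evaluation.** For the regression variants only
  the central 10^3 output survives the crop, so the nested skip nodes are
  computed by *valid* convolutions on exactly the receptive field of that
  subbox (backbone nodes and the coarsest skip node cover their full grid
  with zero padding, as the uncropped network would). This is the
  restriction of the full-box network to the voxels the loss can see and
  cuts the per-box cost roughly fourfold on a CPU. One consequence is that
  batch-normalisation statistics are taken over the *active* region rather
  than the full 40^3 box; the occupancy classifier, whose output is the
  full box, is computed full-box with ordinary zero-padded convolutions.
* **Determinism.** Initialisation uses a Box-Muller normal generator on a
  seeded Mersenne Twister (C++ library normal distributions are
  implementation-defined); forward and backward passes are sequential and
  deterministic, so training is reproducible bit-for-bit given the seed.

Gradients of every layer were verified against central finite differences
(directional derivatives converge to the analytic value as the step
shrinks, to the single-precision noise floor).

Default widths: `base_channels = 16` for production use. The desk-scale
acceptance runs use base 8 for the dual regression network and base 4 for
the occupancy classifier — the classifier solves an easier task and its
full-box output makes each box several times more expensive, so a narrower
backbone is the appropriate scale there.

## The synthetic study system

The generator replaces an MD-simulation dataset with a system whose ground
truth is known in closed form:

* **Pseudo-proteins** (`generate_pseudo_protein()`): a self-avoiding random
  walk with fixed 3.8 A steps (the C-alpha virtual bond), minimum non-bonded
  distance 3.0 A, confined to a sphere sized from the atom count at packing
  fraction ~0.15 so the chain is globular like a real protein domain
  (a free walk of 300 steps would span >100 A and defeat the <=64^3 map
  budget). Dead ends back-track a few steps and regrow; reproducible per
  seed. One pseudo-residue (carbon) per atom.
* **Ensembles** (`generate_ensemble()`): per-atom per-axis amplitudes
  $\sigma_i = \sigma_{\min} + (\sigma_{\max}-\sigma_{\min})\, d_i / \max d$
  with $d_i$ the distance from the centroid — the periphery-flexible
  pattern of globular proteins, with a known closed form. Frames are the
  mean plus i.i.d. isotropic Gaussian noise, so the expected RMSF is
  $\sigma_i\sqrt{3}$ — the parameter-recovery oracle used throughout the
  tests. Defaults $\sigma \in [0.3, 1.2]$ A give RMSF ~0.5-2.1 A, the range
  typical of folded proteins over tens of nanoseconds.
* **Maps** (`generate_heterogeneous_map()`): the mean over frames of each
  frame's simulated density, plus white Gaussian noise at 5% of the
  noise-free maximum — a reconstruction that averages instantaneous
  conformations, so flexible atoms are visibly blurred. The generated
  map/model pairs have map-model fitness (Pearson correlation of simulated
  vs blurred map) above the 0.7 screening level used for real deposits,
  and density at atom sites anti-correlates with $\sigma_i$ — the
  flexibility signal the cryo channel is supposed to carry, asserted on the
  generator itself.

Default entry size is ~300 atoms with maps around 48^3 voxels and 300
frames, which keeps full training on a single CPU within minutes. What the
synthetic system does *not* emulate: secondary structure and realistic
stereochemistry, anisotropic or correlated motions, ligands, membranes,
solvent artefacts, CTF/reconstruction noise structure, or map/model
misalignment. Passing the end-to-end checks therefore demonstrates that the
pipeline is implemented correctly and can learn the blur/topology →
flexibility relationship, not that the trained weights transfer to real
EMDB deposits — training on real maps with MD-derived labels is required
for that.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` train on 10 generated entries
(6 train / 2 validation / 2 held-out test): the dual regression network at
base 8 for 12 epochs without augmentation, and the occupancy classifier at
base 4 for a few epochs. These sizes are the package's desk-scale defaults;
the held-out voxel-level Pearson correlation of the dual variant
(≥ 0.5, typically ~0.7-0.8) and the occupancy F1 at threshold 0.7 on clean
synthetic maps (far easier than experimental maps) are reported by the
acceptance script. On clean synthetic data an exploratory comparison the
package supports (but the shipped checks do not run, to stay within
minutes) is training the `cryo` and `dual` variants on the same split and
seed; across seeds the dual variant's held-out correlation is expected at
or above the map-only variant's, mirroring the motivation for the
dual-channel design.

## Numerical choices and degenerate inputs

* Population (not sample) standard deviations wherever a convention is
  needed (map sigma, z-score normalisation) — deterministic and stated so
  tests can be exact.
* All-zero simulated maps binarise to all zeros ($\sigma = 0$); all-negative
  boxes normalise to all zeros; constant vectors z-score to zeros.
* `world_to_voxel` maps coordinates to the nearest voxel centre with
  `floor((x - origin)/h + 0.5)`; out-of-bounds is a value (`NA`), not an
  error. Voxel indices are 0-based; a voxel's world position is its centre.
* MRC input honours the header's axis-correspondence fields and normalises
  storage order to (x, y, z); the origin comes from the ORIGIN record when
  non-zero, else from start indices times the voxel size (the two dialects
  in circulation). Anisotropic voxel sizes are rejected rather than
  silently averaged.
* Empty masks are errors for losses (undefined mean) but empty *predictions*
  merge to an all-zero, fully unmasked map.
* Tile enumeration is ascending (z, y, x) for determinism; voxel collisions
  in label projection average; duplicate tile indices error.

## Known limitations

* The network is CPU-bound R/C++ code: production-scale training (hundreds
  of entries, base 16, augmentation) takes hours, not minutes. The
  architecture and trainer are nonetheless complete — nothing is stubbed.
* Only proteins are modelled (no nucleic acids, ligands or membranes); the
  mass-weighted Gaussian density ignores electron scattering form factors
  and B-factors.
* Batch-norm statistics over the active region make the cropped regression
  network a slightly different (self-consistent) model from a full-box
  evaluation with spatially global statistics; all training and inference
  go through the same graph, so the distinction never mixes.
* The simulated-map threshold reads $\sigma$ as the standard deviation
  about the mean; r.m.s. about zero is the other defensible reading and
  differs only by the mean offset of the (mostly empty) map.
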