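---
title: "Personalized federated segmentation with frequency-domain aggregation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized federated segmentation with frequency-domain aggregation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Multi-organ segmentation models are usually trained on data pooled from a
single institution. Clinical sites cannot freely exchange images, and their
data differ systematically — in which organs are represented, in acquisition
protocol, in intensity characteristics. Federated learning (FL) lets K sites
train collaboratively by exchanging model parameters instead of images, but
the classic aggregation rule (FedAvg: the element-wise mean of all client
parameters) erases exactly the client-specific knowledge that makes a model
work well on its own site's distribution.

`freqfed` implements and simulates a *personalized* federated strategy for
2D segmentation with two ideas layered on a compact U-Net:

1. **A personalized/shared parameter partition.** The segmentation head
   (the final 1×1 convolution — pixel-wise it is a fully connected
   classifier over feature channels) and the batch-normalization *running
   statistics* (μ, σ²) stay on the client. The BN affine parameters (γ, β)
   and all convolution kernels form the shared representation that is
   communicated. The BN transform is the usual affine renormalization
   `BN(x) = γ·(x−μ)/sqrt(σ²+ε) + β` with ε fixed at 1e-5; evaluation always
   uses the client's own running statistics, which are never aggregated.

2. **Frequency-domain attention aggregation of the shared part.** At each
   round, every shared 4D kernel tensor (cout, cin, kH, kW) is permuted to
   (cin, kH, kW, cout) and flattened to an (cin·kH) × (kW·cout) matrix, and
   transformed with a centered 2D FFT. A rectangular mask keeps the
   coefficients with |u| ≤ r·H/2 and |v| ≤ r·W/2; these *low-frequency*
   components — the coarse, generalizable structure of the weights — are
   pooled across clients, while each client keeps its own high-frequency
   residue. The pooled spectrum plus the client's high part is inverted
   back to a weight tensor.

The pooling itself uses a reciprocal self-attention: with the clients'
masked low-frequency coefficients (real and imaginary parts concatenated)
as rows of `Z`, the attention matrix is the row-wise softmax of the
element-wise reciprocal of the Gram matrix `Z Zᵀ`. Taking the reciprocal
*before* the softmax inverts the usual similarity weighting: a client whose
low-frequency components align strongly with the others contributes a large
Gram entry, hence a small reciprocal, hence a small weight — so the scheme
upweights dissimilar, slow-converging clients rather than letting the
majority dominate. The attended rows are then averaged over clients, so
every client receives the same pooled low-frequency vector. Row sums of the
attention matrix are 1 by construction and all entries are strictly
positive.

The threshold r follows a linear schedule `r(t) = r0 + (r1−r0)·t/T` with
defaults r0 = 0 and r1 = 0.5: early rounds share only the coarsest weight
structure, later rounds progressively more. A fixed-r mode (default 0.25)
is also available.

# Strategy presets

The same training loop dispatches all baselines through two orthogonal
knobs, the parameter partition and the aggregation rule:

| strategy     | partition (personalized)                | aggregation            |
|--------------|------------------------------------------|------------------------|
| `paf_fed`    | head + BN statistics                     | FFT, reciprocal attention |
| `pf_fed`     | head + BN statistics                     | FFT, uniform weights   |
| `fedavg_fft` | nothing                                  | FFT, uniform weights   |
| `fedavg`     | nothing                                  | element-wise mean      |
| `fedbn`      | all BN tensors (γ, β, μ, σ²)             | element-wise mean      |
| `silobn`     | BN statistics (μ, σ²) only               | element-wise mean      |
| `fedrep`     | head only                                | element-wise mean      |
| `local`      | everything                               | none                   |

With r = 1 and uniform attention the spectral path reduces exactly (up to
FFT round-off, < 1e-10) to FedAvg — a limit the test suite checks — and
with K = 1 every strategy degenerates to local training.

# Numerical and design choices

Several points are fixed here because the method definition leaves them
open; each is recorded with its rationale.

* **Reshape convention.** The 2D matrix form of a kernel tensor is
  (cin·kH) × (kW·out) after permuting to (cin, kH, kW, cout), row-major.
  Any fixed invertible reshape works — the spectrum just needs a consistent
  2D geometry — and the shape record stored alongside makes the inversion
  exact to the bit.
* **Mask geometry.** The low/high split is an axis-aligned rectangle in
  centered integer coordinates: deterministic, symmetric under coordinate
  negation for r < 1 (so pooled spectra stay Hermitian and invert to real
  tensors), monotone in r, and always containing the DC coefficient. A
  radial mask would serve equally; the rectangle makes the r = 1 limit
  exact for both axes regardless of aspect ratio.
* **Complex embedding for the attention.** The Gram matrix is computed on
  the concatenation of real and imaginary parts of the masked coefficients,
  which equals the real part of the complex inner product; the softmax then
  acts on ordinary real numbers. Entries of the Gram matrix with magnitude
  below 1e-8 are replaced by ±1e-8 (sign preserved, sign(0) = +1) before
  the reciprocal, so near-orthogonal clients cannot blow up the weights.
  No 1/sqrt(d) temperature is applied — the weighting follows the printed
  formulation without it.
* **Vectors average plainly.** Biases and BN affine vectors are 1D; a
  spatial frequency decomposition of a per-channel scalar list is not
  meaningful, so tensors with fewer than two axes are pooled by the
  element-wise mean. 2D matrices (if an architecture had dense layers) go
  through the FFT directly.
* **Aggregation arithmetic** is double precision throughout, and the
  imaginary residue after inversion is checked against 1e-8 — a violation
  can only mean a broken mask symmetry, and is raised as an error rather
  than silently discarded.
* **U-Net variant.** Downsampling is 2×2 max pooling, upsampling is
  nearest-neighbour followed by a 3×3 convolution, with BN after every
  convolution and a 1×1 head. Weight init is fan-in-scaled Gaussian with an
  explicit seed (the networks here are trained from scratch; pretrained
  encoders are out of scope). The architecture has no dense layers, so
  "fully connected prediction layers" maps to the 1×1 head: a 1×1
  convolution is exactly a pixel-wise fully connected layer.
* **Optimizer.** Adam with client-local state that persists across
  communication rounds (re-initializing it every round would discard the
  moment estimates right when the merged weights change most). Full-scale
  defaults are lr 1e-4 and batch 16; the desk-scale experiments in this
  package use lr 1e-3 and batch 4, the customary regime for a
  ~30k-parameter network trained for a few hundred steps.
* **Loss.** The training loss couples pixel-averaged cross-entropy with a
  negated soft-Dice term summed over all classes (background included),
  `−(2/|C|)·Σ_j (Σ_i O_ij G_ij)/(Σ_i O_ij + Σ_i G_ij)`. The inner ratio
  carries no factor 2 — the 2 sits outside in 2/|C| — so the minimum is −1,
  attained at the exact one-hot truth when every class is present.
  Probabilities are clamped to [1e-7, 1] before the logarithm and the Dice
  denominator carries a 1e-6 smoothing term against empty classes.
* **Metrics.** Evaluation reports the Dice similarity coefficient
  2TP/(2TP+FP+FN) and the average symmetric surface distance in mm, per
  client and per foreground class. Boundaries are 4-connected mask pixels
  with at least one neighbour outside (the image border counts as outside).
  A metric is *undefined* — not zero — when a class is absent from both
  maps (DSC) or a boundary set is empty (ASSD); undefined entries are
  excluded from averages and their counts surfaced in the report.
* **Client scheduling.** All K clients participate in every round,
  sequentially in id order; since the pooled low-frequency vector is
  invariant under client permutation (tested), the execution order cannot
  influence the server aggregate. Each client owns an RNG stream seeded
  `base_seed + id`, so shuffling and augmentation are reproducible and
  independent of the other clients.

* **What is evaluated.** The federation's output is each client's
  personalized model *after its final local update*; the last server
  aggregate is returned separately (`final_shared`) as the starting point
  of a continuing federation. Merging a fresh aggregate into a client
  right before evaluation would pair shared weights the client has never
  trained with BN running statistics and a head adapted to the previous
  weights — a mismatch that systematically penalizes exactly the
  personalized strategies, and corresponds to deploying a model the site
  never saw. All strategies are scored the same way.

# The synthetic phantom generator

Real multi-site abdominal data cannot ship with a package, so the study
conditions are emulated with a controllable generator. Each client draws
2D images containing up to C−1 elliptical "organs" on a dark background;
each class has its own intensity band (means 0.45/0.65/0.85 against a 0.15
background, sd ≈ 0.03), Gaussian pixel noise (sd 0.03), and occasionally a
bright corner blob that is *not* labelled — an acquisition-artifact
distractor. Organ placement resolves overlaps by z-order (the later class
wins), giving adjacent-organ boundaries. Splits are tagged 8:1:1
(floor(n/10) each for validation and test, remainder to training).

A single `heterogeneity` knob in [0, 1] interpolates two kinds of
inter-client shift simultaneously, with label skew deliberately dominant.
*Label-ratio skew*: each client favours one organ class, whose appearance
probability rises toward ~0.95 while the other classes become nearly
absent (toward ~0.05 per image) — the per-site category imbalance regime in
which local-only training cannot learn the rare classes but a federation
can. *Intensity shift*: a client-specific brightness offset up to ±0.05
with mild contrast jitter, the scale of scanner-to-scanner variation
within one modality (a multi-modality federation would need a far larger
shift, which plain weight averaging does not survive). At heterogeneity 0
all clients share one profile. The default experiments use heterogeneity
0.8, four clients and 120 images of 32×32 per client, so a non-favoured
organ appears in roughly 9% of a client's images.

What the phantom *does not* model: anatomy-correlated organ positions, MRI
physics (bias fields, partial-volume effects), 3D structure, and
registration artifacts. Tests passing on phantoms therefore demonstrate the
*mechanics* of the method — partition correctness, spectral aggregation,
convergence behaviour under controlled non-IID conditions — not clinical
performance.

# Scale of the bundled experiments

The package's experiments are deliberately desk-scale so that a full
strategy comparison is a coffee-break computation: 4 clients × 120 images
of 32×32, a depth-2 U-Net of base width 8 (~30k parameters), 10
communication rounds of 2 local epochs, batch 4, lr 1e-3. Full-scale
defaults (batch 16, lr 1e-4, T = 100, E = 5) remain the documented
defaults of `round_config()`.

An honest caveat about what desk scale can and cannot show. The
full-scale setting in which partial sharing demonstrably pays off
fine-tunes a *pretrained* backbone for hundreds of local epochs, so the
clients' weights stay mutually aligned and averaging pools knowledge.
Training this package's small network from scratch for 10 rounds of 2
epochs leaves every client mid-learning-curve in fast-moving,
permutation-unaligned weight space; in that regime the measured
differences between strategies (local, FedAvg, the partitioned and
frequency-domain variants) are of the same order as the run-to-run
realization noise, and their ordering can change with the seed. The test
suite therefore verifies the *mechanics* exhaustively — the FedAvg limit
of the spectral path, the no-op limits, permutation equivariance,
bit-exact personalization conservation — and runs the strategy
comparison with its results reported as measured; a directional
federation-beats-local gate at a fixed seed is included but is known to
be noise-dominated at this scale. Pretrained initialization, which would
recover the full-scale regime, is deliberately out of scope.

# Known limitations

* Sequential simulation of parallel clients; no networking, stragglers,
  partial participation, privacy accounting or secure aggregation.
* The attention is computed independently per weight tensor; a global
  (whole-model) attention variant is not implemented.
* The hand-written network supports the architecture family described here
  (2D, BN, max-pool/nearest-upsample U-Nets); it is a compact reference
  implementation, not a general autograd system.
* ASSD is 2D surface distance on slices; volumetric metrics are out of
  scope.
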