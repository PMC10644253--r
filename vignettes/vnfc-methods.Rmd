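---
title: "Virtual-node functional-connectivity graphs for EEG person identification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-node functional-connectivity graphs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An EEG functional-connectivity (FC) network — the matrix of statistical
dependencies between electrode signals — is highly individual, which makes it
usable as a biometric: given a short window of multi-channel EEG, identify
which person produced it. Plain FC networks ignore *where* electrodes sit on
the scalp, yet volume conduction makes spatially adjacent channels similar,
so spatial structure carries information. `vnfc` implements an identification
pipeline whose core idea is to fuse spatial structure into the FC graph by
adding *virtual nodes*, and to classify the resulting graphs with a small
graph convolutional network (the VN-GCN model).

## Pipeline

1. **Windowing.** Recordings are cut into 1-s windows with 50% overlap
   (`sliding_windows()`); each window is one classification sample tagged
   with its subject. No preprocessing is applied by default (a band-pass
   hook, `bandpass()`, exists but is off): the pipeline is designed to work
   on raw signals.
2. **Connectivity.** Per window, each channel's instantaneous phase is the
   angle of its analytic signal (FFT-based discrete Hilbert transform,
   after demeaning; `instantaneous_phase()`). The phase-locking value
   between channels x and y is
   `PLV = | (1/T) * sum_t exp(i (phi_x(t) - phi_y(t))) |`,
   giving a symmetric n-by-n matrix in [0, 1] with unit diagonal
   (`plv_matrix()`). Weak edges are pruned (`sparsify()`): by default the
   strongest 20% of the n(n-1)/2 pairs are kept. The cutoff is a
   configuration value, never hidden: it is logged in every manifest.
3. **Virtual-node augmentation.** The 64 electrodes of the 10-10 montage are
   divided into 8 spatially contiguous groups of 8 (`assign_groups()`). Each
   group gets a *local virtual node* connected to exactly its members, and a
   single *global virtual node* connects to all local ones
   (`build_augmented_graph()`), yielding a 73-node weighted graph whose
   real-real block is the sparse PLV matrix. Node features carry no signal:
   X is an all-ones 73-by-32 matrix, so the classifier sees only connection
   patterns.
4. **Graph convolution.** With `A~ = A + I` and degree `d~_i = sum_j A~_ij`,
   the propagation operator is `S = D~^(-1/2) A~ D~^(-1/2)`
   (`renormalized_operator()`); each layer computes
   `X' = sigma(S X W + b)` with a per-node, per-feature bias matrix `b`
   (m-by-out). VN-GCN stacks two such layers (widths 32 and 8), flattens the
   73-by-8 output to 584, and maps through a dense layer and softmax to the
   subject labels; training minimizes categorical cross-entropy
   (`build_model()`, `train_model()`).
5. **Experiments.** `run_cv()` runs subject-stratified k-fold
   cross-validation (default 5); `run_channel_reduction()` and
   `run_region_removal()` re-run it under electrode ablations.

Two baselines share the training head: `tinas_gcn`, the same GCN on the
plain 64-node PLV graph (flatten 512), and `cnn_fc`, a small CNN that
consumes the 64-by-64 sparse PLV matrix as an image (2x2 convolution to 32
maps, 2x2 max-pool, 2x2 *depthwise* convolution, 2x2 max-pool, flatten
7,200, dense). Parameter counts are exact and desk-checkable:
`parameter_table()` reproduces 68.0 k (VN-GCN), 59.8 k (plain GCN) and
785.2 k (CNN) under these conventions.

## Conventions that the parameter arithmetic pins down

Three architectural details are underdetermined by shape tables alone; the
package adopts the unique readings that make the per-layer counts come out,
and ships the arithmetic as tests:

* **Bias shape.** A graph-convolution bias must be per-node and per-feature
  (m-by-out): with 32 input features, graph-conv-I then costs
  `32*32 + m*32` (3,360 at m = 73 -> "3.4 k"; 3,072 at m = 64 -> "3.1 k"),
  and graph-conv-II `32*8 + m*8` (840 / 768). A per-feature-only bias cannot
  reproduce those numbers.
* **Node-feature dimension.** N = 32 is the only value consistent with the
  graph-conv-I counts above; it is the package default
  (`make_node_features()`).
* **Depthwise second convolution.** The CNN's second convolution costs 160
  parameters, achievable for 32-map input only as a channel-wise 2x2 kernel
  (`2*2*32 + 32`); a full 2x2x32x32 convolution would cost 4,128. The
  depthwise reading is implemented and flagged here deliberately.

The model manifest (`model_manifest()`) records one deliberate shape
correction: a 63 x 32 first-layer output sometimes quoted for this
architecture is inconsistent with both the 73-node graph and the flatten
length 584 = 73*8; the package uses 73 x 32 and says so in the manifest
rather than silently fixing it.

## Numerical and optimization choices

* **Activation.** Hidden layers use leaky ReLU with slope 0.01. This is a
  deliberate deviation from plain ReLU: every layer input in this
  architecture is non-negative (PLV weights, degrees, previous
  activations), so a unit whose weights drift negative under plain ReLU is
  dead for *all* samples simultaneously and can never recover. In
  development this killed entire layers early in training (a cross-validation
  fold stuck at chance accuracy); the leaky slope removes the failure mode
  while changing nothing else measurable.
* **Initialization.** Glorot-uniform weights, zero biases, seeded; training
  uses Adam (lr 1e-3), batch size 64, categorical cross-entropy, 100 epochs
  by default. All seeds fan out from one run seed via a fixed derivation
  (`derive_seed()`), so every stage is independently reproducible and two
  runs with the same configuration produce byte-identical manifests.
* **Sparsification ties.** "Keep values larger than the threshold" is read
  strictly (`>`); the density rule keeps exactly the top
  `round(q * n(n-1)/2)` pairs with ties broken by pair order, so the
  surviving edge count is deterministic.
* **Diagonal.** The PLV diagonal is 1 by definition but excluded from
  sparsification and from the graph's real-real block; self-loops enter only
  through the renormalization's `A + I`.
* **Degenerate inputs.** Constant channels have undefined phase and raise an
  error naming the channel; recordings shorter than one window, empty
  layouts, single-class training sets and non-finite losses all fail fast
  with diagnostics rather than propagating.

## The synthetic cohort generator

There is no public ground truth for "which coupling produced this EEG", so
the package ships a generator whose ground truth is explicit
(`simulate_cohort()`). Each subject is a sparse symmetric coupling matrix
(the identity fingerprint); each channel is a Kuramoto-style phase
oscillator:

    theta_i(t+dt) = theta_i(t) + 2*pi*f_i*dt
                    + g * sum_j K_ij * sin(theta_j - theta_i) * dt
                    + sigma_phi * sqrt(dt) * eps

with signal `sin(theta_i)`, optional Gaussian spatial mixing across the
montage (a volume-conduction surrogate) and white sensor noise. PLV is
precisely the order parameter of this process: coupled pairs lock, uncoupled
pairs decay to the finite-window null level `~sqrt(pi)/(2*sqrt(T))`.

Defaults (chosen once, before the end-to-end gates were wired, against the
generator's own recovery criteria): 64 channels at 160 Hz, base frequency
10 +/- 1 Hz (alpha band), coupling density 0.05, strength 0.7, coupling gain
5 rad/s, phase noise 2.5 rad/sqrt(s), sensor noise 0.3, smoothing width
0.08. The gain/noise balance matters: with strong gain or dense coupling,
locking percolates through the coupling graph and the whole montage
synchronizes, which destroys pair specificity (recovery correlation between
estimated PLV and true coupling drops from ~0.6 to ~0.04). The chosen regime
keeps directly coupled pairs visibly locked while indirect locking stays
partial.

What the generator does *not* emulate: 1/f spectra, artifacts (blinks,
EMG), nonstationary coupling, realistic head geometry. Passing the synthetic
gates therefore shows that the pipeline recovers planted connectivity
structure under noise — not that it reaches any particular accuracy on real
recordings.

### Known leakage modes, made explicit

* With the default per-window fold split, windows from the same recording
  appear in both train and test folds. This mirrors the common protocol for
  this task, but it is leakage-prone; `run_cv(split_by = "block")` holds out
  contiguous time blocks instead, and both modes are first-class.
* Each simulated recording draws its channel frequencies at random, so a
  recording has a channel-frequency fingerprint visible in PLV even without
  coupling. With one run per subject this fingerprint is itself
  subject-discriminative. The planted-signal ablation tests therefore use
  `shared_freqs = TRUE` (one frequency vector for the whole cohort) and
  `smoothing = 0`, so that *only* the planted coupling distinguishes
  subjects.

## Study sizes used by the tests and the acceptance script

The default evaluation cohort is 10 subjects, 3 runs of 60 s each at 160 Hz
(3,570 windows of 1 s); VN-GCN 5-fold CV on it is the package's headline
stochastic check (observed ~0.93 mean accuracy, shuffled-label control at
~0.10 chance). The ablation sanity checks use smaller planted cohorts (5
subjects, 24-30 s) with 3 folds and fewer epochs: these sizes give stable
directional results while keeping the full suite comfortably re-runnable.

## Ablation protocols

* **Uniform channel reduction** (`reduce_channels()`): layouts for
  56/48/40/32/24/16 channels come from a deterministic farthest-point
  ordering of the montage coordinates, frozen into a shipped JSON file. The
  layouts are nested (16 c 24 c ... c 56) and are a documented
  reconstruction of "uniform thinning" — the original retained sets were
  published only graphically.
* **Region removal** (`remove_region()`): the five scalp regions are defined
  by label prefix, with boundary prefixes (FC, CP, PO, FT, TP) belonging to
  both neighbouring regions, so regions overlap and cover all 64 channels;
  frontal is the largest (26 channels). Masks ship as an editable JSON file.
* Under any ablation, the PLV block is sliced to the kept channels, groups
  are restricted, and a group left empty loses its local virtual node
  (`subgraph_for_layout()`), keeping the augmented graph connected.

## Limitations

* Virtual nodes integrate electrodes only within a group; two adjacent
  electrodes in different groups are not directly linked by the spatial
  scaffold. This is inherent to the construction.
* The group memberships and reduction layouts are reconstructions from
  stated principles (angular sectors; uniform thinning), not published
  electrode lists.
* Real-data reproduction (PhysioNet motor imagery, 109 subjects; UCI KDD)
  requires multi-gigabyte downloads and long training; the EDF path
  (`read_edf()`) and the experiment harness are wired for it, but no real
  accuracy figure is asserted anywhere in the package.
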