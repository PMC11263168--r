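---
title: "Methods: swarm-optimised Otsu segmentation, texture fusion and DBN classification"
author: "adseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swarm-optimised Otsu segmentation, texture fusion and DBN classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`adseg` implements a four-stage analysis chain for 2-D 8-bit grayscale
brain MRI slices: threshold segmentation of the bright region of interest,
texture description of that region, feature-level fusion, and neural
classification. This vignette documents the models, the numerical choices,
and the design decisions that were genuinely open, in enough detail that a
reader can judge what the package's passing tests do and do not establish.

## Otsu thresholding and the within-class variance

A gray-level histogram $d_i$, $i = 0,\dots,255$, is split at a candidate
threshold $t$ into background $[0..t]$ and foreground $[t+1..255]$. With
class weights $w_b(t), w_f(t)$ (pixel counts normalised by the total),
class means $\mu_b, \mu_f$ and class variances $\sigma_b^2, \sigma_f^2$,
the within-class variance

$$\sigma_w^2(t) = w_b(t)\,\sigma_b^2(t) + w_f(t)\,\sigma_f^2(t)$$

is minimised over $t \in [0, 254]$. Minimising $\sigma_w^2$ is equivalent
to maximising the between-class variance because the two add up to the
total histogram variance at every $t$; the test suite checks this
decomposition to $10^{-9}$ relative tolerance. Numerical choices:

* The printed region definitions overlap at $t$; we use the standard
  half-open convention (background $\le t$, foreground $> t$).
* Empty classes get weight, mean and variance 0 rather than `NaN`, so the
  objective is finite on the whole threshold range — a requirement for any
  stochastic search over it.
* Weights are normalised by the pixel count so $\sigma_w^2$ is a variance
  in squared gray levels, comparable across image sizes; the argmin is
  unaffected.
* The exhaustive sweep breaks ties towards the smallest threshold, making
  it deterministic and testable.
* Label 1 (foreground) is the *brighter* region: `apply_threshold` sets
  pixels strictly above $t$ to 1.

## The Tunicate Swarm Algorithm

The swarm search treats the threshold as a continuous position in
$[0, 254]$; the Otsu objective wrapper rounds to the nearest integer
before evaluating, keeping the optimiser generic. Per agent and step, with
control constants $c_1 = 0.7$, $c_2 = 0.3$, $c_3 = 0.5$:

* water-flow advection $F = c_1 f_0$ with $f_0 \sim U(0,1)$;
* gravity balance $G = c_2 + c_3 - F$;
* social force $U = O_{\min} + c_1 (O_{\max} - O_{\min})$ with
  $O_{\min} = 1$, $O_{\max} = 4$, and $A = G / U$;
* food distance $OD = |X_{best} - r\,X|$ with $r \sim U(0,1)$;
* jet propulsion moves to $X_{best} \pm A \cdot OD$ (sign by
  $r \gtrless 0.5$);
* swarming averages with the neighbouring agent,
  $X_i \leftarrow (X_{i-1} + X_i^{jet}) / (2 + c_1)$.

Three wiring decisions were open and were settled by measurement before
freezing the tests:

1. **Neighbour chaining.** The swarm average uses the *previous agent's
   already-updated* position (agent 1 keeps its jet-propulsion move), the
   per-agent loop of the algorithm's source literature. Averaging each
   agent with its own previous position instead collapses the population:
   the $(2+c_1)$ divisor contracts positions towards the origin, and the
   measured agreement with the exhaustive Otsu sweep drops from ~95–99%
   to ~30%.
2. **Immediate best update.** The best-so-far is updated after every agent
   evaluation, so later agents in a sweep exploit earlier improvements.
3. **Known origin bias.** Even with neighbour chaining, the $(2+c_1)$
   average biases the population towards small positions — a documented
   pathology of this metaheuristic. Consequences we measured and state
   rather than hide: on a smooth quadratic the swarm reliably localises
   the optimum to within one gray level but *not* to arbitrary precision
   (median error ~0.16 with the fixed constants), and with fixed
   $c_1, c_2, c_3$ a pure random search of equal budget is more precise.
   With `randomize_c = TRUE` (the fully stochastic original algorithm) the
   swarm beats random search, and that is the configuration under which
   the package asserts the superiority property.

Out-of-bounds moves are clamped to the boundary; termination is the fixed
100-iteration budget; the whole run is reproducible from one seed.

The agreement between `otsu_tsa` and `otsu_exhaustive` is well-posed only
when $\sigma_w^2$ has a strict minimum. Histograms whose modes are far
apart have *empty* valley bins and therefore exact plateaus of
$\sigma_w^2$; any plateau point is an equally correct answer, but only
the sweep's tie-break returns the smallest one. The bimodal histogram
generator (`simulate_bimodal_histogram`) therefore draws overlapping
mixtures (means $U(60,100)$ and $U(140,190)$, SDs $U(15,30)$, 32768
pixels) whose valley stays populated — as in real MRI, where
partial-volume pixels fill the space between tissue modes. Under these
conditions the swarm matches the sweep within ±1 gray level in about
91–99 of 100 histograms depending on the ensemble seed. On the default
phantoms (whose valley is nearly empty) thresholds can differ by tens of
gray levels while the masks agree to Dice ≥ 0.999 — there the package
asserts mask equivalence, the scientifically meaningful property.

## Texture descriptors

**LBP.** The radius-1, 8-neighbour local binary pattern code is
$\sum_p s(g_p - g_c)\,2^p$ with $s(x) = 1$ iff $x \ge 0$; a neighbour
equal to the centre sets its bit, so constant regions code to 255. Bit
$p = 0$ is the East neighbour, proceeding counter-clockwise — any fixed
convention works; this one is shared with the directional masks and
tested.

**LDPv.** The eight directional responses at a pixel are the absolute
responses of the Kirsch compass masks (the canonical choice in the local
directional pattern literature; the arc of three $+5$ coefficients against
five $-3$s sums to zero, giving gray-shift invariance). The code sets the
bits of the $k = 3$ most prominent directions (ties towards the lower
index), so exactly $\binom{8}{3} = 56$ codes are attainable, and each
pixel contributes the *variance* of its eight responses to its code's
histogram bin — edge-rich neighbourhoods weigh more than flat ones.

Both descriptors skip the one-pixel border (no padding), are computed
block-wise on a near-equal 4×4 grid of the interior, L1-normalised per
block, and concatenated LBP-first into one 4992-dimensional vector
(16·256 + 16·56). The published feature counts are dataset-dependent
artefacts of an unstated block scheme and are deliberately not reproduced;
the grid is exposed instead. Features are extracted from the segmented
image with background zeroed, so the descriptor sees the region of
interest only.

## The deep belief network

The classifier is a stack of Bernoulli restricted Boltzmann machines with
published sizes $[8, 6]$, greedily pretrained by single-step contrastive
divergence (CD-1) on min-max scaled features, topped by a softmax layer
(initialised to zeros) and fine-tuned end to end by backpropagation on the
multinomial cross-entropy. Published training settings are used
throughout: 10 CD epochs per layer, 100 fine-tuning epochs, batch size
100, learning rate 0.01, zero momentum, sigmoid activations. The "linear
regression" top layer of the source description cannot produce 3–4-class
decisions; softmax is the faithful multinomial generalisation.

Three details are unstated in the source and were fixed by measurement
once, then frozen:

* **Initialisation.** Weights are Glorot-style for sigmoid units,
  $W \sim U(\pm 4\sqrt{6/(n_v + n_h)})$. With the common small-normal
  init ($\sigma = 0.01$) each layer attenuates the class signal by roughly
  two orders of magnitude, the $[8,6]$ stack passes ~$10^{-4}$ of it, and
  every gradient vanishes — training provably stalls at chance at any
  learning rate.
* **Centering.** Hidden biases are initialised to
  $-\bar{v}W$ (the RBM centering trick), so every unit starts at
  activation ½ for the mean input and stays responsive instead of
  saturating.
* **Gradient normalisation.** Fine-tuning accumulates gradients over each
  mini-batch (the classic delta-rule convention — the gradient of the
  batch-*summed* cross-entropy); CD uses the mean-normalised update. With
  mean-normalised fine-tuning the 200 updates available at desk scale
  (n = 200, batch 100, 100 epochs) cannot rotate the top layer onto the
  separating direction even when the hidden representation is perfectly
  linearly separable.

CD-1 treats real-valued $[0,1]$ features as Bernoulli probabilities
(never sampling the data vector), samples binary hidden states during the
positive phase, and uses mean-field probabilities for the reconstruction.
Inference is a deterministic mean-field forward pass, so prediction is
repeatable bit for bit. The deterministic CD-1 update equals the negative
gradient of the free-energy gap $F(v_0) - F(v_1)$ with the reconstruction
held fixed, which is what the finite-difference tests verify; backprop
gradients are verified against central differences of the summed
cross-entropy through the actual training step.

Mini-batches are drawn without replacement and reshuffled each epoch from
the run seed; the last short batch is kept; the batch size is clamped to
the dataset size. Whether fine-tuning should update the RBM weights or
only the top layer is unstated in the source; the full stack is updated,
matching the stated intent of optimising "the weights".

## The synthetic phantom cohort

Real sMRI cohorts sit behind access agreements, so every stage is
validated on seedable phantoms: a centred bright ellipse
(foreground mean 180) on a dark background (mean 40) with global Gaussian
noise (SD 10) — a learnable bimodal histogram by construction
(contrast ≥ 4 noise SDs) — whose interior carries class-dependent
texture: an oriented sinusoidal grating (period 5/12/19 px, orientation
0°/60°/120°, contrast 30) plus class-specific speckle (SD 4/11/18). The
ellipse is the exact ground-truth mask, so Jaccard/Dice/pixel-accuracy
scores are exact. All randomness derives from one master seed through
per-sample seeds recorded in the manifest, so any sample regenerates
byte for byte.

What the phantoms do *not* emulate: bias fields, partial-volume effects at
the region boundary, anatomical shape variability, 3-D context, and
scanner noise statistics. Passing the desk-scale pipeline (Dice ≥ 0.95,
held-out accuracy ≥ 90% on 150 phantoms) therefore demonstrates that the
implementation is correct and that the chain is discriminative when its
assumptions hold — it does not certify clinical performance on real
cohorts.

The classifier benchmark used in the tests draws two 100-dimensional
Gaussian clusters with a 5-SD mean separation per dimension (n = 200).
Under the alternative reading — total separation 5 SD spread over 100
dimensions — no classifier whose first layer is a random 100→8 projection
can exceed ~76% accuracy (the projection retains
$\sim 5\sqrt{8/100} \approx 1.4$ SD of separation), so the per-dimension
reading is the one under which the stated learning behaviour is
attainable at all.

## Problem sizes and determinism

The shipped validation uses 100 histograms of 32768 pixels for the
threshold-agreement study, 150 phantoms of 128×128 pixels (3 classes, 50
each, stratified 80/20 split) for the end-to-end study, and
10 seeds × 200 samples for the classifier benchmark. The train/test
protocol of the source experiments is unstated; a stratified 80/20 split
is this package's documented choice. Pipeline reports contain only
run-deterministic content (timings go to a separate log), so identical
configurations produce byte-identical reports — asserted in the tests.

## Known limitations

* Single global threshold per image; no multi-level Otsu, no spatial
  regularisation or morphological post-processing.
* The swarm optimiser inherits the origin bias of its published update
  and should not be expected to deliver sub-gray-level precision with the
  fixed control constants.
* Uniform/rotation-invariant LBP variants and multi-scale descriptors are
  out of scope.
* The DBN is CPU-only, CD-1 only, with Bernoulli visible units; no
  persistent CD, dropout or Gaussian visible units.
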