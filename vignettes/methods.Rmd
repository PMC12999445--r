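---
title: "Multi-agent patch-navigation diagnosis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-agent patch-navigation diagnosis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the decision process

`lesionnav` frames dermoscopic lesion classification as a sequential
inspection task rather than a single forward pass. Each episode works on one
224x224 RGB image. A *spatial agent* looks at one 64x64 patch at a time on a
stride-32 grid (6x6 = 36 half-overlapping windows) and can either move its
window (`up/down/left/right`) or commit to a diagnosis; a *temporal/text
agent* encodes a short textual descriptor of the lesion (and, for
longitudinal series, of each frame) and scores the K diagnoses only. With K
classes the joint action space has K + 4 actions: the four navigation
actions, scored by the spatial agent alone, and K classification actions,
scored by both.

Rewards are sparse and clinical: +1 for terminating with the correct class,
-1 for a wrong call, and -0.01 per navigation move so that inspection has a
small but nonzero cost. Returns are discounted with gamma = 0.99. An
immediately correct diagnosis therefore earns exactly 1.0, and every extra
move strictly lowers the attainable return.

## Value decomposition and the team decision

Each agent learns its own action-value function. Team values combine them
additively (Value Decomposition Networks): for class `c`,

    Q_tot(c) = Q1(class_c) + Q2(class_c)

while navigation team values are Q1's entries alone, because the temporal
agent has no navigation actions — the only consistent completion of the
additive scheme for asymmetric action spaces. Greedy play takes the argmax of
the K + 4 team values (ties resolve to the lowest action index, a documented
determinism rule); during training an epsilon-greedy wrapper explores
uniformly. Reported class probabilities are a temperature softmax of the
fused class values with tau = 1, which is shift-invariant and strictly
positive.

The additive rule is the default decision rule. Because the framework is
also described in terms of adaptive weighting, three alternative fusion
rules are available behind the same interface for ablations:

* `attention` — convex weights `alpha = softmax(u1.f + c1, u2.h + c2)` over
  the two agents, scored from their state summaries (spatial feature vector
  `f`, temporal hidden state `h`); the scorer is trained jointly.
* `concat-head` — a learned linear map of the concatenated class-value
  vectors, initialised at the 0.5/0.5 average.
* `fixed-average` — frozen 0.5/0.5 weights; algebraically half the VDN sum.

## Training: CTDE Q-learning

Training is centralized (one joint TD objective) with decentralized
execution (each agent acts from its own observation). Episodes are collected
epsilon-greedily, transitions `(s, a, r, s')` go to a bounded FIFO replay
buffer with uniform sampling, and after each episode the team takes Adam
gradient steps on

    L = mean( (y - Q_tot(s, a))^2 ),  y = r                    (terminal)
                                      y = r + gamma max Q_tot'  (otherwise)

where the bootstrap values `Q_tot'` come from frozen target copies of all
parameters, synced every 200 gradient steps. A plain max (no double-Q
correction) matches the printed target. Defaults, chosen to be standard and
consistent with the supervised baseline settings the framework is compared
against: replay capacity 10,000; batch 32; Adam lr 1e-4; epsilon linear from
1.0 to 0.05 over 60% of episodes; gamma 0.99; tau 1.

Two details are deliberate design choices where the procedure was
underdetermined:

* **Boundary moves clip.** An off-grid move leaves the position unchanged
  but still costs -0.01, keeping the action space state-independent.
* **Horizon.** After `t_max = 16` navigation steps the policy must classify
  (the argmax is restricted to class actions), so every episode ends within
  `t_max + 1` steps. Unbounded episodes would stall early training when the
  policy is near-uniform.

The temporal agent's text input does not change while the spatial agent
navigates, so its hidden state is computed once per episode and held fixed;
its class values still enter the fused decision at every step and its
weights still receive gradients through the classification transitions.

The start position is the grid index nearest the image centre (ties toward
the lower index — (2,2) on the 6x6 grid), reflecting that dermoscopy crops
centre the lesion. The positional embedding is the patch centre normalized
to the unit square, optionally expanded with first-order sine/cosine
features; it is concatenated to the backbone feature vector before the MLP
head, the minimal way to expose position to the value head.

A practical note on learned behaviour: with the -0.01 step penalty small
relative to the +/-1 terminal rewards, a fully trained policy often keeps
inspecting until the horizon forces the (correct) classification; accuracy
is unaffected, but trajectories are not minimal.

## The agents

**Spatial.** The default desk-scale backbone keeps the stated channel
progression 16/32/64 with global average pooling (feature dimension 64) but
realises each block as a stride-2 convolution after a 2x average-pool stem
rather than unit-stride convolution plus max-pool: identical interface and
capacity class, roughly 16x less compute, which keeps full training runs on
a single CPU core practical. A deeper `resnet50-style` option (residual
blocks, 2048 features after global average pooling) exists behind the same
interface for parity with the full-scale architecture; it is randomly
initialised — no pretrained weights are downloaded. The value head is a
two-layer MLP, hidden width 512, ReLU. Patches are ImageNet
channel-normalized (the standard published constants) at model input; raw
images are stored unnormalized. An optional supervised warm start
(`warm_start()`) regresses class values toward +/-1 targets on labelled
data, mirroring the two-stage option of pre-fine-tuning the backbone before
reinforcement learning.

**Temporal/text.** Token embeddings (dimension 32) feed a bidirectional
recurrent encoder — GRU by default, LSTM as a config option; both appear in
the framework's description and the discrepancy is surfaced here rather
than resolved — with 32 hidden units per direction (state dimension 64,
the concatenated final states of the two directions), then a linear head to
K class values. The recurrence is bidirectional as stated in prose even
though the compact recurrence notation is unidirectional. All layers,
including backpropagation through time, are implemented in the package; the
arithmetic is verified against finite differences in the test suite.

## The descriptor: a deterministic stand-in for the VLM

The full-scale system queries a prompt-based visual-language model for a
textual lesion description. This package substitutes a deterministic
rule-based descriptor over the ABCD-style cue axes (asymmetry, border
irregularity, colour heterogeneity, darkness): each cue whose feature
exceeds its threshold emits a fixed phrase ("asymmetric shape", "irregular
border", "multiple colors", "dark pigmentation"); a lesion below all
thresholds is exactly "regular lesion". The vocabulary (11 tokens including
a frame separator) is package-defined, since no output grammar is specified
for the VLM. This preserves the information pathway the temporal encoder
consumes while removing any network dependency. For generated images the
rules read the generator's ground-truth feature record; for images loaded
from disk they read measured statistics (mask-reflection asymmetry,
compactness, quantised-colour counts). A sequence is described frame by
frame with `<sep>` between frames; a single image is described once — the
package does not silently synthesise a pseudo-sequence at inference time,
keeping prediction a pure function of its input.

## The synthetic generator

The generator emulates the statistical structure of a two-class dermoscopy
problem, not its appearance. A lesion is an ellipse-like blob on a noisy
skin-toned background; its boundary is a radial profile with Fourier
harmonics (orders 2-6) for border irregularity plus a one-sided angular
lobe for asymmetry. A first-harmonic radial term alone is, to first order,
just a translation — which re-centring cancels — so the lobe is what makes
the measured mirror asymmetry respond to the asymmetry parameter. The
interior is divided into angular sectors carrying distinct pigment colours.
Malignant draws take strictly higher ranges than benign on every cue
(asymmetry 0.25-0.45 vs 0.0-0.06; border amplitude 0.10-0.20 vs 0.01-0.04;
3-5 vs 1-2 colours; darker palette), so the classes are separable by
construction and the reinforcement-learning task is learnable — a
*property of the benchmark*, verified by a linear probe in the tests.

Pseudo-sequences model slow malignant progression from a single timepoint:
three frames (t-2, t-1, t) with a per-step area growth factor drawn once
per sequence from 5-15% and a per-step darkening factor drawn once from
3-10% ("gradual" implies a consistent trend, hence once per sequence, not
per step). Growth acts on the mask pixel area — the natural measurable
reading — and the realised radial scale is found by bisection so the
*measured* inter-frame area ratio always lies inside [1.05, 1.15] despite
pixel discretisation; darkening is realised exactly by rescaling the
lesion-interior pixels to the target mean intensity. Background and texture
noise fields are a function of the lesion's noise seed only, so they are
identical across the frames of a sequence.

What the generator does **not** emulate: photorealistic texture, hair,
rulers, gel bubbles, vignetting, varying acquisition geometry, or ambiguous
intermediate lesions. Passing the test suite therefore demonstrates that
the algorithmic machinery is correct and can learn a separable visual task
end to end; it says nothing about accuracy on real dermoscopy, which
requires the real datasets and full-scale backbones outside this package's
scope.

## Evaluation protocol

Malignant is the positive class throughout. `evaluate_model()` rolls out
the greedy policy per test item and aggregates: confusion-matrix metrics
(zero-denominator metrics are returned as `NA`, not errors), a ROC curve by
threshold sweep with rank-average tie handling (so the trapezoidal AUC is
the concordance probability with half credit for ties; cross-checked
against an independent ROC implementation in the tests), and decision-curve
analysis with

    NB(t) = sens * prev - (1 - spec) * (1 - prev) * t / (1 - t)

over thresholds 0.01-0.30 (step 0.01) at an assumed screening prevalence of
0.20, against treat-all (`NB(1, 0, prev, t)`) and treat-none (0) references
— all overridable. Cross-validation uses stratified k-fold (per-class
shuffle + round-robin deal, so per-fold class counts deviate from exact
proportionality by at most one). Variant comparison uses one-way ANOVA
followed by Tukey HSD on per-fold metrics; both delegate to the standard
`stats` routines (`oneway.test`, `aov` + `TukeyHSD`) rather than
re-implementing classical inference.

## Numerical and reproducibility choices

* Every stochastic routine takes an explicit seed and restores the caller's
  RNG state; generator outputs are bit-identical across runs for equal
  seeds, and training logs are reproducible from the config seed.
* Argmax ties resolve to the lowest action index everywhere.
* The class-probability softmax subtracts the max value before
  exponentiation.
* The area bisection runs 40 halvings and targets the drawn ratio clipped
  to [1.0505, 1.1495], leaving headroom for the <=0.2% pixel-count residual.
* PNG round trips quantise to 8 bits (error < 1/255 per channel); manifests
  are the exchange format between the simulate/train/evaluate commands.

The test suite and the acceptance script run everything at desk scale: the
learning experiment uses 400 training and 200 held-out images, a 2-class
problem, the small backbone and 3,000 episodes — sizes chosen so a full
verification pass completes on one CPU core while still exercising every
stage (generation, description, navigation, fusion, replay, target sync,
evaluation) end to end.

## Known limitations

* The descriptor is nearly label-revealing on synthetic data (the cue
  thresholds sit between the class ranges), so the temporal agent alone can
  carry much of the synthetic task; the spatial pathway is exercised but
  not stressed. On real data the descriptor would be far noisier.
* Single-image inference does not use temporal evolution; only explicit
  sequences do.
* No prioritized replay, distributional heads, double-Q correction, or
  Transformer temporal encoder; no multi-lesion images or sub-grid patch
  positioning.
* The 4-agent clinical-metadata variant of the full-scale system is out of
  scope.
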