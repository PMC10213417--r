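---
title: "Neuromodulated plasticity as a learned online learning rule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuromodulated plasticity as a learned online learning rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metaspike)
```

# The model

`metaspike` trains spiking networks whose synapses learn *online* through
neuroscience-derived plasticity rules, while the parameters of those rules
are themselves optimized by gradient descent across episodes. Learning
therefore happens at two levels:

* **inner loop** — within one episode, the plastic weights $W$, the
  synaptic traces and the eligibility traces evolve under the plasticity
  dynamics; nothing else changes and nothing is reset mid-episode;
* **outer loop** — across episodes, every constant of those dynamics
  (collectively $\omega$: neuromodulatory network weights, readout weights,
  initial plastic weights, per-synapse STDP rates, trace and eligibility
  constants, and the image encoder for the character task) is updated by
  backpropagation through time (BPTT) on the episode's test loss.

## Neuron dynamics

All neurons are discrete-time current-based leaky integrate-and-fire (CUBA)
units. Each neuron keeps a current trace $u$ and a membrane potential $v$:

$$u_{t+1} = u_t - \alpha_u (u_t - u_{rest}) + \textstyle\sum_i W_i s_{i,t},
\qquad
v_{t+1} = v_t - \alpha_v (v_t - v_{rest}) + R\,u_t .$$

A spike is emitted when $v$ strictly exceeds $v_{th}$, after which $v$ is
hard-reset to $v_{rest}$. Two conventions are possible for which current
the voltage update consumes; the package defaults to the *pre-update* $u_t$
(the literal reading of the update equations) and exposes
`post_update_u = TRUE` in `neuron_params()` as a one-flag alternative. The
unit tests pin the default with hand-unrolled two-step examples.

The spike nonlinearity has a zero-almost-everywhere derivative, so the
backward pass substitutes a surrogate (`surrogate_config()`): by default a
SLAYER-style exponential $a\,e^{-s\,|v - v_{th}|}$, with a fast-sigmoid
alternative. Defaults are $s = 5$, $a = 0.5$ for the generic modules and
$a = 0.3$ in the study runs; smaller peak gains damp the growth of
products of recurrent Jacobians over hundreds of time steps, which we found
necessary for stable meta-gradients.

## Plasticity

Spike timing is summarised by exponentially decaying traces
(`trace_step()`): linear, $x_{t+1} = \alpha_x x_t + \beta s_t$, or
saturating with soft bound $x_{max}$. Retentions $\alpha_x$ (fast) and
$\alpha_\tau$ (slow, used by the triplet rule's second postsynaptic trace)
are exposed independently. Note one asymmetry with common notation: in this
package's update the leak constants of *neurons* are decay fractions
($\alpha_v = 0$ means no leak) while trace constants are retentions
($\alpha_x \to 1$ means slow decay); both conventions are stated on the
respective constructors.

Weight changes follow spike-timing-dependent plasticity
(`pair_stdp_delta()`, `triplet_stdp_delta()`):

$$\Delta W_{ji} = A^+_{ji}\, x^{pre}_i\, s^{post}_j
              - A^-_{ji}\, x^{post}_j\, s^{pre}_i,$$

with the triplet rule additionally scaling the LTP term by the slow
postsynaptic trace read one step earlier. $A^\pm$ implement the weight
dependence (`weight_dependence()`): additive (no dependence),
multiplicative (linear soft bounds), or the power-law interpolation with
exponent $\mu \in [0,1]$ whose endpoints reproduce the other two exactly.
Before fractional exponentiation the weights are clamped to
$[w_{min}, w_{max}]$ so excursions cannot produce complex values. Both
study tasks use the additive rule (pair for the cue task, triplet for the
character task), and the compiled training path implements the additive
rule; the other dependences are available through the R-level operators.

Traces are decayed-and-incremented *first*, then the STDP terms are
computed from the updated traces and the current spikes. This ordering
makes the two-spike protocol behave canonically: pre-then-post at lag 1
potentiates, post-then-pre depresses, and exact pre/post coincidence
cancels under equal rates. An independent brute-force oracle — summing the
geometric decay kernel over all spike pairs — matches the iterative
implementation to $10^{-10}$ in the tests.

## Three-factor application

STDP terms are not applied directly. Each step's LTP and LTD terms are
accumulated, as nonnegative magnitudes, into paired eligibility traces
(`accumulate_eligibility()`):

$$E^\pm_{t+1} = \gamma E^\pm_t + \alpha_e \circ \delta^\pm_t,$$

and realized as weight change only under a modulatory signal
(`apply_modulation()`):

$$W_{t+1} = W_t + M^+ \circ E^+_t - M^- \circ E^-_t.$$

Keeping the two pathways separate lets the modulator scale *and reverse*
potentiation and depression independently. $M^\pm$ broadcast by mode:
global scalar, per-postsynaptic neuron, a per-neuron response function
$h(b_j M)$ ($h$ identity by default, `tanh` selectable), or — the form used
by both study tasks — per-presynaptic input. With $M \equiv 0$ the weights
are bitwise constant over any horizon while traces and eligibilities keep
evolving; this gating is asserted exactly in the tests, not approximately.

## Architecture

The task network (DP-SNN) is feedforward: task inputs project through the
single plastic layer to 48 hidden CUBA neurons, and a fixed (outer-loop
trained) linear readout. The plastic layer is sparse — each synapse exists
with probability 0.5 — and every existing synapse has a fixed type drawn at
initialization (inhibitory with probability 0.2). Weights are stored as
magnitudes and the effective weight is $\max(W, 0) \cdot \text{sign} \cdot
\text{mask}$, so plasticity can never flip a synapse's type, masked
synapses stay exactly zero (weight, eligibility and gradient), and
inhibitory synapses always contribute nonpositive current.

The neuromodulatory network (NM-SNN) is non-plastic: two fully connected
layers of 64 CUBA neurons reading the sensory spikes, the DP-SNN hidden
spikes and (cue task only) the two-dimensional environment feedback. A
trainable linear head maps its second layer's spikes to $2 n_{in}$ values —
per-input LTP and LTD modulation — smoothed by a first-order low-pass
filter (retention $\lambda_m$, default 0.8) so the emitted signal is graded
rather than binary. Where the two 64-neuron layers end and the output
begins is not fixed by the architecture description we follow; we read both
layers as hidden and attach an explicit head.

For the character task a small convolutional encoder (3×3 conv 1→4
channels, per-image channel normalization, ReLU, 2×2 max-pool, 3×3 conv
4→4, normalization, ReLU, pool) flattens 28×28 grayscale images to 196
currents injected into 196 spiking input neurons. A 28×28 input with
same-padding is the unique simple setting producing the 196-dimensional
flattened output. The normalization computes statistics per image and
channel (over space), which keeps `encode_image()` a deterministic map of a
single image; with trainable scale and shift this differs from batch
statistics only in what the normalizer averages over, and it removes any
coupling between the images of an episode.

# Tasks

## One-shot cue association

`generate_cue_episode()` builds a T-maze episode: 20 sensory neurons in
four groups of five (right cues, left cues, decision period, noise), $M$
cue periods each activating one side's group at firing probability 0.75
against a 0.15 baseline, rest gaps, and a decision period with the decision
group active — 350 steps per trial at the study defaults ($M = 5$, 25/30/
50/25 ms periods, 1 ms steps). An episode permutes the 20 rows uniformly
(there are $20! \approx 2.4\times10^{18}$ permutations), presents one
right-majority and one left-majority training trial in random order — with
the feedback vector $(1,0)$ or $(0,1)$ active during their decision windows
— and one feedback-free test trial, 1050 steps in all. The outer loss is
two-term binary cross-entropy on a logistic of the summed decision-window
readout activity, computed on the test trial only. Side sequences draw
each cue's side uniformly and redraw ties (possible only for even $M$).

`mirror_cue_episode()` produces the side-swapped twin of an episode. The
task distribution is symmetric under the swap, so training on mirrored
pairs is unbiased and cancels the label-symmetric part of the gradient
noise exactly (antithetic variates), leaving the discriminative component.

## Sequential one-shot character recognition

`generate_char_episode()` presents one phase-1 image for 20 ms, then five
phase-2 images for 20 ms each (120 steps total); exactly one phase-2 image
is a *different exemplar* of the phase-1 class, in a uniformly random slot,
and the four distractors come from distinct other classes. Modulation is
allowed only during the phase-1 window, so all within-episode learning must
happen in those 20 steps; the weights are exactly frozen afterwards. The
answer is the phase-2 slot with the highest summed readout activity
(lowest index on ties), scored by a softmax cross-entropy.

`generate_glyph_corpus()` synthesises the many-class, few-sample character
corpus the protocol assumes: each class is a random composition of 2–5
quadratic-Bezier stroke primitives; exemplars re-render the prototype under
small affine jitter, stroke-width jitter and pixel noise; optional 90/180/
270-degree rotations register as distinct classes (1623 base classes would
yield 6492). Classes split 80/20 into train/test, so evaluation uses only
never-trained classes. What the generator reproduces about real
handwritten-character corpora: class structure from shared stroke geometry,
within-class variability smaller than between-class variability (asserted
in the tests), many classes with ~20 exemplars each. What it does not:
stroke-order statistics, writer-specific styles, or the long tail of
confusable character pairs — so passing results here demonstrate the
*learning mechanism*, not benchmark parity with any real corpus. An
adapter (`read_glyph_dir()`) can load a real image directory; nothing in
the package depends on it.

# Outer-loop training

`train_cue()` / `train_char()` draw a fresh episode batch each step
(fresh permutations or class draws), simulate the coupled system over every
whole episode, and apply one Adam update (learning rate $10^{-3}$–$3\times
10^{-3}$ in the study configurations, global-norm clip 1–5) to all of
$\omega$. Full-episode BPTT is used — no truncation — implemented in
compiled code as a reverse-mode tape over matrix operations with the
surrogate spike derivative as a custom backward rule. The tape is verified
against central finite differences on smooth sub-paths (frozen spike
rasters for the plasticity chain; sub-threshold trajectories for the neuron
dynamics) to $10^{-5}$ relative error; across the spike discontinuities
themselves the map $\omega \mapsto$ loss is piecewise constant and only the
surrogate provides a descent signal, which is the standard contract of
surrogate-gradient training.

Constrained constants travel in raw form and are mapped on the tape —
retentions ($\alpha_x$, $\alpha_\tau$, $\gamma$, $\lambda_m$) through a
logistic, rates ($\beta$, $\eta^\pm$, readout gain) through exp — so no
gradient step can leave the valid region. The per-synapse rates
$\eta^\pm_{ji}$ and accumulation rates $\alpha_{e,ji}$ are trainable
matrices initialized from shared scalars; trace and eligibility constants
are trainable by default (`freeze` can pin any subset).

One parameter is frozen deliberately: the readout gain. At the chance
plateau the loss is locally minimized by shrinking the gain toward zero,
and because every upstream meta-gradient is proportional to it, that
collapse would silence learning permanently. With the gain fixed the
calibration burden falls on the readout weights and bias, which do not
share this degeneracy.

# Desk-scale study runs and what they show

`scaled_char_study()` (200-class corpus, 300 outer updates of batch 32)
reliably learns the character task: held-out
error far below the 80% chance error, with the non-plastic control —
identical architecture, plasticity and modulation disabled, everything else
still trained — indistinguishable from chance. The learned solution is a
familiarity mechanism: potentiate during phase 1 the synapses of co-active
input-hidden pairs, so the matching phase-2 image, which re-activates a
similar input pattern, drives elevated readout activity. This mechanism is
consistent across episodes, which is why 300 updates suffice.

`scaled_cue_study()` ($M = 3$, shortened periods, slow current trace,
300 outer updates over antithetic pairs) runs the identical pipeline on the
cue task. Under this desk-scale budget the meta-optimization does *not*
reliably depart from chance, and the package reports that outcome rather
than a tuned substitute. The diagnostic experiments behind the
configuration are informative about why, and two of them are kept as tests:

* the *recall* pathway is expressive: if the plastic layer's columns are
  tagged by an idealized one-shot rule (potentiate the right-cue columns,
  depress the left-cue columns, magnitudes comparable to the initial
  weights), the decision-window population activity separates the test
  labels well above chance — provided the current-trace leak is slow
  ($\alpha_u \approx 0.05$) so cue-period drive persists across the
  pre-decision gap. This is asserted as a property test.
* the *tagging* step is the bottleneck: tags realized through the
  eligibility pathway by explicit feedback-conditioned modulation policies
  carry a per-episode signal well below their per-episode noise at these
  durations, because the label-asymmetric information enters only through
  the two feedback bits while every other feature of the episode is
  permutation-randomized.

The full-protocol configuration (`scripts/train_full_cue.R`; study
durations, $M = 5$, long training, many seeds) is provided for the
multi-hour reproduction attempts this package does not run routinely.

# Numerical choices and edge cases

* Ties in every argmax readout resolve to the lowest index,
  deterministically.
* Episode generation, initialization and evaluation consume the R RNG
  only; a `(seed, configuration)` pair reproduces a run bit-for-bit, and
  evaluation helpers restore the caller's RNG state.
* Non-finite membrane potentials abort the episode with a diagnostic
  rather than propagating NaNs through the tape.
* The power-law weight dependence clamps weights to the soft bounds before
  exponentiation; degenerate (near-blank) glyph prototypes are rejected and
  redrawn; even-$M$ side sequences redraw ties.
* Checkpoints (`save_checkpoint()`) serialize the full fit — $\omega$,
  topology, configurations, optimizer state, metrics — as RDS, the
  package's native single-file container.

# Known limitations

* The compiled training path implements the additive weight dependence the
  study tasks use; multiplicative and power-law dependences are available
  in the R operators but not meta-trainable.
* The DP-SNN is feedforward with one hidden layer by design; no recurrent
  hidden connectivity.
* The cue task's desk-scale meta-training does not reach its full-protocol
  performance (see above); the character task does demonstrate the full
  learned three-factor mechanism end to end.
* The glyph corpus is a synthetic stand-in; accuracies on it are not
  comparable to accuracies on real handwritten-character benchmarks.
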