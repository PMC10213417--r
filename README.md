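# metaspike

Learning to learn with neuromodulated synaptic plasticity in spiking neural
networks.

`metaspike` is for computational neuroscientists and neuromorphic-computing
researchers who want to train *online* learners whose within-task learning is
carried entirely by neuroscience-derived plasticity rules — not by gradient
descent — while gradient descent shapes the rules themselves. The package
provides the building blocks (discrete-time CUBA leaky integrate-and-fire
layers with surrogate spike gradients; pair- and triplet-based STDP with
additive, multiplicative and power-law weight dependence; eligibility traces;
three-factor neuromodulated weight application), the two-network system that
uses them (a plastic task network and a non-plastic neuromodulatory network
emitting per-input LTP/LTD signals), episode generators for two one-shot
learning tasks, and the bilevel training loop that optimizes everything by
backpropagation through time across whole episodes.

## The model in brief

Neurons integrate a current trace and a leaky membrane potential

```
u[t+1] = u[t] − αu (u[t] − u_rest) + Σ_i W_i s_i[t]
v[t+1] = v[t] − αv (v[t] − v_rest) + R u[t]
```

with hard reset on threshold crossing and a surrogate derivative for the
spike nonlinearity. Synapses keep activity traces
`x[t+1] = αx x[t] + β s[t]`, and spike-timing-dependent plasticity produces
paired potentiation/depression terms

```
ΔW_ji = A⁺_ji x_pre_i s_post_j − A⁻_ji x_post_j s_pre_i
```

(the triplet rule additionally scales LTP by a slow postsynaptic trace).
These terms accumulate into eligibility traces
`E±[t+1] = γ E±[t] + αe ∘ δ±[t]` and become weight change only under a
modulatory third factor:

```
W[t+1] = W[t] + M⁺ ∘ E⁺[t] − M⁻ ∘ E⁻[t]
```

The modulation `M±` is produced, per presynaptic input and per time step, by
a separate non-plastic spiking network. The outer loop treats every constant
above — modulatory network weights, readout weights, initial plastic
weights, per-synapse STDP rates, trace and eligibility constants — as
meta-parameters ω and optimizes them across episodes with full-episode BPTT;
within an episode, only the plastic weights, traces and eligibilities change.

Two tasks exercise the system: a permuted one-shot T-maze cue-association
task (20 sensory neurons in four groups of five, the roles freshly permuted
every episode, one labelled trial per side before a feedback-free test
trial), and a sequential one-shot character-recognition task (one phase-1
glyph, five phase-2 glyphs, modulation allowed only during phase 1, answer =
the phase-2 window with the highest readout activity) on a synthetic
many-class glyph corpus generated by the package.

## Worked example

One-shot recognition of never-trained glyph classes. Meta-training sees only
the training split of the corpus; every evaluation episode presents classes
from the held-out split, which the system must learn from the single phase-1
presentation via its plastic synapses:

```r
library(metaspike)

corpus <- generate_glyph_corpus(n_classes = 60, samples_per_class = 20,
                                seed = 5)
fit <- train_char(corpus, n_outer = 150, batch = 32, lr = 3e-3, clip = 1,
                  seed = 11)
fit
#> <metaspike_fit> char task, plastic, 150 outer steps
#>   DP-SNN: 196 -> 48 hidden (triplet STDP) -> 1 readout
#>   NM-SNN: 2 x 64 CUBA neurons, per-input LTP/LTD head
#>   final outer loss 0.2453, batch accuracy 0.97

evaluate_char(fit, corpus, split = "test", n_episodes = 300, seed = 99)
#> # A tibble: 1 × 7
#>       n correct accuracy ci_low ci_high error split
#>   <dbl>   <dbl>    <dbl>  <dbl>   <dbl> <dbl> <chr>
#> 1   300     243     0.81  0.761   0.853  0.19 test

np <- baseline_nonplastic("char", corpus = corpus, n_outer = 150,
                          batch = 32, lr = 3e-3, clip = 1, seed = 11)
evaluate_char(np, corpus, split = "test", n_episodes = 300, seed = 99)
#> # A tibble: 1 × 7
#>       n correct accuracy ci_low ci_high error split
#>   <dbl>   <dbl>    <dbl>  <dbl>   <dbl> <dbl> <chr>
#> 1   300      62    0.207  0.162   0.257 0.793 test
```

After 150 meta-updates the plastic system answers 81% of one-shot episodes
on never-trained classes correctly (chance is 20%), while the non-plastic
control — same architecture, readout and encoder still trained, but no
plasticity and no neuromodulation — stays exactly at chance: the plastic
pathway is the only within-episode learning channel. `tidy()` returns the
per-step training metrics, `autoplot()` the learning curve, and
`eval_m_sweep()` the cue-task generalization sweep over the number of cues.

The cue-association counterpart runs through `train_cue()` /
`scaled_cue_study()`; see the methods vignette
(`vignettes/metaspike-methods.Rmd`) for its model, the desk-scale
configurations, and an honest account of which task learns reliably at desk
scale and why.

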