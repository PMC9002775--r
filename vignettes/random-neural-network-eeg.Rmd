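---
title: "Seizure classification with the Gelenbe random neural network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure classification with the Gelenbe random neural network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegrnn)
```

## The model

The random neural network (RNN) of Gelenbe is a queueing-theoretic spiking
model. Neuron $l$ holds a nonnegative integer potential $k_l(t)$; it is
*excited* while $k_l > 0$. Excitatory spikes (+1) and inhibitory spikes
(−1, floored at zero potential) arrive as Poisson streams, both from other
neurons and from exogenous sources. An excited neuron fires at rate $r_l$,
and each emitted spike reaches neuron $j$ as excitatory with probability
$p^+_{l,j}$, as inhibitory with probability $p^-_{l,j}$, or leaves the
network with the departure probability $d(l)$, so that

$$\sum_j \left(p^+_{l,j} + p^-_{l,j}\right) + d(l) = 1 .$$

The weight rates $w^\pm_{l,j} = r_l\, p^\pm_{l,j} \ge 0$ play the role of
classical network weights, with the rate/weight identity
$r_l = (1-d(l))^{-1} \sum_j \big[w^+_{l,j} + w^-_{l,j}\big]$.
In steady state the probability that neuron $l$ is excited has the product
form
$$f_l \;=\; \frac{\lambda^+_l}{r_l + \lambda^-_l}, \qquad
\lambda^\pm_l \;=\; \sum_j f_j\, w^\pm_{j,l} \;+\; \Lambda^\pm_l ,$$
where $\Lambda^\pm_l$ are the exogenous arrival rates. The fixed point is
well defined while the network is *stable* ($f_l < 1$ for all $l$); the
solver caps activations at $1 - 10^{-9}$ and warns when a neuron is driven
past saturation, because outside the stable regime the product form no
longer describes the spiking process.

The classifier configuration is strictly feedforward, 76–100–80–4: 76
input neurons (one per feature), two hidden layers, and 4 output neurons,
one per class (normal, complex partial, electrographic, video-detected).
Departure probability is 1 on the output layer and 0 elsewhere. Because
each layer depends only on the previous one, the steady state is computed
exactly in a single topological pass; general (non-layered) networks fall
back to a damped fixed-point iteration (damping 0.5, tolerance $10^{-10}$,
at most 10 000 iterations).

Two modelling points are not fixed by the published equations and were
decided here:

* **Exogenous drive.** The internal arrival sums omit external terms; we
  add exogenous rates $\Lambda^\pm_l$, the standard device in the
  Gelenbe-RNN literature, and inject each normalized feature as the
  external excitatory rate of its input neuron, scaled by 0.9 so input
  activations stay below one.
* **Output firing rates.** Output neurons have no outgoing weights and
  $d = 1$, so the rate/weight identity degenerates to $0/0$ there; they
  receive a fixed firing rate $r_\text{out} = 1$, which simply sets the
  scale of the output activations $f = \lambda^+ / (1 + \lambda^-)$.

## Training

Training minimizes the mean over samples of
$\tfrac12\sum_c (f_c - y_c)^2$ against one-hot targets by full-batch
projected gradient descent: after each step, negative weight components are
clipped to zero and the firing rates are recomputed from the weights, so
the conservation identities hold after every update. The analytic gradient
is exact reverse-mode differentiation of the layered fixed point. A weight
$w^\pm_{i,j}$ influences the loss through three channels — the excitatory
numerator of neuron $j$, the inhibitory denominator of $j$, and the firing
rate $r_i$ of its *source* neuron, which is the sum of $i$'s outgoing
weights. The third channel is easy to forget; the test suite verifies the
full gradient against central differences (agreement is at the numerical
noise floor, far below the $10^{-4}$ relative bound asserted).

The source never states the RNN's training hyperparameters (only the CNN's
epochs and learning rate). The defaults here — learning rate 0.2, 300
epochs for the pipeline, uniform $[0, 1/\text{fan-out}]$ initialization
with a fixed seed — were chosen so that full-batch descent converges on
the synthetic task; at much smaller steps the optimizer can stall in a
regime where two classes with overlapping low-amplitude statistics remain
merged. Loss monotonicity is only guaranteed (and only asserted) for small
step sizes.

Prediction solves the steady state and returns the class of the maximal
output activation, breaking ties toward the lowest class index.

## The simulator as an independent oracle

`simulate_network()` runs the underlying continuous-time Markov chain
event by event (Gillespie): competing exponential clocks for exogenous
arrivals and for the firing of excited neurons, routing by the network's
probabilities. The time fraction each neuron spends excited must converge
to the analytic $f_l$ — a check that exercises a completely different code
path (integer potentials in C++, no fixed-point algebra). The first 10% of
events are discarded as burn-in since the chain starts empty, and the
measured span is split into 100 batches whose means yield a standard error
that honours the autocorrelation of the busy/idle process. Solver and
simulator are compared within three standard errors on random small
*stable* networks; saturated networks are excluded from this comparison
(the product form does not apply there), though the capped fixed-point
residual is still asserted on them.

## Features and normalization

Recordings are cut into contiguous non-overlapping 1-s windows (19
channels × 500 samples at 500 Hz; trailing partial windows dropped). From
each channel four statistics are taken: population standard deviation,
Fisher excess kurtosis, skewness, and mean — bias-uncorrected moment
ratios, with the convention that a constant channel scores 0 for all three
shape statistics. The feature vector is channel-major,
`[std, kurt, skew, mean]` per channel, 76 values; the ordering is part of
the model contract since trained weights depend on it. Min–max
normalization onto $[0,1]$ is fitted on the training split only; test
values outside the fitted range are clipped, and a feature constant in
training maps to 0. Cross-validation refits the normalizer inside every
fold.

Montage handling follows the 10–20 system; dropping the midline references
Cz and Pz from a 21-channel montage leaves the 19 channels the classifier
expects, and the dropper is a warning no-op on records that already lack
them.

## The synthetic generator

`generate_dataset()` produces seeded 4-class datasets with the exact
structure the pipeline assumes (19 × 500 one-second segments; default
counts 3895/3034/705/111, balancing normal against the three seizure
types combined). All classes share a stationary AR(2) background
(coefficients 0.5, −0.2; innovation SD 15 µV; per-channel gain uniform in
[0.8, 1.2]), and each seizure class adds one distinguishing component:

* class 1 — 3 Hz spike-wave discharges (150 µV biphasic transients),
  raising spread and kurtosis;
* class 2 — a sustained 7 Hz, 60 µV oscillation, raising spread with
  negative excess kurtosis (a sinusoid's is −1.5);
* class 3 — a slow baseline offset and drift (~60 µV), shifting the mean.

Because the classifier consumes only second-to-fourth moments, any
generative model separating the classes in those statistics is adequate;
effect sizes default to clearly separable so that pipeline tests measure
the correctness of the machinery rather than the difficulty of the task.
The generator does **not** emulate spatial dipole structure, inter-channel
correlation of real EEG, artifacts, or patient variability — passing the
synthetic recovery bound therefore demonstrates that the implementation
works end to end, not that the published real-data accuracies are
reproduced; those require the original recordings.

Problem sizes in the shipped tests (400 segments per class for the
recovery check, $10^6$ simulated events per oracle comparison, 50-network
residual sweeps) were chosen as the smallest sizes at which the checks are
statistically meaningful.

## Numerical choices and edge cases

* Activations capped at $1 - 10^{-9}$; a pinned neuron raises a warning
  (layered solver) or is reported after >10 pinned iterations (damped
  solver). Clipped activations contribute zero gradient.
* A neuron with zero total service rate ($r + \lambda^- + \Lambda^- = 0$)
  and positive excitatory drive is degenerate/unstable: an error, never a
  silent `Inf`.
* `firing_rates_from_weights` rejects $d = 1$ with outgoing weight
  (violates conservation) and returns rate 0 for terminal neurons.
* Tie-breaks in prediction go to the lowest class index; undefined metric
  ratios (zero denominators) are reported as 0 and flagged rather than
  `NaN`.
* The DCT pair uses the orthonormal type-II/type-III convention so the
  round trip is exact to $10^{-10}$; the raw unnormalized sums are also
  available since published formulas often omit the scaling constants.
* EDF I/O quantizes to 16-bit integers over a symmetric physical range
  padded by 0.1%; round trips are exact to one quantization step.

## Evaluation conventions

Per-class metrics are one-vs-rest from the 4×4 confusion matrix. The
report exposes both one-vs-rest accuracy and recall per class — published
per-class "accuracy" tables are ambiguous between the two — and overall
precision/recall/F1 are unweighted macro averages, with overall accuracy
the matrix trace over the total. The 90/10 split shuffles without
stratification (plain shuffling is what the source describes); k-fold
cross-validation offers optional stratification that keeps per-fold class
counts within one sample of balance.

## Limitations

Recurrent (non-feedforward) topologies are solvable here but not
trainable; multi-class RNN variants and reinforcement formulations are out
of scope, as is any claim about real-EEG performance. The trainable deep
baselines (CNN, ResNet) are represented by their exact shape/parameter
arithmetic and feature operators; fitting them requires an optional
deep-learning backend this package deliberately does not depend on.
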