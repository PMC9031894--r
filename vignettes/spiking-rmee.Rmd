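---
title: "Recurrent spiking networks under a restricted minimum-error-entropy criterion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent spiking networks under a restricted minimum-error-entropy criterion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikemee)
```

## The model

`spikemee` simulates and trains recurrent networks of three-compartment
spiking neurons. Each neuron has a somatic compartment and two point
dendrites, one excitatory and one inhibitory. All three compartments are
leaky integrators of their synaptic currents; the soma additionally receives
conductance-weighted drive from the dendrites,

$$\tau_m \dot U_m = -U_m + R_m I_m + g_i (U_i - \theta_i)
  + g_e (U_e - \theta_e) - \Gamma_j z_j,$$

with the dendrites following $\tau \dot U = -U + R I$. A spike is emitted
when $U_m$ reaches the adaptive threshold $\Gamma_j = \tau^0 + \alpha
\tau_j$; the deviation $\tau_j$ increments with every spike and relaxes with
the adaptation time constant $\tau_a$,
$\tau_j(t + \Delta t) = \beta_j \tau_j(t) + (1 - \beta_j) z_j(t)$ with
$\beta_j = e^{-\Delta t / \tau_a}$. With $\tau_a = 700$ ms this adaptation is
the network's long memory: the store-recall benchmark is solvable precisely
because the thresholds of recently active neurons remain elevated for
hundreds of milliseconds. The $-\Gamma_j z_j$ term is a *soft reset*: the
threshold value is subtracted rather than the potential being clamped, so
strongly driven neurons keep spiking at the refractory limit (3 ms by
default) while their threshold climbs — the spike-frequency adaptation
visible in a tonically driven cell's lengthening inter-spike intervals.

Reference parameters: $\tau_m = 20$ ms, all resistances 1 Ohm, dendritic
reversal potentials 0 mV, conductances 1 nS, $\alpha = 1.8$, $\tau^0 = 0.01$,
$\tau_a = 700$ ms, synaptic delays 5 ms. The dendritic time constants are not
separately specified in the reference setting; we default both to 20 ms,
matching the soma. Integration is explicit Euler at $\Delta t = 1$ ms
(`neuron_params()` rejects steps larger than half the smallest time
constant). Spikes are stored as indicators $z \in \{0, 1\}$; the alternative
$1/\Delta t$ amplitude convention only rescales the $\Delta t$-multiplied
update terms, and the reset subtracts the full threshold, which is the
convention under which all dynamics here were validated.

### Network and initialization

Three layers: inputs project to all three compartments of the hidden
neurons, hidden somata project laterally (sparse, 10% by default) and to
non-spiking leaky readout neurons ($\tau_{out} = 20$ ms). Weight magnitudes
are Gaussian with scale $w_0 / \sqrt{n_{pre}}$, $w_0 = \Delta t / R_m$. Every
synapse carries a fixed sign: projections onto the inhibitory dendrite are
negative, onto the excitatory dendrite positive, somatic projections mixed
(Bernoulli). If the masked recurrent somatic matrix has spectral radius above
0.95 it is rescaled to 0.95, keeping the linearized recurrence stable.
*Deep rewiring* maintains both the signs and the connection count during
training: any active synapse whose updated weight crosses zero is
disconnected and an equal number of dormant synapses are reconnected at
vanishing magnitude with their stored sign; an L1 penalty (0.01) with
temperature 0 drives the turnover. The L1 shrink is applied decoupled from
the ADAM moments (a $\mathrm{lr} \times l_1$ step after the adaptive
update): folded into the moments, the constant penalty would dominate the
normalized update whenever task gradients are small and silence the network.

### Surrogate-gradient BPTT

The spike threshold has no derivative, so backpropagation through time runs
through the triangular surrogate
$dz/dv = k \max(0, 1 - |v|)$, $k = 0.3$, on the normalized potential
$v = (U_m - \Gamma_j)/\Gamma_j$. The backward pass mirrors every forward
recursion — leaks, conductance coupling, threshold adaptation, soft reset,
delayed synapses — and is validated against central finite differences of a
*surrogate forward* network in which the hard threshold is replaced by the
$C^1$ antiderivative of the triangular function (`surrogate_spike()`); on
that differentiable graph the implementation agrees with finite differences
to $10^{-9}$ relative error. During refractoriness the surrogate derivative
is zeroed.

## The training criteria

### Information-theoretic losses

The error-entropy machinery estimates the Renyi quadratic entropy of the
prediction errors $e_i$ by kernel density estimation:
$H_2(e) = -\log V(e)$ with the *information potential*
$V(e) = N^{-2} \sum_{ij} G_\sigma(e_i - e_j)$. Minimizing $H_2$ concentrates
the error distribution but is *shift invariant*: $V(e + c) = V(e)$, so the
errors can concentrate anywhere. The restricted criterion (RMEE) removes
this degeneracy by quantizing errors onto the fixed codebook $(0, -1, 1)$ —
for probability-scale errors $e = y - \hat p \in [-1, 1]$ these are "correct"
and the two "maximally wrong" positions — giving

$$V_R(e) = N^{-2} \sum_i [\phi_0 G_\sigma(e_i) + \phi_{-1} G_\sigma(e_i + 1)
  + \phi_1 G_\sigma(e_i - 1)],$$

where $\Phi = (\phi_0, \phi_{-1}, \phi_1)$ counts the samples binned to each
codeword ($(-0.5, 0.5)$, $(-1, -0.5)$, $(0.5, 1)$; out-of-range and boundary
samples clamp to the nearest codeword, ties toward 0, so $\sum \phi = N$
always; the first training iteration uses the startup counts $(N, 0, 0)$).
Maximization uses the half-quadratic device: with auxiliaries
$u_i = -e^{-e_i^2/2\sigma^2}$ (and shifted analogues $v_i, s_i$), the
quadratic surrogate $J_{R2} = \sum_i [\phi_0 u_i e_i^2 + \phi_{-1} v_i
(e_i+1)^2 + \phi_1 s_i (e_i-1)^2] \le 0$ touches $V_R$ at the current
auxiliaries, so alternating auxiliary updates with quadratic maximization
never decreases $V_R$ (checked over thousands of random batches). The
per-sample gradient $\partial J_{R2}/\partial e_i$ is exposed directly and
chained through BPTT, so no particular readout nonlinearity is baked in.

Two sign/typo conventions deserve note. The gradient's last term pairs
$\phi_1$ with $s_i$ (the $(e-1)^2$ auxiliary), by the symmetry of the
half-quadratic construction. And since $J_{R2} \le 0$ is *maximized* while
cross-entropy is minimized, the combined supervised criterion is implemented
as the single minimized quantity

$$J = \mu \left(-J_{R2}/N^2\right) + (1 - \mu)\, J_2,
  \qquad \mu \in [0, 1],$$

with $J_2$ the cross-entropy of the logistic readout at the image-boundary
times $t = 20 + 20n$. The $1/N^2$ normalization (the same one $V_R$ carries)
makes $\mu$ insensitive to batch size. $\mu = 1$ is the pure RMEE criterion,
$\mu = 0$ pure cross-entropy; the default $\mu = 0.8$ sits in the regime
where the mixture outperforms either extreme on the noisy sequence task.
Probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ before logs. The
kernel bandwidth defaults to $\sigma = 1$ on probability-scale errors;
errors are scalars per readout sample throughout.

### Reward learning

The navigation task trains with a clipped-surrogate policy-gradient loss:
per iteration, $K$ episodes of $T$ steps are collected under the current
policy, advantages $A = \Omega - V$ are formed from the strictly-future
discounted returns $\Omega(t) = \sum_{t' > t} \gamma^{t'-t} \omega(t')$
($\gamma = 0.99$) and the value head, and the loss
$-\frac{1}{KT}\sum \min(rA, \mathrm{clip}(r, 1 \pm 0.2) A) + \mu_v
\overline{(\Omega - V)^2}$ is minimized together with the RMEE term applied
to the per-episode mean value-prediction errors (startup codebook on
iteration 1) and the firing-rate penalty. Advantages are centered and scaled
per iteration with a floor of 0.1 on the scale: without the floor,
iterations that happen to contain no reward would amplify pure value noise
to the same gradient size as real signal. Additional optimization epochs per
collected batch (open-loop replay of the recorded input streams under the
updated weights, ratio clipping active) are supported; the default is a
single epoch, which measured best at the scaled sizes. Value-loss weight
$\mu_v = 0.5$, entropy bonus 0, ADAM with $(10^{-3}\text{–}10^{-2}, 0.9,
0.999, 10^{-8})$.

### Firing-rate regularization

The penalty $\mu_f n^{-1} \sum_j (\sum_{k,t} z_j - f^0 K T)^2$ holds the
population near the target rate $f^0 = 10$ Hz. Because the squared *count*
grows with the simulated horizon, the task front-ends scale the default
weight as $\mu_f = 4/(KT)^2$; the exported `firing_rate_regularizer()`
keeps the literal definition. A known limitation: with the penalty alone,
gradients stall once neurons leave the surrogate derivative's support, so
regularizer-only training does not converge tightly onto $f^0$ (the test
suite asserts a several-fold gap reduction into a [2, 50] Hz band); in full
task training rates settle around 20–40 Hz.

## The synthetic tasks

**Store–recall** (working memory): 40 input channels; channels 1–10 and
11–20 are two value streams, exactly one active per 10-step frame (Poisson,
50 Hz); channels 21–30 and 31–40 carry store and recall commands (all
channels firing through one 10-step frame each, store in the first half of
the 120-step episode, recall in the second half, value streams silenced
during recall). The target is which stream was active during the store
frame; the readout is the mean logistic output over the recall window.
Chance is 0.5 and an untrained network sits there.

**Noisy glyph sequences**: ten procedural binary 28x28 glyphs stand in for
handwritten digits so no external download is needed. Each trial renders a
cue glyph and five test glyphs for 20 steps each (a scanned row of 28
analog pixel channels per step), corrupted by salt-and-pepper noise (each
pixel replaced by 0/1 with equal odds, probability = the noise fraction;
10% by default). Binary labels mark test images of the reference class. The
reference class is fixed across trials by default (noise-robust
recognition); a rotating-cue variant (`target_class = NULL`) poses the much
harder within-trial matching problem, which does not clear chance at the
scaled network and iteration sizes. Readouts are taken at $t = 20 + 20n$.

**Navigation**: a point agent in the unit square, destination radius 0.05,
speed bound 0.02 per step. Position is encoded per dimension by ten
place-tuned Poisson inputs, $r_i = 500 e^{-100 (\xi_i - \xi)^2}$ Hz; reward
events drive a synchronous 5-neuron input group for 5 steps (a second group
is reserved for negative rewards, which do not occur). Five readouts
parameterize the policy — means $\tanh \lambda_{1,2}$, variances
$\sigma(\lambda_{3,4})$, value $\lambda_5$ — and the sampled velocity is
norm-clipped. On reaching the destination the agent receives reward 1 and is
teleported to a fresh uniform start with the destination unchanged, so one
episode contains multiple finds of the same destination and the
destinations-reached number (DRN) per iteration counts them all; this
continuing protocol is what makes within-episode knowledge of the
destination worth storing. The policy readouts are initialized with gain 5
and the variance-head biases at -1.5: at zero-bias initialization the
sampled action noise (per-axis s.d. about 0.7) swamps the bounded action
means, so the policy has no behavioural authority and reward learning has
nothing to climb.

What the generators deliberately do not emulate: real handwritten digit
statistics (the optional IDX reader can stream real MNIST, untested against
the network), biological water-maze kinematics, or noise in the command
channels. Passing tests therefore demonstrate the learning machinery at the
stated synthetic conditions, not performance on natural data.

## Problem sizes and numerical choices

The shipped test and acceptance runs use scaled-down sizes chosen as the
smallest at which each phenomenon is stable: store-recall with 100 hidden
neurons, 96 episodes per iteration, 200 iterations, learning rate 0.01
(held-out accuracy roughly 0.87-0.95 across training seeds); navigation
with 100 hidden neurons, K = 5
episodes of T = 200 steps, 150 iterations (DRN trend positive in 5/5
seeds); glyph sequences with 100 hidden neurons, 12 trials per iteration,
120 iterations (mu = 0.8 reaches ~0.95-0.97 test accuracy, mu = 1.0 stays
near chance, reproducing the ordering of the mixture over the pure
criterion). Batch sizes well below these (e.g. 24 store-recall episodes) do
not clear chance within the iteration budget. All randomness flows from a
single integer seed through R's default generator: generators called with
an explicit seed restore the caller's RNG state, and trainers seed once at
entry, so identical configurations are bit-reproducible.

Degenerate inputs are defined rather than accidental: empty error batches,
non-finite samples, probabilities outside $[0, 1]$, mismatched auxiliary
lengths and codebook counts all raise immediate errors; an all-zero
codebook gives potential 0; the half-quadratic error update keeps samples
unchanged where the quadratic coefficient vanishes; quantization ties break
toward the 0 codeword.

## Limitations

Pure-R simulation limits practical sizes to a few hundred neurons and a few
hundred time steps per episode — ample for the benchmarks here, an order of
magnitude below the reference experiments. The rotating-cue matching task
and tight rate-regularizer convergence are honest open edges, documented
above. Reward learning at these scales improves exploration and value
prediction reliably, but does not reach the regime where the agent
consistently returns to a found destination within an episode.
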