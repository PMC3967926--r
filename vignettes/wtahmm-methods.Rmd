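---
title: "Stochastic WTA circuits as online HMM learners: model and methods"
author: "wtahmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic WTA circuits as online HMM learners: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtahmm)
```

## The model

A winner-take-all (WTA) circuit is a population of `K` stochastic spiking
neurons receiving afferent input through feedforward synapses (log-weights
`W`, `K x N`) and excitatory input from each other through lateral synapses
(log-weights `V`, `K x K`, 5 ms delay), with divisive inhibition shared by
all members.  The membrane potential of neuron `k` is

    u_k(t) = sum_i W[k,i] x_i(t) + sum_j V[k,j] y_j(t) + b_k - rho_k(t),

where `x` and `y` are the summed EPSP traces of afferent and circuit spikes
and `rho_k` is a refractory variable that decays exponentially from the
neuron's own last spike.  The inhibition is treated as ideal: it normalizes
the circuit's total spike rate to a constant `R`, so spike opportunities
arrive as a homogeneous Poisson process (exponential inter-spike intervals
with mean `1000/R` ms) and, at each opportunity, the spiking neuron is a
draw from the softmax of the momentary membrane potentials.  The softmax's
shift invariance is exactly how the common inhibitory term drops out; it is
therefore never computed explicitly.

Because the EPSP kernels decay exponentially, the tuple (last winner,
synaptic traces) is a Markov state, and the sequence of winners is a sample
path of a hidden Markov model (HMM) whose observation model lives in the
feedforward weights and whose prediction (transition) model lives in the
lateral weights.  Each spike propagates a single posterior sample forward
in time, i.e. the circuit implements *forward sampling* — approximate
online inference that conditions on past observations only.

In discrete-time mode (rectangular EPSP kernels whose width equals a fixed
inter-spike interval) this correspondence is exact and bidirectional:
`map_network_to_hmm()` and `map_hmm_to_network()` convert between the two
representations with per-step conditionals equal to machine precision.
Because the excitabilities `b` enter *every* step's softmax, the lateral
weights of a mapped network absorb `-b`; with that convention the round
trip is exact even for non-uniform initial distributions.

## STDP as a stochastic M-step

When neuron `k` spikes, row `k` of both `W` and `V` is updated by the same
rule,

    dw = eta * (x * exp(-w) - 1),

trace-dependent potentiation scaled by `exp(-w)` minus a constant
depression.  Fixed points: no net change when `x = exp(w)`, constant
depression `eta` at `x = 0`, and stationarity at
`exp(w*) = E[presynaptic trace | postsynaptic spike]` — the M-step of
expectation-maximization (EM) evaluated on the sampled path.  The
`exp(-w)` factor makes potentiation steep for strongly depressed
synapses: a neuron that starts winning a new pattern re-specializes
within a few spikes, which is the engine behind assembly formation.  It
also means a naive discrete-time application can overshoot: a synapse at
the log-weight floor (-10) would receive a kick of order
`eta * x * e^10`.  We therefore cap each update at 3 log units — far
above any update that occurs near equilibrium, so the cap only tames the
first few jumps out of the floor and leaves the rule's fixed points and
local dynamics untouched.

Excitability (prior) learning — `exp(b_k)` tracking each neuron's win
frequency by the same moving average — is available via
`learn_config(learn_b = TRUE)` and is off by default for the spiking
experiments, where all neurons share one prior.  For the discrete
benchmark it matters: with fixed uniform `b`, the transition table decoded
from the lateral weights conflates the learned reverse conditional
`P(previous | current)` with state occupancy, whereas with learned `b` the
decoded table is the exact maximum-likelihood count estimate.

## Rejection and importance sampling

Forward sampling is biased: the state drawn at step `n` never sees the
future observations.  The refinement treats the network as a proposal
distribution.  Over a sequence, each step contributes its instantaneous
input log-likelihood ("surprise") to a running log importance weight; the
per-sequence synaptic updates are held as eligibility tags, and a global
binary decision consolidates or discards them.

* `accept_decision(log_w, log_c)` accepts with probability
  `min(1, exp(log_w - log_c))`.
* `track_c()` adapts the threshold: up by `step_accept` on acceptance,
  down by `step_reject = step_accept / (S - 1)` on rejection.  This is a
  stable negative feedback with equilibrium acceptance rate `1/S` — on
  average `S` replays per input, each replay with freshly drawn input
  spikes.  (The opposite sign convention, lowering the threshold on
  acceptance, is a positive feedback whose acceptance rate collapses; we
  verified this numerically before fixing the direction.)
* `batch_select()` implements the batch alternative: draw `S` proposals,
  normalize their importance weights, and either resample one path
  (rejection) or weight every path's tags by its normalized importance
  weight (importance sampling).

In discrete mode the per-step weight is computed with the row normalizers
of the equivalent HMM tables included, so that the accumulated weight
equals `log p_model(x, y) - log q(y | x)` exactly even early in training
when the emergent normalization has not yet converged.  On enumerable
models the accepted-path distribution then matches the exact posterior
(total variation < 0.01 in our tests at `S = 10`), and averaging
`exp(log_w)` over proposals recovers the exact forward likelihood.  In the
continuous-time circuit the surprise is the network-computable quantity
`logsumexp(u) - logsumexp(u_feedforward)` per WTA group; the feedforward
baseline subtraction removes fluctuations that are common to all replays
of the same input and substantially reduces the variance of the
importance weights.

## Synthetic tasks

The stimulus generators mirror the experimental protocols:

* **Working memory (`memory4`)**: four cue-delay-recall sequences
  (`A B delay a b`, `B A delay b a`, `C D delay c d`, `D C delay d c`),
  chosen with equal probability; the `delay` symbol is shared by all four,
  so the task is non-Markovian in the symbols and forces context coding.
* **Context grammar (`abcd`)**: language exactly `{AABC, BBAC, ABAD,
  BABD}`; the final `C`/`D` is predictable only from the whole prefix.
* **Stationary delay (`two_seq_delay`)**: `A delay` and `B delay` with a
  500 ms constant-rate delay pattern, for the neural-trajectory and
  homeostasis experiments.

Symbols are rendered as fixed-duration Poisson rate patterns (50 ms by
default) over the afferent population.  Dense coding draws each
(symbol, afferent) rate from `Beta(2, 2)` times a 75 Hz maximum — values
chosen, where the sources leave them unstated, to give overlapping but
distinguishable patterns.  Sparse coding activates disjoint pairs of
afferents at 100 Hz per symbol.  Spike times are redrawn at every
presentation and every replay.  Foils are single-symbol substitutions of
grammatical strings, re-checked against the enumerated language.

What the generators deliberately do not emulate: correlated or jittered
(non-Poisson) input noise, graded symbol similarity structure, and
between-pattern silent gaps.  Results on these synthetic streams therefore
speak to the model's computational claims, not to robustness against
realistic sensory statistics.

## Numerical choices

* Event-driven simulation with closed-form trace decay; afferent spikes
  arriving between circuit spikes are integrated at their exact times.
  The hot loops are compiled (Rcpp) and draw from R's RNG, so `set.seed()`
  makes entire experiments reproducible; an R reference implementation of
  the single-step dynamics (`network_step`) is tested against the
  compiled path.
* Softmax with max-subtraction; likelihoods accumulated in the log
  domain; log-weights floored at -10; discrete emission probabilities
  floored at 1e-4 when fitted tables are evaluated on held-out data.
* Default kernels: double-exponential EPSPs (decay 20 ms, rise 2 ms,
  peak-normalized), 5 ms lateral delay, exponential refractory kernel
  (amplitude 5, 10 ms).  The sources print none of these constants.  The
  spiking-experiment drivers use EPSP amplitudes of 0.5 (feedforward) and
  1 (lateral) and a learning rate of 0.1 (working memory) or 0.05
  (trajectories, grammar learning), calibrated once on the
  working-memory task so that training lands in the sparse
  sequential-assembly regime — a small set of crisply ordered specialists
  per sequence with a near-silent remainder — and then frozen.  Assembly
  *breadth* proved to be the model's most sensitive property: over the
  explored constants the trained circuit either concentrates on few
  specialists per sequence or spreads over most of the population
  without stereotyped order, so the packaged defaults favor the ordered
  regime and the recruited counts per sequence are accordingly small.
* Ties in peak-time sorting are broken by neuron index; the first global
  maximum wins.  jPCA uses 6 PCA components and central-difference
  derivatives.
* Homeostatic intrinsic plasticity uses an exponential moving rate
  estimate (10 s window) and nudges each excitability proportionally to
  the rate error; the update rate 0.02 was chosen so adaptation is slow
  relative to the WTA dynamics but converges well within a training run.

## Experiment scales

The packaged experiment drivers run at desk scale, chosen so the full
suite completes on a laptop while reproducing the qualitative phenomena:
the working-memory circuit uses 200 afferents and 100 neurons trained on
a continuous stream of 250 sequence presentations with 100-trial evoked
averages; the trajectory task uses ~200 neurons in WTA groups of 10-50;
the discrete benchmark uses 10 random teachers by default (4 states, 8
symbols, length-10 sequences, 200 training / 2000 validation sequences,
20 epochs; the acceptance suite uses 20 teachers, since the method
ordering is an average property).  Teacher tables are drawn entry-wise
from `Beta(0.03, 0.03)` and renormalized: strongly structured,
near-deterministic teachers — the regime where the quality of the E-step
approximation is visible.  With diffuse teachers all approximations
converge to nearly identical held-out likelihoods and the comparison
degenerates; the printed value of the Beta parameter is not recoverable
from the sources.  The stochastic learners' tables fluctuate around
their fixed points at a scale set by the learning rate, so each
stochastic learner's final model is the probability-space average of its
mapped model over the last 6 epochs; Baum-Welch, being deterministic
batch EM, is evaluated at its converged estimate.  The benchmark enables
excitability learning (`learn_b = TRUE`): with fixed uniform
excitabilities the transition table decoded from the lateral weights is
biased by state occupancy, and that bias grows under posterior-guided
(rejection) training.  At very small state counts the same excitability
feedback can collapse states, which is why it stays off by default
elsewhere.  The stochastic learners of one teacher share their random
initial weights, making the comparison paired.

## Replay measurement

Spontaneous completion is scored by Spearman rank correlation between
neurons' peak firing times in one spontaneous trial (cue and a
three-fold extended delay evoked, then the input turned off) and their
peak times in the trial-averaged evoked template.  The whole trial
enters the comparison: rank order is invariant to the delay extension,
and the evoked segments anchor the ordering so the free-run completion
modulates rather than dominates the statistic.  Single-trial peaks use
20 ms smoothing (single spikes make narrower kernels jitter-dominated);
only neurons that spiked in the spontaneous run are ranked.  The 0.5
median bar in the acceptance suite is this package's own calibration
point — the sources plot replay-correlation histograms without printing
summary values.

## Known limitations

* Hidden-state duration is implicitly exponential per state; long
  durations are represented by assemblies of states, not by explicit
  duration models.
* The idealized inhibition (exact softmax, constant circuit rate) skips
  interneuron dynamics; the importance weight in continuous time relies
  on the emergent normalization and is exact only in discrete mode.  In
  practice its trial-to-trial variance in spiking sessions is large
  (tens of nats even after both baseline subtractions), which blunts the
  benefit of rejection sampling for the spiking grammar task; in
  discrete mode, where the weight is exact, the rejection refinements
  measurably outperform forward sampling.
* Homeostatic intrinsic plasticity equalizes long-run rates partly
  through slow excitability oscillations; at any frozen time point a
  fraction of the population sits below threshold, so stationary
  participation is well below the full-recruitment ideal.
* Forward-sampling learning inherits the known degeneracies of
  single-particle filtering for long sequences; rejection sampling
  mitigates but pays in replays.
* The grammar-learning experiments on published human-subject string
  lists require those lists as user input; they are not distributed with
  the package.
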