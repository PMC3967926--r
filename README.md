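# wtahmm

Winner-take-all (WTA) circuits of stochastic spiking neurons as online
learners of hidden Markov models (HMMs).

## The science

A cortical microcircuit motif — pyramidal cells with lateral excitation
and shared inhibition — can be read as a probabilistic model of its input
stream.  With idealized divisive inhibition, the circuit's spikes are
samples: at each spike opportunity (a Poisson process with circuit rate
`R`), neuron `k` wins with softmax probability

    p(k) ∝ exp( Σ_i W[k,i] x_i + Σ_j V[k,j] y_j + b_k − ρ_k ),

where `x` and `y` are afferent and lateral EPSP traces and `ρ_k` is a
refractory term.  Because exponentially decaying traces make (last winner,
traces) a Markov state, the winner sequence is a forward sample from the
state space of an HMM whose *observation model* sits in the feedforward
log-weights `W` and whose *prediction model* sits in the lateral
log-weights `V`.  A single STDP rule applied to both synapse classes at
each postsynaptic spike,

    Δw = η (x · e^(−w) − 1),

is the stochastic M-step of online expectation-maximization for that HMM:
at stationarity `exp(w*) = E[presynaptic trace | postsynaptic spike]`.
Pure forward sampling is a biased E-step; the package also implements the
refined learner in which per-sequence synaptic tags are consolidated only
when a global acceptance test on the sequence's accumulated importance
weight (the summed instantaneous "surprise") passes — rejection sampling,
with a linearly tracked acceptance threshold or an exact per-batch
normalizer, plus the deterministic importance-sampling variant.

The package contains the full stack around that core: an event-driven
continuous-time simulator (Rcpp), the exact discrete-time equivalence
`map_network_to_hmm()` / `map_hmm_to_network()`, reference HMM machinery
(teacher sampling, scaled forward algorithm, batch Baum-Welch),
finite-state-grammar stimulus generators with Poisson rate-pattern
encodings, and the analysis readouts: PETHs, peak-time sorting,
rank-order replay correlation, selectivity profiling, jPCA, a linear SVM
readout, and likelihood-threshold sequence classification.

## Worked example

Train a discrete-time circuit on sequences from a random teacher HMM and
compare the learned model's held-out likelihood against the teacher's:

```r
library(wtahmm)
set.seed(1)

teacher <- sample_teacher_hmm(K = 4, L = 8, beta_a = 0.03, beta_b = 0.03)
train   <- generate_observations(teacher, n_sequences = 200, length = 10)
test    <- generate_observations(teacher, n_sequences = 500, length = 10)

net <- network_params(n_afferents = 8, n_neurons = 4, mode = "discrete")
fit <- train_session(net, train,
                     learn_config(eta = 0.01, mode = "rejection",
                                  c_strategy = "batch", S = 10,
                                  learn_b = TRUE),
                     epochs = 20)

learned <- map_network_to_hmm(fit$params)
mean(sapply(test, exact_forward_loglik, hmm = wtahmm:::floor_hmm(learned)))
#> [1] -20.28131
mean(sapply(test, exact_forward_loglik, hmm = teacher))
#> [1] -19.35562
```

The learned circuit's mean held-out log-likelihood per 10-symbol sequence
(-20.28 nats) approaches the generating teacher's own (-19.36 nats); the
gap is the price of sampled, online inference with a single-particle
E-step.  The full comparison
(forward sampling vs. rejection sampling at 10 and 100 replays vs.
Baum-Welch, over 10 random teachers) is packaged as

```r
res <- run_experiment(list(experiment = "hmm_benchmark", seed = 1))
res$metrics$mean_val_loglik
```

The spiking experiments are driven the same way, e.g.
`run_experiment(list(experiment = "memory4", seed = 1))` trains a
100-neuron circuit on the four-sequence working-memory stream and reports
how many neurons each sequence recruits.  A thin command-line wrapper
over these drivers is provided at `inst/cli/wtahmm.R`
(`Rscript inst/cli/wtahmm.R reproduce memory4 --seed 1 --out out/`).

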