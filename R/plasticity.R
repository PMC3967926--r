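#' Learning configuration
#'
#' Bundles the learning-rate, sampling-mode and homeostasis settings used
#' by [train_session()] and [run_network()].
#'
#' Modes: `forward` applies the STDP update online at every circuit spike
#' (the plain forward-sampling approximation of the EM E-step);
#' `rejection` accumulates synaptic tags over each input sequence and
#' consolidates them only when the sequence's importance weight passes a
#' stochastic acceptance test, replaying the input (with freshly drawn
#' spikes) until one acceptance; `importance` scales the tags of a batch
#' of `S` replays by their normalized importance weights.
#'
#' The acceptance threshold `log c` is tracked linearly: each acceptance
#' raises it by `step_accept`, each rejection lowers it by `step_reject`.
#' With `step_reject = step_accept / (S - 1)` the equilibrium acceptance
#' rate is `1/S`, i.e. on average `S` replays per input.
#' `c_strategy = "batch"` instead draws `S` replays per iteration and
#' selects one in proportion to its importance weight (the exact
#' normalizing constant for the batch).
#'
#' @param eta learning rate (> 0).
#' @param mode `"forward"`, `"rejection"`, `"importance"` or `"none"`.
#' @param S target mean number of replays per input (>= 1).
#' @param c_strategy `"track"` (linear tracking of `c`) or `"batch"`.
#' @param step_accept,step_reject tracking steps for `log c`.
#' @param warm_start_c initialize the threshold from the first proposal's
#'   log importance weight (continuous-time sessions, where the weight
#'   scale is a priori unknown); `log_c0` is then an offset.
#' @param log_c0 initial `log c`.
#' @param max_replays replay budget per iteration; if exhausted the last
#'   proposal is consolidated and the iteration is flagged in the log.
#' @param floor lower clip for log-weights.
#' @param exclude_self exclude the diagonal of `V` from learning
#'   (continuous mode).
#' @param learn_b learn excitabilities (off: all neurons share the same
#'   prior probability to fire).
#' @param homeostasis enable homeostatic intrinsic plasticity.
#' @param target_rate homeostatic target rate `r*` (Hz per neuron).
#' @param rate_window exponential averaging window of the rate estimate
#'   (ms).
#' @param eta_b homeostatic update rate.
#' @return an object of class `learn_config`.
#' @export
learn_config <- function(eta = 0.05,
                         mode = c("forward", "rejection", "importance",
                                  "none"),
                         S = 10, c_strategy = c("track", "batch"),
                         step_accept = 0.01,
                         step_reject = if (S > 1) step_accept / (S - 1)
                           else step_accept,
                         log_c0 = 0, warm_start_c = FALSE,
                         max_replays = 100 * S, floor = -10,
                         exclude_self = TRUE, learn_b = FALSE,
                         homeostasis = FALSE, target_rate = 10,
                         rate_window = 10000, eta_b = 0.02) {
  mode <- match.arg(mode)
  c_strategy <- match.arg(c_strategy)
  stopifnot(eta >= 0, eta < 1, S >= 1, step_accept > 0, step_reject > 0,
            max_replays >= 1)
  structure(list(eta = eta, mode = mode, S = as.integer(S),
                 c_strategy = c_strategy, step_accept = step_accept,
                 step_reject = step_reject, log_c0 = log_c0,
                 warm_start_c = warm_start_c,
                 max_replays = as.integer(max_replays), floor = floor,
                 exclude_self = exclude_self, learn_b = learn_b,
                 homeostasis = homeostasis, target_rate = target_rate,
                 rate_window = rate_window, eta_b = eta_b),
            class = "learn_config")
}

#' STDP update triggered by one circuit spike
#'
#' When neuron `k` spikes, row `k` of the feedforward and the lateral
#' log-weight matrices is updated by the same rule:
#' `dw = eta (x exp(-w) - 1)` — trace-dependent potentiation scaled by
#' `exp(-w)`, minus a constant depression `eta`.  The potentiation term is
#' steep for strongly depressed synapses, so a neuron re-specializes to a
#' newly won pattern within a few spikes; a per-update cap of 3 log units
#' keeps the discrete jump from overshooting the instantaneous fixed
#' point `w = log(x)` when `w` sits near the floor.  Fixed points: zero
#' net change at `x = exp(w)`, constant depression at `x = 0`, and
#' stationarity at `exp(w*) = E[presynaptic trace | postsynaptic spike]`.
#' The diagonal of `V` is left untouched when `exclude_self` is set.
#'
#' @param params a [network_params()].
#' @param state a [network_state()] decayed to the spike time.
#' @param spike list with at least `neuron` (the spiking circuit neuron).
#' @param eta learning rate.
#' @param exclude_self skip the lateral self-weight.
#' @param floor lower clip for log-weights.
#' @return list with `neuron`, `dW` and `dV` — the additive log-domain
#'   updates for row `neuron` of `W` and `V`.
#' @export
stdp_delta <- function(params, state, spike, eta,
                       exclude_self = params$mode == "continuous",
                       floor = -10) {
  k <- spike$neuron
  stopifnot(k >= 1, k <= params$n_neurons)
  tr <- state_traces(params, state)
  upd <- function(w, x) {
    d <- pmin(ifelse(x > 0, eta * (x * exp(-w) - 1), -eta), 3)
    pmax(w + d, floor) - w
  }
  dW <- upd(params$W[k, ], tr$x)
  dV <- upd(params$V[k, ], tr$y)
  if (exclude_self) dV[k] <- 0
  list(neuron = k, dW = dW, dV = dV)
}

#' Synaptic eligibility store
#'
#' Accumulates tagged (unapplied) weight updates over an input sequence;
#' the tags are consolidated into the parameters on acceptance, or
#' discarded wholesale on rejection.
#'
#' @param params a [network_params()].
#' @return an object of class `eligibility_store` with zeroed `dW`, `dV`,
#'   `db` accumulators.
#' @export
eligibility_store <- function(params) {
  structure(list(dW = matrix(0, params$n_neurons, params$n_afferents),
                 dV = matrix(0, params$n_neurons, params$n_neurons),
                 db = numeric(params$n_neurons), n = 0L),
            class = "eligibility_store")
}

#' Accumulate a delta, or consolidate / discard the store
#'
#' With `decision = "online"` the delta is applied to the parameters
#' immediately.  Otherwise deltas are accumulated into the store;
#' `decision = "accept"` adds the accumulated tags to the parameters
#' (additively in the log-weight domain) and `"reject"` discards them.
#' Accumulation is additive, so accepting two accumulated deltas equals a
#' single application of their sum.  Note that online learning over a
#' sequence is *not* equivalent to deferred acceptance of the same
#' sequence: under online updates the dynamics evolve with the changing
#' weights.
#'
#' @param store an [eligibility_store()].
#' @param params a [network_params()].
#' @param delta a [stdp_delta()] result (for `"online"` / accumulation).
#' @param decision `"online"`, `"tag"`, `"accept"` or `"reject"`.
#' @return list with updated `params` and `store`.
#' @export
accumulate_and_consolidate <- function(store, params, delta = NULL,
                                       decision = c("tag", "online",
                                                    "accept", "reject")) {
  decision <- match.arg(decision)
  if (decision %in% c("online", "tag")) {
    stopifnot(!is.null(delta))
    k <- delta$neuron
    if (decision == "online") {
      params$W[k, ] <- params$W[k, ] + delta$dW
      params$V[k, ] <- params$V[k, ] + delta$dV
    } else {
      store$dW[k, ] <- store$dW[k, ] + delta$dW
      store$dV[k, ] <- store$dV[k, ] + delta$dV
      store$n <- store$n + 1L
    }
    return(list(params = params, store = store))
  }
  if (store$n == 0L && decision == "accept")
    message("consolidating an empty eligibility store: no-op")
  if (decision == "accept") {
    params$W <- params$W + store$dW
    params$V <- params$V + store$dV
    params$b <- params$b + store$db
  }
  list(params = params, store = eligibility_store(params))
}

#' Log importance weight of a completed sequence
#'
#' The accumulated, baseline-corrected instantaneous input log-likelihoods
#' of all circuit spikes over the sequence — the log of the ratio between
#' the HMM target posterior and the forward-sampling proposal for the
#' sampled state path.  Additive over concatenated segments.
#'
#' @param surprise numeric vector (or the `surprise` data.frame of
#'   [run_network()]) of per-step values.
#' @return the summed log importance weight.
#' @export
sequence_log_importance_weight <- function(surprise) {
  if (is.data.frame(surprise)) surprise <- surprise$value
  sum(surprise)
}

#' Stochastic acceptance decision
#'
#' Accept a proposed state sequence with probability
#' `min(1, exp(log_weight - log_c))`.  For a fixed acceptance probability
#' `p` the number of proposals per acceptance is geometric with mean
#' `1/p`; as `c` tends to 0 every sample is accepted and learning reduces
#' to pure forward sampling.
#'
#' @param log_weight sequence log importance weight.
#' @param log_c acceptance scale, log domain.
#' @return logical.
#' @export
accept_decision <- function(log_weight, log_c) {
  stopifnot(is.finite(log_c))
  runif(1) < exp(min(0, log_weight - log_c))
}

#' Linear tracking of the acceptance threshold
#'
#' The threshold `log c` of [accept_decision()] is raised by
#' `step_accept` on every acceptance and lowered by `step_reject` on
#' every rejection — a stable negative feedback whose equilibrium
#' acceptance rate is `step_reject / (step_accept + step_reject)`; with
#' `step_reject = step_accept / (S - 1)` that is `1/S`, giving on
#' average `S` proposals per acceptance.
#'
#' @param log_c current threshold.
#' @param accepted logical outcome of [accept_decision()].
#' @param step_accept,step_reject tracking steps.
#' @return updated `log_c`.
#' @export
track_c <- function(log_c, accepted, step_accept = 0.01,
                    step_reject = step_accept / 9) {
  if (accepted) log_c + step_accept else log_c - step_reject
}

#' Batch normalization: select or weight a batch of proposals
#'
#' Normalizes the importance weights of `N_S` proposed sequences over the
#' batch (the batch estimate of the acceptance constant).  The rejection
#' variant samples one index in proportion to its weight; the importance
#' variant returns the normalized weights for scaling the per-proposal
#' eligibility tags.
#'
#' @param log_weights numeric vector of per-proposal log importance
#'   weights.
#' @param variant `"rejection"` or `"importance"`.
#' @return for `"rejection"`, a list with `index` and `weights`; for
#'   `"importance"`, a list with `weights`.
#' @export
batch_select <- function(log_weights, variant = c("rejection",
                                                  "importance")) {
  variant <- match.arg(variant)
  stopifnot(length(log_weights) >= 1)
  m <- max(log_weights)
  if (!is.finite(m)) stop("all importance weights are zero (-Inf)")
  w <- exp(log_weights - m)
  w <- w / sum(w)
  if (variant == "importance") return(list(weights = w))
  list(index = sample.int(length(w), 1, prob = w), weights = w)
}

#' Homeostatic intrinsic plasticity step
#'
#' Nudges each excitability towards equalized firing:
#' `b_k <- b_k + eta_b (r* - r_k) dt`, with measured rates in Hz and `dt`
#' in seconds.  In closed loop the long-run rate of every neuron converges
#' to the target `r*`.
#'
#' @param b excitabilities.
#' @param rates measured per-neuron rates (Hz).
#' @param target_rate target rate `r*` (Hz).
#' @param eta_b update rate.
#' @param dt elapsed time (s).
#' @return updated `b`.
#' @export
homeostatic_update <- function(b, rates, target_rate = 10, eta_b = 0.02,
                               dt = 1) {
  stopifnot(all(rates >= 0), length(rates) == length(b))
  b + eta_b * (target_rate - rates) * dt
}

#' Train a WTA circuit on a task stream
#'
#' Drives the learning loops over a stream of input sequences.
#'
#' For a *continuous* network the task is a generator function
#' `function(i)` returning a fresh afferent [spike_train()] for iteration
#' `i` (inputs are re-drawn on every presentation and every replay).  In
#' `forward` mode STDP is applied online at every circuit spike; in
#' `rejection` mode each input is replayed with freshly drawn spikes until
#' its synaptic tags are accepted once, with `c` tracked across
#' iterations.  `reset` controls whether the network state is zeroed
#' between sequences (the grammar-learning protocol) or carried over (the
#' continuous-stream protocol).
#'
#' For a *discrete* network the task is a list of integer symbol
#' sequences presented in random order over `epochs` epochs, with the
#' mode/strategy semantics of [learn_config()]; updates are applied at
#' sequence end (modes other than `forward`).
#'
#' @param params a [network_params()].
#' @param task generator function (continuous) or list of integer symbol
#'   sequences (discrete).
#' @param config a [learn_config()].
#' @param iterations number of sequence presentations (continuous mode).
#' @param epochs passes over the task list (discrete mode).
#' @param reset zero the network state between sequences?
#' @param state optional initial state (continuous, `reset = FALSE`).
#' @return list with trained `params`, final `state`, and a training `log`
#'   data.frame (iteration, replays, accepted log-weight, `log c`).
#' @export
train_session <- function(params, task, config = learn_config(),
                          iterations = NULL, epochs = 1, reset = TRUE,
                          state = NULL) {
  stopifnot(inherits(params, "network_params"),
            inherits(config, "learn_config"))
  if (params$mode == "discrete") {
    stopifnot(is.list(task))
    mode <- switch(config$mode, none = -1L, forward = 0L,
                   rejection = if (config$c_strategy == "batch") 2L else 1L,
                   importance = 3L)
    if (mode < 0) return(list(params = params, log = NULL))
    res <- train_discrete_cpp(params$W, params$V, params$b,
                              lapply(task, as.integer), mode, config$eta,
                              config$S, config$step_reject,
                              config$step_accept,
                              config$log_c0, as.integer(epochs), TRUE,
                              config$floor, FALSE, config$learn_b,
                              config$max_replays, TRUE)
    params$W <- res$W; params$V <- res$V; params$b <- res$b
    return(list(params = params,
                log = data.frame(iteration = res$iter,
                                 replays = res$replays,
                                 log_weight = res$logw,
                                 log_c = res$log_c),
                log_c = res$log_c_final))
  }

  stopifnot(is.function(task), !is.null(iterations))
  log_c <- config$log_c0
  warm <- isTRUE(config$warm_start_c)
  it_log <- rep_log <- integer(0); lw_log <- lc_log <- numeric(0)
  for (i in seq_len(iterations)) {
    if (reset || is.null(state)) state <- network_state(params)
    if (config$mode %in% c("forward", "none")) {
      inp <- task(i)
      run <- run_network(params, inp, duration = inp$duration,
                         state = state,
                         learn = if (config$mode == "forward") config)
      params <- run$params
      state <- run$state
      it_log <- c(it_log, i); rep_log <- c(rep_log, 1L)
      lw_log <- c(lw_log,
                  sequence_log_importance_weight(run$surprise))
      lc_log <- c(lc_log, NA_real_)
    } else {
      reps <- 0L; accepted <- FALSE
      state0 <- state
      while (!accepted && reps < config$max_replays) {
        reps <- reps + 1L
        inp <- task(i)
        run <- run_network(params, inp, duration = inp$duration,
                           state = state0, learn = config)
        lw <- sequence_log_importance_weight(run$surprise)
        if (warm) { log_c <- lw + config$log_c0; warm <- FALSE }
        accepted <- accept_decision(lw, log_c)
        log_c <- track_c(log_c, accepted, config$step_accept,
                         config$step_reject)
      }
      # consolidate the accepted (or budget-exhausted, flagged) tags;
      # homeostatic b updates (if any) are applied online, not tagged
      params$W <- params$W + run$tags$dW
      params$V <- params$V + run$tags$dV
      params$b <- run$params$b
      state <- run$state
      it_log <- c(it_log, i); rep_log <- c(rep_log, reps)
      lw_log <- c(lw_log, lw); lc_log <- c(lc_log, log_c)
    }
  }
  list(params = params, state = state,
       log = data.frame(iteration = it_log, replays = rep_log,
                        log_weight = lw_log, log_c = lc_log),
       log_c = log_c)
}
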