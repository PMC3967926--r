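#' Parameters of a stochastic WTA circuit
#'
#' The circuit consists of `n_neurons` stochastic spiking neurons receiving
#' feedforward input from `n_afferents` channels through log-weights `W`
#' (K x N) and lateral excitatory input from each other through log-weights
#' `V` (K x K).  `b` are per-neuron excitabilities.  Divisive inhibition is
#' idealized: at each circuit spike opportunity the winner is drawn from a
#' softmax over the membrane potentials within a WTA group, so the
#' inhibition term never has to be computed explicitly.  Spike opportunities
#' of each group form a homogeneous Poisson process with rate `R`.
#'
#' In `mode = "discrete"` the circuit is the fixed-ISI, rectangular-kernel
#' variant: one step per input symbol, afferent traces are one-hot symbol
#' indicators, and the lateral trace is the one-hot indicator of the
#' previous winner.  In this mode the circuit is exactly a discrete-input,
#' discrete-state HMM (see [map_network_to_hmm()]).
#'
#' Weights default to small equally distributed random values (uniform on
#' `[-0.1, 0]` in log-weight space, drawn from the current RNG stream).  In
#' continuous mode the diagonal of `V` is held at zero (self-excitation is
#' replaced by the refractory kernel); in discrete mode self-transitions
#' live on the diagonal.
#'
#' @param n_afferents number of afferent channels N.
#' @param n_neurons number of circuit neurons K.
#' @param R spike-opportunity rate of each WTA group (Hz).
#' @param groups integer vector of length K partitioning the neurons into
#'   WTA groups (default: a single group).
#' @param W,V,b optional explicit parameter values.
#' @param kernel_ff,kernel_lat,kernel_refr [kernel_spec()]s for the
#'   feedforward EPSPs, lateral EPSPs (5 ms delay by default) and the
#'   refractory mechanism.
#' @param mode `"continuous"` (event-driven, default) or `"discrete"`.
#' @return an object of class `network_params`.
#' @export
network_params <- function(n_afferents, n_neurons, R = 10 * n_neurons,
                           groups = rep(1L, n_neurons),
                           W = NULL, V = NULL, b = NULL,
                           kernel_ff = kernel_spec("double_exp"),
                           kernel_lat = kernel_spec("double_exp", delay = 5),
                           kernel_refr = kernel_spec("refractory",
                                                     tau_decay = 10,
                                                     amplitude = 5),
                           mode = c("continuous", "discrete")) {
  mode <- match.arg(mode)
  stopifnot(n_afferents >= 1, n_neurons >= 1, R > 0,
            length(groups) == n_neurons)
  groups <- as.integer(factor(groups))
  if (is.null(W))
    W <- matrix(runif(n_neurons * n_afferents, -0.1, 0),
                n_neurons, n_afferents)
  if (is.null(V)) {
    V <- matrix(runif(n_neurons^2, -0.1, 0), n_neurons, n_neurons)
    if (mode == "continuous") diag(V) <- 0
  }
  if (is.null(b)) b <- numeric(n_neurons)
  stopifnot(nrow(W) == n_neurons, ncol(W) == n_afferents,
            nrow(V) == n_neurons, ncol(V) == n_neurons,
            length(b) == n_neurons)
  if (mode == "continuous" && any(diag(V) != 0))
    stop("diagonal of V must be zero in continuous mode")
  structure(list(n_afferents = n_afferents, n_neurons = n_neurons, R = R,
                 groups = groups, n_groups = max(groups),
                 W = W, V = V, b = as.numeric(b),
                 kernel_ff = kernel_ff, kernel_lat = kernel_lat,
                 kernel_refr = kernel_refr, mode = mode),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "<network_params> K = %d neurons (%d WTA group%s), N = %d afferents, R = %g Hz, %s mode\n",
    x$n_neurons, x$n_groups, if (x$n_groups > 1) "s" else "",
    x$n_afferents, x$R, x$mode))
  invisible(x)
}

#' Initial (or reset) state of a WTA circuit
#'
#' The tuple (last winner per group, synaptic traces) is the Markov state
#' of the circuit: together with the afferent input it fully determines the
#' distribution of future dynamics.
#'
#' @param params a [network_params()].
#' @param time starting time (ms).
#' @return an object of class `network_state` with zeroed traces, no last
#'   winners, and per-neuron last spike times at `-Inf`.
#' @export
network_state <- function(params, time = 0) {
  K <- params$n_neurons
  structure(list(
    time = time,
    xp = numeric(params$n_afferents), xq = numeric(params$n_afferents),
    yp = numeric(K), yq = numeric(K),
    last_spike = rep(-Inf, K),
    next_t = rep(NA_real_, params$n_groups),
    pend_t = numeric(0), pend_n = integer(0),
    rhat = numeric(K),
    last_winner = rep(NA_integer_, params$n_groups)),
    class = "network_state")
}

kernel_cfg <- function(params) {
  kf <- params$kernel_ff; kl <- params$kernel_lat; kr <- params$kernel_refr
  list(ff_tau_d = kf$tau_decay,
       ff_tau_r = if (kf$family == "double_exp") kf$tau_rise else -1,
       ff_amp = if (kf$family == "double_exp") kf$scale else kf$amplitude,
       lat_tau_d = kl$tau_decay,
       lat_tau_r = if (kl$family == "double_exp") kl$tau_rise else -1,
       lat_amp = if (kl$family == "double_exp") kl$scale else kl$amplitude,
       lat_delay = kl$delay,
       refr_amp = kr$amplitude, refr_tau = kr$tau_decay)
}

state_traces <- function(params, state) {
  kf <- params$kernel_ff; kl <- params$kernel_lat
  x <- if (kf$family == "double_exp") kf$scale * (state$xp - state$xq)
       else kf$amplitude * state$xp
  y <- if (kl$family == "double_exp") kl$scale * (state$yp - state$yq)
       else kl$amplitude * state$yp
  list(x = x, y = y)
}

#' Membrane potentials of all circuit neurons
#'
#' `u_k = sum_i W[k,i] x_i + sum_j V[k,j] y_j + b_k - refractory_k`, where
#' `x` and `y` are the afferent and lateral EPSP traces held in `state` and
#' the refractory term decays exponentially from the neuron's own last
#' spike.  The common inhibition is *not* part of `u`: it is absorbed by the
#' normalization in [winner_distribution()] (softmax shift invariance).
#'
#' @param params a [network_params()].
#' @param state a [network_state()] whose traces are decayed to the current
#'   time.
#' @return numeric vector of K membrane potentials.
#' @export
membrane_potentials <- function(params, state) {
  tr <- state_traces(params, state)
  if (length(tr$x) != params$n_afferents ||
      length(tr$y) != params$n_neurons)
    stop("state/params shape mismatch")
  refr <- refr_term(params, state)
  as.vector(params$W %*% tr$x + params$V %*% tr$y) + params$b - refr
}

refr_term <- function(params, state) {
  ts <- state$time - state$last_spike
  refr <- numeric(length(ts))
  fin <- is.finite(ts)
  refr[fin] <- evaluate_kernel(params$kernel_refr, ts[fin])
  refr
}

#' Per-group winner (softmax) distribution
#'
#' Within each WTA group the probability that neuron `k` fires the group's
#' next spike is `exp(u_k) / sum_l exp(u_l)` over the group's members,
#' computed with max-subtraction for overflow safety.  Adding a constant to
#' all potentials of a group (e.g. the common inhibition) leaves the
#' distribution unchanged.
#'
#' @param u numeric vector of membrane potentials.
#' @param groups integer group labels, same length as `u`.
#' @return numeric vector of probabilities, summing to 1 within each group.
#' @export
winner_distribution <- function(u, groups = rep(1L, length(u))) {
  stopifnot(all(is.finite(u)), length(u) == length(groups))
  if (!length(u)) stop("empty group")
  p <- numeric(length(u))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (!length(idx)) stop("empty group")
    e <- exp(u[idx] - max(u[idx]))
    p[idx] <- e / sum(e)
  }
  p
}

#' Sample inter-spike intervals of a WTA group
#'
#' Spike opportunities of each group form a homogeneous Poisson process
#' with rate `R`; intervals are exponential with mean `1000 / R` ms.
#'
#' @param R group rate (Hz).
#' @param n number of draws.
#' @return inter-spike intervals (ms).
#' @export
sample_isi <- function(R, n = 1) {
  stopifnot(R > 0)
  rexp(n, rate = R / 1000)
}

#' Advance the circuit by one spike event (reference implementation)
#'
#' Samples the next spike opportunity among the WTA groups, decays all
#' traces in closed form to that time (integrating any afferent spikes that
#' fall in the interval at their exact times), draws the winner from the
#' softmax of the membrane potentials, registers its delayed lateral EPSP
#' and returns the per-step input log-likelihood contribution (the
#' "surprise", see [instantaneous_input_loglik()]).
#'
#' This is the plain-R reference path; [run_network()] uses an equivalent
#' compiled event loop.
#'
#' @param params a [network_params()].
#' @param state a [network_state()].
#' @param input optional [spike_train()] or data.frame with columns
#'   `time`, `channel`; only events in `(state$time, t_spike]` are consumed.
#' @return list with `spike` (time, neuron, group), the new `state`, and
#'   `step_loglik`.
#' @export
network_step <- function(params, state, input = NULL) {
  G <- params$n_groups
  for (g in seq_len(G))
    if (is.na(state$next_t[g]))
      state$next_t[g] <- state$time + sample_isi(params$R)
  g <- which.min(state$next_t)
  tn <- state$next_t[g]

  ev <- input_events(input)
  ev <- ev[ev$time > state$time & ev$time <= tn, , drop = FALSE]
  state <- advance_state(params, state, tn, ev)

  u <- membrane_potentials(params, state)
  idx <- which(params$groups == g)
  uff <- as.vector(params$W[idx, , drop = FALSE] %*%
                   state_traces(params, state)$x) + params$b[idx]
  ulat <- u[idx] - uff + params$b[idx]
  pg <- winner_distribution(u[idx])
  k <- idx[sample.int(length(idx), 1, prob = pg)]
  step_loglik <- logsumexp(u[idx]) - logsumexp(uff) - logsumexp(ulat) +
    logsumexp(params$b[idx])

  state$last_spike[k] <- tn
  state$last_winner[g] <- k
  state$pend_t <- c(state$pend_t, tn + params$kernel_lat$delay)
  state$pend_n <- c(state$pend_n, k)
  state$next_t[g] <- tn + sample_isi(params$R)
  list(spike = list(time = tn, neuron = k, group = g),
       state = state, step_loglik = step_loglik)
}

# decay state traces to `to`, integrating the supplied afferent events and
# any matured delayed lateral spikes (exact closed-form updates)
advance_state <- function(params, state, to, events) {
  if (to < state$time) stop("time reversal")
  kf <- params$kernel_ff; kl <- params$kernel_lat
  dt <- to - state$time
  state$xp <- state$xp * exp(-dt / kf$tau_decay)
  state$yp <- state$yp * exp(-dt / kl$tau_decay)
  if (kf$family == "double_exp")
    state$xq <- state$xq * exp(-dt / kf$tau_rise)
  if (kl$family == "double_exp")
    state$yq <- state$yq * exp(-dt / kl$tau_rise)
  if (nrow(events)) {
    age <- to - events$time
    add <- vapply(split(exp(-age / kf$tau_decay), events$channel), sum, 0)
    i <- as.integer(names(add))
    state$xp[i] <- state$xp[i] + add
    if (kf$family == "double_exp") {
      addq <- vapply(split(exp(-age / kf$tau_rise), events$channel), sum, 0)
      state$xq[i] <- state$xq[i] + addq
    }
  }
  mat <- state$pend_t <= to
  if (any(mat)) {
    age <- to - state$pend_t[mat]
    add <- vapply(split(exp(-age / kl$tau_decay), state$pend_n[mat]), sum, 0)
    i <- as.integer(names(add))
    state$yp[i] <- state$yp[i] + add
    if (kl$family == "double_exp") {
      addq <- vapply(split(exp(-age / kl$tau_rise), state$pend_n[mat]),
                     sum, 0)
      state$yq[i] <- state$yq[i] + addq
    }
    state$pend_t <- state$pend_t[!mat]
    state$pend_n <- state$pend_n[!mat]
  }
  state$time <- to
  state
}

input_events <- function(input) {
  if (is.null(input))
    return(data.frame(time = numeric(0), channel = integer(0)))
  if (inherits(input, "spike_train"))
    return(data.frame(time = input$time, channel = input$channel))
  stopifnot(is.data.frame(input), all(c("time", "channel") %in% names(input)))
  input
}

#' Run the circuit over a time window
#'
#' Full event-driven simulation: in `evoked` mode the supplied afferent
#' spike train drives the circuit; in `free` mode no afferent spikes arrive
#' and the circuit runs on its lateral connections alone (existing traces
#' keep decaying).  Optionally applies online STDP or accumulates synaptic
#' tags (see [train_session()] for the learning loops).
#'
#' @param params a [network_params()].
#' @param input a [spike_train()] of afferent events, or `NULL`.
#' @param duration simulated time (ms), counted from `state$time`.
#' @param mode `"evoked"` or `"free"` (forces the input off).
#' @param state optional starting [network_state()] (default: fresh reset).
#' @param learn optional [learn_config()]; `NULL` freezes the weights.
#' @param engine `"cpp"` (default) or `"r"` (reference loop).
#' @return list with `spikes` (a [spike_train()] of circuit spikes, with a
#'   per-spike `group` attribute), `surprise` (data.frame `time`, `group`,
#'   `value`: the per-step input log-likelihood trace), the final `state`,
#'   and — when learning — updated `params` and the accumulated `tags`.
#' @export
run_network <- function(params, input = NULL, duration,
                        mode = c("evoked", "free"), state = NULL,
                        learn = NULL, engine = c("cpp", "r")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  if (is.null(state)) state <- network_state(params)
  if (mode == "free") input <- NULL
  t_end <- state$time + duration

  if (engine == "r") {
    stopifnot(is.null(learn))
    times <- numeric(0); neurons <- integer(0); grp <- integer(0)
    surp <- numeric(0)
    repeat {
      st <- network_step(params, state, input)
      if (st$spike$time > t_end) break
      state <- st$state
      times <- c(times, st$spike$time)
      neurons <- c(neurons, st$spike$neuron)
      grp <- c(grp, st$spike$group)
      surp <- c(surp, st$step_loglik)
    }
    ev <- input_events(input)
    state <- advance_state(params, state, t_end,
                           ev[ev$time > state$time & ev$time <= t_end, ,
                              drop = FALSE])
    return(list(
      spikes = spike_train(times, neurons, duration = t_end,
                           n_channels = params$n_neurons,
                           groups = grp),
      surprise = data.frame(time = times, group = grp, value = surp),
      state = state, params = params))
  }

  lc <- learn_cfg_cpp(learn, params)
  ev <- input_events(input)
  ev <- ev[ev$time > state$time & ev$time <= t_end, , drop = FALSE]
  ev <- ev[order(ev$time), , drop = FALSE]
  res <- sim_run_cpp(params$W, params$V, params$b, params$groups, params$R,
                     kernel_cfg(params), unclass(state),
                     ev$time, as.integer(ev$channel), t_end, lc)
  out_state <- structure(res$state, class = "network_state")
  out_params <- params
  out_params$W <- res$W; out_params$V <- res$V; out_params$b <- res$b
  list(spikes = spike_train(res$spike_t, res$spike_n, duration = t_end,
                            n_channels = params$n_neurons,
                            groups = res$spike_g),
       surprise = data.frame(time = res$spike_t, group = res$spike_g,
                             value = res$surprise),
       state = out_state, params = out_params,
       tags = if (!is.null(learn) && learn$mode %in% c("rejection",
                                                       "importance"))
         list(dW = res$W_tag - params$W, dV = res$V_tag - params$V))
}

learn_cfg_cpp <- function(learn, params) {
  if (is.null(learn))
    return(list(mode = 0L, eta = 0, floor = -10, exclude_self = TRUE,
                homeostasis = FALSE))
  list(mode = switch(learn$mode, none = 0L, forward = 1L, rejection = 2L,
                     importance = 2L),
       eta = learn$eta, floor = learn$floor,
       exclude_self = learn$exclude_self && params$mode == "continuous",
       homeostasis = isTRUE(learn$homeostasis),
       eta_b = learn$eta_b, target_rate = learn$target_rate,
       rate_window = learn$rate_window)
}

#' Instantaneous input log-likelihood ("surprise")
#'
#' The probability of the current afferent activity given the previous
#' network state, `log p(x_t | y_{t-1})`, with the feedforward-only
#' baseline subtracted so that fluctuations injected by the afferent
#' synapses alone cancel: `logsumexp(W x + V y + b) - logsumexp(W x + b)`,
#' per WTA group, summed over groups.  Large negative values signal
#' surprise — afferent input the lateral prediction did not anticipate.
#'
#' For a discrete-mode network (or a [discrete_hmm()]) with previous winner
#' `j` and observed symbol `l`, the unsubtracted quantity is exactly the
#' categorical probability `log sum_k T[j,k] E[k,l]` of the mapped HMM; use
#' `baseline = FALSE` to obtain it.
#'
#' @param params a [network_params()] or [discrete_hmm()].
#' @param state a [network_state()] (continuous mode), or the previous
#'   winner index / `NA` at sequence start (discrete mode).
#' @param x afferent trace values (continuous mode) or an observed symbol
#'   index (discrete mode).
#' @param baseline subtract the feedforward-only baseline? (default `TRUE`
#'   in continuous mode, `FALSE` in discrete mode)
#' @return a single log-likelihood value.
#' @export
instantaneous_input_loglik <- function(params, state, x, baseline = NULL) {
  if (inherits(params, "discrete_hmm") ||
      (inherits(params, "network_params") && params$mode == "discrete")) {
    hmm <- if (inherits(params, "discrete_hmm")) params
           else map_network_to_hmm(params)
    j <- if (is.list(state)) state$last_winner[1] else state
    l <- as.integer(x)
    pr <- if (is.na(j) || j < 1) hmm$pi else hmm$T[j, ]
    val <- log(sum(pr * hmm$E[, l]))
    if (isTRUE(baseline)) val <- val - log(mean(hmm$E[, l]))
    return(val)
  }
  tr <- state_traces(params, state)
  xv <- if (missing(x) || is.null(x)) tr$x else x
  refr <- refr_term(params, state)
  uff <- as.vector(params$W %*% xv) + params$b
  ulat <- as.vector(params$V %*% tr$y) + params$b - refr
  u <- uff + ulat - params$b
  if (is.null(baseline)) baseline <- TRUE
  tot <- 0
  for (g in seq_len(params$n_groups)) {
    idx <- which(params$groups == g)
    tot <- tot + logsumexp(u[idx]) -
      if (baseline) logsumexp(uff[idx]) + logsumexp(ulat[idx]) -
        logsumexp(params$b[idx]) else 0
  }
  tot
}
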