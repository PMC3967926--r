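#' Postsynaptic-response and refractory kernels
#'
#' A kernel specification describes the time course of the excitatory
#' postsynaptic potential (EPSP) evoked by a single presynaptic spike, or of
#' the refractory variable subtracted from a neuron's membrane potential
#' after its own spike.  Four families are supported:
#'
#' * `single_exp`: `amplitude * exp(-t / tau_decay)`, onset amplitude 1 by
#'   default (the kernel of the theoretical analysis),
#' * `double_exp`: difference of exponentials with decay `tau_decay` and
#'   rise `tau_rise`, scaled so the peak equals `amplitude`,
#' * `rect`: `amplitude` on `[0, width)`, used in discrete-time mode where
#'   the kernel width equals the fixed inter-spike interval,
#' * `refractory`: `amplitude * exp(-t / tau_decay)`; its value is
#'   *subtracted* from the membrane potential of the neuron that spiked.
#'
#' All kernels are causal: the value is 0 for negative time arguments.
#' `delay` shifts the whole kernel; it is used for lateral synapses (a spike
#' becomes visible in the postsynaptic trace only `delay` ms later).
#'
#' @param family one of `"single_exp"`, `"double_exp"`, `"rect"`,
#'   `"refractory"`.
#' @param tau_decay decay time constant (ms).
#' @param tau_rise rise time constant (ms), `double_exp` only.
#' @param width kernel width (ms), `rect` only.
#' @param amplitude kernel amplitude (dimensionless); for `double_exp` the
#'   peak value.
#' @param delay synaptic delay (ms).
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("single_exp", "double_exp", "rect",
                                   "refractory"),
                        tau_decay = 20, tau_rise = 2, width = 50,
                        amplitude = 1, delay = 0) {
  family <- match.arg(family)
  stopifnot(tau_decay > 0, tau_rise > 0, width > 0, amplitude > 0,
            delay >= 0)
  if (family == "double_exp" && tau_rise >= tau_decay)
    stop("double_exp requires tau_rise < tau_decay")
  spec <- list(family = family, tau_decay = tau_decay, tau_rise = tau_rise,
               width = width, amplitude = amplitude, delay = delay)
  if (family == "double_exp") {
    tpk <- tau_rise * tau_decay / (tau_decay - tau_rise) *
      log(tau_decay / tau_rise)
    spec$scale <- amplitude /
      (exp(-tpk / tau_decay) - exp(-tpk / tau_rise))
    spec$t_peak <- tpk
  } else {
    spec$scale <- amplitude
  }
  structure(spec, class = "kernel_spec")
}

#' Evaluate a kernel at given times since the presynaptic spike
#'
#' @param spec a [kernel_spec()].
#' @param t_since time since the spike (ms); vectorized.  The configured
#'   `delay` is *not* applied here: `t_since` is measured from kernel onset.
#' @return kernel values (0 for negative `t_since`).  For the `refractory`
#'   family the returned value is the amount subtracted from the membrane
#'   potential.
#' @export
evaluate_kernel <- function(spec, t_since) {
  stopifnot(inherits(spec, "kernel_spec"), all(is.finite(t_since)))
  v <- switch(spec$family,
    single_exp = ,
    refractory = spec$amplitude * exp(-t_since / spec$tau_decay),
    double_exp = spec$scale * (exp(-t_since / spec$tau_decay) -
                               exp(-t_since / spec$tau_rise)),
    rect = ifelse(t_since < spec$width, spec$amplitude, 0))
  v[t_since < 0] <- 0
  v
}

#' Create a synaptic trace vector
#'
#' A trace vector holds, for `n` presynaptic channels, the summed EPSP time
#' courses evoked by all past spikes on each channel.  Between events it is
#' advanced in closed form (exponential decay of the kernel components); no
#' numeric integration is involved.  Exponential-family kernels are stored
#' as a difference of two decaying components; `rect` kernels keep the
#' recent event times instead.
#'
#' @param n number of channels.
#' @param spec the [kernel_spec()] shared by all channels.
#' @param time initial timestamp (ms).
#' @return an object of class `trace_vector`.
#' @export
trace_vector <- function(n, spec = kernel_spec("single_exp"), time = 0) {
  structure(list(n = n, spec = spec, time = time,
                 p = numeric(n), q = numeric(n),
                 pend_t = numeric(0), pend_ch = integer(0)),
            class = "trace_vector")
}

#' Advance a trace vector to a new time and register spikes
#'
#' All channels are decayed in closed form to `new_time`; each channel in
#' `spike_channels` (a multiset: repeats count) then receives one kernel
#' onset *at* `new_time`.  If the kernel has a synaptic `delay`, a
#' registered spike only becomes visible in the trace `delay` ms later;
#' delayed spikes that mature within the advanced interval are integrated
#' at their exact arrival times.
#'
#' @param trace a [trace_vector()].
#' @param new_time target time (ms); must be `>= trace$time`.
#' @param spike_channels integer vector of spiking channel indices (possibly
#'   with repeats, possibly empty).
#' @return the updated `trace_vector`.
#' @export
decay_and_increment <- function(trace, new_time, spike_channels = integer(0)) {
  stopifnot(inherits(trace, "trace_vector"))
  if (new_time < trace$time) stop("time reversal: new_time < trace timestamp")
  spec <- trace$spec
  spike_channels <- as.integer(spike_channels)
  if (length(spike_channels) &&
      (any(spike_channels < 1) || any(spike_channels > trace$n)))
    stop("spike channel out of range")

  # queue new spikes at their effective (delayed) arrival times
  trace$pend_t <- c(trace$pend_t, rep(new_time + spec$delay,
                                      length(spike_channels)))
  trace$pend_ch <- c(trace$pend_ch, spike_channels)

  mature <- trace$pend_t <= new_time
  if (spec$family == "rect") {
    # keep raw event times; drop expired ones
    keep <- !mature | (new_time - trace$pend_t < spec$width)
    trace$pend_t <- trace$pend_t[keep]
    trace$pend_ch <- trace$pend_ch[keep]
    trace$time <- new_time
    return(trace)
  }

  dt <- new_time - trace$time
  trace$p <- trace$p * exp(-dt / spec$tau_decay)
  if (spec$family == "double_exp")
    trace$q <- trace$q * exp(-dt / spec$tau_rise)
  if (any(mature)) {
    age <- new_time - trace$pend_t[mature]
    ch <- trace$pend_ch[mature]
    inc_p <- vapply(split(exp(-age / spec$tau_decay), ch), sum, 0)
    idx <- as.integer(names(inc_p))
    trace$p[idx] <- trace$p[idx] + inc_p
    if (spec$family == "double_exp") {
      inc_q <- vapply(split(exp(-age / spec$tau_rise), ch), sum, 0)
      trace$q[idx] <- trace$q[idx] + inc_q
    }
    trace$pend_t <- trace$pend_t[!mature]
    trace$pend_ch <- trace$pend_ch[!mature]
  }
  trace$time <- new_time
  trace
}

#' Current values of a trace vector
#'
#' @param trace a [trace_vector()].
#' @return numeric vector of per-channel trace values at `trace$time`.
#' @export
trace_values <- function(trace) {
  spec <- trace$spec
  if (spec$family == "rect") {
    v <- numeric(trace$n)
    live <- trace$pend_t <= trace$time &
      (trace$time - trace$pend_t) < spec$width
    if (any(live)) {
      cnt <- table(trace$pend_ch[live])
      v[as.integer(names(cnt))] <- spec$amplitude * as.numeric(cnt)
    }
    return(v)
  }
  if (spec$family == "double_exp") spec$scale * (trace$p - trace$q)
  else spec$amplitude * trace$p
}
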