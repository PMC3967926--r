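#' Spike trains as ordered event lists
#'
#' A spike train is a time-sorted list of `(time, channel)` events together
#' with its duration and channel count.  Circuit output trains additionally
#' carry the WTA group of each spike.
#'
#' @param time event times (ms).
#' @param channel integer channel / neuron ids (1-based).
#' @param duration train duration (ms).
#' @param n_channels number of channels.
#' @param groups optional per-event group ids.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(time = numeric(0), channel = integer(0),
                        duration, n_channels, groups = NULL) {
  stopifnot(length(time) == length(channel), duration >= 0, n_channels >= 1)
  channel <- as.integer(channel)
  if (length(channel) && (min(channel) < 1 || max(channel) > n_channels))
    stop("channel id out of range")
  o <- order(time)
  structure(list(time = time[o], channel = channel[o],
                 groups = if (!is.null(groups)) as.integer(groups)[o],
                 duration = duration, n_channels = n_channels),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d events, %d channels, %.1f ms\n",
              length(x$time), x$n_channels, x$duration))
  invisible(x)
}

#' @export
as.data.frame.spike_train <- function(x, ...) {
  data.frame(time = x$time, channel = x$channel)
}

#' Number of spikes per channel
#' @param x a [spike_train()].
#' @return integer vector of length `n_channels`.
#' @export
spike_counts <- function(x) {
  tabulate(x$channel, nbins = x$n_channels)
}

#' Write / read a spike train as CSV plus JSON sidecar
#'
#' The CSV holds two columns (`time_ms`, `channel`); the sidecar
#' `<path>.json` records duration and channel count.
#'
#' @param x a [spike_train()].
#' @param path CSV file path.
#' @return `write_spike_train` returns `path` invisibly;
#'   `read_spike_train` returns a [spike_train()].
#' @export
write_spike_train <- function(x, path) {
  stopifnot(inherits(x, "spike_train"))
  write.csv(data.frame(time_ms = x$time, channel = x$channel),
            path, row.names = FALSE)
  jsonlite::write_json(list(duration_ms = x$duration,
                            n_channels = x$n_channels),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  d <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  spike_train(d$time_ms, d$channel, duration = meta$duration_ms,
              n_channels = meta$n_channels)
}

#' Write / read network parameters as plain text
#'
#' Dense text serialization of the weight matrices, excitabilities and the
#' scalar configuration of a [network_params()] object.
#'
#' @param params a [network_params()].
#' @param path file path.
#' @export
write_network_params <- function(params, path) {
  obj <- list(n_afferents = params$n_afferents,
              n_neurons = params$n_neurons, R = params$R,
              groups = params$groups, mode = params$mode,
              W = params$W, V = params$V, b = params$b,
              kernel_ff = unclass(params$kernel_ff),
              kernel_lat = unclass(params$kernel_lat),
              kernel_refr = unclass(params$kernel_refr))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_network_params
#' @export
read_network_params <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(k) kernel_spec(k$family, k$tau_decay, k$tau_rise,
                                k$width, k$amplitude, k$delay)
  network_params(o$n_afferents, o$n_neurons, R = o$R, groups = o$groups,
                 W = matrix(o$W, o$n_neurons, o$n_afferents),
                 V = matrix(o$V, o$n_neurons, o$n_neurons),
                 b = o$b, kernel_ff = mk(o$kernel_ff),
                 kernel_lat = mk(o$kernel_lat),
                 kernel_refr = mk(o$kernel_refr), mode = o$mode)
}
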