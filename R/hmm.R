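#' Discrete hidden Markov model
#'
#' Standard discrete-observation HMM with `K` hidden states and an alphabet
#' of `L` symbols: initial distribution `pi`, transition table `T`
#' (`T[j, k] = p(z_n = k | z_{n-1} = j)`) and emission table `E`
#' (`E[k, l] = p(x = l | z = k)`).
#'
#' @param pi initial state distribution (length K).
#' @param T K x K transition table, rows summing to 1.
#' @param E K x L emission table, rows summing to 1.
#' @return an object of class `discrete_hmm`.
#' @export
discrete_hmm <- function(pi, T, E) {
  pi <- as.numeric(pi); T <- as.matrix(T); E <- as.matrix(E)
  K <- length(pi)
  stopifnot(nrow(T) == K, ncol(T) == K, nrow(E) == K)
  if (any(pi < 0) || any(T < 0) || any(E < 0))
    stop("probabilities must be nonnegative")
  if (abs(sum(pi) - 1) > 1e-12 ||
      any(abs(rowSums(T) - 1) > 1e-12) ||
      any(abs(rowSums(E) - 1) > 1e-12))
    stop("pi and all rows of T and E must sum to 1 (tol 1e-12)")
  structure(list(K = K, L = ncol(E), pi = pi, T = T, E = E),
            class = "discrete_hmm")
}

#' @export
print.discrete_hmm <- function(x, ...) {
  cat(sprintf("<discrete_hmm> K = %d states, L = %d symbols\n", x$K, x$L))
  invisible(x)
}

#' Sample a random teacher HMM
#'
#' Every entry of the initial, transition and emission tables is an
#' independent Beta draw; rows are then renormalized.  Symmetric Beta
#' parameters give rows that are uniform in expectation.
#'
#' @param K number of hidden states.
#' @param L alphabet size.
#' @param beta_a,beta_b Beta shape parameters.
#' @return a [discrete_hmm()].
#' @export
sample_teacher_hmm <- function(K = 4, L = 8, beta_a = 0.5, beta_b = 0.5) {
  stopifnot(K >= 1, L >= 1, beta_a > 0, beta_b > 0)
  norm <- function(m) m / rowSums(m)
  pi <- rbeta(K, beta_a, beta_b); pi <- pi / sum(pi)
  T <- norm(matrix(rbeta(K * K, beta_a, beta_b), K, K))
  E <- norm(matrix(rbeta(K * L, beta_a, beta_b), K, L))
  discrete_hmm(pi, T, E)
}

#' Generate observation sequences by ancestral sampling
#'
#' @param hmm a [discrete_hmm()].
#' @param n_sequences number of sequences.
#' @param length sequence length T.
#' @param return_states also return the latent paths?
#' @return list of integer symbol vectors; with `return_states = TRUE` a
#'   list with elements `observations` and `states`.
#' @export
generate_observations <- function(hmm, n_sequences, length,
                                  return_states = FALSE) {
  stopifnot(n_sequences >= 1, length >= 1)
  Z <- matrix(0L, n_sequences, length)
  X <- matrix(0L, n_sequences, length)
  draw <- function(p) sample.int(base::length(p), 1, prob = p)
  for (s in seq_len(n_sequences)) {
    z <- draw(hmm$pi)
    for (n in seq_len(length)) {
      if (n > 1) z <- draw(hmm$T[z, ])
      Z[s, n] <- z
      X[s, n] <- draw(hmm$E[z, ])
    }
  }
  obs <- lapply(seq_len(n_sequences), function(s) X[s, ])
  if (return_states)
    list(observations = obs,
         states = lapply(seq_len(n_sequences), function(s) Z[s, ]))
  else obs
}

#' Exact sequence log-likelihood via the scaled forward algorithm
#'
#' @param hmm a [discrete_hmm()].
#' @param sequence integer symbol vector (1-based).
#' @return `log p(x_1..x_T)`.
#' @export
exact_forward_loglik <- function(hmm, sequence) {
  sequence <- as.integer(sequence)
  stopifnot(all(sequence >= 1), all(sequence <= hmm$L))
  alpha <- hmm$pi * hmm$E[, sequence[1]]
  ll <- 0
  for (n in seq_along(sequence)) {
    if (n > 1) alpha <- as.vector(crossprod(hmm$T, alpha)) *
        hmm$E[, sequence[n]]
    s <- sum(alpha)
    if (s == 0) return(-Inf)
    ll <- ll + log(s)
    alpha <- alpha / s
  }
  ll
}

# epsilon-floored copy (held-out evaluation of fitted models: unseen
# symbols must not yield -Inf)
floor_hmm <- function(hmm, eps = 1e-4) {
  nf <- function(m) { m <- pmax(m, eps); m / rowSums(m) }
  pi <- pmax(hmm$pi, eps)
  discrete_hmm(pi / sum(pi), nf(hmm$T), nf(hmm$E))
}

# probability-space average of several HMMs with aligned states (e.g.
# checkpoints of one training run)
average_hmms <- function(hmms) {
  K <- hmms[[1]]$K
  discrete_hmm(rowMeans(vapply(hmms, `[[`, numeric(K), "pi")),
               Reduce(`+`, lapply(hmms, `[[`, "T")) / length(hmms),
               Reduce(`+`, lapply(hmms, `[[`, "E")) / length(hmms))
}

# forward over many equal-length sequences at once (rows of `X`)
forward_loglik_many <- function(hmm, X) {
  X <- do.call(rbind, lapply(X, as.integer))
  n <- nrow(X); T_len <- ncol(X)
  alpha <- matrix(hmm$pi, n, hmm$K, byrow = TRUE) *
    t(hmm$E[, X[, 1], drop = FALSE])
  ll <- numeric(n)
  for (t in seq_len(T_len)) {
    if (t > 1)
      alpha <- (alpha %*% hmm$T) * t(hmm$E[, X[, t], drop = FALSE])
    s <- rowSums(alpha)
    ll <- ll + log(s)
    alpha <- alpha / s
  }
  ll
}

#' Batch Baum-Welch (EM) fitting
#'
#' Classic batch EM over all sequences per epoch, with per-step scaling to
#' prevent underflow.  The training log-likelihood is non-decreasing across
#' epochs (up to floating point).
#'
#' @param hmm starting [discrete_hmm()].
#' @param sequences list of integer symbol vectors.
#' @param epochs number of EM iterations.
#' @return list with the fitted `hmm` and `loglik`, the total training
#'   log-likelihood after each epoch.
#' @export
baum_welch_fit <- function(hmm, sequences, epochs) {
  stopifnot(length(sequences) >= 1, epochs >= 0)
  K <- hmm$K; L <- hmm$L
  ll_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    pi_acc <- numeric(K)
    T_acc <- matrix(0, K, K)
    E_acc <- matrix(0, K, L)
    total_ll <- 0
    for (x in sequences) {
      x <- as.integer(x); Tn <- length(x)
      alpha <- matrix(0, Tn, K); beta <- matrix(0, Tn, K)
      cs <- numeric(Tn)
      a <- hmm$pi * hmm$E[, x[1]]
      cs[1] <- sum(a); alpha[1, ] <- a / cs[1]
      if (Tn > 1) for (n in 2:Tn) {
        a <- as.vector(crossprod(hmm$T, alpha[n - 1, ])) * hmm$E[, x[n]]
        cs[n] <- sum(a); alpha[n, ] <- a / cs[n]
      }
      beta[Tn, ] <- 1
      if (Tn > 1) for (n in (Tn - 1):1)
        beta[n, ] <- as.vector(hmm$T %*% (hmm$E[, x[n + 1]] *
                                          beta[n + 1, ])) / cs[n + 1]
      gamma <- alpha * beta
      pi_acc <- pi_acc + gamma[1, ]
      for (n in seq_len(Tn))
        E_acc[, x[n]] <- E_acc[, x[n]] + gamma[n, ]
      if (Tn > 1) for (n in 2:Tn)
        T_acc <- T_acc + (alpha[n - 1, ] %o% (hmm$E[, x[n]] *
                                              beta[n, ])) * hmm$T / cs[n]
      total_ll <- total_ll + sum(log(cs))
    }
    ll_trace[ep] <- total_ll
    safe_norm <- function(m) {
      rs <- rowSums(m)
      bad <- rs == 0
      m[bad, ] <- 1
      m / rowSums(m)
    }
    hmm <- discrete_hmm(pi_acc / sum(pi_acc), safe_norm(T_acc),
                        safe_norm(E_acc))
  }
  list(hmm = hmm, loglik = ll_trace)
}

#' Map between a discrete-time network and a standard HMM
#'
#' In discrete-time mode (fixed inter-spike interval, rectangular EPSP
#' kernels of the same length) the WTA circuit is exactly a discrete HMM:
#' the per-step winner conditional is
#' `p(y_n = k | y_{n-1} = j, x_n = l) = softmax_k(W[k,l] + V[k,j] + b_k)`.
#' The corresponding HMM tables are
#' `T[j, k] = exp(V[k,j] + b_k) / sum_k'`,
#' `E[k, l] = exp(W[k,l]) / sum_l'`, and
#' `pi_k = exp(b_k) * sum_l exp(W[k,l]) / norm` — chosen so that the
#' network's one-step conditionals and the mapped HMM's forward-sampling
#' conditionals agree exactly whenever the feedforward rows are normalized
#' (`sum_l exp(W[k,l])` constant in `k`), the condition that emerges
#' automatically from the STDP rule.  The round trip hmm -> network -> hmm
#' is exact.
#'
#' @param params a discrete-mode [network_params()].
#' @return `map_network_to_hmm`: a [discrete_hmm()].
#' @export
map_network_to_hmm <- function(params) {
  stopifnot(inherits(params, "network_params"), params$mode == "discrete")
  eW <- exp(params$W)
  s <- rowSums(eW)
  E <- eW / s
  eV <- exp(t(params$V) + rep(params$b, each = params$n_neurons))
  T <- eV / rowSums(eV)
  pi <- exp(params$b) * s
  discrete_hmm(pi / sum(pi), T, E)
}

#' @rdname map_network_to_hmm
#' @param hmm a [discrete_hmm()].
#' @param isi the fixed inter-spike interval = rectangular kernel width
#'   (ms), only relevant when the discrete-time network is rendered in
#'   real time.
#' @return `map_hmm_to_network`: a discrete-mode [network_params()].
#' @export
map_hmm_to_network <- function(hmm, isi = 50) {
  rect <- kernel_spec("rect", width = isi)
  # b carries log pi and contributes to *every* step's softmax, so the
  # lateral weights absorb -b to leave the step conditional at T * E.
  # log(0) is clamped to keep V + b finite (the shift cancels exactly).
  b <- pmax(log(hmm$pi), -700)
  network_params(n_afferents = hmm$L, n_neurons = hmm$K,
                 R = 1000 / isi,
                 W = log(hmm$E), V = t(log(hmm$T)) - b,
                 b = b,
                 kernel_ff = rect, kernel_lat = rect,
                 kernel_refr = kernel_spec("refractory"),
                 mode = "discrete")
}

#' One-step winner conditionals of a discrete-time network
#'
#' `p(y_n = k | y_{n-1} = j, x_n = l)` for every state pair, as a
#' `K x K x L` array (`[j, k, l]`); `j = 0` (sequence start, zero lateral
#' trace) is returned in the attribute `initial` (`K x L`, `[k, l]`).
#'
#' @param params a discrete-mode [network_params()].
#' @export
network_step_conditionals <- function(params) {
  stopifnot(params$mode == "discrete")
  K <- params$n_neurons; L <- params$n_afferents
  out <- array(0, c(K, K, L))
  init <- matrix(0, K, L)
  for (l in seq_len(L)) {
    u0 <- params$W[, l] + params$b
    init[, l] <- exp(u0 - logsumexp(u0))
    for (j in seq_len(K)) {
      u <- u0 + params$V[, j]
      out[j, , l] <- exp(u - logsumexp(u))
    }
  }
  attr(out, "initial") <- init
  out
}

# forward-sampling conditionals of an HMM: p(z_n = k | z_{n-1} = j, x_n = l)
hmm_step_conditionals <- function(hmm) {
  K <- hmm$K; L <- hmm$L
  out <- array(0, c(K, K, L))
  init <- matrix(0, K, L)
  for (l in seq_len(L)) {
    w0 <- hmm$pi * hmm$E[, l]
    init[, l] <- w0 / sum(w0)
    for (j in seq_len(K)) {
      w <- hmm$T[j, ] * hmm$E[, l]
      out[j, , l] <- w / sum(w)
    }
  }
  attr(out, "initial") <- init
  out
}

#' Approximate a sequence log-likelihood by forward sampling
#'
#' Samples `S` hidden paths from the forward-sampling proposal and returns
#' the log of the mean importance weight.  `S = 1` is the one-sample
#' statistic used for grammaticality classification; as `S` grows the
#' estimate converges to the exact forward log-likelihood.
#'
#' @param model a [discrete_hmm()] or discrete-mode [network_params()].
#' @param x integer symbol sequence.
#' @param S number of sampled paths.
#' @return approximate `log p(x)`.
#' @export
approx_loglik_by_sampling <- function(model, x, S = 1) {
  stopifnot(S >= 1)
  if (inherits(model, "network_params")) model <- map_network_to_hmm(model)
  stopifnot(inherits(model, "discrete_hmm"))
  net <- map_hmm_to_network(model)
  res <- sample_paths_cpp(net$W, net$V, net$b, as.integer(x), as.integer(S),
                          FALSE)
  logsumexp(res$logw) - log(S)
}
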