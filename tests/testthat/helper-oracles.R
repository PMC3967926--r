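# brute-force oracles shared across tests

# all K^T hidden paths of an HMM with their joint probabilities for a fixed
# observation sequence
enumerate_paths <- function(hmm, x) {
  Tn <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(hmm$K)), Tn)))
  colnames(paths) <- NULL
  joint <- apply(paths, 1, function(z) {
    p <- hmm$pi[z[1]] * hmm$E[z[1], x[1]]
    if (Tn > 1) for (n in 2:Tn)
      p <- p * hmm$T[z[n - 1], z[n]] * hmm$E[z[n], x[n]]
    p
  })
  list(paths = paths, joint = joint, posterior = joint / sum(joint),
       key = apply(paths, 1, paste, collapse = "-"))
}

path_keys <- function(m) apply(m, 1, paste, collapse = "-")

# direct kernel-sum evaluation of a trace: sum the kernel over all past
# spikes, channel-wise (the definition the closed-form updates must match)
kernel_sum_trace <- function(spec, events, t, n_channels) {
  v <- numeric(n_channels)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      dt <- t - events$time[i] - spec$delay
      v[events$channel[i]] <- v[events$channel[i]] +
        evaluate_kernel(spec, dt)
    }
  }
  v
}

# best-permutation total-variation distance between emission tables
best_perm_tv <- function(E_hat, E_ref) {
  K <- nrow(E_ref)
  perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == K), ,
                 drop = FALSE]
  min(apply(perms, 1, function(p)
    max(rowSums(abs(E_hat[p, , drop = FALSE] - E_ref)) / 2)))
}

# epsilon-floored copy of an HMM for held-out evaluation
floored <- function(h, eps = 1e-4) {
  nf <- function(m) { m <- pmax(m, eps); m / rowSums(m) }
  discrete_hmm(pmax(h$pi, eps) / sum(pmax(h$pi, eps)), nf(h$T), nf(h$E))
}
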