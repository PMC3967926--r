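#' Peri-event time histogram (PETH)
#'
#' Bins each trial's spikes (default 1 ms bins), smooths with a Gaussian
#' filter and averages over trials, returning rate estimates in Hz per
#' neuron and time bin.  The smoothing kernel is normalized per source bin
#' (edge-corrected), so the total spike mass is conserved exactly:
#' `sum(rates) * bin / 1000 * n_trials = total spike count`.
#'
#' @param trials list of aligned [spike_train()]s of equal duration.
#' @param bin_ms bin width (ms).
#' @param sigma_ms Gaussian smoothing width (ms); 0 disables smoothing.
#' @return an object of class `peth_matrix`: `rates` (neurons x bins, Hz),
#'   `bin_ms`, `sigma_ms`, `time` (bin centers), `n_trials`.
#' @export
peth <- function(trials, bin_ms = 1, sigma_ms = 10) {
  stopifnot(length(trials) >= 1, bin_ms > 0)
  dur <- trials[[1]]$duration
  K <- trials[[1]]$n_channels
  for (tr in trials)
    stopifnot(inherits(tr, "spike_train"),
              abs(tr$duration - dur) < 1e-9, tr$n_channels == K)
  nb <- max(1L, as.integer(ceiling(dur / bin_ms - 1e-9)))
  counts <- matrix(0, K, nb)
  for (tr in trials) {
    if (!length(tr$time)) next
    bins <- pmin(nb, pmax(1L, as.integer(floor(tr$time / bin_ms)) + 1L))
    for (i in seq_along(bins))
      counts[tr$channel[i], bins[i]] <- counts[tr$channel[i], bins[i]] + 1
  }
  if (sigma_ms > 0 && nb > 1) {
    half <- max(1L, as.integer(ceiling(4 * sigma_ms / bin_ms)))
    kern <- exp(-((-half:half) * bin_ms)^2 / (2 * sigma_ms^2))
    sm <- matrix(0, K, nb)
    # per-source normalization conserves mass at the edges
    norm <- vapply(seq_len(nb), function(s) {
      idx <- (s - half):(s + half)
      sum(kern[idx >= 1 & idx <= nb])
    }, 0)
    for (s in seq_len(nb)) {
      idx <- (s - half):(s + half)
      ok <- idx >= 1 & idx <= nb
      sm[, idx[ok]] <- sm[, idx[ok]] +
        counts[, s] %o% (kern[ok] / norm[s])
    }
    counts <- sm
  }
  rates <- counts / length(trials) / (bin_ms / 1000)
  structure(list(rates = rates, bin_ms = bin_ms, sigma_ms = sigma_ms,
                 time = (seq_len(nb) - 0.5) * bin_ms,
                 n_trials = length(trials)),
            class = "peth_matrix")
}

#' @export
print.peth_matrix <- function(x, ...) {
  cat(sprintf("<peth_matrix> %d neurons x %d bins (%g ms), %d trials\n",
              nrow(x$rates), ncol(x$rates), x$bin_ms, x$n_trials))
  invisible(x)
}

#' Concatenate PETHs along time
#'
#' Used to sort neurons by their preferred firing time across all
#' sequences of a task.
#'
#' @param ... `peth_matrix` objects with identical neuron counts.
#' @export
peth_concat <- function(...) {
  ps <- list(...)
  if (length(ps) == 1 && is.list(ps[[1]]) &&
      !inherits(ps[[1]], "peth_matrix")) ps <- ps[[1]]
  r <- do.call(cbind, lapply(ps, function(p) p$rates))
  structure(list(rates = r, bin_ms = ps[[1]]$bin_ms,
                 sigma_ms = ps[[1]]$sigma_ms,
                 time = (seq_len(ncol(r)) - 0.5) * ps[[1]]$bin_ms,
                 n_trials = ps[[1]]$n_trials),
            class = "peth_matrix")
}

#' Sort neurons by the time of their highest average activity
#'
#' Returns the permutation ordering neurons by the argmax time of their
#' (concatenated) PETH; ties are broken by neuron index and the first
#' global maximum wins.  Neurons averaging fewer than
#' `min_spikes_per_seq` spikes per sequence are flagged for exclusion
#' from weight-matrix displays.
#'
#' @param p a [peth()] (possibly [peth_concat()]enated over sequences).
#' @param n_sequences number of concatenated sequences (for the
#'   per-sequence spike threshold).
#' @param min_spikes_per_seq sub-threshold flag level.
#' @return integer permutation with attribute `active` (logical).
#' @export
sort_by_peak <- function(p, n_sequences = 1, min_spikes_per_seq = 1) {
  stopifnot(inherits(p, "peth_matrix"), ncol(p$rates) >= 1)
  peak_bin <- apply(p$rates, 1, which.max)
  ord <- order(peak_bin, seq_len(nrow(p$rates)))
  spikes_per_seq <- rowSums(p$rates) * p$bin_ms / 1000 / n_sequences
  attr(ord, "active") <- (spikes_per_seq >= min_spikes_per_seq)[ord]
  ord
}

#' Rank-order correlation between a single trial and a template
#'
#' Spearman's rank correlation between the peak firing times of the
#' neurons in one (typically spontaneous) trial and their peak times in
#' the trial-averaged evoked template.  Only neurons that spiked at least
#' once in the trial enter; 1 means the sequential order is perfectly
#' preserved, -1 exactly reversed.
#'
#' @param trial a [spike_train()] (single run).
#' @param template a [peth()] template of the evoked activity.
#' @param sigma_ms smoothing for the single-trial peak estimate.
#' @return Spearman correlation in `[-1, 1]`, or `NA` if fewer than two
#'   neurons fired.
#' @export
rank_order_correlation <- function(trial, template, sigma_ms = 10) {
  stopifnot(inherits(trial, "spike_train"),
            inherits(template, "peth_matrix"))
  active <- which(tabulate(trial$channel, template_n(template)) > 0)
  if (length(active) < 2) return(NA_real_)
  tp <- peth(list(trial), bin_ms = template$bin_ms, sigma_ms = sigma_ms)
  t_trial <- apply(tp$rates[active, , drop = FALSE], 1, which.max)
  t_temp <- apply(template$rates[active, , drop = FALSE], 1, which.max)
  suppressWarnings(cor(t_trial, t_temp, method = "spearman"))
}

template_n <- function(template) nrow(template$rates)

#' Context-selectivity profile
#'
#' Classifies each neuron by thresholding its mean rate during the same
#' pattern presented in two different sequence contexts: above threshold
#' in one context only — context specific; in both — context unspecific;
#' in neither — untuned.
#'
#' @param rates_a,rates_b per-neuron mean rates (Hz) in contexts A and B.
#' @param threshold_hz rate threshold (default 10 Hz).
#' @return factor with levels `context_a`, `context_b`, `unspecific`,
#'   `untuned`.
#' @export
selectivity_profile <- function(rates_a, rates_b, threshold_hz = 10) {
  stopifnot(length(rates_a) == length(rates_b))
  a <- rates_a > threshold_hz; b <- rates_b > threshold_hz
  factor(ifelse(a & b, "unspecific",
         ifelse(a, "context_a", ifelse(b, "context_b", "untuned"))),
         levels = c("context_a", "context_b", "unspecific", "untuned"))
}

#' jPCA: projection onto the fastest rotational plane
#'
#' Preprocesses the state trajectories with ordinary PCA (`n_pca`
#' components), fits the skew-symmetric matrix `M` that best maps states
#' to their time derivatives in the least-squares sense (`M = -M'`, so
#' its eigenvalues are purely imaginary), and projects onto the real
#' plane of the eigenvector pair with the largest imaginary eigenvalue —
#' the plane aligned with the fastest rotation.
#'
#' @param trajectories list of numeric matrices (time x neurons), at
#'   least 2 trajectories with at least 3 time points each.
#' @param n_pca PCA components kept in preprocessing.
#' @return list with `projections` (list of time x 2 matrices), `M` (the
#'   skew-symmetric fit), `plane` (n_pca x 2 basis), `pca` (the
#'   `prcomp` object) and `eigenvalues` of `M`.
#' @export
jpca_project <- function(trajectories, n_pca = 6) {
  stopifnot(length(trajectories) >= 2,
            all(vapply(trajectories, nrow, 0L) >= 3))
  X <- do.call(rbind, trajectories)
  n_pca <- min(n_pca, ncol(X), nrow(X) - 1)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  scores <- lapply(trajectories, function(tr)
    scale(tr, center = pc$center, scale = FALSE) %*%
      pc$rotation[, seq_len(n_pca), drop = FALSE])
  # central-difference derivatives per trajectory
  Xs <- list(); dXs <- list()
  for (s in scores) {
    n <- nrow(s)
    dXs[[length(dXs) + 1]] <- (s[3:n, , drop = FALSE] -
                               s[1:(n - 2), , drop = FALSE]) / 2
    Xs[[length(Xs) + 1]] <- s[2:(n - 1), , drop = FALSE]
  }
  Xm <- do.call(rbind, Xs); dXm <- do.call(rbind, dXs)
  d <- n_pca
  # least squares over the skew-symmetric basis
  pairs <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
  A <- matrix(0, nrow(Xm) * d, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    Bp <- matrix(0, d, d); Bp[i, j] <- 1; Bp[j, i] <- -1
    A[, p] <- as.vector(Xm %*% Bp)
  }
  beta <- qr.solve(A, as.vector(dXm))
  M <- matrix(0, d, d)
  for (p in seq_len(nrow(pairs))) {
    M[pairs[p, 1], pairs[p, 2]] <- beta[p]
    M[pairs[p, 2], pairs[p, 1]] <- -beta[p]
  }
  ev <- eigen(M)
  top <- which.max(Im(ev$values))
  v <- ev$vectors[, top]
  plane <- cbind(Re(v), Im(v))
  plane <- qr.Q(qr(plane))
  list(projections = lapply(scores, function(s) s %*% plane),
       M = M, plane = plane, pca = pc, eigenvalues = ev$values)
}

#' Linear readout of the network state
#'
#' Trains a soft-margin linear support vector machine on labeled state
#' vectors (e.g. delay-phase activity) and scores held-out *sequences*: a
#' sequence counts as misclassified if any of its time points falls on
#' the wrong side of the separating plane.
#'
#' @param train_states matrix (samples x neurons) of training state
#'   vectors.
#' @param train_labels factor/vector of class labels (2 classes).
#' @param test_trajectories list of matrices (time x neurons), one per
#'   held-out sequence.
#' @param test_labels true label per held-out sequence.
#' @param cost SVM cost parameter.
#' @return list with the fitted `model`, per-sequence `predictions_ok`
#'   and the mean `accuracy`.
#' @export
linear_readout <- function(train_states, train_labels,
                           test_trajectories, test_labels, cost = 1) {
  train_labels <- factor(train_labels)
  stopifnot(nlevels(train_labels) == 2,
            length(test_trajectories) == length(test_labels))
  fit <- e1071::svm(x = train_states, y = train_labels,
                    kernel = "linear", cost = cost, scale = FALSE)
  ok <- vapply(seq_along(test_trajectories), function(i) {
    pred <- predict(fit, test_trajectories[[i]])
    all(pred == test_labels[i])
  }, TRUE)
  list(model = fit, predictions_ok = ok, accuracy = mean(ok))
}

#' Threshold classification of sequence log-likelihoods
#'
#' The grammaticality criterion: the threshold is the mean of the
#' log-likelihoods of all test sequences; sequences strictly above it are
#' reported grammatical (ties count as not above).
#'
#' @param logliks numeric log-likelihoods of the test set.
#' @param grammatical logical ground-truth labels (both classes must be
#'   present).
#' @return list with `threshold`, predicted `labels` and the fraction
#'   correct `rate`.
#' @export
classify_by_loglik <- function(logliks, grammatical) {
  stopifnot(length(logliks) == length(grammatical),
            length(logliks) >= 2)
  grammatical <- as.logical(grammatical)
  if (!any(grammatical) || all(grammatical))
    stop("test set must contain both grammatical and ungrammatical sequences")
  thr <- mean(logliks)
  pred <- logliks > thr
  list(threshold = thr, labels = pred,
       rate = mean(pred == grammatical))
}
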