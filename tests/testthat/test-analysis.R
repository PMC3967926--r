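test_that("PETH conserves spike mass and flattens homogeneous input", {
  empty <- lapply(1:3, function(i)
    spike_train(numeric(0), integer(0), duration = 100, n_channels = 4))
  p0 <- peth(empty)
  expect_true(all(p0$rates == 0))
  expect_equal(dim(p0$rates), c(4L, 100L))

  set.seed(61)
  trials <- lapply(1:40, function(i) {
    n <- rpois(1, 200)
    spike_train(runif(n, 0, 500), sample.int(2, n, TRUE),
                duration = 500, n_channels = 2)
  })
  p <- peth(trials, bin_ms = 1, sigma_ms = 10)
  total_mass <- sum(p$rates) * p$bin_ms / 1000 * length(trials)
  expect_equal(total_mass, sum(vapply(trials, function(x)
    length(x$time), 0L)), tolerance = 1e-6)
  # homogeneous Poisson at 200 Hz total: flat profile
  prof <- colSums(p$rates)
  expect_lt(sd(prof[50:450]) / mean(prof[50:450]), 0.25)
})

test_that("peak sorting recovers planted sequential order", {
  set.seed(62)
  K <- 12
  centers <- sample(seq(20, 280, length.out = K))
  trials <- lapply(1:30, function(i) {
    times <- unlist(lapply(centers, function(m) rnorm(8, m, 5)))
    ch <- rep(seq_len(K), each = 8)
    ok <- times > 0 & times < 300
    spike_train(times[ok], ch[ok], duration = 300, n_channels = K)
  })
  p <- peth(trials)
  ord <- sort_by_peak(p)
  expect_equal(as.vector(ord), order(centers))
  expect_true(all(attr(ord, "active")))

  one <- peth(list(spike_train(c(5, 7), c(1L, 1L), duration = 20,
                               n_channels = 1)))
  expect_equal(as.integer(sort_by_peak(one)), 1L)

  # permutation equivariance
  perm <- sample(K)
  p2 <- p; p2$rates <- p$rates[perm, ]
  expect_equal(p2$rates[sort_by_peak(p2), ], p$rates[sort_by_peak(p), ])
})

test_that("rank-order correlation hits its analytic extremes", {
  K <- 10
  template <- peth(list(spike_train(seq(10, 100, by = 10), 1:10,
                                    duration = 120, n_channels = K)))
  fwd <- spike_train(seq(11, 101, by = 10), 1:10, duration = 120,
                     n_channels = K)
  rev <- spike_train(seq(11, 101, by = 10), 10:1, duration = 120,
                     n_channels = K)
  expect_equal(rank_order_correlation(fwd, template), 1)
  expect_equal(rank_order_correlation(rev, template), -1)

  set.seed(63)
  r <- vapply(1:300, function(i) {
    tr <- spike_train(runif(K, 0, 120), sample(K), duration = 120,
                      n_channels = K)
    rank_order_correlation(tr, template)
  }, 0)
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(300))
  # fewer than two active neurons: undefined
  expect_true(is.na(rank_order_correlation(
    spike_train(5, 1L, duration = 120, n_channels = K), template)))
})

test_that("selectivity profiling applies the rate threshold rule", {
  lab <- selectivity_profile(c(15, 15, 5, 0.5), c(0.5, 15, 5, 15),
                             threshold_hz = 10)
  expect_equal(as.character(lab),
               c("context_a", "unspecific", "untuned", "context_b"))
})

test_that("jPCA fits a skew-symmetric rotation and recovers a planted plane", {
  set.seed(64)
  # planar rotation embedded in 10 dimensions plus noise
  t_grid <- seq(0, 4 * pi, length.out = 80)
  basis <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  trajs <- lapply(1:6, function(i) {
    phase <- runif(1, 0, 2 * pi)
    circ <- cbind(cos(t_grid + phase), sin(t_grid + phase))
    circ %*% t(basis) + matrix(rnorm(800, 0, 0.02), 80, 10)
  })
  jp <- jpca_project(trajs, n_pca = 6)
  expect_equal(jp$M, -t(jp$M), tolerance = 1e-10)
  expect_true(all(abs(Re(jp$eigenvalues)) < 1e-10))
  # principal angle between recovered plane (in original space) and truth
  plane_orig <- jp$pca$rotation[, seq_len(nrow(jp$plane))] %*% jp$plane
  plane_orig <- qr.Q(qr(plane_orig))
  ang <- acos(pmin(1, svd(t(plane_orig) %*% basis)$d)) * 180 / pi
  expect_lt(max(ang), 5)
  expect_length(jp$projections, 6)
  expect_equal(dim(jp$projections[[1]]), c(80L, 2L))
})

test_that("linear readout separates clusters and scores whole sequences", {
  set.seed(65)
  mk <- function(mu, n) matrix(rnorm(n * 4, mu, 0.3), n, 4)
  train <- rbind(mk(1, 40), mk(-1, 40))
  labs <- rep(c("A", "B"), each = 40)
  test_tr <- c(lapply(1:10, function(i) mk(1, 5)),
               lapply(1:10, function(i) mk(-1, 5)))
  test_lab <- rep(c("A", "B"), each = 10)
  r <- linear_readout(train, labs, test_tr, test_lab)
  expect_equal(r$accuracy, 1)

  # identical class distributions: chance level (single-time-point
  # sequences, so the any-time-point rule reduces to plain 0/1 loss)
  train0 <- rbind(mk(0, 60), mk(0, 60))
  t0 <- c(lapply(1:20, function(i) mk(0, 1)),
          lapply(1:20, function(i) mk(0, 1)))
  r0 <- linear_readout(train0, rep(c("A", "B"), each = 60),
                       t0, rep(c("A", "B"), each = 20))
  expect_lt(abs(r0$accuracy - 0.5), 0.35)

  # positive rescaling of all states: decisions unchanged after refit
  r2 <- linear_readout(train * 3, rep(c("A", "B"), each = 40),
                       lapply(test_tr, `*`, 3), test_lab)
  expect_equal(r2$predictions_ok, r$predictions_ok)
})

test_that("log-likelihood thresholding classifies with the documented tie rule", {
  r <- classify_by_loglik(c(-1, -1, -9, -9), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$rate, 1)
  expect_equal(r$threshold, -5)
  # all equal: ties are 'not above threshold'
  r2 <- classify_by_loglik(rep(-3, 4), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(r2$labels), rep(FALSE, 4))
  expect_equal(r2$rate, 0.75)
  expect_error(classify_by_loglik(c(-1, -2), c(TRUE, TRUE)), "both")

  # a hand-built HMM whose foils contain one illegal bigram scores them
  # strictly below grammatical strings under the exact forward algorithm
  eps <- 1e-4
  Tm <- rbind(c(eps, 1 - eps), c(1 - eps, eps))
  E <- rbind(c(1 - eps, eps), c(eps, 1 - eps))
  h <- discrete_hmm(c(1 - eps, eps), Tm, E)
  gram <- list(c(1L, 2L, 1L, 2L), c(1L, 2L, 1L, 2L))
  foil <- list(c(1L, 1L, 1L, 2L), c(1L, 2L, 2L, 2L))
  ll <- vapply(c(gram, foil), exact_forward_loglik, 0, hmm = h)
  rc <- classify_by_loglik(ll, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rc$rate, 1)
})
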