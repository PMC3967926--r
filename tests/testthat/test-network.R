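make_random_state <- function(params, seed = 1) {
  set.seed(seed)
  st <- network_state(params)
  st$time <- 100
  st$xp <- runif(params$n_afferents, 0, 2)
  st$xq <- runif(params$n_afferents, 0, st$xp)
  st$yp <- runif(params$n_neurons, 0, 2)
  st$yq <- runif(params$n_neurons, 0, st$yp)
  st$last_spike <- 100 - rexp(params$n_neurons, 1 / 20)
  st
}

test_that("membrane potentials match a naive double-loop computation", {
  set.seed(2)
  p <- network_params(7, 5, R = 100)
  st <- make_random_state(p)
  u <- membrane_potentials(p, st)
  tr <- wtahmm:::state_traces(p, st)
  u_ref <- numeric(5)
  for (k in 1:5) {
    acc <- p$b[k]
    for (i in 1:7) acc <- acc + p$W[k, i] * tr$x[i]
    for (j in 1:5) acc <- acc + p$V[k, j] * tr$y[j]
    acc <- acc - p$kernel_refr$amplitude *
      exp(-(st$time - st$last_spike[k]) / p$kernel_refr$tau_decay)
    u_ref[k] <- acc
  }
  expect_equal(u, u_ref, tolerance = 1e-12)

  st0 <- network_state(p)
  expect_equal(membrane_potentials(p, st0), p$b)
})

test_that("winner distribution is a per-group softmax with shift invariance", {
  expect_equal(winner_distribution(rep(1.3, 4)), rep(0.25, 4))
  expect_equal(winner_distribution(c(log(2), 0)), c(2 / 3, 1 / 3))
  u <- c(0.3, -1, 2, 5, 4.2)
  g <- c(1L, 1L, 1L, 2L, 2L)
  p1 <- winner_distribution(u, g)
  p2 <- winner_distribution(u + 7.5, g)  # the common inhibition drops out
  expect_equal(p1, p2)
  expect_equal(sum(p1[g == 1]), 1)
  expect_equal(sum(p1[g == 2]), 1)
  # overflow safety
  expect_equal(winner_distribution(c(1000, 1000)), c(0.5, 0.5))
  expect_error(winner_distribution(numeric(0)), "empty")
})

test_that("inter-spike intervals are exponential with mean 1000/R", {
  set.seed(3)
  isi <- sample_isi(100, 1e4)
  expect_true(all(isi > 0))
  expect_lt(abs(mean(isi) - 10) / 10, 0.03)
  ks <- suppressWarnings(ks.test(isi, "pexp", rate = 0.1))
  expect_gt(ks$p.value, 0.01)
  set.seed(9); a <- sample_isi(50, 10)
  set.seed(9); b <- sample_isi(50, 10)
  expect_identical(a, b)
})

test_that("step winners follow the softmax of the momentary potentials", {
  set.seed(4)
  p <- network_params(3, 4, R = 1000,
                      b = c(0.5, -0.3, 0.1, 0.9),
                      W = matrix(0, 4, 3), V = matrix(0, 4, 4))
  # no input, no learning: potentials are b minus refractory; freeze the
  # refractory out by amplitude 0 so the winner law is exactly softmax(b)
  p$kernel_refr$amplitude <- 0
  st <- network_state(p)
  wins <- integer(4)
  for (i in 1:3000) {
    out <- network_step(p, st)
    st <- out$state
    wins[out$spike$neuron] <- wins[out$spike$neuron] + 1
  }
  expect_gt(chisq.test(wins, p = winner_distribution(p$b))$p.value, 0.01)
})

test_that("run_network matches its event count and is seed-deterministic", {
  set.seed(5)
  p <- network_params(5, 8, R = 400, groups = c(1, 1, 1, 1, 2, 2, 2, 2))
  r0 <- run_network(p, NULL, duration = 0)
  expect_length(r0$spikes$time, 0)
  r <- run_network(p, NULL, duration = 2000)
  # two groups at R = 400 Hz for 2 s: 1600 expected, 3 sigma Poisson bounds
  expect_lt(abs(length(r$spikes$time) - 1600), 3 * sqrt(1600))
  set.seed(11); a <- run_network(p, NULL, duration = 300)
  set.seed(11); b <- run_network(p, NULL, duration = 300)
  expect_identical(a$spikes$time, b$spikes$time)
  expect_identical(a$spikes$channel, b$spikes$channel)
})

test_that("R and compiled event loops agree statistically", {
  set.seed(6)
  # strongly tuned rows so per-neuron rates are clearly non-uniform
  p <- network_params(4, 6, R = 300,
                      W = matrix(rnorm(24, 0, 0.8), 6, 4))
  bank <- make_rate_patterns(c("A", "B"), 4, coding = "dense")
  inp <- encode_sequence_to_spikes(rep(c("A", "B"), 8), bank)
  rc <- run_network(p, inp, duration = inp$duration, engine = "cpp")
  rr <- run_network(p, inp, duration = inp$duration, engine = "r")
  nc <- spike_counts(rc$spikes); nr <- spike_counts(rr$spikes)
  expect_lt(abs(sum(nc) - sum(nr)), 3 * sqrt(sum(nc) + sum(nr)))
  # per-neuron rate profiles correlate
  expect_gt(cor(nc, nr), 0.8)
  # trace evolution agrees exactly on a fixed event schedule
  st_r <- wtahmm:::advance_state(p, network_state(p), 120,
                                 wtahmm:::input_events(inp)[
                                   wtahmm:::input_events(inp)$time <= 120, ])
  lc <- wtahmm:::learn_cfg_cpp(NULL, p)
  ev <- wtahmm:::input_events(inp)
  out <- wtahmm:::sim_run_cpp(p$W, p$V, p$b, p$groups, 1e-9,
                              wtahmm:::kernel_cfg(p),
                              unclass(network_state(p)),
                              ev$time, as.integer(ev$channel), 120, lc)
  expect_equal(out$state$xp, st_r$xp, tolerance = 1e-10)
  expect_equal(out$state$xq, st_r$xq, tolerance = 1e-10)
})

test_that("discrete-time mode reproduces the mapped HMM's one-step law", {
  set.seed(8)
  h <- sample_teacher_hmm(3, 5, 1, 1)
  net <- map_hmm_to_network(h)
  cn <- network_step_conditionals(net)
  ch <- wtahmm:::hmm_step_conditionals(h)
  expect_equal(cn, ch, tolerance = 1e-12)
  # empirical transition counts of the sampled winner chain match the
  # teacher transition table within binomial error
  x <- unlist(generate_observations(h, 1, 400))
  sm <- wtahmm:::sample_paths_cpp(net$W, net$V, net$b, x, 30, FALSE)
  trans <- matrix(0, 3, 3)
  for (s in 1:30) {
    z <- sm$paths[s, ]
    for (n in 2:length(z)) trans[z[n - 1], z[n]] <- trans[z[n - 1], z[n]] + 1
  }
  # compare against the chain implied by teacher + observations: use the
  # aggregate conditional frequency test per source state
  for (j in 1:3) {
    n_j <- sum(trans[j, ])
    phat <- trans[j, ] / n_j
    # forward-sampling conditionals vary with x, so only demand agreement
    # with the column support and rough mass of T
    expect_gt(sum(phat[h$T[j, ] > 0.05]), 0.5)
  }
})

test_that("excitability shifts common to a group leave dynamics unchanged", {
  set.seed(10)
  p <- network_params(3, 4, R = 500)
  p2 <- p; p2$b <- p$b + 3.7
  st <- make_random_state(p)
  expect_equal(winner_distribution(membrane_potentials(p, st)),
               winner_distribution(membrane_potentials(p2, st)))
})

test_that("instantaneous input log-likelihood behaves in discrete mode", {
  # deterministic emissions: observing the certain symbol costs nothing
  h <- discrete_hmm(c(.5, .5), matrix(.5, 2, 2), rbind(c(1, 0), c(1, 0)))
  expect_equal(instantaneous_input_loglik(h, 1, 1), 0)
  # epsilon-floored emissions: an illegal symbol scores log(eps)
  eps <- 1e-4
  E <- rbind(c(1 - eps, eps), c(1 - eps, eps))
  h2 <- discrete_hmm(c(.5, .5), matrix(.5, 2, 2), E)
  expect_equal(instantaneous_input_loglik(h2, 1, 2), log(eps))
})

test_that("sampled path weights integrate to the exact forward likelihood", {
  set.seed(12)
  h <- sample_teacher_hmm(2, 3, 1, 1)
  x <- c(1, 3, 2, 2, 1)
  ll <- approx_loglik_by_sampling(h, x, S = 2e4)
  expect_lt(abs(ll - exact_forward_loglik(h, x)), 0.05)
})

test_that("spike train CSV round trip preserves the train", {
  st <- spike_train(c(3.5, 1.2, 7.8), c(2L, 1L, 2L), duration = 10,
                    n_channels = 3)
  f <- file.path(tempdir(), "train.csv")
  write_spike_train(st, f)
  st2 <- read_spike_train(f)
  expect_equal(st2$time, st$time)
  expect_equal(st2$channel, st$channel)
  expect_equal(st2$duration, 10)
  expect_equal(st2$n_channels, 3)
})
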