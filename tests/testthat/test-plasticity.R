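test_that("STDP updates have the two analytic fixed points", {
  set.seed(21)
  p <- network_params(4, 3, R = 100)
  st <- network_state(p)
  st$time <- 50
  eta <- 0.05
  # zero presynaptic traces: pure depression, identical on every synapse
  d0 <- stdp_delta(p, st, list(neuron = 2), eta)
  expect_equal(unname(d0$dW), rep(-eta, 4))
  expect_equal(d0$dV[-2], rep(-eta, 2))
  expect_equal(d0$dV[2], 0)  # self-weight excluded
  # presynaptic trace exactly exp(w): zero net change
  st$xp <- exp(p$W[2, ]) / p$kernel_ff$scale
  tr <- wtahmm:::state_traces(p, st)
  expect_equal(tr$x, exp(p$W[2, ]))
  d1 <- stdp_delta(p, st, list(neuron = 2), eta)
  expect_equal(unname(d1$dW), rep(0, 4), tolerance = 1e-12)
})

test_that("the empirical mean update vanishes at w* = log E[trace | spike]", {
  set.seed(22)
  # frozen stochastic environment: presynaptic trace drawn iid; the rule's
  # stationary point is the log conditional expectation
  draws <- function(n) sample(c(0.2, 1.4), n, TRUE, prob = c(0.3, 0.7))
  w_star <- log(mean(draws(1e5)))
  p <- network_params(1, 2, R = 100,
                      W = matrix(w_star, 2, 1), V = matrix(0, 2, 2))
  st <- network_state(p)
  eta <- 0.02
  x <- draws(4000)
  deltas <- vapply(x, function(xi) {
    st$xp <- xi / p$kernel_ff$scale
    stdp_delta(p, st, list(neuron = 1), eta)$dW[1]
  }, 0)
  # mean drift vanishes at the fixed point
  expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(length(deltas)))
})

test_that("eligibility tags accumulate additively and reject discards", {
  set.seed(23)
  p <- network_params(3, 2, R = 100)
  store <- eligibility_store(p)
  d1 <- list(neuron = 1, dW = c(.1, -.2, .3), dV = c(0, .05))
  d2 <- list(neuron = 1, dW = c(.2, .1, -.1), dV = c(0, -.02))
  store <- accumulate_and_consolidate(store, p, d1, "tag")$store
  store <- accumulate_and_consolidate(store, p, d2, "tag")$store
  acc <- accumulate_and_consolidate(store, p, decision = "accept")
  expect_equal(acc$params$W[1, ], p$W[1, ] + d1$dW + d2$dW)
  expect_equal(acc$params$W[2, ], p$W[2, ])
  rej <- accumulate_and_consolidate(store, p, decision = "reject")
  expect_equal(rej$params$W, p$W)
  expect_equal(rej$store$n, 0L)
})

test_that("online learning differs from deferred acceptance of a sequence", {
  set.seed(24)
  p <- network_params(6, 5, R = 500)
  bank <- make_rate_patterns(c("A", "B"), 6)
  inp <- encode_sequence_to_spikes(c("A", "B", "A"), bank)
  cfg_on <- learn_config(eta = 0.1, mode = "forward")
  cfg_tag <- learn_config(eta = 0.1, mode = "rejection")
  set.seed(99)
  on <- run_network(p, inp, duration = inp$duration, learn = cfg_on)
  set.seed(99)
  tag <- run_network(p, inp, duration = inp$duration, learn = cfg_tag)
  deferred <- p$W + tag$tags$dW
  # traces evolve under updated weights online, so the results differ
  expect_gt(max(abs(on$params$W - deferred)), 1e-6)
})

test_that("sequence log importance weight is the additive surprise sum", {
  expect_equal(sequence_log_importance_weight(numeric(5)), 0)
  s1 <- c(-.2, .1); s2 <- c(-.4, 0, .3)
  expect_equal(sequence_log_importance_weight(c(s1, s2)),
               sequence_log_importance_weight(s1) +
                 sequence_log_importance_weight(s2))
  expect_equal(sequence_log_importance_weight(
    data.frame(time = 1:2, group = 1, value = c(-1, 2))), 1)
})

test_that("acceptance is capped and geometric in the number of proposals", {
  expect_true(accept_decision(0, 0))       # boundary: probability 1
  expect_true(accept_decision(5, 0))       # capped at 1
  set.seed(25)
  expect_true(all(vapply(1:50, function(i) accept_decision(-0.5, -100),
                         TRUE)))           # c -> 0+ accepts everything
  # fixed acceptance probability p: mean proposals per acceptance -> 1/p
  p_acc <- 0.2
  set.seed(26)
  trials <- vapply(1:5000, function(i) {
    n <- 1
    while (!accept_decision(log(p_acc), 0)) n <- n + 1
    n
  }, 0)
  expect_lt(abs(mean(trials) - 1 / p_acc), 0.15)
})

test_that("threshold tracking equilibrates at the configured replay count", {
  set.seed(27)
  # stationary proposal quality: log weights from a fixed distribution
  logw <- function() rnorm(1, -3, 1)
  run_track <- function(step_accept, step_reject, n = 3e4) {
    log_c <- 0; acc <- logical(n)
    for (i in seq_len(n)) {
      acc[i] <- accept_decision(logw(), log_c)
      log_c <- track_c(log_c, acc[i], step_accept, step_reject)
    }
    mean(acc[-(1:5000)])
  }
  # equal steps: acceptance rate 1/2
  expect_lt(abs(run_track(0.02, 0.02) - 0.5), 0.05)
  # S = 10 steps: long-run mean proposals per acceptance within 20% of 10
  rate <- run_track(0.01, 0.01 / 9)
  expect_lt(abs(1 / rate - 10) / 10, 0.2)
  # an all-accept stream tightens the threshold monotonically
  lc <- 0
  trace <- vapply(1:20, function(i) lc <<- track_c(lc, TRUE), 0)
  expect_true(all(diff(trace) > 0))
})

test_that("batch selection normalizes importance weights over proposals", {
  set.seed(28)
  sel <- vapply(1:4000, function(i) batch_select(rep(-2, 4))$index, 0L)
  expect_gt(chisq.test(tabulate(sel, 4))$p.value, 0.01)
  expect_equal(batch_select(c(-1, -31, -35))$index, 1L)
  w <- batch_select(c(0, -30, -40), "importance")$weights
  expect_equal(w[1], 1, tolerance = 1e-10)
  expect_error(batch_select(rep(-Inf, 3)), "-Inf")
})

test_that("homeostasis nudges excitabilities toward the target rate", {
  b <- c(-1, 0, 1)
  expect_equal(homeostatic_update(b, rates = c(10, 10, 10),
                                  target_rate = 10), b)
  up <- homeostatic_update(b, rates = c(5, 10, 20), target_rate = 10)
  expect_gt(up[1], b[1]); expect_equal(up[2], b[2]); expect_lt(up[3], b[3])
})

test_that("closed-loop homeostasis equalizes long-run rates", {
  set.seed(29)
  K <- 8
  p <- network_params(2, K, R = 10 * K,
                      b = seq(-2, 2, length.out = K),
                      W = matrix(0, K, 2), V = matrix(0, K, K))
  cfg <- learn_config(eta = 0, mode = "forward", homeostasis = TRUE,
                      target_rate = 10, eta_b = 0.05)
  r <- run_network(p, NULL, duration = 6e4, learn = cfg)
  # rates over the second half of the run
  half <- r$spikes$time > 3e4
  rates <- tabulate(r$spikes$channel[half], K) / 30
  expect_lt(max(abs(rates - 10)) / 10, 0.25)
  expect_lt(sd(rates) / mean(rates),
            sd(tabulate(r$spikes$channel[!half], K) / 30) / 10 + 1)
})

test_that("a zero learning rate leaves parameters unchanged", {
  set.seed(30)
  p <- network_params(8, 4, mode = "discrete")
  seqs <- generate_observations(sample_teacher_hmm(4, 8, 1, 1), 20, 6)
  fit <- train_session(p, seqs, learn_config(eta = 0, mode = "forward"),
                       epochs = 2)
  expect_equal(fit$params$W, p$W)
  expect_equal(fit$params$V, p$V)
})

test_that("forward STDP recovers a 2-state teacher's emission rows", {
  set.seed(31)
  E <- rbind(c(.6, .4, 1e-3, 1e-3), c(1e-3, 1e-3, .4, .6))
  teach <- discrete_hmm(c(.5, .5), rbind(c(.8, .2), c(.2, .8)),
                        E / rowSums(E))
  seqs <- generate_observations(teach, 300, 12)
  net <- network_params(4, 2, mode = "discrete")
  cfg <- learn_config(eta = 0.05, mode = "forward")
  fit <- train_session(net, seqs, cfg, epochs = 30)
  # average the mapped model over late checkpoints to remove the
  # stochastic-approximation jitter
  hmms <- list()
  for (e in 1:6) {
    fit <- train_session(fit$params, seqs, cfg, epochs = 1)
    hmms[[e]] <- map_network_to_hmm(fit$params)
  }
  E_hat <- wtahmm:::average_hmms(hmms)$E
  expect_lt(best_perm_tv(E_hat, teach$E), 0.1)
})

test_that("rejection training tracks the configured mean replay count", {
  set.seed(32)
  teach <- sample_teacher_hmm(3, 4, 0.5, 0.5)
  seqs <- generate_observations(teach, 60, 8)
  net <- network_params(4, 3, mode = "discrete")
  fit <- train_session(net, seqs,
                       learn_config(eta = 0.01, mode = "rejection", S = 5,
                                    step_accept = 0.05, learn_b = TRUE),
                       epochs = 30)
  # discard the burn-in while the threshold finds its level
  tail_log <- tail(fit$log, 800)
  expect_lt(abs(mean(tail_log$replays) - 5) / 5, 0.4)
})
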