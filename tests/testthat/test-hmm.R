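test_that("teacher tables are valid, reproducible and uniform in mean", {
  set.seed(41)
  h <- sample_teacher_hmm(4, 8, 0.7, 0.7)
  expect_equal(sum(h$pi), 1, tolerance = 1e-12)
  expect_equal(rowSums(h$T), rep(1, 4), tolerance = 1e-12)
  expect_equal(rowSums(h$E), rep(1, 4), tolerance = 1e-12)
  set.seed(5); a <- sample_teacher_hmm(3, 3)
  set.seed(5); b <- sample_teacher_hmm(3, 3)
  expect_identical(a, b)
  # symmetric Beta draws: expected row entries uniform 1/K
  set.seed(42)
  m <- rowMeans(vapply(1:1000, function(i)
    sample_teacher_hmm(4, 4, 2, 2)$T[, 1], numeric(4)))
  expect_lt(max(abs(m - 0.25)) / 0.25, 0.02 + 3 * 0.01)
})

test_that("ancestral sampling honors the model and the requested sizes", {
  one_hot <- diag(3)
  h <- discrete_hmm(c(1, 0, 0), one_hot[c(2, 3, 1), ], one_hot)
  seqs <- generate_observations(h, 4, 6)
  expect_length(seqs, 4)
  expect_true(all(vapply(seqs, length, 0L) == 6))
  # deterministic model: one repeated sequence
  expect_true(all(vapply(seqs, identical, TRUE, seqs[[1]])))
  expect_equal(seqs[[1]], c(1L, 2L, 3L, 1L, 2L, 3L))

  set.seed(43)
  h2 <- sample_teacher_hmm(3, 4, 1, 1)
  first <- vapply(generate_observations(h2, 4000, 2), `[`, 0L, 1)
  p_first <- as.vector(h2$pi %*% h2$E)
  emp <- tabulate(first, 4) / 4000
  expect_true(all(abs(emp - p_first) <
                    3 * sqrt(p_first * (1 - p_first) / 4000) + 1e-3))
})

test_that("the scaled forward algorithm matches closed forms and enumeration", {
  set.seed(44)
  h <- sample_teacher_hmm(3, 4, 1, 1)
  x1 <- 2L
  expect_equal(exact_forward_loglik(h, x1), log(sum(h$pi * h$E[, 2])))
  h1 <- discrete_hmm(1, matrix(1, 1, 1), matrix(c(.2, .5, .3), 1))
  expect_equal(exact_forward_loglik(h1, c(1, 3, 3, 2)),
               log(.2) + 2 * log(.3) + log(.5))
  h2 <- sample_teacher_hmm(2, 3, 1, 1)
  x <- c(1, 3, 2, 1, 2)
  en <- enumerate_paths(h2, x)
  expect_equal(exact_forward_loglik(h2, x), log(sum(en$joint)),
               tolerance = 1e-12)
  # vectorized forward agrees with the scalar recursion
  seqs <- generate_observations(h2, 5, 5)
  expect_equal(wtahmm:::forward_loglik_many(h2, seqs),
               vapply(seqs, exact_forward_loglik, 0, hmm = h2))
})

test_that("Baum-Welch closed form, monotonicity and teacher recovery hold", {
  set.seed(45)
  # K = 1: one epoch fits the empirical symbol frequencies
  h1 <- discrete_hmm(1, matrix(1, 1, 1), matrix(rep(1 / 3, 3), 1))
  seqs <- list(c(1L, 1L, 2L), c(3L, 1L, 1L))
  fit1 <- baum_welch_fit(h1, seqs, 1)
  expect_equal(as.vector(fit1$hmm$E), c(4, 1, 1) / 6)

  teach <- sample_teacher_hmm(4, 8, 0.4, 0.4)
  train <- generate_observations(teach, 200, 10)
  val <- generate_observations(teach, 800, 10)
  init <- discrete_hmm(prop.table(rbeta(4, 5, 5)),
                       prop.table(matrix(rbeta(16, 5, 5), 4, 4), 1),
                       prop.table(matrix(rbeta(32, 5, 5), 4, 8), 1))
  fit <- baum_welch_fit(init, train, 25)
  expect_true(all(diff(fit$loglik) >= -1e-8 * abs(fit$loglik[-25])))
  ll_fit <- mean(wtahmm:::forward_loglik_many(floored(fit$hmm), val))
  ll_teach <- mean(wtahmm:::forward_loglik_many(teach, val))
  expect_lt((ll_teach - ll_fit) / abs(ll_teach), 0.05)
})

test_that("network/HMM mapping is exact and round-trippable", {
  K <- 3; L <- 4
  uni <- network_params(L, K, W = matrix(0, K, L), V = matrix(0.3, K, K),
                        b = numeric(K), mode = "discrete")
  h_uni <- map_network_to_hmm(uni)
  expect_equal(h_uni$T, matrix(1 / K, K, K))
  expect_equal(h_uni$E, matrix(1 / L, K, L))
  expect_equal(h_uni$pi, rep(1 / K, K))

  set.seed(46)
  for (i in 1:5) {
    h <- sample_teacher_hmm(3, 5, 0.8, 0.8)
    net <- map_hmm_to_network(h)
    h2 <- map_network_to_hmm(net)
    expect_equal(h2$pi, h$pi, tolerance = 1e-12)
    expect_equal(h2$T, h$T, tolerance = 1e-12)
    expect_equal(h2$E, h$E, tolerance = 1e-12)
    cn <- network_step_conditionals(net)
    ch <- wtahmm:::hmm_step_conditionals(h)
    expect_equal(cn, ch, tolerance = 1e-12)
    expect_equal(attr(cn, "initial"), attr(ch, "initial"),
                 tolerance = 1e-12)
  }
})

test_that("sampled likelihood approximations are exact for deterministic
           models and concentrate with more paths", {
  one_hot <- diag(2)
  h <- discrete_hmm(c(1, 0), one_hot[c(2, 1), ],
                    rbind(c(.9, .1), c(.2, .8)))
  x <- c(1L, 2L, 1L)
  # transitions are deterministic: one path, the sample mean is exact
  expect_equal(approx_loglik_by_sampling(h, x, S = 3),
               exact_forward_loglik(h, x), tolerance = 1e-12)

  set.seed(47)
  h2 <- sample_teacher_hmm(2, 3, 1, 1)
  x2 <- c(1, 2, 3, 1)
  est <- function(S) vapply(1:40, function(i)
    approx_loglik_by_sampling(h2, x2, S), 0)
  v1 <- var(est(1)); v50 <- var(est(50))
  expect_lt(v50, v1)
  expect_lt(abs(mean(est(200)) - exact_forward_loglik(h2, x2)), 0.1)
})
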