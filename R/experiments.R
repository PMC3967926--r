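#' Run one of the packaged experiments
#'
#' Reproducible drivers composing the package's simulation, learning,
#' stimulus and analysis operations into the experiment protocols:
#'
#' * `memory4` — the four-sequence working-memory task: a single WTA
#'   circuit learns a continuous stream of cue-delay-recall sequences by
#'   online STDP; reports per-sequence assembly sizes and evoked PETHs.
#' * `mixed_selectivity` — the same task learned by multiple
#'   interconnected WTA groups; reports selectivity profiles, jPCA
#'   projections and a linear readout of the delay-phase state.
#' * `trajectories` — two sequences with a long stationary delay learned
#'   with STDP plus homeostatic intrinsic plasticity; reports the
#'   fraction of the population recruited into each sequence assembly.
#' * `agl_abcd` — grammar learning on the four-string context grammar,
#'   comparing forward-sampling and rejection-sampling learning by
#'   likelihood-threshold classification of grammatical strings against
#'   foils.
#' * `agl_conway` — the same protocol on user-supplied training/test
#'   string lists (files are not shipped; see Details).
#' * `hmm_benchmark` — discrete-time comparison of forward sampling,
#'   batch rejection sampling (two replay budgets) and Baum-Welch on
#'   random teacher HMMs.
#'
#' `agl_conway` requires `train_file` (one space-separated symbol string
#' per line) and `test_file` (same, with a leading `g`/`u` grammaticality
#' token); these are the published training and test lists of the
#' behavioral study, which are not distributed with this package.
#'
#' @param config a list (or path to a YAML file) with at least
#'   `experiment` and `seed`; further entries override the
#'   experiment-specific defaults documented in the internals.  `out_dir`
#'   writes a metrics summary (with config hash and seed) plus trained
#'   parameters.
#' @return a list of experiment-specific results including a `metrics`
#'   list; deterministic given `seed`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$experiment),
            !is.null(config$seed))
  set.seed(config$seed)
  res <- switch(config$experiment,
    memory4 = do.call(experiment_memory4, exp_args(config)),
    mixed_selectivity = do.call(experiment_mixed_selectivity,
                                exp_args(config)),
    trajectories = do.call(experiment_trajectories, exp_args(config)),
    agl_abcd = do.call(experiment_agl_abcd, exp_args(config)),
    agl_conway = do.call(experiment_agl_conway, exp_args(config)),
    hmm_benchmark = do.call(experiment_hmm_benchmark, exp_args(config)),
    stop("unknown experiment: ", config$experiment))
  res$config <- config
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_file <- file.path(config$out_dir, "config.yaml")
    yaml::write_yaml(config, cfg_file)
    meta <- list(experiment = config$experiment, seed = config$seed,
                 config_md5 = unname(tools::md5sum(cfg_file)),
                 metrics = res$metrics)
    jsonlite::write_json(meta, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(res$params))
      write_network_params(res$params,
                           file.path(config$out_dir, "params.json"))
  }
  res
}

exp_args <- function(config) {
  config[setdiff(names(config), c("experiment", "seed", "out_dir"))]
}

# evoked trials of one symbol sequence: fresh afferent noise per trial,
# frozen weights, state reset
evoked_trials <- function(params, bank, symbols, n_trials) {
  lapply(seq_len(n_trials), function(i) {
    inp <- encode_sequence_to_spikes(symbols, bank)
    run_network(params, inp, duration = inp$duration)$spikes
  })
}

experiment_memory4 <- function(n_afferents = 200, n_neurons = 100,
                               iterations = 250, eta = 0.1,
                               R = 10 * n_neurons, n_trials = 100,
                               groups = rep(1L, n_neurons),
                               ff_amp = 0.5, lat_amp = 1,
                               homeostasis = FALSE, ...) {
  g <- builtin_grammar("memory4")
  bank <- make_rate_patterns(g$alphabet, n_afferents, coding = "dense")
  params <- network_params(n_afferents, n_neurons, R = R, groups = groups,
    kernel_ff = kernel_spec("double_exp", amplitude = ff_amp),
    kernel_lat = kernel_spec("double_exp", amplitude = lat_amp, delay = 5),
    kernel_refr = kernel_spec("refractory", tau_decay = 10, amplitude = 5))
  cfg <- learn_config(eta = eta, mode = "forward",
                      homeostasis = homeostasis)
  task <- function(i) encode_sequence_to_spikes(sample_symbol_sequence(g),
                                                bank)
  fit <- train_session(params, task, cfg, iterations = iterations,
                       reset = FALSE)
  sequences <- strsplit(enumerate_language(g)$string, " ")
  trials <- lapply(sequences, function(s)
    evoked_trials(fit$params, bank, s, n_trials))
  recruited <- vapply(trials, function(tr) {
    counts <- vapply(tr, spike_counts, integer(n_neurons))
    sum(rowMeans(counts) >= 1)
  }, 0)
  list(params = fit$params, bank = bank, grammar = g, log = fit$log,
       sequences = sequences, trials = trials,
       metrics = list(recruited_per_sequence = recruited,
                      mean_recruited = mean(recruited)))
}

experiment_trajectories <- function(n_afferents = 100, n_neurons = 200,
                                    group_sizes = NULL, iterations = 200,
                                    eta = 0.05, R = NULL, n_trials = 40,
                                    target_rate = 10, eta_b = 0.002,
                                    rate_window = 20000,
                                    pattern_ms = 100, delay_ms = 500,
                                    ff_amp = 0.5, lat_amp = 1,
                                    min_rate_hz = 1, ...) {
  g <- builtin_grammar("two_seq_delay")
  bank <- make_rate_patterns(g$alphabet, n_afferents, coding = "dense",
                             duration = c(delay = delay_ms, pattern_ms))
  if (is.null(group_sizes)) {
    group_sizes <- integer(0)
    while (sum(group_sizes) < n_neurons)
      group_sizes <- c(group_sizes,
                       sample(10:50, 1))
    group_sizes[length(group_sizes)] <- n_neurons -
      sum(head(group_sizes, -1))
    if (tail(group_sizes, 1) < 10) {
      group_sizes <- head(group_sizes, -1)
      n_neurons <- sum(group_sizes)
    }
  } else n_neurons <- sum(group_sizes)
  groups <- rep(seq_along(group_sizes), group_sizes)
  if (is.null(R)) R <- target_rate * mean(group_sizes)
  params <- network_params(n_afferents, n_neurons, R = R, groups = groups,
    kernel_ff = kernel_spec("double_exp", amplitude = ff_amp),
    kernel_lat = kernel_spec("double_exp", amplitude = lat_amp, delay = 5),
    kernel_refr = kernel_spec("refractory", tau_decay = 10, amplitude = 5))
  cfg <- learn_config(eta = eta, mode = "forward", homeostasis = TRUE,
                      target_rate = target_rate, eta_b = eta_b,
                      rate_window = rate_window)
  task <- function(i) encode_sequence_to_spikes(sample_symbol_sequence(g),
                                                bank)
  fit <- train_session(params, task, cfg, iterations = iterations,
                       reset = FALSE)
  sequences <- strsplit(enumerate_language(g)$string, " ")
  dur <- pattern_ms + delay_ms
  rates <- vapply(sequences, function(s) {
    tr <- evoked_trials(fit$params, bank, s, n_trials)
    counts <- vapply(tr, spike_counts, integer(n_neurons))
    rowMeans(counts) / dur * 1000
  }, numeric(n_neurons))
  active <- rates[, 1] >= min_rate_hz | rates[, 2] >= min_rate_hz
  assign <- ifelse(active, max.col(rates), NA)
  frac <- vapply(1:2, function(a) sum(assign == a, na.rm = TRUE), 0) /
    n_neurons
  list(params = fit$params, bank = bank, grammar = g, log = fit$log,
       rates = rates, assignment = assign,
       metrics = list(assembly_fraction = frac,
                      mean_assembly_fraction = mean(frac),
                      active_fraction = mean(active)))
}

experiment_mixed_selectivity <- function(n_afferents = 100,
                                         n_groups = 8,
                                         iterations = 200, eta = 0.02,
                                         target_rate = 10,
                                         n_trials = 30, ...) {
  g <- builtin_grammar("memory4")
  bank <- make_rate_patterns(g$alphabet, n_afferents, coding = "dense")
  group_sizes <- sample(10:50, n_groups, replace = TRUE)
  n_neurons <- sum(group_sizes)
  groups <- rep(seq_len(n_groups), group_sizes)
  params <- network_params(n_afferents, n_neurons,
                           R = target_rate * mean(group_sizes),
                           groups = groups)
  cfg <- learn_config(eta = eta, mode = "forward")
  task <- function(i) encode_sequence_to_spikes(sample_symbol_sequence(g),
                                                bank)
  fit <- train_session(params, task, cfg, iterations = iterations,
                       reset = FALSE)

  # rate of each neuron during pattern `a` in its two contexts
  seq_a <- c("A", "B", "delay", "a", "b")
  seq_b <- c("B", "A", "delay", "b", "a")
  win_a <- c(150, 200); win_b <- c(200, 250)
  rate_in <- function(symbols, win) {
    tr <- evoked_trials(fit$params, bank, symbols, n_trials)
    counts <- vapply(tr, function(x) {
      sel <- x$time >= win[1] & x$time < win[2]
      tabulate(x$channel[sel], n_neurons)
    }, integer(n_neurons))
    rowMeans(counts) / diff(win) * 1000
  }
  r_a <- rate_in(seq_a, win_a)
  r_b <- rate_in(seq_b, win_b)
  profile <- selectivity_profile(r_a, r_b)

  # delay-phase state trajectories (smoothed PETH columns) for readout/jPCA
  delay_win <- c(100, 150)
  traj_of <- function(symbols, n) lapply(seq_len(n), function(i) {
    sp <- evoked_trials(fit$params, bank, symbols, 1)[[1]]
    p <- peth(list(sp), bin_ms = 5, sigma_ms = 10)
    t(p$rates[, p$time >= delay_win[1] & p$time < delay_win[2],
              drop = FALSE])
  })
  tr_a <- traj_of(seq_a, n_trials); tr_b <- traj_of(seq_b, n_trials)
  half <- n_trials %/% 2
  train_states <- do.call(rbind, c(tr_a[seq_len(half)],
                                   tr_b[seq_len(half)]))
  train_labels <- rep(c("A", "B"),
                      c(sum(vapply(tr_a[seq_len(half)], nrow, 0L)),
                        sum(vapply(tr_b[seq_len(half)], nrow, 0L))))
  test_traj <- c(tr_a[(half + 1):n_trials], tr_b[(half + 1):n_trials])
  test_labels <- rep(c("A", "B"), each = n_trials - half)
  readout <- linear_readout(train_states, train_labels, test_traj,
                            test_labels)
  jp <- jpca_project(c(tr_a, tr_b))
  list(params = fit$params, bank = bank, profile = profile,
       rates_context = cbind(a_in_AB = r_a, a_in_BA = r_b),
       readout = readout, jpca = jp,
       metrics = list(selectivity_counts = as.list(table(profile)),
                      readout_accuracy = readout$accuracy))
}

# likelihood-threshold grammaticality classification with fresh encodings
agl_classification_rate <- function(params, bank, gram_strings,
                                    foil_strings, n_each = 5) {
  enc_ll <- function(symbols) {
    inp <- encode_sequence_to_spikes(symbols, bank)
    sequence_log_importance_weight(
      run_network(params, inp, duration = inp$duration)$surprise)
  }
  gs <- rep(gram_strings, n_each)
  fs <- rep(foil_strings, length.out = length(gs))
  ll <- c(vapply(gs, enc_ll, 0), vapply(fs, enc_ll, 0))
  truth <- rep(c(TRUE, FALSE), c(length(gs), length(fs)))
  classify_by_loglik(ll, truth)$rate
}

experiment_agl_abcd <- function(n_afferents = 8, n_neurons = 30,
                                iterations = 150, eta = 0.05,
                                S = 10, n_test_each = 5,
                                ff_amp = 0.5, lat_amp = 1,
                                modes = c("forward", "rejection"), ...) {
  g <- builtin_grammar("abcd")
  bank <- make_rate_patterns(g$alphabet, n_afferents, coding = "sparse")
  gram <- strsplit(enumerate_language(g)$string, " ")
  foils <- make_foils(g, 20)
  out <- list()
  for (m in modes) {
    params <- network_params(n_afferents, n_neurons,
                             R = 10 * n_neurons,
      kernel_ff = kernel_spec("double_exp", amplitude = ff_amp),
      kernel_lat = kernel_spec("double_exp", amplitude = lat_amp,
                               delay = 5),
      kernel_refr = kernel_spec("refractory", tau_decay = 10,
                                amplitude = 5))
    cfg <- learn_config(eta = eta, mode = m, S = S, step_accept = 1,
                        warm_start_c = TRUE)
    task <- function(i) encode_sequence_to_spikes(
      sample_symbol_sequence(g), bank)
    fit <- train_session(params, task, cfg, iterations = iterations,
                         reset = TRUE)
    rate <- agl_classification_rate(fit$params, bank, gram, foils,
                                    n_each = n_test_each)
    out[[m]] <- list(params = fit$params, log = fit$log, rate = rate)
  }
  list(bank = bank, grammar = g, runs = out,
       metrics = c(lapply(out, function(o) o$rate),
                   list(mean_replays = lapply(out, function(o)
                     mean(o$log$replays)))))
}

experiment_agl_conway <- function(train_file = NULL, test_file = NULL,
                                  n_afferents = 10, n_neurons = 30,
                                  iterations = 200, eta = 0.03,
                                  mode = "forward", S = 10, ...) {
  if (is.null(train_file) || is.null(test_file))
    stop("agl_conway needs the externally published training and test ",
         "string lists: supply `train_file` (one space-separated symbol ",
         "string per line) and `test_file` (same, with a leading g/u ",
         "grammaticality token); they are not distributed with this ",
         "package")
  train <- strsplit(trimws(readLines(train_file)), "\\s+")
  test_raw <- strsplit(trimws(readLines(test_file)), "\\s+")
  test_lab <- vapply(test_raw, function(x) x[1] %in% c("g", "1"), TRUE)
  test <- lapply(test_raw, function(x) x[-1])
  symbols <- sort(unique(unlist(c(train, test))))
  bank <- make_rate_patterns(symbols, n_afferents, coding = "sparse")
  params <- network_params(n_afferents, n_neurons, R = 10 * n_neurons)
  cfg <- learn_config(eta = eta, mode = mode, S = S, step_accept = 1,
                      warm_start_c = TRUE)
  task <- function(i) encode_sequence_to_spikes(
    train[[sample.int(length(train), 1)]], bank)
  fit <- train_session(params, task, cfg, iterations = iterations,
                       reset = TRUE)
  ll <- vapply(test, function(s) {
    inp <- encode_sequence_to_spikes(s, bank)
    sequence_log_importance_weight(
      run_network(fit$params, inp, duration = inp$duration)$surprise)
  }, 0)
  cls <- classify_by_loglik(ll, test_lab)
  list(params = fit$params, bank = bank, log = fit$log,
       logliks = ll, labels = test_lab,
       metrics = list(classification_rate = cls$rate))
}

experiment_hmm_benchmark <- function(n_teachers = 10, K = 4, L = 8,
                                     seq_len = 10, n_train = 200,
                                     n_val = 2000, epochs = 20,
                                     eta = 0.01, teacher_beta = 0.03,
                                     avg_epochs = 6,
                                     S_values = c(10, 100), ...) {
  methods <- c("forward",
               paste0("rejection", S_values), "baum_welch")
  val_ll <- matrix(NA_real_, n_teachers, length(methods),
                   dimnames = list(NULL, methods))
  bw_monotone <- logical(n_teachers)
  teacher_ll <- numeric(n_teachers)
  bw_trace <- NULL
  avg_epochs <- min(avg_epochs, max(epochs, 1))
  for (tt in seq_len(n_teachers)) {
    teacher <- sample_teacher_hmm(K, L, teacher_beta, teacher_beta)
    train <- generate_observations(teacher, n_train, seq_len)
    val <- generate_observations(teacher, n_val, seq_len)
    teacher_ll[tt] <- mean(forward_loglik_many(teacher, val))
    # common random start for the stochastic learners (paired comparison)
    init_seed <- sample.int(2^31 - 2, 1)
    if (epochs == 0) {
      # metrics of the untrained models
      net0 <- network_params(L, K, mode = "discrete")
      val_ll[tt, ] <- mean(forward_loglik_many(
        floor_hmm(map_network_to_hmm(net0)), val))
      next
    }
    for (m in seq_along(methods)) {
      if (methods[m] == "baum_welch") {
        init <- discrete_hmm(
          prop.table(rbeta(K, 5, 5)),
          prop.table(matrix(rbeta(K * K, 5, 5), K, K), 1),
          prop.table(matrix(rbeta(K * L, 5, 5), K, L), 1))
        bw <- baum_welch_fit(init, train, epochs)
        bw_monotone[tt] <- all(diff(bw$loglik) >= -1e-8 *
                                 abs(bw$loglik[-length(bw$loglik)]))
        bw_trace <- bw$loglik
        val_ll[tt, m] <- mean(forward_loglik_many(floor_hmm(bw$hmm), val))
      } else {
        set.seed(init_seed)
        net <- network_params(L, K, mode = "discrete")
        cfg <- if (methods[m] == "forward")
          learn_config(eta = eta, mode = "forward", learn_b = TRUE)
        else learn_config(eta = eta, mode = "rejection",
                          c_strategy = "batch", learn_b = TRUE,
                          S = as.integer(sub("rejection", "",
                                             methods[m])))
        # final model: probability-space average of the mapped model over
        # the last avg_epochs checkpoints (the stochastic learners
        # fluctuate at the moving-average noise floor)
        fit <- train_session(net, train, cfg, epochs = epochs - avg_epochs)
        hmms <- vector("list", avg_epochs)
        for (e in seq_len(avg_epochs)) {
          fit <- train_session(fit$params, train, cfg, epochs = 1)
          hmms[[e]] <- map_network_to_hmm(fit$params)
        }
        val_ll[tt, m] <- mean(forward_loglik_many(
          floor_hmm(average_hmms(hmms)), val))
      }
    }
  }
  list(val_loglik = val_ll, bw_monotone = bw_monotone,
       teacher_loglik = teacher_ll, bw_loglik_trace = bw_trace,
       metrics = list(mean_val_loglik = as.list(colMeans(val_ll)),
                      baum_welch_monotone = all(bw_monotone)))
}
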