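#' Finite-state grammars with symbol-emitting arcs
#'
#' A grammar is a directed graph over named nodes with designated `Start`
#' and `Exit`; each arc carries the symbol it emits and a branch
#' probability.  Symbol sequences are generated by following a path from
#' `Start` to `Exit`, emitting the symbol of every arc passed.
#'
#' @param arcs data.frame with columns `from`, `to`, `symbol`, `prob`.
#' @param start,exit names of the start and exit nodes.
#' @return an object of class `grammar`.
#' @export
grammar <- function(arcs, start = "Start", exit = "Exit") {
  stopifnot(is.data.frame(arcs),
            all(c("from", "to", "symbol", "prob") %in% names(arcs)))
  arcs$from <- as.character(arcs$from); arcs$to <- as.character(arcs$to)
  arcs$symbol <- as.character(arcs$symbol)
  arcs$prob <- as.numeric(arcs$prob)
  nodes <- unique(c(start, arcs$from, arcs$to, exit))
  if (any(arcs$prob <= 0)) stop("branch probabilities must be positive")
  for (nd in setdiff(nodes, exit)) {
    out <- arcs$prob[arcs$from == nd]
    if (!length(out)) stop("node without outgoing arcs: ", nd)
    if (abs(sum(out) - 1) > 1e-9)
      stop("outgoing branch probabilities at node '", nd,
           "' sum to ", sum(out), ", not 1")
  }
  # every node must reach Exit
  reach <- exit
  repeat {
    more <- unique(arcs$from[arcs$to %in% reach])
    new <- setdiff(more, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  if (!all(setdiff(nodes, exit) %in% reach))
    stop("nodes cannot reach Exit: ",
         paste(setdiff(nodes, c(exit, reach)), collapse = ", "))
  structure(list(arcs = arcs, start = start, exit = exit,
                 nodes = nodes, alphabet = sort(unique(arcs$symbol))),
            class = "grammar")
}

#' @export
print.grammar <- function(x, ...) {
  cat(sprintf("<grammar> %d nodes, %d arcs, alphabet {%s}\n",
              length(x$nodes), nrow(x$arcs),
              paste(x$alphabet, collapse = ", ")))
  invisible(x)
}

chain_arcs <- function(prefix, symbols, start, exit, p_first = 1) {
  n <- length(symbols)
  from <- c(start, if (n > 1) paste0(prefix, seq_len(n - 1)))
  to <- c(if (n > 1) paste0(prefix, seq_len(n - 1)), exit)
  data.frame(from = from, to = to, symbol = symbols,
             prob = c(p_first, rep(1, n - 1)))
}

#' Built-in task grammars
#'
#' * `memory4`: the four-sequence working-memory task.  A random choice at
#'   `Start` (equal probabilities) picks one of four cue/recall pairs;
#'   each path then deterministically emits cue (two symbols), `delay`,
#'   and the matching two-symbol recall, e.g. `A B delay a b`.  The
#'   `delay` symbol appears in all four sequences, so the task is
#'   non-Markovian in the symbols alone.
#' * `abcd`: the four-string grammar whose language is exactly
#'   `AABC, BBAC, ABAD, BABD` (uniform).  Whether the last symbol is `C`
#'   or `D` is determined by the first three symbols, so classification
#'   requires integrating context over the whole sequence.
#' * `two_seq_delay`: two sequences `A delay` and `B delay` with a long
#'   stationary delay pattern, used for the neural-trajectory experiments.
#'
#' @param name grammar name.
#' @return a [grammar()].
#' @export
builtin_grammar <- function(name = c("memory4", "abcd", "two_seq_delay")) {
  name <- match.arg(name)
  arcs <- switch(name,
    memory4 = do.call(rbind, list(
      chain_arcs("m1_", c("A", "B", "delay", "a", "b"), "Start", "Exit", .25),
      chain_arcs("m2_", c("B", "A", "delay", "b", "a"), "Start", "Exit", .25),
      chain_arcs("m3_", c("C", "D", "delay", "c", "d"), "Start", "Exit", .25),
      chain_arcs("m4_", c("D", "C", "delay", "d", "c"), "Start", "Exit", .25))),
    abcd = do.call(rbind, list(
      chain_arcs("g1_", c("A", "A", "B", "C"), "Start", "Exit", .25),
      chain_arcs("g2_", c("A", "B", "A", "D"), "Start", "Exit", .25),
      chain_arcs("g3_", c("B", "B", "A", "C"), "Start", "Exit", .25),
      chain_arcs("g4_", c("B", "A", "B", "D"), "Start", "Exit", .25))),
    two_seq_delay = do.call(rbind, list(
      chain_arcs("s1_", c("A", "delay"), "Start", "Exit", .5),
      chain_arcs("s2_", c("B", "delay"), "Start", "Exit", .5))))
  grammar(arcs)
}

#' Serialize / load a grammar as a YAML config
#'
#' The config lists `start`, `exit` and the arcs (`from`, `to`, `symbol`,
#' `prob`); [read_grammar()] validates on load, so malformed configs
#' (e.g. branch probabilities not summing to 1) raise an error.
#'
#' @param g a [grammar()].
#' @param path file path.
#' @export
write_grammar <- function(g, path) {
  yaml::write_yaml(list(start = g$start, exit = g$exit,
                        arcs = lapply(seq_len(nrow(g$arcs)), function(i)
                          as.list(g$arcs[i, ]))), path)
  invisible(path)
}

#' @rdname write_grammar
#' @export
read_grammar <- function(path) {
  o <- yaml::read_yaml(path)
  arcs <- do.call(rbind, lapply(o$arcs, function(a)
    data.frame(from = a$from, to = a$to, symbol = a$symbol,
               prob = a$prob)))
  grammar(arcs, start = o$start, exit = o$exit)
}

#' Enumerate the language of a grammar
#'
#' Depth-first enumeration of all `Start -> Exit` paths with their
#' probabilities.  Intended for the acyclic task grammars; enumeration
#' aborts if strings exceed `max_len`.
#'
#' @param g a [grammar()].
#' @param max_len maximum string length.
#' @return data.frame with `string` (space-separated symbols) and `prob`.
#' @export
enumerate_language <- function(g, max_len = 32) {
  out <- list()
  recurse <- function(node, symbols, prob) {
    if (node == g$exit) {
      out[[length(out) + 1]] <<- list(string = paste(symbols,
                                                     collapse = " "),
                                      prob = prob)
      return(invisible())
    }
    if (length(symbols) >= max_len)
      stop("string longer than max_len; grammar may be cyclic")
    rows <- which(g$arcs$from == node)
    for (i in rows)
      recurse(g$arcs$to[i], c(symbols, g$arcs$symbol[i]),
              prob * g$arcs$prob[i])
  }
  recurse(g$start, character(0), 1)
  agg <- aggregate(prob ~ string,
                   data = do.call(rbind, lapply(out, as.data.frame)),
                   FUN = sum)
  agg[order(-agg$prob, agg$string), , drop = FALSE]
}

#' Sample one symbol sequence from a grammar
#'
#' Follows a random path from `Start` to `Exit`, choosing among outgoing
#' arcs by their branch probabilities.
#'
#' @param g a [grammar()].
#' @return character vector of emitted symbols.
#' @export
sample_symbol_sequence <- function(g) {
  node <- g$start
  symbols <- character(0)
  while (node != g$exit) {
    rows <- which(g$arcs$from == node)
    i <- if (length(rows) == 1) rows
         else rows[sample.int(length(rows), 1, prob = g$arcs$prob[rows])]
    symbols <- c(symbols, g$arcs$symbol[i])
    node <- g$arcs$to[i]
    if (length(symbols) > 10000) stop("runaway grammar walk")
  }
  symbols
}

#' Symbol-to-rate-pattern banks
#'
#' Each symbol is rendered as a fixed-duration pattern of Poisson firing
#' rates over the afferent population.  `dense` coding draws an
#' independent `Beta(beta_a, beta_b)` value per (symbol, afferent) and
#' scales it by `max_rate` — overlapping, distributed patterns.  `sparse`
#' coding activates a disjoint set of `active_per_symbol` channels per
#' symbol at `sparse_rate` Hz and leaves all other channels silent.
#'
#' @param symbols character vector of symbols.
#' @param n_afferents number of afferent channels.
#' @param coding `"dense"` or `"sparse"`.
#' @param duration pattern duration (ms), recycled over symbols; named
#'   vector entries override per symbol (e.g. `c(delay = 500)`).
#' @param max_rate,beta_a,beta_b dense-coding parameters.
#' @param sparse_rate,active_per_symbol sparse-coding parameters.
#' @return an object of class `rate_pattern_bank`: `rates` (symbols x
#'   afferents, Hz) and per-symbol `durations` (ms).
#' @export
make_rate_patterns <- function(symbols, n_afferents,
                               coding = c("dense", "sparse"),
                               duration = 50,
                               max_rate = 75, beta_a = 2, beta_b = 2,
                               sparse_rate = 100, active_per_symbol = 2) {
  coding <- match.arg(coding)
  stopifnot(n_afferents >= 1, length(symbols) >= 1)
  S <- length(symbols)
  if (coding == "dense") {
    rates <- matrix(max_rate * rbeta(S * n_afferents, beta_a, beta_b),
                    S, n_afferents)
  } else {
    if (S * active_per_symbol > n_afferents)
      stop("sparse coding needs at least ", S * active_per_symbol,
           " afferents")
    rates <- matrix(0, S, n_afferents)
    for (s in seq_len(S))
      rates[s, (s - 1) * active_per_symbol + seq_len(active_per_symbol)] <-
        sparse_rate
  }
  rownames(rates) <- symbols
  if (is.null(names(duration))) {
    dur <- rep(duration[[1]], S)
  } else {
    unnamed <- names(duration) == ""
    dur <- rep(if (any(unnamed)) unname(duration[unnamed][1]) else 50, S)
    for (nm in setdiff(names(duration), ""))
      if (nm %in% symbols) dur[match(nm, symbols)] <- duration[[nm]]
  }
  names(dur) <- symbols
  structure(list(rates = rates, durations = dur, symbols = symbols,
                 n_afferents = n_afferents, coding = coding),
            class = "rate_pattern_bank")
}

#' Render a symbol sequence as an afferent Poisson spike train
#'
#' Concatenates the per-symbol rate patterns and draws fresh, independent
#' Poisson spikes for every channel in every pattern window — spike times
#' are never reused between presentations.
#'
#' @param symbols character vector of symbols (all present in `bank`).
#' @param bank a [make_rate_patterns()] bank.
#' @param t0 start time (ms) of the first pattern.
#' @return a [spike_train()] over `bank$n_afferents` channels.
#' @export
encode_sequence_to_spikes <- function(symbols, bank, t0 = 0) {
  stopifnot(inherits(bank, "rate_pattern_bank"),
            all(symbols %in% bank$symbols))
  times <- list(); chans <- list()
  t <- t0
  for (sym in symbols) {
    dur <- bank$durations[[sym]]
    r <- bank$rates[sym, ]
    n <- rpois(length(r), r * dur / 1000)
    if (sum(n) > 0) {
      times[[length(times) + 1]] <- t + runif(sum(n), 0, dur)
      chans[[length(chans) + 1]] <- rep(seq_along(r), n)
    }
    t <- t + dur
  }
  spike_train(unlist(c(times, list(numeric(0)))),
              unlist(c(chans, list(integer(0)))),
              duration = t, n_channels = bank$n_afferents)
}

#' Construct ungrammatical foil sequences
#'
#' Length-matched strings that the grammar cannot generate, produced by
#' substituting a single symbol of a grammatical string at a random
#' position and re-checking the result against the enumerated language.
#'
#' @param g a [grammar()] with at least two symbols.
#' @param n number of foils.
#' @param max_tries give up after this many rejected proposals.
#' @return list of character vectors (symbol sequences).
#' @export
make_foils <- function(g, n, max_tries = 1000 * n) {
  stopifnot(length(g$alphabet) >= 2, n >= 1)
  lang <- enumerate_language(g)
  foils <- list(); tries <- 0
  while (length(foils) < n && tries < max_tries) {
    tries <- tries + 1
    src <- strsplit(lang$string[sample.int(nrow(lang), 1,
                                           prob = lang$prob)], " ")[[1]]
    pos <- sample.int(length(src), 1)
    alt <- setdiff(g$alphabet, src[pos])
    src[pos] <- alt[sample.int(length(alt), 1)]
    if (!(paste(src, collapse = " ") %in% lang$string))
      foils[[length(foils) + 1]] <- src
  }
  if (length(foils) < n) stop("could not generate enough foils")
  foils
}
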