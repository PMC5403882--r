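## Shared fixtures and independent oracles for the test suite.

## A minimal one-population graph for engine-level tests: `n` unconnected
## neurons with a single 0.5 ms receptor channel.
mini_graph <- function(n = 1L, channels = c(ext = 0.5)) {
  pops <- data.frame(name = "P", column = 1L, count = as.integer(n),
                     base = "X", ei = "E", start = 1L,
                     end = as.integer(n), stringsAsFactors = FALSE)
  structure(list(pops = pops,
                 synapses = data.frame(pre = integer(0), post = integer(0),
                                       weight = numeric(0),
                                       delay = numeric(0), tau = numeric(0),
                                       rule = integer(0)),
                 rules = data.frame(),
                 channels = list(P = channels),
                 meta = list(dt = 0.1, n_columns = 1L, scale = 1, seed = 1L,
                             expected = numeric(0))),
            class = "network_graph")
}

## Hand-built two-neuron graph: neuron 1 projects one synapse onto neuron 2.
two_neuron_graph <- function(w = 175.6, tau = 0.5, delay = 1.0) {
  pops <- data.frame(name = c("A", "B"), column = 1L, count = 1L,
                     base = "X", ei = if (w > 0) "E" else "I",
                     start = 1:2, end = 1:2, stringsAsFactors = FALSE)
  structure(list(pops = pops,
                 synapses = data.frame(pre = 1L, post = 2L, weight = w,
                                       delay = delay, tau = tau, rule = 1L),
                 rules = data.frame(name = "A:B", kind = "budget",
                                    p = NA_real_, stringsAsFactors = FALSE),
                 channels = list(A = c(ext = 0.5), B = c(syn = tau)),
                 meta = list(dt = 0.1, n_columns = 1L, scale = 1, seed = 1L,
                             expected = 1)),
            class = "network_graph")
}

## Synthetic spike_record with Poisson spiking at given per-column rates,
## for analysis-level tests with planted ground truth.
synthetic_record <- function(rates_hz, n_per_col = 50, duration = 600,
                             seed = 1) {
  set.seed(seed)
  n_cols <- length(rates_hz)
  pops <- data.frame(name = "L23_Pyr", column = seq_len(n_cols),
                     count = n_per_col, base = "L23E", ei = "E",
                     start = (seq_len(n_cols) - 1L) * n_per_col + 1L,
                     end = seq_len(n_cols) * n_per_col,
                     stringsAsFactors = FALSE)
  sp <- do.call(rbind, lapply(seq_len(n_cols), function(cl) {
    neuron <- pops$start[cl]:pops$end[cl]
    counts <- stats::rpois(n_per_col, rates_hz[cl] * duration / 1000)
    data.frame(neuron = rep(neuron, counts),
               time = stats::runif(sum(counts), 0, duration))
  }))
  structure(list(spikes = sp[order(sp$time), ], pops = pops,
                 duration = duration, dt = 0.1, seed = seed),
            class = "spike_record")
}

## Independent oracle for rate-model attractors: integrate the dynamics
## from many initial conditions and collect the distinct limit points.
## Completely bypasses the Newton/active-set machinery.
integration_attractors <- function(params, n_starts = 40, t_end = 4000,
                                   f_max = 120, tol = 1e-3, seed = 99) {
  set.seed(seed)
  ends <- list()
  for (i in seq_len(n_starts)) {
    f0 <- stats::runif(4, 0, f_max)
    tr <- integrate_rates(params, f0, duration = t_end, dt = 0.1,
                          record = as.integer(t_end / 0.1))
    fin <- tr[nrow(tr), -1]
    ## confirm convergence (not a cycle): derivative small at the endpoint
    d <- rate_derivatives(pmax(fin, 0), params)
    if (max(abs(d)) > 1e-6) next
    dup <- any(vapply(ends, function(g) max(abs(fin - g)) < tol, logical(1)))
    if (!dup) ends[[length(ends) + 1L]] <- fin
  }
  ends
}

## Dense-grid integration oracle for the SST silencing threshold:
## continuation by direct integration. Walks the SST drive upward in fine
## steps, integrating from the previous attractor state, and reports the
## last drive at which a pyramidal-active limit point persists. Because the
## attractor basin shrinks toward the fold, this is a LOWER bound on the
## true disappearance point (wherever it reports "alive", an attractor
## genuinely exists; it may lose the branch slightly early).
oracle_sst_threshold <- function(params, from = params$I_s, to = 367,
                                 step = 0.1) {
  carry <- c(10, 3, 1, 19)
  last_alive <- NA_real_
  for (I in seq(from, to, by = step)) {
    p <- params
    p$I_s <- I
    tr <- integrate_rates(p, carry, duration = 4000, dt = 0.1,
                          record = 40000L)
    fin <- tr[nrow(tr), -1]
    if (fin[1] > 0.01) {
      last_alive <- I
      carry <- fin
    } else break
  }
  last_alive
}
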