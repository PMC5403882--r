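#' Background drive specification
#'
#' Every neuron receives cell-type-specific background input as an
#' aggregate Poisson barrage: a fixed number of external fibers per
#' population, each carrying an independent Poisson train at a per-fiber
#' rate, with peak current 87.9 +/- 8.8 pA. The layer 2/3 interneuron types
#' share the inhibitory fiber count but have their own per-fiber rates
#' (PV 10 Hz, SST 2 Hz, VIP 8 Hz); all other rates default to 8 Hz.
#'
#' @param overrides Named list of per-fiber rate overrides (Hz), keyed by
#'   population name (e.g. `list(L23_SST = 6)`). Unknown names are an error.
#' @return Data frame with columns `pop`, `column` (0 = all columns),
#'   `fibers`, `rate_per_fiber_hz`, `aggregate_hz`.
#' @examples
#' background_drive()                  # defaults
#' background_drive(list(L23_VIP = 2)) # lowered VIP drive
#' @export
background_drive <- function(overrides = NULL) {
  rates <- BACKGROUND_RATES
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(rates))
    if (length(bad) > 0) stop("unknown population(s): ",
                              paste(bad, collapse = ", "))
    rates[names(overrides)] <- unlist(overrides)
  }
  if (any(rates < 0)) stop("background rates must be >= 0")
  data.frame(pop = names(BACKGROUND_FIBERS), column = 0L,
             fibers = unname(BACKGROUND_FIBERS),
             rate_per_fiber_hz = unname(rates[names(BACKGROUND_FIBERS)]),
             aggregate_hz = unname(BACKGROUND_FIBERS *
                                   rates[names(BACKGROUND_FIBERS)]),
             stringsAsFactors = FALSE)
}

new_experiment_spec <- function(name, n_columns, thal_rates, trials,
                                run_length, onset, stim_duration,
                                analysis_window, edge_cols = integer(0),
                                background_overrides = NULL,
                                intercol_p = NULL, extra = list()) {
  stopifnot(length(thal_rates) == n_columns)
  structure(c(list(name = name, n_columns = as.integer(n_columns),
                   thal_rates = thal_rates, trials = as.integer(trials),
                   run_length = run_length, onset = onset,
                   stim_duration = stim_duration,
                   analysis_window = analysis_window,
                   edge_cols = as.integer(edge_cols),
                   background_overrides = background_overrides,
                   intercol_p = intercol_p), extra),
            class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("experiment_spec '%s': %d column(s), %d trial(s), %g ms\n",
              x$name, x$n_columns, x$trials, x$run_length))
  cat(" thalamic rates (Hz):", paste(x$thal_rates, collapse = " "), "\n")
  invisible(x)
}

#' Single-column thalamic pulse experiment
#'
#' A transient thalamic volley: a single 10 ms wave of spikes starting at
#' 400 ms, delivered to layers 4 and 6 of one column, with PSTHs analyzed
#' over 350-600 ms. Named variants modify the background drive of one
#' superficial interneuron type: `sst_high` raises the SST per-fiber rate,
#' `vip_low` lowers and `vip_high` raises the VIP per-fiber rate.
#'
#' @param variant One of "default", "sst_high", "vip_low", "vip_high".
#' @param trials Number of independent trials (default 100).
#' @param thal_rate Thalamic firing rate during the pulse, Hz.
#' @param pulse_width Pulse duration, ms.
#' @param sst_high_rate,vip_low_rate,vip_high_rate Per-fiber background
#'   rates (Hz) used by the respective variants.
#' @return An `experiment_spec`.
#' @export
make_pulse_experiment <- function(variant = c("default", "sst_high",
                                              "vip_low", "vip_high"),
                                  trials = 100L, thal_rate = 100,
                                  pulse_width = 10,
                                  sst_high_rate = 6, vip_low_rate = 2,
                                  vip_high_rate = 14) {
  variant <- match.arg(variant)
  bg <- switch(variant,
               default = NULL,
               sst_high = list(L23_SST = sst_high_rate),
               vip_low = list(L23_VIP = vip_low_rate),
               vip_high = list(L23_VIP = vip_high_rate))
  new_experiment_spec(paste0("pulse_", variant), n_columns = 1L,
                      thal_rates = thal_rate, trials = trials,
                      run_length = 700, onset = 400,
                      stim_duration = pulse_width,
                      analysis_window = c(350, 600),
                      background_overrides = bg)
}

#' Figure-ground experiment
#'
#' A contiguous block of "figure" columns receives elevated thalamic drive
#' (80 Hz) against a 40 Hz "ground", 400-500 ms after onset, in the
#' 13-column periodic network. The first and last figure columns are the
#' edges; responses are edge-normalized per trial.
#'
#' @param fig_rate,ground_rate Thalamic rates (Hz) for figure and ground.
#' @param figure_cols Indices of the figure columns (default 5:9).
#' @param n_columns Number of columns (default 13).
#' @param trials Number of trials (default 100).
#' @param intercol_p Named list of intercolumnar probability overrides
#'   (see [build_network()]), e.g. `list(pyr_sst = 0.04)`.
#' @return An `experiment_spec`.
#' @export
make_figure_ground <- function(fig_rate = 80, ground_rate = 40,
                               figure_cols = 5:9, n_columns = 13L,
                               trials = 100L, intercol_p = NULL) {
  stopifnot(all(figure_cols >= 1), all(figure_cols <= n_columns))
  rates <- rep(ground_rate, n_columns)
  rates[figure_cols] <- fig_rate
  new_experiment_spec("figure_ground", n_columns = n_columns,
                      thal_rates = rates, trials = trials,
                      run_length = 600, onset = 400, stim_duration = 100,
                      analysis_window = c(400, 500),
                      edge_cols = range(figure_cols),
                      intercol_p = intercol_p)
}

#' Two-object experiment
#'
#' A dominant object (80 Hz thalamic drive to column 5) and a non-dominant
#' object (60 Hz to column 8) embedded in 40 Hz ground, with a sweep of
#' the intercolumnar Pyr->SST connection probability from its 0.2% baseline
#' up to 4% (a factor of 20).
#'
#' @param dom_col,dom_rate Dominant object column and rate (Hz).
#' @param nondom_col,nondom_rate Non-dominant object column and rate (Hz).
#' @param ground Ground thalamic rate, Hz.
#' @param n_columns Number of columns.
#' @param trials Trials per sweep point.
#' @param pyr_sst_grid Pyr->SST probability sweep (endpoints 0.002, 0.04).
#' @return An `experiment_spec` with a `pyr_sst_grid` element; run one
#'   sweep point by passing `intercol_p = list(pyr_sst = <value>)` to
#'   [run_experiment()].
#' @export
make_two_object <- function(dom_col = 5L, dom_rate = 80, nondom_col = 8L,
                            nondom_rate = 60, ground = 40, n_columns = 13L,
                            trials = 100L,
                            pyr_sst_grid = c(0.002, 0.004, 0.008, 0.02, 0.04)) {
  stopifnot(dom_col != nondom_col)
  rates <- rep(ground, n_columns)
  rates[dom_col] <- dom_rate
  rates[nondom_col] <- nondom_rate
  new_experiment_spec("two_object", n_columns = n_columns,
                      thal_rates = rates, trials = trials,
                      run_length = 600, onset = 400, stim_duration = 100,
                      analysis_window = c(400, 500),
                      extra = list(pyr_sst_grid = pyr_sst_grid,
                                   dom_col = as.integer(dom_col),
                                   nondom_col = as.integer(nondom_col)))
}

#' Top-down modulation experiment
#'
#' One preferred column (7) receives 80 Hz geniculate drive while all
#' others receive 40 Hz, and the background drives of VIP and SST cells are
#' varied on a factorial grid, identically in every column (non-specific
#' top-down signaling). The output of interest is the preferred versus
#' non-preferred normalized pyramidal response per grid cell.
#'
#' @param pref_col Preferred column (default 7).
#' @param pref_rate,ground Thalamic rates, Hz.
#' @param vip_bg_grid,sst_bg_grid Per-fiber background rate grids (Hz) for
#'   VIP and SST cells.
#' @param n_columns Number of columns.
#' @param trials Trials per grid cell.
#' @return An `experiment_spec` with `vip_bg_grid` and `sst_bg_grid`; run
#'   one grid cell by passing the matching `background_overrides`.
#' @export
make_topdown <- function(pref_col = 7L, pref_rate = 80, ground = 40,
                         vip_bg_grid = c(2, 5, 8, 11, 14),
                         sst_bg_grid = c(2, 4, 6, 8), n_columns = 13L,
                         trials = 100L) {
  stopifnot(length(vip_bg_grid) > 0, length(sst_bg_grid) > 0)
  rates <- rep(ground, n_columns)
  rates[pref_col] <- pref_rate
  new_experiment_spec("topdown", n_columns = n_columns, thal_rates = rates,
                      trials = trials, run_length = 600, onset = 400,
                      stim_duration = 100, analysis_window = c(400, 500),
                      extra = list(vip_bg_grid = vip_bg_grid,
                                   sst_bg_grid = sst_bg_grid,
                                   pref_col = as.integer(pref_col)))
}

#' Run an experiment: build the network and simulate all trials
#'
#' Builds the network once for the experiment's connectivity (structure
#' seed derived from `seed`), realizes the thalamic projection, then runs
#' `trials` independent simulations whose input realizations differ only
#' through per-trial seeds derived from `seed` by a fixed counter scheme.
#'
#' @param spec An `experiment_spec`.
#' @param seed Master seed; all randomness derives from it.
#' @param scale Network scale factor in (0, 1] (1 = full size).
#' @param trials Override the spec's trial count (e.g. for smoke runs).
#' @param compensate_weights Passed to the builder (default FALSE: raw
#'   downscaling; weight compensation inflates synaptic fluctuations and
#'   destabilizes the layer 2/3 regime at small scales).
#' @param intercol_p Overrides merged over the spec's own (sweeps).
#' @param background_overrides Overrides merged over the spec's own.
#' @param keep_graph Attach the built graph to the result (default FALSE).
#' @return List of class `experiment_result`: `records` (list of
#'   `spike_record`), `spec`, `seed`, `scale`, `trial_seeds`.
#' @export
run_experiment <- function(spec, seed = 1L, scale = 1,
                           trials = spec$trials,
                           compensate_weights = FALSE,
                           intercol_p = NULL, background_overrides = NULL,
                           keep_graph = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  icp <- spec$intercol_p
  if (!is.null(intercol_p)) {
    icp <- modifyList(icp %||% list(), intercol_p)
  }
  bgo <- spec$background_overrides
  if (!is.null(background_overrides)) {
    bgo <- modifyList(bgo %||% list(), background_overrides)
  }
  build_seed <- seed * 131L + 17L
  graph <- if (spec$n_columns == 1L) {
    build_column(seed = build_seed, scale = scale,
                 compensate_weights = compensate_weights)
  } else {
    build_network(n_columns = spec$n_columns, seed = build_seed,
                  scale = scale, intercol_p = icp,
                  compensate_weights = compensate_weights)
  }
  thal_proj <- build_thalamic_projection(graph, seed = build_seed + 1L)
  bg <- background_drive(bgo)
  prep <- prepare_simulation(graph, background = bg,
                             thalamus = list(projection = thal_proj,
                                             rates = spec$thal_rates,
                                             onset = spec$onset,
                                             stim_duration = spec$stim_duration))
  trial_seeds <- seed * 10000L + seq_len(trials)
  records <- lapply(trial_seeds, function(ts) {
    simulate(duration = spec$run_length, seed = ts, prep = prep)
  })
  out <- list(records = records, spec = spec, seed = seed, scale = scale,
              trial_seeds = trial_seeds,
              intercol_p = icp, background_overrides = bgo)
  if (keep_graph) out$graph <- graph
  structure(out, class = "experiment_result")
}
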