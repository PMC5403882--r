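## selection helper: global indices of one population (optionally one column)
pop_indices <- function(pops, population, column = NULL) {
  sel <- pops$name == population
  if (!is.null(column)) sel <- sel & pops$column == column
  rows <- pops[sel, ]
  if (nrow(rows) == 0L) stop("no such population: ", population)
  list(idx = unlist(Map(seq.int, rows$start, rows$end)),
       n = sum(rows$count))
}

#' Mean population firing rate in a time window
#'
#' Spike count of the population inside the window divided by neuron count
#' and window length: Hz per neuron.
#'
#' @param rec A `spike_record`.
#' @param population Population name (e.g. "L23_Pyr").
#' @param window Numeric `c(t0, t1)` in ms (spikes with `t0 < t <= t1`).
#' @param column Restrict to one column (default: all columns pooled).
#' @return Rate in Hz.
#' @export
population_rate <- function(rec, population, window, column = NULL) {
  stopifnot(window[2] > window[1], window[1] >= 0,
            window[2] <= rec$duration + 1e-9)
  sel <- pop_indices(rec$pops, population, column)
  sp <- rec$spikes
  cnt <- sum(sp$neuron %in% sel$idx & sp$time > window[1] &
             sp$time <= window[2])
  cnt / (sel$n * (window[2] - window[1])) * 1000
}

#' Per-column population rates
#'
#' @inheritParams population_rate
#' @return Numeric vector of Hz, one entry per column.
#' @export
column_rates <- function(rec, population = "L23_Pyr", window) {
  cols <- sort(unique(rec$pops$column))
  vapply(cols, function(cl) population_rate(rec, population, window, cl),
         numeric(1))
}

#' Trial-averaged peri-stimulus time histogram
#'
#' Bins spikes of one population across trials and normalizes to Hz per
#' neuron. Default bin width 5 ms.
#'
#' @param records List of `spike_record` (trials).
#' @param population Population name.
#' @param bin Bin width, ms.
#' @param column Restrict to one column (optional).
#' @return Object of class `psth`: list with `mid` (bin centers, ms),
#'   `rate` (Hz/neuron), `bin`, `population`, `n_trials`.
#' @export
psth <- function(records, population, bin = 5, column = NULL) {
  if (inherits(records, "spike_record")) records <- list(records)
  dur <- records[[1L]]$duration
  sel <- pop_indices(records[[1L]]$pops, population, column)
  breaks <- seq(0, dur, by = bin)
  counts <- numeric(length(breaks) - 1L)
  for (rec in records) {
    sp <- rec$spikes
    t <- sp$time[sp$neuron %in% sel$idx]
    if (length(t) > 0) {
      counts <- counts + tabulate(findInterval(t, breaks,
                                               left.open = TRUE,
                                               rightmost.closed = TRUE),
                                  nbins = length(counts))
    }
  }
  rate <- counts / (length(records) * sel$n * bin) * 1000
  structure(list(mid = breaks[-1L] - bin / 2, rate = rate, bin = bin,
                 population = population, n_trials = length(records)),
            class = "psth")
}

#' Edge-normalized column response profile
#'
#' Computes per-column layer 2/3 pyramidal rates in the analysis window for
#' every trial, then normalizes. In `per_trial_edge_mean` mode each trial's
#' rates are divided by that trial's mean edge-column rate before
#' averaging (so the edge mean is 1 by construction); trials whose edge
#' mean is zero are excluded and counted. In `pooled_reference` mode the
#' trial-averaged rates are divided by the supplied `reference` scalar
#' (e.g. the edge mean of a baseline condition).
#'
#' @param records List of `spike_record` (>= 2 trials for standard errors).
#' @param edge_cols Integer vector of edge column indices.
#' @param mode `"per_trial_edge_mean"` (default) or `"pooled_reference"`.
#' @param window Analysis window `c(t0, t1)` ms.
#' @param reference Reference scalar for `pooled_reference` mode.
#' @param population Population to read out (default layer 2/3 Pyr).
#' @return Object of class `column_profile`: list with `profile`
#'   (normalized mean per column), `se` (standard error across trials),
#'   `raw` (trial x column rate matrix, Hz), `mode`, `edge_cols`,
#'   `n_excluded`.
#' @export
edge_normalized_profile <- function(records, edge_cols,
                                    mode = c("per_trial_edge_mean",
                                             "pooled_reference"),
                                    window, reference = NULL,
                                    population = "L23_Pyr") {
  mode <- match.arg(mode)
  stopifnot(length(records) >= 2L)
  n_cols <- length(unique(records[[1L]]$pops$column))
  raw <- t(vapply(records, function(rec) {
    column_rates(rec, population, window)
  }, numeric(n_cols)))
  n_excluded <- 0L
  if (mode == "per_trial_edge_mean") {
    edge_mean <- rowMeans(raw[, edge_cols, drop = FALSE])
    keep <- edge_mean > 0
    n_excluded <- sum(!keep)
    if (!any(keep)) stop("all trials have zero edge-column response")
    norm <- raw[keep, , drop = FALSE] / edge_mean[keep]
    profile <- colMeans(norm)
    se <- apply(norm, 2L, stats::sd) / sqrt(nrow(norm))
  } else {
    if (is.null(reference) || reference <= 0) {
      stop("pooled_reference mode needs a positive reference scalar")
    }
    profile <- colMeans(raw) / reference
    se <- apply(raw, 2L, stats::sd) / sqrt(nrow(raw)) / reference
  }
  structure(list(profile = profile, se = se, raw = raw, mode = mode,
                 edge_cols = edge_cols, n_excluded = n_excluded),
            class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  cat("column_profile (", x$mode, "):\n", sep = "")
  print(round(rbind(profile = x$profile, se = x$se), 3))
  invisible(x)
}

#' Response onset latencies from PSTHs
#'
#' The onset latency of a PSTH is the left edge of the first bin after
#' stimulus onset whose rate exceeds the baseline mean plus `k` baseline
#' standard deviations, sustained for `persist` consecutive bins. PSTHs
#' that never cross are reported as `NA` ("absent").
#'
#' @param psths Named list of `psth` objects (e.g. one per cell type).
#' @param baseline_window `c(t0, t1)` ms over which baseline mean and SD
#'   are estimated; must precede the stimulus.
#' @param onset Stimulus onset time, ms; crossings are searched after it.
#' @param k Threshold in baseline SDs (default 3).
#' @param persist Number of consecutive suprathreshold bins required.
#' @return List with `latency` (named vector, ms or NA) and `order` (names
#'   sorted by latency, absent last).
#' @export
onset_latencies <- function(psths, baseline_window, onset, k = 3,
                            persist = 2L) {
  lat <- vapply(psths, function(p) {
    base <- p$rate[p$mid > baseline_window[1] & p$mid <= baseline_window[2]]
    thr <- mean(base) + k * stats::sd(base)
    cand <- which(p$mid > onset & p$rate > thr)
    if (length(cand) == 0L) return(NA_real_)
    for (i in cand) {
      run <- i:min(i + persist - 1L, length(p$rate))
      if (length(run) == persist && all(p$rate[run] > thr)) {
        return(p$mid[i] - p$bin / 2)
      }
    }
    NA_real_
  }, numeric(1))
  list(latency = lat, order = names(sort(lat, na.last = TRUE)))
}

#' Bin a population rate time series
#'
#' @param rec A `spike_record`.
#' @param population Population name.
#' @param bin Bin width, ms (default 1).
#' @param column Restrict to one column (optional).
#' @return List with `mid` (ms) and `rate` (Hz/neuron).
#' @export
bin_population_rate <- function(rec, population, bin = 1, column = NULL) {
  p <- psth(list(rec), population, bin = bin, column = column)
  list(mid = p$mid, rate = p$rate)
}

#' Dominant oscillation frequency of a population rate series
#'
#' Removes the mean, computes the periodogram, smooths it with a short
#' running mean, and reports the frequency of the largest peak when its
#' smoothed power exceeds `min_ratio` times the median smoothed power
#' (otherwise the oscillation is reported absent). Asynchronous (white)
#' firing has a flat spectrum and yields no peak by this criterion.
#'
#' @param rate Numeric rate series (Hz), regularly sampled.
#' @param bin Sample spacing of `rate`, ms.
#' @param window Restrict to this time window `c(t0, t1)` in ms (>= 500 ms
#'   long), assuming `rate` starts at time 0; NULL uses the whole series.
#' @param min_ratio Peak-to-median power ratio required (default 3).
#' @param span Running-mean smoothing width in spectral bins (odd).
#' @return NULL if no oscillation; otherwise list with `frequency` (Hz)
#'   and `power_ratio`.
#' @export
oscillation_frequency <- function(rate, bin = 1, window = NULL,
                                  min_ratio = 3, span = 7L) {
  if (!is.null(window)) {
    stopifnot(window[2] - window[1] >= 500)
    idx <- seq_along(rate) * bin
    rate <- rate[idx > window[1] & idx <= window[2]]
  }
  n <- length(rate)
  if (n < 16L) stop("rate series too short")
  x <- rate - mean(rate)
  if (stats::sd(x) == 0) return(NULL)
  pw <- Mod(stats::fft(x))^2 / n
  half <- pw[2:floor(n / 2)]
  freq <- (seq_along(half)) / (n * bin / 1000)   # Hz
  ## running-mean smoothing
  sm <- stats::filter(half, rep(1 / span, span), sides = 2)
  ok <- !is.na(sm)
  sm <- sm[ok]; freq <- freq[ok]
  ratio <- max(sm) / stats::median(sm)
  if (ratio < min_ratio) return(NULL)
  list(frequency = freq[which.max(sm)], power_ratio = ratio)
}
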