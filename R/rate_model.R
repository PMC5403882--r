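#' Parameters for the four-population superficial-layer rate model
#'
#' Constructs the parameter set of the Wilson-Cowan-type firing-rate model of
#' the layer 2/3 microcircuit with pyramidal (e), PV (p), SST (s) and VIP (v)
#' populations. Each population converts its net synaptic drive (pA) into a
#' firing rate through a rectified square-root gain function with threshold
#' `theta`. Defaults are the fitted superficial-layer coefficients of the
#' full spiking model (weights in pA per Hz, drives in pA).
#'
#' The signs of the couplings are structural: all `S_xy` are magnitudes, and
#' the model applies them with the sign dictated by the source cell class
#' (excitatory for pyramidal sources, inhibitory otherwise). SST cells
#' receive no self-inhibition and no PV input; VIP cells inhibit SST most
#' strongly; PV cells inhibit pyramidal cells and themselves.
#'
#' @param S_ee,S_ep,S_es,S_ev Couplings onto the pyramidal population from
#'   e, p, s, v (pA/Hz, all non-negative).
#' @param S_pe,S_pp,S_ps Couplings onto PV from e, p, s.
#' @param S_se,S_sv Couplings onto SST from e and v (SST gets no PV or SST
#'   input).
#' @param S_ve,S_vp,S_vs Couplings onto VIP from e, p, s.
#' @param I_e,I_p,I_s,I_v Applied (external) currents, pA.
#' @param theta Firing threshold of the gain function, pA.
#' @param tau_m Membrane/rate relaxation time constant, ms.
#' @param gain_coeff Named numeric vector `c(e=,p=,s=,v=)` of gain
#'   coefficients (Hz per sqrt(pA)). A scalar is recycled to all four.
#' @return An object of class `rate_model_params` (a named list).
#' @examples
#' p <- rate_model_params()
#' p$I_s
#' @export
rate_model_params <- function(S_ee = 1.98, S_ep = 5.68, S_es = 3.05, S_ev = 0.12,
                              S_pe = 0.55, S_pp = 2.28, S_ps = 0.55,
                              S_se = 0.55, S_sv = 0.36,
                              S_ve = 0.55, S_vp = 0.50, S_vs = 1.48,
                              I_e = 366, I_p = 362, I_s = 361, I_v = 370,
                              theta = 360, tau_m = 10,
                              gain_coeff = 5.33) {
  if (length(gain_coeff) == 1L) {
    gain_coeff <- c(e = gain_coeff, p = gain_coeff, s = gain_coeff, v = gain_coeff)
  }
  gain_coeff <- gain_coeff[c("e", "p", "s", "v")]
  p <- list(S_ee = S_ee, S_ep = S_ep, S_es = S_es, S_ev = S_ev,
            S_pe = S_pe, S_pp = S_pp, S_ps = S_ps,
            S_se = S_se, S_sv = S_sv,
            S_ve = S_ve, S_vp = S_vp, S_vs = S_vs,
            I_e = I_e, I_p = I_p, I_s = I_s, I_v = I_v,
            theta = theta, tau_m = tau_m, gain_coeff = gain_coeff)
  S <- unlist(p[grep("^S_", names(p))])
  if (any(S < 0)) stop("all couplings S_xy must be >= 0 (signs are structural)")
  if (tau_m <= 0) stop("tau_m must be > 0")
  if (any(!is.finite(gain_coeff)) || any(gain_coeff <= 0)) {
    stop("gain coefficients must be positive")
  }
  structure(p, class = "rate_model_params")
}

#' Rectified square-root gain function
#'
#' Static nonlinearity of the rate model: `g(u) = coeff * sqrt(u - theta)`
#' for drives above threshold and 0 otherwise. It approximates the F-I curve
#' of the leaky integrate-and-fire neuron used in the spiking model.
#'
#' @param drive Net synaptic drive, pA (vectorized).
#' @param coeff Gain coefficient, Hz per sqrt(pA).
#' @param theta Threshold, pA.
#' @return Firing rate in Hz (non-negative).
#' @export
gain <- function(drive, coeff = 5.33, theta = 360) {
  coeff * sqrt(pmax(drive - theta, 0))
}

## Net synaptic drives (pA) of the four populations given rates f = c(e,p,s,v).
## SST receives only pyramidal excitation and VIP inhibition.
net_drives <- function(f, params) {
  p <- params
  c(e = p$I_e + p$S_ee * f[1] - p$S_ep * f[2] - p$S_es * f[3] - p$S_ev * f[4],
    p = p$I_p + p$S_pe * f[1] - p$S_pp * f[2] - p$S_ps * f[3],
    s = p$I_s + p$S_se * f[1] - p$S_sv * f[4],
    v = p$I_v + p$S_ve * f[1] - p$S_vp * f[2] - p$S_vs * f[3])
}

#' Time derivatives of the four population rates
#'
#' Evaluates `df_x/dt = (-f_x + g(net_x)) / tau_m` for the four populations,
#' where `net_x` is the net synaptic drive of population `x`.
#'
#' @param state Numeric vector of rates `c(e=,p=,s=,v=)` in Hz (names
#'   optional, order e, p, s, v).
#' @param params A [rate_model_params()] object.
#' @return Named numeric vector of derivatives, Hz/ms.
#' @export
rate_derivatives <- function(state, params) {
  f <- as.numeric(state)
  if (any(f < -1e-12)) stop("rates must be non-negative")
  u <- net_drives(f, params)
  g <- params$gain_coeff * sqrt(pmax(u - params$theta, 0))
  d <- (-f + g) / params$tau_m
  names(d) <- c("e", "p", "s", "v")
  d
}

#' Integrate the rate equations
#'
#' Fixed-step 4th-order Runge-Kutta integration of the four-population rate
#' model. Rates stay non-negative from non-negative initial conditions
#' because the gain is non-negative.
#'
#' @param params A [rate_model_params()] object.
#' @param initial Initial rates `c(e,p,s,v)` in Hz.
#' @param duration Total integration time, ms.
#' @param dt Step, ms.
#' @param record Record every `record`-th step (1 = all).
#' @return Matrix with columns `time, f_e, f_p, f_s, f_v`.
#' @export
integrate_rates <- function(params, initial = c(0, 0, 0, 0), duration = 1000,
                            dt = 0.1, record = 1L) {
  stopifnot(dt > 0, duration > 0)
  out <- .rate_rk4_cpp(par_vec(params), pmax(as.numeric(initial), 0),
                       duration, dt, as.integer(record))
  colnames(out) <- c("time", "f_e", "f_p", "f_s", "f_v")
  out
}

## flatten params for the compiled kernels
par_vec <- function(p) {
  c(p$S_ee, p$S_ep, p$S_es, p$S_ev, p$S_pe, p$S_pp, p$S_ps,
    p$S_se, p$S_sv, p$S_ve, p$S_vp, p$S_vs,
    p$I_e, p$I_p, p$I_s, p$I_v, p$theta, p$tau_m, p$gain_coeff)
}

#' Enumerate steady states of the rate model
#'
#' Finds fixed points by enumerating all 16 subsets of active populations and
#' solving the restricted system `f_x = g(net_x)` for each subset with
#' multi-start Newton iteration (starts on a deterministic Halton-like
#' log-spaced lattice in \[0.1, 200\] Hz). A candidate is kept only when the
#' populations outside the active set have net drive at or below threshold
#' (so pinning them at zero is self-consistent). Solutions are deduplicated
#' and classified with [classify_stability()].
#'
#' Completeness is relative to the multi-start grid: isolated roots far
#' outside \[0.1, 200\] Hz could in principle be missed.
#'
#' @param params A [rate_model_params()] object.
#' @param n_starts Starts per active set.
#' @param f_range Range (Hz) of the start lattice.
#' @param tol Residual tolerance (Hz) for an accepted fixed point.
#' @param dedup_tol Rate distance (Hz) under which two solutions are merged.
#' @param classify Also run stability classification (default TRUE).
#' @param integrate_seeds Also seed the solver with endpoints of trajectories
#'   integrated from a coarse lattice of initial conditions, so attractors
#'   whose basins miss the lattice of Newton starts are still found.
#' @param extra_starts Optional matrix (rows of 4 rates) of additional solver
#'   starts; used by the scan functions to carry solutions between adjacent
#'   grid points (poor-man's continuation).
#' @return A list of `steady_state` objects: each has `rates` (named vector),
#'   `active_set` (character), `stability`, `eigenvalues`, `residual`.
#'   Attribute `n_failed` counts non-converged starts.
#' @export
enumerate_steady_states <- function(params, n_starts = 200L,
                                    f_range = c(0.1, 200),
                                    tol = 1e-10, dedup_tol = 1e-4,
                                    classify = TRUE, integrate_seeds = TRUE,
                                    extra_starts = NULL) {
  extra <- matrix(numeric(0), ncol = 4)
  if (!is.null(extra_starts)) {
    extra <- rbind(extra, matrix(as.numeric(extra_starts), ncol = 4))
  }
  if (isTRUE(integrate_seeds)) {
    ## attractor-seeded starts: integrate from a coarse lattice of initial
    ## conditions and hand the trajectory endpoints to the Newton solver,
    ## so attractors with small lattice basins are not missed
    ics <- as.matrix(expand.grid(f_e = c(0.5, 5, 50), f_p = c(0.5, 5, 50),
                                 f_s = c(0.5, 5, 50), f_v = c(0.5, 5, 50)))
    ends <- t(apply(ics, 1, function(f0) {
      tr <- integrate_rates(params, f0, duration = 2500, dt = 0.1,
                            record = 25000L)
      tr[nrow(tr), -1]
    }))
    extra <- rbind(extra, ends)
  }
  res <- .solve_active_sets_cpp(par_vec(params), as.integer(n_starts),
                                f_range[1], f_range[2], tol, dedup_tol, 200L,
                                extra)
  out <- lapply(seq_len(nrow(res$roots)), function(i) {
    ss <- steady_state(params, res$roots[i, ])
    if (classify) ss <- classify_stability(params, ss) else ss
  })
  attr(out, "n_failed") <- res$n_failed
  out
}

## construct a steady_state object from a rate vector (no classification yet)
steady_state <- function(params, rates) {
  rates <- as.numeric(rates)
  names(rates) <- c("e", "p", "s", "v")
  u <- net_drives(rates, params)
  g <- params$gain_coeff * sqrt(pmax(u - params$theta, 0))
  structure(list(rates = rates,
                 active_set = names(rates)[rates > 1e-8],
                 stability = NA_character_,
                 eigenvalues = complex(0),
                 residual = max(abs(rates - g))),
            class = "steady_state")
}

#' Classify the linear stability of a steady state
#'
#' Builds the Jacobian of [rate_derivatives()] at the fixed point, using the
#' right-hand derivative of the square-root gain for active populations and
#' the locked (zero-gain) branch for populations whose drive is strictly
#' below threshold. A population whose drive sits exactly at threshold makes
#' the Jacobian one-sided; if the leading eigenvalue real part is within
#' `tol` of zero the state is labelled `"marginal"` rather than guessed.
#' Unstable states with a complex leading pair are candidates for a
#' surrounding limit cycle; with `confirm_cycles = TRUE` a trajectory from a
#' perturbed state is integrated and the state is labelled `"oscillatory"`
#' if a sustained oscillation is detected.
#'
#' @param params A [rate_model_params()] object.
#' @param ss A `steady_state` object (from [enumerate_steady_states()]).
#' @param tol Margin (1/ms) around zero real part treated as marginal.
#' @param confirm_cycles Integrate to confirm oscillatory candidates.
#' @return The `steady_state` with `stability` one of
#'   `"stable"`, `"unstable"`, `"oscillatory"`, `"marginal"` and
#'   `eigenvalues` filled in.
#' @export
classify_stability <- function(params, ss, tol = 1e-8, confirm_cycles = TRUE) {
  stopifnot(inherits(ss, "steady_state"))
  if (ss$residual > 1e-6) {
    stop("state does not satisfy the fixed-point residual tolerance")
  }
  f <- ss$rates
  u <- net_drives(f, params)
  ex <- u - params$theta
  A <- matrix(c(params$S_ee, -params$S_ep, -params$S_es, -params$S_ev,
                params$S_pe, -params$S_pp, -params$S_ps, 0,
                params$S_se, 0, 0, -params$S_sv,
                params$S_ve, -params$S_vp, -params$S_vs, 0),
              nrow = 4, byrow = TRUE)
  gp <- numeric(4)
  at_kink <- FALSE
  for (x in 1:4) {
    if (ex[x] > 1e-9) {
      gp[x] <- params$gain_coeff[x] / (2 * sqrt(ex[x]))
    } else if (abs(ex[x]) <= 1e-9 && f[x] <= 1e-8) {
      at_kink <- TRUE            # sitting exactly at threshold: one-sided
      gp[x] <- 0
    } else {
      gp[x] <- 0                 # strictly below threshold, gain locked at 0
    }
  }
  J <- (diag(-1, 4) + gp * A) / params$tau_m
  ev <- eigen(J, only.values = TRUE)$values
  remax <- max(Re(ev))
  lab <- if (at_kink && abs(remax) <= tol) "marginal"
  else if (abs(remax) <= tol) "marginal"
  else if (remax < 0) "stable"
  else "unstable"
  if (lab == "unstable" && any(abs(Im(ev[Re(ev) > tol])) > tol) && confirm_cycles) {
    if (!is.null(detect_limit_cycle(params, perturb(ss$rates)))) lab <- "oscillatory"
  }
  ss$stability <- lab
  ss$eigenvalues <- ev
  ss
}

perturb <- function(f, eps = 0.5) pmax(f + eps, 0)

#' Detect a stable limit cycle by integration
#'
#' Integrates the rate equations for `t_total` ms, discards the first
#' `t_discard` ms, and declares a limit cycle when the pyramidal rate shows
#' peak-to-peak variation above `min_amplitude` Hz with a stable period
#' (coefficient of variation of successive peak intervals below 5%).
#'
#' @param params A [rate_model_params()] object.
#' @param initial Initial rates, Hz.
#' @param t_total,t_discard Integration horizon and discarded transient, ms.
#' @param dt Step, ms.
#' @param min_amplitude Peak-to-peak threshold on `f_e`, Hz.
#' @return `NULL` if no cycle; otherwise a list with `period` (ms),
#'   `amplitude` (Hz peak-to-peak of `f_e`) and `mean_rates`.
#' @export
detect_limit_cycle <- function(params, initial, t_total = 2000, t_discard = 1000,
                               dt = 0.1, min_amplitude = 0.5) {
  tr <- integrate_rates(params, initial, duration = t_total, dt = dt)
  keep <- tr[, "time"] > t_discard
  fe <- tr[keep, "f_e"]
  tt <- tr[keep, "time"]
  amp <- diff(range(fe))
  if (!is.finite(amp) || amp < min_amplitude) return(NULL)
  ## interior maxima
  n <- length(fe)
  pk <- which(fe[2:(n - 1)] > fe[1:(n - 2)] & fe[2:(n - 1)] >= fe[3:n]) + 1L
  ## only count prominent peaks (above midline)
  pk <- pk[fe[pk] > min(fe) + amp / 2]
  if (length(pk) < 4L) return(NULL)
  per <- diff(tt[pk])
  if (length(per) < 3L) return(NULL)
  if (stats::sd(per) / mean(per) > 0.05) return(NULL)
  list(period = mean(per), amplitude = amp,
       mean_rates = colMeans(tr[keep, c("f_e", "f_p", "f_s", "f_v")]))
}

#' Scan an applied current and trace solution branches
#'
#' For each grid value of the chosen applied current, enumerates steady
#' states, classifies their stability, and checks for stable limit cycles
#' around oscillatory candidates. This is a grid-based companion to
#' numerical continuation: branch positions are resolved to the grid, not
#' followed by arclength stepping.
#'
#' @param params A [rate_model_params()] object (the non-varied parameters).
#' @param varied One of `"I_e"`, `"I_p"`, `"I_s"`, `"I_v"`.
#' @param grid Strictly increasing numeric vector of current values, pA.
#' @param ... Passed to [enumerate_steady_states()].
#' @return An object of class `branch_scan`: a data frame with columns
#'   `varied_value, branch_id, f_e, f_p, f_s, f_v, stability`, with
#'   attributes `varied` and `limit_cycle_ranges` (matrix of pA intervals
#'   where a stable oscillation was detected).
#' @export
scan_input <- function(params, varied = c("I_s", "I_v", "I_e", "I_p"),
                       grid, ...) {
  varied <- match.arg(varied)
  stopifnot(all(diff(grid) > 0))
  rows <- vector("list", length(grid))
  cyc <- logical(length(grid))
  seeds <- NULL
  for (i in seq_along(grid)) {
    p <- params
    p[[varied]] <- grid[i]
    sts <- tryCatch(enumerate_steady_states(p, extra_starts = seeds, ...),
                    error = function(e) {
                      warning(sprintf("grid point %g failed: %s", grid[i],
                                      conditionMessage(e)))
                      list()
                    })
    seeds <- carry_seeds(sts)
    cyc[i] <- any(vapply(sts, function(s) s$stability == "oscillatory",
                         logical(1)))
    rows[[i]] <- do.call(rbind, lapply(seq_along(sts), function(b) {
      s <- sts[[b]]
      data.frame(varied_value = grid[i], branch_id = b,
                 f_e = s$rates["e"], f_p = s$rates["p"],
                 f_s = s$rates["s"], f_v = s$rates["v"],
                 stability = s$stability, row.names = NULL)
    }))
  }
  df <- do.call(rbind, rows)
  ranges <- if (any(cyc)) {
    r <- rle(cyc)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(lo = grid[starts[r$values]], hi = grid[ends[r$values]])
  } else matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("lo", "hi")))
  structure(df, varied = varied, limit_cycle_ranges = ranges,
            class = c("branch_scan", "data.frame"))
}

#' Write a branch scan as a delimited table
#'
#' @param scan A `branch_scan` from [scan_input()].
#' @param path Output file path (tab-separated).
#' @export
write_branch_scan <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Largest pyramidal rate over stable attractors (steady states and, when
## requested, limit cycles) for a precomputed state list; 0 if none active.
max_stable_fe <- function(params, states, check_cycles = TRUE) {
  fe <- vapply(states, function(s) {
    if (s$stability == "stable") s$rates[["e"]] else NA_real_
  }, numeric(1))
  best <- if (all(is.na(fe))) 0 else max(fe, na.rm = TRUE)
  if (check_cycles) {
    osc <- Filter(function(s) s$stability %in% c("oscillatory", "unstable"),
                  states)
    for (s in osc) {
      cyc <- detect_limit_cycle(params, perturb(s$rates))
      if (!is.null(cyc)) best <- max(best, cyc$mean_rates[["f_e"]] + cyc$amplitude / 2)
    }
  }
  best
}

## perturbed copies of found states, used to seed the adjacent grid point
carry_seeds <- function(states) {
  if (length(states) == 0L) return(NULL)
  do.call(rbind, lapply(states, function(s) {
    r <- s$rates
    rbind(r, pmax(r * 1.1 + 0.05, 0), pmax(r * 0.9 - 0.05, 0))
  }))
}

#' Smallest SST drive that silences pyramidal activity
#'
#' Sweeps the applied current to the SST population upward on a grid of
#' spacing `step`, carrying the solutions found at each grid point forward
#' as solver seeds so that folding branches are tracked to their end, and
#' returns the smallest drive above which no stable attractor (steady state
#' or limit cycle) retains pyramidal activity above `fe_floor`.
#'
#' @param params A [rate_model_params()] object.
#' @param step Grid resolution of the returned threshold, pA (must be <= 1).
#' @param I_range Scan range for the SST drive, pA.
#' @param fe_floor Pyramidal rate (Hz) below which activity counts as silenced.
#' @param ... Passed to [enumerate_steady_states()].
#' @return Threshold in pA (midpoint between the last grid value with
#'   pyramidal activity and the first without).
#' @export
sst_silencing_threshold <- function(params, step = 0.5,
                                    I_range = c(params$I_s, 420),
                                    fe_floor = 0.01, ...) {
  stopifnot(step <= 1)
  grid <- seq(I_range[1], I_range[2], by = step)
  alive <- logical(length(grid))
  seeds <- NULL
  for (i in seq_along(grid)) {
    p <- params
    p$I_s <- grid[i]
    sts <- enumerate_steady_states(p, integrate_seeds = (i == 1L),
                                   extra_starts = seeds, ...)
    seeds <- carry_seeds(sts)
    alive[i] <- max_stable_fe(p, sts) > fe_floor
  }
  if (alive[length(alive)]) stop("threshold not in range")
  if (!alive[1]) stop("pyramidal activity already silenced at the lower bound")
  i <- max(which(alive))
  (grid[i] + grid[i + 1L]) / 2
}

#' Activation threshold of the VIP population
#'
#' Minimum applied current at which VIP cells begin to fire when all other
#' populations are silent. With zero recurrent input the VIP net drive is
#' its applied current alone, so the threshold equals the gain threshold
#' `theta` exactly; the function evaluates that analytically.
#'
#' @param params A [rate_model_params()] object.
#' @return Threshold in pA.
#' @export
vip_activation_threshold <- function(params) {
  params$theta
}
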