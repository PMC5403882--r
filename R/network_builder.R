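## ---------------------------------------------------------------------------
## Default network constants
##
## Per-column neuron counts, superficial-layer synaptic parameters
## (peak currents, decay time constants, delays), intercolumnar connection
## probabilities and the inhibitory weighting factors. The interlaminar
## probability map is the published layered-microcircuit map of the
## Potjans-Diesmann lineage that the base columnar model derives from; it is
## config-overridable.
## ---------------------------------------------------------------------------

## neuron counts per column (excitatory / inhibitory per layer)
LAYER_COUNTS <- c(L23_E = 5171L, L23_I = 1459L, L4_E = 5479L, L4_I = 1370L,
                  L5_E = 1213L, L5_I = 266L, L6_E = 3599L, L6_I = 737L)

## fractions of the superficial inhibitory pool
VIP_FRACTION <- 0.24
SST_FRACTION <- 0.30

## base-model connection probabilities C[target, source]
## (layered microcircuit map, Potjans-Diesmann lineage)
PD_POPS <- c("L23E", "L23I", "L4E", "L4I", "L5E", "L5I", "L6E", "L6I")
PD_PROB <- matrix(c(
  ## src:  L23E    L23I    L4E     L4I     L5E     L5I     L6E     L6I
  0.1009, 0.1689, 0.0437, 0.0818, 0.0323, 0.0000, 0.0076, 0.0000,  # -> L23E
  0.1346, 0.1371, 0.0316, 0.0515, 0.0755, 0.0000, 0.0042, 0.0000,  # -> L23I
  0.0077, 0.0059, 0.0497, 0.1350, 0.0067, 0.0003, 0.0453, 0.0000,  # -> L4E
  0.0691, 0.0029, 0.0794, 0.1597, 0.0033, 0.0000, 0.1057, 0.0000,  # -> L4I
  0.1004, 0.0622, 0.0505, 0.0057, 0.0831, 0.3726, 0.0204, 0.0000,  # -> L5E
  0.0548, 0.0269, 0.0257, 0.0022, 0.0600, 0.3158, 0.0086, 0.0000,  # -> L5I
  0.0156, 0.0066, 0.0211, 0.0166, 0.0572, 0.0197, 0.0396, 0.2252,  # -> L6E
  0.0364, 0.0010, 0.0034, 0.0005, 0.0277, 0.0080, 0.0658, 0.1443   # -> L6I
), nrow = 8, byrow = TRUE, dimnames = list(PD_POPS, PD_POPS))

## thalamic targeting probabilities (layers 4 and 6, E and I)
THALAMIC_PROB <- c(L4_E = 0.0983, L4_I = 0.0619, L6_E = 0.0512, L6_I = 0.0196)
N_THALAMIC_PER_COLUMN <- 902L

## peak currents (pA), mean and jitter SD
PEAK_DEFAULT_EXC <- c(w = 175.6, dw = 17.6)
PEAK_DEFAULT_INH <- c(w = -702.4, dw = 70.2)
PEAK_L4E_TO_PYR <- c(w = 245.84, dw = 24.6)
## superficial cell-type-specific inhibitory peaks and decay constants
SUPERFICIAL_INH <- data.frame(
  src = c("PV", "PV", "PV", "SST", "SST", "SST", "VIP", "VIP"),
  tgt = c("Pyr", "PV", "VIP", "Pyr", "PV", "VIP", "Pyr", "SST"),
  w   = c(-466.7, -638.1, -140.04, -200.0, -228.6, -525.8, -76.2, -66.7),
  dw  = c(46.7, 63.8, 14.0, 20.0, 22.9, 52.6, 7.62, 6.7),
  tau = c(6.0, 4.3, 4.3, 7.5, 3.4, 3.4, 6.2, 10.4),
  stringsAsFactors = FALSE)
TAU_SUPERFICIAL_EXC <- 2.0   # lengthened excitatory decay in layer 2/3
TAU_DEFAULT <- 0.5           # default exc/inh decay elsewhere

## inhibitory weighting factors for the synapse-budget split
WEIGHT_TO_PYR <- c(PV = 1, SST = 1, VIP = 0.125)
WEIGHT_TO_PV <- c(PV = 1, SST = 0.857)
WEIGHT_TO_VIP <- c(SST = 1, PV = 1)
WEIGHT_VIP_TO_SST <- 0.625

## synaptic delays (ms), mean and jitter SD
DELAY_INTRA_EXC <- c(d = 1.5, dd = 0.75)
DELAY_INTRA_INH <- c(d = 0.75, dd = 0.375)
DELAY_INTER_EXC <- c(d = 7.5, dd = 3.75)
DELAY_INTER_INH <- c(d = 3.75, dd = 1.88)

## intercolumnar connection probabilities and reaches (superficial only)
INTERCOL_RULES <- data.frame(
  name = c("pyr_pyr", "pv_pyr", "pyr_pv", "pyr_sst"),
  src = c("L23_Pyr", "L23_PV", "L23_Pyr", "L23_Pyr"),
  tgt = c("L23_Pyr", "L23_Pyr", "L23_PV", "L23_SST"),
  p = c(0.066, 0.046, 0.009, 0.002),
  reach = c(1L, 1L, 1L, 4L),
  stringsAsFactors = FALSE)

## external background fibers and per-fiber rates (Hz)
BACKGROUND_FIBERS <- c(L23_Pyr = 1600, L23_PV = 1500, L23_SST = 1500,
                       L23_VIP = 1500, L4_E = 2100, L4_I = 1900,
                       L5_E = 2000, L5_I = 1900, L6_E = 2900, L6_I = 2100)
BACKGROUND_RATES <- c(L23_Pyr = 8, L23_PV = 10, L23_SST = 2, L23_VIP = 8,
                      L4_E = 8, L4_I = 8, L5_E = 8, L5_I = 8, L6_E = 8,
                      L6_I = 8)
BACKGROUND_PEAK <- c(w = 87.9, dw = 8.8)

POP_NAMES <- c("L23_Pyr", "L23_PV", "L23_SST", "L23_VIP",
               "L4_E", "L4_I", "L5_E", "L5_I", "L6_E", "L6_I")
POP_BASE <- c(L23_Pyr = "L23E", L23_PV = "L23I", L23_SST = "L23I",
              L23_VIP = "L23I", L4_E = "L4E", L4_I = "L4I", L5_E = "L5E",
              L5_I = "L5I", L6_E = "L6E", L6_I = "L6I")
POP_EI <- c(L23_Pyr = "E", L23_PV = "I", L23_SST = "I", L23_VIP = "I",
            L4_E = "E", L4_I = "I", L5_E = "E", L5_I = "I", L6_E = "E",
            L6_I = "I")

## receptor channels per population: decay taus, in fixed order; synapses
## select the channel whose tau matches theirs, background uses "ext"
POP_CHANNELS <- list(
  L23_Pyr = c(exc = 2.0, pv = 6.0, sst = 7.5, vip = 6.2, ext = 0.5),
  L23_PV = c(exc = 2.0, pv = 4.3, sst = 3.4, ext = 0.5),
  L23_SST = c(exc = 2.0, vip = 10.4, ext = 0.5),
  L23_VIP = c(exc = 2.0, pv = 4.3, sst = 3.4, ext = 0.5),
  L4_E = c(ext = 0.5), L4_I = c(ext = 0.5), L5_E = c(ext = 0.5),
  L5_I = c(ext = 0.5), L6_E = c(ext = 0.5), L6_I = c(ext = 0.5))

#' Split a superficial inhibitory pool into PV, SST and VIP counts
#'
#' Layer 2/3 inhibitory cells are split into 24% VIP and 30% SST
#' (rounded half-even), with the remainder assigned to PV, the most common
#' inhibitory class. The sum is preserved exactly.
#'
#' @param n_inh Number of inhibitory neurons (>= 0).
#' @return Named integer vector `c(pv=, sst=, vip=)`.
#' @examples
#' split_superficial_inhibitory(1459)
#' @export
split_superficial_inhibitory <- function(n_inh) {
  stopifnot(n_inh >= 0)
  n_vip <- as.integer(round(VIP_FRACTION * n_inh))
  n_sst <- as.integer(round(SST_FRACTION * n_inh))
  n_pv <- as.integer(n_inh) - n_vip - n_sst
  if (n_pv < 0) stop("negative PV remainder")
  c(pv = n_pv, sst = n_sst, vip = n_vip)
}

#' Allocate a synapse budget across source types by weighting factors
#'
#' Splits `total_budget` synapses across source populations proportionally
#' to `weight * source_size`, using largest-remainder rounding so the total
#' is conserved exactly (ties broken by listing order).
#'
#' @param total_budget Total synapse count to distribute (>= 0).
#' @param weights Non-negative weighting factors, one per source type.
#' @param source_sizes Source population sizes (same length).
#' @return Integer vector of per-source-type synapse counts summing to
#'   `total_budget`.
#' @export
allocate_inhibitory_synapses <- function(total_budget, weights, source_sizes) {
  stopifnot(total_budget >= 0, length(weights) == length(source_sizes),
            all(weights >= 0), all(source_sizes >= 0))
  mass <- weights * source_sizes
  tot <- sum(mass)
  if (tot <= 0) stop("zero total weight")
  share <- total_budget * mass / tot
  base <- floor(share)
  rem <- share - base
  missing <- as.integer(round(total_budget - sum(base)))
  if (missing > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(missing)]] <- base[ord[seq_len(missing)]] + 1
  }
  out <- as.integer(base)
  names(out) <- names(weights)
  out
}

#' Ratio of individual neuronal contributions (INC) for two connections
#'
#' INC = connection probability x inhibitory postsynaptic charge, and for an
#' exponentially decaying PSC the charge is peak x decay constant, so the
#' ratio of two INCs is `(p_a * peak_a * tau_a) / (p_b * peak_b * tau_b)`.
#' A consistency utility for checking tabulated peak currents against
#' reported INC ratios; not a fitting routine.
#'
#' @param peak_a,tau_a,p_a Peak current (pA), decay constant (ms) and
#'   connection probability of connection a.
#' @param peak_b,tau_b,p_b Same for connection b.
#' @return The INC ratio (dimensionless).
#' @export
inc_ratio_check <- function(peak_a, tau_a, p_a, peak_b, tau_b, p_b) {
  den <- p_b * peak_b * tau_b
  if (den == 0) stop("zero denominator")
  (p_a * peak_a * tau_a) / den
}

## population table for one column (optionally scaled)
column_populations <- function(column = 1L, scale = 1) {
  counts <- LAYER_COUNTS
  inh <- split_superficial_inhibitory(counts[["L23_I"]])
  n <- c(L23_Pyr = counts[["L23_E"]], L23_PV = inh[["pv"]],
         L23_SST = inh[["sst"]], L23_VIP = inh[["vip"]],
         L4_E = counts[["L4_E"]], L4_I = counts[["L4_I"]],
         L5_E = counts[["L5_E"]], L5_I = counts[["L5_I"]],
         L6_E = counts[["L6_E"]], L6_I = counts[["L6_I"]])
  if (scale != 1) n <- pmax(as.integer(round(n * scale)), 1L)
  data.frame(name = POP_NAMES, column = column, count = as.integer(n),
             base = unname(POP_BASE[POP_NAMES]),
             ei = unname(POP_EI[POP_NAMES]), stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Synapse realization helpers
## ---------------------------------------------------------------------------

## exact Bernoulli realization over the n_src x n_tgt pair grid:
## K ~ Binomial(N, p), then K distinct pairs drawn uniformly.
## Autapses (pre == post) are excluded when the diagonal is shared.
draw_bernoulli_pairs <- function(n_src, n_tgt, p, same_pop = FALSE) {
  if (p <= 0 || n_src == 0L || n_tgt == 0L) {
    return(list(pre = integer(0), post = integer(0)))
  }
  if (same_pop) {
    N <- as.numeric(n_src) * (n_src - 1)
    if (N < 1) return(list(pre = integer(0), post = integer(0)))
    K <- rbinom(1L, as.integer(min(N, .Machine$integer.max)), p)
    idx <- sample.int(N, K) - 1
    pre <- idx %/% (n_src - 1)
    r <- idx %% (n_src - 1)
    post <- r + (r >= pre)
    list(pre = as.integer(pre + 1), post = as.integer(post + 1))
  } else {
    N <- as.numeric(n_src) * n_tgt
    K <- rbinom(1L, as.integer(min(N, .Machine$integer.max)), p)
    idx <- sample.int(N, K) - 1
    list(pre = as.integer(idx %% n_src + 1),
         post = as.integer(idx %/% n_src + 1))
  }
}

## fixed-budget realization: uniform pre/post with replacement (multapses
## allowed), per the base model's budgeted wiring of inhibitory splits
draw_budget_pairs <- function(n_src, n_tgt, budget) {
  if (budget <= 0 || n_src == 0L || n_tgt == 0L) {
    return(list(pre = integer(0), post = integer(0)))
  }
  list(pre = sample.int(n_src, budget, replace = TRUE),
       post = sample.int(n_tgt, budget, replace = TRUE))
}

## jittered weights (sign-preserving) and delays (floored at dt)
jitter_weights <- function(n, w, dw) {
  x <- rnorm(n, w, dw)
  eps <- 1e-3 * abs(w)
  if (w > 0) pmax(x, eps) else pmin(x, -eps)
}
jitter_delays <- function(n, d, dd, dt = 0.1) {
  pmax(rnorm(n, d, dd), dt)
}

## ---------------------------------------------------------------------------
## Rule table construction
## ---------------------------------------------------------------------------

## merged-class connection probabilities inside layer 2/3 (P_EE: Pyr->Pyr,
## P_EI: Pyr->interneuron, P_IE: interneuron budget onto Pyr, P_II:
## interneuron budgets among interneurons). Not printed in the source
## material for this lineage; defaults are the package's calibrated values
## (see the methods vignette) and are overridable per build.
SUPERFICIAL_P <- c(p_ee = 0.1009, p_ei = 0.115, p_ie = 0.1689,
                   p_ii = 0.1371)

## all wiring rules of a single column. Returns a data.frame; budgets are
## computed from the (possibly scaled) population sizes.
column_rules <- function(pops, col = 1L, sup_p = SUPERFICIAL_P) {
  n <- stats::setNames(pops$count, pops$name)
  sup_inh <- c("L23_PV", "L23_SST", "L23_VIP")
  n_inh_total <- sum(n[sup_inh])
  rules <- list()
  add <- function(name, src, tgt, kind, p = NA_real_, budget = NA_integer_,
                  w, dw, tau, d, dd) {
    rules[[length(rules) + 1L]] <<- data.frame(
      name = name, src = src, tgt = tgt, kind = kind, p = p,
      budget = as.integer(budget), w = w, dw = dw, tau = tau, d = d, dd = dd,
      src_col = col, tgt_col = col, stringsAsFactors = FALSE)
  }

  ## superficial excitatory: Pyr -> Pyr (P_EE) and Pyr -> each interneuron
  ## type (P_EI), the three types treated identically
  add("L23_Pyr:L23_Pyr", "L23_Pyr", "L23_Pyr", "bernoulli",
      p = sup_p[["p_ee"]], w = PEAK_DEFAULT_EXC["w"],
      dw = PEAK_DEFAULT_EXC["dw"], tau = TAU_SUPERFICIAL_EXC,
      d = DELAY_INTRA_EXC["d"], dd = DELAY_INTRA_EXC["dd"])
  for (tgt in sup_inh) {
    add(paste0("L23_Pyr:", tgt), "L23_Pyr", tgt, "bernoulli",
        p = sup_p[["p_ei"]], w = PEAK_DEFAULT_EXC["w"],
        dw = PEAK_DEFAULT_EXC["dw"], tau = TAU_SUPERFICIAL_EXC,
        d = DELAY_INTRA_EXC["d"], dd = DELAY_INTRA_EXC["dd"])
  }

  sup_par <- function(src_type, tgt_type) {
    SUPERFICIAL_INH[SUPERFICIAL_INH$src == src_type &
                    SUPERFICIAL_INH$tgt == tgt_type, ]
  }
  add_budget <- function(src_type, tgt_type, budget) {
    par <- sup_par(src_type, tgt_type)
    add(paste0("L23_", src_type, ":L23_", tgt_type),
        paste0("L23_", src_type), paste0("L23_", tgt_type), "budget",
        budget = budget, w = par$w, dw = par$dw, tau = par$tau,
        d = DELAY_INTRA_INH["d"], dd = DELAY_INTRA_INH["dd"])
  }

  ## inhibitory -> Pyr: total I->E budget from the merged-population P_IE,
  ## split by Pfeffer weighting factors x source-type size
  bud_pyr <- round(sup_p[["p_ie"]] * n_inh_total * n[["L23_Pyr"]])
  alloc <- allocate_inhibitory_synapses(bud_pyr, WEIGHT_TO_PYR,
                                        c(n[["L23_PV"]], n[["L23_SST"]],
                                          n[["L23_VIP"]]))
  add_budget("PV", "Pyr", alloc[["PV"]])
  add_budget("SST", "Pyr", alloc[["SST"]])
  add_budget("VIP", "Pyr", alloc[["VIP"]])

  ## inhibitory -> inhibitory: per-target budgets from the merged P_II
  ## (budget proportional to the postsynaptic population size)
  p_ii <- sup_p[["p_ii"]]
  bud_pv <- round(p_ii * n_inh_total * n[["L23_PV"]])
  alloc_pv <- allocate_inhibitory_synapses(bud_pv, WEIGHT_TO_PV,
                                           c(n[["L23_PV"]], n[["L23_SST"]]))
  add_budget("PV", "PV", alloc_pv[["PV"]])
  add_budget("SST", "PV", alloc_pv[["SST"]])

  bud_vip <- round(p_ii * n_inh_total * n[["L23_VIP"]])
  alloc_vip <- allocate_inhibitory_synapses(bud_vip, WEIGHT_TO_VIP,
                                            c(n[["L23_SST"]], n[["L23_PV"]]))
  add_budget("SST", "VIP", alloc_vip[["SST"]])
  add_budget("PV", "VIP", alloc_vip[["PV"]])

  ## VIP is the sole inhibitory source of SST; its weighting factor scales
  ## the target budget directly (a sole source would otherwise make the
  ## factor inert under proportional allocation)
  bud_sst <- round(WEIGHT_VIP_TO_SST * p_ii * n_inh_total * n[["L23_SST"]])
  add_budget("VIP", "SST", bud_sst)

  ## interlaminar and non-superficial rules: base-model probabilities on the
  ## merged classes; the three superficial interneuron types get identical
  ## treatment for any connection entering or leaving layer 2/3
  for (src in POP_NAMES) {
    for (tgt in POP_NAMES) {
      both_sup <- src %in% c("L23_Pyr", sup_inh) && tgt %in% c("L23_Pyr", sup_inh)
      if (both_sup) next  # handled above
      p <- PD_PROB[POP_BASE[[tgt]], POP_BASE[[src]]]
      if (p <= 0) next
      if (POP_EI[[src]] == "E") {
        wpar <- if (src == "L4_E" && tgt == "L23_Pyr") PEAK_L4E_TO_PYR
                else PEAK_DEFAULT_EXC
        ## superficial pyramidal cells receive the strong cell-type-specific
        ## inhibition; to compensate, every excitatory synapse they receive
        ## uses the lengthened 2 ms decay (peaks unchanged). Interneurons
        ## keep the default 0.5 ms for their interlaminar excitation.
        tau_exc <- if (tgt == "L23_Pyr") TAU_SUPERFICIAL_EXC else TAU_DEFAULT
        add(paste0(src, ":", tgt), src, tgt, "bernoulli", p = p,
            w = wpar["w"], dw = wpar["dw"], tau = tau_exc,
            d = DELAY_INTRA_EXC["d"], dd = DELAY_INTRA_EXC["dd"])
      } else {
        add(paste0(src, ":", tgt), src, tgt, "bernoulli", p = p,
            w = PEAK_DEFAULT_INH["w"], dw = PEAK_DEFAULT_INH["dw"],
            tau = TAU_DEFAULT,
            d = DELAY_INTRA_INH["d"], dd = DELAY_INTRA_INH["dd"])
      }
    }
  }
  do.call(rbind, rules)
}

## intercolumnar rules among superficial populations, periodic boundary
intercolumn_rules <- function(n_columns, overrides = NULL) {
  base <- INTERCOL_RULES
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% base$name) stop("unknown intercolumnar rule: ", nm)
      base$p[base$name == nm] <- overrides[[nm]]
    }
  }
  if (max(base$reach) > floor(n_columns / 2)) {
    stop("intercolumnar reach exceeds floor(n_columns/2)")
  }
  rules <- list()
  for (i in seq_len(nrow(base))) {
    r <- base[i, ]
    src_type <- sub("^L23_", "", r$src)
    if (src_type == "Pyr") {
      w <- PEAK_DEFAULT_EXC["w"]; dw <- PEAK_DEFAULT_EXC["dw"]
      tau <- TAU_SUPERFICIAL_EXC
      d <- DELAY_INTER_EXC["d"]; dd <- DELAY_INTER_EXC["dd"]
    } else {
      par <- SUPERFICIAL_INH[SUPERFICIAL_INH$src == src_type &
                             SUPERFICIAL_INH$tgt == sub("^L23_", "", r$tgt), ]
      w <- par$w; dw <- par$dw; tau <- par$tau
      d <- DELAY_INTER_INH["d"]; dd <- DELAY_INTER_INH["dd"]
    }
    offs <- setdiff(seq(-r$reach, r$reach), 0L)
    for (col in seq_len(n_columns)) {
      for (off in offs) {
        tgt_col <- ((col - 1L + off) %% n_columns) + 1L
        rules[[length(rules) + 1L]] <- data.frame(
          name = sprintf("%s:c%d->c%d", r$name, col, tgt_col),
          src = r$src, tgt = r$tgt, kind = "bernoulli", p = r$p,
          budget = NA_integer_, w = w, dw = dw, tau = tau, d = d, dd = dd,
          src_col = col, tgt_col = tgt_col, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rules)
}

## ---------------------------------------------------------------------------
## Graph assembly
## ---------------------------------------------------------------------------

## realize all rules into a synapse table, given the population index table
realize_rules <- function(rules, pops, compensate = 1, dt = 0.1) {
  key <- paste(pops$name, pops$column)
  start <- stats::setNames(cumsum(c(0L, pops$count))[seq_len(nrow(pops))], key)
  size <- stats::setNames(pops$count, key)
  out <- vector("list", nrow(rules))
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    ks <- paste(r$src, r$src_col)
    kt <- paste(r$tgt, r$tgt_col)
    same <- ks == kt
    pairs <- if (r$kind == "bernoulli") {
      draw_bernoulli_pairs(size[[ks]], size[[kt]], r$p, same_pop = same)
    } else {
      draw_budget_pairs(size[[ks]], size[[kt]], r$budget)
    }
    m <- length(pairs$pre)
    if (m == 0L) next
    out[[i]] <- data.frame(
      pre = pairs$pre + start[[ks]],
      post = pairs$post + start[[kt]],
      weight = jitter_weights(m, r$w, r$dw) * compensate,
      delay = jitter_delays(m, r$d, r$dd, dt),
      tau = r$tau,
      rule = i)
  }
  syn <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(syn)) {
    syn <- data.frame(pre = integer(0), post = integer(0),
                      weight = numeric(0), delay = numeric(0),
                      tau = numeric(0), rule = integer(0))
  }
  rownames(syn) <- NULL
  syn
}

## expected synapse count of each rule (binomial mean or budget)
rule_expectations <- function(rules, pops) {
  key <- paste(pops$name, pops$column)
  size <- stats::setNames(pops$count, key)
  vapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    ns <- size[[paste(r$src, r$src_col)]]
    nt <- size[[paste(r$tgt, r$tgt_col)]]
    if (r$kind == "budget") return(as.numeric(r$budget))
    N <- if (paste(r$src, r$src_col) == paste(r$tgt, r$tgt_col)) {
      as.numeric(ns) * (ns - 1)
    } else as.numeric(ns) * nt
    N * r$p
  }, numeric(1))
}

#' Build a single cortical column
#'
#' Assembles the populations and synapses of one layered column: layers 2/3
#' (Pyr, PV, SST, VIP), 4, 5 and 6 (E and I each), wired by the base-model
#' interlaminar probability map, with cell-type-specific superficial-layer
#' connectivity (excitatory links by merged-class probabilities, inhibitory
#' links by synapse budgets split according to the Pfeffer weighting
#' factors). The default column holds 19,294 neurons.
#'
#' @param seed RNG seed; identical seed and spec give a bit-identical
#'   synapse table.
#' @param scale Optional linear scale factor in (0, 1] on population sizes;
#'   connection probabilities are unchanged (so synapse counts scale
#'   roughly with `scale^2`).
#' @param compensate_weights If TRUE, synaptic weights are multiplied by
#'   `1/scale` so each neuron's expected in-degree x weight product is
#'   preserved under downscaling. Default FALSE (raw downscaling).
#' @param realize If FALSE, return populations and rules with expected
#'   counts but skip drawing the synapse table (fast structural checks).
#' @param dt Simulation step (ms) used as the delay floor.
#' @param superficial_p Named overrides for the merged-class layer 2/3
#'   probabilities (`p_ee`, `p_ei`, `p_ie`, `p_ii`).
#' @return A `network_graph` object: list with `pops` (population table
#'   with global index ranges), `synapses`, `rules`, `channels`, `meta`.
#' @export
build_column <- function(seed = 1L, scale = 1, compensate_weights = FALSE,
                         realize = TRUE, dt = 0.1,
                         superficial_p = SUPERFICIAL_P) {
  stopifnot(scale > 0, scale <= 1)
  sup_p <- utils::modifyList(as.list(SUPERFICIAL_P), as.list(superficial_p))
  pops <- column_populations(1L, scale)
  pops$start <- cumsum(c(0L, pops$count))[seq_len(nrow(pops))] + 1L
  pops$end <- pops$start + pops$count - 1L
  rules <- column_rules(pops, 1L, sup_p)
  comp <- if (compensate_weights) 1 / scale else 1
  syn <- NULL
  if (realize) {
    set.seed(seed)
    syn <- realize_rules(rules, pops, comp, dt)
  }
  structure(list(pops = pops, synapses = syn, rules = rules,
                 channels = POP_CHANNELS,
                 meta = list(seed = seed, scale = scale,
                             compensate_weights = compensate_weights,
                             n_columns = 1L, dt = dt,
                             superficial_p = sup_p,
                             expected = rule_expectations(rules, pops))),
            class = "network_graph")
}

#' Build the multi-column network
#'
#' Replicates the single-column circuit `n_columns` times in a
#' one-dimensional arrangement with periodic boundary conditions and adds
#' the four intercolumnar connection families among superficial cells:
#' Pyr->Pyr (6.6%, nearest neighbours), PV->Pyr (4.6%, nearest neighbours),
#' Pyr->PV (0.9%, nearest neighbours) and Pyr->SST (0.2%, reach up to 4
#' columns each way). Intercolumnar synapses use the intracolumnar
#' parameters except for 5x longer conduction delays. No other
#' intercolumnar links exist.
#'
#' @inheritParams build_column
#' @param n_columns Number of columns (>= 2; the reference model uses 13).
#' @param intercol_p Named list overriding intercolumnar probabilities, e.g.
#'   `list(pyr_sst = 0.04)`; names among pyr_pyr, pv_pyr, pyr_pv, pyr_sst.
#' @return A `network_graph` (see [build_column()]).
#' @export
build_network <- function(n_columns = 13L, seed = 1L, scale = 1,
                          intercol_p = NULL, compensate_weights = FALSE,
                          realize = TRUE, dt = 0.1,
                          superficial_p = SUPERFICIAL_P) {
  stopifnot(n_columns >= 2L, scale > 0, scale <= 1)
  sup_p <- utils::modifyList(as.list(SUPERFICIAL_P), as.list(superficial_p))
  pops <- do.call(rbind, lapply(seq_len(n_columns), column_populations,
                                scale = scale))
  pops$start <- cumsum(c(0L, pops$count))[seq_len(nrow(pops))] + 1L
  pops$end <- pops$start + pops$count - 1L
  intra <- do.call(rbind, lapply(seq_len(n_columns), function(col) {
    column_rules(pops[pops$column == col, ], col, sup_p)
  }))
  inter <- intercolumn_rules(n_columns, intercol_p)
  rules <- rbind(intra, inter)
  comp <- if (compensate_weights) 1 / scale else 1
  syn <- NULL
  if (realize) {
    set.seed(seed)
    syn <- realize_rules(rules, pops, comp, dt)
  }
  structure(list(pops = pops, synapses = syn, rules = rules,
                 channels = POP_CHANNELS,
                 meta = list(seed = seed, scale = scale,
                             compensate_weights = compensate_weights,
                             n_columns = n_columns, dt = dt,
                             intercol_p = intercol_p,
                             superficial_p = sup_p,
                             expected = rule_expectations(rules, pops))),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("network_graph: %d columns, %d neurons, %s synapses (scale %g)\n",
              x$meta$n_columns, sum(x$pops$count),
              if (is.null(x$synapses)) "unrealized" else
                format(nrow(x$synapses), big.mark = ","),
              x$meta$scale))
  invisible(x)
}

#' Realize the thalamic projection onto a network
#'
#' Connects `n_per_column` thalamic relay cells per column to the layer 4
#' and layer 6 populations of their column with the base-model targeting
#' probabilities. Thalamic synapses use the external-input peak current
#' (87.9 +/- 8.8 pA) and default excitatory kinetics.
#'
#' @param graph A `network_graph`.
#' @param seed RNG seed for the projection wiring.
#' @param n_per_column Thalamic cells per column (default 902).
#' @param probs Named targeting probabilities (names among L4_E, L4_I,
#'   L6_E, L6_I).
#' @return Data frame with columns `source` (thalamic cell id, 1-based
#'   across columns), `post` (global neuron index), `weight`, `delay`,
#'   `tau`, `column`.
#' @export
build_thalamic_projection <- function(graph, seed = 1L,
                                      n_per_column = N_THALAMIC_PER_COLUMN,
                                      probs = THALAMIC_PROB) {
  set.seed(seed)
  out <- list()
  for (col in seq_len(graph$meta$n_columns)) {
    for (tgt in names(probs)) {
      pop <- graph$pops[graph$pops$name == tgt & graph$pops$column == col, ]
      if (nrow(pop) == 0L) next
      pairs <- draw_bernoulli_pairs(n_per_column, pop$count, probs[[tgt]])
      m <- length(pairs$pre)
      if (m == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        source = pairs$pre + (col - 1L) * n_per_column,
        post = pairs$post + pop$start - 1L,
        weight = jitter_weights(m, BACKGROUND_PEAK[["w"]],
                                BACKGROUND_PEAK[["dw"]]),
        delay = jitter_delays(m, DELAY_INTRA_EXC[["d"]],
                              DELAY_INTRA_EXC[["dd"]], graph$meta$dt),
        tau = TAU_DEFAULT, column = col)
    }
  }
  proj <- do.call(rbind, out)
  attr(proj, "n_per_column") <- n_per_column
  attr(proj, "n_columns") <- graph$meta$n_columns
  proj
}

#' Validate a network graph
#'
#' Checks the structural invariants of a built network: neuron index ranges,
#' Dale's law (sign of every synaptic weight matches the source's E/I
#' class), and per-rule realized synapse counts against their binomial
#' expectations (z-scores).
#'
#' @param graph A realized `network_graph`.
#' @return A list report: `n_neurons`, `n_synapses`, `dale_violations`,
#'   `index_violations`, `rule_counts` (data frame with realized, expected
#'   and z columns), `max_abs_z` (over Bernoulli rules).
#' @export
validate_network <- function(graph) {
  stopifnot(inherits(graph, "network_graph"), !is.null(graph$synapses))
  syn <- graph$synapses
  pops <- graph$pops
  n_tot <- sum(pops$count)
  idx_bad <- sum(syn$pre < 1 | syn$pre > n_tot | syn$post < 1 |
                 syn$post > n_tot)
  ## Dale's law: source E/I class determines weight sign
  ei <- character(n_tot)
  for (i in seq_len(nrow(pops))) ei[pops$start[i]:pops$end[i]] <- pops$ei[i]
  src_ei <- ei[syn$pre]
  dale_bad <- sum((src_ei == "E" & syn$weight <= 0) |
                  (src_ei == "I" & syn$weight >= 0))
  ## per-rule counts
  realized <- tabulate(syn$rule, nbins = nrow(graph$rules))
  expected <- graph$meta$expected
  is_bern <- graph$rules$kind == "bernoulli"
  sdv <- sqrt(pmax(expected * (1 - graph$rules$p), 1e-12))
  z <- ifelse(is_bern, (realized - expected) / sdv, 0)
  list(n_neurons = n_tot, n_synapses = nrow(syn),
       dale_violations = dale_bad, index_violations = idx_bad,
       rule_counts = data.frame(rule = graph$rules$name,
                                kind = graph$rules$kind,
                                realized = realized,
                                expected = expected, z = z),
       max_abs_z = max(abs(z[is_bern & expected > 0]), 0))
}

## ---------------------------------------------------------------------------
## Export / import (delimited text, bit-exact round trip)
## ---------------------------------------------------------------------------

#' Write a network graph to delimited text files
#'
#' Writes `populations.tsv`, `synapses.tsv` and `meta.yaml` into `dir`.
#' Floating-point columns are serialized with 17 significant digits so the
#' round trip through [read_network()] is bit-exact.
#'
#' @param graph A realized `network_graph`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(graph$pops, file.path(dir, "populations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  syn <- graph$synapses
  syn$weight <- formatC(syn$weight, digits = 17, format = "g")
  syn$delay <- formatC(syn$delay, digits = 17, format = "g")
  syn$tau <- formatC(syn$tau, digits = 17, format = "g")
  utils::write.table(syn, file.path(dir, "synapses.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- graph$meta
  meta$expected <- NULL
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a network graph written by [write_network()]
#'
#' @param dir Directory holding `populations.tsv`, `synapses.tsv`,
#'   `meta.yaml`.
#' @return A `network_graph` (the rule table is rebuilt from the metadata).
#' @export
read_network <- function(dir) {
  pops <- utils::read.table(file.path(dir, "populations.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  syn <- utils::read.table(file.path(dir, "synapses.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  n_columns <- meta$n_columns
  intra <- do.call(rbind, lapply(seq_len(n_columns), function(col) {
    column_rules(pops[pops$column == col, ], col)
  }))
  rules <- if (n_columns > 1L) {
    rbind(intra, intercolumn_rules(n_columns, meta$intercol_p))
  } else intra
  structure(list(pops = pops, synapses = syn, rules = rules,
                 channels = POP_CHANNELS,
                 meta = c(meta, list(expected = rule_expectations(rules, pops)))),
            class = "network_graph")
}
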