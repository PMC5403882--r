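test_that("superficial inhibitory split follows the 24/30/46 fractions", {
  expect_equal(split_superficial_inhibitory(100),
               c(pv = 46L, sst = 30L, vip = 24L))
  expect_equal(split_superficial_inhibitory(0), c(pv = 0L, sst = 0L, vip = 0L))
  expect_equal(split_superficial_inhibitory(1459),
               c(pv = 671L, sst = 438L, vip = 350L))
  ## sum conserved for a range of sizes
  for (n in c(1, 7, 113, 730, 2918)) {
    expect_equal(sum(split_superficial_inhibitory(n)), n)
  }
})

test_that("budget allocation is proportional and conserved exactly", {
  ## largest-remainder on weight x size shares; exact shares for the
  ## (1, 1, 0.125) weighting with equal sizes are (470.59, 470.59, 58.82),
  ## so the canonical allocation is (471, 470, 59) with the listing-order
  ## tie-break
  a <- allocate_inhibitory_synapses(1000, c(1, 1, 0.125), c(100, 100, 100))
  expect_equal(unname(a), c(471L, 470L, 59L))
  expect_equal(sum(a), 1000L)

  expect_equal(sum(allocate_inhibitory_synapses(0, c(1, 2), c(10, 10))), 0L)
  b <- allocate_inhibitory_synapses(77, c(0, 3, 0), c(5, 5, 5))
  expect_equal(unname(b), c(0L, 77L, 0L))
  expect_error(allocate_inhibitory_synapses(10, c(0, 0), c(5, 5)),
               "zero total weight")

  ## conservation under many random cases
  set.seed(7)
  for (i in 1:20) {
    w <- stats::runif(4)
    sz <- sample(1:500, 4)
    B <- sample(0:5000, 1)
    out <- allocate_inhibitory_synapses(B, w, sz)
    expect_equal(sum(out), B)
    ## proportionality within 1 synapse of the exact share
    expect_true(all(abs(out - B * w * sz / sum(w * sz)) <= 1))
  }
})

test_that("INC ratio utility reproduces tabulated charge ratios", {
  expect_equal(inc_ratio_check(1, 1, 1, 1, 1, 1), 1.0)
  expect_equal(inc_ratio_check(10, 2, 1, 5, 2, 1), 2.0)
  ## SST->VIP vs SST->PV with equal decay and unit probability
  expect_equal(inc_ratio_check(-525.8, 3.4, 1, -228.6, 3.4, 1), 2.30,
               tolerance = 1e-3)
  expect_error(inc_ratio_check(1, 1, 1, 0, 1, 1), "zero denominator")
})

test_that("default single column holds exactly 19,294 neurons per the census", {
  g <- build_column(seed = 1, realize = FALSE)
  expect_equal(sum(g$pops$count), 19294L)
  n <- stats::setNames(g$pops$count, g$pops$name)
  expect_equal(unname(n["L23_Pyr"]), 5171L)
  expect_equal(unname(n["L23_PV"] + n["L23_SST"] + n["L23_VIP"]), 1459L)
  expect_equal(unname(n["L4_E"]), 5479L)
  expect_equal(unname(n["L4_I"]), 1370L)
  expect_equal(unname(n["L5_E"]), 1213L)
  expect_equal(unname(n["L5_I"]), 266L)
  expect_equal(unname(n["L6_E"]), 3599L)
  expect_equal(unname(n["L6_I"]), 737L)
  ## global index ranges tile the network without gaps
  expect_equal(g$pops$start, cumsum(c(0L, g$pops$count[-10])) + 1L)
  expect_equal(g$pops$end[10], 19294L)
})

test_that("realized column obeys Dale's law and binomial counts", {
  g <- build_column(seed = 3, scale = 0.1)
  v <- validate_network(g)
  expect_equal(v$dale_violations, 0)
  expect_equal(v$index_violations, 0)
  ## budget rules realize their budget exactly
  bud <- v$rule_counts[v$rule_counts$kind == "budget", ]
  expect_true(all(bud$realized == bud$expected))
  ## a planted sign flip is caught
  g2 <- g
  i_inh <- which(g2$synapses$weight < 0)[1]
  g2$synapses$weight[i_inh] <- -g2$synapses$weight[i_inh]
  expect_equal(validate_network(g2)$dale_violations, 1)
})

test_that("per-rule Bernoulli counts stay within 5 sigma across seeds", {
  worst <- 0
  for (seed in 1:10) {
    g <- build_column(seed = seed, scale = 0.05)
    v <- validate_network(g)
    worst <- max(worst, v$max_abs_z)
  }
  expect_lt(worst, 5)
})

test_that("identical seed and spec give a bit-identical synapse table", {
  g1 <- build_column(seed = 11, scale = 0.05)
  g2 <- build_column(seed = 11, scale = 0.05)
  expect_identical(g1$synapses, g2$synapses)
  g3 <- build_column(seed = 12, scale = 0.05)
  expect_false(identical(g3$synapses$pre, g1$synapses$pre))
})

test_that("multi-column wiring: reach sets, periodicity and 5x delays", {
  g <- build_network(n_columns = 13, seed = 5, scale = 0.05)
  rules <- g$rules
  inter <- rules[rules$src_col != rules$tgt_col, ]
  ## only the four superficial families cross columns
  expect_setequal(unique(paste(inter$src, inter$tgt)),
                  c("L23_Pyr L23_Pyr", "L23_PV L23_Pyr",
                    "L23_Pyr L23_PV", "L23_Pyr L23_SST"))
  ## SST cells in column 7 receive intercolumnar excitation from exactly
  ## the 8 columns at offsets +-1..+-4
  sst7 <- inter[inter$tgt == "L23_SST" & inter$tgt_col == 7, ]
  expect_setequal(sst7$src_col, c(3, 4, 5, 6, 8, 9, 10, 11))
  ## periodic wrap: column 1 receives Pyr->SST from columns 10..13 and 2..5
  sst1 <- inter[inter$tgt == "L23_SST" & inter$tgt_col == 1, ]
  expect_setequal(sst1$src_col, c(10, 11, 12, 13, 2, 3, 4, 5))
  ## nearest-neighbour families reach exactly +-1
  pp7 <- inter[inter$src == "L23_Pyr" & inter$tgt == "L23_Pyr" &
               inter$tgt_col == 7, ]
  expect_setequal(pp7$src_col, c(6, 8))
  ## intercolumnar delays are 5x the intracolumnar ones
  intra_exc <- rules[rules$src == "L23_Pyr" & rules$tgt == "L23_Pyr" &
                     rules$src_col == rules$tgt_col, ][1, ]
  inter_exc <- inter[inter$src == "L23_Pyr" & inter$tgt == "L23_Pyr", ][1, ]
  expect_equal(inter_exc$d / intra_exc$d, 5)
  inter_inh <- inter[inter$src == "L23_PV", ][1, ]
  intra_inh <- rules[rules$src == "L23_PV" & rules$tgt == "L23_Pyr" &
                     rules$src_col == rules$tgt_col, ][1, ]
  expect_equal(inter_inh$d / intra_inh$d, 5)
  ## excessive reach is rejected
  expect_error(build_network(n_columns = 5, seed = 1, scale = 0.05,
                             realize = FALSE),
               "reach")
})

test_that("intercolumnar probability overrides apply and others are rejected", {
  g <- build_network(n_columns = 13, seed = 5, scale = 0.05, realize = FALSE,
                     intercol_p = list(pyr_sst = 0.04))
  inter <- g$rules[g$rules$src_col != g$rules$tgt_col &
                   g$rules$tgt == "L23_SST", ]
  expect_true(all(inter$p == 0.04))
  expect_error(build_network(n_columns = 13, seed = 1, scale = 0.05,
                             realize = FALSE,
                             intercol_p = list(nope = 0.1)),
               "unknown intercolumnar rule")
})

test_that("902 thalamic cells attach per column to layers 4 and 6", {
  g <- build_network(n_columns = 13, seed = 6, scale = 0.05)
  proj <- build_thalamic_projection(g, seed = 7)
  expect_equal(attr(proj, "n_per_column"), 902L)
  expect_equal(max(proj$source), 902L * 13L)
  ## thalamic targets are only L4/L6 populations
  pop_of <- rep(g$pops$name, g$pops$count)
  tgt_pops <- unique(pop_of[proj$post])
  expect_true(all(tgt_pops %in% c("L4_E", "L4_I", "L6_E", "L6_I")))
  ## all weights positive (thalamic drive is excitatory)
  expect_true(all(proj$weight > 0))
})

test_that("weight compensation preserves in-degree x weight at small scale", {
  ## expected per-neuron in-degree x weight product, computed from the rule
  ## table (not the realization)
  product <- function(g) {
    key <- paste(g$pops$name, g$pops$column)
    size <- stats::setNames(g$pops$count, key)
    comp <- if (isTRUE(g$meta$compensate_weights)) 1 / g$meta$scale else 1
    ex <- g$meta$expected
    sum(ex * abs(g$rules$w) * comp /
        size[paste(g$rules$tgt, g$rules$tgt_col)])
  }
  g_full <- build_column(seed = 1, scale = 1, realize = FALSE)
  g_comp <- build_column(seed = 1, scale = 0.2, realize = FALSE,
                         compensate_weights = TRUE)
  expect_equal(product(g_comp) / product(g_full), 1, tolerance = 0.01)
})

test_that("network export/import round trip is bit-exact", {
  g <- build_column(seed = 9, scale = 0.05)
  d <- file.path(tempdir(), "net_rt")
  write_network(g, d)
  g2 <- read_network(d)
  expect_equal(g2$pops$count, g$pops$count)
  expect_identical(g2$synapses$pre, g$synapses$pre)
  expect_identical(g2$synapses$post, g$synapses$post)
  expect_identical(g2$synapses$weight, g$synapses$weight)
  expect_identical(g2$synapses$delay, g$synapses$delay)
  unlink(d, recursive = TRUE)
})
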