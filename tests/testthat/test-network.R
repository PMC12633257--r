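# Network construction, blockade, coefficient application and simulation
# determinism on reduced-scale networks.

test_that("the realized graph is fully determined by the wiring seed", {
  s1 <- build_network(micro_spec(seed = 5))
  s2 <- build_network(micro_spec(seed = 5))
  expect_identical(s1$syn, s2$syn)
  expect_identical(s1$gaps, s2$gaps)
  s3 <- build_network(micro_spec(seed = 6))
  expect_false(identical(s1$syn, s3$syn))
})

test_that("only the seven nonzero connection classes are realized", {
  net <- build_network(micro_spec(seed = 2))
  expect_true(all(net$syn$class %in%
    c("PC->PC", "PC->LBC", "PC->NGC", "LBC->PC", "LBC->LBC",
      "NGC->LBC", "NGC->PC")))
  # no LBC->NGC and no NGC->NGC synapses anywhere
  pops <- net$populations
  expect_false(any(pops[net$syn$pre_cell] == "LBC" &
                   pops[net$syn$post_cell] == "NGC"))
  expect_false(any(pops[net$syn$pre_cell] == "NGC" &
                   pops[net$syn$post_cell] == "NGC"))
})

test_that("zero probability scale removes synapses but keeps gap junctions", {
  spec <- micro_spec(seed = 3, probability_scale = 0)
  net <- build_network(spec)
  expect_equal(nrow(net$syn), 0)
  expect_gt(nrow(net$gaps), 0)
})

test_that("per-class connection counts match the binomial expectation", {
  # over 20 wiring seeds, realized connection counts stay within 3 SD of
  # Binomial(n_pairs, min(1, 6 p_base))
  spec <- micro_spec(n_pc = 20, n_lbc = 5, n_ngc = 5)
  ct <- spec$connection_table
  counts <- matrix(0, 20, nrow(ct))
  for (k in 1:20) {
    spec$seed <- 100 + k
    net <- build_network(spec)
    con <- unique(net$syn[c("pre_cell", "post_cell", "class")])
    counts[k, ] <- vapply(ct$class, function(cl)
      sum(con$class == cl), 0)
  }
  sizes <- c(PC = 20, LBC = 5, NGC = 5)
  for (j in seq_len(nrow(ct))) {
    parts <- strsplit(ct$class[j], "->", fixed = TRUE)[[1]]
    npairs <- sizes[parts[1]] * sizes[parts[2]] -
      (if (parts[1] == parts[2]) sizes[parts[1]] else 0)
    p <- min(1, 6 * ct$p_base[j])
    mu <- npairs * p
    sd3 <- 3 * sqrt(npairs * p * (1 - p) / 20)  # SE of the mean over seeds
    expect_lt(abs(mean(counts[, j]) - mu), max(sd3, 1e-9),
              label = paste(ct$class[j], "count"))
  }
})

test_that("blockade zeroes the targeted classes and round-trips exactly", {
  net <- build_network(micro_spec(seed = 4))
  w0 <- net$syn$weight_uS
  nB <- apply_blockade(net, list(gabaA = FALSE, gabaB = TRUE))
  eff <- ifelse(nB$syn$blocked, 0, nB$syn$weight_uS)
  ngc_origin <- nB$populations[nB$syn$pre_cell] == "NGC"
  expect_true(all(eff[ngc_origin] == 0))
  expect_true(all(eff[!ngc_origin] == w0[!ngc_origin]))
  # GABA_A blockade (default reading) silences LBC->PC only
  nA <- apply_blockade(net, list(gabaA = TRUE, gabaB = FALSE))
  expect_true(all(nA$syn$blocked[nA$syn$class == "LBC->PC"]))
  expect_false(any(nA$syn$blocked[nA$syn$class == "LBC->LBC"]))
  # the wider pharmacological flag extends it to LBC->LBC
  spec2 <- micro_spec(seed = 4, block_all_gabaA = TRUE)
  nA2 <- apply_blockade(build_network(spec2), list(gabaA = TRUE))
  expect_true(all(nA2$syn$blocked[nA2$syn$class == "LBC->LBC"]))
  # un-blockade restores the stored weights untouched
  back <- apply_blockade(nB, list(gabaA = FALSE, gabaB = FALSE))
  expect_identical(back$syn$weight_uS, w0)
  expect_false(any(back$syn$blocked))
})

test_that("conductance coefficients scale densities and invert exactly", {
  net <- build_network(micro_spec(seed = 8))
  cs <- coefficient_set(c(CaHVA = 1.164, Ih = 1.034, GABA_B = 1.084))
  # identity coefficients change nothing
  id <- coefficient_set(c(CaHVA = 1, Ih = 1, GABA_B = 1))
  expect_identical(apply_coefficients(net, id)$syn, net$syn)
  expect_identical(apply_coefficients(net, id)$cells, net$cells)
  mod <- apply_coefficients(net, cs, "PC")
  pc1 <- which(mod$populations == "PC")[1]
  expect_equal(mod$cells[[pc1]]$sections[[1]]$channels$CaHVA,
               net$cells[[pc1]]$sections[[1]]$channels$CaHVA * 1.164)
  # GABA_B coefficient scales only synapses onto targeted populations
  onto_pc <- net$syn$receptor == "GABA_B" &
    net$populations[net$syn$post_cell] == "PC"
  expect_equal(mod$syn$weight_uS[onto_pc],
               net$syn$weight_uS[onto_pc] * 1.084)
  onto_lbc <- net$syn$receptor == "GABA_B" &
    net$populations[net$syn$post_cell] == "LBC"
  expect_equal(mod$syn$weight_uS[onto_lbc], net$syn$weight_uS[onto_lbc])
  # non-targeted populations keep their densities
  lbc1 <- which(net$populations == "LBC")[1]
  expect_identical(mod$cells[[lbc1]], net$cells[[lbc1]])
  # applying c then 1/c restores everything to near machine precision
  inv <- coefficient_set(1 / cs$coefficients)
  restored <- apply_coefficients(mod, inv, "PC")
  expect_equal(restored$syn$weight_uS, net$syn$weight_uS, tolerance = 1e-12)
  expect_equal(restored$cells[[pc1]]$sections[[1]]$channels$CaHVA,
               net$cells[[pc1]]$sections[[1]]$channels$CaHVA,
               tolerance = 1e-12)
  expect_error(apply_coefficients(net, coefficient_set(c(NoSuch = 1.1))),
               "not mapping")
})

test_that("no background and no conductances mean no spikes", {
  spec <- micro_spec(n_pc = 6, n_lbc = 2, n_ngc = 2, seed = 1,
                     conductances = conductance_set(0, 0, 0, 0, 0),
                     background = data.frame(receptor = "AMPA",
                                             rate_hz = 0, weight_uS = 0))
  sts <- simulate_network(build_network(spec), duration = 1500, seed = 1,
                          transient = 200)
  expect_equal(nrow(sts$spikes), 0)
})

test_that("network simulation is bit-reproducible under a fixed seed pair", {
  spec <- micro_spec(n_pc = 10, n_lbc = 3, n_ngc = 3, seed = 21)
  net <- build_network(spec)
  s1 <- simulate_network(net, duration = 2500, seed = 9, transient = 500)
  s2 <- simulate_network(net, duration = 2500, seed = 9, transient = 500)
  expect_identical(s1$spikes, s2$spikes)
  s3 <- simulate_network(net, duration = 2500, seed = 10, transient = 500)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("removing fast inhibition does not decrease the PC rate", {
  # slow inhibition is silenced in both arms: in the intact circuit,
  # removing GABA_A recruits extra GABA_B through the NGC loop, which can
  # mask the direct disinhibition being tested here
  seeds <- 1:5
  rate <- function(g_I, seed) {
    spec <- micro_spec(n_pc = 12, n_lbc = 4, n_ngc = 4, seed = seed,
                       conductances = conductance_set(g_I = g_I, g_N = 0))
    sts <- simulate_network(build_network(spec), duration = 3500, seed = seed,
                            transient = 500)
    firing_rate(sts, "PC")
  }
  with_i <- vapply(seeds, function(s) rate(0.5, s), 0)
  without_i <- vapply(seeds, function(s) rate(0, s), 0)
  expect_gte(mean(without_i), mean(with_i))
})

test_that("doubling the duration roughly doubles total spike counts", {
  seeds <- 1:5
  counts <- function(dur, seed) {
    spec <- micro_spec(n_pc = 12, n_lbc = 4, n_ngc = 4, seed = seed)
    sts <- simulate_network(build_network(spec), duration = dur, seed = seed,
                            transient = 500)
    sum(sts$spikes$time_ms > 500)
  }
  short <- vapply(seeds, function(s) counts(3500, s), 0)   # 3 s window
  long <- vapply(seeds, function(s) counts(6500, s), 0)    # 6 s window
  ratio <- long / short
  expect_lt(abs(mean(ratio) - 2), 2 * sd(ratio))
})
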