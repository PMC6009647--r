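test_that("degenerate configurations give empty or exact traces", {
  cfg0 <- sim_config(p_site = 0, rho_off = 0, n_molecules = 20, seed = 1)
  sim0 <- simulate_molecules(amp_map, cfg0)
  expect_true(all(vapply(sim0$traces,
                         function(t) length(t$positions_nm) == 0,
                         logical(1))))

  sim1 <- simulate_molecules(amp_map, noiseless_cfg(n = 5))
  for (tr in sim1$traces) {
    expect_equal(tr$positions_nm, amp_sites * 0.34 * 1.6)
    expect_equal(tr$length_nm, 5000 * 0.34 * 1.6)
  }
  expect_error(simulate_molecules(amp_map, sim_config(n_molecules = 0)),
               "positive")
})

test_that("label counts match the closed-form expectation", {
  cfg <- sim_config(n_molecules = 5000, seed = 2)  # p 0.92, rho 0.46
  sim <- simulate_molecules(amp_map, cfg)
  counts <- vapply(sim$traces, function(t) length(t$positions_nm), numeric(1))
  mu <- 9 * 0.92 + 0.46 * 5
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se)

  ## off-site counts are Poisson(rho L): mean and variance agree within 3 SE
  off <- vapply(sim$truth, function(t) length(t$off_site), numeric(1))
  lam <- 0.46 * 5
  expect_lt(abs(mean(off) - lam), 3 * sqrt(lam / 5000))
  var_se <- sqrt(2 / (5000 - 1)) * lam  # SE of a Poisson variance estimate
  expect_lt(abs(var(off) - lam), 3 * var_se)
  ## off-site positions are uniform along the molecule
  allpos <- unlist(lapply(sim$truth, function(t) t$off_site))
  expect_gt(ks.test(allpos, "punif", 0, 5000)$p.value, 1e-4)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_molecules = 10, seed = 33)
  a <- simulate_molecules(amp_map, cfg)
  b <- simulate_molecules(amp_map, cfg)
  expect_identical(a, b)
  cfg2 <- sim_config(n_molecules = 10, seed = 34)
  expect_false(identical(simulate_molecules(amp_map, cfg2), a))
})

test_that("mirroring a trace twice restores the original", {
  sim <- simulate_molecules(amp_map, sim_config(n_molecules = 5, seed = 9))
  for (tr in sim$traces)
    expect_equal(mirror_trace(mirror_trace(tr))$positions_nm,
                 tr$positions_nm, tolerance = 1e-12)
})

test_that("per-molecule stretch honours the truncation band", {
  cfg <- sim_config(n_molecules = 2000, seed = 4)
  s <- vapply(simulate_molecules(amp_map, cfg)$truth,
              function(t) t$stretch, numeric(1))
  expect_true(all(s >= 1.6 * 0.8 & s <= 1.6 * 1.2))
  expect_lt(abs(mean(s) - 1.6), 0.02)

  cfgu <- sim_config(n_molecules = 500, seed = 4, stretch_dist = "uniform")
  su <- vapply(simulate_molecules(amp_map, cfgu)$truth,
               function(t) t$stretch, numeric(1))
  expect_true(all(su >= 1.6 * 0.9 & su <= 1.6 * 1.1))
})

test_that("plasmid fields conserve emitters and flag decoys", {
  cfg <- sim_config(preset = "plasmid", n_molecules = 1, seed = 5)
  expect_equal(nrow(simulate_plasmid_field(puc_map, cfg, 0)$truth), 0L)

  fl <- simulate_plasmid_field(puc_map, cfg, 50, field = c(360, 360))
  expect_equal(sum(fl$truth$n_labels), nrow(fl$emitters))
  expect_false(any(fl$truth$decoy))

  fl2 <- simulate_plasmid_field(puc_map, cfg, 30, field = c(360, 360),
                                decoy_frac = 0.3)
  expect_equal(sum(fl2$truth$decoy), 9L)
  expect_error(simulate_plasmid_field(puc_map, cfg, 500, field = c(60, 60)),
               "packing")
})

test_that("kinetic time courses follow the saturation model", {
  cfg <- sim_config(preset = "plasmid", seed = 6)
  sim0 <- simulate_kinetics(c(0), k = 0.28, p_inf = 0.875, puc_map, cfg,
                            n_per_time = 2000)
  ## at t = 0 only off-target labeling contributes
  lam <- 0.37 * 2.686
  expect_lt(abs(mean(sim0$counts[[1]]) - lam), 3 * sqrt(lam / 2000))

  ## saturation: t = 100/k reaches the plateau mean
  simInf <- simulate_kinetics(c(100 / 0.28), k = 0.28, p_inf = 0.875,
                              puc_map, cfg, n_per_time = 2000)
  muInf <- 4 * 0.875 + lam
  seInf <- sd(simInf$counts[[1]]) / sqrt(2000)
  expect_lt(abs(mean(simInf$counts[[1]]) - muInf), 3 * seInf)

  ## intermediate time matches off + sites * p_inf * (1 - exp(-k t))
  sim10 <- simulate_kinetics(c(10), k = 0.28, p_inf = 0.875, puc_map, cfg,
                             n_per_time = 2000)
  mu10 <- lam + 4 * 0.875 * (1 - exp(-2.8))
  se10 <- sd(sim10$counts[[1]]) / sqrt(2000)
  expect_lt(abs(mean(sim10$counts[[1]]) - mu10), 3 * se10)

  expect_error(simulate_kinetics(c(-1), k = 0.28, p_inf = 0.9, puc_map, cfg),
               "negative")
})

test_that("trace CSV round trip preserves molecules", {
  sim <- simulate_molecules(amp_map, sim_config(n_molecules = 4, seed = 8))
  f <- withr::local_tempfile(fileext = ".csv")
  write_traces(sim$traces, f)
  back <- read_traces(f)
  expect_equal(length(back), 4L)
  for (i in 1:4) {
    expect_equal(back[[i]]$positions_nm, sim$traces[[i]]$positions_nm)
    expect_equal(back[[i]]$length_nm, sim$traces[[i]]$length_nm)
  }
})
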