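## helper: build a trace directly from bp positions at stretch 1.6
bp_trace <- function(bp, length_bp, id = 1)
  structure(list(molecule = id, positions_nm = sort(bp) * 0.34 * 1.6,
                 length_nm = length_bp * 0.34 * 1.6),
            class = "molecule_trace")

test_that("unmatched labels interpolate linearly between anchors", {
  map2 <- reference_map("two", 3000, "TCGA", c(1000, 2000))
  ## outer labels slightly off their sites, middle label exactly midway
  tr <- bp_trace(c(995, 1500, 2005), 3000)
  a <- align(tr, map2)
  expect_equal(nrow(a$pairs), 2L)
  p <- place_labels(a, tr, map2)
  expect_equal(p$coord[p$status == "matched"], c(1000, 2000))
  expect_equal(p$coord[p$status == "unmatched"], 1500, tolerance = 1e-6)
})

test_that("fully matched molecules place all labels at site coordinates", {
  sim <- simulate_molecules(amp_map, noiseless_cfg(n = 2))
  for (i in 1:2) {
    a <- align(sim$traces[[i]], amp_map)
    p <- place_labels(a, sim$traces[[i]], amp_map)
    expect_equal(p$coord, amp_sites)
    expect_true(all(p$status == "matched"))
  }
})

test_that("a controlled off-site label is placed within 3 sigma of its position", {
  ## one off-site label at true bp 3210 (flanked by matched sites), full
  ## site occupancy, sigma 50 bp
  set.seed(31)
  sigma <- 50
  hits <- vapply(1:1000, function(i) {
    bp <- c(amp_sites, 3210) + rnorm(10, 0, sigma)
    s <- 1.6 * (1 + runif(1, -0.05, 0.05))
    tr <- structure(list(molecule = i, positions_nm = sort(bp * 0.34 * s),
                         length_nm = 5000 * 0.34 * s),
                    class = "molecule_trace")
    a <- align(tr, amp_map)
    ## condition on the intended geometry: all nine sites matched to their
    ## own labels, the off-site label left unmatched (identity swaps with a
    ## nearby site label are a matching ambiguity, not a placement error)
    if (nrow(a$pairs) != 9 ||
        !identical(a$unmatched_labels, which(order(bp) == 10)))
      return(NA)
    p <- place_labels(a, tr, amp_map)
    un <- p$coord[p$status == "unmatched"]
    ## interpolation propagates the flanking anchors' own localization
    ## noise: var = sigma^2 (1 + (1-t)^2 + t^2) at relative position t
    ## between the anchors (t = (3210-3050)/(3700-3050))
    t <- (3210 - 3050) / (3700 - 3050)
    sd_eff <- sigma * sqrt(1 + (1 - t)^2 + t^2)
    length(un) == 1 && abs(un - 3210) <= 3 * sd_eff
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.99)
})

test_that("dual-strand removal follows the nearest-first single-removal rule", {
  p <- data.frame(molecule = 1, coord = c(1000, 1050, 1080),
                  status = c("matched", "unmatched", "unmatched"),
                  site = c(1L, NA, NA))
  r <- remove_dual_strand(p)
  expect_equal(r$status, c("matched", "removed_dual", "unmatched"))

  ## leftmost-first variant picks the lower coordinate instead
  p2 <- data.frame(molecule = 1, coord = c(1000, 940, 1050),
                   status = c("matched", "unmatched", "unmatched"),
                   site = c(1L, NA, NA))
  expect_equal(remove_dual_strand(p2)$status[3], "removed_dual")
  expect_equal(remove_dual_strand(p2, rule = "leftmost")$status[2],
               "removed_dual")

  ## no unmatched labels: unchanged
  p3 <- data.frame(molecule = 1, coord = 1000, status = "matched", site = 1L)
  expect_identical(remove_dual_strand(p3), p3)

  ## each unmatched label is removed at most once
  p4 <- data.frame(molecule = 1, coord = c(1000, 1060, 1120),
                   status = c("matched", "unmatched", "matched"),
                   site = c(1L, NA, 2L))
  r4 <- remove_dual_strand(p4)
  expect_equal(sum(r4$status == "removed_dual"), 1L)

  ## at most one removal per matched label
  p5 <- data.frame(molecule = 1, coord = c(1000, 1010, 1020, 1030),
                   status = c("matched", rep("unmatched", 3)),
                   site = c(1L, NA, NA, NA))
  expect_equal(sum(remove_dual_strand(p5)$status == "removed_dual"), 1L)
})

test_that("labels are conserved through placement and removal", {
  cfg <- sim_config(p_second = 0.4, n_molecules = 50, seed = 8)
  sim <- simulate_molecules(amp_map, cfg)
  for (i in seq_along(sim$traces)) {
    a <- align_best_orientation(sim$traces[[i]], amp_map)
    p <- remove_dual_strand(place_labels(a, sim$traces[[i]], amp_map))
    expect_equal(nrow(p), length(sim$traces[[i]]$positions_nm))
    expect_true(all(p$status %in% c("matched", "unmatched", "removed_dual")))
    ## removals never exceed the number of matched labels
    expect_lte(sum(p$status == "removed_dual"),
               sum(p$status == "matched"))
  }
})

test_that("consensus histogram counts every non-removed label once", {
  map2 <- reference_map("two", 1000, "TCGA", c(100, 700))
  tr <- bp_trace(c(100, 700), 1000)
  a <- align(tr, map2)
  p <- place_labels(a, tr, map2)
  h <- build_consensus(p, map2, bin_width = 50)
  expect_equal(sum(h$counts > 0), 2L)
  expect_equal(sum(h$counts), 2L)
  expect_error(build_consensus(p, map2, bin_width = 0), "positive")

  cfg <- sim_config(n_molecules = 30, seed = 12)
  sim <- simulate_molecules(amp_map, cfg)
  placed <- do.call(rbind, lapply(seq_along(sim$traces), function(i) {
    a <- align_best_orientation(sim$traces[[i]], amp_map)
    remove_dual_strand(place_labels(a, sim$traces[[i]], amp_map))
  }))
  h2 <- build_consensus(placed, amp_map)
  expect_equal(sum(h2$counts), sum(placed$status != "removed_dual"))
  expect_equal(h2$n_molecules, 30L)
})

test_that("close site pairs accumulate about twice the isolated-site counts", {
  cfg <- sim_config(p_site = 0.95, rho_off = 0.05, sigma_loc = 25,
                    n_molecules = 300, seed = 17)
  sim <- simulate_molecules(amp_map, cfg)
  placed <- do.call(rbind, lapply(seq_along(sim$traces), function(i) {
    a <- align_best_orientation(sim$traces[[i]], amp_map)
    place_labels(a, sim$traces[[i]], amp_map)
  }))
  h <- build_consensus(placed, amp_map, bin_width = 50)
  win_counts <- function(center, half = 100) {
    lo <- findInterval(center - half, h$breaks)
    hi <- findInterval(center + half - 1e-9, h$breaks)
    sum(h$counts[lo:hi])
  }
  pair_region <- (win_counts(650) + win_counts(3000)) / 2
  isolated <- mean(c(win_counts(1500), win_counts(2100), win_counts(3700),
                     win_counts(4300)))
  expect_gt(pair_region / isolated, 1.6)
  expect_lt(pair_region / isolated, 2.4)
  ## the two sites of a pair land in adjacent but distinct 50 bp bins
  expect_gt(h$counts[findInterval(600, h$breaks)], 0)
  expect_gt(h$counts[findInterval(700, h$breaks)], 0)
})

test_that("offsite statistics follow their definitions", {
  placed <- do.call(rbind, lapply(1:10, function(m)
    data.frame(molecule = m, coord = c(500, 2600 + m * 10),
               status = c("unmatched", "unmatched"), site = NA)))
  st <- offsite_stats(placed, amp_map, n_molecules = 10)
  expect_equal(st$offsite_density, 20 / (10 * 5))
  expect_equal(st$offsite_fraction, 1)

  placed2 <- data.frame(molecule = 1, coord = amp_sites,
                        status = "matched", site = seq_along(amp_sites))
  st2 <- offsite_stats(placed2, amp_map, n_molecules = 1)
  expect_equal(st2$offsite_fraction, 0)
  expect_equal(st2$offsite_density, 0)
})

test_that("uniform off-site labels yield calibrated uniformity p-values", {
  set.seed(3)
  ps <- replicate(300, {
    x <- runif(40, 0, 5000)
    placed <- data.frame(molecule = 1, coord = x, status = "unmatched",
                         site = NA)
    offsite_stats(placed, amp_map, n_molecules = 1)$uniformity_p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 1e-3)
})

test_that("dual-strand removal restores single-strand per-site counts", {
  ## a map with well-separated sites isolates the removal rule from
  ## close-pair cross-matching ambiguity
  S <- n_sites(puc_map)
  p_site <- 0.9
  cfg <- sim_config(p_site = p_site, p_second = 0.5, rho_off = 0,
                    sigma_loc = 25, n_molecules = 300, seed = 19)
  sim <- simulate_molecules(puc_map, cfg)
  per_mol_before <- numeric(300)
  per_mol_after <- numeric(300)
  for (i in 1:300) {
    a <- align_best_orientation(sim$traces[[i]], puc_map)
    p <- place_labels(a, sim$traces[[i]], puc_map)
    per_mol_before[i] <- sum(p$status != "removed_dual")
    p <- remove_dual_strand(p)
    per_mol_after[i] <- sum(p$status != "removed_dual")
  }
  ## before removal the dual-strand labels inflate the count ...
  expect_gt(mean(per_mol_before) / S, p_site * 1.3)
  ## ... after removal the single-strand expectation is restored
  se <- sd(per_mol_after / S) / sqrt(300)
  expect_lt(abs(mean(per_mol_after) / S - p_site), 3 * se)
})
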