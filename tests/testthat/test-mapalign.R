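test_that("to_bp inverts the physical mapping", {
  expect_equal(to_bp(544, 1.6), 1000)
  expect_equal(to_bp(numeric(), 1.6), numeric())
  sim <- simulate_molecules(amp_map, noiseless_cfg(n = 3, seed = 2))
  for (tr in sim$traces)
    expect_equal(to_bp(tr, 1.6), amp_sites, tolerance = 1e-9)
})

test_that("a noiseless full-occupancy trace aligns perfectly", {
  sim <- simulate_molecules(amp_map, noiseless_cfg(n = 1))
  a <- align(sim$traces[[1]], amp_map)
  expect_equal(a$score, 9)
  expect_equal(nrow(a$pairs), 9L)
  expect_equal(a$pairs[, 1], 1:9)
  expect_equal(a$pairs[, 2], 1:9)
  expect_equal(a$fitted_stretch, 1.6, tolerance = 1e-9)
  expect_equal(length(a$skipped_sites), 0L)
})

test_that("empty traces yield an all-skipped alignment", {
  tr <- structure(list(molecule = 1, positions_nm = numeric(),
                       length_nm = 2720), class = "molecule_trace")
  a <- align(tr, amp_map, alignment_params(free_ends = TRUE))
  expect_equal(a$score, 0)
  expect_equal(a$skipped_sites, 1:9)
  a2 <- align(tr, amp_map, alignment_params(free_ends = FALSE))
  expect_equal(a2$score, -9 * 0.5)
})

test_that("the DP equals exhaustive monotone-matching enumeration", {
  set.seed(77)
  params <- alignment_params()
  for (i in 1:60) {
    inst <- random_align_instance()
    p <- params
    p$free_ends <- i %% 2 == 0
    got <- mtagmap:::dp_align_cpp(inst$labels, inst$sites, p$match_width,
                                  p$match_score, p$miss_site_penalty,
                                  p$extra_label_penalty, p$free_ends,
                                  p$flat_score, FALSE)
    want <- oracle_align(inst$labels, inst$sites, p)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    expect_equal(got$matches, want$matches)
    expect_equal(unname(got$pairs), unname(want$pairs))
  }
})

test_that("a mirrored perfect trace is recognized as reverse", {
  sim <- simulate_molecules(amp_map, noiseless_cfg(n = 1))
  fwd <- align_best_orientation(sim$traces[[1]], amp_map)
  expect_equal(fwd$orientation, "forward")
  mir <- mirror_trace(sim$traces[[1]])
  rev <- align_best_orientation(mir, amp_map)
  expect_equal(rev$orientation, "reverse")
  expect_equal(rev$score, fwd$score, tolerance = 1e-9)
})

test_that("exact ties on a symmetric map break to forward", {
  ## site layout symmetric under reflection about the molecule midpoint
  sym <- reference_map("sym", 2000, "TCGA", c(500, 998, 1496))
  tr <- structure(list(molecule = 1,
                       positions_nm = c(500, 998, 1496) * 0.34 * 1.6,
                       length_nm = (2000 - 4) * 0.34 * 1.6),
                  class = "molecule_trace")
  a <- align_best_orientation(tr, sym)
  expect_equal(a$orientation, "forward")
})

test_that("the DP objective is invariant under mirroring labels and sites", {
  set.seed(5)
  p <- alignment_params()
  for (i in 1:100) {
    inst <- random_align_instance()
    C <- 2000
    mlab <- sort(C - inst$labels)
    msite <- sort(C - inst$sites)
    a <- mtagmap:::dp_align_cpp(inst$labels, inst$sites, p$match_width,
                                p$match_score, p$miss_site_penalty,
                                p$extra_label_penalty, TRUE, FALSE, FALSE)
    b <- mtagmap:::dp_align_cpp(mlab, msite, p$match_width, p$match_score,
                                p$miss_site_penalty, p$extra_label_penalty,
                                TRUE, FALSE, FALSE)
    expect_equal(b$score, a$score, tolerance = 1e-9)
    expect_equal(b$matches, a$matches)
  }
  ## flat scoring preserves the score under mirroring too
  inst <- list(labels = c(100, 260, 410), sites = c(120, 400))
  fa <- mtagmap:::dp_align_cpp(inst$labels, inst$sites, 150, 1, 0.5, 0.25,
                               TRUE, TRUE, FALSE)
  fb <- mtagmap:::dp_align_cpp(sort(1000 - inst$labels),
                               sort(1000 - inst$sites), 150, 1, 0.5, 0.25,
                               TRUE, TRUE, FALSE)
  expect_equal(fb$score, fa$score, tolerance = 1e-9)
})

test_that("reported scores match independent recomputation", {
  cfg <- sim_config(n_molecules = 20, seed = 66)
  sim <- simulate_molecules(amp_map, cfg)
  params <- alignment_params()
  for (tr in sim$traces) {
    a <- align_best_orientation(tr, amp_map, params)
    expect_equal(a$score, score_alignment(a, amp_map, params),
                 tolerance = 1e-9)
  }
})

test_that("with vanishing noise the matched fraction approaches p_site", {
  p <- 0.8
  cfg <- sim_config(p_site = p, rho_off = 0, sigma_loc = 0, stretch_tol = 0,
                    flip_prob = 0, n_molecules = 500, seed = 91)
  sim <- simulate_molecules(amp_map, cfg)
  matched <- vapply(seq_along(sim$traces), function(i)
    nrow(align(sim$traces[[i]], amp_map)$pairs), numeric(1))
  frac <- sum(matched) / (500 * 9)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / (500 * 9)))
})

test_that("orientation is recovered for informative molecules", {
  cfg <- sim_config(p_site = 0.9, sigma_loc = 50, n_molecules = 200,
                    seed = 14)
  sim <- simulate_molecules(amp_map, cfg)
  alns <- lapply(sim$traces, align_best_orientation, refmap = amp_map)
  nlab <- vapply(sim$traces, function(t) length(t$positions_nm), numeric(1))
  ok <- mapply(function(a, t) (a$orientation == "reverse") == t$flipped,
               alns, sim$truth)
  expect_gte(mean(ok[nlab >= 4]), 0.95)
})
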