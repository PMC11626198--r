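test_that("generators are pure functions of (parameters, seed)", {
  a <- gen_titration(kd = 1e-6, seed = 42)
  b <- gen_titration(kd = 1e-6, seed = 42)
  expect_identical(a$series$anisotropy, b$series$anisotropy)
  expect_false(identical(
    a$series$anisotropy, gen_titration(kd = 1e-6, seed = 43)$series$anisotropy))
  e1 <- gen_chain_ensemble(20, n_frames = 10, seed = 7)
  e2 <- gen_chain_ensemble(20, n_frames = 10, seed = 7)
  expect_identical(e1$ens$coords, e2$ens$coords)
  c1 <- gen_rna_conformers(tar_seq(), c(4, 6), 9, seed = 5)
  c2 <- gen_rna_conformers(tar_seq(), c(4, 6), 9, seed = 5)
  expect_identical(c1$conformers$coords, c2$conformers$coords)
  t1 <- gen_turbidity(2.5, seed = 9)
  t2 <- gen_turbidity(2.5, seed = 9)
  expect_identical(t1$curve$a340, t2$curve$a340)
  # generators restore the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(gen_titration(kd = 1e-6, seed = 3))
  expect_identical(runif(1), before)
})

test_that("titration generator: noiseless limit and replicate statistics", {
  clean <- gen_titration(kd = 5e-7, r_free = 0.05, r_bound = 0.2,
                         noise_sd = 0, seed = 1)
  model <- anisotropy_model(clean$truth$params$probe,
                            clean$series$titrant_totals,
                            list(kd = 5e-7, r_free = 0.05, r_bound = 0.2))
  expect_equal(clean$series$anisotropy, model, tolerance = 1e-14)
  # replicate SD at n = 3 averages to noise_sd * c4 over many points
  big <- gen_titration(kd = 5e-7, n_points = 400L, noise_sd = 0.002,
                       replicates = 3L, seed = 2)
  c4 <- sqrt(2 / (3 - 1)) * gamma(3 / 2) / gamma(1)  # E[sd]/sigma at n=3
  expect_equal(mean(big$series$replicate_sd), 0.002 * c4, tolerance = 0.05)
  expect_error(gen_titration(kd = 1e-6, noise_sd = -1), "noise_sd")
})

test_that("chain generator: Gaussian-chain Rg, compaction, helicity closure", {
  ge <- gen_chain_ensemble(50, bond_b = 3.8, n_frames = 1200, seed = 31)
  rms_rg <- sqrt(mean(rg_distribution(ge$ens)$rg^2))
  expect_equal(rms_rg, 3.8 * sqrt((50^2 - 1) / (6 * 50)), tolerance = 0.03)
  # compaction scales every mean distance linearly
  g1 <- gen_chain_ensemble(20, n_frames = 50, seed = 8, compaction = 1)
  g2 <- gen_chain_ensemble(20, n_frames = 50, seed = 8, compaction = 0.5)
  expect_equal(mean_distance_map(g2$ens), 0.5 * mean_distance_map(g1$ens),
               tolerance = 1e-12)
  expect_error(gen_chain_ensemble(20, helix_region = c(10, 25, 1)), "range")
})

test_that("hairpin conformers: collinear limit, bend statistics, topology", {
  hx <- hairpin_indices(c(4, 6), 9)
  g0 <- gen_rna_conformers(tar_seq(), c(4, 6), 9, bend_deg = 0,
                           jitter_deg = 0, n_conformers = 2, seed = 1)
  expect_equal(dim(g0$conformers$coords)[2], 29)
  a0 <- interhelical_angle(g0$conformers$coords[1, , ], hx$stem1, hx$stem2)
  expect_lt(a0, 0.5)
  # mean realized bend ~ bend_deg within jitter / sqrt(n)
  g1 <- gen_rna_conformers(tar_seq(), c(4, 6), 9, bend_deg = 40,
                           jitter_deg = 8, n_conformers = 60, seed = 3)
  ang <- vapply(1:60, function(k)
    interhelical_angle(g1$conformers$coords[k, , ], hx$stem1, hx$stem2),
    numeric(1))
  expect_equal(mean(ang), 40, tolerance = 3 * 8 / sqrt(60) / 40)
  expect_error(gen_rna_conformers(tar_seq(), c(4, 4), 9), "length")
})

test_that("truth records round-trip as JSON", {
  gen <- gen_turbidity(2.5, seed = 12)
  f <- tempfile(fileext = ".json")
  write_truth(gen$truth, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$generator, "gen_turbidity")
  expect_equal(back$seed, 12)
  expect_equal(back$params$peak_ratio, 2.5)
})
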