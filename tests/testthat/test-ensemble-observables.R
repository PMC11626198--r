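test_that("radius of gyration and KDE normalization", {
  # two sites at distance d -> Rg = d / 2
  two <- ensemble(array(c(0, 0, 0, 0, 4, 0), c(1, 2, 3)))
  expect_equal(rg_distribution(two)$rg, 2)
  # three collinear equally spaced sites -> Rg = d * sqrt(2/3)
  three <- ensemble(array(c(0, 3, 6, rep(0, 6)), c(1, 3, 3)))
  expect_equal(rg_distribution(three)$rg, 3 * sqrt(2 / 3))
  # KDE integrates to 1
  ge <- gen_chain_ensemble(30, n_frames = 150, seed = 9)
  rd <- rg_distribution(ge$ens)
  dens <- rd$density
  area <- sum(diff(dens$x) * (head(dens$y, -1) + tail(dens$y, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-3)
})

test_that("mean distance map matches a brute-force recount", {
  set.seed(11)
  coords <- array(rnorm(3 * 5 * 3), c(3, 5, 3))
  ens <- ensemble(coords)
  m <- mean_distance_map(ens)
  expect_true(isSymmetric(unname(m)))
  expect_equal(unname(diag(m)), rep(0, 5))
  # exhaustive per-frame recomputation
  ref <- matrix(0, 5, 5)
  for (f in 1:3) for (i in 1:5) for (j in 1:5)
    ref[i, j] <- ref[i, j] + sqrt(sum((coords[f, i, ] - coords[f, j, ])^2)) / 3
  expect_equal(unname(m), ref, tolerance = 1e-12)
  # single frame equals that frame's distances
  one <- ensemble(coords[1, , , drop = FALSE])
  expect_equal(unname(mean_distance_map(one)),
               as.matrix(dist(coords[1, , ])), ignore_attr = TRUE)
})

test_that("AFRC null model: scaling, Rg calibration, closed form", {
  ref <- afrc_reference(68)
  expect_equal(ref$rg, 20.8, tolerance = 1 / 20.8)  # within +/- 1 A
  # sqrt scaling: <r> at 4k = 2 <r> at k
  expect_equal(ref$mean_distance[40], 2 * ref$mean_distance[10])
  # closed form at n = 2: one separation, mean = sqrt(8 / 3 pi) * b
  r2 <- afrc_reference(2, b = 5)
  expect_equal(r2$mean_distance[1], sqrt(8 / (3 * pi)) * 5)
  expect_equal(r2$rg, 5 * sqrt((4 - 1) / 12))
  expect_true(all(diff(ref$mean_distance) > 0))
  expect_error(afrc_reference(1), ">= 2")
})

test_that("normalized distance map self-normalizes and scales linearly", {
  ref <- afrc_reference(40, b = 6.2)
  ge <- gen_chain_ensemble(40, bond_b = 6.2, n_frames = 1500, seed = 21,
                           step = "gaussian")
  m <- mean_distance_map(ge$ens)
  nd <- normalized_distance_map(m, ref)
  off <- abs(outer(1:40, 1:40, "-")) > 0
  expect_true(all(abs(nd[off] - 1) < 0.05))
  expect_true(all(is.na(diag(nd))))
  # uniform scaling halves every ratio
  nd2 <- normalized_distance_map(m * 0.5, ref)
  expect_equal(nd2[off], nd[off] * 0.5)
  # Gaussian chain with bond b vs reference prefactor b2: ratios = b / b2
  ref2 <- afrc_reference(40, b = 3.1)
  nd3 <- normalized_distance_map(m, ref2)
  expect_equal(mean(nd3[off] / nd[off]), 2, tolerance = 1e-9)
  expect_error(normalized_distance_map(m[1:10, 1:10], ref), "size")
})

test_that("PRE ratios: limits, bounds, and dual-implementation oracle", {
  ge <- gen_chain_ensemble(30, n_frames = 40, seed = 13)
  prof <- pre_profile(ge$ens, 15)
  expect_equal(prof$ratio[15], 0)             # at the label
  expect_true(all(prof$ratio >= 0 & prof$ratio <= 1))
  # independent straight-line implementation agrees to 1e-10
  oracle <- gen_pre_truth(ge$ens, 15)
  expect_equal(prof$ratio, oracle$profile$ratio, tolerance = 1e-10)
  # far site -> ratio ~ 1
  far <- ensemble(array(c(0, 1e5, rep(0, 4)), c(1, 2, 3)))
  expect_equal(pre_profile(far, 1)$ratio[2], 1, tolerance = 1e-6)
  # single frame at fixed 20 A against direct formula evaluation
  fixed <- ensemble(array(c(0, 20, rep(0, 4)), c(1, 2, 3)))
  p <- pre_params()
  g2 <- p$K * p$tau_c / 20^6
  expect_equal(pre_profile(fixed, 1)$ratio[2],
               p$r2_dia * exp(-g2 * p$t_d) / (p$r2_dia + g2),
               tolerance = 1e-12)
  # Gamma2 forced to zero -> all ratios 1 away from the label
  p0 <- pre_params(); p0$K <- 0
  expect_equal(pre_profile(ge$ens, 15, p0)$ratio[-15], rep(1, 29))
})

test_that("helicity profile counts alpha-basin runs", {
  full <- gen_chain_ensemble(20, helix_region = c(1, 20, 1),
                             n_frames = 30, seed = 2)
  hp <- helicity_profile(full$ens)
  expect_equal(hp$helix_fraction[5:15], rep(1, 11))
  none <- gen_chain_ensemble(20, n_frames = 30, seed = 2)
  expect_equal(helicity_profile(none$ens)$helix_fraction, rep(0, 20))
  half <- gen_chain_ensemble(30, helix_region = c(8, 22, 0.5),
                             n_frames = 600, seed = 4)
  hf <- helicity_profile(half$ens)$helix_fraction[15]
  expect_equal(hf, 0.5, tolerance = 0.12)
  no_dih <- ensemble(array(rnorm(2 * 5 * 3), c(2, 5, 3)))
  expect_error(helicity_profile(no_dih), "dihedral")
})

test_that("secondary-structure propensity from CA/CB shifts", {
  n <- 12
  mk <- function(d_ca, d_cb) shift_table(
    rep(1:n, each = 2), rep(c("CA", "CB"), n),
    c(rbind(58 + d_ca, 30 + d_cb)), c(rbind(rep(58, n), rep(30, n))))
  # measured = reference -> zero propensity
  expect_equal(ssp_from_shifts(mk(rep(0, n), rep(0, n)))$ssp, rep(0, n))
  # full-helix secondary shifts -> propensity ~ 1
  expect_equal(ssp_from_shifts(mk(rep(2.8, n), rep(0, n)))$ssp, rep(1, n))
  # antisymmetry under sign flip of the secondary shifts
  up <- ssp_from_shifts(mk(rep(1.1, n), rep(-0.4, n)))$ssp
  dn <- ssp_from_shifts(mk(rep(-1.1, n), rep(0.4, n)))$ssp
  expect_equal(up, -dn)
  no_ref <- shift_table(1:3, rep("CA", 3), c(58, 58, 58))
  expect_error(ssp_from_shifts(no_ref), "reference")
})

test_that("chemical shift perturbations combine and maximize correctly", {
  a <- shift_table(c(1, 1, 2), c("H", "N", "CA"), c(8.0, 120, 58),
                   c(8.0, 120, 58))
  b <- shift_table(c(1, 1, 2), c("H", "N", "CA"), c(8.1, 120.5, 58.3),
                   c(8.0, 120, 58))
  out <- csp(a, b)
  # combined = sqrt((0.10^2 + (0.154 * 0.5)^2) / 2)
  expect_equal(out$csp[1], sqrt((0.1^2 + 0.077^2) / 2), tolerance = 1e-9)
  # single carbon nucleus: max-variant equals |delta|
  expect_equal(out$max_c_csp[2], 0.3, tolerance = 1e-9)
  # identical tables -> zero everywhere
  z <- csp(a, a)
  expect_equal(z$csp, rep(0, 2))
  expect_error(csp(a, shift_table(9, "H", 8, 8)), "common")
})

test_that("Debye scattering closed forms", {
  one <- ensemble(array(0, c(1, 1, 3)))
  q <- seq(0, 0.5, by = 0.05)
  expect_warning(s1 <- debye_scattering(one, q), NA)
  expect_equal(s1$intensity, rep(1, length(q)))
  # two sites at distance d: I(q) = 2 (1 + sin(qd)/(qd))
  d <- 10
  two <- ensemble(array(c(0, d, rep(0, 4)), c(1, 2, 3)))
  s2 <- debye_scattering(two, q)
  expected <- 2 * (1 + ifelse(q == 0, 1, sin(q * d) / (q * d)))
  expect_equal(s2$intensity, expected, tolerance = 1e-12)
  # I(0) = N^2
  ge <- gen_chain_ensemble(12, n_frames = 5, seed = 3)
  expect_equal(debye_scattering(ge$ens, 0)$intensity, 144)
})

test_that("Guinier fit recovers model curves exactly and is scale-free", {
  q <- seq(0.005, 0.2, by = 0.005)
  ideal <- scattering_curve(q, 100 * exp(-q^2 * 24.5^2 / 3))
  fit <- guinier_fit(ideal)
  expect_equal(fit$rg, 24.5, tolerance = 1e-6)
  expect_equal(fit$i0, 100, tolerance = 1e-6)
  scaled <- scattering_curve(q, 7.3 * ideal$intensity)
  expect_equal(guinier_fit(scaled)$rg, fit$rg, tolerance = 1e-9)
  rising <- scattering_curve(q, exp(q^2 * 50))
  expect_error(guinier_fit(rising), "non-Guinier")
  # rigid body: Debye curve Rg matches coordinate-space Rg within 2%
  hx <- gen_rna_conformers(tar_seq(), c(4, 6), 9, bend_deg = 45,
                           n_conformers = 1, jitter_deg = 0, seed = 8)
  rig <- ensemble(hx$conformers$coords[1, , , drop = FALSE])
  rg_coord <- rg_distribution(rig)$rg[1]
  sc <- debye_scattering(rig, seq(0.002, 0.12, by = 0.002))
  expect_equal(guinier_fit(sc)$rg, rg_coord, tolerance = 0.02)
})

test_that("dimensionless Kratky transform peaks at (sqrt(3), 3/e)", {
  q <- seq(0.001, 0.35, by = 0.001)
  rg <- 24.5
  ideal <- scattering_curve(q, exp(-q^2 * rg^2 / 3))
  k <- kratky_dimensionless(ideal, rg)
  expect_equal(k$x[which.max(k$y)], sqrt(3), tolerance = 0.02)
  expect_equal(max(k$y), 3 / exp(1), tolerance = 1e-3)
  # y(0) = 0 and scale invariance
  expect_equal(kratky_dimensionless(
    scattering_curve(c(0, q), c(1, exp(-q^2 * rg^2 / 3))), rg)$y[1], 0)
  k2 <- kratky_dimensionless(scattering_curve(q, 55 * ideal$intensity), rg)
  expect_equal(k2$y, k$y, tolerance = 1e-12)
})

test_that("SAXS dat files round-trip", {
  q <- seq(0.01, 0.2, by = 0.01)
  sc <- scattering_curve(q, exp(-q^2 * 100), err = rep(0.01, length(q)))
  f <- tempfile(fileext = ".dat")
  write_saxs_dat(sc, f)
  back <- read_saxs_dat(f)
  expect_equal(back$q, sc$q)
  expect_equal(back$intensity, sc$intensity, tolerance = 1e-12)
})
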