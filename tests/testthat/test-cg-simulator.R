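test_that("topology construction: beads, bonds, rigid groups", {
  serf <- serf_seq()
  top <- build_topology(protein = serf)
  expect_equal(nrow(top$beads), 68)
  expect_equal(nrow(top$bonds), 67)
  # truncation: residues 1-34
  half <- bio_seq(serf$residues[1:34], "protein")
  top34 <- build_topology(protein = half)
  expect_equal(nrow(top34$beads), 34)
  expect_equal(nrow(top34$bonds), 33)
  # rigid conformers carry no bonds and must match the sequence length
  gc <- gen_rna_conformers(tar_seq(), c(4, 6), 9, n_conformers = 3, seed = 1)
  topr <- build_topology(serf, gc$conformers)
  expect_equal(nrow(topr$beads), 97)
  expect_equal(nrow(topr$bonds), 67)
  expect_equal(dim(topr$rigid$coords)[1], 3)
  bad <- gc$conformers
  bad$coords <- bad$coords[, 1:20, , drop = FALSE]
  expect_error(build_topology(serf, bad), "bead count")
  expect_error(build_topology(protein = NULL, rna = NULL), "no molecules")
})

test_that("pair energy: truncation, symmetry, electrostatic closed form", {
  ff <- load_forcefield()
  cfg <- sim_config(box_edge = 25, nonbonded_cutoff = 10)
  # short-range term vanishes beyond 3 sigma (uncharged pair)
  u <- pair_energy("A", "G", 3 * (0.504 + 0.450) / 2 + 1e-9, cfg)
  expect_equal(u, 0)
  expect_lt(pair_energy("F", "F", 0.7, cfg), 0)  # attractive well
  # symmetric in its arguments
  r <- seq(0.4, 1.5, by = 0.1)
  expect_equal(pair_energy("R", "u", r, cfg), pair_energy("u", "R", r, cfg))
  # opposite unit charges at r = lambda_D: U_el = -(lB kBT / lambda) / e
  lam <- debye_length(cfg$ionic_strength_mM, cfg$temperature_K,
                      cfg$dielectric)
  plus <- data.frame(charge_e = 1, sigma_nm = 0.1, epsilon_kJmol = 0,
                     mu = 2, nu = 1)
  minus <- plus; minus$charge_e <- -1
  kBT <- 0.0083144626 * cfg$temperature_K
  lB <- bjerrum_length(cfg$temperature_K, cfg$dielectric)
  shift <- -(lB * kBT / cfg$nonbonded_cutoff) *
    exp(-cfg$nonbonded_cutoff / lam)
  expect_equal(pair_energy(plus, minus, lam, cfg),
               -(lB * kBT / lam) * exp(-1) - shift, tolerance = 1e-10)
  # like charges repel
  expect_gt(pair_energy(plus, plus, lam, cfg), 0)
  expect_error(pair_energy("A", "A", 0, cfg), "r must be > 0")
  expect_error(build_topology(protein = bio_seq("AB", "protein")), "invalid")
})

test_that("simulations are bitwise reproducible and thermostatted", {
  top <- build_topology(protein = bio_seq(strrep("GS", 10), "protein"))
  # friction 1/ps for the thermostat check: kinetic-energy relaxation is
  # fast enough that 1e5 steps give a tight temperature average
  cfg <- sim_config(box_edge = 10, n_steps = 100000L, save_every = 100L,
                    seed = 3, friction_per_ps = 1)
  tr1 <- run_simulation(top, cfg)
  tr2 <- run_simulation(top, cfg)
  expect_identical(tr1$frames, tr2$frames)
  expect_true(all(is.finite(tr1$frames)))
  # equipartition: kinetic temperature within 2% of the set point
  expect_equal(mean(tr1$kinetic_temperature), 300, tolerance = 0.02)
  # harmonic bonds fluctuate about r0 within thermal broadening
  nf <- dim(tr1$frames)[1]
  bl <- vapply(seq_len(nf), function(f)
    mean(sqrt(rowSums((tr1$frames[f, 2:20, ] -
                         tr1$frames[f, 1:19, ])^2))), numeric(1))
  # sd of a single bond ~ sqrt(kBT / k) ~ 0.018 nm; the mean is much tighter
  expect_equal(mean(bl), 0.381, tolerance = 0.02)
})

test_that("bound-state classification matches a brute-force oracle", {
  # hand-built 4-frame toy: two 2-bead chains, 2 frames in contact
  fr <- array(0, c(4, 4, 3))
  sep <- c(0.5, 5, 0.6, 4)  # frames 1 and 3 bound at cutoff 1
  for (f in 1:4) {
    fr[f, 1, ] <- c(1, 1, 1); fr[f, 2, ] <- c(1.4, 1, 1)
    fr[f, 3, ] <- c(1 + sep[f], 1, 1); fr[f, 4, ] <- c(1.4 + sep[f], 1, 1)
  }
  traj <- toy_trajectory(fr, c("protein", "protein", "rna", "rna"))
  st <- classify_bound(traj, cutoff = 1)
  expect_equal(st$bound_fraction, 0.5)
  expect_equal(st$bound, c(TRUE, FALSE, TRUE, FALSE))
  # random toy trajectory against an O(N^2) recount (with min-image wrap)
  set.seed(99)
  fr2 <- array(runif(20 * 8 * 3, 0, 10), c(20, 8, 3))
  traj2 <- toy_trajectory(fr2, rep(c("protein", "rna"), each = 4))
  st2 <- classify_bound(traj2, cutoff = 2.5)
  oracle <- brute_contacts(traj2, 2.5)
  expect_equal(st2$n_contacts, oracle$counts)
  expect_equal(st2$bound, oracle$counts >= 1)
  # unbound everywhere -> f_b = 0
  far <- toy_trajectory(array(rep(c(1, 1, 1, 4.5, 1, 1), each = 3),
                              c(3, 2, 3)), c("protein", "rna"))
  expect_equal(classify_bound(far, cutoff = 1)$bound_fraction, 0)
  single <- toy_trajectory(fr[, 1:2, , drop = FALSE],
                           c("protein", "protein"))
  expect_error(classify_bound(single, cutoff = 1), "single chain")
})

test_that("apparent KD follows single-pair mass action", {
  cfg <- sim_config(box_edge = 25)
  st <- structure(list(bound_fraction = 0.5), class = "binding_states")
  # f_b = 0.5, 25 nm box: 0.5 / (V NA) = 53.1 uM
  expect_equal(apparent_kd(st, cfg) * 1e6, 53.1, tolerance = 0.01)
  expect_warning(kd0 <- apparent_kd(
    structure(list(bound_fraction = 1), class = "binding_states"), cfg),
    "bound")
  expect_equal(kd0, 0)
  expect_warning(kdi <- apparent_kd(
    structure(list(bound_fraction = 0), class = "binding_states"), cfg),
    "unbound|no bound")
  expect_true(is.infinite(kdi))
  # equal f_b in equal boxes -> affinity ratio 1
  expect_equal(relative_affinity(st, st, cfg), 1)
  cfg2 <- sim_config(box_edge = 30)
  expect_error(relative_affinity(st, st, cfg, cfg2), "equal box")
})

test_that("contact frequencies match recounts and respect bounds", {
  set.seed(7)
  fr <- array(runif(15 * 6 * 3, 0, 10), c(15, 6, 3))
  traj <- toy_trajectory(fr, rep(c("protein", "rna"), each = 3))
  cm <- contact_frequency(traj, cutoff = 3)
  oracle <- brute_contacts(traj, 3)
  expect_equal(unname(cm$frequency), oracle$freq)
  expect_true(all(cm$frequency >= 0 & cm$frequency <= 1))
  # static bound geometry -> frequencies exactly 0 or 1
  stat <- array(NA_real_, c(2, 6, 3))
  pts <- matrix(c(1, 1, 1, 1.5, 1, 1, 5, 5, 5,
                  1.2, 1, 1, 1.7, 1, 1, 5.5, 5, 5), ncol = 3, byrow = TRUE)
  for (f in 1:2) stat[f, , ] <- pts
  trs <- toy_trajectory(stat, rep(c("protein", "rna"), each = 3))
  cms <- contact_frequency(trs, cutoff = 1.0)
  expect_true(all(cms$frequency %in% c(0, 1)))
  # restricting to bound frames never lowers a frequency
  st <- classify_bound(traj, cutoff = 3)
  if (any(st$bound) && !all(st$bound)) {
    cmb <- contact_frequency(traj, cutoff = 3, frames = st$bound)
    expect_true(all(cmb$frequency >= cm$frequency - 1e-12))
  }
  expect_error(contact_frequency(toy_trajectory(fr[, 1:3, , drop = FALSE],
                                                rep("protein", 3)),
                                 cutoff = 3), "single chain")
})

test_that("per-state Rg statistics conserve frames and handle rigid pairs", {
  # rigid two-bead chain at fixed separation d -> Rg = d / 2 every frame
  fr <- array(0, c(3, 4, 3))
  for (f in 1:3) {
    fr[f, 1, ] <- c(1, 1, 1); fr[f, 2, ] <- c(3, 1, 1)   # d = 2
    fr[f, 3, ] <- c(6, 6, 6); fr[f, 4, ] <- c(6.5, 6, 6)
  }
  traj <- toy_trajectory(fr, c("protein", "protein", "rna", "rna"))
  st <- classify_bound(traj, cutoff = 1)
  out <- rg_by_state(traj, st, "protein")
  expect_equal(out$rg, rep(1, 3))
  expect_equal(out$bound_stats$n + out$unbound_stats$n, 3)
  expect_error(rg_by_state(traj, st, "dna"), "not present")
})

test_that("flexible-polymer Rg approaches the Gaussian-chain closed form", {
  # bonds only: zero out every nonbonded term via a neutral zero-epsilon table
  ff <- load_forcefield()
  ff$epsilon_kJmol[] <- 0
  ff$charge_e[] <- 0
  n <- 40
  top <- build_topology(protein = bio_seq(strrep("G", n), "protein"), ff = ff)
  cfg <- sim_config(box_edge = 20, n_steps = 150000L, save_every = 50L,
                    seed = 5, friction_per_ps = 0.05)
  tr <- run_simulation(top, cfg)
  rg <- vapply(seq_len(dim(tr$frames)[1]), function(f) {
    x <- tr$frames[f, , ]
    sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
  }, numeric(1))
  b <- 0.381
  expect_equal(mean(rg), b * sqrt(n / 6), tolerance = 0.08)
})

test_that("trajectory container round-trips with its JSON sidecar", {
  top <- build_topology(protein = bio_seq("GSGSGS", "protein"))
  cfg <- sim_config(box_edge = 10, n_steps = 2000L, save_every = 100L,
                    seed = 2)
  tr <- run_simulation(top, cfg)
  base <- tempfile()
  write_trajectory(tr, base)
  back <- read_trajectory(base)
  expect_identical(back$frames, tr$frames)
  side <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(side$units, "nm")
  expect_equal(side$seed, 2)
  expect_equal(side$n_frames, dim(tr$frames)[1])
})
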