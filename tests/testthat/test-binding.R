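test_that("1:1 anisotropy model solves the depletion quadratic exactly", {
  par <- list(kd = 1e-6, r_free = 0, r_bound = 1)
  # no titrant -> free probe
  expect_equal(anisotropy_model(1e-8, 0, par), 0)
  # saturation limit
  expect_equal(anisotropy_model(1e-8, 1, par), 1, tolerance = 1e-5)
  # equal probe, titrant, kd: fraction bound = (3 - sqrt(5)) / 2
  fb <- anisotropy_model(1e-6, 1e-6, par)
  expect_equal(fb, (3 - sqrt(5)) / 2, tolerance = 1e-12)
  # independent numeric root of the mass balance
  root <- uniroot(function(cc) (1e-6 - cc) * (1e-6 - cc) / 1e-6 - cc,
                  c(0, 1e-6), tol = 1e-18)$root
  expect_equal(fb, root / 1e-6, tolerance = 1e-9)
  expect_error(anisotropy_model(1e-8, -1, par), "concentrations")
  expect_error(anisotropy_model(1e-8, 1e-6, list(kd = -1, r_free = 0,
                                                 r_bound = 1)), "kd")
})

test_that("1:1 model is monotone and bounded by its endpoints", {
  par <- list(kd = 5e-7, r_free = 0.05, r_bound = 0.2)
  x <- 10^seq(-9, -4, length.out = 50)
  r <- anisotropy_model(1e-8, x, par)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= par$r_free & r <= par$r_bound))
})

test_that("2:1 sequential model conserves mass and nests the endpoints", {
  par <- list(kd = c(1e-6, 4e-6), r_free = 0.05, r_bound = 0.2)
  x <- 10^seq(-8, -4, length.out = 30)
  r <- anisotropy_model(1e-8, x, par, "two_to_one")
  expect_true(all(r >= 0.05 - 1e-12 & r <= 0.2 + 1e-12))
  expect_equal(anisotropy_model(1e-8, 0, par, "two_to_one"), 0.05)
  # saturation drives everything to P2R at the shared endpoint
  expect_equal(anisotropy_model(1e-8, 0.1, par, "two_to_one"), 0.2,
               tolerance = 1e-3)
})

test_that("noiseless synthetic data are recovered exactly", {
  gen <- gen_titration(kd = 6.7e-7, r_free = 0.08, r_bound = 0.2,
                       noise_sd = 0, replicates = 1L, seed = 5)
  fit <- fit_isotherm(gen$series, "one_to_one")
  expect_equal(fit$kd_app, 6.7e-7, tolerance = 1e-6)
  expect_equal(fit$r_free, 0.08, tolerance = 1e-8)
  expect_equal(fit$r_bound, 0.2, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-16)
})

test_that("kd recovery from noisy data lands inside the 95% CI", {
  gen <- gen_titration(kd = 1.9e-6, noise_sd = 0.002, replicates = 3L,
                       seed = 1)
  fit <- fit_isotherm(gen$series, "one_to_one")
  ci <- fit$ci[fit$ci$parameter == "kd_app", ]
  expect_gt(1.9e-6, ci$lower)
  expect_lt(1.9e-6, ci$upper)
})

test_that("flat titrations raise an unidentifiability error", {
  flat <- titration_series(1e-8, 10^seq(-9, -5, length.out = 8),
                           rep(0.05, 8))
  expect_error(fit_isotherm(flat), "unidentifiable|transition")
})

test_that("model comparison prefers the generating model", {
  gen1 <- gen_titration(kd = 6.7e-7, noise_sd = 0.002, seed = 3)
  f1 <- fit_isotherm(gen1$series, "one_to_one")
  f2 <- fit_isotherm(gen1$series, "two_to_one")
  sel <- compare_models(f1, f2)
  expect_equal(sel$preferred, "one_to_one")
  # a fit compared with itself is a tie
  self <- compare_models(f1, f1)
  expect_true(self$tie)
  # mismatched data are rejected
  gen2 <- gen_titration(kd = 6.7e-7, noise_sd = 0.002, seed = 4)
  f3 <- fit_isotherm(gen2$series, "one_to_one")
  expect_error(compare_models(f1, f3), "same data")
})

test_that("strongly two-site data prefer the 2:1 model", {
  # distinct endpoints for PR and P2R, well-separated constants
  x <- 10^seq(-8.5, -3.5, length.out = 24)
  r <- anisotropy_model(1e-8, x,
                        list(kd = c(1e-7, 1e-5), r_free = 0.05,
                             r_bound = c(0.12, 0.25)), "two_to_one")
  ts <- titration_series(1e-8, x, r)
  f1 <- fit_isotherm(ts, "one_to_one")
  f2 <- fit_isotherm(ts, "two_to_one", shared_endpoint = FALSE)
  sel <- compare_models(f1, f2)
  expect_equal(sel$preferred, "two_to_one")
  expect_length(f2$kd_app, 2)
  expect_length(f2$r_bound, 2)
})

test_that("titration CSV and binding-fit JSON round-trip", {
  gen <- gen_titration(kd = 6.7e-7, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_titration_csv(gen$series, f)
  back <- read_titration_csv(f)
  expect_equal(back$probe_total, gen$series$probe_total)
  expect_equal(back$anisotropy, gen$series$anisotropy)
  fit <- fit_isotherm(back, "one_to_one")
  j <- tempfile(fileext = ".json")
  write_binding_fit(fit, j)
  obj <- jsonlite::read_json(j)
  expect_equal(obj$kd_app_M, fit$kd_app, tolerance = 1e-12)
})
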