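test_that("equilibrium constants follow Kd = kd/ka and Ka = 1/Kd", {
  # values from the packaged kinetic-constant table (mutant-probe synthetic
  # targets), printed at 3 significant figures
  expect_equal(signif(kd_equilibrium(9.72e7, 4.26e-3), 3), 4.38e-11)
  expect_equal(signif(kd_equilibrium(8.17e6, 3.86e-4), 3), 4.72e-11)
  expect_equal(signif(ka_equilibrium(4.3827e-11), 3), 2.28e10)
  expect_equal(signif(ka_equilibrium(4.7246e-11), 3), 2.12e10)
  expect_identical(kd_equilibrium(1, 1), 1)
  expect_identical(ka_equilibrium(1), 1)
  expect_error(kd_equilibrium(-1, 1), "ka")
  expect_error(kd_equilibrium(1, 0), "kd")
  expect_error(ka_equilibrium(0), "Kd")
})

test_that("Ka * Kd == 1 holds for kinetic_params across magnitudes", {
  set.seed(42)
  for (i in 1:50) {
    p <- kinetic_params(10^runif(1, -2, 9), 10^runif(1, -8, 2))
    expect_equal(p$Ka * p$Kd, 1, tolerance = 1e-12)
  }
  expect_error(kinetic_params(0, 1), "ka")
  expect_error(kinetic_params(1, Inf), "kd")
})

test_that("observed rate is ka*C + kd", {
  p <- default_params()
  expect_equal(observed_rate(p, 1e-7), 0.101)
  expect_equal(observed_rate(p, 0), p$kd)
  expect_error(observed_rate(p, -1), "conc")
})

test_that("closed-form phases agree with an independent RK4 integration", {
  p <- default_params()
  times <- seq(0, 300, length.out = 1000)
  ode <- ode_association(p$ka, p$kd, p$rmax, 1e-7, times)
  cf <- simulate_association(p, 1e-7, times)
  expect_lt(max(abs(cf[-1] - ode[-1]) / abs(ode[-1])), 1e-6)
  expect_equal(cf[1], 0)
  # analytic plateau
  req <- p$rmax * p$ka * 1e-7 / (p$ka * 1e-7 + p$kd)
  expect_equal(simulate_association(p, 1e-7, 1e6, t0 = 0), req,
               tolerance = 1e-12)
  expect_true(all(diff(cf) > 0))         # strictly increasing
  expect_true(all(cf <= req + 1e-12))    # bounded by Req

  tdis <- seq(0, 600, length.out = 1000)
  oded <- ode_dissociation(p$kd, req, tdis)
  cfd <- simulate_dissociation(p, req, tdis)
  expect_lt(max(abs(cfd - oded) / abs(oded)), 1e-6)
  expect_equal(cfd[1], req)
  expect_true(all(diff(cfd) < 0) && all(cfd > 0))
  # half-life identity
  expect_equal(simulate_dissociation(p, 10, log(2) / p$kd, t0 = 0), 5)
  expect_error(simulate_association(p, 0, times), "conc")
  expect_error(simulate_dissociation(p, -1, tdis), "r0")
})

test_that("a second randomly-drawn parameter set also matches the oracle", {
  set.seed(7)
  p <- kinetic_params(10^runif(1, 4, 8), 10^runif(1, -5, -2), 80)
  times <- seq(0, 300, length.out = 1000)
  ode <- ode_association(p$ka, p$kd, p$rmax, 1e-7, times, dt = 0.01)
  cf <- simulate_association(p, 1e-7, times)
  expect_lt(max(abs(cf[-1] - ode[-1]) / pmax(abs(ode[-1]), 1e-12)), 1e-6)
})

test_that("injection schedules are validated", {
  expect_error(injection_phase("association", 300, 0), "analyte")
  expect_error(injection_phase("dissociation", 600, 1e-7), "analyte")
  expect_error(injection_phase("baseline", 0), "duration")
  sched <- hybridization_schedule(1e-7)
  expect_length(sched, 2L)
  bad <- rev(sched)  # dissociation before association
  expect_error(simulate_sensorgram(bad, default_params()), "follow")
  expect_error(simulate_sensorgram(sched[1], default_params()), "exactly one")
})

test_that("simulate_sensorgram: noise-free limit, determinism, MC mean", {
  p <- default_params()
  sched <- hybridization_schedule(1e-7)
  sg <- simulate_sensorgram(sched, p)
  ia <- sg$phase == "association"
  expect_equal(sg$response[ia],
               simulate_association(p, 1e-7, sg$time[ia]), tolerance = 1e-12)
  r300 <- sg$response[sg$time == 300]
  id <- sg$phase == "dissociation"
  expect_equal(sg$response[id],
               simulate_dissociation(p, r300, sg$time[id], t0 = 300),
               tolerance = 1e-12)
  # same seed => identical traces; noise requires a seed
  s1 <- simulate_sensorgram(sched, p, noise_sd = 0.5, seed = 3)
  s2 <- simulate_sensorgram(sched, p, noise_sd = 0.5, seed = 3)
  expect_identical(s1$response, s2$response)
  expect_error(simulate_sensorgram(sched, p, noise_sd = 0.5), "seed")
  # Monte-Carlo: the mean of 200 replicates tracks the noise-free
  # trajectory; with 901 grid points a small number of 3-sigma exceedances
  # is expected by multiplicity, so bound the per-point rate at 3 sigma and
  # the maximum at 4.5 sigma
  acc <- 0
  for (s in 1:200)
    acc <- acc + simulate_sensorgram(sched, p, noise_sd = 0.5,
                                     seed = s)$response
  z <- abs(acc / 200 - sg$response) / (0.5 / sqrt(200))
  expect_gte(mean(z <= 3), 0.99)
  expect_true(all(z <= 4.5))
  # drift is linear in time
  sd3 <- simulate_sensorgram(sched, p, drift = 0.01)
  expect_equal(sd3$response - sg$response, 0.01 * sg$time, tolerance = 1e-12)
})

test_that("noise-free fits recover the generating parameters to 1e-4", {
  p <- default_params()
  sg <- simulate_sensorgram(hybridization_schedule(1e-7), p)
  f <- fit_1to1(sg, 1e-7)
  expect_true(f$converged)
  expect_lt(abs(f$estimate$ka - p$ka) / p$ka, 1e-4)
  expect_lt(abs(f$estimate$kd - p$kd) / p$kd, 1e-4)
  expect_lt(abs(f$estimate$rmax - p$rmax) / p$rmax, 1e-4)
})

test_that("degenerate fits are reported honestly", {
  p <- default_params()
  sg <- simulate_sensorgram(hybridization_schedule(1e-7), p)
  flat <- sg
  flat$response <- rep(0, nrow(flat))
  f <- fit_1to1(flat, 1e-7)
  expect_false(f$converged)
  expect_true(all(is.na(f$se)))
  expect_error(fit_1to1(sg, -1), "conc")
  short <- sg[sg$time <= 5, ]
  class(short) <- class(sg)
  attr(short, "conc") <- 1e-7
  expect_error(fit_1to1(short, 1e-7), ">= 10 points")
})

test_that("log-uniform recovery: >= 90% of noisy fits within 10%", {
  # ka in [1e4, 1e8], kd in [1e-5, 1e-2], C = 1e-7 M, noise 0.5 RU.
  # Sampled at 10 Hz: kobs reaches ~10 s^-1 at the fast corner and is not
  # resolvable on a 1 Hz grid (see the methods vignette).
  set.seed(99)
  n <- 40
  lka <- runif(n, 4, 8); lkd <- runif(n, -5, -2)
  ok <- logical(n)
  for (i in 1:n) {
    p <- kinetic_params(10^lka[i], 10^lkd[i], 100)
    sg <- simulate_sensorgram(hybridization_schedule(1e-7), p,
                              noise_sd = 0.5, seed = 1000 + i,
                              sampling_hz = 10)
    f <- fit_1to1(sg, 1e-7)
    ok[i] <- f$converged &&
      abs(f$estimate$ka - p$ka) / p$ka <= 0.1 &&
      abs(f$estimate$kd - p$kd) / p$kd <= 0.1
  }
  expect_gte(mean(ok), 0.9)
})

test_that("fit standard errors are finite and calibrated in magnitude", {
  p <- default_params()
  f <- fit_1to1(simulate_sensorgram(hybridization_schedule(1e-7), p,
                                    noise_sd = 0.5, seed = 11), 1e-7)
  expect_true(all(is.finite(f$se)))
  # the observed error should be within a few reported sigmas
  expect_lt(abs(f$estimate$ka - p$ka), 10 * f$se[["ka"]])
  expect_lt(abs(f$estimate$kd - p$kd), 10 * f$se[["kd"]])
})
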