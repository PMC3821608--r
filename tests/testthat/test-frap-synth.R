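# Synthetic bleach generator: closed form, simulator, confinement.

test_that("uniform-disk closed form has the right limits and monotonicity", {
  tau <- 50^2 / (4 * 1.28e2)  # omega = 50 um, D = 1.28e-6 cm^2/s
  expect_equal(soumpasis_recovery(1e9, 50, 1.28e-6), 1, tolerance = 1e-4)
  expect_equal(soumpasis_recovery(0, 50, 1.28e-6), 0)
  expect_gt(soumpasis_recovery(4 * tau, 50, 1.28e-6),
            soumpasis_recovery(tau, 50, 1.28e-6))
  tt <- seq(0.01, 100, length.out = 400)
  expect_true(all(diff(soumpasis_recovery(tt, 50, 1.28e-6)) > 0))
})

test_that("solving the closed form for f = 1/2 gives the 0.224 coefficient", {
  # independent root-finding oracle on the closed form itself
  omega <- 50
  D <- 1.28e-6
  root <- uniroot(function(t) soumpasis_recovery(t, omega, D) - 0.5,
                  c(0.1, 100), tol = 1e-10)$root
  coef <- root * (D * 1e8) / omega^2
  expect_equal(coef, 0.224, tolerance = 0.001 / 0.224)
})

test_that("scenario invariants are enforced before running", {
  expect_error(bleach_scenario(omega = 10, grid_spacing = 5),
               class = "permstrut_bad_discretization")
  expect_error(bleach_scenario(omega = 50, domain_width = 100),
               class = "permstrut_bad_discretization")
  expect_error(bleach_scenario(bleach_fraction = 0),
               class = "permstrut_domain_error")
  # explicit-mode stability is checked before stepping
  sc <- water_scenario(dt = 1)  # D dt / h^2 > 1/4 at h = 5
  expect_error(simulate_recovery(sc, solver = "explicit"),
               class = "permstrut_bad_discretization")
})

test_that("a motionless field never recovers and seeds are reproducible", {
  cv0 <- simulate_recovery(bleach_scenario(D_true = 0, noise_sigma = 0))
  expect_true(all(cv0$f == 0))
  a <- simulate_recovery(bleach_scenario(noise_sigma = 0.02, seed = 42))
  b <- simulate_recovery(bleach_scenario(noise_sigma = 0.02, seed = 42))
  c <- simulate_recovery(bleach_scenario(noise_sigma = 0.02, seed = 43))
  expect_identical(a$f, b$f)
  expect_false(identical(a$f, c$f))
})

test_that("noise-free simulation matches the closed form in the window", {
  # oracle-agreement contract: domain >= 10 omega, t in [0.1, 10] tau
  sc <- water_scenario(domain_width = 600, domain_height = 600, T = 50,
                       dt = 0.25)
  cv <- simulate_recovery(sc)
  tau <- sc$omega^2 / (4 * sc$D_true * 1e8)
  sel <- cv$times >= 0.1 * tau & cv$times <= 10 * tau
  f_oracle <- soumpasis_recovery(cv$times[sel], sc$omega, sc$D_true)
  expect_lt(max(abs(cv$f[sel] - f_oracle) / f_oracle), 0.02)
})

test_that("normalized output is invariant to the bleach depth", {
  f_half <- simulate_recovery(water_scenario(bleach_fraction = 0.5))$f
  f_deep <- simulate_recovery(water_scenario(bleach_fraction = 0.95))$f
  expect_equal(f_half, f_deep, tolerance = 1e-10)
})

test_that("the explicit grid solver converges onto the spectral solution", {
  diff_at <- function(h, dt) {
    sc <- bleach_scenario(D_true = 1e-6, omega = 20, grid_spacing = h,
                          domain_width = 200, domain_height = 200,
                          dt = dt, T = 6, noise_sigma = 0)
    cs <- simulate_recovery(sc, solver = "spectral")
    ce <- simulate_recovery(sc, solver = "explicit")
    max(abs(approx(cs$times, cs$f, xout = seq(0.3, 6, by = 0.3))$y -
              approx(ce$times, ce$f, xout = seq(0.3, 6, by = 0.3))$y))
  }
  d_coarse <- diff_at(4, 0.03)
  d_fine <- diff_at(2, 0.008)
  expect_lt(d_coarse, 0.05)
  # the sampled-grid solver carries an O(h) bleach-edge bias; refining the
  # grid must shrink the gap to the exact eigenfunction solution
  expect_lt(d_fine, d_coarse)
})

test_that("noise-free analysis recovers the generator's input diffusivity", {
  for (D in c(0.5e-6, 1.28e-6, 2e-6)) {
    cv <- simulate_recovery(water_scenario(D_true = D))
    expect_equal(frap_analyze(cv)$D, D, tolerance = 0.05)
  }
})

test_that("parameter recovery under noise is accurate in the median", {
  for (D in c(0.5e-6, 1e-6, 2e-6)) {
    errs <- vapply(1:20, function(s) {
      sc <- bleach_scenario(D_true = D, noise_sigma = 0.02, seed = s)
      abs(frap_analyze(simulate_recovery(sc))$D - D) / D
    }, numeric(1))
    expect_lt(median(errs), 0.10)
  }
})

test_that("explicit confined runs conserve total fluorophore", {
  sc <- bleach_scenario(D_true = 1e-6, omega = 10, grid_spacing = 2,
                        line_width = 40, domain_height = 40,
                        dt = 0.005, T = 1, noise_sigma = 0)
  masses <- permstrut:::.explicit_total_mass(sc, n_steps = 200)
  # relative drift per simulated second below 1e-6
  drift <- abs(masses - masses[1]) / masses[1]
  expect_lt(max(drift) / 1.0, 1e-6)
})

test_that("confinement never speeds recovery and vanishes for wide lines", {
  sc <- bleach_scenario(D_true = 1.28e-6, omega = 50, line_width = 120,
                        domain_height = 600, noise_sigma = 0)
  eff <- confinement_effect(sc)
  expect_gte(eff$relative_gap, 0)
  expect_gt(eff$relative_gap, 0.05)  # tight line: a clear slowdown
  # measured printed-line width: gap still non-negative, but tiny
  sc2 <- bleach_scenario(D_true = 1.28e-6, omega = 50, line_width = 310,
                         domain_height = 600, noise_sigma = 0)
  eff2 <- confinement_effect(sc2)
  expect_gte(eff2$relative_gap, -1e-6)
  expect_lt(abs(eff2$relative_gap), eff$relative_gap)
  # very wide line converges to the infinite film
  sc3 <- bleach_scenario(D_true = 1.28e-6, omega = 50, line_width = 500,
                         domain_height = 600, noise_sigma = 0)
  expect_lt(abs(confinement_effect(sc3)$relative_gap), 1e-3)
  # spot larger than the line is rejected
  expect_error(
    confinement_effect(bleach_scenario(D_true = 1.28e-6, omega = 50,
                                       line_width = 90,
                                       domain_height = 600,
                                       noise_sigma = 0)),
    class = "permstrut_spot_exceeds_line")
})
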