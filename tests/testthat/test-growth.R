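# Monod growth stepping and the coupled quasi-steady simulation loop.

test_that("Monod stepping honours its algebraic limit cases", {
  p <- kinetic_params(k_d = 0)
  rho <- array(c(1e12, 5e13), dim = c(2, 1, 1))
  # no oxygen, no decay: unchanged
  expect_equal(update_cells(rho, array(0, dim(rho)), dt = 10, p), rho)
  # saturating oxygen for one division time: factor 2^(C0/(K + C0)) ~ 1.960
  grown <- update_cells(rho, array(p$c_0, dim(rho)), dt = p$t_d, p)
  expect_equal(as.numeric(grown / rho), rep(2^(0.1 / 0.103), 2),
               tolerance = 1e-3)
  # cap at the maximum density
  at_max <- array(p$rho_max, dim(rho))
  expect_equal(update_cells(at_max, array(p$c_0, dim(rho)), dt = 50, p),
               at_max)
  # decay floors at zero and struts stay empty
  pd <- kinetic_params(k_d = 0.5)
  mask <- array(c(FALSE, TRUE), dim(rho))
  dec <- update_cells(rho, array(0, dim(rho)), dt = 1e4, pd,
                      strut_mask = mask)
  expect_true(all(dec >= 0))
  expect_equal(dec[2, 1, 1], 0)
  expect_error(update_cells(rho, rho, dt = 0, p),
               class = "permstrut_domain_error")
})

test_that("a zero-duration run returns the seeded state unchanged", {
  s <- run_simulation(small_lattice_spec(), kinetic_params(d_s = 0),
                      t_end = 0)
  expect_length(s$times, 1L)
  p <- kinetic_params()
  expect_equal(unique(s$rho_profile[, 1]), p$rho_0)
  expect_equal(unique(s$c_profile[, 1]), p$c_0)
})

test_that("bounds hold at every checkpoint of a coupled run", {
  p <- kinetic_params(d_s = 0.5 * D_W_OXYGEN)
  s <- run_simulation(small_lattice_spec(), p, dt_growth = 4, t_end = 400,
                      stop_when_steady = FALSE)
  expect_true(all(s$c_bounds[, "min"] >= -1e-12))
  expect_true(all(s$c_bounds[, "max"] <= p$c_0 * (1 + 1e-8)))
  expect_true(all(s$rho_bounds[, "min"] >= 0))
  expect_true(all(s$rho_bounds[, "max"] <= p$rho_max))
})

test_that("density is per-voxel non-decreasing when decay is off", {
  p <- kinetic_params(d_s = 0, k_d = 0)
  s <- run_simulation(small_lattice_spec(thickness = 200), p,
                      dt_growth = 8, t_end = 320,
                      stop_when_steady = FALSE, keep_fields = TRUE)
  for (k in seq_along(s$fields)[-1]) {
    expect_true(all(s$fields[[k]] - s$fields[[k - 1]] >= -1e-6 * p$rho_max))
  }
})

test_that("quarter-period symmetry reduction reproduces the full solve", {
  p <- kinetic_params(d_s = 0.25 * D_W_OXYGEN)
  for (arr in c("lattice", "staggered")) {
    spec <- small_lattice_spec(thickness = 200, arrangement = arr)
    s_full <- run_simulation(spec, p, dt_growth = 6, t_end = 60,
                             stop_when_steady = FALSE, use_symmetry = FALSE,
                             oxygen_tol = 1e-8)
    s_quart <- run_simulation(spec, p, dt_growth = 6, t_end = 60,
                              stop_when_steady = FALSE, use_symmetry = TRUE,
                              oxygen_tol = 1e-8)
    expect_equal(dim(s_quart$grid$labels)[1:2],
                 dim(s_full$grid$labels)[1:2] / 2)
    expect_equal(s_quart$rho_profile, s_full$rho_profile,
                 tolerance = 1e-6, info = arr)
    expect_equal(s_quart$c_profile, s_full$c_profile, tolerance = 1e-6,
                 info = arr)
  }
})

test_that("top-surface saturation time matches the doubling-count estimate", {
  # thin column, oxygen held near C0 by weak consumption, no decay:
  # log2(rho_max / rho_0) * t_d / (C0 / (K + C0)) ~ 357 h
  p <- kinetic_params(v_max = 3.3e-18, k_d = 0, d_s = 0)
  s <- run_simulation(column_spec(100, voxel = 10), p, dt_growth = 2,
                      t_end = 800)
  expected <- log2(p$rho_max / p$rho_0) * p$t_d / (p$c_0 / (p$k + p$c_0))
  expect_equal(expected, 357, tolerance = 0.01)
  top <- top_saturation_time(s)
  expect_equal(top$t_hours, expected, tolerance = 0.05)
  # every voxel sees near-C0 oxygen, so the whole column saturates together
  # and the steady-state criterion fires shortly after
  expect_true(s$converged)
  expect_equal(saturation_time(s), expected, tolerance = 0.10)
})

test_that("permeable struts deepen growth monotonically in D_s", {
  p0 <- kinetic_params()
  depths <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(r) {
    p <- kinetic_params(d_s = r * D_W_OXYGEN)
    s <- run_simulation(small_lattice_spec(), p, dt_growth = 4,
                        t_end = 500, stop_when_steady = FALSE)
    saturated_depth(s$rho_profile[, length(s$times)], p$rho_max,
                    s$grid$voxel_size)
  }, numeric(1))
  expect_true(all(diff(depths) >= 0))
  # fully permeable strictly beats impermeable
  expect_gt(depths[5], depths[1])
})

test_that("halving the voxel size moves the front by at most one coarse voxel", {
  p <- kinetic_params(d_s = 0)
  d_coarse <- local({
    s <- run_simulation(small_lattice_spec(voxel = 10), p, dt_growth = 4,
                        t_end = 400, stop_when_steady = FALSE)
    saturated_depth(s$rho_profile[, length(s$times)], p$rho_max, 10)
  })
  d_fine <- local({
    s <- run_simulation(small_lattice_spec(voxel = 5), p, dt_growth = 4,
                        t_end = 400, stop_when_steady = FALSE)
    saturated_depth(s$rho_profile[, length(s$times)], p$rho_max, 5)
  })
  expect_lte(abs(d_fine - d_coarse), 10)
})
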