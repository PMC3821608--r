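# Saturated depth, saturation time, surface timing and the sweep driver.

test_that("depth profile averages culture voxels only", {
  g <- build_scaffold(scaffold_spec(alpha = 0.5, pitch = 120,
                                    total_thickness = 200, voxel_size = 10))
  # uniform density: profile is flat
  rho <- uniform_rho(g, 2.1e11)
  prof <- depth_profile(rho, g)
  expect_equal(prof$mean_rho, rep(2.1e11, 20))
  expect_equal(prof$z_um, seq(5, 195, by = 10))
  # mixed field: matches a brute-force masked loop
  set.seed(7)
  rho2 <- array(runif(length(g$labels)), dim = dim(g$labels))
  rho2[g$labels == 1L] <- 0
  prof2 <- depth_profile(rho2, g)
  brute <- vapply(seq_len(dim(g$labels)[3]), function(k) {
    sl <- rho2[, , k]
    mean(sl[g$labels[, , k] == 0L])
  }, numeric(1))
  expect_equal(prof2$mean_rho, brute)
  # step field: step profile
  rho3 <- uniform_rho(g, 0)
  rho3[, , 1:10][g$labels[, , 1:10] == 0L] <- 1.5e14
  prof3 <- depth_profile(rho3, g)
  expect_equal(prof3$mean_rho, rep(c(1.5e14, 0), each = 10))
})

test_that("saturated depth walks the contiguous saturated slabs from the top", {
  rho_max <- 1.5e14
  # fully saturated: whole thickness
  expect_equal(saturated_depth(rep(rho_max, 100), rho_max, 10), 1000)
  # nothing saturated: zero
  expect_equal(saturated_depth(rep(0.5 * rho_max, 100), rho_max, 10), 0)
  # step at 90 um on a 10 um grid
  prof <- c(rep(rho_max, 9), rep(0, 91))
  expect_equal(saturated_depth(prof, rho_max, 10), 90)
  # threshold semantics: values just under the cut stop the walk
  prof2 <- c(rep(0.995 * rho_max, 5), rep(0.98 * rho_max, 95))
  expect_equal(saturated_depth(prof2, rho_max, 10, threshold_frac = 0.99),
               50)
  expect_equal(saturated_depth(prof2, rho_max, 10, threshold_frac = 0.95),
               1000)
  # slabs without culture voxels are skipped, not blocking
  prof3 <- c(rho_max, NA, rho_max, 0.1 * rho_max)
  expect_equal(saturated_depth(prof3, rho_max, 10), 30)
  # invariant to appending converged (identical) checkpoints: the depth is
  # a pure function of the final profile
  expect_equal(saturated_depth(c(prof, prof[100]), rho_max, 10),
               saturated_depth(prof, rho_max, 10) )
})

test_that("saturation time fires after the rate excursion, not at seeding", {
  mk <- function(rate) list(times = seq(0, by = 2, length.out = length(rate) + 1),
                            max_drho_per_day = c(NA, rate))
  # quiescent start below eps, excursion, then settling: first sub-eps
  # checkpoint after the excursion
  r <- c(5e-4, 8e-4, 0.05, 0.2, 0.04, 2e-3, 9e-4, 5e-4)
  expect_equal(saturation_time(mk(r)), 14)
  # static series: first evaluable checkpoint
  expect_equal(saturation_time(mk(rep(1e-5, 5))), 2)
  # still changing at the end: not-converged signal
  expect_error(saturation_time(mk(c(1e-4, 0.1, 0.2, 0.3))),
               class = "permstrut_not_converged")
  expect_error(saturation_time(list(times = c(0, 2),
                                    max_drho_per_day = c(NA, 1))),
               class = "permstrut_malformed_input")
})

test_that("bottom peak detection flags monotone series", {
  mk <- function(b) list(times = seq(0, by = 2, length.out = length(b)),
                         bottom_density = b)
  mono <- mk(seq(1e11, 1e12, length.out = 20))
  expect_false(bottom_peak_time(mono)$defined)
  peaked <- mk(c(seq(1, 7), seq(6, 1)) * 1e11)
  bp <- bottom_peak_time(peaked, t_s = 100)
  expect_true(bp$defined)
  expect_equal(bp$t_hours, 12)  # checkpoint 7 of the constructed series
  expect_equal(bp$frac, 0.12)
  expect_equal(bp$peak_density, 7e11)
})

test_that("bottom peak arrives later with permeable struts", {
  base <- small_lattice_spec()
  run <- function(ds) {
    run_simulation(base, kinetic_params(d_s = ds), dt_growth = 4,
                   t_end = 600, stop_when_steady = FALSE)
  }
  s0 <- run(0)
  s93 <- run(0.93 * D_W_OXYGEN)
  b0 <- bottom_peak_time(s0)
  b93 <- bottom_peak_time(s93)
  expect_true(b0$defined && b93$defined)
  expect_gte(b93$t_hours, b0$t_hours)
})

test_that("metrics are invariant to transposing the lateral axes", {
  g <- build_scaffold(scaffold_spec(alpha = 0.5, pitch = 120,
                                    total_thickness = 200, voxel_size = 10))
  set.seed(11)
  rho <- array(runif(length(g$labels), max = 1.5e14), dim = dim(g$labels))
  rho[g$labels == 1L] <- 0
  gt <- structure(list(labels = aperm(g$labels, c(2, 1, 3)),
                       voxel_size = g$voxel_size, spec = g$spec),
                  class = "voxel_grid")
  rt <- aperm(rho, c(2, 1, 3))
  expect_equal(depth_profile(rho, g)$mean_rho, depth_profile(rt, gt)$mean_rho)
  expect_equal(saturated_depth(depth_profile(rho, g), 1.5e14, 10),
               saturated_depth(depth_profile(rt, gt), 1.5e14, 10))
})

test_that("the sweep driver tabulates and normalizes by the D_w reference", {
  empty <- sweep_scaffolds(numeric(0), character(0), numeric(0))
  expect_equal(nrow(empty), 0)
  base <- small_lattice_spec(thickness = 200)
  tab <- sweep_scaffolds(alphas = c(0.3, 0.5), arrangements = "lattice",
                         ds_over_dw = c(0, 1), spec_base = base,
                         dt_growth = 8, t_end = 480,
                         stop_when_steady = FALSE)
  expect_equal(nrow(tab), 4)
  expect_false(any(duplicated(tab[, c("alpha", "arrangement",
                                      "ds_over_dw")])))
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$saturated_depth_um >= 0))
  # fractions normalized by the matching ds_over_dw = 1 run
  for (a in c(0.3, 0.5)) {
    ref <- tab$t_s_hr[tab$alpha == a & tab$ds_over_dw == 1]
    sub <- tab[tab$alpha == a, ]
    expect_equal(sub$top_sat_frac, sub$top_sat_hr / ref)
  }
  # permeable never shallower than impermeable at equal alpha
  for (a in c(0.3, 0.5)) {
    sub <- tab[tab$alpha == a, ]
    expect_gte(sub$saturated_depth_um[sub$ds_over_dw == 1],
               sub$saturated_depth_um[sub$ds_over_dw == 0])
  }
})
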