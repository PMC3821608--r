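## Headline metrics: depth profiles, saturated depth, timing fractions.

#' Laterally averaged cell-density depth profile
#'
#' Mean density per depth slab over culture voxels only; strut voxels are
#' excluded from the average.  Slabs without any culture voxel are flagged
#' with `NA`.
#'
#' @param rho cell-density array over the grid (or a [run_simulation()]
#'   final field).
#' @param grid the matching [build_scaffold()] grid.
#' @return data.frame with `z_um` (slab centre depth from the top surface),
#'   `mean_rho` and `n_culture`.
#' @export
depth_profile <- function(rho, grid) {
  d <- dim(grid$labels)
  if (!identical(dim(rho), d))
    ps_stop("permstrut_domain_error", "rho shape must match the grid")
  nz <- d[3L]
  cult <- matrix(grid$labels == 0L, nrow = d[1L] * d[2L], ncol = nz)
  m <- matrix(rho, nrow = d[1L] * d[2L], ncol = nz)
  n_cult <- colSums(cult)
  mean_rho <- ifelse(n_cult > 0, colSums(m * cult) / pmax(n_cult, 1L),
                     NA_real_)
  data.frame(z_um = (seq_len(nz) - 0.5) * grid$voxel_size,
             mean_rho = mean_rho, n_culture = n_cult)
}

#' Saturated depth of a density profile
#'
#' The depth, measured from the media-exposed surface, down to which the
#' laterally averaged cell density has reached the predetermined maximum:
#' the lower edge of the deepest slab such that every shallower culture slab
#' has mean density at least `threshold_frac * rho_max`.  Slabs without
#' culture voxels are skipped.  Returns 0 when the top slab is unsaturated.
#' The default 0.99 threshold stands in for "reaches the maximum" because
#' capped exponential growth only attains the cap asymptotically.
#'
#' @param profile numeric vector of per-slab mean densities ordered top to
#'   bottom (or a [depth_profile()] data.frame).
#' @param rho_max maximum cell density, cells/m^3.
#' @param voxel_size slab thickness, micrometers.
#' @param threshold_frac saturation threshold as a fraction of `rho_max`.
#' @return saturated depth in micrometers.
#' @export
saturated_depth <- function(profile, rho_max, voxel_size,
                            threshold_frac = 0.99) {
  if (is.data.frame(profile)) profile <- profile$mean_rho
  sat <- profile >= threshold_frac * rho_max
  depth <- 0
  for (k in seq_along(sat)) {
    if (is.na(sat[k])) { depth <- k * voxel_size; next }  # no culture: skip
    if (!sat[k]) break
    depth <- k * voxel_size
  }
  depth
}

# internal: first sub-eps per-day rate after the rate has peaked above eps
.steady_index <- function(rate, eps) {
  usable <- which(!is.na(rate))
  if (length(usable) == 0L) return(NA_integer_)
  r <- rate[usable]
  hot <- which(r >= eps)
  if (length(hot) == 0L) return(usable[1L])
  after <- which(r < eps & seq_along(r) > max(hot))
  if (length(after) == 0L) return(NA_integer_)
  usable[after[1L]]
}

#' Saturation time of a simulation series
#'
#' First checkpoint at which the per-day density change satisfies
#' max |d rho| / rho_max < `eps_per_day`, taken after the change rate has
#' exceeded the criterion (densities start so far below `rho_max` that the
#' raw rate is trivially small at seeding; requiring a prior excursion above
#' the threshold makes the criterion detect the approach to steady state
#' rather than the quiescent start).  For a series whose rate never exceeds
#' the threshold, the first evaluable checkpoint time is returned.
#'
#' @param series a [run_simulation()] result (needs at least 3 checkpoints).
#' @param eps_per_day steady-state criterion.
#' @return saturation time t_s in hours.
#' @export
saturation_time <- function(series, eps_per_day = 1e-3) {
  if (length(series$times) < 3L)
    ps_stop("permstrut_malformed_input", "series needs >= 3 checkpoints")
  idx <- .steady_index(series$max_drho_per_day, eps_per_day)
  if (is.na(idx))
    ps_stop("permstrut_not_converged",
            "series never meets the steady-state criterion",
            max_rate_tail = utils::tail(series$max_drho_per_day, 3L))
  series$times[idx]
}

#' Time at which the top surface reaches the maximum density
#'
#' First checkpoint at which the shallowest culture slab's mean density
#' reaches `threshold_frac * rho_max`, optionally expressed as a fraction of
#' a supplied saturation time.
#'
#' @param series a [run_simulation()] result.
#' @param t_s normalizing saturation time in hours (by convention the t_s of
#'   the fully permeable strut model); `NULL` returns only the absolute time.
#' @param threshold_frac saturation threshold.
#' @return list with `t_hours` (NA when never reached) and `frac`.
#' @export
top_saturation_time <- function(series, t_s = NULL, threshold_frac = 0.99) {
  thr <- threshold_frac * series$params$rho_max
  idx <- which(series$top_density >= thr)[1L]
  t_hours <- if (is.na(idx)) NA_real_ else series$times[idx]
  list(t_hours = t_hours,
       frac = if (is.null(t_s)) NA_real_ else t_hours / t_s)
}

#' Time of the bottom-surface density peak
#'
#' Locates the checkpoint maximizing the bottom-slab mean density.  The
#' deep scaffold is transiently oxygenated while the seeded density is still
#' low; as the upper layers fill in they shade the bottom, whose density
#' then declines under the decay term, producing an interior peak.  The
#' peak is flagged undefined when the maximum sits at the final checkpoint
#' (no decline observed, e.g. with `k_d = 0`).
#'
#' @param series a [run_simulation()] result.
#' @param t_s normalizing saturation time in hours (optional).
#' @return list with `t_hours`, `frac`, `peak_density` and `defined`.
#' @export
bottom_peak_time <- function(series, t_s = NULL) {
  b <- series$bottom_density
  idx <- which.max(b)
  defined <- idx < length(b) && b[idx] > b[length(b)]
  list(t_hours = if (defined) series$times[idx] else NA_real_,
       frac = if (defined && !is.null(t_s)) series$times[idx] / t_s
              else NA_real_,
       peak_density = b[idx], defined = defined)
}

#' Sweep scaffold configurations and tabulate metrics
#'
#' Runs the coupled simulation over the cross product of strut volume
#' fractions, arrangements and strut-to-water diffusivity ratios, and
#' tabulates saturated depth and timing metrics.  Within each
#' (alpha, arrangement) group the timing fractions are normalized by the
#' saturation time of that group's `ds_over_dw = 1` member when present
#' (the free-water-strut reference model), else left `NA`.  Individual run
#' failures are recorded and the sweep continues.
#'
#' @param alphas numeric vector of strut volume fractions.
#' @param arrangements character vector, subset of
#'   `c("lattice", "staggered")`.
#' @param ds_over_dw numeric vector of strut diffusivity ratios in `[0, 1]`.
#' @param spec_base a [scaffold_spec()] providing the shared geometry.
#' @param params_base a [kinetic_params()] providing the shared kinetics.
#' @param threshold_frac saturation threshold for the depth/timing metrics.
#' @param ... further arguments passed to [run_simulation()].
#' @return data.frame with columns `alpha`, `arrangement`, `ds_over_dw`,
#'   `pitch_um`, `voxel_um`, `kd_per_hr`, `saturated_depth_um`, `t_s_hr`,
#'   `top_sat_frac`, `bottom_peak_frac`, `converged`, `error`.
#' @export
sweep_scaffolds <- function(alphas, arrangements, ds_over_dw,
                            spec_base = scaffold_spec(),
                            params_base = kinetic_params(),
                            threshold_frac = 0.99, ...) {
  combos <- expand.grid(alpha = alphas, arrangement = arrangements,
                        ds_over_dw = ds_over_dw,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  n <- nrow(combos)
  out <- data.frame(combos,
                    pitch_um = rep(spec_base$pitch, n),
                    voxel_um = rep(spec_base$voxel_size, n),
                    kd_per_hr = rep(params_base$k_d, n),
                    saturated_depth_um = rep(NA_real_, n),
                    t_s_hr = rep(NA_real_, n),
                    top_sat_hr = rep(NA_real_, n),
                    bottom_peak_hr = rep(NA_real_, n),
                    top_sat_frac = rep(NA_real_, n),
                    bottom_peak_frac = rep(NA_real_, n),
                    converged = rep(NA, n),
                    error = rep(NA_character_, n))
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    res <- tryCatch({
      spec <- scaffold_spec(total_thickness = spec_base$total_thickness,
                            layer_height = spec_base$layer_height,
                            pitch = spec_base$pitch,
                            alpha = combos$alpha[i],
                            arrangement = combos$arrangement[i],
                            voxel_size = spec_base$voxel_size)
      params <- kinetic_params(v_max = params_base$v_max,
                               k_m = params_base$k_m, k = params_base$k,
                               c_0 = params_base$c_0,
                               rho_0 = params_base$rho_0,
                               rho_max = params_base$rho_max,
                               t_d = params_base$t_d,
                               d_t = params_base$d_t,
                               d_s = combos$ds_over_dw[i] * D_W_OXYGEN,
                               k_d = params_base$k_d)
      series <- run_simulation(spec, params, ...)
      prof <- series$rho_profile[, length(series$times)]
      list(depth = saturated_depth(prof, params$rho_max,
                                   series$grid$voxel_size, threshold_frac),
           t_s = series$t_s,
           top = top_saturation_time(series,
                                     threshold_frac = threshold_frac),
           bottom = bottom_peak_time(series),
           converged = series$converged)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
    } else {
      out$saturated_depth_um[i] <- res$depth
      out$t_s_hr[i] <- res$t_s
      out$top_sat_hr[i] <- res$top$t_hours
      out$bottom_peak_hr[i] <- res$bottom$t_hours
      out$converged[i] <- res$converged
    }
  }
  # normalize timing by the group's free-water-strut saturation time
  for (g in split(seq_len(n), paste(out$alpha, out$arrangement))) {
    ref <- g[which(out$ds_over_dw[g] == 1)][1L]
    if (!is.na(ref) && !is.na(out$t_s_hr[ref])) {
      out$top_sat_frac[g] <- out$top_sat_hr[g] / out$t_s_hr[ref]
      out$bottom_peak_frac[g] <- out$bottom_peak_hr[g] / out$t_s_hr[ref]
    }
  }
  out
}
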