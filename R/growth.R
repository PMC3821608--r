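## Monod proliferation and the coupled quasi-steady growth loop.

#' Advance cell density by Monod doubling kinetics
#'
#' The specific doubling rate is r_g = r_g_max * C / (K + C) (doublings per
#' hour; r_g_max = 1 / t_d), reduced by the constant decay rate `k_d`, and
#' density advances as rho * 2^((r_g - k_d) * dt), hard-capped at `rho_max`
#' and floored at 0.  Base-2 exponentiation is deliberate: the rate is a
#' doubling rate, so one division time at saturating oxygen doubles the
#' population.  Strut voxels stay at zero.
#'
#' @param rho cell-density array, cells/m^3.
#' @param C oxygen concentration array, mol/m^3.
#' @param dt time step, hours.
#' @param params a [kinetic_params()].
#' @param strut_mask optional logical array marking strut voxels.
#' @return updated density array.
#' @export
update_cells <- function(rho, C, dt, params, strut_mask = NULL) {
  if (dt <= 0)
    ps_stop("permstrut_domain_error", "dt must be positive")
  r_net <- params$r_g_max * C / (params$k + C) - params$k_d
  rho_new <- pmin(pmax(rho * 2^(r_net * dt), 0), params$rho_max)
  attributes(rho_new) <- attributes(rho)
  if (!is.null(strut_mask)) rho_new[strut_mask] <- 0
  rho_new
}

# Lateral index of the pore centre: the vertical culture line farthest from
# any strut within its own slab patterns.  This is the line along which the
# published depth profiles of comparable block-scaffold models are read
# (the best-supplied culture path for impermeable struts, the
# least-supplied one for permeable struts).
.pore_center <- function(lab) {
  d <- dim(lab)
  mind <- matrix(Inf, d[1L], d[2L])
  seen <- list()
  for (k in seq_len(d[3L])) {
    pat <- matrix(lab[, , k], d[1L], d[2L])
    key <- paste(which(pat == 1L), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    st <- which(pat == 1L, arr.ind = TRUE)
    if (nrow(st) == 0L) next
    for (j in seq_len(d[2L])) {
      dy2 <- (st[, 2L] - j)^2
      for (i in seq_len(d[1L])) {
        mind[i, j] <- min(mind[i, j], min((st[, 1L] - i)^2 + dy2))
      }
    }
  }
  as.integer(which(mind == max(mind), arr.ind = TRUE)[1L, ])
}

# lateral mirror symmetry about both period mid-planes?
.laterally_symmetric <- function(lab) {
  d <- dim(lab)
  d[1L] %% 2L == 0L && d[2L] %% 2L == 0L &&
    identical(lab, lab[d[1L]:1L, , , drop = FALSE]) &&
    identical(lab, lab[, d[2L]:1L, , drop = FALSE])
}

#' Coupled oxygen / cell-growth simulation of a scaffold
#'
#' Operator-split time stepping: at each growth step of `dt_growth` hours
#' the oxygen field is brought to quasi-steady state by [steady_oxygen()]
#' (oxygen equilibrates over seconds, roughly four orders of magnitude
#' faster than the division time, so the split is benign), then the density
#' advances one Monod step via [update_cells()].  Cells start uniformly at
#' `rho_0` on culture voxels; oxygen starts at `C_0` everywhere.
#'
#' Each checkpoint records laterally averaged depth profiles of density and
#' oxygen (culture voxels only), the top and bottom slab means, field bounds
#' and the per-day density-change rate used by the steady-state criterion
#' max |d rho| / rho_max < `eps_per_day`.  Because densities start at about
#' 0.1 percent of `rho_max`, the raw rate is below the criterion at seeding;
#' the run therefore stops at the first sub-threshold step *after* the rate
#' has exceeded the threshold (see [saturation_time()]).
#'
#' When both lateral period mid-planes are mirror planes of the strut
#' pattern (true for the centred lattice and staggered layouts), the solve
#' runs on one quarter of the lateral period by default; mirror symmetry
#' makes the laterally averaged results identical to the full period.
#'
#' @param spec a [scaffold_spec()] (or a prebuilt [build_scaffold()] grid).
#' @param params a [kinetic_params()].
#' @param dt_growth growth time step, hours.
#' @param t_end simulation horizon, hours.
#' @param stop_when_steady stop at the steady-state criterion; if `t_end`
#'   arrives first a `permstrut_not_steady` warning is raised and
#'   `converged` is `FALSE`.
#' @param eps_per_day steady-state criterion on max |d rho| / rho_max per
#'   day.
#' @param use_symmetry solve one quarter of the lateral period when the
#'   pattern allows it.
#' @param keep_fields also store the full density field at each checkpoint
#'   (memory-hungry; meant for small diagnostic runs).
#' @param oxygen_tol Picard tolerance passed to [steady_oxygen()].
#' @param max_wall_s wall-clock budget in seconds; when exceeded the run
#'   stops at the last completed step (with a `permstrut_wall_budget`
#'   warning) and is reported as not converged unless the steady criterion
#'   was already met.
#' @return object of class `sim_series`: checkpoint times (h); `nz` x K
#'   profile matrices `rho_profile` (lateral culture mean), `rho_profile_max`
#'   (per-slab culture maximum, tracking the deepest confluent point),
#'   `rho_profile_pore` and `c_profile_pore` (the pore-centre vertical line,
#'   the culture path farthest from any strut) and `c_profile`; `top_density`
#'   / `bottom_density` traces; `max_drho_per_day`; bound diagnostics; the
#'   final fields; convergence flag and `t_s` (NA when not converged).
#' @export
run_simulation <- function(spec, params = kinetic_params(),
                           dt_growth = 2, t_end = 1440,
                           stop_when_steady = TRUE, eps_per_day = 1e-3,
                           use_symmetry = TRUE, keep_fields = FALSE,
                           oxygen_tol = 1e-6, max_wall_s = Inf) {
  grid <- if (inherits(spec, "voxel_grid")) spec else build_scaffold(spec)
  lab <- grid$labels
  if (use_symmetry && .laterally_symmetric(lab)) {
    d <- dim(lab)
    grid <- structure(list(labels = lab[seq_len(d[1L] / 2L),
                                        seq_len(d[2L] / 2L), , drop = FALSE],
                           voxel_size = grid$voxel_size, spec = grid$spec),
                      class = "voxel_grid")
    lab <- grid$labels
  }
  d <- dim(lab)
  nz <- d[3L]
  culture <- lab == 0L
  cult_mat <- matrix(culture, nrow = d[1L] * d[2L], ncol = nz)
  n_cult <- pmax(colSums(cult_mat), 1L)
  profile_of <- function(field) {
    m <- matrix(field, nrow = d[1L] * d[2L], ncol = nz)
    colSums(m * cult_mat) / n_cult
  }
  # per-slab maximum over culture voxels (strut voxels carry 0 density, so
  # the plain column maximum is the culture maximum)
  profile_max_of <- function(field) {
    apply(matrix(field, nrow = d[1L] * d[2L], ncol = nz), 2L, max)
  }
  pore <- .pore_center(lab)

  rho <- array(0, dim = d)
  rho[culture] <- params$rho_0
  C <- array(params$c_0, dim = d)
  C_prev <- NULL  # previous quasi-steady field, for warm-start extrapolation

  n_steps <- if (t_end <= 0) 0L else ceiling(t_end / dt_growth)
  K <- n_steps + 1L
  times <- numeric(K)
  rho_profile <- matrix(NA_real_, nz, K)
  rho_profile_max <- matrix(NA_real_, nz, K)
  rho_profile_pore <- matrix(NA_real_, nz, K)
  c_profile <- matrix(NA_real_, nz, K)
  c_profile_pore <- matrix(NA_real_, nz, K)
  rate <- rep(NA_real_, K)
  cmin <- cmax <- rmin <- rmax <- numeric(K)
  fields <- if (keep_fields) vector("list", K) else NULL

  record <- function(k, t) {
    times[k] <<- t
    rho_profile[, k] <<- profile_of(rho)
    rho_profile_max[, k] <<- profile_max_of(rho)
    rho_profile_pore[, k] <<- rho[pore[1L], pore[2L], ]
    c_profile[, k] <<- profile_of(C)
    c_profile_pore[, k] <<- C[pore[1L], pore[2L], ]
    cmin[k] <<- min(C); cmax[k] <<- max(C)
    rmin[k] <<- min(rho); rmax[k] <<- max(rho)
    if (keep_fields) fields[[k]] <<- rho
  }
  record(1L, 0)

  seen_fast <- FALSE
  stopped <- FALSE
  k_last <- 1L
  wall_start <- proc.time()[3L]
  for (s in seq_len(n_steps)) {
    if (proc.time()[3L] - wall_start > max_wall_s) {
      ps_warn("permstrut_wall_budget",
              sprintf("wall-clock budget (%g s) exhausted at t = %g h",
                      max_wall_s, (s - 1L) * dt_growth))
      break
    }
    t_now <- s * dt_growth
    # linear extrapolation of the slowly drifting quasi-steady field makes
    # a better Picard starting point than the previous field itself
    guess <- if (is.null(C_prev)) C else {
      g <- pmin(pmax(2 * C - C_prev, 0), params$c_0)
      dim(g) <- d
      g
    }
    C_prev <- C
    C <- steady_oxygen(grid, rho, params, tol = oxygen_tol, c_init = guess)
    rho_new <- update_cells(rho, C, dt_growth, params, strut_mask = !culture)
    rate_now <- max(abs(rho_new - rho)) / params$rho_max / (dt_growth / 24)
    rho <- rho_new
    k_last <- s + 1L
    record(k_last, t_now)
    rate[k_last] <- rate_now
    if (rate_now >= eps_per_day) seen_fast <- TRUE
    if (stop_when_steady && seen_fast && rate_now < eps_per_day) {
      stopped <- TRUE
      break
    }
  }
  keep <- seq_len(k_last)
  sidx <- if (k_last >= 2L) .steady_index(rate[keep], eps_per_day)
          else NA_integer_
  converged <- !is.na(sidx)
  t_s <- if (converged) times[sidx] else NA_real_
  if (stop_when_steady && !stopped && !converged && n_steps > 0L)
    ps_warn("permstrut_not_steady",
            sprintf("steady-state criterion (%g/day) not met by t_end = %g h",
                    eps_per_day, t_end))
  structure(list(times = times[keep],
                 rho_profile = rho_profile[, keep, drop = FALSE],
                 rho_profile_max = rho_profile_max[, keep, drop = FALSE],
                 rho_profile_pore = rho_profile_pore[, keep, drop = FALSE],
                 c_profile = c_profile[, keep, drop = FALSE],
                 c_profile_pore = c_profile_pore[, keep, drop = FALSE],
                 pore_index = pore,
                 top_density = rho_profile[1L, keep],
                 bottom_density = rho_profile[nz, keep],
                 max_drho_per_day = rate[keep],
                 c_bounds = cbind(min = cmin[keep], max = cmax[keep]),
                 rho_bounds = cbind(min = rmin[keep], max = rmax[keep]),
                 final = list(C = C, rho = rho),
                 fields = if (keep_fields) fields[keep] else NULL,
                 grid = grid, params = params,
                 dt_growth = dt_growth, eps_per_day = eps_per_day,
                 converged = converged, t_s = t_s),
            class = "sim_series")
}

#' @export
print.sim_series <- function(x, ...) {
  K <- length(x$times)
  cat(sprintf("<sim_series> %d checkpoints over %.1f h (dt = %g h)\n",
              K, x$times[K], x$dt_growth))
  cat(sprintf("  converged: %s%s\n", x$converged,
              if (x$converged) sprintf(" (t_s = %.1f h = %.2f days)",
                                       x$t_s, x$t_s / 24) else ""))
  cat(sprintf("  top/bottom density at end: %.3g / %.3g cells/m^3\n",
              x$top_density[K], x$bottom_density[K]))
  invisible(x)
}

#' @export
plot.sim_series <- function(x, what = c("profile", "surfaces"), ...) {
  what <- match.arg(what)
  nz <- nrow(x$rho_profile)
  z <- (seq_len(nz) - 0.5) * x$grid$voxel_size
  if (what == "profile") {
    K <- length(x$times)
    sel <- unique(round(seq(1, K, length.out = 6)))
    matplot(z, x$rho_profile[, sel], type = "l", lty = 1,
            xlab = "depth (um)", ylab = "mean cell density (cells/m^3)", ...)
    legend("topright", legend = sprintf("%.0f h", x$times[sel]),
           col = seq_along(sel), lty = 1, cex = 0.7)
  } else {
    matplot(x$times, cbind(x$top_density, x$bottom_density), type = "l",
            lty = 1, xlab = "time (h)", ylab = "cell density (cells/m^3)",
            ...)
    legend("right", legend = c("top slab", "bottom slab"), col = 1:2,
           lty = 1, cex = 0.7)
  }
  invisible(x)
}
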