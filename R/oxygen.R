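## Heterogeneous oxygen transport with Michaelis-Menten consumption.

# voxel diffusivity field in m^2/s from labels
.voxel_diffusivity <- function(grid, params) {
  d <- ifelse(grid$labels == 1L, params$d_s, params$d_t)
  array(.cm2s_to_m2s(d), dim = dim(grid$labels))
}

#' Face-centred diffusivities of a labelled grid
#'
#' Each interior voxel face carries the harmonic mean of the two adjacent
#' voxel diffusivities (exact for piecewise-constant coefficients), so a
#' culture|strut face with an impermeable strut (`d_s = 0`) is a zero-flux
#' face.  Faces on the top (Dirichlet) boundary carry the adjacent voxel's
#' own diffusivity; all other boundary faces are zero-flux and reported as 0.
#'
#' @param grid a [build_scaffold()] result.
#' @param params a [kinetic_params()] object supplying `d_t` and `d_s`.
#' @return list of arrays `x`, `y`, `z` (interior faces along each axis,
#'   e.g. `x` has dim `c(nx - 1, ny, nz)`) and `top` (the `nx` x `ny` top
#'   faces), all in cm^2/s.
#' @export
face_diffusivity <- function(grid, params) {
  d <- ifelse(grid$labels == 1L, params$d_s, params$d_t)
  hm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  nd <- dim(d)
  list(x = hm(d[-nd[1L], , , drop = FALSE], d[-1L, , , drop = FALSE]),
       y = hm(d[, -nd[2L], , drop = FALSE], d[, -1L, , drop = FALSE]),
       z = hm(d[, , -nd[3L], drop = FALSE], d[, , -1L, drop = FALSE]),
       top = d[, , 1L])
}

#' Quasi-steady oxygen field under Michaelis-Menten consumption
#'
#' Solves div(D grad C) = rho V_max C / (K_m + C) over the voxel grid with
#' C = C_0 held on the top (media-exposed) face, zero flux at the bottom
#' wall and mirror-symmetric lateral faces.  The saturating sink is handled
#' by Picard iteration: the sink coefficient rho V_max / (K_m + C) is frozen
#' at the current iterate, the resulting linear 7-point system is solved by
#' preconditioned conjugate gradients, and the loop repeats until the
#' largest update is below `tol * C_0`.  A damping factor of 0.7 is applied
#' when the update stagnates.  The discrete operator is an M-matrix, so the
#' solution inherits the maximum principle: 0 <= C <= C_0.
#'
#' Strut voxels that are fully decoupled (impermeable strut material and no
#' sink) keep C = C_0, the trapped initial concentration of a sealed solid.
#'
#' @param grid a [build_scaffold()] result.
#' @param rho cell-density array (cells/m^3) over the grid; must be zero on
#'   strut voxels.
#' @param params a [kinetic_params()].
#' @param tol Picard convergence tolerance on max |dC| / C_0.
#' @param max_iter Picard iteration cap.
#' @param c_init optional warm-start field (defaults to uniform C_0).
#' @param linear_tol relative-residual tolerance of the inner linear solves.
#' @return oxygen concentration array (mol/m^3) with attributes
#'   `picard_iterations` and `picard_history`.
#' @export
steady_oxygen <- function(grid, rho, params, tol = 1e-6, max_iter = 100L,
                          c_init = NULL, linear_tol = 1e-9) {
  lab <- grid$labels
  if (!identical(dim(rho), dim(lab)))
    ps_stop("permstrut_domain_error", "rho shape must match the grid")
  if (any(rho < 0) || any(rho[lab == 1L] != 0))
    ps_stop("permstrut_domain_error",
            "rho must be non-negative and zero on strut voxels")
  dvox <- .voxel_diffusivity(grid, params)
  h <- .um_to_m(grid$voxel_size)
  n <- length(lab)
  C <- if (is.null(c_init)) array(params$c_0, dim = dim(lab)) else c_init
  zeros <- numeric(n)
  history <- numeric(0)
  prev_delta <- Inf
  dC_prev <- NULL
  for (it in seq_len(max_iter)) {
    a <- rho * params$v_max / (params$k_m + pmax(C, 0))
    sol <- .fv_solve_cpp(as.numeric(dvox), dim(lab), h, as.numeric(a),
                         zeros, params$c_0, as.numeric(C),
                         tol = linear_tol, maxit = 20000L)
    C_new <- array(sol$x, dim = dim(lab))
    dC <- C_new - C
    delta <- max(abs(dC)) / params$c_0
    history <- c(history, delta)
    if (delta < tol) {
      attr(C_new, "picard_iterations") <- it
      attr(C_new, "picard_history") <- history
      return(C_new)
    }
    if (it >= 2L && delta >= prev_delta) {
      # stagnation: damp the update
      C <- 0.7 * C_new + 0.3 * C
      dC_prev <- NULL
    } else if (!is.null(dC_prev)) {
      # the frozen-coefficient fixed point contracts linearly; accelerate
      # along the dominant error mode (Aitken), clamped to physical range
      r_est <- delta / prev_delta
      if (r_est > 0.05 && r_est < 0.95) {
        C <- pmin(pmax(C_new + dC * (r_est / (1 - r_est)), 0), params$c_0)
        dim(C) <- dim(C_new)
        dC_prev <- NULL
      } else {
        C <- C_new
        dC_prev <- dC
      }
    } else {
      C <- C_new
      dC_prev <- dC
    }
    prev_delta <- delta
  }
  ps_stop("permstrut_nonconvergence",
          sprintf("Picard iteration did not reach tol = %g in %d iterations",
                  tol, max_iter),
          residual_history = history)
}

#' Transient oxygen relaxation (implicit Euler)
#'
#' Backward-Euler integration of dC/dt = div(D grad C) - rho V_max C /
#' (K_m + C) at fixed cell density, with the sink coefficient evaluated at
#' the previous step.  Used as an independent cross-check: run to
#' equilibrium it must agree with [steady_oxygen()], which justifies the
#' quasi-steady coupling of the growth loop (oxygen equilibrates in seconds,
#' cells divide over tens of hours).
#'
#' @inheritParams steady_oxygen
#' @param dt_s time step, seconds.
#' @param t_end_s total integration time, seconds.
#' @return oxygen concentration array (mol/m^3).
#' @export
transient_oxygen <- function(grid, rho, params, dt_s, t_end_s,
                             c_init = NULL, linear_tol = 1e-9) {
  lab <- grid$labels
  dvox <- .voxel_diffusivity(grid, params)
  h <- .um_to_m(grid$voxel_size)
  C <- if (is.null(c_init)) array(params$c_0, dim = dim(lab)) else c_init
  n_steps <- ceiling(t_end_s / dt_s)
  inv_dt <- 1 / dt_s
  for (s in seq_len(n_steps)) {
    a <- rho * params$v_max / (params$k_m + pmax(C, 0))
    sol <- .fv_solve_cpp(as.numeric(dvox), dim(lab), h,
                         as.numeric(a) + inv_dt, as.numeric(C) * inv_dt,
                         params$c_0, as.numeric(C),
                         tol = linear_tol, maxit = 20000L)
    C <- array(sol$x, dim = dim(lab))
  }
  C
}
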