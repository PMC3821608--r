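#' Construct a normalized FRAP recovery curve
#'
#' A recovery curve holds the fractional fluorescence f(t) of a bleached spot
#' together with the bleach-spot radius `omega` that the half-time relation
#' needs.  Fractional fluorescence follows the full-recovery convention
#' f(t) = (F(t) - F0) / (Fpre - F0), so f starts near 0 at the end of the
#' bleach and approaches 1 (mobile fraction assumed 1).
#'
#' @param times numeric vector of sample times in seconds, strictly
#'   increasing, first sample at (or just after) the end of the bleach.
#' @param f numeric vector of fractional fluorescence, same length as
#'   `times`.
#' @param omega bleach-spot radius in micrometers.
#' @param meta free-form provenance list (sample id, reference intensities
#'   used during normalization, ...).
#' @return an object of class `recovery_curve`.
#' @seealso [normalize_recovery()], [estimate_half_time()], [frap_analyze()]
#' @export
recovery_curve <- function(times, f, omega, meta = list()) {
  times <- as.numeric(times)
  f <- as.numeric(f)
  if (length(times) != length(f) || length(f) < 3L)
    ps_stop("permstrut_malformed_input",
            "need matching times/f vectors with at least 3 samples")
  if (any(!is.finite(times)) || any(!is.finite(f)))
    ps_stop("permstrut_malformed_input", "non-finite values in trace")
  if (any(diff(times) <= 0))
    ps_stop("permstrut_malformed_input", "times must be strictly increasing")
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0)
    ps_stop("permstrut_domain_error", "omega must be a single positive radius")
  if (any(f < -0.1) || any(f > 1.2))
    ps_stop("permstrut_malformed_input",
            "fractional fluorescence outside [-0.1, 1.2]; check normalization")
  if (abs(f[1L]) > 0.05)
    ps_warn("permstrut_suspect_normalization",
            sprintf(paste0("first sample f = %.3f is far from 0; the bleach ",
                           "end or the normalization references may be off"),
                    f[1L]))
  structure(list(times = times, f = f, omega = omega, meta = meta),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve> %d samples, t in [%.3g, %.3g] s, omega = %g um\n",
              length(x$times), x$times[1L], x$times[length(x$times)], x$omega))
  cat(sprintf("  f range [%.3f, %.3f]\n", min(x$f), max(x$f)))
  invisible(x)
}

#' @export
plot.recovery_curve <- function(x, ..., xlab = "time (s)",
                                ylab = "fractional fluorescence") {
  plot(x$times, x$f, xlab = xlab, ylab = ylab, type = "p", pch = 16,
       cex = 0.6, ...)
  abline(h = c(0, 0.5, 1), lty = 3, col = "grey60")
  invisible(x)
}

#' Normalize a raw intensity trace to fractional fluorescence
#'
#' Applies f(t) = (F(t) - F0) / (Fpre - F0), where `Fpre` is the mean
#' pre-bleach intensity and `F0` the first post-bleach intensity, and shifts
#' times so the end of the bleach is t = 0.  The output is invariant to any
#' positive rescaling of the raw intensities (detector gain drops out).
#'
#' @param trace data.frame with columns `time_s` and `intensity` (raw
#'   post-bleach samples).
#' @param f_pre mean pre-bleach intensity; must exceed `f0`.
#' @param f0 first post-bleach intensity; defaults to the trace's first
#'   intensity sample.
#' @param omega bleach-spot radius in micrometers.
#' @param meta provenance list; the references used are recorded in it.
#' @return a [recovery_curve()].
#' @export
normalize_recovery <- function(trace, f_pre, f0 = trace$intensity[1L],
                               omega, meta = list()) {
  if (is.null(trace$time_s) || is.null(trace$intensity) ||
      nrow(trace) == 0L)
    ps_stop("permstrut_malformed_input",
            "trace needs non-empty columns time_s and intensity")
  if (any(diff(trace$time_s) <= 0))
    ps_stop("permstrut_malformed_input", "times must be strictly increasing")
  if (!(f_pre > f0) || f0 < 0)
    ps_stop("permstrut_invalid_bleach",
            sprintf("need f_pre > f0 >= 0 (got f_pre = %g, f0 = %g)",
                    f_pre, f0))
  f <- (trace$intensity - f0) / (f_pre - f0)
  meta$f_pre <- f_pre
  meta$f0 <- f0
  recovery_curve(trace$time_s - trace$time_s[1L], f, omega, meta)
}

#' Average replicate recovery curves on a common time grid
#'
#' Replicate spots are typically acquired at slightly different frame times;
#' curves are linearly interpolated onto a shared grid spanning the common
#' time range and averaged pointwise, with the per-point standard deviation
#' reported alongside.
#'
#' @param curves list of [recovery_curve()] objects with equal `omega`.
#' @param n_grid number of points in the common grid (default: the median
#'   replicate length).
#' @return list with elements `curve` (the mean [recovery_curve()]) and `sd`
#'   (pointwise standard deviation across replicates).
#' @export
average_recovery_curves <- function(curves, n_grid = NULL) {
  if (length(curves) < 2L)
    ps_stop("permstrut_malformed_input", "need at least two curves to average")
  omegas <- vapply(curves, function(cv) cv$omega, numeric(1))
  if (diff(range(omegas)) > 1e-8 * mean(omegas))
    ps_stop("permstrut_malformed_input",
            "curves have differing bleach-spot radii")
  t_lo <- max(vapply(curves, function(cv) min(cv$times), numeric(1)))
  t_hi <- min(vapply(curves, function(cv) max(cv$times), numeric(1)))
  if (t_hi <= t_lo)
    ps_stop("permstrut_malformed_input", "curves share no common time range")
  if (is.null(n_grid))
    n_grid <- as.integer(median(vapply(curves, function(cv)
      length(cv$times), numeric(1))))
  grid <- seq(t_lo, t_hi, length.out = max(3L, n_grid))
  fs <- vapply(curves, function(cv)
    approx(cv$times, cv$f, xout = grid)$y, numeric(length(grid)))
  m <- rowMeans(fs)
  s <- apply(fs, 1L, sd)
  list(curve = recovery_curve(grid, m, omegas[1L],
                              meta = list(n_replicates = length(curves))),
       sd = s)
}

#' Read or write a FRAP trace CSV
#'
#' The CSV carries either raw intensities (columns `time_s,intensity`,
#' normalized on read when `f_pre` is supplied) or an already normalized
#' trace (columns `time_s,f`).  A header row is required.
#'
#' @param path file path.
#' @param omega bleach-spot radius in micrometers.
#' @param f_pre,f0 normalization references for raw traces; ignored when the
#'   file already holds fractional fluorescence.
#' @return a [recovery_curve()].
#' @export
read_recovery_csv <- function(path, omega, f_pre = NULL, f0 = NULL) {
  d <- read.csv(path)
  if (!is.null(d$f))
    return(recovery_curve(d$time_s - d$time_s[1L], d$f, omega,
                          meta = list(source = path)))
  if (is.null(d$time_s) || is.null(d$intensity))
    ps_stop("permstrut_malformed_input",
            "CSV must have columns time_s,intensity or time_s,f")
  if (is.null(f_pre))
    ps_stop("permstrut_malformed_input",
            "raw intensity trace needs f_pre for normalization")
  if (is.null(f0)) f0 <- d$intensity[1L]
  normalize_recovery(d, f_pre = f_pre, f0 = f0, omega = omega,
                     meta = list(source = path))
}

#' @rdname read_recovery_csv
#' @param curve a [recovery_curve()] to write (normalized form).
#' @export
write_recovery_csv <- function(curve, path) {
  write.csv(data.frame(time_s = curve$times, f = curve$f), path,
            row.names = FALSE)
  invisible(path)
}

#' Mean intensity of a circular ROI through a TIFF time stack
#'
#' Convenience reader for image time series: extracts the mean intensity
#' inside a circular region per frame, yielding the raw trace that
#' [normalize_recovery()] consumes.  Frame times are `(0:(n-1)) * frame_dt`.
#'
#' @param path multi-frame TIFF file.
#' @param center_px ROI centre, length-2 (x, y) in pixels (1-based).
#' @param radius_px ROI radius in pixels.
#' @param um_per_px physical pixel pitch; the implied ROI radius in
#'   micrometers is recorded as `omega` metadata.
#' @param frame_dt frame interval in seconds.
#' @return data.frame with columns `time_s`, `intensity`, plus attribute
#'   `omega_um`.
#' @export
read_frap_stack <- function(path, center_px, radius_px, um_per_px,
                            frame_dt) {
  if (!requireNamespace("tiff", quietly = TRUE))
    ps_stop("permstrut_missing_dependency",
            "the 'tiff' package is required to read image stacks")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  nr <- nrow(frames[[1L]]); nc <- ncol(frames[[1L]])
  # matrix row = y, col = x
  mask <- outer(seq_len(nr) - center_px[2L], seq_len(nc) - center_px[1L],
                function(dy, dx) dx * dx + dy * dy) <= radius_px^2
  if (!any(mask))
    ps_stop("permstrut_domain_error", "ROI contains no pixels")
  mean_roi <- vapply(frames, function(fr) mean(fr[mask]), numeric(1))
  out <- data.frame(time_s = (seq_along(frames) - 1L) * frame_dt,
                    intensity = mean_roi)
  attr(out, "omega_um") <- radius_px * um_per_px
  out
}
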