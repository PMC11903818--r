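#' Construct a wavenumber axis
#'
#' Builds the inclusive, strictly descending spectral grid of a QCL-IR
#' measurement. The instrument emulated here scans from 1800 to 948 cm^-1 at a
#' 2 cm^-1 resolution, which yields 427 samples; other grids (e.g. compressed
#' band sets for small test scenes) are allowed as long as the range is an
#' integer multiple of the step.
#'
#' @param start First (largest) wavenumber in cm^-1.
#' @param stop Last (smallest) wavenumber in cm^-1. Must satisfy
#'   `start >= stop`.
#' @param step Grid spacing in cm^-1, positive. `(start - stop)` must be an
#'   integer multiple of `step` (to within floating-point tolerance), otherwise
#'   the grid does not close on `stop` and the configuration is rejected.
#' @return An object of class `wavenumber_axis`: a list with `start`, `stop`,
#'   `step`, `values` (descending numeric vector) and `count`.
#' @examples
#' ax <- make_wavenumber_axis(1800, 948, 2)
#' ax$count # 427
#' @export
make_wavenumber_axis <- function(start, stop, step) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
            length(start) == 1L, length(stop) == 1L, length(step) == 1L)
  if (step <= 0) stop("`step` must be > 0")
  if (start < stop) stop("`start` must be >= `stop` (descending grid)")
  n_steps <- (start - stop) / step
  if (abs(n_steps - round(n_steps)) > 1e-6) {
    stop(sprintf("range %g..%g cm^-1 is not divisible by step %g cm^-1",
                 start, stop, step))
  }
  n <- as.integer(round(n_steps)) + 1L
  values <- start - step * (seq_len(n) - 1)
  structure(
    list(start = start, stop = stop, step = step,
         values = values, count = n),
    class = "wavenumber_axis"
  )
}

#' @export
print.wavenumber_axis <- function(x, ...) {
  cat(sprintf("<wavenumber_axis> %g -> %g cm^-1, step %g (%d samples)\n",
              x$start, x$stop, x$step, x$count))
  invisible(x)
}

#' @export
length.wavenumber_axis <- function(x) x$count
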