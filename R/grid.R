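#' Regular wavelength grids
#'
#' NIR instruments of the class targeted here emit spectra on a dense,
#' equally spaced wavelength grid.  A `wavelength_grid` records the start
#' wavelength, the spacing, and the number of points; the implied
#' wavelengths are `start_nm + i * step_nm` for `i = 0 ... n_points - 1`.
#'
#' The grid follows a half-open convention `[start_nm, end_nm)`: the end
#' wavelength itself is not a grid point.  This is the only convention
#' under which the canonical acquisition range 900-2500 nm at 3.125 nm
#' spacing yields exactly 512 points.
#'
#' @param start_nm first wavelength (nm).
#' @param end_nm exclusive upper bound of the range (nm).
#' @param step_nm spacing between consecutive points (nm), > 0.
#' @return An object of class `wavelength_grid` with fields `start_nm`,
#'   `step_nm`, `n_points`.
#' @examples
#' g <- make_grid(900, 2500, 3.125)
#' g$n_points            # 512
#' head(wavelengths(g))
#' @seealso [wavelengths()], [default_grid()]
#' @export
make_grid <- function(start_nm, end_nm, step_nm) {
  check(is.numeric(start_nm) && is.numeric(end_nm) && is.numeric(step_nm),
        "grid parameters must be numeric")
  check(end_nm > start_nm, "end_nm (%g) must exceed start_nm (%g)", end_nm, start_nm)
  check(step_nm > 0, "step_nm must be positive, got %g", step_nm)
  ratio <- (end_nm - start_nm) / step_nm
  n <- round(ratio)
  rem <- abs(ratio - n)
  check(rem < 1e-9,
        "grid range (%g to %g) is not divisible by step %g (remainder %g steps)",
        start_nm, end_nm, step_nm, rem)
  check(n >= 2, "grid must have at least 2 points, got %d", n)
  structure(list(start_nm = start_nm, step_nm = step_nm, n_points = as.integer(n)),
            class = "wavelength_grid")
}

#' @param grid a `wavelength_grid`.
#' @return `wavelengths()` returns the numeric vector of implied wavelengths.
#' @rdname make_grid
#' @export
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  grid$start_nm + (seq_len(grid$n_points) - 1) * grid$step_nm
}

#' @return `default_grid()` returns the 512-point, 900-2500 nm, 3.125 nm
#'   acquisition grid used throughout the package defaults.
#' @rdname make_grid
#' @export
default_grid <- function() make_grid(900, 2500, 3.125)

# Recover a wavelength_grid from a vector of wavelengths, validating equal
# spacing.  `where` labels error messages (e.g. a file name).
grid_from_wavelengths <- function(wl, where = "wavelength vector", tol = 1e-6) {
  check(length(wl) >= 2, "%s: need at least 2 wavelengths", where)
  d <- diff(wl)
  check(all(d > 0), "%s: wavelengths are not strictly increasing", where)
  step <- d[1]
  bad <- which(abs(d - step) > tol * max(1, step))
  if (length(bad)) {
    stop(sprintf("%s: unequal spacing at column %d (gap %g, expected %g)",
                 where, bad[1] + 1, d[bad[1]], step), call. = FALSE)
  }
  make_grid(wl[1], wl[length(wl)] + step, step)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm, %d points\n",
              x$start_nm, x$start_nm + x$n_points * x$step_nm,
              x$step_nm, x$n_points))
  invisible(x)
}

#' @export
format.wavelength_grid <- function(x, ...) {
  sprintf("%g:%g:%g", x$start_nm, x$start_nm + x$n_points * x$step_nm, x$step_nm)
}
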