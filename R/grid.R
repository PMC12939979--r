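#' Construct a uniform wavelength grid
#'
#' A wavelength grid is the axis every spectrum in a dataset is sampled on:
#' an inclusive, uniformly spaced sequence of nanometre positions. The
#' default acquisition geometry used throughout the package is 400--1800 nm
#' at 4 nm resolution, i.e. 351 variables.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must exceed `start_nm`.
#' @param step_nm Spacing (nm); `(stop_nm - start_nm)` must be divisible by it.
#'
#' @return An object of class `wavelength_grid`: a list with elements
#'   `start_nm`, `stop_nm`, `step_nm` and `values` (the full nm vector).
#' @examples
#' g <- make_grid(400, 1800, 4)
#' length(g$values)  # 351
#' @export
make_grid <- function(start_nm, stop_nm, step_nm) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (step_nm <= 0) stop("step_nm must be positive")
  if (stop_nm <= start_nm) stop("stop_nm must exceed start_nm")
  span <- stop_nm - start_nm
  rem <- span %% step_nm
  if (abs(rem) > 1e-9 && abs(rem - step_nm) > 1e-9) {
    stop(sprintf(
      "grid span %g nm is not divisible by step %g nm (remainder %g)",
      span, step_nm, rem
    ))
  }
  values <- seq(start_nm, stop_nm, by = step_nm)
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         values = values),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm, %d points\n",
              x$start_nm, x$stop_nm, x$step_nm, length(x$values)))
  invisible(x)
}

#' @export
length.wavelength_grid <- function(x) length(x$values)

# Infer a wavelength_grid from a numeric header; errors on non-uniform spacing.
grid_from_values <- function(values) {
  if (any(is.na(values))) stop("non-numeric wavelength in header")
  if (length(values) < 2) stop("grid needs at least two wavelengths")
  d <- diff(values)
  if (any(d <= 0)) stop("wavelengths must be strictly increasing")
  if (max(d) - min(d) > 1e-6) {
    stop(sprintf("non-uniform spacing in wavelength header (steps %g to %g nm)",
                 min(d), max(d)))
  }
  make_grid(values[1], values[length(values)], d[1])
}
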