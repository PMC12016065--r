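#' Age x DNAm evaluation grid
#'
#' Defines the rectangular grid on which per-CpG density kernels are
#' evaluated. The default is the standard clock grid: 101 points per axis,
#' ages 0--100 years on the x-axis and 0--100% DNAm on the y-axis, i.e. a
#' step of exactly 1 on each axis.
#'
#' @param age_min,age_max Age axis limits in years.
#' @param dnam_min,dnam_max DNAm axis limits in percent.
#' @param n_points Number of grid points per axis.
#' @return An object of class `"grid_spec"`.
#' @examples
#' g <- grid_spec()
#' head(grid_ages(g))
#' @export
grid_spec <- function(age_min = 0, age_max = 100, n_points = 101,
                      dnam_min = 0, dnam_max = 100) {
  stopifnot(is.numeric(age_min), is.numeric(age_max), age_max > age_min,
            is.numeric(dnam_min), is.numeric(dnam_max), dnam_max > dnam_min,
            n_points >= 2)
  structure(list(age_min = as.numeric(age_min), age_max = as.numeric(age_max),
                 dnam_min = as.numeric(dnam_min),
                 dnam_max = as.numeric(dnam_max),
                 n_points = as.integer(n_points)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
grid_ages <- function(grid) {
  seq(grid$age_min, grid$age_max, length.out = grid$n_points)
}

#' @rdname grid_spec
#' @export
grid_dnam <- function(grid) {
  seq(grid$dnam_min, grid$dnam_max, length.out = grid$n_points)
}

# step sizes implied by the grid
grid_age_step <- function(grid) (grid$age_max - grid$age_min) / (grid$n_points - 1)
grid_dnam_step <- function(grid) (grid$dnam_max - grid$dnam_min) / (grid$n_points - 1)

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid: %d x %d points, age [%g, %g] years, DNAm [%g, %g]%%\n",
              x$n_points, x$n_points, x$age_min, x$age_max,
              x$dnam_min, x$dnam_max))
  invisible(x)
}
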