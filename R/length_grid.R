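#' Build the shared length-class grid
#'
#' All species share one discretisation of body length into `n_l` half-open
#' classes `[lower, upper)`. By default the classes partition `(0, max_Linf]`
#' into equal widths; explicit class boundaries may be supplied instead.
#'
#' @param n_l Number of length classes (default 32). Ignored when `bounds`
#'   is supplied.
#' @param max_Linf Largest asymptotic length in the community (cm); the grid
#'   spans `[0, max_Linf]`.
#' @param bounds Optional numeric vector of explicit class boundaries
#'   (length `n_l + 1`), strictly increasing.
#' @return An object of class `length_grid`: a list with `n_l`,
#'   `lower_bounds`, `upper_bounds` and `midpoints` (all in cm).
#' @examples
#' g <- build_length_grid(n_l = 32, max_Linf = 160)
#' g$midpoints[1:4]
#' @export
build_length_grid <- function(n_l = 32L, max_Linf = NULL, bounds = NULL) {
  if (is.null(bounds)) {
    if (is.null(max_Linf) || !is.finite(max_Linf) || max_Linf <= 0) {
      stop("`max_Linf` must be a positive number when `bounds` is not given")
    }
    n_l <- as.integer(n_l)
    if (is.na(n_l) || n_l < 2L) stop("`n_l` must be an integer >= 2")
    bounds <- seq(0, max_Linf, length.out = n_l + 1L)
  } else {
    bounds <- as.numeric(bounds)
    if (length(bounds) < 3L) stop("`bounds` must define at least 2 classes")
    if (any(!is.finite(bounds))) stop("`bounds` must be finite")
    if (any(diff(bounds) <= 0)) {
      stop("`bounds` must be strictly increasing (degenerate or reversed class)")
    }
    n_l <- length(bounds) - 1L
  }
  grid <- list(
    n_l = n_l,
    lower_bounds = bounds[-(n_l + 1L)],
    upper_bounds = bounds[-1L],
    midpoints = (bounds[-(n_l + 1L)] + bounds[-1L]) / 2
  )
  class(grid) <- "length_grid"
  grid
}

#' @export
print.length_grid <- function(x, ...) {
  cat("Length grid:", x$n_l, "classes on [",
      format(x$lower_bounds[1]), ",", format(x$upper_bounds[x$n_l]), ") cm\n")
  invisible(x)
}

#' Class weights for one species
#'
#' Weight at the class midpoint under the allometric length-weight relation
#' `w = W_a * L^W_b` (grams, with L in cm).
#'
#' @param grid A `length_grid`.
#' @param W_a,W_b Length-weight coefficients.
#' @return Numeric vector of length `grid$n_l`.
#' @keywords internal
class_weights <- function(grid, W_a, W_b) {
  W_a * grid$midpoints^W_b
}
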