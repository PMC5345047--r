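#' @keywords internal
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Run code with a local, restored RNG state
#'
#' All generators route their randomness through this helper so that a given
#' seed yields bit-identical output and the caller's RNG stream is untouched.
#'
#' @keywords internal
#' @noRd
local_seed <- function(seed, expr) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  withr::with_seed(as.integer(seed), expr)
}

#' Test which points fall inside a polygon
#'
#' @param points two-column matrix of (row, col) pixel coordinates.
#' @param polygon two-column matrix of (row, col) vertices.
#' @return logical vector.
#' @keywords internal
#' @noRd
points_in_polygon <- function(points, polygon) {
  points <- matrix(as.numeric(points), ncol = 2)
  polygon <- matrix(as.numeric(polygon), ncol = 2)
  mgcv::in.out(polygon, points)
}

#' Shoelace area of a polygon (in squared input units)
#' @keywords internal
#' @noRd
polygon_area <- function(polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}
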