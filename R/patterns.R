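#' Rectangular observation window
#'
#' Defines the rectangular region (in metres) inside which a mapped census
#' lives. All point patterns, toroidal shifts and edge corrections refer to
#' this window.
#'
#' @param x_min,x_max,y_min,y_max Window bounds in metres; `x_max > x_min`
#'   and `y_max > y_min`.
#' @return An object of class `pp_window` with fields `x_min`, `x_max`,
#'   `y_min`, `y_max`.
#' @examples
#' w <- pp_window(0, 1000, 0, 500)
#' window_area(w) # 50 ha
#' @export
pp_window <- function(x_min, x_max, y_min, y_max) {
  stopifnot(is.numeric(x_min), is.numeric(x_max),
            is.numeric(y_min), is.numeric(y_max))
  if (!(x_max > x_min && y_max > y_min)) {
    stop("invalid window: need x_max > x_min and y_max > y_min")
  }
  structure(list(x_min = as.numeric(x_min), x_max = as.numeric(x_max),
                 y_min = as.numeric(y_min), y_max = as.numeric(y_max)),
            class = "pp_window")
}

#' @rdname pp_window
#' @param window A `pp_window`.
#' @export
window_area <- function(window) {
  (window$x_max - window$x_min) * (window$y_max - window$y_min)
}

window_sides <- function(window) {
  c(width = window$x_max - window$x_min,
    height = window$y_max - window$y_min)
}

#' @export
print.pp_window <- function(x, ...) {
  cat(sprintf("window [%g, %g] x [%g, %g] m (area %g m^2)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, window_area(x)))
  invisible(x)
}

#' Planar point pattern
#'
#' Stores the stem locations of one species inside a rectangular window.
#' Coordinates are continuous metres; bounds are closed, so points on the
#' window edge are valid.
#'
#' @param x,y Numeric coordinate vectors of equal length.
#' @param window A [pp_window()].
#' @return An object of class `pp_pattern` with fields `x`, `y`, `window`.
#' @examples
#' p <- pp_pattern(c(1, 2), c(3, 4), pp_window(0, 10, 0, 10))
#' n_points(p)
#' @export
pp_pattern <- function(x, y, window) {
  stopifnot(inherits(window, "pp_window"), length(x) == length(y))
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) && (any(x < window$x_min) || any(x > window$x_max) ||
                    any(y < window$y_min) || any(y > window$y_max))) {
    stop("points outside the observation window")
  }
  structure(list(x = x, y = y, window = window), class = "pp_pattern")
}

#' @rdname pp_pattern
#' @param pattern A `pp_pattern`.
#' @export
n_points <- function(pattern) length(pattern$x)

#' @rdname pp_pattern
#' @export
intensity_of <- function(pattern) n_points(pattern) / window_area(pattern$window)

#' @export
print.pp_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points, ", n_points(x)))
  print(x$window)
  invisible(x)
}

#' Toroidal shift of a point pattern
#'
#' Translates every point by `(dx, dy)` with wraparound on the rectangular
#' window, i.e. treating the window as a torus. The window and the point
#' count are unchanged, and all within-pattern toroidal distances are
#' preserved (the shift is a torus isometry). Shifting one species while
#' holding the other fixed is the null model for interspecific independence:
#' it breaks any cross-species dependence while retaining each species'
#' internal spatial structure.
#'
#' @param pattern A [pp_pattern()].
#' @param dx,dy Real offsets in metres (any sign; they wrap).
#' @return The shifted `pp_pattern`.
#' @examples
#' w <- pp_window(0, 1000, 0, 500)
#' toroidal_shift(pp_pattern(999, 499, w), 5, 5) # point moves to (4, 4)
#' @export
toroidal_shift <- function(pattern, dx, dy) {
  stopifnot(inherits(pattern, "pp_pattern"))
  w <- pattern$window
  sides <- window_sides(w)
  x <- (pattern$x - w$x_min + dx) %% sides[["width"]] + w$x_min
  y <- (pattern$y - w$y_min + dy) %% sides[["height"]] + w$y_min
  pp_pattern(x, y, w)
}

#' Pairwise toroidal distances within a pattern
#'
#' Distances between all unordered point pairs measured on the torus induced
#' by the window (shortest wrapped separation in each axis). Invariant under
#' [toroidal_shift()].
#'
#' @param pattern A [pp_pattern()].
#' @return Numeric vector of length `n(n-1)/2`.
#' @export
toroidal_pairdist <- function(pattern) {
  stopifnot(inherits(pattern, "pp_pattern"))
  n <- n_points(pattern)
  if (n < 2) return(numeric(0))
  sides <- window_sides(pattern$window)
  dx <- abs(outer(pattern$x, pattern$x, "-"))
  dx <- pmin(dx, sides[["width"]] - dx)
  dy <- abs(outer(pattern$y, pattern$y, "-"))
  dy <- pmin(dy, sides[["height"]] - dy)
  d <- sqrt(dx^2 + dy^2)
  d[lower.tri(d)]
}
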