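`%||%` <- function(a, b) if (is.null(a)) b else a

#' Test points against a closed polygon
#'
#' Even-odd (ray crossing) point-in-polygon test, vectorised over query
#' points. Points exactly on an edge may fall on either side; the pixel
#' geometry used in this package never depends on edge pixels.
#'
#' @param px,py numeric vectors of query coordinates.
#' @param poly data frame with columns `x`, `y` giving the polygon vertices
#'   (closing edge implied).
#' @return logical vector, `TRUE` for points inside the polygon.
#' @export
point_in_polygon <- function(px, py, poly) {
  stopifnot(is.data.frame(poly), all(c("x", "y") %in% names(poly)))
  x <- poly$x
  y <- poly$y
  n <- length(x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    dy <- y[j] - y[i]
    if (dy != 0) {
      crosses <- ((y[i] > py) != (y[j] > py)) &
        (px < (x[j] - x[i]) * (py - y[i]) / dy + x[i])
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

#' Regular polygon approximating a circle
#'
#' @param cx,cy centre coordinates.
#' @param r radius.
#' @param n number of vertices.
#' @return data frame with columns `x`, `y`.
#' @export
circle_polygon <- function(cx, cy, r, n = 72L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
}

# centroid of polygon vertices (sufficient for the near-regular contours used here)
polygon_centroid <- function(poly) c(mean(poly$x), mean(poly$y))

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper) {
    stop(sprintf("`%s` = %g is outside the allowed range", name, x),
         call. = FALSE)
  }
  invisible(x)
}
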