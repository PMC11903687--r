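#' Rectangular region of interest
#'
#' Axis-aligned rectangle in nm used as the analysis field for images,
#' tessellations and random controls.  The origin convention is top-left at
#' `(xmin, ymin)`; pixel centres of derived images lie at
#' `xmin + (j - 0.5) * pixel_size`.
#'
#' @param width,height extent in nm (must be positive).
#' @param xmin,ymin coordinates of the origin corner in nm.
#' @return An object of class `"roi"`: a list with `xmin`, `xmax`, `ymin`,
#'   `ymax`.
#' @examples
#' r <- roi(2000, 2000)
#' roi_area(r)
#' @export
roi <- function(width, height, xmin = 0, ymin = 0) {
  stopifnot(is.numeric(width), is.numeric(height), length(width) == 1L,
            length(height) == 1L)
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop("ROI width and height must be positive and finite")
  structure(list(xmin = xmin, xmax = xmin + width,
                 ymin = ymin, ymax = ymin + height),
            class = "roi")
}

#' @rdname roi
#' @param x an `roi` object.
#' @export
roi_area <- function(x) {
  stopifnot(inherits(x, "roi"))
  (x$xmax - x$xmin) * (x$ymax - x$ymin)
}

#' @rdname roi
#' @export
roi_center <- function(x) {
  stopifnot(inherits(x, "roi"))
  c(x = (x$xmin + x$xmax) / 2, y = (x$ymin + x$ymax) / 2)
}

as_roi <- function(x) {
  if (inherits(x, "roi")) return(x)
  if (is.numeric(x) && length(x) == 4L)  # c(xmin, xmax, ymin, ymax)
    return(structure(list(xmin = x[1], xmax = x[2], ymin = x[3], ymax = x[4]),
                     class = "roi"))
  stop("cannot interpret `roi`: supply roi() or c(xmin, xmax, ymin, ymax)")
}

in_roi <- function(x, y, r) {
  x >= r$xmin & x <= r$xmax & y >= r$ymin & y <= r$ymax
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> x: [%g, %g] nm, y: [%g, %g] nm (area %g um^2)\n",
              x$xmin, x$xmax, x$ymin, x$ymax, roi_area(x) / 1e6))
  invisible(x)
}

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  Generators take one explicit seed per
# call and must not leak state into (or depend on) the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# scalar checks -------------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("`%s` must be supplied", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name))
  if (x < lower || x > upper)
    stop(sprintf("`%s` must be in [%g, %g], got %g", name, lower, upper, x))
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x))
    stop(sprintf("`%s` must be an integer, got %g", name, x))
  invisible(as.integer(x))
}
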