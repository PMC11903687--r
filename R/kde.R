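#' KDE reconstruction parameters
#'
#' Parameters of the kernel-density PALM reconstruction.  Each localization
#' contributes an isotropic Gaussian kernel centred on its coordinates with
#' SD equal to `A` times its uncertainty; the image is the average of the
#' kernels, optionally mixed with a constant-statistics background term.
#'
#' @param A unitless proportionality coefficient between kernel SD and
#'   localization uncertainty (instrument calibration; default 6).
#' @param pixel_size reconstruction pixel size in nm (default 10).
#' @param alpha mixture weight of the localization term in `[0, 1]`; with
#'   `alpha = 1` (default) no background term is added.
#' @param bg_mu,bg_sigma mean and SD of the i.i.d. per-pixel Gaussian
#'   background used when `alpha < 1`.
#' @param u_min,u_max admissible localization uncertainty bounds in nm;
#'   spots outside the bounds are treated as noise and discarded.  Defaults
#'   (2, 60) bracket the ~20 nm precision of the emulated acquisitions.
#' @param kernel_truncation kernel support radius in multiples of the kernel
#'   SD (default 4; the discarded mass is < 3.4e-4).
#' @return A list of class `"kde_params"`.
#' @export
kde_params <- function(A = 6, pixel_size = 10, alpha = 1,
                       bg_mu = 0, bg_sigma = 0,
                       u_min = 2, u_max = 60, kernel_truncation = 4) {
  check_number(A, "A", lower = 1e-12)
  check_number(pixel_size, "pixel_size", lower = 1e-12)
  check_number(alpha, "alpha", lower = 0, upper = 1)
  check_number(bg_mu, "bg_mu")
  check_number(bg_sigma, "bg_sigma", lower = 0)
  check_number(u_min, "u_min", lower = 0)
  check_number(u_max, "u_max")
  if (u_min >= u_max) stop("`u_min` must be smaller than `u_max`")
  check_number(kernel_truncation, "kernel_truncation", lower = 0.5)
  structure(list(A = A, pixel_size = pixel_size, alpha = alpha,
                 bg_mu = bg_mu, bg_sigma = bg_sigma, u_min = u_min,
                 u_max = u_max, kernel_truncation = kernel_truncation),
            class = "kde_params")
}

#' Rolling-window schedule for PALM movies
#'
#' Windows are `[s*t + 1, s*t + W]` for `t = 0, 1, 2, ...` while they fit in
#' the acquisition.  With `include_partial = TRUE` one final window truncated
#' at `n_frames` is appended when frames remain past the last full window and
#' its end frame is not already covered.  The default acquisition of 5008
#' frames with `W = 1002`, `s = 6` gives 668 full windows plus one truncated
#' window, i.e. 669 reconstructions; with `include_partial = FALSE` only the
#' 668 full windows are produced and the discrepancy is reported via
#' `message()`.
#'
#' @param n_frames total number of acquisition frames.
#' @param W window length in frames (default 1002).
#' @param s step between window starts in frames (default 6).
#' @param include_partial append the final truncated window (default TRUE).
#' @return A list of class `"window_schedule"` with `windows` (data.frame of
#'   `start`, `end`), `n_windows`, `W`, `s`, `include_partial`.
#' @examples
#' window_schedule(5008, 1002, 6)$n_windows  # 669
#' @export
window_schedule <- function(n_frames, W = 1002, s = 6,
                            include_partial = TRUE) {
  check_count(n_frames, "n_frames", lower = 1L)
  check_count(W, "W", lower = 1L)
  check_count(s, "s", lower = 1L)
  t_full <- if (n_frames >= W) 0:((n_frames - W) %/% s) else integer()
  start <- s * t_full + 1
  end <- start + W - 1
  partial_used <- FALSE
  t_next <- if (length(t_full)) max(t_full) + 1 else 0
  p_start <- s * t_next + 1
  if (p_start <= n_frames && !any(end == n_frames)) {
    if (include_partial) {
      start <- c(start, p_start)
      end <- c(end, n_frames)
      partial_used <- TRUE
      message(sprintf(
        "window_schedule: appended truncated window [%d, %d] (%d frames); %d windows total",
        p_start, n_frames, n_frames - p_start + 1, length(start)))
    } else {
      message(sprintf(
        "window_schedule: frames %d-%d not covered (include_partial = FALSE); %d full windows",
        p_start, n_frames, length(start)))
    }
  }
  if (!length(start))
    stop("no window fits: n_frames < W and include_partial = FALSE")
  structure(list(windows = data.frame(start = start, end = end),
                 n_windows = length(start), W = W, s = s,
                 include_partial = include_partial,
                 partial_used = partial_used),
            class = "window_schedule")
}

#' @export
print.window_schedule <- function(x, ...) {
  cat(sprintf("<window_schedule> %d windows (W = %d, step = %d)%s\n",
              x$n_windows, x$W, x$s,
              if (x$partial_used) ", last truncated" else ""))
  invisible(x)
}

new_probability_image <- function(values, roi, pixel_size) {
  stopifnot(is.matrix(values), all(is.finite(values)), all(values >= 0))
  structure(list(values = values, roi = roi, pixel_size = pixel_size),
            class = "probability_image")
}

#' @export
print.probability_image <- function(x, ...) {
  cat(sprintf("<probability_image> %d x %d px @ %g nm, sum*px^2 = %.4g\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              sum(x$values) * x$pixel_size^2))
  invisible(x)
}

#' Pixel-centre coordinates of an image grid
#'
#' @param image a `probability_image`.
#' @return list with vectors `x` (column centres) and `y` (row centres), nm.
#' @export
pixel_centers <- function(image) {
  px <- image$pixel_size
  list(x = image$roi$xmin + (seq_len(ncol(image$values)) - 0.5) * px,
       y = image$roi$ymin + (seq_len(nrow(image$values)) - 0.5) * px)
}

#' Integral of a probability image
#'
#' Midpoint-rule integral: sum of pixel values times pixel area.  With
#' `alpha = 1` and all kernels well inside the ROI this is 1 within 1%.
#'
#' @param image a `probability_image`.
#' @export
integrate_image <- function(image) {
  sum(image$values) * image$pixel_size^2
}

#' KDE existence-probability image from a localization table
#'
#' Each retained spot i contributes the isotropic Gaussian
#' \deqn{p_i(x,y) = \frac{1}{2\pi (A u_i)^2}
#'       \exp\!\left(-\frac{(x-x_i)^2+(y-y_i)^2}{2 (A u_i)^2}\right)}
#' and the image is \eqn{p = \alpha \frac{1}{N}\sum_i p_i + (1-\alpha)
#' p_{bg}} sampled at pixel centres.  Spots with uncertainties outside
#' `[u_min, u_max]` are discarded as physically implausible.  Kernels are
#' truncated at `kernel_truncation` SDs.  Units of the values are 1/nm^2.
#'
#' @param table a [localization_table()].
#' @param params a [kde_params()].
#' @param roi an [roi()] (or `c(xmin, xmax, ymin, ymax)`).
#' @param bg_seed seed for the i.i.d. background draw when `alpha < 1`.
#' @return A `probability_image`; rows index y, columns index x.
#' @examples
#' tab <- localization_table(frame = 1, x = 500, y = 500, uncertainty = 20)
#' img <- kde_image(tab, kde_params(), roi(1000, 1000))
#' integrate_image(img)
#' @export
kde_image <- function(table, params = kde_params(), roi, bg_seed = NULL) {
  validate_localization_table(table)
  roi <- as_roi(roi)
  px <- params$pixel_size
  width <- roi$xmax - roi$xmin
  height <- roi$ymax - roi$ymin
  if (width <= 0 || height <= 0) stop("ROI has zero area")
  nx <- max(1L, as.integer(round(width / px)))
  ny <- max(1L, as.integer(round(height / px)))
  keep <- table$uncertainty >= params$u_min &
          table$uncertainty <= params$u_max
  tab <- table[keep, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("no spots remain after the uncertainty filter [",
         params$u_min, ", ", params$u_max, "] nm")
  cx <- roi$xmin + (seq_len(nx) - 0.5) * px
  cy <- roi$ymin + (seq_len(ny) - 0.5) * px
  acc <- matrix(0, ny, nx)
  N <- nrow(tab)
  for (i in seq_len(N)) {
    s <- params$A * tab$uncertainty[i]
    r <- params$kernel_truncation * s
    jx <- which(cx >= tab$x[i] - r & cx <= tab$x[i] + r)
    jy <- which(cy >= tab$y[i] - r & cy <= tab$y[i] + r)
    if (!length(jx) || !length(jy)) next
    gx <- dnorm(cx[jx], tab$x[i], s)
    gy <- dnorm(cy[jy], tab$y[i], s)
    acc[jy, jx] <- acc[jy, jx] + tcrossprod(gy, gx)
  }
  vals <- params$alpha * acc / N
  if (params$alpha < 1) {
    bg <- with_seed(bg_seed,
                    rnorm(nx * ny, params$bg_mu, params$bg_sigma))
    vals <- vals + (1 - params$alpha) * pmax(matrix(bg, ny, nx), 0)
  }
  new_probability_image(vals, roi, px)
}

#' Reconstruct a PALM movie over a rolling-window schedule
#'
#' Frame t of the movie is the KDE image of the localizations whose frames
#' fall in window t of the schedule.
#'
#' @param table a [localization_table()].
#' @param schedule a [window_schedule()].
#' @param params a [kde_params()].
#' @param roi the reconstruction field.
#' @param strict if `TRUE`, an empty window is an error; otherwise an
#'   all-zero (background-only) frame is emitted with a `message()`.
#' @return A list of class `"palm_movie"` with elements `frames` (list of
#'   `probability_image`), `schedule`, `params`, `roi`.
#' @export
palm_movie <- function(table, schedule, params = kde_params(), roi,
                       strict = FALSE) {
  stopifnot(inherits(schedule, "window_schedule"))
  roi <- as_roi(roi)
  frames <- vector("list", schedule$n_windows)
  empty <- 0L
  for (t in seq_len(schedule$n_windows)) {
    w <- schedule$windows[t, ]
    sub <- table[table$frame >= w$start & table$frame <= w$end, ,
                 drop = FALSE]
    keep <- sub$uncertainty >= params$u_min & sub$uncertainty <= params$u_max
    if (!any(keep)) {
      if (strict)
        stop(sprintf("window %d [%d, %d] contains no localizations",
                     t, w$start, w$end))
      empty <- empty + 1L
      px <- params$pixel_size
      nx <- max(1L, as.integer(round((roi$xmax - roi$xmin) / px)))
      ny <- max(1L, as.integer(round((roi$ymax - roi$ymin) / px)))
      frames[[t]] <- new_probability_image(matrix(0, ny, nx), roi, px)
    } else {
      frames[[t]] <- kde_image(sub, params, roi)
    }
  }
  if (empty)
    message(sprintf("palm_movie: %d empty window(s) emitted as background",
                    empty))
  structure(list(frames = frames, schedule = schedule, params = params,
                 roi = roi),
            class = "palm_movie")
}

#' @export
print.palm_movie <- function(x, ...) {
  cat(sprintf("<palm_movie> %d frames, %d x %d px @ %g nm\n",
              length(x$frames), nrow(x$frames[[1]]$values),
              ncol(x$frames[[1]]$values), x$params$pixel_size))
  invisible(x)
}

#' Block average of an image sequence
#'
#' Averages non-overlapping blocks of `k` consecutive frames, converting a
#' high-frame-rate particle movie to the frame rate of the PALM movie (e.g.
#' 200 Hz averaged over 6 frames to 33.3 frames/s).  Output frame j is the
#' mean of input frames `(j-1)*k + 1` to `j*k`; trailing frames that do not
#' fill a block are dropped.
#'
#' @param stack a list of numeric matrices (or of `probability_image`s, or a
#'   `palm_movie`).
#' @param k block length in frames (>= 1, at most the stack length).
#' @return A list of the same element type of length `floor(length/k)`.
#' @export
rolling_average <- function(stack, k) {
  check_count(k, "k", lower = 1L)
  if (inherits(stack, "palm_movie")) stack <- stack$frames
  stopifnot(is.list(stack), length(stack) >= 1L)
  if (k > length(stack))
    stop("`k` exceeds the stack length (", length(stack), ")")
  is_pi <- inherits(stack[[1]], "probability_image")
  mat <- function(f) if (is_pi) f$values else f
  n_out <- length(stack) %/% k
  out <- vector("list", n_out)
  for (j in seq_len(n_out)) {
    idx <- ((j - 1) * k + 1):(j * k)
    m <- Reduce(`+`, lapply(stack[idx], mat)) / k
    out[[j]] <- if (is_pi)
      new_probability_image(m, stack[[idx[1]]]$roi,
                            stack[[idx[1]]]$pixel_size)
    else m
  }
  out
}
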