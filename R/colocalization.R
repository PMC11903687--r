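mask_geometry <- function(mask, pixel_size = NULL, origin = NULL) {
  if (inherits(mask, c("otsu_result", "li_result"))) {
    img <- mask$image
    if (!is.null(img)) {
      pixel_size <- pixel_size %||% img$pixel_size
      origin <- origin %||% c(img$roi$xmin, img$roi$ymin)
    }
    mask <- mask$mask
  }
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  list(mask = mask, pixel_size = pixel_size %||% 1,
       origin = origin %||% c(0, 0))
}

# mask value at the pixel containing each point (points outside the grid are
# clamped to the border pixel)
mask_at_points <- function(geom, x, y) {
  px <- geom$pixel_size
  ix <- pmin(pmax(floor((x - geom$origin[1]) / px) + 1, 1), ncol(geom$mask))
  iy <- pmin(pmax(floor((y - geom$origin[2]) / px) + 1, 1), nrow(geom$mask))
  geom$mask[cbind(iy, ix)]
}

contour_segments <- function(contours) {
  stopifnot(inherits(contours, "contour_set"), length(contours) >= 1L)
  p1 <- do.call(rbind, lapply(contours, function(p)
    p[-nrow(p), , drop = FALSE]))
  p2 <- do.call(rbind, lapply(contours, function(p)
    p[-1L, , drop = FALSE]))
  list(p1 = p1, p2 = p2)
}

dist_to_segments <- function(x, y, seg) {
  ax <- seg$p1[, 1]; ay <- seg$p1[, 2]
  bx <- seg$p2[, 1]; by <- seg$p2[, 2]
  abx <- bx - ax; aby <- by - ay
  len2 <- abx^2 + aby^2
  len2[len2 == 0] <- 1e-300
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    t <- ((x[i] - ax) * abx + (y[i] - ay) * aby) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- x[i] - (ax + t * abx)
    dy <- y[i] - (ay + t * aby)
    out[i] <- sqrt(min(dx^2 + dy^2))
  }
  out
}

#' Signed distance from points to the nearest structure contour
#'
#' Euclidean distance from each point to the nearest contour polyline, with
#' negative sign when the point lies inside the segmented structure (the
#' mask is TRUE at the pixel containing the point).  This is the geometric
#' primitive of the contour-distance colocalization statistic: a particle at
#' -d nm sits d nm inside the nearest membrane structure.
#'
#' @param points two-column matrix or data.frame of `(x, y)` in nm.
#' @param contours a [extract_contours()] result derived from `mask`.
#' @param mask the binary mask the contours came from (logical matrix or a
#'   thresholding result carrying its geometry).
#' @param pixel_size,origin grid geometry when `mask` is a bare matrix.
#' @return Numeric vector of signed distances in nm.
#' @export
signed_contour_distance <- function(points, contours, mask,
                                    pixel_size = NULL, origin = NULL) {
  if (length(contours) == 0L) stop("empty contour set")
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  geom <- mask_geometry(mask, pixel_size, origin)
  seg <- contour_segments(contours)
  d <- dist_to_segments(pts[, 1], pts[, 2], seg)
  inside <- mask_at_points(geom, pts[, 1], pts[, 2])
  ifelse(inside, -d, d)
}

as_frame_list <- function(x) {
  if (is.list(x) && !is.data.frame(x) &&
      !inherits(x, c("otsu_result", "li_result"))) x else list(x)
}

profile_bins <- function(values, bin_width) {
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  seq(lo, hi, by = bin_width)
}

#' Signed contour-distance profile with a random-spot control
#'
#' Pools signed distances from particle positions to segmented-structure
#' contours over all frames, bins them (50 nm default), and normalizes the
#' per-bin relative frequency by that of spatially uniform random spots
#' evaluated against the same per-frame masks.  A normalized ratio above 1
#' in the negative-distance bins means the particles are enriched inside the
#' structures.
#'
#' @param points per-frame list (or single matrix) of particle `(x, y)`
#'   positions in nm.
#' @param masks per-frame list (or single) of binary masks or thresholding
#'   results; contours are derived per frame.
#' @param roi the field over which control spots are drawn.
#' @param bin_width histogram bin width in nm (default 50).
#' @param control `"monte_carlo"` draws `n_random` uniform spots (pooled
#'   over frames); `"analytic"` evaluates the signed distance at every pixel
#'   centre of each frame's grid, an exact area-weighted quadrature of the
#'   uniform distribution at pixel resolution.
#' @param n_random total number of Monte-Carlo control spots (default 1e5).
#' @param pixel_size,origin grid geometry when masks are bare matrices.
#' @param seed seed for the Monte-Carlo control.
#' @return A data.frame of class `"distance_profile"` with columns `lo`,
#'   `hi`, `center`, `observed`, `control` (relative frequencies summing to
#'   1) and `ratio` (`NA` where the control bin is empty).
#' @export
distance_profile <- function(points, masks, roi, bin_width = 50,
                             control = c("monte_carlo", "analytic"),
                             n_random = 1e5, pixel_size = NULL,
                             origin = NULL, seed = NULL) {
  control <- match.arg(control)
  check_number(bin_width, "bin_width", lower = 1e-9)
  roi <- as_roi(roi)
  points <- as_frame_list(points)
  masks <- as_frame_list(masks)
  if (length(points) != length(masks)) {
    if (length(masks) == 1L) masks <- rep(masks, length(points))
    else stop("`points` and `masks` must have the same number of frames")
  }
  n_frames <- length(points)
  obs <- vector("list", n_frames)
  ctl <- vector("list", n_frames)
  mc_per_frame <- ceiling(n_random / n_frames)
  with_seed(seed, for (f in seq_len(n_frames)) {
    geom <- mask_geometry(masks[[f]], pixel_size, origin)
    if (!any(geom$mask)) next
    contours <- extract_contours(geom$mask, geom$pixel_size, geom$origin)
    pts <- as.matrix(as.data.frame(points[[f]]))[, 1:2, drop = FALSE]
    if (nrow(pts))
      obs[[f]] <- signed_contour_distance(pts, contours, geom$mask,
                                          geom$pixel_size, geom$origin)
    if (control == "monte_carlo") {
      rx <- runif(mc_per_frame, roi$xmin, roi$xmax)
      ry <- runif(mc_per_frame, roi$ymin, roi$ymax)
      ctl[[f]] <- signed_contour_distance(cbind(rx, ry), contours,
                                          geom$mask, geom$pixel_size,
                                          geom$origin)
    } else {
      ctr <- pixel_centers(list(values = geom$mask,
                                roi = list(xmin = geom$origin[1],
                                           ymin = geom$origin[2]),
                                pixel_size = geom$pixel_size))
      gx <- rep(ctr$x, each = length(ctr$y))
      gy <- rep(ctr$y, times = length(ctr$x))
      ctl[[f]] <- signed_contour_distance(cbind(gx, gy), contours,
                                          geom$mask, geom$pixel_size,
                                          geom$origin)
    }
  })
  obs <- unlist(obs)
  ctl <- unlist(ctl)
  if (!length(obs))
    stop("no particle positions in any frame with a non-empty mask")
  breaks <- profile_bins(c(obs, ctl), bin_width)
  h_obs <- graphics::hist(obs, breaks = breaks, plot = FALSE)$counts
  h_ctl <- graphics::hist(ctl, breaks = breaks, plot = FALSE)$counts
  observed <- h_obs / sum(h_obs)
  ctrl_rel <- h_ctl / sum(h_ctl)
  ratio <- ifelse(ctrl_rel > 0, observed / ctrl_rel, NA_real_)
  if (any(is.na(ratio) & observed > 0))
    warning("observed counts fall in bins with an empty control; ",
            "those ratios are NA")
  out <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                    center = (breaks[-length(breaks)] + breaks[-1]) / 2,
                    observed = observed, control = ctrl_rel, ratio = ratio)
  class(out) <- c("distance_profile", "data.frame")
  attr(out, "bin_width") <- bin_width
  out
}

#' Enrichment score over a distance range
#'
#' Mean of the normalized contour-distance ratio over the bins lying fully
#' inside `range` (default -200 to 0 nm, i.e. just inside the structure
#' boundary).  Values near 1 indicate chance-level association; larger
#' values indicate enrichment of particles within the structures.
#'
#' @param profile a [distance_profile()].
#' @param range length-2 numeric, nm.
#' @return A single number.
#' @export
enrichment_score <- function(profile, range = c(-200, 0)) {
  stopifnot(inherits(profile, "distance_profile"), length(range) == 2L)
  sel <- profile$lo >= range[1] & profile$hi <= range[2] &
         !is.na(profile$ratio)
  if (!any(sel)) stop("no defined profile bins inside the range")
  mean(profile$ratio[sel])
}

#' Pair cross-correlation of two point channels with a rotation control
#'
#' Measures all green-red pairwise distances per frame, pooled over frames,
#' and normalizes the per-bin distance density R(r) by that of a control
#' N(r) in which the green channel is rotated 180 degrees about the ROI
#' centre (torus-wrapped back into the ROI, preserving the point count).
#' C(r) = R(r)/N(r) is 1 for independent channels and peaks at short r for
#' truly colocalized channels.
#'
#' @param green,red per-frame lists (or single matrices) of `(x, y)` nm.
#' @param roi the analysis region (used for the rotation centre and wrap).
#' @param bin_width distance bin width in nm (default 50).
#' @param r_max largest distance binned (default: half the ROI diagonal).
#' @param wrap_control wrap rotated points torus-style into the ROI
#'   (default); otherwise points landing outside the ROI are discarded.
#' @return A data.frame of class `"ccf_profile"` with columns `lo`, `hi`,
#'   `center`, `observed`, `control` (relative pair-distance frequencies)
#'   and `ratio` (= C(r)).
#' @export
pair_cross_correlation <- function(green, red, roi, bin_width = 50,
                                   r_max = NULL, wrap_control = TRUE) {
  roi <- as_roi(roi)
  if (roi_area(roi) <= 0) stop("ROI of zero area: rotation centre undefined")
  green <- as_frame_list(green)
  red <- as_frame_list(red)
  if (length(green) != length(red))
    stop("`green` and `red` must have the same number of frames")
  ctr <- roi_center(roi)
  w <- roi$xmax - roi$xmin; h <- roi$ymax - roi$ymin
  if (is.null(r_max)) r_max <- sqrt(w^2 + h^2) / 2
  breaks <- seq(0, ceiling(r_max / bin_width) * bin_width, by = bin_width)
  cnt_obs <- cnt_ctl <- numeric(length(breaks) - 1L)
  any_pairs <- FALSE
  for (f in seq_along(green)) {
    g <- as.matrix(as.data.frame(green[[f]]))[, 1:2, drop = FALSE]
    r <- as.matrix(as.data.frame(red[[f]]))[, 1:2, drop = FALSE]
    if (!nrow(g) || !nrow(r)) next
    any_pairs <- TRUE
    d <- sqrt(outer(g[, 1], r[, 1], "-")^2 + outer(g[, 2], r[, 2], "-")^2)
    cnt_obs <- cnt_obs + graphics::hist(d[d <= max(breaks)],
                                        breaks = breaks,
                                        plot = FALSE)$counts
    gx <- 2 * ctr["x"] - g[, 1]
    gy <- 2 * ctr["y"] - g[, 2]
    if (wrap_control) {
      gx <- roi$xmin + (gx - roi$xmin) %% w
      gy <- roi$ymin + (gy - roi$ymin) %% h
    } else {
      keep <- in_roi(gx, gy, roi)
      gx <- gx[keep]; gy <- gy[keep]
      if (!length(gx)) next
    }
    dc <- sqrt(outer(gx, r[, 1], "-")^2 + outer(gy, r[, 2], "-")^2)
    cnt_ctl <- cnt_ctl + graphics::hist(dc[dc <= max(breaks)],
                                        breaks = breaks,
                                        plot = FALSE)$counts
  }
  if (!any_pairs) stop("no frame contains points in both channels")
  observed <- cnt_obs / sum(cnt_obs)
  control <- cnt_ctl / sum(cnt_ctl)
  ratio <- ifelse(control > 0, observed / control, NA_real_)
  out <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                    center = (breaks[-length(breaks)] + breaks[-1]) / 2,
                    observed = observed, control = control, ratio = ratio)
  class(out) <- c("ccf_profile", "data.frame")
  attr(out, "bin_width") <- bin_width
  out
}

#' Colocalization event statistics for tracked particles
#'
#' An event is a maximal run of >= `min_frames` consecutive frames during
#' which a track's position lies inside the (per-frame) structure mask.
#' Reports the event frequency and the density of distinct colocalized
#' particles, both per um^2 of analysed membrane per minute.
#'
#' @param tracks a [link_particles()] result (columns `track`, `frame`,
#'   `x`, `y`); frames index into `masks`.
#' @param masks per-frame list of binary masks or thresholding results
#'   (recycled if a single mask is given).
#' @param frame_interval time between mask frames in seconds.
#' @param roi_area_um2 analysed area in um^2.
#' @param min_frames minimum run length for an event (default 1).
#' @param pixel_size,origin grid geometry when masks are bare matrices.
#' @return A list with `n_events`, `n_colocalized_tracks`,
#'   `event_frequency` (events/um^2/min), `particle_density`
#'   (particles/um^2/min), `duration_min`, `area_um2`.
#' @export
colocalization_event_stats <- function(tracks, masks, frame_interval,
                                       roi_area_um2, min_frames = 1L,
                                       pixel_size = NULL, origin = NULL) {
  check_number(frame_interval, "frame_interval", lower = 1e-12)
  check_number(roi_area_um2, "roi_area_um2", lower = 1e-12)
  check_count(min_frames, "min_frames", lower = 1L)
  masks <- as_frame_list(masks)
  geoms <- lapply(masks, mask_geometry, pixel_size = pixel_size,
                  origin = origin)
  n_frames <- max(length(masks), max(tracks$frame))
  if (length(geoms) == 1L) geoms <- rep(geoms, n_frames)
  if (max(tracks$frame) > length(geoms))
    stop("track frames exceed the number of mask frames")
  n_events <- 0L
  coloc_tracks <- 0L
  for (tr in split(seq_len(nrow(tracks)), tracks$track)) {
    f <- tracks$frame[tr]
    inside <- vapply(seq_along(tr), function(i)
      mask_at_points(geoms[[f[i]]], tracks$x[tr[i]], tracks$y[tr[i]]),
      logical(1))
    # runs of consecutive frames inside
    r <- rle(inside)
    runs <- r$lengths[r$values]
    # split runs at frame gaps: conservative, gaps are rare in dense tracks
    n_ev <- sum(runs >= min_frames)
    n_events <- n_events + n_ev
    if (n_ev > 0) coloc_tracks <- coloc_tracks + 1L
  }
  duration_min <- length(geoms) * frame_interval / 60
  list(n_events = n_events, n_colocalized_tracks = coloc_tracks,
       event_frequency = n_events / (roi_area_um2 * duration_min),
       particle_density = coloc_tracks / (roi_area_um2 * duration_min),
       duration_min = duration_min, area_um2 = roi_area_um2)
}

#' Count overlapping particles in a two-color image pair
#'
#' Binarizes both registered channels with the Li threshold, counts
#' connected components of at least `min_area_px` pixels in each channel (G
#' and R) and in the AND image (M, only colocalized spots), and reports the
#' M/R ratio.  Supplying `positive_control_mr` (the M/R of a same-marker
#' control) rescales the ratio so the control reads 100%; rescaled values
#' can exceed 100%.
#'
#' @param image_G,image_R numeric matrices (or `probability_image`s) of
#'   identical dimensions.
#' @param min_area_px minimum component size in pixels (default 4, which
#'   suppresses single-pixel noise).
#' @param positive_control_mr optional M/R of the positive control.
#' @return A list of class `"overlap_counts"`: `G`, `R`, `M`, `mr_ratio`,
#'   and `mr_percent_normalized` when a control is given.
#' @export
count_overlap_particles <- function(image_G, image_R, min_area_px = 4L,
                                    positive_control_mr = NULL) {
  vg <- image_values(image_G)
  vr <- image_values(image_R)
  if (!all(dim(vg) == dim(vr)))
    stop("channel images must have identical dimensions")
  check_count(min_area_px, "min_area_px", lower = 1L)
  mg <- li_threshold(vg)$mask
  mr <- li_threshold(vr)$mask
  count_particles <- function(mask) {
    if (!any(mask)) return(0L)
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(lab[lab > 0])
    sum(sizes >= min_area_px)
  }
  G <- count_particles(mg)
  R <- count_particles(mr)
  M <- count_particles(mg & mr)
  ratio <- if (R > 0) M / R else NA_real_
  out <- list(G = G, R = R, M = M, mr_ratio = ratio)
  if (!is.null(positive_control_mr)) {
    check_number(positive_control_mr, "positive_control_mr", lower = 1e-12)
    out$mr_percent_normalized <- 100 * ratio / positive_control_mr
  }
  class(out) <- "overlap_counts"
  out
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat(sprintf("<overlap_counts> G = %d, R = %d, M = %d; M/R = %.3f%s\n",
              x$G, x$R, x$M, x$mr_ratio,
              if (!is.null(x$mr_percent_normalized))
                sprintf(" (%.1f%% of control)", x$mr_percent_normalized)
              else ""))
  invisible(x)
}
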