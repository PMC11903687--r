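test_that("signed contour distances have correct magnitude and sign", {
  px <- 10
  m <- disk_mask(2000, px, 1000, 1000, 500)
  cs <- extract_contours(m, pixel_size = px)
  d <- signed_contour_distance(rbind(c(1000, 1000),   # centre
                                     c(1620, 1000),   # 120 nm outside
                                     c(1400, 1000)),  # 100 nm inside
                               cs, m, pixel_size = px)
  expect_equal(d[1], -500, tolerance = 0.02)
  expect_equal(d[2], 120, tolerance = 0.1)
  expect_equal(d[3], -100, tolerance = 0.1)
  expect_error(signed_contour_distance(cbind(1, 1), structure(list(),
                                       class = "contour_set"), m,
                                       pixel_size = px),
               "empty contour")
})

test_that("distances match a brute-force scan over contour geometry", {
  set.seed(51)
  px <- 10
  m <- disk_mask(2000, px, 900, 1100, 420)
  m[disk_mask(2000, px, 1500, 400, 180)] <- TRUE
  cs <- extract_contours(m, pixel_size = px)
  pts <- cbind(runif(100, 0, 2000), runif(100, 0, 2000))
  d <- abs(signed_contour_distance(pts, cs, m, pixel_size = px))
  # oracle: exhaustive scan over every contour edge with dense sampling
  verts <- do.call(rbind, lapply(unclass(cs), function(p) {
    segs <- cbind(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE])
    do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
      t <- seq(0, 1, length.out = 25)
      cbind(segs[i, 1] + t * (segs[i, 3] - segs[i, 1]),
            segs[i, 2] + t * (segs[i, 4] - segs[i, 2]))
    }))
  }))
  d_oracle <- apply(pts, 1, function(p)
    min(sqrt((verts[, 1] - p[1])^2 + (verts[, 2] - p[2])^2)))
  expect_lt(max(abs(d - d_oracle)), 1)
  # sign matches mask membership at the containing pixel
  sgn <- signed_contour_distance(pts, cs, m, pixel_size = px)
  ix <- pmin(pmax(floor(pts[, 1] / px) + 1, 1), ncol(m))
  iy <- pmin(pmax(floor(pts[, 2] / px) + 1, 1), nrow(m))
  expect_identical(sgn < 0, m[cbind(iy, ix)])
})

test_that("uniform points give a flat normalized distance profile", {
  set.seed(52)
  px <- 10
  m <- disk_mask(2000, px, 1000, 1000, 450)
  pts <- cbind(runif(20000, 0, 2000), runif(20000, 0, 2000))
  prof <- distance_profile(pts, m, roi(2000, 2000), control = "analytic",
                           pixel_size = px, bin_width = 100)
  # bins holding meaningful control mass are flat at 1
  sel <- !is.na(prof$ratio) & prof$control > 0.05
  expect_gte(sum(sel), 5)
  expect_true(all(abs(prof$ratio[sel] - 1) < 0.1))
  expect_equal(sum(prof$observed), 1, tolerance = 1e-9)
  expect_equal(sum(prof$control), 1, tolerance = 1e-9)
  expect_equal(enrichment_score(prof), 1, tolerance = 0.1)
  expect_error(distance_profile(pts[0, ], m, roi(2000, 2000),
                                control = "analytic", pixel_size = px),
               "no particle positions")
})

test_that("mask-confined points are enriched by the inverse area fraction", {
  set.seed(53)
  px <- 10
  m <- disk_mask(2000, px, 1000, 1000, 357)  # ~10% of the ROI
  area_frac <- mean(m)
  th <- runif(5000, 0, 2 * pi); r <- 357 * sqrt(runif(5000))
  inside <- cbind(1000 + r * cos(th), 1000 + r * sin(th))
  prof <- distance_profile(inside, m, roi(2000, 2000),
                           control = "analytic", pixel_size = px)
  expect_equal(enrichment_score(prof, c(-200, 0)), 1 / area_frac,
               tolerance = 0.1)
  # enrichment is linear in a uniform scaling of the ratios
  prof2 <- prof
  prof2$ratio <- prof2$ratio * 3
  expect_equal(enrichment_score(prof2, c(-200, 0)),
               3 * enrichment_score(prof, c(-200, 0)))
  expect_error(enrichment_score(prof, c(-1e6, -9e5)), "no defined")
})

test_that("monte-carlo and analytic controls agree", {
  set.seed(54)
  px <- 20
  m <- disk_mask(2000, px, 800, 1200, 400)
  pts <- cbind(runif(2000, 0, 2000), runif(2000, 0, 2000))
  pa <- distance_profile(pts, m, roi(2000, 2000), control = "analytic",
                         pixel_size = px)
  pm <- distance_profile(pts, m, roi(2000, 2000), control = "monte_carlo",
                         n_random = 2e5, pixel_size = px, seed = 1)
  sel <- pa$control > 0.02
  expect_equal(pm$control[sel], pa$control[sel], tolerance = 0.05)
  # seeded control is reproducible
  pm2 <- distance_profile(pts, m, roi(2000, 2000), control = "monte_carlo",
                          n_random = 2e5, pixel_size = px, seed = 1)
  expect_identical(pm$control, pm2$control)
})

test_that("pair cross-correlation is flat for independent channels", {
  set.seed(55)
  r <- roi(10000, 10000)
  g <- lapply(1:25, function(i) cbind(runif(400, 0, 10000),
                                      runif(400, 0, 10000)))
  rd <- lapply(1:25, function(i) cbind(runif(400, 0, 10000),
                                       runif(400, 0, 10000)))
  p <- pair_cross_correlation(g, rd, r, bin_width = 250)
  sel <- p$center < 2500
  expect_true(all(abs(p$ratio[sel] - 1) < 0.1))
})

test_that("jittered paired channels produce a short-range peak", {
  set.seed(56)
  r <- roi(10000, 10000)
  g <- lapply(1:20, function(i) cbind(runif(200, 0, 10000),
                                      runif(200, 0, 10000)))
  rd <- lapply(g, function(m) m + matrix(rnorm(length(m), 0, 20), ncol = 2))
  p <- pair_cross_correlation(g, rd, r, bin_width = 50)
  plateau <- mean(p$ratio[p$center > 2000 & p$center < 4000], na.rm = TRUE)
  expect_gte(p$ratio[1] / plateau, 5)
})

test_that("rotation control matches observed for symmetric green fields", {
  set.seed(57)
  r <- roi(4000, 4000)
  # 180-degree symmetric green constellation
  half <- cbind(runif(150, 0, 4000), runif(150, 0, 4000))
  g <- rbind(half, cbind(4000 - half[, 1], 4000 - half[, 2]))
  rd <- cbind(runif(400, 0, 4000), runif(400, 0, 4000))
  p <- pair_cross_correlation(list(g), list(rd), r, bin_width = 100)
  sel <- p$center < 1500
  expect_true(all(abs(p$ratio[sel] - 1) < 0.15))
  # translation invariance of both channels and the ROI
  sh <- 1234
  p2 <- pair_cross_correlation(list(g + sh), list(rd + sh),
                               structure(list(xmin = sh, xmax = 4000 + sh,
                                              ymin = sh, ymax = 4000 + sh),
                                         class = "roi"), bin_width = 100)
  expect_equal(p2$ratio, p$ratio, tolerance = 1e-12)
  expect_error(pair_cross_correlation(list(g[0, ]), list(rd[0, ]), r),
               "no frame contains")
})

test_that("event statistics count mask-residence runs correctly", {
  px <- 100
  m_in <- matrix(FALSE, 20, 20); m_in[5:8, 5:8] <- TRUE
  m_out <- matrix(FALSE, 20, 20); m_out[15:18, 15:18] <- TRUE
  # track inside the mask during frames 4-6 only (one 3-frame run)
  tr <- data.frame(track = 1, frame = 1:10,
                   x = c(rep(100, 3), rep(650, 3), rep(100, 4)),
                   y = c(rep(100, 3), rep(650, 3), rep(100, 4)))
  st <- colocalization_event_stats(tr, rep(list(m_in), 10),
                                   frame_interval = 6, roi_area_um2 = 100,
                                   pixel_size = px)
  expect_equal(st$n_events, 1L)
  expect_equal(st$duration_min, 1)
  expect_equal(st$event_frequency, 0.01)
  expect_equal(st$particle_density, 0.01)
  # track never inside -> zero events
  st0 <- colocalization_event_stats(tr, rep(list(m_out), 10),
                                    frame_interval = 6, roi_area_um2 = 100,
                                    pixel_size = px)
  expect_equal(st0$n_events, 0L)
  expect_equal(st0$event_frequency, 0)
})

test_that("event frequency recovers a generative entry rate", {
  set.seed(58)
  px <- 100
  m <- matrix(FALSE, 50, 50); m[21:30, 21:30] <- TRUE  # 1 um^2 patch
  n_frames <- 2000
  rate <- 0.05  # entries per frame into the patch
  frames_entered <- which(runif(n_frames) < rate)
  # each entry: a distinct 2-frame track inside the mask
  tr <- do.call(rbind, lapply(seq_along(frames_entered), function(i) {
    f <- frames_entered[i]
    data.frame(track = i, frame = c(f, min(f + 1, n_frames)),
               x = runif(1, 2100, 2900), y = runif(1, 2100, 2900))
  }))
  st <- colocalization_event_stats(tr, rep(list(m), n_frames),
                                   frame_interval = 0.03,
                                   roi_area_um2 = 25, min_frames = 1,
                                   pixel_size = px)
  expected <- rate * n_frames
  expect_lt(abs(st$n_events - expected), 3 * sqrt(expected))
})

test_that("overlap particle counting reproduces known M/R ratios", {
  mk <- function(spots) {
    img <- matrix(1, 64, 64)
    for (s in spots) img[s[1]:(s[1] + 3), s[2]:(s[2] + 3)] <- 100
    img
  }
  g <- mk(list(c(5, 5), c(30, 30), c(50, 10)))
  r <- mk(list(c(5, 5), c(30, 30), c(10, 50)))
  oc <- count_overlap_particles(g, r)
  expect_equal(oc$G, 3L)
  expect_equal(oc$R, 3L)
  expect_equal(oc$M, 2L)
  expect_equal(oc$mr_ratio, 2 / 3, tolerance = 1e-12)
  expect_lte(oc$M, min(oc$G, oc$R))
  # identical channels -> M/R = 1; self-normalization reads 100%
  self <- count_overlap_particles(g, g, positive_control_mr = 1)
  expect_equal(self$mr_ratio, 1)
  expect_equal(self$mr_percent_normalized, 100)
  # disjoint particle sets -> M/R = 0
  r2 <- mk(list(c(50, 50)))
  expect_equal(count_overlap_particles(g, r2)$mr_ratio, 0)
  expect_error(count_overlap_particles(g, matrix(1, 32, 32)), "dimensions")
})

test_that("overlap counting recovers a generative co-occurrence fraction", {
  set.seed(59)
  pop <- sample_two_color_population(
    population_spec(subtype_weights = c("CD63" = 0.5,
                                        "CD9+CD63+CD81" = 0.5),
                    lambda_copies = 50, n_vesicles = 60, seed = 12))
  # render detected vesicles as bright spots on a 256 x 256 grid;
  # red = CD63 channel, green = CD9 channel
  img_g <- matrix(1, 256, 256); img_r <- matrix(1, 256, 256)
  pos <- cbind(((0:59) %% 15) * 16 + 5, ((0:59) %/% 15) * 16 + 5)
  for (i in 1:60) {
    px <- pos[i, ]
    if (pop$CD9_green[i])
      img_g[px[1]:(px[1] + 2), px[2]:(px[2] + 2)] <- 100
    if (pop$CD63_red[i])
      img_r[px[1]:(px[1] + 2), px[2]:(px[2] + 2)] <- 100
  }
  oc <- count_overlap_particles(img_g, img_r, min_area_px = 4)
  f <- oc$mr_ratio
  # truth: half of CD63+ vesicles also carry CD9
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / oc$R))
})
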