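test_that("otsu separates a two-level image perfectly", {
  img <- matrix(c(rep(0, 4), rep(10, 4)), 2, 4)
  res <- otsu_threshold(img)
  expect_gt(res$threshold, 0)
  expect_lte(res$threshold, 10)
  expect_equal(res$n_in, 4L)
  expect_equal(res$n_out, 4L)
  expect_equal(res$intraclass_variance, 0)
  expect_equal(res$mu_in, 10)
  expect_equal(res$mu_out, 0)
  expect_error(otsu_threshold(matrix(5, 3, 3)), "constant image")
})

test_that("otsu and li match exhaustive brute-force minimization", {
  set.seed(41)
  for (i in 1:100) {
    nr <- sample(4:16, 1); nc <- sample(4:16, 1)
    img <- matrix(sample(1:255, nr * nc, TRUE), nr, nc)
    if (length(unique(as.numeric(img))) < 2) next
    o <- otsu_threshold(img)
    bo <- brute_otsu(img)
    # same achieved criterion (thresholds may sit anywhere on the optimal
    # plateau between two data values)
    expect_equal(o$intraclass_variance, bo$icv, tolerance = 1e-9)
    expect_identical(o$mask, img >= bo$threshold)
    l <- li_threshold(img)
    bl <- brute_li(img)
    expect_equal(li_eta(l$threshold, as.numeric(img)), bl$eta,
                 tolerance = 1e-9)
  }
})

test_that("otsu is translation equivariant with aligned bins", {
  set.seed(42)
  img <- matrix(runif(256, 0, 5), 16, 16)
  t0 <- otsu_threshold(img)$threshold
  t1 <- otsu_threshold(img + 7.5)$threshold
  expect_equal(t1 - t0, 7.5, tolerance = 1e-9)
})

test_that("li threshold scales with the image and splits bimodal modes", {
  set.seed(43)
  img <- matrix(c(rnorm(300, 20, 2), rnorm(212, 80, 5)), 16, 32)
  res <- li_threshold(img)
  # the minimum cross-entropy threshold separates the modes (it sits
  # closer to the dimmer mode by construction)
  expect_gt(res$threshold, 22)
  expect_lt(res$threshold, 75)
  expect_true(all(img[img > 60] >= res$threshold))  # bright mode captured
  expect_equal(li_threshold(img * 3)$threshold, 3 * res$threshold,
               tolerance = 0.02)
  # the iterative fixed point agrees on clean bimodal images
  it <- li_threshold(img, method = "iterative")
  expect_identical(res$mask, it$mask)
  expect_error(li_threshold(img - 30), "positive")
})

test_that("contours trace mask boundaries at sub-pixel midpoints", {
  # 10 x 10 px square, px = 10 nm
  m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
  cs <- extract_contours(m, pixel_size = 10)
  expect_length(cs, 1L)
  # perimeter ~ 4 * 100 nm, within corner-rounding tolerance
  expect_equal(polygon_perimeter(cs[[1]]), 400, tolerance = 0.05)
  # outer ring is counterclockwise (positive signed area)
  expect_gt(polygon_area_signed(cs[[1]]), 0)
  expect_equal(polygon_area_signed(cs[[1]]), 100 * 100, tolerance = 0.05)
  # two disjoint blobs -> two polygons
  m2 <- m; m2[2:4, 2:4] <- TRUE
  expect_length(extract_contours(m2, pixel_size = 10), 2L)
  # a hole yields an inner clockwise ring
  m3 <- m; m3[9:12, 9:12] <- FALSE
  cs3 <- extract_contours(m3, pixel_size = 10)
  expect_length(cs3, 2L)
  areas <- vapply(cs3, polygon_area_signed, numeric(1))
  expect_equal(sum(areas > 0), 1L)
  expect_equal(sum(areas < 0), 1L)
  expect_error(extract_contours(matrix(FALSE, 4, 4), 10), "empty mask")
})

test_that("contour polygon area tracks pixel count for large blobs", {
  set.seed(44)
  # random blob >= 100 px from a dilated random walk
  m <- matrix(FALSE, 40, 40)
  pos <- c(20, 20)
  for (i in 1:300) {
    m[pos[1], pos[2]] <- TRUE
    pos <- pmin(pmax(pos + sample(c(-1, 0, 1), 2, TRUE), 3), 38)
  }
  # dilate once so the blob is solid
  md <- m
  for (dr in -1:1) for (dc in -1:1)
    md[3:38, 3:38] <- md[3:38, 3:38] | m[3:38 + dr, 3:38 + dc]
  cs <- extract_contours(md, pixel_size = 10)
  area_poly <- sum(vapply(cs, polygon_area_signed, numeric(1)))
  expect_equal(area_poly, sum(md) * 100, tolerance = 0.05)
})

test_that("voronoi objects find dense clusters and ignore uniform noise", {
  set.seed(45)
  # uniform points, factor 5 -> no objects (checked over several draws)
  for (i in 1:5) {
    u <- data.frame(x = runif(400, 0, 5000), y = runif(400, 0, 5000))
    expect_length(voronoi_objects(u, 5, 100, roi(5000, 5000)), 0L)
  }
  # dense 500-point disk in background -> exactly one object holding at
  # least 95% of the disk points
  th <- runif(500, 0, 2 * pi); r <- 200 * sqrt(runif(500))
  disk <- data.frame(x = 2500 + r * cos(th), y = 2500 + r * sin(th))
  bg <- data.frame(x = runif(300, 0, 5000), y = runif(300, 0, 5000))
  vo <- voronoi_objects(rbind(disk, bg), 5, 100, roi(5000, 5000))
  expect_length(vo, 1L)
  expect_gte(sum(vo[[1]]$indices <= 500), 475)
  expect_error(voronoi_objects(disk[1:3, ], 5, 10, roi(5000, 5000)),
               "at least 4")
})

test_that("the minimum-localization filter is a strict boundary", {
  # a 99-localization cluster built so that exactly its 99 members exceed
  # the density threshold: a 9 x 11 grid at 20 nm pitch inside a sparse
  # fence ring that clamps the rim cells without itself reaching seed
  # density
  set.seed(46)
  g <- expand.grid(x = seq(0, 8) * 20, y = seq(0, 10) * 20)
  pts <- data.frame(x = 2000 + g$x + runif(99, -2, 2),
                    y = 2000 + g$y + runif(99, -2, 2))
  fx <- range(pts$x); fy <- range(pts$y); off <- 200
  fence <- rbind(
    data.frame(x = seq(fx[1] - off, fx[2] + off, by = 130), y = fy[1] - off),
    data.frame(x = seq(fx[1] - off, fx[2] + off, by = 130), y = fy[2] + off),
    data.frame(x = fx[1] - off,
               y = seq(fy[1] - off + 130, fy[2] + off - 130, by = 130)),
    data.frame(x = fx[2] + off,
               y = seq(fy[1] - off + 130, fy[2] + off - 130, by = 130)))
  bg <- data.frame(x = runif(40, 0, 4000), y = runif(40, 0, 4000))
  tab <- rbind(pts, fence, bg)
  # 99 members at min 100 -> discarded; at min 99 -> retained
  strict <- voronoi_objects(tab, 5, 100, roi(4000, 4000))
  loose <- voronoi_objects(tab, 5, 99, roi(4000, 4000))
  expect_length(strict, 0L)
  expect_length(loose, 1L)
  expect_equal(loose[[1]]$n, 99L)
})

test_that("object membership is invariant under localization reorder", {
  set.seed(47)
  sim <- simulate_vesicle_field(4, field = roi(4000, 4000), seed = 9)
  vo1 <- voronoi_objects(sim$table, 5, 100, sim$field)
  perm <- sample(nrow(sim$table))
  shuffled <- as.data.frame(sim$table)[perm, ]
  vo2 <- voronoi_objects(shuffled, 5, 100, sim$field)
  sets1 <- lapply(vo1, function(o) sort(o$indices))
  sets2 <- lapply(vo2, function(o) sort(perm[o$indices]))
  key <- function(s) paste(s, collapse = ",")
  expect_setequal(vapply(sets1, key, character(1)),
                  vapply(sets2, key, character(1)))
})

test_that("diameter estimators behave geometrically", {
  set.seed(48)
  sim <- simulate_vesicle_field(4, field = roi(4000, 4000), seed = 10)
  vo <- voronoi_objects(sim$table, 5, 100, sim$field)
  expect_gt(length(vo), 0)
  obj <- vo[[1]]
  # doubling all coordinates (and uncertainties) doubles the estimates
  tab2 <- as.data.frame(sim$table)
  tab2$x <- tab2$x * 2; tab2$y <- tab2$y * 2
  tab2$uncertainty <- tab2$uncertainty * 2
  vo2 <- voronoi_objects(tab2, 5, 100, roi(8000, 8000))
  d1 <- sort(vapply(vo, `[[`, numeric(1), "diameter"))
  d2 <- sort(vapply(vo2, `[[`, numeric(1), "diameter"))
  expect_equal(d2, 2 * d1, tolerance = 1e-6)
  expect_equal(object_diameter(obj, "area"), 2 * sqrt(obj$area / pi))
  expect_gt(object_diameter(obj, "feret"), object_diameter(obj, "shell"))
  # precision-zero uniform disk: area estimate converges to the true
  # diameter as n grows
  th <- runif(3000, 0, 2 * pi); r <- 400 * sqrt(runif(3000))
  disk <- data.frame(x = 4000 + r * cos(th), y = 4000 + r * sin(th),
                     uncertainty = 1e-6)
  bg <- data.frame(x = runif(200, 0, 8000), y = runif(200, 0, 8000),
                   uncertainty = 1e-6)
  vo3 <- voronoi_objects(rbind(disk, bg), 5, 100, roi(8000, 8000))
  expect_length(vo3, 1L)
  # finite-n skirt: rim cells extend slightly beyond the disk edge
  expect_equal(object_diameter(vo3[[1]], "area"), 800, tolerance = 0.08)
  # ... and shrinks with n (convergence toward the true diameter)
  sparse <- rbind(disk[1:400, ], bg)
  vo4 <- voronoi_objects(sparse, 5, 100, roi(8000, 8000))
  expect_lt(abs(object_diameter(vo3[[1]], "area") - 800),
            abs(object_diameter(vo4[[1]], "area") - 800))
})

test_that("shell diameter is monotone in the true vesicle diameter", {
  ds <- c(70, 111, 150)
  est <- vapply(ds, function(d) {
    sim <- simulate_vesicle_field(6, field = roi(5000, 5000),
                                  true_diameter = d, seed = 77)
    vo <- voronoi_objects(sim$table, 5, 100, sim$field)
    mean(vapply(vo, `[[`, numeric(1), "diameter"))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
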