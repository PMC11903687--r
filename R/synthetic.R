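#' Specification of a synthetic SMLM acquisition field
#'
#' Describes a photoactivation acquisition over a rectangular field: point
#' emitters blink on stochastically inside circular nanodomains (clusters) on
#' top of a uniform background, and each localization is perturbed by its own
#' localization uncertainty.  Defaults emulate a 200 frames/s acquisition of
#' 5008 frames with ~20 nm localization precision.
#'
#' @param roi_width,roi_height field extent in nm.
#' @param n_frames number of acquisition frames.
#' @param cluster_centers two-column matrix (or data.frame) of cluster
#'   centres in nm; may have zero rows.
#' @param cluster_radius cluster disk radius in nm.
#' @param cluster_rate expected localizations per cluster per frame.
#' @param background_rate expected background localizations per um^2 per
#'   frame.
#' @param precision_mean,precision_sd mean and SD of the per-spot
#'   localization uncertainty in nm; draws are truncated below at 1 nm.
#' @param seed integer seed making the realization reproducible.
#' @return A list of class `"field_spec"`.
#' @export
field_spec <- function(roi_width = 25600, roi_height = 25600,
                       n_frames = 5008,
                       cluster_centers = matrix(numeric(), ncol = 2),
                       cluster_radius = 100, cluster_rate = 0.5,
                       background_rate = 0.001,
                       precision_mean = 20, precision_sd = 1,
                       seed = 1L) {
  check_number(roi_width, "roi_width", lower = 1e-9)
  check_number(roi_height, "roi_height", lower = 1e-9)
  check_count(n_frames, "n_frames", lower = 1L)
  check_number(cluster_radius, "cluster_radius", lower = 1e-9)
  check_number(cluster_rate, "cluster_rate", lower = 0)
  check_number(background_rate, "background_rate", lower = 0)
  check_number(precision_mean, "precision_mean", lower = 0)
  check_number(precision_sd, "precision_sd", lower = 0)
  cc <- as.matrix(cluster_centers)
  if (length(cc) && ncol(cc) != 2L)
    stop("`cluster_centers` must have two columns (x, y)")
  storage.mode(cc) <- "double"
  if (nrow(cc)) {
    inside <- cc[, 1] >= 0 & cc[, 1] <= roi_width &
              cc[, 2] >= 0 & cc[, 2] <= roi_height
    if (!all(inside))
      stop("cluster centre(s) outside the ROI: row(s) ",
           paste(which(!inside), collapse = ", "))
  }
  structure(list(roi_width = roi_width, roi_height = roi_height,
                 n_frames = as.integer(n_frames), cluster_centers = cc,
                 cluster_radius = cluster_radius,
                 cluster_rate = cluster_rate,
                 background_rate = background_rate,
                 precision_mean = precision_mean,
                 precision_sd = precision_sd, seed = seed),
            class = "field_spec")
}

# Positive-truncated normal; uncertainties below 1 nm would make degenerate
# KDE kernels, so the floor is 1 nm.
draw_precision <- function(n, mean, sd, floor = 1) {
  if (n == 0L) return(numeric())
  u <- rnorm(n, mean, sd)
  while (any(bad <- u < floor)) u[bad] <- rnorm(sum(bad), mean, sd)
  u
}

#' Generate blinking localizations for a clustered field
#'
#' Per frame, each cluster contributes `Poisson(cluster_rate)` localizations
#' uniform in its disk and the background contributes
#' `Poisson(background_rate * area)` localizations uniform in the ROI.  Every
#' spot receives an uncertainty drawn from a truncated normal and its
#' coordinates are perturbed by isotropic Gaussian noise with that SD.
#'
#' @param spec a [field_spec()].
#' @return A [localization_table()] sorted by frame, with extra columns
#'   `x_true`, `y_true` (pre-noise positions) and `origin`
#'   (`"cluster"`/`"background"`).
#' @examples
#' fs <- field_spec(roi_width = 2000, roi_height = 2000, n_frames = 100,
#'                  cluster_centers = cbind(1000, 1000), seed = 7)
#' tab <- generate_localization_field(fs)
#' @export
generate_localization_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  with_seed(spec$seed, {
    n_cl <- nrow(spec$cluster_centers)
    area_um2 <- spec$roi_width * spec$roi_height / 1e6
    # per frame counts
    n_clust <- if (n_cl) matrix(rpois(spec$n_frames * n_cl,
                                      spec$cluster_rate),
                                nrow = spec$n_frames)
               else matrix(0L, spec$n_frames, 0)
    n_bg <- rpois(spec$n_frames, spec$background_rate * area_um2)
    frames <- x <- y <- origin_cl <- list()
    if (n_cl) {
      tot <- colSums(n_clust)
      for (k in seq_len(n_cl)) {
        nk <- tot[k]
        if (nk == 0) next
        # uniform in disk
        r <- spec$cluster_radius * sqrt(runif(nk))
        th <- runif(nk, 0, 2 * pi)
        frames[[length(frames) + 1L]] <-
          rep(seq_len(spec$n_frames), n_clust[, k])
        x[[length(x) + 1L]] <- spec$cluster_centers[k, 1] + r * cos(th)
        y[[length(y) + 1L]] <- spec$cluster_centers[k, 2] + r * sin(th)
        origin_cl[[length(origin_cl) + 1L]] <- rep("cluster", nk)
      }
    }
    nbg <- sum(n_bg)
    if (nbg) {
      frames[[length(frames) + 1L]] <- rep(seq_len(spec$n_frames), n_bg)
      x[[length(x) + 1L]] <- runif(nbg, 0, spec$roi_width)
      y[[length(y) + 1L]] <- runif(nbg, 0, spec$roi_height)
      origin_cl[[length(origin_cl) + 1L]] <- rep("background", nbg)
    }
    frame <- unlist(frames) %||% integer()
    xt <- unlist(x) %||% numeric()
    yt <- unlist(y) %||% numeric()
    org <- unlist(origin_cl) %||% character()
    u <- draw_precision(length(frame), spec$precision_mean,
                        spec$precision_sd)
    localization_table(frame = frame,
                       x = xt + rnorm(length(xt), 0, u),
                       y = yt + rnorm(length(yt), 0, u),
                       uncertainty = u,
                       x_true = xt, y_true = yt, origin = org)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specification of a single synthetic vesicle
#'
#' Membrane-protein fluorophores sit on the *surface* of a sphere of the true
#' vesicle diameter; the dSTORM image is the orthographic projection of that
#' shell blurred by the localization precision.  Vesicles are imaged on glass
#' where the whole shell lies within the evanescent field, so no axial
#' weighting is applied.
#'
#' @param true_diameter sphere diameter in nm.
#' @param n_localizations number of localizations (>= 1).
#' @param precision localization precision in nm (isotropic Gaussian SD;
#'   may be 0 for noise-free geometry checks).
#' @param center projected sphere centre `(x, y)` in nm.
#' @param seed integer seed.
#' @return A list of class `"vesicle_spec"`.
#' @export
vesicle_spec <- function(true_diameter = 111, n_localizations = 200,
                         precision = 20, center = c(0, 0), seed = 1L) {
  check_number(true_diameter, "true_diameter", lower = 0)
  check_count(n_localizations, "n_localizations", lower = 1L)
  check_number(precision, "precision", lower = 0)
  stopifnot(is.numeric(center), length(center) == 2L, all(is.finite(center)))
  structure(list(true_diameter = true_diameter,
                 n_localizations = as.integer(n_localizations),
                 precision = precision, center = as.numeric(center),
                 seed = seed),
            class = "vesicle_spec")
}

#' Generate localizations for one spherical-shell vesicle
#'
#' Points are drawn uniformly on the sphere surface, orthographically
#' projected to the imaging plane, shifted to the requested centre, and
#' perturbed by Gaussian localization noise.  Frames are assigned
#' sequentially (one localization per frame), mimicking sparse dSTORM
#' blinking.
#'
#' @param spec a [vesicle_spec()].
#' @return A [localization_table()] with extra columns `x_true`, `y_true`.
#' @examples
#' v <- generate_vesicle_localizations(vesicle_spec(true_diameter = 100,
#'                                                  precision = 0))
#' max(sqrt(v$x^2 + v$y^2)) <= 50
#' @export
generate_vesicle_localizations <- function(spec) {
  stopifnot(inherits(spec, "vesicle_spec"))
  with_seed(spec$seed, {
    n <- spec$n_localizations
    R <- spec$true_diameter / 2
    # uniform on sphere: z ~ U(-R, R), azimuth uniform
    z <- runif(n, -R, R)
    th <- runif(n, 0, 2 * pi)
    rho <- sqrt(pmax(R^2 - z^2, 0))
    xt <- spec$center[1] + rho * cos(th)
    yt <- spec$center[2] + rho * sin(th)
    u <- rep(max(spec$precision, 1e-6), n)
    localization_table(frame = seq_len(n),
                       x = xt + rnorm(n, 0, spec$precision),
                       y = yt + rnorm(n, 0, spec$precision),
                       uncertainty = u, x_true = xt, y_true = yt)
  })
}

#' Simulate a dSTORM field of vesicles on glass
#'
#' Composes [generate_vesicle_localizations()] for `n_vesicles` vesicles laid
#' out on a jittered grid (enforcing a minimum spacing) with a uniform
#' background of nonspecific localizations, as in a glass-surface dSTORM
#' acquisition.  This is the input expected by [voronoi_objects()].
#'
#' @param n_vesicles number of vesicles in the field.
#' @param field an [roi()] giving the field extent.
#' @param true_diameter vesicle diameter in nm.
#' @param n_localizations per-vesicle localization count; either a single
#'   number or a range `c(min, max)` sampled uniformly.
#' @param precision localization precision in nm.
#' @param background_density nonspecific background localizations per um^2
#'   accumulated over the acquisition.
#' @param margin minimum distance from vesicle centres to the field edge, nm.
#' @param seed integer seed.
#' @return A list with elements `table` (a [localization_table()]; column
#'   `vesicle` holds the generating vesicle index, 0 for background),
#'   `centers` (matrix of vesicle centres) and `field`.
#' @export
simulate_vesicle_field <- function(n_vesicles, field = roi(6400, 6400),
                                   true_diameter = 111,
                                   n_localizations = c(150, 300),
                                   precision = 20,
                                   background_density = 100,
                                   margin = 400, seed = 1L) {
  check_count(n_vesicles, "n_vesicles", lower = 1L)
  field <- as_roi(field)
  with_seed(seed, {
    w <- field$xmax - field$xmin - 2 * margin
    h <- field$ymax - field$ymin - 2 * margin
    ncol_grid <- ceiling(sqrt(n_vesicles * w / h))
    nrow_grid <- ceiling(n_vesicles / ncol_grid)
    sx <- w / ncol_grid; sy <- h / nrow_grid
    g <- expand.grid(i = seq_len(ncol_grid), j = seq_len(nrow_grid))
    g <- g[seq_len(n_vesicles), , drop = FALSE]
    jit <- 0.2  # fraction of spacing
    cx <- field$xmin + margin + (g$i - 0.5) * sx + runif(n_vesicles, -jit, jit) * sx
    cy <- field$ymin + margin + (g$j - 0.5) * sy + runif(n_vesicles, -jit, jit) * sy
    nl <- if (length(n_localizations) == 2L)
      round(runif(n_vesicles, n_localizations[1], n_localizations[2]))
    else rep(round(n_localizations[1]), n_vesicles)
    seeds <- sample.int(.Machine$integer.max, n_vesicles + 1L)
    parts <- vector("list", n_vesicles + 1L)
    for (k in seq_len(n_vesicles)) {
      vs <- vesicle_spec(true_diameter = true_diameter,
                         n_localizations = nl[k], precision = precision,
                         center = c(cx[k], cy[k]), seed = seeds[k])
      tab <- generate_vesicle_localizations(vs)
      tab$vesicle <- k
      parts[[k]] <- as.data.frame(tab)
    }
    n_bg <- rpois(1, background_density * roi_area(field) / 1e6)
    if (n_bg) {
      parts[[n_vesicles + 1L]] <- data.frame(
        frame = seq_len(n_bg),
        x = runif(n_bg, field$xmin, field$xmax),
        y = runif(n_bg, field$ymin, field$ymax),
        uncertainty = rep(max(precision, 1e-6), n_bg),
        x_true = NA_real_, y_true = NA_real_, vesicle = 0L)
    }
    all <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    tab <- do.call(localization_table, as.list(all))
    list(table = tab, centers = cbind(x = cx, y = cy), field = field)
  })
}

#' Specification of a labeled vesicle population
#'
#' Copy-number and subtype model for two-color single-vesicle imaging: each
#' vesicle belongs to a subtype (a subset of the tetraspanin markers CD9,
#' CD63, CD81), carries a zero-truncated Poisson number of labeled copies per
#' marker channel, and each fluorophore contributes a log-normal monomer
#' intensity.
#'
#' @param subtype_weights named numeric vector of subtype fractions; names
#'   are marker subsets written like `"CD63"` or `"CD9+CD63+CD81"`.  Must be
#'   non-negative and sum to 1 (tolerance 1e-9).
#' @param lambda_copies mean fluorophore copies per vesicle and channel
#'   (Poisson mean before zero truncation); must be positive.
#' @param monomer_log_mean,monomer_log_sd log-normal parameters of the
#'   single-fluorophore intensity (natural log).  The default log-mean puts
#'   the monomer median at ~164 photons, the calibrated single-TMR photon
#'   count of the instrument model.
#' @param n_vesicles number of vesicles to draw.
#' @param seed integer seed.
#' @return A list of class `"population_spec"`.
#' @export
population_spec <- function(subtype_weights = c("CD63" = 0.5,
                                                "CD9+CD63+CD81" = 0.5),
                            lambda_copies = 4.5,
                            monomer_log_mean = log(164.2),
                            monomer_log_sd = 0.4,
                            n_vesicles = 1000, seed = 1L) {
  check_number(lambda_copies, "lambda_copies")
  if (lambda_copies <= 0) stop("`lambda_copies` must be > 0")
  check_number(monomer_log_mean, "monomer_log_mean")
  check_number(monomer_log_sd, "monomer_log_sd", lower = 0)
  check_count(n_vesicles, "n_vesicles", lower = 0L)
  w <- subtype_weights
  if (is.null(names(w)) || any(!nzchar(names(w))))
    stop("`subtype_weights` must be a named vector of marker subsets")
  if (any(w < 0)) stop("subtype weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9)
    stop(sprintf("subtype weights must sum to 1 (got %.12f)", sum(w)))
  lapply(names(w), parse_subset)  # validates names
  structure(list(subtype_weights = w, lambda_copies = lambda_copies,
                 monomer_log_mean = monomer_log_mean,
                 monomer_log_sd = monomer_log_sd,
                 n_vesicles = as.integer(n_vesicles), seed = seed),
            class = "population_spec")
}

markers3 <- c("CD9", "CD63", "CD81")

parse_subset <- function(name) {
  parts <- unique(strsplit(name, "+", fixed = TRUE)[[1]])
  bad <- setdiff(parts, markers3)
  if (length(bad) || !length(parts))
    stop("invalid marker subset name: '", name, "'")
  parts[order(match(parts, markers3))]  # canonical CD9, CD63, CD81 order
}

# zero-truncated Poisson via inverse cdf on a uniform restricted to
# [P(X=0), 1): exact and vectorized.
rztpois <- function(n, lambda) {
  if (n == 0L) return(integer())
  p0 <- exp(-lambda)
  stats::qpois(p0 + runif(n) * (1 - p0), lambda)
}

#' Sample per-vesicle total fluorescence intensities
#'
#' Forward model of the single-vesicle intensity histogram: the copy number
#' is zero-truncated Poisson (only labeled vesicles are detected) and the
#' total intensity is the sum of that many i.i.d. log-normal monomer
#' intensities.
#'
#' @param spec a [population_spec()].
#' @return A data.frame with columns `copies` and `intensity`.
#' @examples
#' pop <- population_spec(n_vesicles = 500, seed = 3)
#' head(sample_vesicle_intensities(pop))
#' @export
sample_vesicle_intensities <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(spec$seed, {
    n <- spec$n_vesicles
    copies <- rztpois(n, spec$lambda_copies)
    total <- sum(copies)
    draws <- exp(rnorm(total, spec$monomer_log_mean, spec$monomer_log_sd))
    grp <- rep(seq_len(n), copies)
    intensity <- as.numeric(tapply(draws, factor(grp, levels = seq_len(n)),
                                   sum))
    if (n == 0L) intensity <- numeric()
    data.frame(copies = copies, intensity = intensity)
  })
}

#' Sample a two-color detection table for a vesicle population
#'
#' Each vesicle draws a subtype from the mixture; every marker present in the
#' subtype is independently detected in each channel with probability
#' `1 - exp(-lambda_copies)` (the probability of carrying at least one
#' labeled copy).  Markers absent from the subtype are never detected.
#'
#' @param spec a [population_spec()].
#' @return A data.frame with one row per vesicle: `subtype` (subset name)
#'   and logical columns `<marker>_green` / `<marker>_red` for CD9, CD63,
#'   CD81.
#' @export
sample_two_color_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(spec$seed, {
    n <- spec$n_vesicles
    w <- spec$subtype_weights
    d <- 1 - exp(-spec$lambda_copies)
    cols <- as.vector(outer(markers3, c("green", "red"), paste, sep = "_"))
    out <- data.frame(subtype = character(n))
    for (cl in cols) out[[cl]] <- logical(n)
    if (n == 0L) return(out)
    sub_idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    out$subtype <- names(w)[sub_idx]
    members <- lapply(names(w), parse_subset)
    for (m in markers3) {
      has <- vapply(members, function(s) m %in% s, logical(1))[sub_idx]
      out[[paste0(m, "_green")]] <- has & (runif(n) < d)
      out[[paste0(m, "_red")]]   <- has & (runif(n) < d)
    }
    out
  })
}
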