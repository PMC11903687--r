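#' Fit a single log-normal to monomer intensities
#'
#' Maximum-likelihood log-normal fit to the intensity distribution of
#' surface-immobilized single fluorophores: the log-mean and log-SD are the
#' mean and SD of the log intensities.  This calibrates the monomer
#' component from which n-mer components are built.
#'
#' @param intensities positive numeric vector, length >= 50.
#' @return A list of class `"monomer_fit"`: `log_mean`, `log_sd`, `n`,
#'   `median` (= `exp(log_mean)`), and `ks_statistic` (Kolmogorov-Smirnov
#'   distance between the sample and the fitted log-normal, a
#'   goodness-of-fit summary).
#' @examples
#' x <- exp(rnorm(500, log(164), 0.3))
#' fit_monomer_lognormal(x)$median
#' @export
fit_monomer_lognormal <- function(intensities) {
  x <- as.numeric(intensities)
  if (any(!is.finite(x) | x <= 0))
    stop("intensities must be positive and finite")
  if (length(x) < 50L)
    stop("need at least 50 intensities to calibrate the monomer, got ",
         length(x))
  lx <- log(x)
  mu <- mean(lx)
  sigma <- sd(lx)
  if (!is.finite(sigma) || sigma < 1e-12)
    stop("degenerate sample: all intensities are (nearly) identical")
  ks <- suppressWarnings(
    stats::ks.test(x, stats::plnorm, meanlog = mu, sdlog = sigma))
  structure(list(log_mean = mu, log_sd = sigma, n = length(x),
                 median = exp(mu), ks_statistic = unname(ks$statistic)),
            class = "monomer_fit")
}

#' @export
print.monomer_fit <- function(x, ...) {
  cat(sprintf(
    "<monomer_fit> log-mean %.4f (median %.4g), log-sd %.4f, n = %d, KS = %.3f\n",
    x$log_mean, x$median, x$log_sd, x$n, x$ks_statistic))
  invisible(x)
}

# component densities (on intensity) for n = 1..n_max, evaluated at xs.
# scaled: monomer log-normal shifted by ln(n) in log space (same log-sd).
# convolution: exact n-fold convolution of the monomer density, computed on
# a shared linear grid via a power-of-two FFT (f_n = ifft(fft(f_1)^n)).
nmer_density_table <- function(xs, n_max, mu, sigma,
                               mode = c("scaled", "convolution")) {
  mode <- match.arg(mode)
  if (mode == "scaled")
    return(vapply(seq_len(n_max), function(n)
      stats::dlnorm(xs, meanlog = mu + log(n), sdlog = sigma),
      numeric(length(xs))))
  upper <- stats::qlnorm(1 - 1e-7, mu, sigma) * n_max * 1.2
  m <- 8192L
  dx <- upper / m
  grid <- (seq_len(m) - 0.5) * dx
  f1 <- stats::dlnorm(grid, mu, sigma)
  Fpad <- stats::fft(c(f1, rep(0, m)))
  out <- matrix(0, length(xs), n_max)
  for (n in seq_len(n_max)) {
    if (n == 1L) dens <- f1
    else {
      dens <- Re(stats::fft(Fpad^n, inverse = TRUE))[seq_len(m)] /
        (2 * m) * dx^(n - 1)
      dens <- pmax(dens, 0)
    }
    # grid for f_n is offset by (n-1)/2 * dx (sum of n half-offset grids)
    gn <- grid + (n - 1) * dx / 2
    out[, n] <- stats::approx(gn, dens, xout = xs, yleft = 0, yright = 0,
                              rule = 1)$y
  }
  out[is.na(out)] <- 0
  out
}

#' Fit an oligomer mixture to single-vesicle intensities
#'
#' Decomposes the single-vesicle intensity histogram as a non-negative
#' mixture of monomer, dimer, ..., `n_max`-mer components built from the
#' calibrated monomer log-normal.  In the default `"scaled"` construction
#' the n-mer component is the monomer density shifted by `ln n` in log space
#' (same log-SD), the standard approximation used in stepwise-bleaching
#' stoichiometry; `"convolution"` uses the exact n-fold convolution of the
#' monomer density instead (the two agree within the fit tolerance for
#' log-SD up to ~0.4).  Weights are obtained by non-negative least squares
#' of the density-normalized histogram (Freedman-Diaconis bin width) against
#' the component densities, then normalized to sum to 1; the mean copy
#' number is \eqn{\lambda = \sum_n n \pi_n}.
#'
#' @param intensities positive numeric vector, length >= 200.
#' @param monomer a [fit_monomer_lognormal()] result, or a list with
#'   `log_mean` and `log_sd`.
#' @param n_max largest oligomer considered (default 10).
#' @param mode `"scaled"` (default) or `"convolution"` component model.
#' @return A list of class `"stoichiometry_fit"`: `weights` (length
#'   `n_max`, simplex), `lambda`, `monomer`, `residual` (RMS difference
#'   between fitted and empirical bin densities), `n`, `mode`.
#' @export
fit_intensity_mixture <- function(intensities, monomer, n_max = 10L,
                                  mode = c("scaled", "convolution")) {
  mode <- match.arg(mode)
  x <- as.numeric(intensities)
  if (any(!is.finite(x) | x <= 0))
    stop("intensities must be positive and finite")
  if (length(x) < 200L)
    stop("need at least 200 intensities for a mixture fit, got ", length(x))
  check_count(n_max, "n_max", lower = 1L)
  mu <- monomer$log_mean
  sigma <- monomer$log_sd
  check_number(mu, "monomer$log_mean")
  check_number(sigma, "monomer$log_sd", lower = 1e-12)
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  occupied <- sum(h$counts > 0)
  if (occupied < n_max)
    stop(sprintf(
      "histogram has %d occupied bins for %d components: under-determined; supply more/wider data",
      occupied, n_max))
  dens <- h$density
  mids <- h$mids
  widths <- diff(h$breaks)
  C <- nmer_density_table(mids, n_max, mu, sigma, mode)
  # fit expected counts to observed counts with Poisson weights
  # (1/sqrt(count), floored at 1), which keeps empty tail bins informative
  # without letting them dominate
  A <- C * (length(x) * widths)
  b <- h$counts
  wts <- 1 / sqrt(pmax(b, 1))
  # a component with most of its probability mass beyond the observed
  # intensity range cannot carry real weight (its particles would have been
  # observed there); excluding such components keeps NNLS from inflating
  # their raw weights to fit a handful of tail counts
  in_range_mass <- colSums(C * widths)
  identifiable <- in_range_mass > 0.5
  w <- numeric(n_max)
  fit <- pracma::lsqnonneg(A[, identifiable, drop = FALSE] * wts, b * wts)
  w[identifiable] <- fit$x
  if (sum(w) <= 0)
    stop("mixture fit degenerate: all component weights zero")
  pi_n <- w / sum(w)
  lambda <- sum(seq_len(n_max) * pi_n)
  fitted <- as.numeric(C %*% w)
  structure(list(weights = pi_n, lambda = lambda,
                 monomer = list(log_mean = mu, log_sd = sigma),
                 residual = sqrt(mean((fitted - dens)^2)),
                 n = length(x), n_max = as.integer(n_max), mode = mode),
            class = "stoichiometry_fit")
}

#' @export
print.stoichiometry_fit <- function(x, ...) {
  cat(sprintf(
    "<stoichiometry_fit> lambda = %.3f copies/particle (n_max = %d, %s)\n",
    x$lambda, x$n_max, x$mode))
  cat("weights:", paste(sprintf("%d-mer %.3f", seq_along(x$weights),
                                x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Poisson detection fraction
#'
#' Probability that a vesicle carrying a Poisson(`lambda`) number of labeled
#' molecules carries at least one, i.e. the fraction of vesicles of that
#' class that is detectable at all: `1 - exp(-lambda)`.  At the measured
#' mean copy numbers of 4.2-4.8 per vesicle this is 98.5-99.2%, the basis
#' for treating the detected particles as essentially all vesicles carrying
#' the marker.
#'
#' @param lambda mean copy number (vectorized, must be >= 0).
#' @return Detection probability in `[0, 1)`.
#' @examples
#' poisson_detect_fraction(c(4.2, 4.8))
#' @export
poisson_detect_fraction <- function(lambda) {
  if (!is.numeric(lambda) || any(!is.finite(lambda)))
    stop("`lambda` must be numeric and finite")
  if (any(lambda < 0)) stop("`lambda` must be non-negative")
  1 - exp(-lambda)
}

# ---------------------------------------------------------------------------
# subtype mixtures over subsets of {CD9, CD63, CD81}

subset_names7 <- function() {
  subs <- list()
  for (k in 1:3)
    subs <- c(subs, utils::combn(markers3, k, simplify = FALSE))
  vapply(subs, paste, character(1), collapse = "+")
}

#' Subtype mixture over tetraspanin marker subsets
#'
#' A vesicle subtype is the subset of markers (CD9, CD63, CD81) it carries;
#' a population is a probability vector over the 7 non-empty subsets.
#'
#' @param weights named numeric vector; names are subsets like `"CD63"` or
#'   `"CD9+CD63+CD81"` (order inside a name is irrelevant); missing subsets
#'   get weight 0.  Must be non-negative and sum to 1.
#' @param residual,non_unique optional fit diagnostics attached by
#'   [fit_subtype_mixture()].
#' @return A list of class `"subtype_mixture"` with `weights` (named,
#'   canonical order), `residual`, `non_unique`.
#' @export
subtype_mixture <- function(weights, residual = NA_real_,
                            non_unique = FALSE) {
  canon <- subset_names7()
  w <- setNames(numeric(length(canon)), canon)
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("`weights` must be named by marker subsets")
  for (nm in names(weights)) {
    key <- paste(parse_subset(nm), collapse = "+")
    w[key] <- w[key] + weights[[nm]]
  }
  if (any(w < -1e-12)) stop("subtype weights must be non-negative")
  w <- pmax(w, 0)
  if (abs(sum(w) - 1) > 1e-6)
    stop(sprintf("subtype weights must sum to 1 (got %.8f)", sum(w)))
  structure(list(weights = w, residual = residual,
                 non_unique = non_unique),
            class = "subtype_mixture")
}

#' @export
print.subtype_mixture <- function(x, ...) {
  w <- x$weights[x$weights > 1e-9]
  cat("<subtype_mixture>",
      paste(sprintf("%s: %.3f", names(w), w), collapse = ", "), "\n")
  if (is.finite(x$residual))
    cat(sprintf("  fit residual %.3g%s\n", x$residual,
                if (isTRUE(x$non_unique)) " (non-unique solution)" else ""))
  invisible(x)
}

# membership matrix: subsets x markers
subset_membership <- function() {
  canon <- subset_names7()
  m <- vapply(markers3, function(mk)
    vapply(strsplit(canon, "+", fixed = TRUE), function(s) mk %in% s,
           logical(1)), logical(length(canon)))
  rownames(m) <- canon
  m
}

#' Predict the pairwise two-color colocalization table
#'
#' Forward model of the two-color colocalization experiment: entry
#' `[A, B]` is the percentage of particles detected with Halo-tagged marker
#' B (red) that are also detected with mGFP-tagged marker A (green),
#' \deqn{100 \cdot d_G \cdot \frac{\sum_{S \supseteq \{A,B\}} w_S}
#'       {\sum_{S \ni B} w_S}}
#' with detection independent across channels (`d_G`, `d_R` the per-channel
#' detection probabilities; `d_R` cancels in the ratio).
#'
#' @param mixture a [subtype_mixture()] (or its named weights vector).
#' @param detection_prob per-channel detection probability: a single value
#'   or `c(green, red)`; entries must be in (0, 1].
#' @return A 3x3 matrix of percentages; rows = green (mGFP) marker A,
#'   columns = red (Halo) marker B.
#' @examples
#' m <- subtype_mixture(c("CD63" = 0.5, "CD9+CD63+CD81" = 0.5))
#' predict_pairwise_table(m, 1)
#' @export
predict_pairwise_table <- function(mixture, detection_prob = 1) {
  if (!inherits(mixture, "subtype_mixture"))
    mixture <- subtype_mixture(mixture)
  d <- rep(as.numeric(detection_prob), length.out = 2)
  if (any(d <= 0 | d > 1))
    stop("detection probabilities must be in (0, 1]")
  d_G <- d[1]
  w <- mixture$weights
  mem <- subset_membership()
  tab <- matrix(NA_real_, 3, 3, dimnames = list(markers3, markers3))
  for (B in markers3) {
    denom <- sum(w[mem[, B]])
    if (denom <= 0)
      stop("marker ", B, " absent from all weighted subsets: ",
           "conditional column undefined")
    for (A in markers3)
      tab[A, B] <- 100 * d_G * sum(w[mem[, A] & mem[, B]]) / denom
  }
  tab
}

# linear system for the normalized table: for each ordered pair (A, B),
# sum_{S >= {A,B}} w_S - r_AB * sum_{S ∋ B} w_S = 0
subtype_design <- function(r) {
  mem <- subset_membership()
  rows <- list()
  for (B in markers3) for (A in markers3) {
    if (A == B) next
    rows[[length(rows) + 1L]] <-
      as.numeric(mem[, A] & mem[, B]) - r[A, B] * as.numeric(mem[, B])
  }
  do.call(rbind, rows)
}

solve_weights_support <- function(M, support, penalty = 100) {
  k <- length(support)
  A <- rbind(M[, support, drop = FALSE], rep(penalty, k))
  b <- c(rep(0, nrow(M)), penalty)
  fit <- pracma::lsqnonneg(A, b)
  w <- fit$x
  s <- sum(w)
  if (s < 1e-8) return(NULL)
  w / s
}

#' Infer the subtype mixture from a pairwise colocalization table
#'
#' Inverts [predict_pairwise_table()]: finds simplex weights over the 7
#' marker subsets whose predicted table matches the measured one in least
#' squares.  The table must be diagonal-normalized (each same-marker entry
#' = 100%, the positive-control normalization), which makes the fit
#' independent of the detection probabilities.  Because 6 off-diagonal
#' constraints cannot always pin down 6 free weights, near-optimal solutions
#' are searched over all weight supports and the sparsest support within 1%
#' of the best residual is returned; ties are flagged as non-unique.
#'
#' @param table 3x3 numeric matrix of percentages with rows/columns ordered
#'   CD9, CD63, CD81 (row = green marker, column = red marker); diagonal
#'   must equal 100 within `diag_tol`.
#' @param detection_prob kept for interface symmetry with
#'   [predict_pairwise_table()]; it cancels under diagonal normalization.
#' @param diag_tol allowed deviation of diagonal entries from 100
#'   (default 1).
#' @return A [subtype_mixture()] with `residual` (RMS over the six
#'   off-diagonal normalized entries, percentage points) and `non_unique`.
#' @export
fit_subtype_mixture <- function(table, detection_prob = 1, diag_tol = 1) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(3, 3)))
    stop("`table` must be a 3x3 matrix")
  if (is.null(rownames(tab))) dimnames(tab) <- list(markers3, markers3)
  tab <- tab[markers3, markers3]
  if (any(!is.finite(tab) | tab < 0))
    stop("table entries must be finite and non-negative")
  if (any(abs(diag(tab) - 100) > diag_tol))
    stop("diagonal entries must be normalized to 100 (+/- ", diag_tol, ")")
  r <- tab / 100
  M <- subtype_design(r)
  norm_tab <- function(w) {
    p <- predict_pairwise_table(subtype_mixture(w), 1)
    sweep(p, 2, diag(p), "/") * 100
  }
  resid_of <- function(w) {
    p <- norm_tab(w)
    off <- row(p) != col(p)
    sqrt(mean((p[off] - tab[off])^2))
  }
  canon <- subset_names7()
  w_full <- solve_weights_support(M, seq_along(canon))
  if (is.null(w_full)) stop("subtype fit failed: degenerate system")
  names(w_full) <- canon
  res_min <- resid_of(w_full)
  # sparsity tie-break: smallest support achieving a near-minimal residual
  near_tol <- res_min * 1.01 + 1e-6
  best_w <- w_full
  best_res <- res_min
  best_size <- sum(w_full > 1e-9)
  n_near_at_best <- 1L
  for (size in 1:6) {
    supports <- utils::combn(seq_along(canon), size, simplify = FALSE)
    found <- list()
    for (sup in supports) {
      w <- solve_weights_support(M, sup)
      if (is.null(w)) next
      wf <- setNames(numeric(length(canon)), canon)
      wf[sup] <- w
      # all markers must still be representable
      ok <- tryCatch({ resid_of(wf) }, error = function(e) NA_real_)
      if (!is.na(ok) && ok <= near_tol) found[[length(found) + 1L]] <-
          list(w = wf, res = ok)
    }
    if (length(found)) {
      res_vals <- vapply(found, `[[`, numeric(1), "res")
      j <- which.min(res_vals)
      best_w <- found[[j]]$w
      best_res <- res_vals[j]
      best_size <- size
      n_near_at_best <- length(found)
      break
    }
  }
  subtype_mixture(best_w, residual = best_res,
                  non_unique = n_near_at_best > 1L)
}
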