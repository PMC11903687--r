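# shared fixtures and independent oracles, built in code at test time

# circular binary mask on a square grid; rows = y, cols = x
disk_mask <- function(width, pixel_size, cx, cy, radius) {
  ctr <- seq(pixel_size / 2, width - pixel_size / 2, by = pixel_size)
  outer(ctr, ctr, function(y, x) sqrt((x - cx)^2 + (y - cy)^2) <= radius)
}

# exhaustive Otsu: scan every distinct value as threshold (v >= theta in)
brute_otsu <- function(v) {
  v <- as.numeric(v)
  best <- Inf; bt <- NA_real_
  for (th in sort(unique(v))) {
    lo <- v[v < th]; hi <- v[v >= th]
    if (!length(lo) || !length(hi)) next
    icv <- (length(hi) * mean((hi - mean(hi))^2) +
            length(lo) * mean((lo - mean(lo))^2)) / length(v)
    if (icv < best) { best <- icv; bt <- th }
  }
  list(threshold = bt, icv = best)
}

# exhaustive minimum cross-entropy threshold
brute_li <- function(v) {
  v <- as.numeric(v)
  best <- Inf; bt <- NA_real_
  for (th in sort(unique(v))[-1]) {
    lo <- v[v < th]; hi <- v[v >= th]
    eta <- -sum(lo) * log(mean(lo)) - sum(hi) * log(mean(hi))
    if (eta < best) { best <- eta; bt <- th }
  }
  list(threshold = bt, eta = best)
}

li_eta <- function(th, v) {
  lo <- v[v < th]; hi <- v[v >= th]
  -sum(lo) * log(mean(lo)) - sum(hi) * log(mean(hi))
}

# optimal frame-to-frame assignment by exhaustive permutation (<= 6 points)
brute_assignment <- function(prev, cur, max_disp) {
  np <- nrow(prev); nc <- nrow(cur)
  k <- min(np, nc)
  d <- sqrt(outer(prev[, 1], cur[, 1], "-")^2 +
            outer(prev[, 2], cur[, 2], "-")^2)
  best <- NULL; best_cost <- Inf
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (p in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
    out
  }
  idx_prev <- utils::combn(np, k, simplify = FALSE)
  idx_cur <- utils::combn(nc, k, simplify = FALSE)
  for (ip in idx_prev) for (ic in idx_cur) for (p in perms(ic)) {
    dd <- d[cbind(ip, p)]
    if (any(dd > max_disp)) next
    cost <- sum(dd)
    if (cost < best_cost) { best_cost <- cost; best <- cbind(ip, p) }
  }
  best
}
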