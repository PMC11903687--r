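#' Localization tables
#'
#' A localization table holds one row per detected fluorophore spot with its
#' acquisition frame (1-based), fitted coordinates in nm, and the per-spot
#' localization uncertainty (standard error of the fitted position) in nm.
#' This is the ThunderSTORM export model: frame, `x [nm]`, `y [nm]`,
#' `uncertainty [nm]`.  Extra columns are carried along untouched and ignored
#' by all computations.
#'
#' @param frame integer vector of 1-based frame indices.
#' @param x,y coordinates in nm.
#' @param uncertainty localization uncertainties in nm (strictly positive).
#' @param ... additional equal-length columns to carry (e.g. intensities).
#' @return A `data.frame` of class `"localization_table"`, sorted by frame.
#' @examples
#' localization_table(frame = c(1, 1, 2), x = c(0, 10, 5),
#'                    y = c(0, 5, 2), uncertainty = c(20, 18, 22))
#' @export
localization_table <- function(frame = integer(), x = numeric(),
                               y = numeric(), uncertainty = numeric(), ...) {
  df <- data.frame(frame = as.numeric(frame), x = as.numeric(x),
                   y = as.numeric(y), uncertainty = as.numeric(uncertainty),
                   ...)
  validate_localization_table(df)
  df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("localization_table", "data.frame")
  df
}

validate_localization_table <- function(df) {
  required <- c("frame", "x", "y", "uncertainty")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("localization table is missing column(s): ",
         paste(missing, collapse = ", "))
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop(sprintf("invalid localization table: %s in row(s) %s", what,
                   paste(head(idx, 10L), collapse = ", ")), call. = FALSE)
  }
  bad_row(!is.finite(df$x) | !is.finite(df$y), "non-finite coordinate")
  bad_row(!is.finite(df$frame) | df$frame < 1 | df$frame != round(df$frame),
          "frame not a positive integer")
  bad_row(!is.finite(df$uncertainty) | df$uncertainty <= 0,
          "non-positive uncertainty")
  invisible(df)
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("<localization_table> %d spots, frames %s-%s\n", nrow(x),
              if (nrow(x)) min(x$frame) else "-",
              if (nrow(x)) max(x$frame) else "-"))
  if (nrow(x)) print.data.frame(head(x, 6L))
  invisible(x)
}

# keep class through subsetting
#' @export
`[.localization_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) &&
      all(c("frame", "x", "y", "uncertainty") %in% names(out)))
    class(out) <- c("localization_table", "data.frame")
  out
}

#' CSV dialects for localization tables
#'
#' Maps the canonical column names to the header names used in a CSV file.
#' The default is the ThunderSTORM export dialect.
#'
#' @param frame,x,y,uncertainty header names in the file.
#' @return Named list of class `"loc_dialect"`.
#' @export
thunderstorm_dialect <- function(frame = "frame", x = "x [nm]", y = "y [nm]",
                                 uncertainty = "uncertainty [nm]") {
  structure(list(frame = frame, x = x, y = y, uncertainty = uncertainty),
            class = "loc_dialect")
}

#' Read a localization table from CSV
#'
#' Parses a ThunderSTORM-style CSV.  Rows violating the table invariants
#' (non-finite coordinates, non-positive uncertainties, bad frame indices)
#' abort with the offending row numbers.  Columns not named in the dialect
#' are preserved.
#'
#' @param path path to a CSV file with a header row.
#' @param dialect a [thunderstorm_dialect()] mapping canonical to file
#'   column names.
#' @return A [localization_table()].
#' @export
read_localizations <- function(path, dialect = thunderstorm_dialect()) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L && ncol(raw) == 0L) stop("empty file: ", path)
  for (canon in names(dialect)) {
    col <- dialect[[canon]]
    if (!col %in% names(raw))
      stop(sprintf("missing mandatory column '%s' in %s", col, path))
    v <- raw[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value in column '%s', row(s) %s", col,
                     paste(head(bad, 10L), collapse = ", ")))
      v <- vn
    }
    raw[[col]] <- v
  }
  extras <- raw[, setdiff(names(raw), unlist(dialect)), drop = FALSE]
  args <- c(list(frame = raw[[dialect$frame]], x = raw[[dialect$x]],
                 y = raw[[dialect$y]],
                 uncertainty = raw[[dialect$uncertainty]]),
            as.list(extras))
  do.call(localization_table, args)
}

#' Write a localization table to CSV
#'
#' Writes the canonical ThunderSTORM header (plus any extra columns) with at
#' least six significant digits, so that a write/read round trip reproduces
#' the table.
#'
#' @param table a [localization_table()].
#' @param path output path.
#' @param dialect column-name mapping, see [thunderstorm_dialect()].
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path,
                                dialect = thunderstorm_dialect()) {
  validate_localization_table(table)
  out <- as.data.frame(table)
  names(out)[match(c("frame", "x", "y", "uncertainty"), names(out))] <-
    unlist(dialect)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.finite(v) & v == round(v), format(v, scientific = FALSE),
           format(v, digits = 10))
  })
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Link per-frame detections into particle tracks
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames: all
#' candidate links shorter than `max_displacement` are considered in order of
#' increasing distance, and a detection joins at most one track.  Unlinked
#' detections start new tracks.  No gap closing is performed: a particle that
#' disappears for a frame restarts as a new track.  Downstream analyses only
#' need positions, not kinetic fidelity.
#'
#' @param detections a data.frame with columns `frame`, `x`, `y` (nm) and
#'   optionally `intensity`; a [localization_table()] works as-is.
#' @param max_displacement maximum allowed frame-to-frame step in nm.
#' @return A data.frame of class `"particle_tracks"` with columns `track`,
#'   `frame`, `x`, `y` (and `intensity` if supplied), sorted by track then
#'   frame.
#' @export
link_particles <- function(detections, max_displacement) {
  check_number(max_displacement, "max_displacement", lower = 0)
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  det <- as.data.frame(detections)
  det <- det[order(det$frame), , drop = FALSE]
  n <- nrow(det)
  track <- integer(n)
  if (n) {
    frames <- sort(unique(det$frame))
    idx_by_frame <- split(seq_len(n), det$frame)
    next_id <- 0L
    prev_idx <- integer(0)
    for (f in frames) {
      cur_idx <- idx_by_frame[[as.character(f)]]
      linked <- rep(FALSE, length(cur_idx))
      if (length(prev_idx) && f == prev_frame + 1) {
        dx <- outer(det$x[prev_idx], det$x[cur_idx], "-")
        dy <- outer(det$y[prev_idx], det$y[cur_idx], "-")
        d <- sqrt(dx^2 + dy^2)
        cand <- which(d <= max_displacement, arr.ind = TRUE)
        if (nrow(cand)) {
          cand <- cand[order(d[cand]), , drop = FALSE]
          used_prev <- rep(FALSE, length(prev_idx))
          for (k in seq_len(nrow(cand))) {
            i <- cand[k, 1]; j <- cand[k, 2]
            if (!used_prev[i] && !linked[j]) {
              track[cur_idx[j]] <- track[prev_idx[i]]
              used_prev[i] <- TRUE
              linked[j] <- TRUE
            }
          }
        }
      }
      for (j in which(!linked)) {
        next_id <- next_id + 1L
        track[cur_idx[j]] <- next_id
      }
      prev_idx <- cur_idx
      prev_frame <- f
    }
  }
  out <- data.frame(track = track, det, row.names = NULL)
  out <- out[order(out$track, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("particle_tracks", "data.frame")
  out
}
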