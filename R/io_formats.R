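#' Write an image stack as TIFF with a JSON sidecar
#'
#' Stores a probability-image sequence (or list of matrices) as a multi-page
#' TIFF.  TIFF pages hold values rescaled to `[0, 1]`; the sidecar JSON
#' (same path with extension `.json`) records the scale factor, pixel size
#' and ROI so [read_image_stack()] restores the original values and
#' geometry.
#'
#' @param stack a `palm_movie`, a list of `probability_image`s, or a list
#'   of numeric matrices.
#' @param path output TIFF path.
#' @param pixel_size,roi geometry recorded in the sidecar when `stack` is a
#'   bare matrix list.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, pixel_size = NULL, roi = NULL) {
  if (inherits(stack, "palm_movie")) stack <- stack$frames
  if (inherits(stack, "probability_image")) stack <- list(stack)
  stopifnot(is.list(stack), length(stack) >= 1L)
  if (inherits(stack[[1]], "probability_image")) {
    pixel_size <- stack[[1]]$pixel_size
    roi <- stack[[1]]$roi
    mats <- lapply(stack, `[[`, "values")
  } else mats <- stack
  top <- max(vapply(mats, max, numeric(1)), 0)
  scale <- if (top > 0) top else 1
  tiff::writeTIFF(lapply(mats, function(m) m / scale), path,
                  bits.per.sample = 32L)
  meta <- list(scale = scale, pixel_size = pixel_size,
               n_frames = length(mats),
               roi = if (!is.null(roi))
                 unclass(as_roi(roi))[c("xmin", "xmax", "ymin", "ymax")])
  jsonlite::write_json(meta, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path; the sidecar JSON is looked up next to it.
#' @return A list of `probability_image`s when geometry is available,
#'   otherwise a list of matrices.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pages <- lapply(pages, function(m) m * meta$scale)
    if (!is.null(meta$roi) && !is.null(meta$pixel_size)) {
      r <- as_roi(c(meta$roi$xmin, meta$roi$xmax, meta$roi$ymin,
                    meta$roi$ymax))
      return(lapply(pages, new_probability_image, roi = r,
                    pixel_size = meta$pixel_size))
    }
  }
  pages
}

#' Write a binary mask as an 8-bit TIFF
#'
#' @param mask logical matrix or a thresholding result.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, c("otsu_result", "li_result"))) mask <- mask$mask
  tiff::writeTIFF((mask * 1), path, bits.per.sample = 8L)
  invisible(path)
}

#' Write contours as GeoJSON-style JSON (nm coordinates)
#'
#' @param contours a [extract_contours()] result.
#' @param path output path.
#' @export
write_contours_json <- function(contours, path) {
  feats <- lapply(unclass(contours), function(p)
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(p, 1, c,
                                                         simplify = FALSE)))),
         properties = list(units = "nm")))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a distance or cross-correlation profile as CSV
#'
#' Columns: bin centre, observed and control relative frequencies, ratio.
#'
#' @param profile a `distance_profile` or `ccf_profile`.
#' @param path output path.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile)[, c("center", "observed", "control",
                                       "ratio")],
            path, row.names = FALSE)
  invisible(path)
}

#' Save / load generator specs as YAML
#'
#' @param spec a [field_spec()], [vesicle_spec()] or [population_spec()].
#' @param path YAML path.
#' @export
write_spec_yaml <- function(spec, path) {
  cls <- class(spec)[1]
  lst <- unclass(spec)
  if (!is.null(lst$cluster_centers))
    lst$cluster_centers <- apply(as.matrix(lst$cluster_centers), 1, c,
                                 simplify = FALSE)
  if (!is.null(lst$subtype_weights))
    lst$subtype_weights <- as.list(lst$subtype_weights)
  yaml::write_yaml(c(list(spec_type = cls), lst), path)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @export
read_spec_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  cls <- lst$spec_type
  lst$spec_type <- NULL
  if (!is.null(lst$cluster_centers))
    lst$cluster_centers <- do.call(rbind, lst$cluster_centers)
  if (!is.null(lst$subtype_weights))
    lst$subtype_weights <- unlist(lst$subtype_weights)
  maker <- switch(cls,
                  field_spec = field_spec,
                  vesicle_spec = vesicle_spec,
                  population_spec = population_spec,
                  stop("unknown spec_type: ", cls))
  do.call(maker, lst)
}
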