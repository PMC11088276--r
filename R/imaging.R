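# Nuclei segmentation and per-cell intensity quantification: the classical
# smooth -> threshold -> fill -> distance-transform watershed -> filter
# stack, with every step parameterized. EBImage supplies the primitives.

#' Segmentation parameters
#'
#' @param smoothing_sigma Gaussian pre-smoothing scale in px.
#' @param threshold `"otsu"` for a global Otsu threshold on the smoothed
#'   image, or a numeric intensity cutoff on the 0-1 scale.
#' @param min_area,max_area Retained object area bounds in px.
#' @param min_split_distance Minimum centre separation (px) at which
#'   touching nuclei are declumped by the watershed; smaller structures are
#'   treated as one object.
#' @param watershed_tolerance Minimum distance-map depth (px) between two
#'   basins for them to stay separate objects; larger values merge more.
#' @param exclude_border Drop objects touching the image border. Off by
#'   default for whole-well counting (tiles jointly cover the well); on for
#'   per-cell intensity work.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma = 1,
                                threshold = "otsu",
                                min_area = 10,
                                max_area = 2000,
                                min_split_distance = 4,
                                watershed_tolerance = 0.5,
                                exclude_border = FALSE) {
  if (min_area >= max_area) .fail_param("min_area must be < max_area")
  if (smoothing_sigma < 0) .fail_param("smoothing_sigma must be >= 0")
  if (min_split_distance < 1) .fail_param("min_split_distance must be >= 1")
  if (watershed_tolerance <= 0) .fail_param("watershed_tolerance must be > 0")
  if (!(identical(threshold, "otsu") ||
        (is.numeric(threshold) && length(threshold) == 1)))
    .fail_param("threshold must be \"otsu\" or a single numeric cutoff")
  structure(list(smoothing_sigma = smoothing_sigma, threshold = threshold,
                 min_area = min_area, max_area = max_area,
                 min_split_distance = min_split_distance,
                 watershed_tolerance = watershed_tolerance,
                 exclude_border = exclude_border),
            class = "segmentation_params")
}

.check_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    .fail_param("image must be a numeric matrix")
  if (any(dim(img) < 16))
    .fail_param("image must be at least 16x16 px")
  if (any(!is.finite(img)) || any(img < 0))
    .fail_param("image intensities must be finite and >= 0")
  invisible(img)
}

# Relabel a label matrix to consecutive 1..K in raster order of first
# occurrence (deterministic tie-break: lower original label / earlier pixel).
.relabel <- function(lab) {
  u <- unique(as.vector(lab))
  u <- sort(u[u > 0])
  if (length(u) == 0) return(list(labels = lab * 0L, n = 0L))
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- map[lab[nz]]
  list(labels = out, n = length(u))
}

#' Segment nuclei in a nuclear-stain image
#'
#' Deterministic pipeline: Gaussian smoothing, global threshold (Otsu or
#' fixed), hole filling, distance-transform watershed declumping, area
#' filtering and optional border exclusion. A constant (or fully saturated)
#' image yields zero objects with a QC flag rather than an error.
#'
#' @param img Numeric intensity matrix (values on a 0-1 scale; rescale
#'   integer images first, e.g. via [read_grayscale_image()]).
#' @param params A [segmentation_params()] list.
#' @return Object of class `nuclei_mask`: list with
#'   \describe{
#'     \item{labels}{integer label matrix, 0 = background, labels
#'       consecutive from 1;}
#'     \item{objects}{data.frame `label, area, centroid_row, centroid_col,
#'       touches_border` for retained objects;}
#'     \item{qc}{list of flags (`constant_image`, counts of objects dropped
#'       by each filter).}
#'   }
#' @export
segment_nuclei <- function(img, params = segmentation_params()) {
  .check_image(img)
  stopifnot(inherits(params, "segmentation_params"))
  qc <- list(constant_image = FALSE, dropped_small = 0L, dropped_large = 0L,
             dropped_border = 0L)

  rng <- range(img)
  if (diff(rng) < .Machine$double.eps) {
    qc$constant_image <- TRUE
    return(structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                          objects = .empty_objects(), qc = qc),
                     class = "nuclei_mask"))
  }

  x <- EBImage::Image(img)
  if (params$smoothing_sigma > 0)
    x <- EBImage::gblur(x, sigma = params$smoothing_sigma)
  thr <- if (identical(params$threshold, "otsu"))
    EBImage::otsu(x, range = c(0, 1)) else params$threshold
  mask <- x > thr
  if (!any(mask)) {
    return(structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                          objects = .empty_objects(), qc = qc),
                     class = "nuclei_mask"))
  }
  mask <- EBImage::fillHull(mask)
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                            ext = max(1L, as.integer(params$min_split_distance)))
  lab <- EBImage::imageData(lab)

  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$min_area & areas <= params$max_area)
  qc$dropped_small <- sum(areas > 0 & areas < params$min_area)
  qc$dropped_large <- sum(areas > params$max_area)

  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  if (params$exclude_border) {
    qc$dropped_border <- length(intersect(keep, border_labels))
    keep <- setdiff(keep, border_labels)
  }

  lab[!(lab %in% keep)] <- 0L
  rl <- .relabel(lab)
  labels <- rl$labels

  objects <- .object_table(labels, border_labels_old = NULL)
  structure(list(labels = labels, objects = objects, qc = qc),
            class = "nuclei_mask")
}

.empty_objects <- function() {
  data.frame(label = integer(), area = integer(),
             centroid_row = numeric(), centroid_col = numeric(),
             touches_border = logical())
}

.object_table <- function(labels, border_labels_old = NULL) {
  idx <- which(labels > 0)
  if (length(idx) == 0) return(.empty_objects())
  lb <- labels[idx]
  rw <- (idx - 1L) %% nrow(labels) + 1L
  cl <- (idx - 1L) %/% nrow(labels) + 1L
  area <- as.integer(tabulate(lb))
  cr <- tapply(rw, lb, mean)
  cc <- tapply(cl, lb, mean)
  on_border <- rw == 1L | rw == nrow(labels) | cl == 1L | cl == ncol(labels)
  tb <- tapply(on_border, lb, any)
  data.frame(label = seq_along(area), area = area,
             centroid_row = as.numeric(cr), centroid_col = as.numeric(cc),
             touches_border = as.logical(tb), row.names = NULL)
}

#' @export
print.nuclei_mask <- function(x, ...) {
  cat(sprintf("nuclei_mask: %d objects in a %dx%d image\n",
              nrow(x$objects), nrow(x$labels), ncol(x$labels)))
  if (x$qc$constant_image) cat("  QC: constant image, no segmentation\n")
  invisible(x)
}

#' Count nuclei across the image tiles covering one well
#'
#' @param images List of image matrices (e.g. the four fields jointly
#'   covering a well).
#' @param params A [segmentation_params()] list.
#' @return Integer total object count (sum over tiles).
#' @export
count_nuclei_in_well <- function(images, params = segmentation_params()) {
  if (!is.list(images) || length(images) == 0)
    .fail_param("images must be a nonempty list of image matrices")
  sum(vapply(images,
             function(im) nrow(segment_nuclei(im, params)$objects),
             integer(1)))
}

#' Per-cell signal intensity over segmented regions
#'
#' For each retained object, the mean (or other statistic) of a signal
#' channel over the object's region. With `dilate_radius > 0` the nuclear
#' mask is expanded into a cytoplasm-proxy region: the binary mask is
#' dilated by a disc and labels are propagated into the new territory
#' (Voronoi-style on the intensity landscape), so touching cells keep
#' distinct regions.
#'
#' @param signal_img Numeric matrix, same dimensions as the mask.
#' @param mask A `nuclei_mask` from [segment_nuclei()].
#' @param statistic `"mean"` (default), `"median"` or `"total"`.
#' @param dilate_radius Disc radius (px) for cytoplasmic expansion; 0 uses
#'   the nuclear region as-is.
#' @return data.frame `label, value`, one row per retained object.
#' @export
per_cell_intensity <- function(signal_img, mask,
                               statistic = c("mean", "median", "total"),
                               dilate_radius = 0) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(mask, "nuclei_mask"))
  if (!is.matrix(signal_img) || !all(dim(signal_img) == dim(mask$labels)))
    .fail_param("signal image and mask dimensions must match")
  labels <- mask$labels
  if (dilate_radius > 0 && any(labels > 0)) {
    kern <- EBImage::makeBrush(2 * as.integer(dilate_radius) + 1, shape = "disc")
    dil <- EBImage::dilate(labels > 0, kern)
    labels <- EBImage::imageData(EBImage::propagate(
      EBImage::Image(signal_img), seeds = EBImage::Image(labels), mask = dil))
    storage.mode(labels) <- "integer"
  }
  idx <- which(labels > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(), value = numeric()))
  f <- switch(statistic, mean = mean, median = stats::median, total = sum)
  vals <- tapply(signal_img[idx], labels[idx], f)
  data.frame(label = as.integer(names(vals)), value = as.numeric(vals),
             row.names = NULL)
}

#' Read / write grayscale images
#'
#' Thin wrappers over the tiff package: images are numeric matrices on a
#' 0-1 scale in memory and 16-bit grayscale TIFF on disk.
#'
#' @param path File path.
#' @rdname image_io
#' @export
read_grayscale_image <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  .check_image(m)
  m
}

#' @param img Numeric matrix with values in `[0, 1]`.
#' @rdname image_io
#' @export
write_grayscale_image <- function(img, path) {
  .check_image(img)
  tiff::writeTIFF(pmin(pmax(img, 0), 1), path, bits.per.sample = 16)
  invisible(path)
}

#' Write a label map as 16-bit TIFF and its object table as CSV
#'
#' @param mask A `nuclei_mask`.
#' @param tiff_path,csv_path Output paths (either may be `NULL` to skip).
#' @export
write_nuclei_mask <- function(mask, tiff_path = NULL, csv_path = NULL) {
  stopifnot(inherits(mask, "nuclei_mask"))
  if (!is.null(tiff_path))
    tiff::writeTIFF(mask$labels / 65535, tiff_path, bits.per.sample = 16)
  if (!is.null(csv_path))
    utils::write.csv(mask$objects, csv_path, row.names = FALSE)
  invisible(mask)
}
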