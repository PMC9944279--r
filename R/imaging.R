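#' Imaging configuration
#'
#' Settings for the fixed detection pipeline
#' flatten -> (channel subtraction if RGB) -> binarize -> extract -> filter.
#'
#' @param pixel_scale physical length per pixel, in `unit`.
#' @param unit length unit of areas/ECDs emitted: `"um"` for filter
#'   micrographs (default min ECD 3 um), `"mm"` for tank shadowgraphs
#'   (aggregate analyses use min ECD 0.4 mm).
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param threshold_value for `"fixed"`: intensity in original units; pixels
#'   darker than or equal to this value (before inversion) are foreground.
#' @param min_ecd lower ECD cutoff in `unit`; particles exactly at the
#'   cutoff are kept (closed bound).
#' @param max_ecd optional upper ECD cutoff in `unit` (closed), default Inf.
#' @param connectivity pixel connectivity for component labeling, 4 or 8
#'   (default 8).
#' @param exclude_border drop components touching the frame border,
#'   default FALSE.
#' @param imaged_volume_L reference volume for suspension imaging
#'   (concentrations per litre).
#' @param filtered_volume_mL filtered volume for filter micrographs
#'   (concentrations per mL).
#' @param filter_area_fraction fraction of the filter area covered by the
#'   inspected fields of view (used to scale counts to the whole filter).
#' @param flatten_sigma Gaussian sigma (pixels) for background estimation;
#'   default `NULL` lets [flatten_background()] pick max(dim)/8. Should be
#'   at least ~5x the largest expected blob diameter.
#' @param denoise_sigma Gaussian sigma (pixels) of a light denoising blur
#'   applied before inversion and thresholding; default 0 (off) keeps
#'   clean scenes pixel-exact. A sigma of ~1 px stabilises the global
#'   Otsu threshold on noisy frames, where the broad background mode can
#'   otherwise dominate the histogram.
#' @return a validated list of class `agg_imaging_config`.
#' @export
imaging_config <- function(pixel_scale = 1, unit = c("um", "mm"),
                           threshold_method = c("otsu", "fixed"),
                           threshold_value = NULL,
                           min_ecd = 3, max_ecd = Inf,
                           connectivity = 8, exclude_border = FALSE,
                           imaged_volume_L = NULL, filtered_volume_mL = NULL,
                           filter_area_fraction = NULL,
                           flatten_sigma = NULL, denoise_sigma = 0) {
  unit <- match.arg(unit)
  threshold_method <- match.arg(threshold_method)
  check_number(pixel_scale, "pixel_scale", function(v) v > 0, "> 0")
  if (threshold_method == "fixed") {
    check_number(threshold_value, "threshold_value")
  }
  check_number(min_ecd, "min_ecd", function(v) v >= 0, ">= 0")
  if (!identical(max_ecd, Inf)) check_number(max_ecd, "max_ecd",
                                             function(v) v > 0, "> 0")
  if (!connectivity %in% c(4, 8)) {
    abort_config("`connectivity` must be 4 or 8")
  }
  if (!is.null(imaged_volume_L)) {
    check_number(imaged_volume_L, "imaged_volume_L", function(v) v > 0, "> 0")
  }
  if (!is.null(filtered_volume_mL)) {
    check_number(filtered_volume_mL, "filtered_volume_mL",
                 function(v) v > 0, "> 0")
  }
  if (!is.null(filter_area_fraction)) {
    check_number(filter_area_fraction, "filter_area_fraction",
                 function(v) v > 0 && v <= 1, "in (0, 1]")
  }
  if (!is.null(flatten_sigma)) {
    check_number(flatten_sigma, "flatten_sigma", function(v) v > 0, "> 0")
  }
  check_number(denoise_sigma, "denoise_sigma", function(v) v >= 0, ">= 0")
  structure(list(
    pixel_scale = pixel_scale, unit = unit,
    threshold_method = threshold_method, threshold_value = threshold_value,
    min_ecd = min_ecd, max_ecd = max_ecd,
    connectivity = as.integer(connectivity), exclude_border = exclude_border,
    imaged_volume_L = imaged_volume_L, filtered_volume_mL = filtered_volume_mL,
    filter_area_fraction = filter_area_fraction, flatten_sigma = flatten_sigma,
    denoise_sigma = denoise_sigma
  ), class = "agg_imaging_config")
}

#' Correct an image for uneven background illumination
#'
#' Estimates the low-frequency illumination component with a large-kernel
#' Gaussian blur, subtracts it, and restores the original mean intensity.
#' A constant image is returned unchanged, and blob/background contrast
#' sign is preserved.
#'
#' @param image single-channel numeric matrix.
#' @param sigma Gaussian sigma in pixels; default max(dim)/8 (large relative
#'   to any particle so particles survive the correction).
#' @return matrix of the same size with the illumination ramp removed and
#'   the mean intensity preserved.
#' @export
flatten_background <- function(image, sigma = NULL) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort_config("`image` must be a single-channel numeric matrix")
  }
  if (diff(range(image)) == 0) return(image)
  sigma <- sigma %||% (max(dim(image)) / 8)
  # the Gaussian brush spans ~6 sigma and must fit inside the frame
  sigma <- min(sigma, (min(dim(image)) - 3) / 6.2)
  # replicate boundary: a circular boundary would wrap the illumination
  # ramp around the frame and ruin the estimate near the edges
  bg <- EBImage::gblur(image, sigma = sigma, boundary = "replicate")
  flat <- image - bg
  flat + mean(image) - mean(flat)
}

#' Subtract the blue channel from the red channel
#'
#' Pixelwise max(R - B, 0). On stained brightfield micrographs this removes
#' chlorophyll-related (red-dominant) areas and diatom cell outlines,
#' leaving blue-stained polymer particles dark against the background.
#'
#' @param rgb_image rows x cols x 3 numeric array (R, G, B).
#' @return single-channel matrix.
#' @examples
#' px <- array(c(200, 120, 50) / 255, dim = c(1, 1, 3))
#' subtract_channels(px) * 255 # 150
#' @export
subtract_channels <- function(rgb_image) {
  if (!is.array(rgb_image) || length(dim(rgb_image)) != 3 ||
      dim(rgb_image)[3] != 3) {
    abort_config("`rgb_image` must be a rows x cols x 3 array")
  }
  out <- pmax(rgb_image[, , 1] - rgb_image[, , 3], 0)
  dim(out) <- dim(rgb_image)[1:2]
  out
}

#' Invert an image and apply a global threshold
#'
#' The image is reversed in color (`max(image) - image`, so dark particles
#' become bright) and a single global threshold is applied; foreground
#' (TRUE) pixels are particles. With `"otsu"` the threshold is computed on
#' the inverted image via Otsu's method over its own intensity range, which
#' makes the mask invariant to adding a constant to the image. A
#' single-valued image cannot be thresholded by Otsu and raises an error
#' rather than returning a silently empty mask.
#'
#' @param image single-channel numeric matrix.
#' @param config an [imaging_config()]; uses `threshold_method` and
#'   `threshold_value`.
#' @return logical matrix mask (TRUE = particle), with the chosen threshold
#'   attached as attribute `"threshold"` (in original intensity units).
#' @export
binarize <- function(image, config = imaging_config()) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort_config("`image` must be a single-channel numeric matrix")
  }
  if (config$denoise_sigma > 0) {
    image <- EBImage::gblur(image, sigma = config$denoise_sigma)
  }
  inv <- max(image) - image
  if (config$threshold_method == "otsu") {
    if (diff(range(image)) == 0) {
      abort_config("cannot apply Otsu threshold to a single-valued image")
    }
    thr_inv <- EBImage::otsu(EBImage::Image(inv), range = range(inv))
    mask <- inv > thr_inv
    thr_orig <- max(image) - thr_inv
  } else {
    # fixed threshold is specified in original intensity: pixels at or
    # below the value are particles
    mask <- image <= config$threshold_value
    thr_orig <- config$threshold_value
  }
  structure(mask, threshold = thr_orig)
}

# Two-pass connected-component labeling with union-find; 4- or
# 8-connectivity. Operates on the (usually sparse) foreground only.
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  nxt <- 0L
  offs <- if (connectivity == 8) {
    list(c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(-1L, 1L))
  } else {
    list(c(-1L, 0L), c(0L, -1L))
  }
  idx <- which(mask)
  if (length(idx) == 0) return(labels)
  # column-major order guarantees up/left (and diagonal) neighbours are
  # already labeled when visited
  for (p in idx) {
    i <- ((p - 1L) %% nr) + 1L
    j <- ((p - 1L) %/% nr) + 1L
    neigh <- integer(0)
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc && labels[ii, jj] > 0L) {
        neigh <- c(neigh, labels[ii, jj])
      }
    }
    if (length(neigh) == 0) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      labels[i, j] <- nxt
    } else {
      roots <- vapply(unique(neigh), find, integer(1))
      r <- min(roots)
      labels[i, j] <- r
      for (x in roots) parent[x] <- r
    }
  }
  # resolve chains and relabel compactly
  roots <- vapply(seq_len(nxt), find, integer(1))
  compact <- match(roots, sort(unique(roots)))
  labels[labels > 0L] <- compact[labels[labels > 0L]]
  labels
}

#' Measure particles from a binary mask
#'
#' Labels connected components with the configured connectivity and
#' measures each: pixel count, area `A = npix * pixel_scale^2`, equivalent
#' circular diameter `ECD = 2 sqrt(A / pi)`, and intensity-free centroid in
#' pixel coordinates.
#'
#' @param mask logical matrix (TRUE = particle).
#' @param config an [imaging_config()].
#' @param frame frame number recorded in the output, default 1.
#' @return tibble of detections: `id`, `frame`, `npix`, `area`, `ecd`,
#'   `x_px`, `y_px`, `unit`.
#' @export
extract_particles <- function(mask, config = imaging_config(), frame = 1L) {
  if (!is.matrix(mask) || !is.logical(c(mask[1]))) {
    storage.mode(mask) <- "logical"
  }
  labels <- label_components(mask, config$connectivity)
  n <- max(labels)
  if (n == 0) {
    return(tibble(id = integer(), frame = integer(), npix = integer(),
                  area = numeric(), ecd = numeric(),
                  x_px = numeric(), y_px = numeric(), unit = character()))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  i <- ((idx - 1L) %% nrow(mask)) + 1L
  j <- ((idx - 1L) %/% nrow(mask)) + 1L
  npix <- tabulate(lab, nbins = n)
  # centroids of pixel centers (pixel (i,j) center at (j - 0.5, i - 0.5))
  x <- as.numeric(rowsum(j - 0.5, lab)[, 1]) / npix
  y <- as.numeric(rowsum(i - 0.5, lab)[, 1]) / npix
  keep <- rep(TRUE, n)
  if (isTRUE(config$exclude_border)) {
    border <- unique(lab[i == 1L | i == nrow(mask) | j == 1L | j == ncol(mask)])
    keep[border] <- FALSE
  }
  area <- npix * config$pixel_scale^2
  tibble(id = seq_len(n), frame = as.integer(frame), npix = npix,
         area = area, ecd = ecd_from_area(area),
         x_px = x, y_px = y, unit = config$unit)[keep, ] %>%
    mutate(id = row_number())
}

#' Apply the ECD size filter to detections
#'
#' Keeps particles with `min_ecd <= ECD <= max_ecd` (closed bounds; a
#' particle exactly at the cutoff is kept). Idempotent. Units declared in
#' the detections must match the configuration.
#'
#' @param detections tibble from [extract_particles()].
#' @param config an [imaging_config()].
#' @return the filtered tibble.
#' @export
filter_particles <- function(detections, config = imaging_config()) {
  if (!all(c("ecd", "unit") %in% names(detections))) {
    abort_config("`detections` must have `ecd` and `unit` columns")
  }
  units <- unique(detections$unit)
  if (length(units) > 0 && !identical(units, config$unit)) {
    abort_config("unit mismatch: detections in '", paste(units, collapse = ","),
                 "' but config declares '", config$unit, "'")
  }
  dplyr::filter(detections, .data$ecd >= config$min_ecd,
                .data$ecd <= config$max_ecd)
}

#' Convert a particle count to a concentration
#'
#' For suspension imaging (`imaged_volume_L` set) the count is divided by
#' the imaged volume, giving particles per litre. For filter micrographs
#' (`filtered_volume_mL` set) the count over the inspected fields is first
#' scaled up by the covered filter-area fraction and then divided by the
#' filtered volume, giving particles per mL.
#'
#' @param count non-negative particle count.
#' @param config an [imaging_config()] with exactly one reference volume set.
#' @return concentration (per L for suspensions, per mL for filters).
#' @examples
#' to_concentration(21, imaging_config(imaged_volume_L = 0.7))           # 30 / L
#' to_concentration(12, imaging_config(filtered_volume_mL = 2,
#'                                     filter_area_fraction = 0.1))      # 60 / mL
#' @export
to_concentration <- function(count, config) {
  if (!is.numeric(count) || any(count < 0)) {
    abort_config("`count` must be non-negative")
  }
  has_susp <- !is.null(config$imaged_volume_L)
  has_filt <- !is.null(config$filtered_volume_mL)
  if (has_susp == has_filt) {
    abort_config("set exactly one of `imaged_volume_L` or `filtered_volume_mL`")
  }
  if (has_susp) {
    count / config$imaged_volume_L
  } else {
    frac <- config$filter_area_fraction %||% 1
    (count / frac) / config$filtered_volume_mL
  }
}

#' Run the full detection pipeline on one image or a frame list
#'
#' Fixed order: background flattening, channel subtraction (RGB input
#' only), inversion + global threshold, connected-component measurement,
#' ECD size filter.
#'
#' @param image numeric matrix (grayscale), rows x cols x 3 array (RGB), or
#'   a list of such frames.
#' @param config an [imaging_config()].
#' @return tibble of detections over all frames (column `frame` indexes the
#'   input list).
#' @export
detect_particles <- function(image, config = imaging_config()) {
  frames <- if (is.list(image)) image else list(image)
  out <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    img <- frames[[f]]
    if (is.array(img) && length(dim(img)) == 3) {
      for (ch in 1:3) {
        img[, , ch] <- flatten_background(img[, , ch], config$flatten_sigma)
      }
      img <- subtract_channels(img)
    } else {
      img <- flatten_background(img, config$flatten_sigma)
    }
    mask <- binarize(img, config)
    out[[f]] <- extract_particles(mask, config, frame = f)
  }
  filter_particles(bind_rows(out), config) %>%
    mutate(id = row_number())
}

#' Match detections to a ground-truth table
#'
#' Greedy nearest-centroid matching within a radius, per frame. Used to
#' score recall and precision of the detection stage on synthetic scenes.
#'
#' @param truth truth tibble (columns `frame` (optional), `x_px`, `y_px`,
#'   `r_px`).
#' @param detections detection tibble (columns `frame`, `x_px`, `y_px`).
#' @param max_dist_px maximum centroid distance counted as a match;
#'   default the truth blob radius.
#' @return list with `recall`, `precision`, `matches` (tibble truth_id,
#'   detection_id, frame, dist_px).
#' @export
match_detections <- function(truth, detections, max_dist_px = NULL) {
  if (nrow(truth) == 0) {
    return(list(recall = NA_real_,
                precision = if (nrow(detections) == 0) NA_real_ else 0,
                matches = tibble()))
  }
  if (!"frame" %in% names(truth)) truth$frame <- 1L
  if (!"frame" %in% names(detections)) detections$frame <- 1L
  matches <- list()
  used <- integer(0)
  for (k in seq_len(nrow(truth))) {
    cand <- detections[detections$frame == truth$frame[k] &
                         !seq_len(nrow(detections)) %in% used, , drop = FALSE]
    cand_idx <- which(detections$frame == truth$frame[k] &
                        !seq_len(nrow(detections)) %in% used)
    if (length(cand_idx) == 0) next
    dist <- sqrt((cand$x_px - truth$x_px[k])^2 + (cand$y_px - truth$y_px[k])^2)
    lim <- max_dist_px %||% truth$r_px[k]
    if (min(dist) <= lim) {
      j <- cand_idx[which.min(dist)]
      used <- c(used, j)
      matches[[length(matches) + 1]] <-
        tibble(truth_id = truth$id[k], detection_id = detections$id[j],
               frame = truth$frame[k], dist_px = min(dist))
    }
  }
  m <- bind_rows(matches)
  list(recall = nrow(m) / nrow(truth),
       precision = if (nrow(detections) > 0) nrow(m) / nrow(detections) else NA_real_,
       matches = m)
}
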