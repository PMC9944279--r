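#' Parameters of a synthetic imaging scene
#'
#' Describes how a population is rendered into images: a back-lit
#' shadowgraph frame (dark aggregates on a light background, one grayscale
#' channel) or a stained brightfield micrograph (RGB, blue-dominant polymer
#' particles and red-dominant cell bodies on a warm background).
#'
#' @param image_shape c(rows, cols) in pixels.
#' @param pixel_scale physical length of one pixel, in `unit`.
#' @param unit length unit of `pixel_scale` (and of truth areas/ECDs):
#'   `"mm"` for shadowgraph tank imaging, `"um"` for filter micrographs.
#' @param background background intensity in \[0, 1\].
#' @param blob_intensity intensity of rendered particles in \[0, 1\]; the
#'   contrast `abs(background - blob_intensity)` must exceed 3x `noise_sd`
#'   for a clean scene.
#' @param background_gradient amplitude of a linear illumination ramp added
#'   across the frame (grayscale units), default 0.
#' @param noise_sd sd of additive Gaussian pixel noise, default 0.
#' @param channel_mode `"shadowgraph_gray"` or `"stained_rgb"`.
#' @return a validated list of class `agg_scene_params`.
#' @export
scene_params <- function(image_shape = c(256, 256),
                         pixel_scale = 0.05,
                         unit = c("mm", "um"),
                         background = 0.85,
                         blob_intensity = 0.25,
                         background_gradient = 0,
                         noise_sd = 0,
                         channel_mode = c("shadowgraph_gray", "stained_rgb")) {
  unit <- match.arg(unit)
  channel_mode <- match.arg(channel_mode)
  if (!is.numeric(image_shape) || length(image_shape) != 2 ||
      any(image_shape < 8) || any(image_shape != round(image_shape))) {
    abort_config("`image_shape` must be two integer pixel dimensions >= 8")
  }
  check_number(pixel_scale, "pixel_scale", function(v) v > 0, "> 0")
  check_number(background, "background", function(v) v >= 0 && v <= 1, "in [0,1]")
  check_number(blob_intensity, "blob_intensity",
               function(v) v >= 0 && v <= 1, "in [0,1]")
  check_number(background_gradient, "background_gradient",
               function(v) v >= 0, ">= 0")
  check_number(noise_sd, "noise_sd", function(v) v >= 0, ">= 0")
  if (noise_sd > 0 && abs(background - blob_intensity) <= 3 * noise_sd) {
    abort_config("blob/background contrast must exceed 3x `noise_sd`")
  }
  structure(list(
    image_shape = as.integer(image_shape), pixel_scale = pixel_scale,
    unit = unit, background = background, blob_intensity = blob_intensity,
    background_gradient = background_gradient, noise_sd = noise_sd,
    channel_mode = channel_mode
  ), class = "agg_scene_params")
}

# Rasterize a disc: a pixel belongs to the disc iff its center lies inside.
# Pixel (i, j) has center (i - 0.5, j - 0.5) in pixel units (rows, cols).
disc_pixels <- function(shape, cx, cy, r_px) {
  rows <- pmax(1L, floor(cy - r_px)):pmin(shape[1], ceiling(cy + r_px))
  cols <- pmax(1L, floor(cx - r_px)):pmin(shape[2], ceiling(cx + r_px))
  grid <- expand.grid(i = rows, j = cols)
  inside <- (grid$i - 0.5 - cy)^2 + (grid$j - 0.5 - cx)^2 <= r_px^2
  grid[inside, , drop = FALSE]
}

add_scene_effects <- function(img, scene) {
  shape <- dim(img)
  if (scene$background_gradient > 0) {
    ramp <- matrix(rep(seq(0, scene$background_gradient, length.out = shape[2]),
                       each = shape[1]), nrow = shape[1])
    img <- img + ramp
  }
  if (scene$noise_sd > 0) {
    img <- img + matrix(rnorm(prod(shape), sd = scene$noise_sd),
                        nrow = shape[1])
  }
  img
}

# Draw non-overlapping disc centers by rejection sampling.
place_discs <- function(shape, r_px, margin = 1, max_tries = 400) {
  n <- length(r_px)
  cx <- cy <- numeric(n)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, r_px[k] + margin, shape[2] - r_px[k] - margin)
      y <- runif(1, r_px[k] + margin, shape[1] - r_px[k] - margin)
      if (k == 1 ||
          all((x - cx[seq_len(k - 1)])^2 + (y - cy[seq_len(k - 1)])^2 >
              (r_px[k] + r_px[seq_len(k - 1)] + 2)^2)) {
        cx[k] <- x; cy[k] <- y; ok <- TRUE; break
      }
    }
    if (!ok) {
      abort_config("could not place all particles without overlap; ",
                   "use a larger frame or fewer particles")
    }
  }
  list(cx = cx, cy = cy)
}

#' Render a population as a shadowgraph image sequence with ground truth
#'
#' Each aggregate is drawn as a dark disc on a light background (telecentric
#' back-lit imaging), distributed over as many frames as needed; optional
#' linear illumination gradient and Gaussian noise are added per frame. The
#' returned truth table records, per rendered aggregate, the frame, centroid
#' (pixel coordinates), rasterized pixel count, analytic area and ECD in
#' scene units.
#'
#' @param population table from [generate_aggregate_population()]; an empty
#'   population yields one pure-background frame and an empty truth table.
#' @param scene a [scene_params()] object (shadowgraph mode).
#' @param per_frame maximum aggregates rendered per frame, default 10.
#' @param seed integer RNG seed (placement and noise).
#' @return list with `frames` (list of matrices in \[0,1\]-ish intensity),
#'   `truth` (tibble), `scene`.
#' @export
generate_image_sequence <- function(population, scene = scene_params(),
                                    per_frame = 10, seed = 1L) {
  if (scene$channel_mode != "shadowgraph_gray") {
    abort_config("`scene` must use channel_mode = 'shadowgraph_gray'")
  }
  check_number(per_frame, "per_frame", function(v) v >= 1, ">= 1")
  check_number(seed, "seed", function(v) v == round(v), "integer")
  shape <- scene$image_shape

  n <- nrow(population)
  truth_cols <- c("id", "frame", "x_px", "y_px", "r_px", "npix",
                  "area", "ecd", "unit")
  if (n == 0) {
    frame <- matrix(scene$background, shape[1], shape[2])
    frame <- withr::with_seed(seed, add_scene_effects(frame, scene))
    truth <- tibble::as_tibble(setNames(
      list(integer(), integer(), numeric(), numeric(), numeric(), integer(),
           numeric(), numeric(), character()), truth_cols))
    return(list(frames = list(frame), truth = truth, scene = scene))
  }

  r_px <- (population$d_mm / 2) / scene$pixel_scale
  if (scene$unit == "um") r_px <- (population$d_mm * 1000 / 2) / scene$pixel_scale
  too_big <- 2 * r_px + 4 > min(shape)
  if (any(too_big)) {
    abort_config("aggregate(s) larger than the frame at this pixel scale: id ",
                 paste(population$id[too_big], collapse = ", "))
  }

  frame_of <- ceiling(seq_len(n) / per_frame)
  withr::with_seed(seed, {
    frames <- list()
    truth <- vector("list", max(frame_of))
    for (f in seq_len(max(frame_of))) {
      idx <- which(frame_of == f)
      img <- matrix(scene$background, shape[1], shape[2])
      pos <- place_discs(shape, r_px[idx])
      npix <- integer(length(idx))
      for (k in seq_along(idx)) {
        px <- disc_pixels(shape, pos$cx[k], pos$cy[k], r_px[idx[k]])
        img[cbind(px$i, px$j)] <- scene$blob_intensity
        npix[k] <- nrow(px)
      }
      frames[[f]] <- add_scene_effects(img, scene)
      d_unit <- if (scene$unit == "um") population$d_mm[idx] * 1000 else population$d_mm[idx]
      truth[[f]] <- tibble(
        id = population$id[idx], frame = f,
        x_px = pos$cx, y_px = pos$cy, r_px = r_px[idx], npix = npix,
        area = pi * (d_unit / 2)^2, ecd = d_unit, unit = scene$unit
      )
    }
    list(frames = frames, truth = bind_rows(truth), scene = scene)
  })
}

#' Render a stained filter micrograph (RGB) with ground truth
#'
#' Emulates brightfield micrographs of stained polymer particles on a
#' filter: polymer blobs are blue-dominant (R - B near zero after channel
#' subtraction), cell bodies red-dominant (high R - B), the background
#' mildly red-dominant. Channel arithmetic (`subtract_channels()`) followed
#' by inversion and thresholding therefore isolates the polymer particles
#' and removes cells.
#'
#' @param n_polymer,n_cells number of polymer blobs and cell bodies.
#' @param polymer_ecd_range,cell_ecd_range ECD ranges in scene units
#'   (defaults in um).
#' @param scene a [scene_params()] object with `channel_mode = "stained_rgb"`
#'   (unit um).
#' @param seed integer RNG seed.
#' @return list with `image` (rows x cols x 3 array), `truth` (tibble with
#'   `type` polymer/cell), `scene`.
#' @export
generate_stained_micrograph <- function(n_polymer = 5, n_cells = 0,
                                        polymer_ecd_range = c(4, 20),
                                        cell_ecd_range = c(5, 15),
                                        scene = scene_params(
                                          pixel_scale = 0.5, unit = "um",
                                          channel_mode = "stained_rgb"),
                                        seed = 1L) {
  if (scene$channel_mode != "stained_rgb") {
    abort_config("`scene` must use channel_mode = 'stained_rgb'")
  }
  check_number(n_polymer, "n_polymer", function(v) v >= 0 && v == round(v))
  check_number(n_cells, "n_cells", function(v) v >= 0 && v == round(v))
  check_number(seed, "seed", function(v) v == round(v), "integer")
  shape <- scene$image_shape

  withr::with_seed(seed, {
    n <- n_polymer + n_cells
    type <- rep(c("polymer", "cell"), c(n_polymer, n_cells))
    ecd <- c(
      if (n_polymer > 0) runif(n_polymer, polymer_ecd_range[1], polymer_ecd_range[2]),
      if (n_cells > 0) runif(n_cells, cell_ecd_range[1], cell_ecd_range[2])
    )
    r_px <- (ecd / 2) / scene$pixel_scale

    # channel intensities: background warm (R > B); polymer blue; cells red
    bg <- c(r = 0.80, g = 0.78, b = 0.55)
    polymer <- c(r = 0.45, g = 0.55, b = 0.75)
    cellcol <- c(r = 0.90, g = 0.40, b = 0.25)
    img <- array(rep(bg, each = prod(shape)), dim = c(shape, 3))

    truth <- tibble(id = integer(), type = character(), x_px = numeric(),
                    y_px = numeric(), r_px = numeric(), npix = integer(),
                    area = numeric(), ecd = numeric(), unit = character())
    if (n > 0) {
      pos <- place_discs(shape, r_px)
      npix <- integer(n)
      for (k in seq_len(n)) {
        px <- disc_pixels(shape, pos$cx[k], pos$cy[k], r_px[k])
        col <- if (type[k] == "polymer") polymer else cellcol
        for (ch in 1:3) img[cbind(px$i, px$j, ch)] <- col[ch]
        npix[k] <- nrow(px)
      }
      truth <- tibble(
        id = seq_len(n), type = type, x_px = pos$cx, y_px = pos$cy,
        r_px = r_px, npix = npix, area = pi * (ecd / 2)^2, ecd = ecd,
        unit = scene$unit
      )
    }
    if (scene$noise_sd > 0) {
      img <- img + array(rnorm(length(img), sd = scene$noise_sd), dim = dim(img))
    }
    list(image = img, truth = truth, scene = scene)
  })
}

#' Write an image stack and parameter echo to disk
#'
#' Frames are written as TIFF files (one per frame) together with the truth
#' table as CSV and a YAML echo of the scene parameters, so a rendered
#' data set is fully reproducible from its output directory.
#'
#' @param sequence result of [generate_image_sequence()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_image_sequence <- function(sequence, dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort_config("package 'tiff' is required to write image stacks")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (f in seq_along(sequence$frames)) {
    path <- file.path(dir, sprintf("frame_%03d.tiff", f))
    img <- pmin(pmax(sequence$frames[[f]], 0), 1)
    tiff::writeTIFF(img, path, bits.per.sample = 16)
    files <- c(files, path)
  }
  truth_path <- file.path(dir, "truth.csv")
  write.csv(sequence$truth, truth_path, row.names = FALSE)
  yaml_path <- file.path(dir, "scene.yaml")
  yaml::write_yaml(unclass(sequence$scene), yaml_path)
  invisible(c(files, truth_path, yaml_path))
}
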