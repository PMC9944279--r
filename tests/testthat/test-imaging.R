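test_that("background flattening removes a ramp but preserves the mean", {
  # uniform image unchanged
  u <- matrix(0.7, 60, 60)
  expect_identical(flatten_background(u), u)

  # blob + linear ramp: residual background variation well below the ramp
  base <- matrix(0.8, 120, 120)
  base[50:60, 50:60] <- 0.2
  ramp_amp <- 0.3
  ramp <- matrix(rep(seq(0, ramp_amp, length.out = 120), each = 120),
                 nrow = 120)
  flat <- flatten_background(base + ramp, sigma = 15)
  clean <- flatten_background(base, sigma = 15)
  bg_mask <- base == 0.8
  expect_lt(sd((flat - clean)[bg_mask]), 0.1 * ramp_amp)
  expect_equal(mean(flat), mean(base + ramp), tolerance = 1e-8)
  # contrast sign preserved: blob stays darker than surrounding background
  expect_lt(mean(flat[50:60, 50:60]), mean(flat[bg_mask]))
})

test_that("channel subtraction is max(R - B, 0)", {
  px <- function(r, b) array(c(r, 0.5, b), dim = c(1, 1, 3))
  expect_equal(subtract_channels(px(200/255, 50/255))[1, 1], 150/255)
  expect_equal(subtract_channels(px(50/255, 200/255))[1, 1], 0)
  gray <- array(0.4, dim = c(4, 4, 3))
  expect_true(all(subtract_channels(gray) == 0))
  expect_error(subtract_channels(matrix(1, 3, 3)), "3 array")
})

test_that("binarization inverts then thresholds, recovering truth exactly on clean scenes", {
  img <- matrix(0.85, 80, 80)
  truth_mask <- matrix(FALSE, 80, 80)
  truth_mask[10:20, 30:40] <- TRUE
  truth_mask[50:55, 60:70] <- TRUE
  img[truth_mask] <- 0.25
  mask <- binarize(img, mm_config())
  expect_identical(unname(mask == TRUE), unname(truth_mask))
})

test_that("Otsu masks are invariant to adding a constant", {
  set.seed(1)
  img <- matrix(0.8 + rnorm(400, sd = 0.01), 20, 20)
  img[5:10, 5:10] <- 0.2 + rnorm(36, sd = 0.01)
  m1 <- binarize(img, mm_config())
  m2 <- binarize(img + 0.07, mm_config())
  expect_identical(unname(m1 == TRUE), unname(m2 == TRUE))
})

test_that("single-valued images cannot be Otsu-thresholded", {
  expect_error(binarize(matrix(0.5, 10, 10), mm_config()), "single-valued")
  # fixed threshold handles the all-background frame instead
  m <- binarize(matrix(0.5, 10, 10),
                mm_config(threshold_method = "fixed", threshold_value = 0.3))
  expect_equal(sum(m), 0)
})

test_that("extracted disc measurements match the rasterization oracle", {
  mask <- matrix(FALSE, 60, 60)
  cx <- 30; cy <- 30; r <- 10
  for (i in 1:60) for (j in 1:60) {
    if ((i - 0.5 - cy)^2 + (j - 0.5 - cx)^2 <= r^2) mask[i, j] <- TRUE
  }
  cfg <- imaging_config(pixel_scale = 1, unit = "um", min_ecd = 0)
  det <- extract_particles(mask, cfg)
  oracle_npix <- raster_disc_count(60, 60, cx, cy, r)
  expect_equal(nrow(det), 1)
  expect_equal(det$npix, oracle_npix)
  expect_equal(det$area, oracle_npix) # 1 um/px
  # ~ pi r^2 within discretization, ECD ~ 20 um
  expect_equal(det$area, pi * r^2, tolerance = 0.02)
  expect_equal(det$ecd, 20, tolerance = 0.02)
  expect_equal(c(det$x_px, det$y_px), c(cx, cy), tolerance = 0.2)
})

test_that("empty masks give empty detection tables", {
  det <- extract_particles(matrix(FALSE, 10, 10), imaging_config())
  expect_equal(nrow(det), 0)
})

test_that("diagonally touching blobs split by connectivity", {
  mask <- matrix(FALSE, 8, 8)
  mask[2:3, 2:3] <- TRUE
  mask[4:5, 4:5] <- TRUE # touches the first only diagonally
  cfg8 <- imaging_config(pixel_scale = 1, unit = "um", min_ecd = 0,
                         connectivity = 8)
  cfg4 <- imaging_config(pixel_scale = 1, unit = "um", min_ecd = 0,
                         connectivity = 4)
  expect_equal(nrow(extract_particles(mask, cfg8)), 1)
  expect_equal(nrow(extract_particles(mask, cfg4)), 2)
})

test_that("4-connectivity labeling agrees with the EBImage reference", {
  set.seed(42)
  mask <- matrix(runif(2500) < 0.3, 50, 50)
  ours <- aggsink:::label_components(mask, connectivity = 4)
  ref <- EBImage::bwlabel(mask)
  # same partition: label images identical up to renumbering
  expect_equal(max(ours), max(ref))
  key <- paste(ours[mask], ref[mask])
  expect_equal(length(unique(key)), max(ours))
})

test_that("border exclusion drops components touching the frame edge", {
  mask <- matrix(FALSE, 20, 20)
  mask[1:3, 5:7] <- TRUE      # touches row 1
  mask[10:12, 10:12] <- TRUE  # interior
  cfg <- imaging_config(pixel_scale = 1, unit = "um", min_ecd = 0,
                        exclude_border = TRUE)
  expect_equal(nrow(extract_particles(mask, cfg)), 1)
})

test_that("the ECD size filter uses closed bounds and is idempotent", {
  det <- tibble::tibble(id = 1:3, frame = 1L, npix = 1L,
                        area = pi * (c(2.9, 3, 5) / 2)^2,
                        ecd = c(2.9, 3, 5),
                        x_px = 0, y_px = 0, unit = "um")
  cfg <- imaging_config(pixel_scale = 1, unit = "um", min_ecd = 3)
  kept <- filter_particles(det, cfg)
  expect_equal(kept$ecd, c(3, 5)) # boundary value kept
  expect_identical(filter_particles(kept, cfg), kept)

  # aggregate-scale rule: 0.39 mm removed at a 0.4 mm cutoff
  agg <- tibble::tibble(id = 1:2, frame = 1L, npix = 1L,
                        area = pi * (c(0.39, 0.41) / 2)^2,
                        ecd = c(0.39, 0.41), x_px = 0, y_px = 0, unit = "mm")
  expect_equal(filter_particles(agg, mm_config())$ecd, 0.41)

  # unit mismatch is an error
  expect_error(filter_particles(det, mm_config()), "unit mismatch")
})

test_that("every emitted detection satisfies the ECD-area relation", {
  pop <- generate_aggregate_population(
    population_params(n_aggregates = 12, d_range = c(0.5, 2), seed = 13))
  seq <- generate_image_sequence(pop, clean_scene(), seed = 13)
  det <- detect_particles(seq$frames, mm_config())
  expect_true(all(abs(det$ecd - 2 * sqrt(det$area / pi)) < 1e-9))
})

test_that("counts convert to concentrations by the declared reference volume", {
  expect_equal(to_concentration(21, imaging_config(imaged_volume_L = 0.7)), 30)
  expect_equal(
    to_concentration(12, imaging_config(filtered_volume_mL = 2,
                                        filter_area_fraction = 0.1)), 60)
  expect_equal(to_concentration(0, imaging_config(imaged_volume_L = 0.7)), 0)
  expect_error(imaging_config(imaged_volume_L = -1),
               class = "aggsink_config_error")
  expect_error(to_concentration(5, imaging_config()), "exactly one")
})

test_that("detection survives noise and illumination gradients at fixed seeds", {
  recalls <- precisions <- numeric(3)
  for (s in 1:3) {
    pop <- generate_aggregate_population(
      population_params(n_aggregates = 12, d_range = c(0.5, 2), seed = s))
    scene <- scene_params(image_shape = c(250, 250), pixel_scale = 0.05,
                          unit = "mm", background = 0.85,
                          blob_intensity = 0.25, background_gradient = 0.1,
                          noise_sd = 0.12) # 20% of the 0.6 contrast
    seq <- generate_image_sequence(pop, scene, per_frame = 4, seed = s)
    det <- detect_particles(seq$frames, mm_config(denoise_sigma = 1))
    m <- match_detections(seq$truth, det)
    recalls[s] <- m$recall
    precisions[s] <- m$precision
  }
  expect_true(all(recalls >= 0.95))
  expect_true(all(precisions >= 0.95))
})
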