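#' Build a geometric size-class grid
#'
#' Size classes in which each upper diameter is `ratio` times the lower:
#' edges `lower_anchor * ratio^k`, k = 0..n_bins, contiguous and strictly
#' increasing. The default anchor 0.35 mm with ratio 1.3 puts the smallest
#' class at 0.35-0.455 mm (0.35-0.46 at two decimals) and the eleventh
#' upper edge at 6.27 mm.
#'
#' @param lower_anchor lower edge of the smallest class, in mm, > 0.
#' @param ratio upper/lower ratio of each class, > 1 (default 1.3).
#' @param n_bins number of classes (default 11).
#' @return tibble of class `agg_bins` with columns `bin`, `lower`, `upper`,
#'   `width` (all mm).
#' @examples
#' build_bins(0.35, 1.3, 11)
#' @export
build_bins <- function(lower_anchor = 0.35, ratio = 1.3, n_bins = 11) {
  check_number(lower_anchor, "lower_anchor", function(v) v > 0, "> 0")
  check_number(ratio, "ratio", function(v) v > 1, "> 1")
  check_number(n_bins, "n_bins", function(v) v >= 1 && v == round(v),
               "positive integer")
  edges <- lower_anchor * ratio^(0:n_bins)
  out <- tibble(bin = seq_len(n_bins),
                lower = edges[-length(edges)],
                upper = edges[-1],
                width = diff(edges))
  class(out) <- c("agg_bins", class(out))
  out
}

bin_membership <- function(ecd_mm, bins) {
  edges <- c(bins$lower, bins$upper[nrow(bins)])
  # lower-closed, upper-open intervals
  k <- findInterval(ecd_mm, edges, left.open = FALSE)
  k[ecd_mm >= edges[length(edges)]] <- NA_integer_
  k[k == 0] <- NA_integer_
  k
}

#' Aggregate number concentration and size spectrum per size class
#'
#' Counts detections into the size-class grid (lower-closed, upper-open
#' intervals), converts to number concentration `N(d)` (# L^-1) using the
#' sample volume, and normalises by the class width to the size spectrum
#' `n(d) = N(d) / delta_d` (# L^-1 mm^-1). Detections outside the grid are
#' not silently dropped: their count is reported via a message and recorded
#' in the `n_out_of_range` attribute.
#'
#' @param detections tibble with an `ecd` column in mm (column `unit`, if
#'   present, must be "mm").
#' @param bins an [build_bins()] grid.
#' @param sample_volume_L sampled volume in litres, > 0.
#' @return tibble of class `agg_spectrum`: per class `bin`, `lower`,
#'   `upper`, `width`, `count`, `n_conc` (N(d), # L^-1), `n_spec` (n(d),
#'   # L^-1 mm^-1), `v_agg_mm3` (mean single-aggregate volume), `nvd_mm3_L`
#'   (volume spectrum, filled by [volume_spectrum()]).
#' @export
number_spectrum <- function(detections, bins, sample_volume_L) {
  check_number(sample_volume_L, "sample_volume_L", function(v) v > 0, "> 0")
  if (!"ecd" %in% names(detections)) {
    abort_config("`detections` must have an `ecd` column (mm)")
  }
  if ("unit" %in% names(detections) && nrow(detections) > 0 &&
      !all(detections$unit == "mm")) {
    abort_config("number_spectrum() expects ECD in mm; got unit '",
                 paste(unique(detections$unit), collapse = ","), "'")
  }
  k <- bin_membership(detections$ecd, bins)
  n_out <- sum(is.na(k))
  if (n_out > 0) {
    rlang::inform(sprintf(
      "number_spectrum: %d detection(s) outside the size grid were not binned",
      n_out))
  }
  nb <- nrow(bins)
  count <- tabulate(k[!is.na(k)], nbins = nb)
  vol <- sphere_volume_or_zero(detections$ecd)
  v_agg <- rep(0, nb)
  if (any(!is.na(k))) {
    sums <- rowsum(vol[!is.na(k)], k[!is.na(k)])
    v_agg[as.integer(rownames(sums))] <- sums[, 1] / count[as.integer(rownames(sums))]
  }
  out <- bins %>%
    as_tibble() %>%
    mutate(count = count,
           n_conc = count / sample_volume_L,
           n_spec = .data$n_conc / .data$width,
           v_agg_mm3 = v_agg,
           nvd_mm3_L = NA_real_)
  attr(out, "sample_volume_L") <- sample_volume_L
  attr(out, "n_out_of_range") <- n_out
  class(out) <- c("agg_spectrum", class(out))
  out
}

# sphere_volume() rejects non-positive diameters; spectra tolerate an empty
# detection table.
sphere_volume_or_zero <- function(d) {
  if (length(d) == 0) return(numeric(0))
  sphere_volume(d)
}

#' Volume spectrum per size class
#'
#' Fills `nvd = n(d) * V_agg * delta_d` (mm^3 L^-1), where `V_agg` is the
#' mean volume of the single aggregates actually observed in each class
#' (not the class midpoint); empty classes get 0. The sum of `nvd` over
#' classes equals the cumulative aggregate volume concentration of the
#' binned detections.
#'
#' @param spectrum result of [number_spectrum()].
#' @return the spectrum with `nvd_mm3_L` populated.
#' @export
volume_spectrum <- function(spectrum) {
  if (!inherits(spectrum, "agg_spectrum")) {
    abort_config("`spectrum` must come from number_spectrum()")
  }
  spectrum %>%
    mutate(nvd_mm3_L = .data$n_spec * .data$v_agg_mm3 * .data$width)
}

#' Log-transform a spectrum with the empty-bin sentinel
#'
#' Adds `log10_n_spec` and `log10_nvd` columns: log10 of the positive
#' values, with exactly -1.0 wherever the value is 0 (so empty classes stay
#' plottable on the log axis). Negative values are an error.
#'
#' @param spectrum result of [number_spectrum()] or [volume_spectrum()].
#' @param sentinel value substituted for log10(0), default -1.0.
#' @return the spectrum with log10 columns appended.
#' @export
log_transform_spectrum <- function(spectrum, sentinel = -1.0) {
  if (!inherits(spectrum, "agg_spectrum")) {
    abort_config("`spectrum` must come from number_spectrum()")
  }
  out <- spectrum %>%
    mutate(log10_n_spec = log10_with_sentinel(.data$n_spec, sentinel))
  if (!all(is.na(spectrum$nvd_mm3_L))) {
    out <- out %>%
      mutate(log10_nvd = log10_with_sentinel(.data$nvd_mm3_L, sentinel))
  }
  out
}

#' Cumulative aggregate volume concentration
#'
#' Sum of single-aggregate sphere volumes over the sample volume,
#' in mm^3 L^-1. Equals the sum of the volume spectrum over classes when
#' all detections fall inside the grid.
#'
#' @param detections tibble with `ecd` in mm.
#' @param sample_volume_L sampled volume in litres, > 0.
#' @return cumulative volume concentration, mm^3 L^-1.
#' @examples
#' cumulative_volume(tibble::tibble(ecd = c(1, 1)), 1) # ~1.047
#' @export
cumulative_volume <- function(detections, sample_volume_L) {
  check_number(sample_volume_L, "sample_volume_L", function(v) v > 0, "> 0")
  sum(sphere_volume_or_zero(detections$ecd)) / sample_volume_L
}
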