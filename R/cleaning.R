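# Background-cleaning segmentation: lightness-channel thresholding in
# CIELAB space, connected-component labelling, and rejection of
# components that are too small (debris, dust, paper fibres) or too far
# from the image centre (rulers and other staged objects). The surviving
# mask is multiplied with the original image to give a "cleaned" image.

#' Cleaning pipeline configuration
#'
#' @param stretch_percentiles c(low, high) percentiles (0-100) between
#'   which the lightness channel is linearly stretched to full range
#'   before thresholding. The high anchor must reach into the root
#'   brightness: roots typically cover only ~1-3% of a pouch image, so
#'   the default uses the 99.9th percentile, not the 99th.
#' @param threshold Integer 0-255, or `"otsu"` to pick the global
#'   threshold by Otsu's method on the stretched lightness histogram.
#' @param connectivity Pixel connectivity for component labelling, 4 or
#'   8. Thin diagonal roots need 8 to stay a single component.
#' @param min_area_px Components smaller than this many pixels are
#'   rejected. The default 200 is calibrated for 100 px/cm imagery
#'   (0.02 cm^2, i.e. 2 mm^2); scale it by `(pixels_per_cm / 100)^2`
#'   for other resolutions (see [default_cleaning_config()]).
#' @param max_center_dist_frac Components whose centroid is farther from
#'   the image centre than this fraction of the half-diagonal are
#'   rejected. The lenient default only removes extreme off-centre
#'   objects such as rulers at the image border.
#' @param keep_largest_always Keep the largest component unconditionally
#'   so that the root system itself can never be rejected.
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(stretch_percentiles = c(0.5, 99.9),
                            threshold = "otsu",
                            connectivity = 8,
                            min_area_px = 200,
                            max_center_dist_frac = 0.95,
                            keep_largest_always = TRUE) {
  sp <- stretch_percentiles
  if (length(sp) != 2 || sp[1] >= sp[2] || sp[1] < 0 || sp[2] > 100)
    stopf("stretch_percentiles must be increasing within 0-100")
  if (!identical(threshold, "otsu") &&
      (!is.numeric(threshold) || threshold < 0 || threshold > 255))
    stopf("threshold must be 'otsu' or a number in 0-255")
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  if (min_area_px < 1) stopf("min_area_px must be >= 1")
  if (max_center_dist_frac <= 0 || max_center_dist_frac > 1)
    stopf("max_center_dist_frac must be in (0, 1]")
  structure(list(stretch_percentiles = sp, threshold = threshold,
                 connectivity = connectivity, min_area_px = min_area_px,
                 max_center_dist_frac = max_center_dist_frac,
                 keep_largest_always = isTRUE(keep_largest_always)),
            class = "cleaning_config")
}

#' Cleaning configuration scaled to an image resolution
#'
#' Same defaults as [cleaning_config()] with `min_area_px` rescaled so
#' the area cut-off corresponds to the same physical size (2 mm^2) at
#' any resolution.
#'
#' @param pixels_per_cm Image scale.
#' @param ... Overrides passed to [cleaning_config()].
#' @export
default_cleaning_config <- function(pixels_per_cm = 100, ...) {
  args <- list(...)
  if (is.null(args$min_area_px))
    args$min_area_px <- max(1, round(200 * (pixels_per_cm / 100)^2))
  do.call(cleaning_config, args)
}

binary_mask <- function(mask, stage) {
  structure(list(mask = mask, stage = stage), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d (%s), %d foreground px\n",
              nrow(x$mask), ncol(x$mask), x$stage, sum(x$mask)))
  invisible(x)
}

# Otsu's threshold on 8-bit values: maximize between-class variance.
# Returns the threshold t such that foreground = value > t.
otsu_threshold <- function(v) {
  h <- tabulate(as.integer(v) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  which.max(sigma_b) - 1L  # threshold level (0-based)
}

#' Segment bright foreground from a pouch image
#'
#' Converts RGB to CIELAB and keeps the lightness channel, linearly
#' stretches it between the configured percentiles to the full 0-255
#' range (clipping outside), and binarizes at the configured global
#' threshold (Otsu's method by default).
#'
#' @param image A [pouch_image].
#' @param config A [cleaning_config()].
#' @return A `binary_mask` with stage `"raw-threshold"`.
#' @export
segment_foreground <- function(image, config = cleaning_config()) {
  stopifnot(inherits(image, "pouch_image"))
  px <- image$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  code <- as.vector(px[, , 1]) * 65536L + as.vector(px[, , 2]) * 256L +
    as.vector(px[, , 3])
  uc <- unique(code)
  rgb <- cbind(uc %/% 65536L, (uc %/% 256L) %% 256L, uc %% 256L) / 255
  L_u <- convertColor(rgb, from = "sRGB", to = "Lab")[, 1] * 255 / 100
  L <- matrix(L_u[match(code, uc)], H, W)

  q <- quantile(L, config$stretch_percentiles / 100, names = FALSE)
  if (q[2] > q[1]) {
    L <- (L - q[1]) / (q[2] - q[1]) * 255
    L[L < 0] <- 0
    L[L > 255] <- 255
  }

  thr <- config$threshold
  if (identical(thr, "otsu")) {
    if (var(as.vector(L)) == 0) {
      warnf("blank image (zero variance): falling back to threshold 127.5")
      thr <- 127.5
    } else {
      thr <- otsu_threshold(round(L))
    }
  }
  binary_mask(L > thr, "raw-threshold")
}

#' Label connected components of a binary mask
#'
#' @param mask A `binary_mask` or logical matrix.
#' @param connectivity 4 or 8.
#' @return An object of class `labeled_components`: `labels` (integer
#'   matrix, 0 = background) and `table` (data.frame with `label`,
#'   `area_px`, `centroid_row`, `centroid_col`).
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  if (!is.logical(m) || !is.matrix(m)) stopf("mask must be a logical matrix")
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  labels <- cc_label_cpp(m, as.integer(connectivity))
  n <- max(labels)
  if (n == 0) {
    tab <- data.frame(label = integer(0), area_px = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
  } else {
    idx <- which(labels > 0)
    lab <- labels[idx]
    area <- tabulate(lab, nbins = n)
    rows <- ((idx - 1L) %% nrow(m)) + 1L
    cols <- ((idx - 1L) %/% nrow(m)) + 1L
    tab <- data.frame(
      label = seq_len(n),
      area_px = area,
      centroid_row = as.vector(rowsum(as.numeric(rows), lab)) / area,
      centroid_col = as.vector(rowsum(as.numeric(cols), lab)) / area
    )
  }
  structure(list(labels = labels, table = tab),
            class = "labeled_components")
}

#' @export
print.labeled_components <- function(x, ...) {
  cat(sprintf("<labeled_components> %d components over %d px\n",
              nrow(x$table), sum(x$table$area_px)))
  invisible(x)
}

#' Filter labelled components by size and centre distance
#'
#' Keeps a component iff its area is at least `min_area_px` and its
#' centroid lies within `max_center_dist_frac` of the half-diagonal from
#' the image centre; with `keep_largest_always` the largest component is
#' retained unconditionally.
#'
#' @param components A `labeled_components` object.
#' @param image_shape c(H, W); defaults to the label map's shape.
#' @param config A [cleaning_config()].
#' @return A `binary_mask` with stage `"cleaned"`.
#' @export
filter_components <- function(components, image_shape = dim(components$labels),
                              config = cleaning_config()) {
  stopifnot(inherits(components, "labeled_components"))
  tab <- components$table
  H <- image_shape[1]; W <- image_shape[2]
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  half_diag <- sqrt(H^2 + W^2) / 2
  keep <- rep(FALSE, nrow(tab))
  if (nrow(tab) > 0) {
    d <- sqrt((tab$centroid_row - ctr[1])^2 + (tab$centroid_col - ctr[2])^2)
    keep <- tab$area_px >= config$min_area_px &
      d <= config$max_center_dist_frac * half_diag
    if (config$keep_largest_always)
      keep[which.max(tab$area_px)] <- TRUE
  }
  if (nrow(tab) > 0 && !any(keep))
    warnf("all components rejected: check threshold/min_area settings")
  kept_labels <- tab$label[keep]
  mask <- matrix(components$labels %in% kept_labels,
                 nrow(components$labels), ncol(components$labels))
  binary_mask(mask, "cleaned")
}

#' Segment and clean a pouch image
#'
#' Composition of [segment_foreground()], [label_components()] and
#' [filter_components()]; the final mask is multiplied with the original
#' image to produce the cleaned image.
#'
#' @param image A [pouch_image].
#' @param config A [cleaning_config()].
#' @return List with `cleaned_image` (a [pouch_image] with background
#'   zeroed), `cleaned_mask` and `raw_mask` (`binary_mask` objects), and
#'   `components`.
#' @export
clean_image <- function(image, config = cleaning_config()) {
  raw <- segment_foreground(image, config)
  comp <- label_components(raw, config$connectivity)
  cleaned <- filter_components(comp, dim(raw$mask), config)
  px <- image$pixels
  px[, , 1][!cleaned$mask] <- 0L
  px[, , 2][!cleaned$mask] <- 0L
  px[, , 3][!cleaned$mask] <- 0L
  out <- pouch_image(px, image$pixels_per_cm, id = image$id)
  list(cleaned_image = out, cleaned_mask = cleaned, raw_mask = raw,
       components = comp)
}
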