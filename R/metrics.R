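#' Per-class RGB calibration boxes
#'
#' Channel-wise min/max bounds for the mixed (green), unmixed-blue and
#' unmixed-yellow pixel classes. A pixel belongs to a class when all three
#' of its channels fall inside that class's box; the mixed box takes
#' precedence when boxes overlap.
#'
#' @param mixed,blue,yellow numeric length-6 vectors
#'   `(r_min, r_max, g_min, g_max, b_min, b_max)`, 0-255.
#' @return object of class `rgb_calibration`.
#' @export
rgb_calibration <- function(mixed, blue, yellow) {
  chk <- function(b, nm) {
    b <- as.numeric(b)
    if (length(b) != 6) stop(nm, ": need 6 bounds")
    if (any(b[c(1, 3, 5)] > b[c(2, 4, 6)]))
      stop(nm, ": min bound exceeds max")
    b
  }
  cal <- structure(list(mixed = chk(mixed, "mixed"), blue = chk(blue, "blue"),
                        yellow = chk(yellow, "yellow")),
                   class = "rgb_calibration")
  for (nm in c("blue", "yellow"))
    if (.boxes_overlap(cal$mixed, cal[[nm]]))
      warning("mixed and ", nm, " calibration boxes overlap")
  cal
}

.boxes_overlap <- function(a, b) {
  all(a[c(1, 3, 5)] <= b[c(2, 4, 6)] & b[c(1, 3, 5)] <= a[c(2, 4, 6)])
}

#' @export
print.rgb_calibration <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("  %-6s R[%g,%g] G[%g,%g] B[%g,%g]\n", nm,
                x[[nm]][1], x[[nm]][2], x[[nm]][3], x[[nm]][4],
                x[[nm]][5], x[[nm]][6]))
  invisible(x)
}

#' Default calibration matching the synthetic fixture anchors
#' @param margin box half-width around each anchor (intensity levels).
#' @export
default_calibration <- function(margin = 25) {
  a <- fixture_colors()
  box <- function(v) as.vector(rbind(v - margin, v + margin))
  rgb_calibration(mixed = box(a$mixed), blue = box(a$blue),
                  yellow = box(a$yellow))
}

#' Calibrate RGB class ranges from reference images
#'
#' Per class, the channel bounds are the `[p, 100-p]` percentiles of that
#' class's reference pixels, widened by `margin` levels — robust to a small
#' fraction of outlier pixels.
#'
#' @param pure_blue_img,pure_yellow_img,mixed_img H x W x 3 arrays (0-255)
#'   of single-class reference content.
#' @param p trim percentile (default 1).
#' @param margin widening margin (levels).
#' @return an [rgb_calibration()]; error if the mixed box overlaps an
#'   unmixed box after calibration.
#' @export
calibrate_rgb_ranges <- function(pure_blue_img, pure_yellow_img, mixed_img,
                                 p = 1, margin = 5) {
  bounds <- function(img) {
    out <- numeric(6)
    for (ch in 1:3) {
      q <- stats::quantile(img[, , ch], c(p / 100, 1 - p / 100),
                           names = FALSE, type = 1)
      out[2 * ch - 1] <- q[1] - margin
      out[2 * ch] <- q[2] + margin
    }
    out
  }
  cal <- list(mixed = bounds(mixed_img), blue = bounds(pure_blue_img),
              yellow = bounds(pure_yellow_img))
  for (nm in c("blue", "yellow"))
    if (.boxes_overlap(cal$mixed, cal[[nm]])) {
      ov <- prod(pmax(0, pmin(cal$mixed[c(2, 4, 6)], cal[[nm]][c(2, 4, 6)]) -
                        pmax(cal$mixed[c(1, 3, 5)], cal[[nm]][c(1, 3, 5)])))
      stop(sprintf(
        "mixed and %s boxes overlap after calibration (overlap volume %g)",
        nm, ov))
    }
  structure(cal, class = "rgb_calibration")
}

#' Square region of interest inside the channel
#'
#' The measurement window: a square of `side` um (default 380, inset from
#' the 400 um channel to avoid wall shadows), positioned by its center in
#' pixel coordinates.
#'
#' @param center_row,center_col ROI center (pixels).
#' @param side side length (um).
#' @param pixel_size um per pixel.
#' @return object of class `roi` with the covered pixel index ranges.
#' @export
roi <- function(center_row, center_col, side = 380, pixel_size = 1) {
  side_px <- round(side / pixel_size)
  if (side_px < 10) stop("ROI under 10 px: need a finer pixel size")
  half <- side_px %/% 2
  structure(list(rows = (center_row - half):(center_row + half - 1 +
                                               side_px %% 2),
                 cols = (center_col - half):(center_col + half - 1 +
                                               side_px %% 2),
                 side = side, pixel_size = pixel_size),
            class = "roi")
}

#' Classify ROI pixels into mixed / unmixed / unclassified
#'
#' Each pixel is tested against the mixed box first (precedence when boxes
#' overlap), then the blue and yellow unmixed boxes; pixels in no box are
#' unclassified. Counts always sum to the ROI pixel total.
#'
#' @param img H x W x 3 array (0-255).
#' @param roi_ a [roi()].
#' @param calib an [rgb_calibration()].
#' @return object of class `pixel_class_counts`: `n_mixed`, `n_unmixed`,
#'   `n_unclassified`, `total`.
#' @export
classify_pixels <- function(img, roi_, calib) {
  if (length(dim(img)) != 3 || dim(img)[3] < 3)
    stop("grayscale input: need an RGB image")
  stopifnot(inherits(roi_, "roi"), inherits(calib, "rgb_calibration"))
  if (min(roi_$rows) < 1 || max(roi_$rows) > dim(img)[1] ||
      min(roi_$cols) < 1 || max(roi_$cols) > dim(img)[2])
    stop("ROI extends beyond the image")
  R <- img[roi_$rows, roi_$cols, 1]
  G <- img[roi_$rows, roi_$cols, 2]
  B <- img[roi_$rows, roi_$cols, 3]
  inbox <- function(b) R >= b[1] & R <= b[2] & G >= b[3] & G <= b[4] &
    B >= b[5] & B <= b[6]
  mixed <- inbox(calib$mixed)
  unmixed <- (inbox(calib$blue) | inbox(calib$yellow)) & !mixed
  total <- length(R)
  structure(list(n_mixed = sum(mixed), n_unmixed = sum(unmixed),
                 n_unclassified = total - sum(mixed) - sum(unmixed),
                 total = total),
            class = "pixel_class_counts")
}

#' @export
print.pixel_class_counts <- function(x, ...) {
  cat(sprintf("<pixel_class_counts> mixed %d, unmixed %d, unclassified %d / %d\n",
              x$n_mixed, x$n_unmixed, x$n_unclassified, x$total))
  invisible(x)
}

#' Image-based mixing index from pixel counts
#'
#' MI = N_mixed / (N_mixed + N_unmixed), in [0, 1] (0 = unmixed co-flow,
#' 1 = fully mixed). Unclassified pixels are excluded from the denominator
#' and reported; a warning is raised when they exceed 10% of the ROI.
#'
#' @param counts a [classify_pixels()] result.
#' @return object of class `mix_index_result` with `value`, the counts and
#'   the unclassified fraction.
#' @export
mixing_index <- function(counts) {
  stopifnot(inherits(counts, "pixel_class_counts"))
  denom <- counts$n_mixed + counts$n_unmixed
  if (denom == 0) stop("no classified pixels: cannot evaluate the index")
  fu <- counts$n_unclassified / counts$total
  if (fu > 0.10)
    warning(sprintf("%.1f%% of ROI pixels unclassified", 100 * fu))
  structure(list(value = counts$n_mixed / denom, method = "image",
                 counts = counts, unclassified_fraction = fu),
            class = "mix_index_result")
}

#' @export
print.mix_index_result <- function(x, ...) {
  cat(sprintf("<mix_index_result> MI = %.4f (%s)\n", x$value, x$method))
  invisible(x)
}

#' Grid of measurement ROIs near a station
#'
#' Places `n` non-overlapping ROIs centered on the channel axis in axial
#' succession around the station column, inset from the walls (for a
#' 400 um channel and a 380 um ROI, 10 um each side).
#'
#' @param channel_mask logical H x W matrix marking channel pixels.
#' @param station_col image column (pixels) of the station.
#' @param n number of ROIs.
#' @param side ROI side (um).
#' @param pixel_size um per pixel.
#' @return list of [roi()] objects.
#' @export
roi_grid <- function(channel_mask, station_col, n = 3, side = 380,
                     pixel_size = 1) {
  side_px <- round(side / pixel_size)
  ch_rows <- which(rowSums(channel_mask) > 0)
  if (length(ch_rows) < side_px)
    stop(sprintf(
      "channel (%d px) narrower than the ROI (%d px): use a smaller side",
      length(ch_rows), side_px))
  inset <- (length(ch_rows) - side_px) %/% 2
  half <- side_px %/% 2
  center_row <- min(ch_rows) + inset + half
  ncol_img <- ncol(channel_mask)
  offs <- (seq_len(n) - (n + 1) / 2) * side_px
  lapply(offs, function(o) {
    cc <- min(max(round(station_col + o), half + 1), ncol_img - half)
    roi(center_row, cc, side, pixel_size)
  })
}

#' Mean mixing index per station from a micrograph series
#'
#' One row per station: mean and standard deviation of the image mixing
#' index over the ROI grid (three ROIs by default), plus the unclassified
#' pixel fraction.
#'
#' @param images list of H x W x 3 arrays (0-255), one per station.
#' @param stations station distances (mm), same length as `images`.
#' @param calib an [rgb_calibration()].
#' @param pixel_size um per pixel (single value or per image).
#' @param channel_masks optional list of logical masks; defaults to all
#'   image rows.
#' @param n number of ROIs per station.
#' @return data frame (station, mi_mean, mi_sd, unclassified).
#' @export
mi_vs_distance <- function(images, stations, calib, pixel_size,
                           channel_masks = NULL, n = 3) {
  if (length(images) != length(stations))
    stop("images and stations lengths differ")
  if (missing(pixel_size) || is.null(pixel_size))
    stop("pixel size metadata is required")
  pixel_size <- rep_len(pixel_size, length(images))
  rows <- lapply(seq_along(images), function(k) {
    img <- images[[k]]
    msk <- if (is.null(channel_masks)) matrix(TRUE, dim(img)[1], dim(img)[2])
    else channel_masks[[k]]
    rois <- roi_grid(msk, station_col = round(dim(img)[2] / 2), n = n,
                     pixel_size = pixel_size[k])
    mis <- vapply(rois, function(r) {
      mixing_index(classify_pixels(img, r, calib))$value
    }, numeric(1))
    uncl <- vapply(rois, function(r) {
      cnt <- classify_pixels(img, r, calib)
      cnt$n_unclassified / cnt$total
    }, numeric(1))
    data.frame(station = stations[k], mi_mean = mean(mis),
               mi_sd = stats::sd(mis), unclassified = mean(uncl))
  })
  do.call(rbind, rows)
}
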