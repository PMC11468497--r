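# Synthetic test inputs: analytic velocity fields, dye micrographs with
# known per-pixel classes, and a deterministic fixture bundle. These
# emulate the measurement inputs (blue/yellow dye co-flow imaged inside a
# 400 um channel) with exactly known ground truth; they model pixel
# classes, not dye photophysics.

#' Default color anchors of the synthetic dye micrographs
#'
#' Pure-blue, pure-yellow and mixed-green RGB anchors chosen so the three
#' calibration boxes stay disjoint under additive noise of sd <= 8 levels.
#' @return named list of RGB triplets (0-255).
#' @export
fixture_colors <- function() {
  list(blue = c(40, 70, 200), yellow = c(230, 215, 60),
       mixed = c(90, 170, 110))
}

#' Analytic channel flow field (plug or parabolic slot)
#'
#' Builds a straight-channel grid and fills it with the exact closed-form
#' profile: spatially constant u = Q/(W H) for `"plug"`, or the Poiseuille
#' slot parabola peaking at 1.5x the mean for `"parabolic_slot"`; v = 0.
#' Used as the independent oracle for the solver and the particle tracker.
#'
#' @param kind `"plug"` or `"parabolic_slot"`.
#' @param Q flow rate (uL/min).
#' @param section a [channel_section()].
#' @param length channel length (mm).
#' @param cell grid cell (um).
#' @return a `flow_field` (no pressure; residuals empty).
#' @export
analytic_field <- function(kind = c("plug", "parabolic_slot"), Q = 50,
                           section = channel_section(), length = 20,
                           cell = NULL) {
  kind <- match.arg(kind)
  if (Q < 0) stop("Q must be >= 0")
  path <- centerline_path(c(0, length), c(0, 0), section$width)
  grid <- build_sim_grid(path, cell = cell)
  ub <- mean_speed(Q, section)
  rows <- which(grid$mask[1, ] == 1L)
  W_mm <- length(rows) * grid$cell / 1000
  u <- matrix(0, grid$nx + 1, grid$ny)
  prof <- if (kind == "plug") rep(ub, length(rows)) else {
    yy <- (grid$yc[rows] - mean(grid$yc[rows]))   # mm from centerline
    1.5 * ub * (1 - (2 * yy / W_mm)^2)
  }
  for (i in seq_len(grid$nx + 1)) u[i, rows] <- prof
  v <- matrix(0, grid$nx, grid$ny + 1)
  uc <- (u[-1, , drop = FALSE] + u[-(grid$nx + 1), , drop = FALSE]) / 2
  uin <- numeric(grid$ny); uin[rows] <- prof
  structure(list(u = u, v = v, p = matrix(0, grid$nx, grid$ny),
                 speed = abs(uc) * ifelse(grid$mask == 1L, 1, NA),
                 uc = uc, vc = matrix(0, grid$nx, grid$ny),
                 Y = NULL, grid = grid, props = fluid_props(), Q = Q,
                 height = section$height,
                 inlet = list(uin = uin, rows = rows,
                              u_plug = if (kind == "plug") ub else 1.5 * ub),
                 resid = matrix(numeric(0), 0, 3), converged = TRUE,
                 steps = 0L, kind = kind),
            class = "flow_field")
}

#' Synthetic dye micrograph with known pixel classes
#'
#' Renders a plan-view channel band whose pixel class follows a transverse
#' mixing profile m(y) in [0, 1]: below `thresholds[1]` the pixel is
#' unmixed side A (blue), above `thresholds[2]` unmixed side B (yellow),
#' otherwise mixed (green). Pixel color is the class anchor plus additive
#' Gaussian noise clipped so every pixel stays inside its calibration box.
#' The exact per-pixel labels and class counts are returned as ground
#' truth.
#'
#' @param width_px,height_px image size in pixels.
#' @param channel_rows integer range of rows occupied by the channel; the
#'   rest is background (black).
#' @param m transverse mixing profile: function of y in [0, 1] (fraction
#'   across the channel) returning values in [0, 1], or a single number.
#' @param pixel_size um per pixel.
#' @param noise_sd additive RGB noise (intensity levels).
#' @param colors anchors, see [fixture_colors()].
#' @param thresholds class thresholds on m.
#' @param margin half-width of each class box around its anchor.
#' @param seed RNG seed.
#' @return object of class `micrograph_truth`: `img` (H x W x 3 array,
#'   0-255), `labels` (H x W character), `counts`, `pixel_size`,
#'   `channel_mask`.
#' @export
synthetic_micrograph <- function(width_px = 400, height_px = 400,
                                 channel_rows = NULL, m = 0.5,
                                 pixel_size = 1, noise_sd = 4,
                                 colors = fixture_colors(),
                                 thresholds = c(0.35, 0.65),
                                 margin = 20, seed = 1L) {
  if (is.null(channel_rows)) channel_rows <- seq_len(height_px)
  if (noise_sd > 0 && 3 * noise_sd > margin)
    stop("noise too large for the class box separation (3*sd > margin)")
  mf <- if (is.function(m)) m else function(y) rep(m, length(y))
  set.seed(seed)
  img <- array(0, dim = c(height_px, width_px, 3))
  labels <- matrix(NA_character_, height_px, width_px)
  yfrac <- (match(channel_rows, channel_rows) - 0.5) / length(channel_rows)
  mv <- mf(yfrac)
  stopifnot(all(mv >= 0 & mv <= 1))
  cls <- ifelse(mv < thresholds[1], "blue",
                ifelse(mv > thresholds[2], "yellow", "mixed"))
  for (k in seq_along(channel_rows)) {
    r <- channel_rows[k]
    anchor <- colors[[cls[k]]]
    px <- matrix(rep(anchor, each = width_px), width_px, 3)
    if (noise_sd > 0) {
      nz <- matrix(stats::rnorm(width_px * 3, 0, noise_sd), width_px, 3)
      nz <- pmin(pmax(nz, -margin), margin)
      px <- px + nz
    }
    px <- pmin(pmax(round(px), 0), 255)
    img[r, , ] <- px
    labels[r, ] <- cls[k]
  }
  counts <- table(factor(labels, levels = c("blue", "yellow", "mixed")))
  structure(list(img = img, labels = labels,
                 counts = c(n_blue = unname(counts["blue"]),
                            n_yellow = unname(counts["yellow"]),
                            n_mixed = unname(counts["mixed"])),
                 pixel_size = pixel_size,
                 channel_mask = row(labels) %in% channel_rows &
                   !is.na(labels),
                 colors = colors, margin = margin,
                 thresholds = thresholds),
            class = "micrograph_truth")
}

#' @export
print.micrograph_truth <- function(x, ...) {
  cat(sprintf("<micrograph_truth> %d x %d px at %g um/px; %s\n",
              dim(x$img)[1], dim(x$img)[2], x$pixel_size,
              paste(names(x$counts), x$counts, sep = "=", collapse = " ")))
  invisible(x)
}

#' Transverse mixing profile after diffusive spreading
#'
#' erf-shaped local mixed fraction for an interface of diffusion length
#' `ell` (um) at the channel midline: m(y) = (1 + erf((y - 0.5) W / ell))/2
#' mapped so m = 0 on the blue side, 1 on the yellow side.
#' @param ell diffusion length (um).
#' @param W channel width (um).
#' @return function of y-fraction in [0, 1].
#' @export
erf_mixing_profile <- function(ell, W = 400) {
  function(y) (1 + pracma::erf((y - 0.5) * W / max(ell, 1e-9))) / 2
}

#' Write a micrograph fixture to PNG
#' @param truth a [synthetic_micrograph()] result.
#' @param file output .png path.
#' @export
write_micrograph_png <- function(truth, file) {
  png::writePNG(truth$img / 255, file)
  invisible(file)
}

#' Read an RGB image into the 0-255 array convention
#' @param file a .png file path.
#' @return H x W x 3 numeric array, 0-255.
#' @export
read_micrograph <- function(file) {
  a <- png::readPNG(file)
  if (length(dim(a)) < 3 || dim(a)[3] < 3) stop("grayscale input: need RGB")
  round(a[, , 1:3] * 255)
}

#' Deterministic fixture bundle for the full test suite
#'
#' Generates, in `dir`: the six-station micrograph series (0-40 mm from
#' the junction, mixed fraction increasing downstream as diffusion widens
#' the interface), pure reference images for calibration, and a JSON
#' manifest with the parameters and MD5 hash of every artifact. Identical
#' seeds give byte-identical bundles.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param stations station distances (mm).
#' @param Q flow rate (uL/min) used to scale the diffusion lengths.
#' @return manifest list (invisibly written to `manifest.json`).
#' @export
fixture_suite <- function(dir, seed = 0L,
                          stations = c(0, 10, 15, 20, 25, 40), Q = 50) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sec <- channel_section()
  ub <- mean_speed(Q, sec)
  D <- fluid_props()$diffusivity
  files <- list()
  params <- list(seed = seed, stations = stations, Q = Q,
                 colors = fixture_colors())
  # pure calibration references
  refs <- list(blue = 0, yellow = 1, mixed = 0.5)
  for (nm in names(refs)) {
    tr <- synthetic_micrograph(200, 200, m = refs[[nm]], noise_sd = 4,
                               seed = seed + match(nm, names(refs)))
    f <- file.path(dir, sprintf("ref_%s.png", nm))
    write_micrograph_png(tr, f)
    files[[basename(f)]] <- unname(tools::md5sum(f))
  }
  # station series: diffusion length ell = sqrt(2 D t), t = s/ubar
  for (k in seq_along(stations)) {
    s <- stations[k]
    ell <- sqrt(2 * D * (s / 1000) / ub) * 1e6   # um
    tr <- synthetic_micrograph(1200, 400, m = erf_mixing_profile(ell),
                               noise_sd = 4, seed = seed + 100 + k)
    f <- file.path(dir, sprintf("station_%02.0fmm.png", s))
    write_micrograph_png(tr, f)
    files[[basename(f)]] <- unname(tools::md5sum(f))
  }
  manifest <- list(params = params, files = files,
                   param_hash = .hash_obj(params))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.hash_obj <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
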