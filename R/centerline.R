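#' Width-annotated channel centerline
#'
#' A `centerline_path` is an ordered polyline (x, y in mm) with a cumulative
#' arc length `s` (mm, measured from the junction), a per-vertex channel
#' width `w` (um) and a per-vertex segment tag. It is the common currency
#' between the geometry, toolpath and flow-simulation layers.
#'
#' @param x,y vertex coordinates (mm).
#' @param w per-vertex width (um); recycled if length 1.
#' @param tag per-vertex segment tag; recycled.
#' @param w0 nominal width (um) recorded for fidelity checks.
#' @return object of class `centerline_path`.
#' @export
centerline_path <- function(x, y, w, tag = "body", w0 = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  w <- rep_len(w, length(x))
  tag <- rep_len(tag, length(x))
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite coordinates")
  if (any(w <= 0)) stop("all widths must be > 0")
  ds <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(ds == 0)) {
    keep <- c(TRUE, ds > 0)
    x <- x[keep]; y <- y[keep]; w <- w[keep]; tag <- tag[keep]
    ds <- sqrt(diff(x)^2 + diff(y)^2)
  }
  structure(list(x = x, y = y, s = c(0, cumsum(ds)), w = w, tag = tag,
                 w0 = if (is.null(w0)) w[1] else w0),
            class = "centerline_path")
}

#' @export
print.centerline_path <- function(x, ...) {
  cat(sprintf(
    "<centerline_path> %d vertices, arc length %.3f mm, width %g-%g um\n",
    length(x$x), max(x$s), min(x$w), max(x$w)))
  invisible(x)
}

#' Total arc length of a path (mm)
#' @param path a [centerline_path()].
#' @export
path_length <- function(path) max(path$s)

#' Integral of width along arc length
#'
#' Trapezoidal integral of w(s) ds, in mm^2 (widths converted from um).
#' Equals the plan-view channel area for gentle curvature.
#' @param path a [centerline_path()].
#' @export
path_width_integral <- function(path) {
  w_mm <- path$w / 1000
  sum(diff(path$s) * (w_mm[-length(w_mm)] + w_mm[-1]) / 2)
}

#' Sinusoidal (zigzag) mixer centerline
#'
#' Samples the centerline y = A sin(2 pi x / lambda) over `n_periods`
#' wavelengths, preceded and followed by straight lead-in/lead-out runs, and
#' attaches the constant nominal width. The sinusoid is discretized so the
#' chord deviation stays below `spec$chord_tol`. Zero amplitude degenerates
#' to a straight channel.
#'
#' @param spec a [mixer_spec()] with design `"zigzag"`, `"vzigzag"` or
#'   `"straight"`.
#' @return a [centerline_path()]; for `"vzigzag"` the width profile is then
#'   applied by [vzigzag_centerline()].
#' @export
zigzag_centerline <- function(spec) {
  stopifnot(inherits(spec, "mixer_spec"))
  if (!spec$design %in% c("zigzag", "vzigzag", "straight"))
    stop("zigzag_centerline needs a zigzag/vzigzag/straight design")
  if (spec$wavelength <= 0 || spec$width <= 0)
    stop("wavelength and width must be positive")
  A <- spec$amplitude
  lam <- spec$wavelength
  if (spec$design == "straight" || A == 0) {
    L <- if (spec$design == "straight") spec$body_length else
      spec$lead_in + spec$n_periods * lam + spec$lead_out
    n <- max(2L, ceiling(L / 0.2) + 1L)
    return(centerline_path(seq(0, L, length.out = n), rep(0, n),
                           spec$width, "body", w0 = spec$width))
  }
  # chord-tolerance sampling: for a curve with local curvature radius R the
  # chord sagitta of a step dx is ~ (ds)^2/(8R); bound with the apex radius
  kmax <- A * (2 * pi / lam)^2
  step <- sqrt(8 * spec$chord_tol / kmax)
  step <- min(step, lam / 40)
  xs <- seq(0, spec$n_periods * lam, by = step)
  if (xs[length(xs)] < spec$n_periods * lam)
    xs <- c(xs, spec$n_periods * lam)
  x <- c(seq(0, spec$lead_in, length.out = max(2, ceiling(spec$lead_in / step))),
         spec$lead_in + xs[-1],
         spec$lead_in + spec$n_periods * lam +
           seq(step, spec$lead_out, length.out = max(2, ceiling(spec$lead_out / step))))
  y <- ifelse(x <= spec$lead_in | x >= spec$lead_in + spec$n_periods * lam,
              0, A * sin(2 * pi * (x - spec$lead_in) / lam))
  tag <- ifelse(x <= spec$lead_in, "lead_in",
                ifelse(x >= spec$lead_in + spec$n_periods * lam,
                       "lead_out", "body"))
  centerline_path(x, y, spec$width, tag, w0 = spec$width)
}

#' Apply a variable-width profile to a centerline
#'
#' Sets w(s) = w0 outside the given arc-length zones, `f * w0` on the zone
#' plateaus, and linear ramps of length `ramp_length` on either side of each
#' plateau. Vertices are inserted at every ramp break so plateau samples hit
#' `f * w0` exactly; the (x, y) trace of the centerline is never altered.
#'
#' @param path a [centerline_path()] with (piecewise) constant width.
#' @param f widening factor (>= 1).
#' @param zones two-column matrix of plateau arc-length intervals
#'   `[s_start, s_end]` (mm); must be non-overlapping including ramps.
#' @param ramp_length ramp length (mm) on each side of each plateau.
#' @return a new [centerline_path()] with the profile applied.
#' @export
apply_width_profile <- function(path, f, zones, ramp_length) {
  stopifnot(inherits(path, "centerline_path"))
  if (f < 1) stop("widen factor f must be >= 1")
  if (ramp_length <= 0) stop("ramp_length must be > 0")
  zones <- matrix(as.numeric(zones), ncol = 2)
  if (any(zones[, 2] <= zones[, 1])) stop("zone end must exceed start")
  if (any(zones < 0) || any(zones > max(path$s)))
    stop("widen zones must lie within the path arc length")
  o <- order(zones[, 1]); zones <- zones[o, , drop = FALSE]
  if (nrow(zones) > 1) {
    lo <- zones[-1, 1] - ramp_length
    hi <- zones[-nrow(zones), 2] + ramp_length
    if (any(lo < hi)) stop("widen zones (including ramps) overlap")
  }
  if (f == 1) return(path)
  w0 <- path$w0
  width_at <- function(s) {
    w <- rep(w0, length(s))
    for (k in seq_len(nrow(zones))) {
      a <- zones[k, 1]; b <- zones[k, 2]
      plateau <- s >= a & s <= b
      up <- s > a - ramp_length & s < a
      dn <- s > b & s < b + ramp_length
      w[plateau] <- f * w0
      w[up] <- w0 + (f - 1) * w0 * (s[up] - (a - ramp_length)) / ramp_length
      w[dn] <- w0 + (f - 1) * w0 * (b + ramp_length - s[dn]) / ramp_length
    }
    w
  }
  # insert vertices at ramp breakpoints so plateaus/ramps are exact
  brk <- sort(unique(c(t(cbind(zones[, 1] - ramp_length, zones[, 1],
                               zones[, 2], zones[, 2] + ramp_length)))))
  brk <- brk[brk > 0 & brk < max(path$s)]
  s_new <- sort(unique(c(path$s, brk)))
  x <- stats::approx(path$s, path$x, xout = s_new)$y
  y <- stats::approx(path$s, path$y, xout = s_new)$y
  tag <- path$tag[pmin(findInterval(s_new, path$s), length(path$tag))]
  out <- centerline_path(x, y, width_at(s_new), tag, w0 = w0)
  out$zones <- zones
  out$ramp_length <- ramp_length
  out$widen_factor <- f
  out
}

#' Default widen zones of the V-zigzag
#'
#' One plateau per sinusoid extremum (arc-length centered on each apex),
#' plateau length `spec$plateau_length`, ramps `spec$ramp_length`.
#' @param spec a [mixer_spec()].
#' @param path the constant-width sinusoid from [zigzag_centerline()].
#' @return two-column matrix of arc-length intervals (mm).
#' @export
vzigzag_zones <- function(spec, path) {
  lam <- spec$wavelength
  x_apex <- spec$lead_in + (seq_len(2 * spec$n_periods) * 2 - 1) * lam / 4
  s_apex <- vapply(x_apex, function(xa) {
    i <- which.min(abs(path$x - xa))
    stats::approx(path$x[max(1, i - 2):min(length(path$x), i + 2)],
                  path$s[max(1, i - 2):min(length(path$x), i + 2)],
                  xout = xa)$y
  }, numeric(1))
  cbind(s_apex - spec$plateau_length / 2, s_apex + spec$plateau_length / 2)
}

#' Variable-width V-zigzag centerline
#'
#' Convenience wrapper: sinusoid from [zigzag_centerline()] with the default
#' widening profile (factor `spec$widen_factor`, one plateau per apex)
#' applied via [apply_width_profile()].
#' @param spec a [mixer_spec()] with design `"vzigzag"`.
#' @export
vzigzag_centerline <- function(spec) {
  base <- zigzag_centerline(spec)
  apply_width_profile(base, spec$widen_factor, vzigzag_zones(spec, base),
                      spec$ramp_length)
}

#' Continuous looped unit-cell mixer path (hex / diamond)
#'
#' Tiles `spec$n_periods` repeats of the unit cell as one continuous stroke:
#' each cell outline is traced as a closed loop and consecutive cells share a
#' boundary vertex/edge, so the nozzle never lifts. Hex cells are point-top
#' regular hexagons (side `cell_side`) sharing vertical edges; diamond cells
#' are squares rotated 45 degrees (diagonal `cell_diagonal`) sharing their
#' left/right vertices.
#'
#' @param spec a [mixer_spec()] with design `"hex"` or `"diamond"`.
#' @return a [centerline_path()] (closed-walk, not simple).
#' @export
unit_cell_mixer <- function(spec) {
  stopifnot(inherits(spec, "mixer_spec"))
  if (!spec$design %in% c("hex", "diamond"))
    stop("unit_cell_mixer needs a hex or diamond design")
  n <- spec$n_periods
  if (n < 1) stop("repeats must be >= 1")
  # each repeat = full cell outline loop + a return pass over the bottom
  # edges that carries the nozzle to the next cell's start vertex, so the
  # stroke is continuous and total length is exactly n x the unit length
  if (spec$design == "hex") {
    a <- spec$cell_side
    hw <- a * cos(pi / 6)               # half width across flats
    # point-top hexagon; start at the bottom of the left vertical edge
    unit <- cbind(
      x = c(-hw, 0, hw, hw, 0, -hw, 0, hw),
      y = c(a / 2, a, a / 2, -a / 2, -a, -a / 2, -a, -a / 2))
    start <- c(-hw, -a / 2)
    pitch <- 2 * hw
  } else {
    d <- spec$cell_diagonal
    s2 <- d / 2
    unit <- cbind(x = c(0, s2, 0, -s2, 0, s2),
                  y = c(s2, 0, -s2, 0, -s2, 0))
    start <- c(-s2, 0)
    pitch <- d
  }
  xs <- start[1]; ys <- start[2]
  for (k in seq_len(n)) {
    off <- (k - 1) * pitch
    xs <- c(xs, unit[, 1] + off)
    ys <- c(ys, unit[, 2])
  }
  centerline_path(xs, ys, spec$width, "body", w0 = spec$width)
}

#' Y-junction channel network
#'
#' Two straight inlet arms meeting at the origin with full angle
#' `spec$inlet_angle`, feeding a body path (the mixer or a straight channel)
#' that starts at the junction. Downstream distance s is measured from the
#' junction vertex, which all three paths share exactly.
#'
#' @param spec a [mixer_spec()].
#' @param body optional [centerline_path()] for the body; default is the
#'   design's own centerline.
#' @return object of class `channel_network`: list of named
#'   [centerline_path()]s (`arm_top`, `arm_bottom`, `body`) plus port labels.
#' @export
y_junction <- function(spec, body = NULL) {
  stopifnot(inherits(spec, "mixer_spec"))
  if (spec$arm_length <= 0) stop("arm length must be > 0")
  half <- spec$inlet_angle / 2 * pi / 180
  L <- spec$arm_length
  arm_top <- centerline_path(c(-L * cos(half), 0), c(L * sin(half), 0),
                             spec$width, "arm", w0 = spec$width)
  arm_bot <- centerline_path(c(-L * cos(half), 0), c(-L * sin(half), 0),
                             spec$width, "arm", w0 = spec$width)
  if (is.null(body)) {
    body <- switch(spec$design,
                   vzigzag = vzigzag_centerline(spec),
                   hex = , diamond = unit_cell_mixer(spec),
                   zigzag_centerline(spec))
  }
  structure(list(arm_top = arm_top, arm_bottom = arm_bot, body = body,
                 junction = c(0, 0),
                 ports = c(arm_top = "inlet", arm_bottom = "inlet",
                           body = "outlet")),
            class = "channel_network")
}

#' @export
print.channel_network <- function(x, ...) {
  cat("<channel_network>", length(x$ports), "ports;",
      paste(names(x$ports), collapse = ", "), "\n")
  invisible(x)
}

#' Coaxial flow-focusing layout
#'
#' One central core inlet flanked by two shell inlets merging at the origin
#' into a single outlet of shell width: the plan-view of the coaxial
#' junction used to template core-shell fibers (core 0.4 mm inside a 1 mm
#' shell by default).
#'
#' @param core_width core channel width (mm).
#' @param shell_width shell/outlet channel width (mm).
#' @param arm_length inlet arm length (mm).
#' @param outlet_length outlet channel length (mm).
#' @param shell_angle approach angle of the shell arms (deg from axis).
#' @return a `channel_network` with paths `core`, `shell_top`,
#'   `shell_bottom`, `outlet`.
#' @export
flow_focusing_layout <- function(core_width = 0.4, shell_width = 1.0,
                                 arm_length = 10, outlet_length = 20,
                                 shell_angle = 45) {
  if (core_width >= shell_width)
    stop("core width must be smaller than shell width")
  if (arm_length <= 0 || outlet_length <= 0) stop("lengths must be > 0")
  th <- shell_angle * pi / 180
  core <- centerline_path(c(-arm_length, 0), c(0, 0),
                          core_width * 1000, "core", w0 = core_width * 1000)
  annulus <- (shell_width - core_width) / 2 * 1000   # per-side shell width, um
  sh_top <- centerline_path(c(-arm_length * cos(th), 0),
                            c(arm_length * sin(th), 0),
                            annulus, "shell", w0 = annulus)
  sh_bot <- centerline_path(c(-arm_length * cos(th), 0),
                            c(-arm_length * sin(th), 0),
                            annulus, "shell", w0 = annulus)
  outlet <- centerline_path(c(0, outlet_length), c(0, 0),
                            shell_width * 1000, "outlet",
                            w0 = shell_width * 1000)
  structure(list(core = core, shell_top = sh_top, shell_bottom = sh_bot,
                 outlet = outlet, junction = c(0, 0),
                 ports = c(core = "inlet", shell_top = "inlet",
                           shell_bottom = "inlet", outlet = "outlet")),
            class = "channel_network")
}
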