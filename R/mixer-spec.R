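#' Parametric mixer design specification
#'
#' Collects every geometric parameter of a single-layer printed micromixer:
#' the sinusoidal body (amplitude and wavelength), nominal channel width,
#' widening factor and zones for the variable-width design, the Y-junction
#' inlet arms, and the coaxial flow-focusing widths.
#'
#' Defaults follow the printed devices: amplitude 1.5 mm, wavelength 3.3 mm,
#' nominal extruded width 400 um, layer height 300 um, widening factor 1.5,
#' and 60 mm long Y-channel bodies. All plan-view coordinates are in mm with
#' the junction at the origin and flow along +x; widths are in um.
#'
#' @param design one of `"straight"`, `"zigzag"`, `"vzigzag"`, `"hex"`,
#'   `"diamond"`, `"flow_focusing"`.
#' @param amplitude sinusoid amplitude A (mm).
#' @param wavelength sinusoid wavelength lambda (mm); the centerline is
#'   y = A sin(2 pi x / lambda).
#' @param width nominal channel width w0 (um).
#' @param layer_height extruded layer height (um).
#' @param widen_factor width multiplier f (>= 1) at widened plateaus.
#' @param n_periods number of sinusoid periods (or unit-cell repeats).
#' @param body_length body channel length for the straight design (mm).
#' @param lead_in,lead_out straight run lengths before/after the periodic
#'   body (mm); the lead-in carries the inlet.
#' @param plateau_length,ramp_length widened-plateau and ramp lengths (mm)
#'   for the V-zigzag; defaults lambda/4 and lambda/12.
#' @param inlet_angle full angle between the two Y-junction inlet arms (deg).
#' @param arm_length Y-junction inlet arm length (mm).
#' @param cell_side unit-cell side length for hex (mm) ; half-diagonal is
#'   derived for diamond.
#' @param cell_diagonal unit-cell diagonal for diamond (mm).
#' @param core_width,shell_width flow-focusing core and shell channel widths
#'   (mm).
#' @param chord_tol maximum chord deviation when sampling curves (mm).
#'
#' @return An object of class `mixer_spec`.
#' @examples
#' mixer_spec("vzigzag", n_periods = 3)
#' @export
mixer_spec <- function(design = c("zigzag", "vzigzag", "straight", "hex",
                                  "diamond", "flow_focusing"),
                       amplitude = 1.5, wavelength = 3.3,
                       width = 400, layer_height = 300,
                       widen_factor = 1.5, n_periods = 6L,
                       body_length = 60, lead_in = 1.5, lead_out = 1.5,
                       plateau_length = wavelength / 4,
                       ramp_length = wavelength / 12,
                       inlet_angle = 60, arm_length = 10,
                       cell_side = 0.8, cell_diagonal = 1.6,
                       core_width = 0.4, shell_width = 1.0,
                       chord_tol = 0.005) {
  design <- match.arg(design)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (wavelength <= 0) stop("wavelength must be > 0")
  if (width <= 0) stop("nominal width must be > 0")
  if (layer_height <= 0) stop("layer height must be > 0")
  if (widen_factor < 1) stop("widen_factor must be >= 1")
  if (n_periods < 1) stop("n_periods must be >= 1")
  if (inlet_angle <= 0 || inlet_angle >= 180)
    stop("inlet_angle must lie in (0, 180) degrees")
  if (arm_length <= 0) stop("arm_length must be > 0")
  if (core_width >= shell_width)
    stop("core_width must be smaller than shell_width")
  if (chord_tol <= 0) stop("chord_tol must be > 0")
  structure(list(
    design = design, amplitude = amplitude, wavelength = wavelength,
    width = width, layer_height = layer_height,
    widen_factor = widen_factor, n_periods = as.integer(n_periods),
    body_length = body_length, lead_in = lead_in, lead_out = lead_out,
    plateau_length = plateau_length, ramp_length = ramp_length,
    inlet_angle = inlet_angle, arm_length = arm_length,
    cell_side = cell_side, cell_diagonal = cell_diagonal,
    core_width = core_width, shell_width = shell_width,
    chord_tol = chord_tol
  ), class = "mixer_spec")
}

#' @export
print.mixer_spec <- function(x, ...) {
  cat("<mixer_spec>", x$design, "\n")
  cat(sprintf("  A = %g mm, lambda = %g mm, w0 = %g um, f = %g\n",
              x$amplitude, x$wavelength, x$width, x$widen_factor))
  cat(sprintf("  periods/repeats = %d, lead-in/out = %g/%g mm\n",
              x$n_periods, x$lead_in, x$lead_out))
  invisible(x)
}
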