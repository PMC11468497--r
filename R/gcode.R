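#' Machine settings for single-layer variable-width extrusion
#'
#' Defaults reproduce the printer settings used for the ABS devices:
#' 240 C nozzle, 100 C bed, 200 mm/min print speed, 400 um extruded width,
#' 300 um layer height, 1.75 mm filament. The 100 um nozzle variant halves
#' the print speed (`base_feed = 100`).
#'
#' @param nozzle_temp nozzle temperature (C).
#' @param bed_temp build-plate temperature (C).
#' @param base_feed print speed at nominal width (mm/min).
#' @param width nominal extruded width (um).
#' @param layer_height extruded layer height (um).
#' @param filament_diameter filament diameter (mm).
#' @param nozzle_diameter nozzle bore (um).
#' @param cross_section `"rectangle"` models the extrudate as w x h;
#'   `"rounded"` subtracts the corner area h^2 (1 - pi/4).
#' @return object of class `print_params`.
#' @export
print_params <- function(nozzle_temp = 240, bed_temp = 100, base_feed = 200,
                         width = 400, layer_height = 300,
                         filament_diameter = 1.75, nozzle_diameter = 400,
                         cross_section = c("rectangle", "rounded")) {
  cross_section <- match.arg(cross_section)
  vals <- c(nozzle_temp, bed_temp, base_feed, width, layer_height,
            filament_diameter, nozzle_diameter)
  if (any(vals <= 0)) stop("all print parameters must be positive")
  if (layer_height > width)
    stop("layer height must not exceed extruded width")
  structure(list(nozzle_temp = nozzle_temp, bed_temp = bed_temp,
                 base_feed = base_feed, width = width,
                 layer_height = layer_height,
                 filament_diameter = filament_diameter,
                 nozzle_diameter = nozzle_diameter,
                 cross_section = cross_section),
            class = "print_params")
}

.bead_area_mm2 <- function(w_um, h_um, cross_section = "rectangle") {
  a <- (w_um / 1000) * (h_um / 1000)
  if (cross_section == "rounded") a <- a - (h_um / 1000)^2 * (1 - pi / 4)
  a
}

#' Filament length for one extruded segment
#'
#' Volumetric equality of the deposited bead and the consumed filament:
#' E = L w h / (pi (d_f / 2)^2) under the rectangular cross-section model.
#'
#' @param L segment length (mm).
#' @param w extruded width (um).
#' @param h layer height (um).
#' @param d_f filament diameter (mm).
#' @param cross_section see [print_params()].
#' @return filament length E (mm).
#' @examples
#' extrusion_for_segment(10, 400, 300, 1.75)  # ~0.4989 mm
#' @export
extrusion_for_segment <- function(L, w, h, d_f,
                                  cross_section = "rectangle") {
  if (any(w <= 0) || any(h <= 0)) stop("width and height must be positive")
  if (d_f <= 0) stop("filament diameter must be positive")
  if (any(L < 0)) stop("segment length must be >= 0")
  L * .bead_area_mm2(w, h, cross_section) / (pi * (d_f / 2)^2)
}

#' Feed rate realizing a target extruded width
#'
#' In `constant_volumetric` mode the melt flow through the nozzle is held
#' constant, so wider beads are printed slower: F = base_feed * (w0 / w).
#' In `constant_feed` mode the carriage speed never changes and the
#' extrusion rate per mm is scaled instead.
#'
#' @param w target width (um).
#' @param w0 nominal width (um).
#' @param base_feed feed at nominal width (mm/min).
#' @param mode `"constant_volumetric"` or `"constant_feed"`.
#' @return feed rate F (mm/min).
#' @export
feed_for_width <- function(w, w0, base_feed,
                           mode = c("constant_volumetric", "constant_feed")) {
  mode <- match.arg(mode)
  if (any(w <= 0)) stop("width must be positive")
  if (mode == "constant_volumetric") base_feed * (w0 / w) else
    rep_len(base_feed, length(w))
}

#' Convert a centerline into a variable-width extrusion program
#'
#' Emits one continuous extruding polyline (no travel moves inside the
#' body). Long segments are split so none exceeds `max_segment` and width
#' ramps stay resolved; each move's E comes from [extrusion_for_segment()]
#' at the segment's mean width, and its F from [feed_for_width()].
#'
#' @param path a [centerline_path()].
#' @param params a [print_params()].
#' @param mode extrusion/feed split, see [feed_for_width()].
#' @param max_segment maximum emitted segment length (mm).
#' @param e_mode `"relative"` (default, M83) or `"absolute"` (M82) E values.
#' @return object of class `gcode_program`: data frame of moves plus
#'   header/footer blocks and a dialect tag.
#' @export
path_to_gcode <- function(path, params,
                          mode = c("constant_volumetric", "constant_feed"),
                          max_segment = 0.2,
                          e_mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  e_mode <- match.arg(e_mode)
  stopifnot(inherits(params, "print_params"))
  if (is.null(path)) {
    moves <- data.frame(x = numeric(0), y = numeric(0), e = numeric(0),
                        f = numeric(0))
  } else {
    stopifnot(inherits(path, "centerline_path"))
    s_new <- sort(unique(c(path$s,
                           seq(0, max(path$s), by = max_segment))))
    x <- stats::approx(path$s, path$x, xout = s_new)$y
    y <- stats::approx(path$s, path$y, xout = s_new)$y
    w <- stats::approx(path$s, path$w, xout = s_new)$y
    L <- diff(s_new)
    wm <- (w[-1] + w[-length(w)]) / 2
    e <- extrusion_for_segment(L, wm, params$layer_height,
                               params$filament_diameter,
                               params$cross_section)
    f <- feed_for_width(wm, params$width, params$base_feed, mode)
    moves <- data.frame(x = x[-1], y = y[-1], e = e, f = f)
    attr(moves, "start") <- c(x[1], y[1])
  }
  header <- c(
    "; micromix single-layer variable-width extrusion",
    sprintf("; mode=%s cross_section=%s", mode, params$cross_section),
    sprintf("M104 S%g ; nozzle temperature C", params$nozzle_temp),
    sprintf("M140 S%g ; bed temperature C", params$bed_temp),
    sprintf("M109 S%g", params$nozzle_temp),
    sprintf("M190 S%g", params$bed_temp),
    "G21 ; millimetres",
    "G90 ; absolute XY",
    if (e_mode == "relative") "M83 ; relative extrusion" else
      "M82 ; absolute extrusion",
    "G92 E0")
  structure(list(moves = moves, header = header,
                 footer = c("M104 S0", "M140 S0", "M84"),
                 dialect = "marlin", e_mode = e_mode,
                 base_feed = params$base_feed),
            class = "gcode_program")
}

#' @export
print.gcode_program <- function(x, ...) {
  cat(sprintf("<gcode_program> %s, %d moves, total E %.4f mm\n",
              x$dialect, nrow(x$moves), sum(x$moves$e)))
  invisible(x)
}

#' Total extruded filament length of a program (mm)
#' @param program a `gcode_program`.
#' @export
total_extrusion <- function(program) sum(program$moves$e)

#' Serialize a G-code program to text
#' @param program a `gcode_program`.
#' @param file output path; if NULL the lines are returned.
#' @export
write_gcode <- function(program, file = NULL) {
  lines <- program$header
  m <- program$moves
  if (nrow(m)) {
    st <- attr(m, "start")
    lines <- c(lines, sprintf("G0 X%.5f Y%.5f F%g", st[1], st[2],
                              program$base_feed * 10))
    ee <- if (program$e_mode == "absolute") cumsum(m$e) else m$e
    lines <- c(lines, sprintf("G1 X%.8f Y%.8f E%.10f F%.6f",
                              m$x, m$y, ee, m$f))
  }
  lines <- c(lines, program$footer)
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(file)
}

#' Parse Marlin-dialect G-code written by [write_gcode()]
#' @param lines character vector of G-code lines, or a file path.
#' @return a `gcode_program`.
#' @export
parse_gcode <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  e_mode <- if (any(grepl("^M82", lines))) "absolute" else "relative"
  g1 <- grep("^G1 ", lines, value = TRUE)
  g0 <- grep("^G0 ", lines, value = TRUE)
  num <- function(v, key) as.numeric(sub(sprintf(".*%s([-0-9.]+).*", key),
                                         "\\1", v))
  moves <- if (length(g1)) {
    data.frame(x = num(g1, "X"), y = num(g1, "Y"),
               e = num(g1, "E"), f = num(g1, "F"))
  } else data.frame(x = numeric(0), y = numeric(0), e = numeric(0),
                    f = numeric(0))
  if (e_mode == "absolute" && nrow(moves))
    moves$e <- diff(c(0, moves$e))
  if (length(g0))
    attr(moves, "start") <- c(num(g0[1], "X"), num(g0[1], "Y"))
  hdr_end <- grep("^G92 E0", lines)[1]
  ftr_start <- grep("^M104 S0", lines)[1]
  base_feed <- {
    f0 <- num(g0[1], "F")
    if (length(f0) && is.finite(f0)) f0 / 10 else 200
  }
  structure(list(moves = moves,
                 header = lines[seq_len(hdr_end)],
                 footer = lines[ftr_start:length(lines)],
                 dialect = "marlin", e_mode = e_mode,
                 base_feed = base_feed),
            class = "gcode_program")
}

#' Volume-conservation check of a program against its design
#'
#' Relative error between the total extruded filament volume (sum E times
#' the filament cross-section) and the designed channel volume
#' (integral of w(s) h ds). Freshly generated programs close to machine
#' precision.
#'
#' @param program a `gcode_program`.
#' @param path the generating [centerline_path()].
#' @param params the [print_params()] used.
#' @return relative volume error (dimensionless).
#' @export
verify_volume <- function(program, path, params) {
  a_f <- pi * (params$filament_diameter / 2)^2
  v_prog <- total_extrusion(program) * a_f
  s_fine <- sort(unique(c(path$s, seq(0, max(path$s), by = 0.05))))
  w <- stats::approx(path$s, path$w, xout = s_fine)$y
  a_bead <- .bead_area_mm2(w, params$layer_height, params$cross_section)
  v_design <- sum(diff(s_fine) * (a_bead[-1] + a_bead[-length(a_bead)]) / 2)
  if (v_design <= 0) stop("design volume is zero; cannot verify")
  abs(v_prog - v_design) / v_design
}
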