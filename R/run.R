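# Single entry point wiring YAML configs to the modules, with a
# reproducible run manifest (config hash + MD5 of every artifact).

.schema <- list(
  design = c("design", "amplitude", "wavelength", "width", "layer_height",
             "widen_factor", "n_periods", "body_length", "lead_in",
             "lead_out", "plateau_length", "ramp_length", "inlet_angle",
             "arm_length", "cell_side", "cell_diagonal", "core_width",
             "shell_width", "chord_tol"),
  print = c("nozzle_temp", "bed_temp", "base_feed", "width", "layer_height",
            "filament_diameter", "nozzle_diameter", "cross_section",
            "mode"),
  flow = c("Q", "height", "density", "viscosity", "diffusivity", "cell",
           "stations", "c_factor", "max_steps"),
  imaging = c("pixel_size", "stations", "margin", "trim_percentile"),
  seed = NULL)

.validate_config <- function(cfg) {
  unknown_top <- setdiff(names(cfg), names(.schema))
  if (length(unknown_top))
    stop("unknown config section(s): ", paste(unknown_top, collapse = ", "))
  for (sec in intersect(names(cfg), c("design", "print", "flow", "imaging"))) {
    bad <- setdiff(names(cfg[[sec]]), .schema[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  cfg
}

.cfg_spec <- function(cfg) do.call(mixer_spec, cfg$design %||% list())
.cfg_params <- function(cfg) {
  pp <- cfg$print %||% list()
  pp$mode <- NULL
  do.call(print_params, pp)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one pipeline stage from a config
#'
#' Subcommands: `design` (centerline CSV, outline WKT + SVG), `gcode`
#' (Marlin program), `simulate` (flow + species solve, field CSV and
#' MI-vs-distance table), `mixindex` (image series MI table), `tracks`
#' (particle advection CSVs) and `fixtures` (synthetic image bundle).
#' Every run writes `run_manifest.json` with the config hash and an MD5
#' per artifact, so identical configs and seeds give identical manifests.
#'
#' @param subcommand one of design, gcode, simulate, mixindex, tracks,
#'   fixtures.
#' @param config named list (see the schema in the vignette) or a YAML
#'   file path.
#' @param out_dir output directory.
#' @param seed integer seed for every stochastic step.
#' @return invisibly, the list of artifact paths.
#' @export
run <- function(subcommand = c("design", "gcode", "simulate", "mixindex",
                               "tracks", "fixtures"),
                config = list(), out_dir = ".", seed = 0L) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  arts <- character(0)
  add <- function(f) arts <<- c(arts, f)

  if (subcommand == "design") {
    spec <- .cfg_spec(config)
    path <- switch(spec$design,
                   vzigzag = vzigzag_centerline(spec),
                   hex = , diamond = unit_cell_mixer(spec),
                   zigzag_centerline(spec))
    f1 <- file.path(out_dir, "centerline.csv")
    write_centerline_csv(path, f1); add(f1)
    poly <- path_to_polygon(path)
    f2 <- file.path(out_dir, "outline.wkt"); write_wkt(poly, f2); add(f2)
    f3 <- file.path(out_dir, "outline.svg")
    write_svg(poly, f3, path = path); add(f3)
  } else if (subcommand == "gcode") {
    spec <- .cfg_spec(config)
    params <- .cfg_params(config)
    mode <- (config$print %||% list())$mode %||% "constant_volumetric"
    path <- switch(spec$design,
                   vzigzag = vzigzag_centerline(spec),
                   hex = , diamond = unit_cell_mixer(spec),
                   zigzag_centerline(spec))
    prog <- path_to_gcode(path, params, mode = mode)
    f <- file.path(out_dir, "mixer.gcode")
    write_gcode(prog, f); add(f)
  } else if (subcommand == "simulate") {
    spec <- .cfg_spec(config)
    fl <- config$flow %||% list()
    props <- fluid_props(density = fl$density %||% 998,
                         viscosity = fl$viscosity %||% 1e-3,
                         diffusivity = fl$diffusivity %||% 2.3e-9)
    path <- switch(spec$design,
                   vzigzag = vzigzag_centerline(spec),
                   zigzag_centerline(spec))
    grid <- build_sim_grid(path, cell = fl$cell)
    ctrl <- solver_control(c_factor = fl$c_factor %||% 6,
                           max_steps = fl$max_steps %||% 400000L)
    for (Q in (fl$Q %||% 50)) {
      fld <- solve_steady_flow(grid, Q, props,
                               height = fl$height %||% 300, control = ctrl)
      fld <- solve_species(fld, props, control = ctrl)
      f1 <- file.path(out_dir, sprintf("field_Q%g.csv", Q))
      write_field_csv(fld, f1); add(f1)
      tab <- field_mi_table(fld, fl$stations %||% c(0, 10, 15, 20, 25, 40))
      f2 <- file.path(out_dir, sprintf("mi_vs_distance_Q%g.csv", Q))
      utils::write.csv(tab, f2, row.names = FALSE); add(f2)
    }
  } else if (subcommand == "mixindex") {
    im <- config$imaging %||% list()
    fix_dir <- file.path(out_dir, "fixtures")
    fixture_suite(fix_dir, seed = seed)
    refs <- lapply(c("blue", "yellow", "mixed"), function(nm)
      read_micrograph(file.path(fix_dir, sprintf("ref_%s.png", nm))))
    calib <- calibrate_rgb_ranges(refs[[1]], refs[[2]], refs[[3]],
                                  p = im$trim_percentile %||% 1,
                                  margin = im$margin %||% 5)
    stations <- im$stations %||% c(0, 10, 15, 20, 25, 40)
    imgs <- lapply(stations, function(s)
      read_micrograph(file.path(fix_dir, sprintf("station_%02.0fmm.png", s))))
    tab <- mi_vs_distance(imgs, stations, calib,
                          pixel_size = im$pixel_size %||% 1)
    f <- file.path(out_dir, "mixindex.csv")
    utils::write.csv(tab, f, row.names = FALSE); add(f)
  } else if (subcommand == "tracks") {
    fl <- config$flow %||% list()
    fld <- analytic_field("parabolic_slot", Q = (fl$Q %||% 50)[1],
                          length = 10)
    w_mm <- fld$grid$path$w0 / 1000
    ys <- seq(-w_mm / 2 * 0.9, w_mm / 2 * 0.9, length.out = 15)
    tr <- advect_particles(fld, cbind(0.5, ys), duration = 1)
    f1 <- file.path(out_dir, "tracks.csv"); write_tracks_csv(tr, f1); add(f1)
    prof <- velocity_profile_from_tracks(tr, x0 = 5)
    f2 <- file.path(out_dir, "velocity_profile.csv")
    utils::write.csv(prof$profile, f2, row.names = FALSE); add(f2)
  } else if (subcommand == "fixtures") {
    man <- fixture_suite(file.path(out_dir, "fixtures"), seed = seed)
    add(file.path(out_dir, "fixtures", "manifest.json"))
  }

  manifest <- list(subcommand = subcommand, seed = seed,
                   config_hash = .hash_obj(config),
                   artifacts = as.list(stats::setNames(
                     unname(tools::md5sum(arts)), basename(arts))))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(arts)
}
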