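#' Working-fluid properties
#'
#' Water-like defaults used throughout: density 998 kg/m^3, viscosity
#' 1 mPa s, species mass diffusion coefficient 2.3e-9 m^2/s (self-diffusion
#' of water). Gravity is off by default for the plan-view simulations.
#'
#' @param density kg/m^3.
#' @param viscosity Pa s.
#' @param diffusivity mass diffusion coefficient D_m (m^2/s).
#' @param gravity m/s^2 (0 by default).
#' @return object of class `fluid_props`.
#' @export
fluid_props <- function(density = 998, viscosity = 1.0e-3,
                        diffusivity = 2.3e-9, gravity = 0) {
  if (density <= 0 || viscosity <= 0) stop("density and viscosity must be > 0")
  if (diffusivity < 0 || gravity < 0) stop("negative diffusivity/gravity")
  structure(list(density = density, viscosity = viscosity,
                 diffusivity = diffusivity, gravity = gravity),
            class = "fluid_props")
}

#' Rectangular channel cross-section
#'
#' @param width channel width W (um).
#' @param height channel height H (um).
#' @return object of class `channel_section` with the hydraulic diameter
#'   D_h = 2WH/(W+H) (um) derived, never stored independently.
#' @export
channel_section <- function(width = 400, height = 300) {
  if (width <= 0 || height <= 0) stop("W and H must be positive")
  structure(list(width = width, height = height), class = "channel_section")
}

#' Hydraulic diameter of a section (um)
#' @param section a [channel_section()].
#' @export
hydraulic_diameter <- function(section) {
  2 * section$width * section$height / (section$width + section$height)
}

.ul_min_to_m3s <- function(Q) Q * 1e-9 / 60

#' Mean (superficial) speed in a section (m/s)
#' @param Q flow rate (uL/min).
#' @param section a [channel_section()].
#' @export
mean_speed <- function(Q, section) {
  .ul_min_to_m3s(Q) / (section$width * section$height * 1e-12)
}

#' Channel Reynolds number
#'
#' Re = rho ubar D_h / mu with ubar = Q/(W H). For the 400 x 300 um device
#' with water this spans about 0.047 (1 uL/min) to 47 (1000 uL/min).
#'
#' @param Q flow rate (uL/min).
#' @param section a [channel_section()].
#' @param props a [fluid_props()].
#' @export
reynolds_number <- function(Q, section = channel_section(),
                            props = fluid_props()) {
  if (any(Q < 0)) stop("Q must be >= 0")
  props$density * mean_speed(Q, section) * hydraulic_diameter(section) *
    1e-6 / props$viscosity
}

#' Fully developed slot-flow (plan-view Poiseuille) profile
#'
#' u(y) = 1.5 ubar (1 - (2y/W)^2): parabola across the width, peaking at
#' 1.5x the mean on the centerline, zero at the walls.
#'
#' @param Q flow rate (uL/min).
#' @param section a [channel_section()].
#' @param y transverse position(s) from the centerline (um).
#' @return speed u(y) in m/s.
#' @export
poiseuille_slot_profile <- function(Q, section, y) {
  if (any(abs(y) > section$width / 2 + 1e-9)) stop("y outside the channel")
  1.5 * mean_speed(Q, section) * (1 - (2 * y / section$width)^2)
}

#' Closed-form mixing index for plug-flow straight-channel diffusion
#'
#' Cosine eigenmode series for pure transverse diffusion of an initial
#' half/half step between zero-flux walls: sigma(t)/sigma_0 with
#' t = s / ubar, decay exp(-D (k pi / W)^2 t), and MI = 1 - sigma/sigma_0.
#'
#' @param s downstream distance (mm).
#' @param ubar plug speed (m/s).
#' @param W channel width (um).
#' @param D diffusion coefficient (m^2/s).
#' @param kmax highest mode summed (odd modes contribute).
#' @return mixing index in [0, 1].
#' @export
diffusion_closed_form_mi <- function(s, ubar, W, D, kmax = 199) {
  t <- (s / 1000) / ubar
  Wm <- W * 1e-6
  k <- seq(1, kmax, by = 2)
  a2 <- 4 / (k^2 * pi^2)
  var_t <- sum(a2 * exp(-2 * D * (k * pi / Wm)^2 * t)) / 2
  var_0 <- sum(a2) / 2   # truncated-series initial variance, so MI(0) = 0
  1 - sqrt(var_t / var_0)
}

#' Build a masked simulation grid from a centerline
#'
#' Rasterizes the channel (all points within w(s)/2 of the centerline) onto
#' a uniform grid. The west boundary of the grid coincides with the path
#' start and carries the inlet; the east boundary coincides with the path
#' end and carries the outlet.
#'
#' @param path a [centerline_path()] starting at its inlet and running
#'   toward +x.
#' @param cell cell size (um); default resolves the nominal width with 20
#'   cells.
#' @param pad wall padding (cells) added above/below the channel.
#' @return object of class `sim_grid`.
#' @export
build_sim_grid <- function(path, cell = NULL, pad = 2L) {
  stopifnot(inherits(path, "centerline_path"))
  if (is.null(cell)) cell <- path$w0 / 20
  cell_mm <- cell / 1000
  d <- .densify_path(path, cell_mm / 2)
  x0 <- path$x[1]
  x1 <- path$x[length(path$x)]
  nx <- max(2L, round((x1 - x0) / cell_mm))
  ymin <- min(d$y - d$w / 2000); ymax <- max(d$y + d$w / 2000)
  j0 <- floor((ymin - path$y[1]) / cell_mm) - pad
  j1 <- ceiling((ymax - path$y[1]) / cell_mm) + pad
  y0 <- path$y[1] + j0 * cell_mm
  ny <- as.integer(j1 - j0)
  mask <- matrix(0L, nx, ny)
  xc <- x0 + (seq_len(nx) - 0.5) * cell_mm
  yc <- y0 + (seq_len(ny) - 0.5) * cell_mm
  for (k in seq_along(d$x)) {
    r <- d$w[k] / 2000
    irange <- which(xc >= d$x[k] - r & xc <= d$x[k] + r)
    if (!length(irange)) next
    jrange <- which(yc >= d$y[k] - r & yc <= d$y[k] + r)
    if (!length(jrange)) next
    dx2 <- (xc[irange] - d$x[k])^2
    dy2 <- (yc[jrange] - d$y[k])^2
    mask[irange, jrange] <- mask[irange, jrange] |
      (outer(dx2, dy2, "+") <= r^2)
  }
  mask <- mask * 1L
  if (!any(mask[1, ] == 1L)) stop("no inlet cells: path must start at x0")
  if (!any(mask[nx, ] == 1L)) stop("no outlet cells: path must end at x1")
  structure(list(cell = cell, cell_m = cell * 1e-6, x0 = x0, y0 = y0,
                 nx = nx, ny = ny, mask = mask, path = path,
                 xc = xc, yc = yc),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> %d x %d cells of %g um, %d in channel\n",
              x$nx, x$ny, x$cell, sum(x$mask)))
  invisible(x)
}

#' Solver settings for the steady flow and species marches
#'
#' @param c_factor pseudo-sound speed as a multiple of the inlet speed
#'   (artificial compressibility).
#' @param cfl time-step safety factor.
#' @param tol_div dimensionless continuity residual target.
#' @param tol_change dimensionless per-step velocity-change target.
#' @param max_steps iteration cap for the flow march.
#' @param check_every residual check interval (steps).
#' @param species_cfl,species_tol,species_max_steps same controls for the
#'   scalar march.
#' @param species_t_factor scalar march horizon as a multiple of the
#'   domain residence time.
#' @export
solver_control <- function(c_factor = 6, cfl = 0.7, tol_div = 1e-3,
                           tol_change = 2e-7, max_steps = 400000L,
                           check_every = 500L,
                           species_cfl = 0.4, species_tol = 1e-7,
                           species_max_steps = 400000L,
                           species_t_factor = 4) {
  structure(list(c_factor = c_factor, cfl = cfl, tol_div = tol_div,
                 tol_change = tol_change, max_steps = as.integer(max_steps),
                 check_every = as.integer(check_every),
                 species_cfl = species_cfl, species_tol = species_tol,
                 species_max_steps = as.integer(species_max_steps),
                 species_t_factor = species_t_factor),
            class = "solver_control")
}

.inlet_plug <- function(grid, Q, height_um) {
  inlet_rows <- which(grid$mask[1, ] == 1L)
  W_in <- length(inlet_rows) * grid$cell * 1e-6        # m
  u_plug <- .ul_min_to_m3s(Q) / (W_in * height_um * 1e-6)
  uin <- numeric(grid$ny)
  uin[inlet_rows] <- u_plug
  list(uin = uin, rows = inlet_rows, u_plug = u_plug)
}

#' Solve steady laminar flow in a channel grid
#'
#' Marches the incompressible momentum equations (no-slip walls, plug
#' inlet, zero-gradient mass-balanced outlet) to steady state with an
#' artificial-compressibility scheme on a staggered grid. The out-of-plane
#' height enters only through the inlet speed ubar = Q/(W H).
#'
#' @param grid a [build_sim_grid()] result.
#' @param Q total flow rate (uL/min).
#' @param props a [fluid_props()].
#' @param height channel (out-of-plane) height (um).
#' @param control a [solver_control()].
#' @param init `"poiseuille"` warm-starts from the local fully developed
#'   profile, `"zero"` starts from rest.
#' @return object of class `flow_field` with face velocities `u`, `v`,
#'   cell pressures `p`, cell-centered speeds, the residual history and the
#'   grid.
#' @export
solve_steady_flow <- function(grid, Q, props = fluid_props(), height = 300,
                              control = solver_control(),
                              init = c("poiseuille", "zero")) {
  stopifnot(inherits(grid, "sim_grid"))
  init <- match.arg(init)
  if (Q < 0) stop("Q must be >= 0")
  inl <- .inlet_plug(grid, Q, height)
  u0 <- p0 <- NULL
  if (Q > 0 && init == "poiseuille") {
    u0 <- matrix(0, grid$nx + 1, grid$ny)
    p0 <- matrix(0, grid$nx, grid$ny)
    dpdx <- numeric(grid$nx)
    for (i in seq_len(grid$nx + 1)) {
      ii <- min(max(i, 1), grid$nx)
      rows <- which(grid$mask[ii, ] == 1L)
      if (!length(rows)) next
      Wloc <- length(rows) * grid$cell_m
      um <- .ul_min_to_m3s(Q) / (Wloc * height * 1e-6)
      yy <- (seq_along(rows) - 0.5) / length(rows) - 0.5   # -0.5..0.5
      u0[i, rows] <- 1.5 * um * (1 - (2 * yy)^2)
      if (ii == i) dpdx[i] <- 12 * props$viscosity * um / Wloc^2
    }
    # slot-flow pressure estimate integrated back from the outlet
    pcol <- rev(cumsum(rev(dpdx))) * grid$cell_m
    for (i in seq_len(grid$nx)) p0[i, grid$mask[i, ] == 1L] <- pcol[i]
  }
  res <- cpp_solve_flow(grid$mask, grid$cell_m, props$density,
                        props$viscosity, inl$uin,
                        control$c_factor, control$cfl, control$tol_div,
                        control$tol_change, control$max_steps,
                        control$check_every, u0, NULL, p0)
  if (!res$converged && Q > 0) {
    warning(sprintf(
      "flow march hit max_steps (%d); last residuals div=%.3g change=%.3g",
      control$max_steps, res$div_max,
      res$resid[nrow(res$resid), "change"]))
  }
  uc <- (res$u[-1, , drop = FALSE] + res$u[-(grid$nx + 1), , drop = FALSE]) / 2
  vc <- (res$v[, -1, drop = FALSE] + res$v[, -(grid$ny + 1), drop = FALSE]) / 2
  structure(list(u = res$u, v = res$v, p = res$p,
                 speed = sqrt(uc^2 + vc^2) * ifelse(grid$mask == 1L, 1, NA),
                 uc = uc, vc = vc,
                 Y = NULL, grid = grid, props = props, Q = Q,
                 height = height, inlet = inl,
                 resid = res$resid, converged = res$converged,
                 steps = res$steps),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> Q = %g uL/min, %d x %d cells, peak speed %.3g m/s%s\n",
    x$Q, x$grid$nx, x$grid$ny, max(x$speed, na.rm = TRUE),
    if (!is.null(x$Y)) ", species solved" else ""))
  invisible(x)
}

#' Solve steady passive species transport on a flow field
#'
#' Marches Fickian advection-diffusion of the mass fraction Y to steady
#' state with a van-Leer TVD bounded scheme: inlet values 1 (above the
#' centerline) and 0 (below), zero-flux walls, advective outflow.
#'
#' @param field a [solve_steady_flow()] result (or [analytic_field()]).
#' @param props a [fluid_props()]; `diffusivity` is used.
#' @param control a [solver_control()].
#' @param y_split transverse coordinate (mm) separating the Y=1 (above)
#'   and Y=0 (below) inlet streams; defaults to the centerline start.
#' @param inlet_values species values as `c(above, below)`.
#' @return the field with `$Y` (mass fraction per cell) attached.
#' @export
solve_species <- function(field, props = field$props,
                          control = solver_control(), y_split = NULL,
                          inlet_values = c(1, 0)) {
  stopifnot(inherits(field, "flow_field"))
  grid <- field$grid
  if (is.null(y_split)) y_split <- grid$path$y[1]
  yin <- ifelse(grid$yc > y_split, inlet_values[1], inlet_values[2])
  u_in <- max(abs(field$inlet$uin))
  L <- (max(grid$path$s) / 1000)
  t_max <- if (u_in > 0) control$species_t_factor * L / field$inlet$u_plug *
    1.5 else 10 * (max(grid$ny * grid$cell_m, 1e-6))^2 / props$diffusivity
  res <- cpp_solve_species(grid$mask, field$u, field$v, grid$cell_m,
                           props$diffusivity, yin,
                           control$species_cfl, t_max,
                           control$species_tol, 200L,
                           control$species_max_steps)
  if (res$ymax > 1 + 1e-4 || res$ymin < -1e-4)
    stop(sprintf("species overshoot: Y in [%.3g, %.3g]", res$ymin, res$ymax))
  field$Y <- res$Y
  field$species_info <- res[c("t", "steps", "converged", "ymin", "ymax")]
  field$y_split <- y_split
  field
}

# sample points of the cross-section normal to the centerline at station s;
# returns in-channel points and interpolators
.section_points <- function(field, s, spacing = NULL) {
  grid <- field$grid
  path <- grid$path
  if (s < 0 || s > max(path$s)) stop("station outside the channel body")
  if (is.null(spacing)) spacing <- grid$cell / 2
  px <- stats::approx(path$s, path$x, xout = s)$y
  py <- stats::approx(path$s, path$y, xout = s)$y
  eps <- min(0.05, max(path$s) / 100)
  tx <- stats::approx(path$s, path$x, xout = min(s + eps, max(path$s)))$y -
    stats::approx(path$s, path$x, xout = max(s - eps, 0))$y
  ty <- stats::approx(path$s, path$y, xout = min(s + eps, max(path$s)))$y -
    stats::approx(path$s, path$y, xout = max(s - eps, 0))$y
  tl <- sqrt(tx^2 + ty^2); tx <- tx / tl; ty <- ty / tl
  wloc <- stats::approx(path$s, path$w, xout = s)$y / 1000
  off <- seq(-wloc / 2 + grid$cell / 2000, wloc / 2 - grid$cell / 2000,
             by = spacing / 1000)
  pts <- cbind(px - ty * off, py + tx * off)
  inside <- .bilinear(field$grid, field$speed, pts[, 1], pts[, 2],
                      na_ok = TRUE)
  keep <- !is.na(inside)
  list(x = pts[keep, 1], y = pts[keep, 2], offset = off[keep],
       center = c(px, py), normal = c(-ty, tx), tangent = c(tx, ty))
}

# bilinear interpolation of a cell-centered matrix at (x, y) in mm
.bilinear <- function(grid, M, x, y, na_ok = FALSE) {
  fx <- (x - grid$x0) / (grid$cell / 1000) - 0.5
  fy <- (y - grid$y0) / (grid$cell / 1000) - 0.5
  i0 <- pmin(pmax(floor(fx), 0), grid$nx - 1)
  j0 <- pmin(pmax(floor(fy), 0), grid$ny - 1)
  i1 <- pmin(i0 + 1, grid$nx - 1)
  j1 <- pmin(j0 + 1, grid$ny - 1)
  wx <- pmin(pmax(fx - i0, 0), 1)
  wy <- pmin(pmax(fy - j0, 0), 1)
  g <- function(i, j) M[cbind(i + 1, j + 1)]
  v00 <- g(i0, j0); v10 <- g(i1, j0); v01 <- g(i0, j1); v11 <- g(i1, j1)
  out <- (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
    (1 - wx) * wy * v01 + wx * wy * v11
  if (!na_ok) {
    # fall back to nearest non-NA corner at the walls
    nn <- is.na(out)
    if (any(nn)) {
      alt <- ifelse(is.na(v00[nn]), ifelse(is.na(v10[nn]),
                    ifelse(is.na(v01[nn]), v11[nn], v01[nn]), v10[nn]),
                    v00[nn])
      out[nn] <- alt
    }
  }
  out
}

#' Field-based mixing index at a station
#'
#' MI = 1 - sigma(s)/sigma_max, where sigma is the (population) standard
#' deviation of the species mass fraction over the in-channel samples of
#' the cross-section normal to the centerline at arc length s, and
#' sigma_max is the same quantity at the mixing-channel entrance.
#'
#' @param field a [solve_species()] result.
#' @param s station arc length from the junction (mm).
#' @param entrance entrance station (mm) defining sigma_max.
#' @return list with `mi`, `sigma`, `sigma_max`, `s`.
#' @export
field_mixing_index <- function(field, s, entrance = NULL) {
  if (is.null(field$Y)) stop("species not solved; call solve_species first")
  if (is.null(entrance)) entrance <- 2 * field$grid$cell / 1000
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  sig_at <- function(st) {
    sp <- .section_points(field, st)
    vals <- .bilinear(field$grid, field$Y, sp$x, sp$y, na_ok = TRUE)
    psd(vals[!is.na(vals)])
  }
  sigma_max <- sig_at(entrance)
  if (sigma_max <= 0) stop("sigma_max is zero: inlets are not distinct")
  sigma <- sig_at(s)
  list(mi = 1 - sigma / sigma_max, sigma = sigma, sigma_max = sigma_max,
       s = s)
}

#' Centerline speed at a station
#' @param field a `flow_field`.
#' @param s station arc length (mm).
#' @return speed (m/s) interpolated at the centerline point.
#' @export
centerline_speed <- function(field, s) {
  path <- field$grid$path
  if (s < 0 || s > max(path$s)) stop("station outside the channel body")
  px <- stats::approx(path$s, path$x, xout = s)$y
  py <- stats::approx(path$s, path$y, xout = s)$y
  v <- .bilinear(field$grid, field$speed, px, py, na_ok = TRUE)
  if (is.na(v)) stop(sprintf("station %.3f mm lies in the wall", s))
  v
}

#' Ratio of centerline speeds between two stations
#'
#' (speed at the narrow station) / (speed at the wide station); about the
#' widening factor for long plateaus and larger when the widened pocket is
#' short and curved.
#' @param field a `flow_field` (or give `field_wide` for a second design).
#' @param s_narrow,s_wide stations (mm).
#' @param field_wide optional second field evaluated at `s_wide`.
#' @export
centerline_speed_ratio <- function(field, s_narrow, s_wide,
                                   field_wide = field) {
  centerline_speed(field, s_narrow) / centerline_speed(field_wide, s_wide)
}

#' Volumetric flux through the cross-section at a station
#'
#' Integrates the normal velocity over the in-channel section samples;
#' useful for mass-conservation checks (flux equals the inlet Q within the
#' solver's continuity tolerance).
#' @param field a `flow_field`.
#' @param s station (mm).
#' @return flux per unit out-of-plane depth times height, in uL/min.
#' @export
section_flux <- function(field, s) {
  grid <- field$grid
  path <- grid$path
  px <- stats::approx(path$s, path$x, xout = s)$y
  py <- stats::approx(path$s, path$y, xout = s)$y
  sp <- .section_points(field, s)
  tx <- sp$tangent[1]; ty <- sp$tangent[2]
  wloc <- stats::approx(path$s, path$w, xout = s)$y / 1000   # mm
  dl_mm <- grid$cell / 8000
  off <- seq(-wloc / 2 + dl_mm / 2, wloc / 2 - dl_mm / 2, by = dl_mm)
  xs <- px - ty * off; ys <- py + tx * off
  # taper linearly to the no-slip wall inside the last half-cell
  uq <- .bilinear(grid, field$uc, xs, ys)
  vq <- .bilinear(grid, field$vc, xs, ys)
  wall_dist <- pmin(off - (-wloc / 2), wloc / 2 - off)
  fac <- pmin(1, wall_dist / (grid$cell / 2000))
  un <- (uq * tx + vq * ty) * fac
  sum(un * dl_mm * 1e-3) * (field$height * 1e-6) * 60e9
}

#' Species concentration profile across a station
#' @param field a [solve_species()] result.
#' @param s station (mm).
#' @return data frame of transverse offset (mm) and mass fraction.
#' @export
section_species <- function(field, s) {
  sp <- .section_points(field, s)
  data.frame(offset = sp$offset,
             Y = .bilinear(field$grid, field$Y, sp$x, sp$y))
}

#' Mixing index versus distance table from a field
#' @param field a [solve_species()] result.
#' @param stations arc-length stations (mm).
#' @return data frame (station, mi, sigma).
#' @export
field_mi_table <- function(field, stations = c(0, 10, 15, 20, 25, 40)) {
  stations <- stations[stations <= max(field$grid$path$s)]
  ent <- 2 * field$grid$cell / 1000
  rows <- lapply(stations, function(s) {
    r <- field_mixing_index(field, max(s, ent))
    data.frame(station = s, mi = r$mi, sigma = r$sigma)
  })
  do.call(rbind, rows)
}

#' Export a flow field as a structured CSV dump
#' @param field a `flow_field`.
#' @param file output path.
#' @export
write_field_csv <- function(field, file) {
  g <- field$grid
  df <- expand.grid(i = seq_len(g$nx), j = seq_len(g$ny))
  df$x <- g$xc[df$i]; df$y <- g$yc[df$j]
  df$in_channel <- as.vector(g$mask) == 1L
  df$u <- as.vector(field$uc); df$v <- as.vector(field$vc)
  df$p <- as.vector(field$p)
  df$Y <- if (is.null(field$Y)) NA_real_ else as.vector(field$Y)
  utils::write.csv(df[, c("x", "y", "in_channel", "u", "v", "p", "Y")],
                   file, row.names = FALSE)
  invisible(file)
}
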