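#' Advect tracer particles through a flow field
#'
#' Integrates passive point tracers (no inertia; beads are tiny relative to
#' the channel) with classical 4th-order Runge-Kutta at sub-frame steps and
#' samples positions at the camera frame rate. A particle's track ends when
#' it reaches the outlet or a wall: the last step is shortened to land on
#' the boundary.
#'
#' @param field a [solve_steady_flow()] or [analytic_field()] result.
#' @param seeds two-column matrix of seed positions (mm).
#' @param frame_rate sampling rate (Hz), default 100.
#' @param duration track duration (s).
#' @param substeps RK4 sub-steps per frame.
#' @param brownian_sd optional diffusive kick per frame (mm, standard
#'   deviation per axis); 0 disables it.
#' @param seed RNG seed for the Brownian kick.
#' @return list of `track` objects: data frames (t, x, y, speed) with the
#'   particle id and the transverse position at the first frame.
#' @export
advect_particles <- function(field, seeds, frame_rate = 100, duration = 1,
                             substeps = 10L, brownian_sd = 0, seed = 0L) {
  stopifnot(inherits(field, "flow_field"))
  seeds <- matrix(seeds, ncol = 2)
  grid <- field$grid
  inside <- function(x, y) !is.na(.bilinear(grid, field$speed, x, y,
                                            na_ok = TRUE))
  bad <- which(!inside(seeds[, 1], seeds[, 2]))
  if (length(bad))
    stop("seed(s) in wall: ", paste(bad, collapse = ", "))
  vel <- function(x, y) {
    cbind(.bilinear(grid, field$uc, x, y),
          .bilinear(grid, field$vc, x, y)) * 1000  # m/s -> mm/s
  }
  if (brownian_sd > 0) set.seed(seed)
  dt <- 1 / frame_rate / substeps
  n_frames <- ceiling(duration * frame_rate)
  x_end <- grid$x0 + grid$nx * grid$cell / 1000
  tracks <- vector("list", nrow(seeds))
  for (pid in seq_len(nrow(seeds))) {
    px <- seeds[pid, 1]; py <- seeds[pid, 2]
    tt <- 0
    xs <- px; ys <- py; ts <- tt
    alive <- TRUE
    for (f in seq_len(n_frames)) {
      if (!alive) break
      for (k in seq_len(substeps)) {
        k1 <- vel(px, py)
        k2 <- vel(px + dt / 2 * k1[1], py + dt / 2 * k1[2])
        k3 <- vel(px + dt / 2 * k2[1], py + dt / 2 * k2[2])
        k4 <- vel(px + dt * k3[1], py + dt * k3[2])
        dx <- dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
        dy <- dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
        nx_ <- px + dx; ny_ <- py + dy
        if (nx_ >= x_end || !inside(nx_, ny_)) {
          # shorten the step to land on the boundary, then terminate
          lo <- 0; hi <- 1
          for (it in 1:25) {
            mid <- (lo + hi) / 2
            if (px + mid * dx < x_end && inside(px + mid * dx, py + mid * dy))
              lo <- mid else hi <- mid
          }
          px <- px + lo * dx; py <- py + lo * dy
          alive <- FALSE
          break
        }
        px <- nx_; py <- ny_
      }
      if (brownian_sd > 0 && alive) {
        cand <- c(px + stats::rnorm(1, 0, brownian_sd),
                  py + stats::rnorm(1, 0, brownian_sd))
        if (inside(cand[1], cand[2])) { px <- cand[1]; py <- cand[2] }
      }
      tt <- f / frame_rate
      xs <- c(xs, px); ys <- c(ys, py); ts <- c(ts, tt)
      if (!alive) break
    }
    sp <- c(sqrt(diff(xs)^2 + diff(ys)^2) / diff(ts), NA)
    tracks[[pid]] <- structure(
      data.frame(t = ts, x = xs, y = ys, speed = sp),
      id = pid, y0 = ys[1], class = c("track", "data.frame"))
  }
  tracks
}

#' Cross-channel velocity profile recovered from tracks
#'
#' Bins the per-step speeds of all track samples near a streamwise section
#' by transverse position and reports the mean speed per bin, with the
#' goodness of a parabolic (Poiseuille) fit.
#'
#' @param tracks list of tracks from [advect_particles()].
#' @param x0 section position (mm).
#' @param halfwidth samples within `x0 +/- halfwidth` (mm) are used.
#' @param bins number of transverse bins (ignored when fewer distinct
#'   positions exist).
#' @return list with `profile` (data frame y, speed, n) and `r_squared` of
#'   the parabolic fit (NA with < 3 bins).
#' @export
velocity_profile_from_tracks <- function(tracks, x0, halfwidth = 0.25,
                                         bins = 12) {
  pts <- do.call(rbind, lapply(tracks, function(tr)
    tr[!is.na(tr$speed) & abs(tr$x - x0) <= halfwidth, c("y", "speed")]))
  if (is.null(pts) || !nrow(pts)) stop("no track samples cross the section")
  if (length(unique(pts$y)) < bins) {
    prof <- stats::aggregate(speed ~ y, pts, mean)
    prof$n <- as.vector(table(pts$y)[as.character(prof$y)])
  } else {
    br <- seq(min(pts$y) - 1e-9, max(pts$y) + 1e-9, length.out = bins + 1)
    grp <- cut(pts$y, br, include.lowest = TRUE)
    prof <- data.frame(y = tapply(pts$y, grp, mean),
                       speed = tapply(pts$speed, grp, mean),
                       n = as.vector(table(grp)))
    prof <- prof[!is.na(prof$speed), ]
  }
  r2 <- NA_real_
  if (nrow(prof) >= 3) {
    fit <- stats::lm(speed ~ y + I(y^2), data = prof)
    r2 <- summary(fit)$r.squared
  }
  list(profile = prof, r_squared = r2)
}

#' Streak length of a moving bead at a given exposure
#'
#' A bead moving at `speed` during an exposure of `exposure` seconds leaves
#' a streak of length speed x exposure on the sensor.
#'
#' @param speed bead speed (mm/s).
#' @param exposure exposure time (s), default 5 ms.
#' @return streak length (um).
#' @examples
#' streak_length(10.4)  # 52 um
#' @export
streak_length <- function(speed, exposure = 5e-3) {
  if (any(speed < 0)) stop("speed must be >= 0")
  speed * exposure * 1000
}

#' Write tracks as a tidy CSV (id, t, x, y, speed)
#' @param tracks list of tracks.
#' @param file output path.
#' @export
write_tracks_csv <- function(tracks, file) {
  df <- do.call(rbind, lapply(tracks, function(tr) {
    tr$id <- attr(tr, "id"); tr
  }))
  utils::write.csv(df[, c("id", "t", "x", "y", "speed")], file,
                   row.names = FALSE)
  invisible(file)
}
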