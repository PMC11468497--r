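# Channel outline construction: offset a width-annotated centerline by
# +/- w(s)/2 along its normals. Joins are rounded implicitly by densifying
# the path; where the local curvature radius drops below w/2 the inner
# offset self-intersects and the resulting loops are excised.

.densify_path <- function(path, step) {
  s_new <- sort(unique(c(path$s, seq(0, max(path$s), by = step))))
  list(s = s_new,
       x = stats::approx(path$s, path$x, xout = s_new)$y,
       y = stats::approx(path$s, path$y, xout = s_new)$y,
       w = stats::approx(path$s, path$w, xout = s_new)$y)
}

.path_normals <- function(x, y) {
  n <- length(x)
  tx <- c(x[2] - x[1], x[-(1:2)] - x[-c(n - 1, n)], x[n] - x[n - 1])
  ty <- c(y[2] - y[1], y[-(1:2)] - y[-c(n - 1, n)], y[n] - y[n - 1])
  len <- sqrt(tx^2 + ty^2)
  cbind(-ty / len, tx / len)   # left normal
}

# remove local self-intersection loops from a polyline (inner offsets at
# tight apexes); window-limited O(n * win) segment intersection walk
.remove_loops <- function(x, y, win = 200L) {
  repeat {
    n <- length(x)
    if (n < 4) break
    cut <- NULL
    i <- 1L
    while (i <= n - 3) {
      jmax <- min(n - 1L, i + win)
      js <- (i + 2L):jmax
      # segment i: p1->p2 ; segments j: q1->q2
      p1x <- x[i]; p1y <- y[i]; dx1 <- x[i + 1] - p1x; dy1 <- y[i + 1] - p1y
      q1x <- x[js]; q1y <- y[js]
      dx2 <- x[js + 1] - q1x; dy2 <- y[js + 1] - q1y
      den <- dx1 * dy2 - dy1 * dx2
      ok <- abs(den) > 1e-14
      t1 <- ((q1x - p1x) * dy2 - (q1y - p1y) * dx2) / den
      t2 <- ((q1x - p1x) * dy1 - (q1y - p1y) * dx1) / den
      hit <- ok & t1 > 1e-9 & t1 < 1 - 1e-9 & t2 > 1e-9 & t2 < 1 - 1e-9
      if (any(hit)) {
        j <- js[which(hit)[1]]
        tt <- t1[which(hit)[1]]
        cut <- list(i = i, j = j, px = p1x + tt * dx1, py = p1y + tt * dy1)
        break
      }
      i <- i + 1L
    }
    if (is.null(cut)) break
    keep <- c(seq_len(cut$i), (cut$j + 1L):n)
    x <- c(x[seq_len(cut$i)], cut$px, x[(cut$j + 1L):n])
    y <- c(y[seq_len(cut$i)], cut$py, y[(cut$j + 1L):n])
  }
  cbind(x, y)
}

#' Channel outline polygon from a centerline
#'
#' Offsets the centerline by half the local width on each side and closes
#' the boundary with end caps, producing the plan-view channel outline. The
#' path is densified to `step` before offsetting (this rounds joins); inner
#' offset loops at apexes whose curvature radius is below w/2 are excised,
#' with an error if `on_self_intersect = "error"`.
#'
#' @param path a [centerline_path()] (simple, non-self-intersecting).
#' @param step densification step along arc length (mm).
#' @param on_self_intersect `"repair"` (default) removes offset loops;
#'   `"error"` fails naming the offending arc length.
#' @return object of class `channel_polygon`: closed counter-clockwise
#'   outer ring (`x`, `y`, mm), plus the inlet/outlet end-cap edges.
#' @export
path_to_polygon <- function(path, step = 0.02,
                            on_self_intersect = c("repair", "error")) {
  stopifnot(inherits(path, "centerline_path"))
  on_self_intersect <- match.arg(on_self_intersect)
  d <- .densify_path(path, step)
  nrm <- .path_normals(d$x, d$y)
  half <- d$w / 2000   # um -> mm
  lx <- d$x + nrm[, 1] * half; ly <- d$y + nrm[, 2] * half
  rx <- d$x - nrm[, 1] * half; ry <- d$y - nrm[, 2] * half
  left <- .remove_loops(lx, ly)
  right <- .remove_loops(rx, ry)
  if (on_self_intersect == "error" &&
      (nrow(left) < length(lx) || nrow(right) < length(rx))) {
    bad <- which(seq_along(lx) > nrow(left))[1]
    stop(sprintf(
      "offset self-intersects near arc length %.3f mm (curvature radius < w/2)",
      d$s[min(bad, length(d$s))]))
  }
  x <- c(left[, 1], rev(right[, 1]))
  y <- c(left[, 2], rev(right[, 2]))
  # close ring
  x <- c(x, x[1]); y <- c(y, y[1])
  area2 <- sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)])
  if (area2 < 0) { x <- rev(x); y <- rev(y) }   # enforce CCW
  structure(list(
    x = x, y = y,
    inlet_edge = cbind(c(left[1, 1], right[1, 1]),
                       c(left[1, 2], right[1, 2])),
    outlet_edge = cbind(c(left[nrow(left), 1], right[nrow(right), 1]),
                        c(left[nrow(left), 2], right[nrow(right), 2])),
    source_area = path_width_integral(path)
  ), class = "channel_polygon")
}

#' @export
print.channel_polygon <- function(x, ...) {
  cat(sprintf("<channel_polygon> %d boundary vertices, area %.4f mm^2\n",
              length(x$x) - 1, polygon_area(x)))
  invisible(x)
}

#' Shoelace area of a channel polygon (mm^2)
#' @param poly a `channel_polygon`.
#' @export
polygon_area <- function(poly) {
  x <- poly$x; y <- poly$y
  abs(sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)])) / 2
}

#' Check a channel polygon for boundary self-intersections
#'
#' Brute-force segment pair test (adjacent pairs excluded). Returns TRUE for
#' a simple (valid) ring.
#' @param poly a `channel_polygon`.
#' @export
polygon_is_valid <- function(poly) {
  x <- poly$x; y <- poly$y
  n <- length(x) - 1
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]   # first/last segments are adjacent
    if (!length(js)) next
    dx1 <- x[i + 1] - x[i]; dy1 <- y[i + 1] - y[i]
    dx2 <- x[js + 1] - x[js]; dy2 <- y[js + 1] - y[js]
    den <- dx1 * dy2 - dy1 * dx2
    ok <- abs(den) > 1e-14
    t1 <- ((x[js] - x[i]) * dy2 - (y[js] - y[i]) * dx2) / den
    t2 <- ((x[js] - x[i]) * dy1 - (y[js] - y[i]) * dx1) / den
    if (any(ok & t1 > 1e-9 & t1 < 1 - 1e-9 & t2 > 1e-9 & t2 < 1 - 1e-9))
      return(FALSE)
  }
  TRUE
}

#' Local channel width measured from the polygon
#'
#' For sample points along the centerline, the distance between the two
#' boundary intersections of the local normal line. Used for width-fidelity
#' checks against the designed w(s).
#' @param poly a `channel_polygon`.
#' @param path the generating [centerline_path()].
#' @param at arc-length stations (mm) at which to measure.
#' @return numeric vector of widths (um).
#' @export
polygon_local_width <- function(poly, path, at) {
  d <- .densify_path(path, 0.02)
  nrm <- .path_normals(d$x, d$y)
  vapply(at, function(s0) {
    i <- which.min(abs(d$s - s0))
    px <- d$x[i]; py <- d$y[i]; nx <- nrm[i, 1]; ny <- nrm[i, 2]
    # intersect the normal line with every boundary segment
    x <- poly$x; y <- poly$y
    bx1 <- x[-length(x)]; by1 <- y[-length(y)]
    dx2 <- diff(x); dy2 <- diff(y)
    den <- nx * dy2 - ny * dx2
    ok <- abs(den) > 1e-14
    t1 <- ((bx1 - px) * dy2 - (by1 - py) * dx2) / den
    t2 <- ((bx1 - px) * ny - (by1 - py) * nx) / den
    hits <- t1[ok & t2 >= 0 & t2 <= 1]
    if (length(hits) < 2) return(NA_real_)
    (max(hits) - min(hits)) * 1000
  }, numeric(1))
}

#' Write a polygon as WKT
#' @param poly a `channel_polygon`.
#' @param file output path; if NULL the WKT string is returned.
#' @export
write_wkt <- function(poly, file = NULL) {
  wkt <- sprintf("POLYGON ((%s))",
                 paste(sprintf("%.6f %.6f", poly$x, poly$y), collapse = ", "))
  if (is.null(file)) return(wkt)
  writeLines(wkt, file)
  invisible(wkt)
}

#' Write a polygon (and optional centerline) as a standalone SVG
#' @param poly a `channel_polygon`.
#' @param file output .svg path.
#' @param path optional [centerline_path()] drawn as a dashed line.
#' @export
write_svg <- function(poly, file, path = NULL) {
  pad <- 0.5
  xr <- range(poly$x) + c(-pad, pad); yr <- range(poly$y) + c(-pad, pad)
  sc <- 50  # px per mm
  mapx <- function(x) (x - xr[1]) * sc
  mapy <- function(y) (yr[2] - y) * sc
  pts <- paste(sprintf("%.2f,%.2f", mapx(poly$x), mapy(poly$y)),
               collapse = " ")
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f">',
            diff(xr) * sc, diff(yr) * sc),
    sprintf('<polygon points="%s" fill="#cfe8ff" stroke="#1f4e79" stroke-width="1"/>',
            pts))
  if (!is.null(path))
    lines <- c(lines, sprintf(
      '<polyline points="%s" fill="none" stroke="#c03" stroke-width="0.7" stroke-dasharray="4 3"/>',
      paste(sprintf("%.2f,%.2f", mapx(path$x), mapy(path$y)), collapse = " ")))
  lines <- c(lines, "</svg>")
  writeLines(lines, file)
  invisible(file)
}

#' Export a centerline as a CSV of (s, x, y, w)
#' @param path a [centerline_path()].
#' @param file output .csv path.
#' @export
write_centerline_csv <- function(path, file) {
  utils::write.csv(data.frame(s_mm = path$s, x_mm = path$x, y_mm = path$y,
                              w_um = path$w),
                   file, row.names = FALSE)
  invisible(file)
}
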