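test_that("zero-amplitude sinusoid degenerates to a straight channel", {
  spec <- mixer_spec("zigzag", amplitude = 0, wavelength = 3.3,
                     n_periods = 5, lead_in = 1.5, lead_out = 1.5)
  p <- zigzag_centerline(spec)
  expect_equal(max(abs(p$y)), 0, tolerance = 1e-12)
  L <- 1.5 + 5 * 3.3 + 1.5
  expect_equal(path_length(p), L, tolerance = 1e-9)
  # vertex-for-vertex against an explicit straight path at the same s
  expect_equal(stats::approx(p$s, p$y, xout = seq(0, L, 0.5))$y,
               rep(0, length(seq(0, L, 0.5))), tolerance = 1e-9)
})

test_that("sinusoid centerline has the designed span and arc length", {
  spec <- mixer_spec("zigzag", amplitude = 1.5, wavelength = 3.3,
                     n_periods = 2)
  p <- zigzag_centerline(spec)
  # peak-to-peak transverse span 2A = 3.0 mm
  expect_equal(diff(range(p$y)), 3.0, tolerance = 1e-3)
  # one-period arc length against adaptive quadrature of sqrt(1 + y'^2)
  lam <- 3.3; A <- 1.5
  oracle <- pracma::integral(function(x)
    sqrt(1 + (A * 2 * pi / lam * cos(2 * pi * x / lam))^2), 0, lam)
  body <- p$s[p$tag == "body"]
  in_period <- p$x >= spec$lead_in & p$x <= spec$lead_in + lam
  s_period <- diff(range(p$s[in_period]))
  expect_lt(abs(s_period - oracle) / oracle, 1e-3)
})

test_that("width profile: identity, exact plateaus, integral oracle", {
  spec <- mixer_spec("vzigzag", n_periods = 2)
  base <- zigzag_centerline(spec)
  # f = 1 returns identical widths
  expect_identical(apply_width_profile(base, 1, cbind(2, 3), 0.3)$w, base$w)
  zones <- cbind(5, 6)
  p <- apply_width_profile(base, 1.5, zones, 0.3)
  # centerline is never altered by widening
  expect_equal(stats::approx(p$s, p$x, xout = base$s)$y, base$x,
               tolerance = 1e-9)
  expect_equal(stats::approx(p$s, p$y, xout = base$s)$y, base$y,
               tolerance = 1e-9)
  # plateau samples exactly f * w0
  expect_equal(max(p$w) / p$w0, 1.5)
  expect_true(all(abs(p$w[p$s >= 5 & p$s <= 6] - 600) < 1e-9))
  # excess integral = plateau*(f-1)*w0 + two ramp trapezoids
  excess <- path_width_integral(p) - path_width_integral(base)
  oracle <- (6 - 5) * 0.5 * 0.4 + 2 * (0.3 * 0.5 * 0.4 / 2)
  expect_equal(excess, oracle, tolerance = 1e-9)
  # overlapping zones rejected
  expect_error(apply_width_profile(base, 1.5, rbind(c(5, 6), c(6.2, 7)), 0.3),
               "overlap")
})

test_that("V-zigzag default profile widens every apex by exactly 1.5", {
  spec <- mixer_spec("vzigzag", n_periods = 3)
  p <- vzigzag_centerline(spec)
  expect_equal(max(p$w) / p$w0, spec$widen_factor)
  expect_equal(min(p$w), p$w0)
  zones <- vzigzag_zones(spec, zigzag_centerline(spec))
  expect_equal(nrow(zones), 2 * 3)
  for (k in seq_len(nrow(zones))) {
    mid <- mean(zones[k, ])
    expect_equal(stats::approx(p$s, p$w, xout = mid)$y, 600,
                 tolerance = 1e-9)
  }
})

test_that("unit-cell mixers are continuous, additive and sized as designed", {
  for (design in c("hex", "diamond")) {
    p1 <- unit_cell_mixer(mixer_spec(design, n_periods = 1))
    p3 <- unit_cell_mixer(mixer_spec(design, n_periods = 3))
    # arc length strictly increasing = one continuous stroke
    expect_true(all(diff(p3$s) > 0))
    expect_equal(path_length(p3), 3 * path_length(p1), tolerance = 1e-12)
  }
  hex3 <- unit_cell_mixer(mixer_spec("hex", n_periods = 3, cell_side = 0.8))
  expect_equal(diff(range(hex3$x)), 2 * 0.8 * cos(pi / 6) * 3,
               tolerance = 1e-12)
  expect_error(unit_cell_mixer(mixer_spec("hex", n_periods = 0)),
               "n_periods")
})

test_that("Y-junction arms are symmetric and share the junction vertex", {
  spec <- mixer_spec("straight", body_length = 60, inlet_angle = 60)
  net <- y_junction(spec)
  top <- net$arm_top; bot <- net$arm_bottom
  expect_equal(top$x, bot$x, tolerance = 1e-12)
  expect_equal(top$y, -bot$y, tolerance = 1e-12)
  # all three paths share the junction coordinates exactly
  expect_identical(c(top$x[length(top$x)], top$y[length(top$y)]), c(0, 0))
  expect_identical(c(net$body$x[1], net$body$y[1]), c(0, 0))
  # measurement stations all inside the 60 mm body
  expect_true(all(c(0, 10, 15, 20, 25, 40) <= path_length(net$body)))
  expect_error(y_junction(mixer_spec("straight", arm_length = 0)))
})

test_that("flow-focusing layout has the designed widths and symmetry", {
  ff <- flow_focusing_layout(core_width = 0.4, shell_width = 1.0)
  expect_equal(ff$core$w0 / ff$outlet$w0, 0.4)
  # core = shell/2 gives a per-side shell annulus of shell/4
  ff2 <- flow_focusing_layout(core_width = 0.5, shell_width = 1.0)
  expect_equal(ff2$shell_top$w0 / 1000, 0.25)
  expect_equal(ff$shell_top$y, -ff$shell_bottom$y, tolerance = 1e-12)
  expect_error(flow_focusing_layout(core_width = 1, shell_width = 1))
})

test_that("polygon offsetting reproduces areas and widths", {
  # straight channel: exact rectangle
  p <- straight_path(20, 400)
  poly <- path_to_polygon(p)
  expect_true(polygon_is_valid(poly))
  expect_equal(polygon_area(poly), 8.0, tolerance = 1e-6)
  # gentle sinusoid: area within 1% of integral w ds
  spec <- mixer_spec("zigzag", amplitude = 0.6, n_periods = 2)
  ps <- zigzag_centerline(spec)
  polys <- path_to_polygon(ps)
  expect_true(polygon_is_valid(polys))
  expect_lt(abs(polygon_area(polys) - path_width_integral(ps)) /
              path_width_integral(ps), 0.01)
  # V-zigzag at gentle amplitude: measured local width ratio ~ 1.5
  specv <- mixer_spec("vzigzag", amplitude = 0.6, n_periods = 2)
  pv <- vzigzag_centerline(specv)
  polyv <- path_to_polygon(pv)
  zones <- pv$zones
  w_wide <- polygon_local_width(polyv, pv, rowMeans(zones))
  mid_narrow <- (zones[1, 2] + zones[2, 1]) / 2
  w_nom <- polygon_local_width(polyv, pv, mid_narrow)
  expect_equal(mean(w_wide, na.rm = TRUE) / w_nom, 1.5, tolerance = 0.05)
  # polygon area converges to the width integral as the chord is refined
  err_for <- function(tol) {
    sp <- mixer_spec("zigzag", amplitude = 0.6, n_periods = 2,
                     chord_tol = tol)
    pp <- zigzag_centerline(sp)
    abs(polygon_area(path_to_polygon(pp, step = tol * 4)) -
          path_width_integral(pp))
  }
  expect_lt(err_for(0.002), err_for(0.02))
})

test_that("default V-zigzag outline is repaired at tight apexes", {
  pv <- vzigzag_centerline(mixer_spec("vzigzag", n_periods = 2))
  expect_error(path_to_polygon(pv, on_self_intersect = "error"),
               "self-intersect")
  poly <- path_to_polygon(pv)
  expect_true(polygon_is_valid(poly))
})

test_that("spec validation rejects bad parameters", {
  expect_error(mixer_spec("zigzag", wavelength = 0), "wavelength")
  expect_error(mixer_spec("zigzag", width = -1), "width")
  expect_error(mixer_spec("zigzag", widen_factor = 0.5), "widen_factor")
  expect_error(mixer_spec("flow_focusing", core_width = 2), "core_width")
  expect_error(centerline_path(c(0, 1), c(0, 0), -5), "widths")
})

test_that("design exports round-trip (CSV) and are well-formed (WKT/SVG)", {
  p <- vzigzag_centerline(mixer_spec("vzigzag", n_periods = 2))
  f <- tempfile(fileext = ".csv")
  write_centerline_csv(p, f)
  back <- utils::read.csv(f)
  expect_equal(back$w_um, p$w, tolerance = 1e-9)
  wkt <- write_wkt(path_to_polygon(p))
  expect_match(wkt, "^POLYGON \\(\\(")
  svg <- tempfile(fileext = ".svg")
  write_svg(path_to_polygon(p), svg, path = p)
  expect_match(readLines(svg)[1], "<svg")
})
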