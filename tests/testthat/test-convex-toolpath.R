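test_that("segment extrusion follows the volumetric-equality model", {
  # volumetric oracle: bead volume / filament cross-section
  v_bead <- 10 * 0.4 * 0.3                      # mm^3
  a_fil <- pi * (1.75 / 2)^2                    # mm^2
  expect_equal(extrusion_for_segment(10, 400, 300, 1.75), v_bead / a_fil,
               tolerance = 1e-12)
  expect_equal(extrusion_for_segment(10, 400, 300, 1.75), 0.4989,
               tolerance = 1e-4)
  expect_identical(extrusion_for_segment(0, 400, 300, 1.75), 0)
  # linear in width
  expect_equal(extrusion_for_segment(10, 800, 300, 1.75),
               2 * extrusion_for_segment(10, 400, 300, 1.75))
  expect_error(extrusion_for_segment(10, 400, 300, 0), "filament")
})

test_that("feed co-modulation matches the constant-melt-flow model", {
  expect_equal(feed_for_width(400, 400, 200), 200)
  expect_equal(feed_for_width(600, 400, 200), 200 / 1.5)
  expect_equal(feed_for_width(600, 400, 200, mode = "constant_feed"), 200)
  expect_error(feed_for_width(0, 400, 200), "width")
})

test_that("path_to_gcode: continuity, totals and plateau extrusion ratio", {
  pp <- print_params()
  prog <- path_to_gcode(straight_path(20), pp)
  expect_equal(total_extrusion(prog),
               2 * extrusion_for_segment(10, 400, 300, 1.75),
               tolerance = 1e-12)
  expect_equal(total_extrusion(prog), 0.9977, tolerance = 1e-3)
  # one continuous extruding polyline: every move extrudes
  expect_true(all(prog$moves$e > 0))
  # V-zigzag in constant_feed mode: E-per-mm in plateaus 1.5x nominal
  pv <- vzigzag_centerline(mixer_spec("vzigzag", n_periods = 2))
  pg <- path_to_gcode(pv, pp, mode = "constant_feed")
  seg_len <- sqrt(diff(c(attr(pg$moves, "start")[1], pg$moves$x))^2 +
                    diff(c(attr(pg$moves, "start")[2], pg$moves$y))^2)
  e_per_mm <- pg$moves$e / seg_len
  expect_equal(max(e_per_mm) / min(e_per_mm), 1.5, tolerance = 1e-6)
  expect_true(all(pg$moves$f == pp$base_feed))
  # constant_volumetric: plateau feed is base/1.5
  pg2 <- path_to_gcode(pv, pp, mode = "constant_volumetric")
  expect_equal(min(pg2$moves$f), pp$base_feed / 1.5, tolerance = 1e-9)
  # empty path: header + footer only
  pe <- path_to_gcode(NULL, pp)
  expect_identical(nrow(pe$moves), 0L)
  expect_identical(total_extrusion(pe), 0)
})

test_that("header encodes the machine settings", {
  prog <- path_to_gcode(straight_path(5), print_params())
  hdr <- paste(prog$header, collapse = "\n")
  expect_match(hdr, "M104 S240")
  expect_match(hdr, "M140 S100")
  expect_match(hdr, "G92 E0")
})

test_that("volume conservation and E additivity", {
  pp <- print_params()
  pv <- vzigzag_centerline(mixer_spec("vzigzag", n_periods = 2))
  prog <- path_to_gcode(pv, pp)
  expect_lt(verify_volume(prog, pv, pp), 1e-9)
  # rounded cross-section model stays volume-consistent
  ppr <- print_params(cross_section = "rounded")
  progr <- path_to_gcode(pv, ppr)
  expect_lt(verify_volume(progr, pv, ppr), 1e-9)
  expect_lt(total_extrusion(progr), total_extrusion(prog))
  # doubling one E shows up as that segment's volume share
  prog2 <- prog
  prog2$moves$e[5] <- 2 * prog2$moves$e[5]
  share <- prog$moves$e[5] * pi * (1.75 / 2)^2 /
    (path_width_integral(pv) * 0.3)
  expect_equal(verify_volume(prog2, pv, pp), share, tolerance = 1e-6)
  # splitting a segment leaves the total unchanged
  p1 <- straight_path(20)
  p2 <- centerline_path(c(0, 7.3, 20), c(0, 0, 0), 400)
  expect_equal(total_extrusion(path_to_gcode(p1, pp)),
               total_extrusion(path_to_gcode(p2, pp)), tolerance = 1e-12)
})

test_that("gcode dialect round-trips field-for-field", {
  pp <- print_params()
  pv <- vzigzag_centerline(mixer_spec("vzigzag", n_periods = 2))
  for (em in c("relative", "absolute")) {
    prog <- path_to_gcode(pv, pp, e_mode = em)
    back <- parse_gcode(write_gcode(prog))
    expect_identical(back$e_mode, em)
    expect_equal(back$moves$x, prog$moves$x, tolerance = 1e-7)
    expect_equal(back$moves$y, prog$moves$y, tolerance = 1e-7)
    expect_equal(back$moves$e, prog$moves$e, tolerance = 1e-6)
    expect_equal(back$moves$f, prog$moves$f, tolerance = 1e-7)
  }
  f <- tempfile(fileext = ".gcode")
  write_gcode(path_to_gcode(pv, pp), f)
  expect_equal(parse_gcode(f)$moves$e, path_to_gcode(pv, pp)$moves$e,
               tolerance = 1e-6)
})
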