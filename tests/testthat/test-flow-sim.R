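test_that("Reynolds number matches the device operating range and is linear in Q", {
  sec <- default_section()
  expect_equal(reynolds_number(0, sec), 0)
  expect_equal(reynolds_number(1, sec), 0.047, tolerance = 0.02)
  expect_equal(reynolds_number(1000, sec), 1000 * reynolds_number(1, sec),
               tolerance = 1e-12)
  expect_equal(hydraulic_diameter(sec), 2 * 400 * 300 / 700)
  expect_error(channel_section(0, 300), "positive")
})

test_that("slot profile: no-slip, peak and flux normalization", {
  sec <- default_section()
  expect_equal(poiseuille_slot_profile(50, sec, c(-200, 200)), c(0, 0))
  expect_equal(poiseuille_slot_profile(50, sec, 0), 0.010417,
               tolerance = 1e-4)
  flux_mean <- pracma::integral(function(y)
    poiseuille_slot_profile(50, sec, y), -200, 200) / 400
  expect_equal(flux_mean, mean_speed(50, sec), tolerance = 1e-6)
  expect_error(poiseuille_slot_profile(50, sec, 300), "outside")
})

test_that("closed-form diffusion MI has the right limits and matches a
           finite-difference oracle", {
  expect_equal(diffusion_closed_form_mi(0, 1e-3, 400, 2.3e-9), 0,
               tolerance = 1e-9)
  expect_equal(diffusion_closed_form_mi(1e7, 1e-3, 400, 2.3e-9), 1,
               tolerance = 1e-9)
  # Fo = D t / W^2 = 0.1
  W <- 400e-6; D <- 2.3e-9; ub <- 1e-3
  t <- 0.1 * W^2 / D
  mi <- diffusion_closed_form_mi(t * ub * 1000, ub, 400, D)
  expect_equal(mi, 0.664, tolerance = 1e-3)
  # independent brute-force FD diffusion oracle
  expect_equal(mi, fd_step_diffusion_mi(t, W, D), tolerance = 2e-3)
})

test_that("steady solver reproduces the analytic slot profile", {
  grid <- build_sim_grid(straight_path(3, 400))
  fld <- solve_steady_flow(grid, 50)
  expect_true(fld$converged)
  sec <- default_section()
  # developed peak within 2% of 1.5 ubar
  expect_equal(centerline_speed(fld, 2.5),
               poiseuille_slot_profile(50, sec, 0), tolerance = 0.02)
  # full profile shape at several offsets
  sp <- section_species  # silence lints
  for (y_um in c(-150, -50, 100)) {
    px <- 2.5; py <- y_um / 1000
    got <- micromix:::.bilinear(grid, fld$speed, px, py)
    expect_equal(got, poiseuille_slot_profile(50, sec, y_um),
                 tolerance = 0.03)
  }
  # mass conservation at any cross-section
  for (s in c(0.5, 1.5, 2.5))
    expect_equal(section_flux(fld, s), 50, tolerance = 0.005)
  # Q = 0 gives an identically zero field
  f0 <- solve_steady_flow(grid, 0)
  expect_equal(max(abs(f0$u)), 0)
  expect_equal(max(abs(f0$v)), 0)
})

test_that("species transport is bounded, conservative and index-symmetric", {
  fld <- analytic_field("parabolic_slot", Q = 20, length = 6)
  fld <- solve_species(fld)
  Y <- fld$Y[fld$grid$mask == 1L]
  expect_true(all(Y >= -1e-8 & Y <= 1 + 1e-8))
  # flow-weighted outlet mean equals inlet mean (0.5) within 1%
  g <- fld$grid
  out <- g$nx
  wts <- fld$uc[out, g$mask[out, ] == 1L]
  ybar <- sum(wts * fld$Y[out, g$mask[out, ] == 1L]) / sum(wts)
  expect_equal(ybar, 0.5, tolerance = 0.01)
  # MI invariant to species relabeling (Y vs 1 - Y)
  mi1 <- field_mixing_index(fld, 5)$mi
  fld2 <- fld; fld2$Y <- 1 - fld2$Y
  expect_equal(field_mixing_index(fld2, 5)$mi, mi1, tolerance = 1e-12)
  # fully mixed inlets give Y = 0.5 everywhere
  fldm <- solve_species(analytic_field("plug", Q = 20, length = 6),
                        inlet_values = c(0.5, 0.5))
  expect_equal(range(fldm$Y, na.rm = TRUE), c(0.5, 0.5), tolerance = 1e-9)
  expect_error(field_mixing_index(fldm, 5), "sigma_max")
})

test_that("plug-flow MI profile matches the eigenmode series within 5%", {
  fld <- solve_species(analytic_field("plug", Q = 50, length = 20))
  ub <- mean_speed(50, default_section())
  for (s in c(5, 10, 20)) {
    mi_num <- field_mixing_index(fld, s)$mi
    mi_ana <- diffusion_closed_form_mi(s, ub, 400, 2.3e-9)
    expect_equal(mi_num, mi_ana, tolerance = 0.05)
  }
  # MI non-decreasing with distance
  tab <- field_mi_table(fld, stations = seq(1, 19, by = 2))
  expect_true(all(diff(tab$mi) > -1e-3))
})

test_that("numerical diffusion is controlled in the zero-diffusion limit", {
  fld <- analytic_field("plug", Q = 50, length = 10)
  props0 <- fluid_props(diffusivity = 1e-18)
  fld <- solve_species(fld, props = props0)
  # step stays sharp: at 10 mm (500 cells traveled) the 0.05-0.95
  # transition spans only a few cells
  prof <- section_species(fld, 9.5)
  trans <- sum(prof$Y > 0.05 & prof$Y < 0.95)
  expect_lt(trans, 6)
})

test_that("reported MI is grid-converged at the default resolution", {
  mi_at <- function(cell) {
    g <- build_sim_grid(straight_path(8, 400), cell = cell)
    f <- solve_steady_flow(g, 10)
    f <- solve_species(f)
    field_mixing_index(f, 7)$mi
  }
  mi20 <- mi_at(20); mi40 <- mi_at(40)
  expect_lt(abs(mi20 - mi40) / mi20, 0.03)
})

test_that("V-zigzag wide pockets decelerate the centerline flow", {
  spec <- mixer_spec("vzigzag", n_periods = 1, lead_in = 1, lead_out = 1)
  pv <- vzigzag_centerline(spec)
  fld <- solve_steady_flow(build_sim_grid(pv), 50)
  zones <- pv$zones
  s_wide <- mean(zones[1, ])
  s_narrow <- (zones[1, 2] + zones[2, 1]) / 2
  r <- centerline_speed_ratio(fld, s_narrow, s_wide)
  expect_gt(r, 1.2)
  # identical straight sections give ratio 1
  fs <- solve_steady_flow(build_sim_grid(straight_path(4, 400)), 50)
  expect_equal(centerline_speed_ratio(fs, 2, 3), 1, tolerance = 0.01)
})

test_that("solver rejects and reports bad inputs", {
  grid <- build_sim_grid(straight_path(2, 400))
  expect_error(solve_steady_flow(grid, -1), "Q")
  fld <- solve_steady_flow(grid, 10)
  expect_error(field_mixing_index(fld, 1), "species")
  fld <- solve_species(fld)
  expect_error(field_mixing_index(fld, 10), "outside")
  expect_error(centerline_speed(fld, -1), "outside")
})
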