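test_that("horizontal rope angle follows arcsin(s / L)", {
  expect_equal(rope_angle_horizontal(0, 5), 0)
  expect_equal(rope_angle_horizontal(2.5, 2.5), 90)
  expect_equal(rope_angle_horizontal(1.25, 2.5), 30, tolerance = 1e-12)
  expect_error(rope_angle_horizontal(2.6, 2.5), "exceed")
  expect_error(rope_angle_horizontal(-0.1, 2.5), ">= 0")
})

test_that("horizontal restoring acceleration is g sin cos with its 45-degree maximum", {
  expect_equal(axial_accel_horizontal(0), 0)
  expect_equal(axial_accel_horizontal(45), 9.81 / 2, tolerance = 1e-12)
  expect_equal(axial_accel_horizontal(30), 9.81 * 0.5 * sqrt(3) / 2,
               tolerance = 1e-12)  # 4.248
  angles <- seq(0, 90, by = 1)
  acc <- axial_accel_horizontal(angles)
  expect_equal(angles[which.max(acc)], 45)
})

test_that("tilted rope angle adds the suspension angle to the swing", {
  expect_equal(rope_angle_hut(0, 2.5, LUNAR_DEG), LUNAR_DEG)
  expect_equal(rope_angle_hut(1.25, 2.5, LUNAR_DEG), 39.5, tolerance = 1e-12)
  expect_equal(rope_angle_hut(2.5, 2.5, LUNAR_DEG), 90 + LUNAR_DEG)
  expect_error(rope_angle_hut(3, 2.5, LUNAR_DEG), "exceed")
})

test_that("tilted axial acceleration matches equilibrium and hand-worked values", {
  equil <- axial_accel_hut(LUNAR_DEG, LUNAR_DEG)
  expect_equal(equil, axial_g(LUNAR_DEG), tolerance = 1e-12)   # 1.619
  expect_equal(round(equil, 3), 1.619)
  expect_equal(round(axial_accel_hut(25.76, LUNAR_DEG), 3), 4.093)
  expect_error(axial_accel_hut(5, LUNAR_DEG), ">=")
})

test_that("tilted model reduces exactly to the horizontal model at zero tilt", {
  for (L in c(2.5, 5, 7.5, 10)) {
    s <- seq(0, 0.95 * L, length.out = 40)
    ang_h <- rope_angle_horizontal(s, L)
    ang_t <- rope_angle_hut(s, L, 0)
    expect_equal(ang_t, ang_h, tolerance = 1e-12)
    expect_equal(axial_accel_hut(ang_t, 0), axial_accel_horizontal(ang_h),
                 tolerance = 1e-12)
  }
})

test_that("the retained non-restoring variant never exceeds equilibrium", {
  ang <- seq(LUNAR_DEG, 60, length.out = 30)
  printed <- axial_accel_hut(ang, LUNAR_DEG, printed_form = TRUE)
  expect_true(all(printed <= axial_g(LUNAR_DEG) + 1e-12))
  # whereas the restoring form starts at equilibrium and rises
  restoring <- axial_accel_hut(ang, LUNAR_DEG)
  expect_true(all(restoring >= axial_g(LUNAR_DEG) - 1e-12))
})

test_that("mass weighting averages per-rope accelerations", {
  f <- hutsim_segments()$mass_fraction
  expect_equal(total_axial_accel(rep(3.2, 4), f), 3.2, tolerance = 1e-12)
  a <- c(1.7, 1.9, 2.2, 2.6)
  expect_equal(total_axial_accel(a, f), sum(a * f), tolerance = 1e-12)
  expect_true(total_axial_accel(a, f) >= min(a) &&
                total_axial_accel(a, f) <= max(a))
  expect_error(total_axial_accel(a, f * 0.9), "sum to 1")
})

test_that("error curve starts at zero error, grows with displacement, shrinks with rope length", {
  body <- ref_body()
  curve <- pendulum_error_curve(body, LUNAR_DEG, 2.5, s_max_m = 0.7,
                                n_points = 41)
  at0 <- curve[curve$s_axial_m == 0, ]
  expect_equal(at0$additional_accel_ms2, rep(0, 5), tolerance = 1e-12)
  # per rope: additional acceleration strictly increasing in s
  for (r in c("ankle", "knee", "pelvis", "thorax", "total")) {
    add <- curve$additional_accel_ms2[curve$rope == r]
    expect_true(all(diff(add) > 0))
  }
  # per-rope ordering at fixed s: shorter ropes err more
  wide <- tidyr::pivot_wider(
    curve[curve$rope != "total", c("s_axial_m", "rope", "additional_accel_ms2")],
    names_from = "rope", values_from = "additional_accel_ms2")
  wide <- wide[wide$s_axial_m > 0, ]
  expect_true(all(wide$thorax >= wide$pelvis & wide$pelvis >= wide$knee &
                    wide$knee >= wide$ankle))
  # longer ankle rope: pointwise smaller error everywhere
  longer <- pendulum_error_curve(body, LUNAR_DEG, 5, s_max_m = 0.7,
                                 n_points = 41)
  expect_true(all(longer$additional_accel_ms2 <= curve$additional_accel_ms2 + 1e-12))
  # total lies between the extreme rope groups at every displacement
  tot <- curve$additional_accel_ms2[curve$rope == "total"][-1]
  expect_true(all(tot >= wide$ankle - 1e-12 & tot <= wide$thorax + 1e-12))
  expect_error(pendulum_error_curve(body, LUNAR_DEG, 2.5, s_max_m = 3), "shortest")
})

test_that("error curve at the reference rig matches an independent re-derivation", {
  body <- ref_body()
  curve <- pendulum_error_curve(body, LUNAR_DEG, 2.5, s_max_m = 0.6,
                                n_points = 4)  # s = 0, 0.2, 0.4, 0.6
  geom <- rope_geometry(body, LUNAR_DEG, 2.5)
  for (s in c(0.2, 0.4, 0.6)) {
    th <- asin(s / geom$length_m) * 180 / pi + LUNAR_DEG
    a <- 9.81 * sin(th * pi / 180) * cos((th - LUNAR_DEG) * pi / 180)
    expected_total <- sum(a * body$mass_fraction) - 9.81 * sin(LUNAR_DEG * pi / 180)
    got <- curve$additional_accel_ms2[curve$rope == "total" &
                                        abs(curve$s_axial_m - s) < 1e-9]
    expect_equal(got, expected_total, tolerance = 1e-12)
  }
})

test_that("jump apex converges to the ballistic limit for very long ropes", {
  res <- jump_apex(ref_body(), LUNAR_DEG, 1e6, v0 = 1)
  ballistic <- 1 / (2 * 9.81 * sin(LUNAR_DEG * pi / 180))  # 0.3088 m
  expect_equal(res$apex_m, ballistic, tolerance = 0.005)
  expect_equal(res$ballistic_apex_m, ballistic, tolerance = 1e-12)
  expect_false(res$headroom_exceeded)
})

test_that("jump apex handles degenerate and flagged cases", {
  still <- jump_apex(ref_body(), LUNAR_DEG, 2.5, v0 = 0)
  expect_equal(still$apex_m, 0)
  expect_equal(still$flight_time_s, 0)
  expect_warning(big <- jump_apex(ref_body(), LUNAR_DEG, 10, v0 = 2),
                 "headroom")
  expect_true(big$headroom_exceeded)
  expect_error(suppressWarnings(jump_apex(ref_body(), LUNAR_DEG, 2.5, v0 = 10)),
               "valid displacement")
})

test_that("jump apex agrees with the energy-balance oracle and sits below ballistic", {
  body <- ref_body()
  for (v0 in c(0.5, 1, 1.5)) {
    for (theta in c(9.5, 22.3)) {
      for (L in c(2.5, 5)) {
        got <- suppressWarnings(jump_apex(body, theta, L, v0))
        oracle <- apex_energy_oracle(body, theta, L, v0)
        expect_equal(got$apex_m, oracle, tolerance = 1e-3)
        expect_lt(got$apex_m, got$ballistic_apex_m)
      }
    }
  }
})
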