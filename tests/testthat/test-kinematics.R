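plan <- stage_plan(substeps = 10L)

test_that("contact radius schedule hits the observed stage-end radii", {
  expect_identical(contact_radius_schedule(0, plan), 0)
  expect_equal(contact_radius_schedule(300, plan), 3.35)
  expect_equal(contact_radius_schedule(600, plan), 19.8)
  expect_equal(contact_radius_schedule(7200, plan), 19.8)
  # continuity across the stage boundaries
  eps <- 1e-9
  expect_equal(contact_radius_schedule(300 - eps, plan),
               contact_radius_schedule(300 + eps, plan), tolerance = 1e-6)
  expect_error(contact_radius_schedule(-1, plan), "negative")
})

test_that("stage plan validates its ordering", {
  expect_error(stage_plan(t_attach = 700), "boundaries")
  expect_error(stage_plan(dt_stage = c(0.5, -0.1, 0.05)), "positive")
  expect_error(stage_plan(substeps = 0), "substeps")
})

test_that("cap geometry solves the volume-conserving height", {
  # a = 0 reduces to the full sphere
  cap0 <- cap_shape(0, V_SPHERE)
  expect_equal(cap0$h, 20, tolerance = 1e-12)
  expect_equal(cap0$R_s, 10, tolerance = 1e-12)
  # frozen value from the bisection oracle on the monotone cubic
  cap <- cap_shape(19.8, V_SPHERE)
  expect_equal(cap$h, 6.56180224, tolerance = 1e-7)
  expect_equal(cap$R_s, 33.15379165, tolerance = 1e-7)
  expect_equal(cap$h, oracle_cap_height(19.8, V_SPHERE), tolerance = 1e-9)
  # invariants: volume recovered, sphere-radius relation
  for (a in c(0.5, 3.35, 11, 19.8)) {
    cp <- cap_shape(a, V_SPHERE)
    expect_equal(pi * cp$h * (3 * a^2 + cp$h^2) / 6, V_SPHERE,
                 tolerance = 1e-8)
    expect_equal(cp$R_s, (a^2 + cp$h^2) / (2 * cp$h), tolerance = 1e-12)
  }
  # h strictly decreasing in a at fixed volume
  hs <- vapply(seq(0, 19.8, length.out = 25),
               function(a) cap_shape(a, V_SPHERE)$h, numeric(1))
  expect_true(all(diff(hs) < 0))
  expect_error(cap_shape(-1, V_SPHERE), ">= 0")
  expect_error(cap_shape(1, -5), "> 0")
})

test_that("area-fraction map reproduces the tangent sphere at t = 0", {
  mesh <- build_meridian_mesh(10, 101)
  frame <- map_reference_to_current(mesh, cap_shape(0, V_SPHERE), 0)
  expect_equal(frame$lambda_a, rep(1, mesh$n), tolerance = 1e-12)
  # every node sits on the sphere of radius 10 tangent at the origin
  expect_equal(frame$rho^2 + (frame$y - 10)^2, rep(100, mesh$n),
               tolerance = 1e-8)
  # apex gap is the diameter
  expect_equal(frame$g_N[1], 20, tolerance = 1e-12)
  expect_equal(frame$g_N[mesh$n], 0)
})

test_that("map conserves area bookkeeping and uniform stretch", {
  mesh <- build_meridian_mesh(10, 200)
  for (a in c(3.35, 11, 19.8)) {
    cap <- cap_shape(a, V_SPHERE)
    frame <- map_reference_to_current(mesh, cap, NA)
    expect_equal(sum(frame$lambda_a * mesh$weights), cap$area,
                 tolerance = 1e-8)
    expect_true(all(frame$g_N >= 0))
    expect_true(all(frame$g_N[frame$contact] == 0))
    # contact nodes fill the disc: outermost contact node near radius a
    expect_lt(max(frame$rho[frame$contact]), a + 1e-9)
    # node ordering preserved along the meridian (rho decreasing from rim
    # only after the widest point; cumulative fraction strictly monotone)
    f <- (1 + cos(mesh$theta)) / 2
    expect_true(all(diff(f) < 0))
  }
  end_frame <- map_reference_to_current(mesh, cap_shape(19.8, V_SPHERE), NA)
  expect_equal(end_frame$lambda_a[1], 2.06784312, tolerance = 1e-7)
})

test_that("gap continuity in time at each node", {
  mesh <- build_meridian_mesh(10, 80)
  g_at <- function(t) {
    a <- contact_radius_schedule(t, plan)
    map_reference_to_current(mesh, cap_shape(a, V_SPHERE), t)$g_N
  }
  for (t in c(150, 300, 450)) {
    d <- abs(g_at(t + 0.05) - g_at(t))
    expect_lt(max(d), 0.2)  # bounded by schedule speed x small dt + mesh res
  }
})

test_that("contact complementarity check flags only true violations", {
  expect_identical(hsm_check(c(0, 0.5, 0.5), c(-1, 0, -1)), 3L)
  expect_identical(hsm_check(0, -1), integer(0))
  expect_identical(hsm_check(0.5, 0), integer(0))
  expect_identical(hsm_check(-0.1, 0), 1L)     # penetration
  expect_identical(hsm_check(0.5, 2), 1L)      # tensile traction
  expect_error(hsm_check(c(0, 1), 0), "equal length")
})

test_that("gap function validates non-penetration", {
  mesh <- build_meridian_mesh(10, 30)
  frame <- map_reference_to_current(mesh, cap_shape(5, V_SPHERE), 0)
  expect_identical(gap_function(frame), frame$g_N)
  frame$y[3] <- -1
  expect_error(gap_function(frame), "interpenetration")
})
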