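test_that("entry point realizes the AP-vertex / anterior-third rule", {
  fem <- cylinder_femur(R = 6, L = 300)
  e <- entry_point(fem)
  p <- attr(e, "frame_point")
  # flat proximal cap: local AP extent is [-6, 6], anterior-third
  # boundary measured from posterior = y_min + 2/3 * range = R/3
  expect_equal(p[2], 6 / 3, tolerance = 0.35)
  # AP projection coincides with the apex projection
  expect_lt(abs(p[1]), 0.5)
  expect_lt(abs(p[3]), 0.5)

  # synthetic femur: symmetric trochanteric cap, apex at the origin
  f <- build_femur(femur_params())
  pf <- attr(entry_point(f), "frame_point")
  expect_lt(abs(pf[1]), 0.5)
  expect_lt(abs(pf[3]), 0.5)
})

test_that("entry point is translation-equivariant", {
  fem <- cylinder_femur()
  e0 <- entry_point(fem)
  t <- c(12.5, -3.25, 40)
  lm1 <- landmarks(fem$landmarks$gt_apex + t,
                   fem$landmarks$head_center + t,
                   sweep(fem$landmarks$shaft_axis_points, 2, t, "+"),
                   fem$landmarks$anterior_dir)
  fem1 <- femur_model(new_mesh(sweep(fem$mesh$vertices, 2, t, "+"),
                               fem$mesh$faces), lm1)
  expect_equal(as.numeric(entry_point(fem1)), as.numeric(e0) + t,
               tolerance = 1e-9)
})

test_that("a matched femur/nail pair converges to a near-exact fit", {
  p <- femur_params(anterior_bow_radius = Inf, neck_shaft_angle = 130,
                    anteversion = 10)
  f <- build_femur(p)
  s <- nail_spec(total_length = 200, proximal_diameter = 16,
                 distal_diameter = 10, bend_angle = 0, bend_station = 90,
                 ccd_angle = 130)
  nm <- build_nail_mesh(s)
  pl <- place_nail(f, nm, s)
  expect_true(pl$converged)
  expect_lt(pl$head_center_miss, 0.5)
  # deterministic: identical transform across runs
  pl2 <- place_nail(f, nm, s)
  expect_identical(rigid_matrix44(pl$transform),
                   rigid_matrix44(pl2$transform))
})

test_that("placement is rigid-equivariant", {
  p <- femur_params(anterior_bow_radius = Inf, neck_shaft_angle = 130)
  f <- build_femur(p)
  s <- make_pfna2_spec(200, 10)
  nm <- build_nail_mesh(s)
  pl0 <- place_nail(f, nm, s)
  set.seed(21)
  for (i in 1:3) {
    tr <- rigid_random(translation_scale = 60)
    lm1 <- landmarks(rigid_apply(tr, f$landmarks$gt_apex),
                     rigid_apply(tr, f$landmarks$head_center),
                     rigid_apply(tr, f$landmarks$shaft_axis_points),
                     as.numeric(tr$R %*% f$landmarks$anterior_dir))
    f1 <- femur_model(transform_mesh(f$mesh, tr), lm1)
    pl1 <- place_nail(f1, nm, s)
    expect_equal(rigid_matrix44(pl1$transform),
                 rigid_matrix44(rigid_compose(tr, pl0$transform)),
                 tolerance = 1e-6)
    expect_equal(pl1$insertion_depth, pl0$insertion_depth,
                 tolerance = 1e-6)
  }
})

test_that("a grossly mismatched head-element angle fails to converge", {
  p <- femur_params(anterior_bow_radius = Inf, neck_shaft_angle = 130)
  f <- build_femur(p)
  s <- nail_spec(total_length = 200, proximal_diameter = 16,
                 distal_diameter = 10, bend_angle = 0, bend_station = 90,
                 ccd_angle = 160)  # 30 degrees off the neck axis
  nm <- build_nail_mesh(s)
  pl <- place_nail(f, nm, s)
  expect_false(pl$converged)
  expect_gt(pl$head_center_miss, 1)
  # the reported best miss is the infimum: a 10x finer brute-force grid
  # finds nothing better
  e <- entry_point(f)
  fine <- solve_depth_rotation(f, nm, s, e,
                               grid = list(depth_step = 0.1,
                                           rot_step = 0.1))
  expect_equal(pl$head_center_miss, fine$miss, tolerance = 0.01)
})

test_that("the solver recovers an analytically constructed optimum", {
  fem <- cylinder_femur(R = 12, L = 300)
  s <- nail_spec(total_length = 150, proximal_diameter = 14,
                 distal_diameter = 10, bend_angle = 0, bend_station = 70,
                 ccd_angle = 130)
  nm <- build_nail_mesh(s)
  e <- entry_point(fem)
  e_f <- attr(e, "frame_point")
  # put the head centre exactly on the head-element line realized at
  # depth 17.3 mm, rotation 12 deg
  d_star <- 17.3
  phi_star <- 12
  R <- rot_z(phi_star)
  base <- as.numeric(R %*% nm$head_axis$base) + e_f + c(0, 0, d_star)
  dir <- as.numeric(R %*% nm$head_axis$dir)
  hc <- base + 55 * dir
  lm <- landmarks(fem$landmarks$gt_apex, hc,
                  fem$landmarks$shaft_axis_points, c(0, 1, 0))
  fem2 <- femur_model(fem$mesh, lm)
  sol <- solve_depth_rotation(fem2, nm, s, entry_point(fem2))
  expect_equal(sol$depth, d_star, tolerance = 0.05)
  expect_equal(sol$rotation, phi_star, tolerance = 0.05)
  expect_lt(sol$miss, 0.01)

  # oracle equivalence: 10x finer brute force lands on the same optimum
  fine <- solve_depth_rotation(fem2, nm, s, entry_point(fem2),
                               grid = list(depth_step = 0.1,
                                           rot_step = 0.1))
  expect_equal(fine$depth, sol$depth, tolerance = 0.02)
  expect_equal(fine$rotation, sol$rotation, tolerance = 0.02)
})

test_that("symmetric double minima break toward the documented side", {
  fem <- cylinder_femur(R = 12, L = 300)
  s <- nail_spec(total_length = 150, proximal_diameter = 14,
                 distal_diameter = 10, bend_angle = 0, bend_station = 70,
                 ccd_angle = 130)
  nm <- build_nail_mesh(s)
  # entry on the canal axis and a head centre in the x-z plane make the
  # objective exactly symmetric in the rotation; the solver must return
  # the smaller (negative) branch
  entry <- c(0, 0, 0)
  attr(entry, "frame_point") <- c(0, 0, 0)
  hc <- c(-60, 0, -20)
  lm <- landmarks(fem$landmarks$gt_apex, hc,
                  fem$landmarks$shaft_axis_points, c(0, 1, 0))
  fem2 <- femur_model(fem$mesh, lm)
  sol <- solve_depth_rotation(fem2, nm, s, entry)
  solm <- solve_depth_rotation(fem2, nm, s, entry)
  expect_identical(sol, solm)
  if (abs(sol$rotation) > 0.05) expect_lt(sol$rotation, 0)
})

test_that("an empty depth range is a geometry error", {
  fem <- cylinder_femur()
  s <- make_pfna2_spec(200, 10)
  nm <- build_nail_mesh(s)
  expect_error(solve_depth_rotation(fem, nm, s, entry_point(fem),
                                    grid = list(depth_range = c(10, 10))),
               class = "femfit_geometry_error")
})
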