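# Analytic constructions: nail cylinder r = 5 inside canal cylinder
# R = 6. Coaxial -> uniform clearance 1 mm; 2 mm offset -> closed-form
# max penetration offset + r - R = 1 mm.

test_that("coaxial cylinders give a uniform -1 mm field and no patches", {
  fem <- cylinder_femur(R = 6, L = 300)
  nl <- cylinder_nail(r = 5, L = 100)
  pl <- manual_placement(depth = 50)
  field <- penetration_field(fem, nl$mesh, pl, density = 4)
  expect_equal(max(abs(field$depth + 1)), 0, tolerance = 0.05)
  expect_length(extract_patches(field), 0)
})

test_that("a 2 mm offset produces one closed-form penetration patch", {
  fem <- cylinder_femur(R = 6, L = 300)
  nl <- cylinder_nail(r = 5, L = 100)
  pl <- manual_placement(depth = 50, y_off = 2)
  field <- penetration_field(fem, nl$mesh, pl, density = 4)
  expect_equal(max(field$depth), 1, tolerance = 0.05)
  pats <- extract_patches(field)
  expect_length(pats, 1)
  expect_equal(pats[[1]]$max_thickness, 1, tolerance = 0.05)
  # resolution stability: doubling density barely moves the maximum
  field2 <- penetration_field(fem, nl$mesh, pl, density = 8)
  expect_lt(abs(max(field2$depth) - max(field$depth)), 0.05)
})

test_that("disjoint contact zones form separate patches", {
  # two clusters of supra-threshold samples 30 mm apart, linkage 5 mm
  set.seed(2)
  pts <- rbind(cbind(runif(40, -1, 1), 6, seq(50, 54, length.out = 40)),
               cbind(runif(40, -1, 1), 6, seq(84, 88, length.out = 40)))
  f <- stub_field(pts, depth = rep(0.5, 80),
                  station = pts[, 3] - 40)
  pats <- extract_patches(f, threshold = 0.1, linkage_radius = 5)
  expect_length(pats, 2)
  one <- extract_patches(f, threshold = 0.1, linkage_radius = 40)
  expect_length(one, 1)
})

test_that("patch attributes summarize their members", {
  pts <- cbind(0, 6, 50:59)
  f <- stub_field(pts, depth = c(0.2, 0.4, 1.3, 0.9, 0.5, 0.2, 0.3, 0.4,
                                 0.2, 0.15), station = 10:19)
  p <- extract_patches(f, threshold = 0.1, linkage_radius = 2)[[1]]
  expect_equal(p$max_thickness, 1.3)
  expect_equal(p$axial_length, 9)
  expect_equal(p$centroid_station, mean(10:19))
  expect_equal(p$dist_to_gt_apex, sqrt(6^2 + mean(50:59)^2))
})

test_that("region classification is nail-relative with proximal ties", {
  s <- make_pfna2_spec(200, 10)  # bend station 90
  pl <- manual_placement(depth = 0)
  mkpatch <- function(st) structure(list(centroid_station = st,
                                         centroid = c(0, 6, st)),
                                    class = "impingement_patch")
  expect_equal(classify_region(mkpatch(20), pl, s), "proximal")
  expect_equal(classify_region(mkpatch(195), pl, s), "distal")
  expect_equal(classify_region(mkpatch(120), pl, s), "middle")
  # boundaries belong to the more proximal region
  expect_equal(classify_region(mkpatch(100), pl, s), "proximal")
  expect_equal(classify_region(mkpatch(150), pl, s), "middle")
})

test_that("side classification uses frame sectors with x-sector ties", {
  nl <- cylinder_nail(r = 5, L = 100)
  pl <- manual_placement(depth = 0)
  mkpatch <- function(dx, dy, st = 50)
    structure(list(centroid_station = st, centroid = c(dx, dy, st)),
              class = "impingement_patch")
  expect_equal(classify_side(mkpatch(0, 6), pl, nl$mesh), "anterior")
  expect_equal(classify_side(mkpatch(0, -6), pl, nl$mesh), "posterior")
  expect_equal(classify_side(mkpatch(6, 0), pl, nl$mesh), "lateral")
  expect_equal(classify_side(mkpatch(-6, 0), pl, nl$mesh), "medial")
  # exact 45-degree boundary resolves to the mediolateral sector
  expect_equal(classify_side(mkpatch(6, 6), pl, nl$mesh), "lateral")
  expect_error(classify_side(mkpatch(0, 0), pl, nl$mesh),
               class = "femfit_geometry_error")
})

test_that("protrusion reads the tip height above the GT plane", {
  nl <- cylinder_nail()
  expect_equal(protrusion_length(nl$mesh, manual_placement(-1.48)), 1.48)
  expect_equal(protrusion_length(nl$mesh, manual_placement(3)), 0)
})

test_that("anterior mid-shaft gap follows translation arithmetic", {
  fem <- cylinder_femur(R = 6, L = 300)
  nl <- cylinder_nail(r = 5, L = 100)
  g0 <- max_gap_middle(fem, nl$mesh, manual_placement(50))
  expect_equal(g0$max_gap, 1, tolerance = 0.05)
  expect_true(all(abs(g0$gaps$gap - 1) < 0.05))
  g1 <- max_gap_middle(fem, nl$mesh, manual_placement(50, y_off = 0.5))
  expect_equal(g0$max_gap - g1$max_gap, 0.5, tolerance = 0.05)
})

test_that("a chord-placed nail in a bowed canal gaps most mid-insertion", {
  # uniform canal (radius 6) on an 800 mm bow; nail laid along the chord
  # between the axis points at z = 60 and z = 240, touching both: the
  # anterior gap is radius difference + circular-segment sagitta, so it
  # peaks between the touch points and falls toward both ends
  p <- femur_params(anterior_bow_radius = 800, proximal_flare_radius = 6,
                    isthmus_radius = 6)
  f <- build_femur(p)
  s <- nail_spec(total_length = 200, proximal_diameter = 10,
                 distal_diameter = 10, bend_angle = 0, bend_station = 30,
                 ccd_angle = 130, head_station = 20)
  nm <- build_nail_mesh(s)
  Pa <- femfit:::canal_axis_eval(p, femfit:::canal_station_at_z(p, 60))$points[1, ]
  Pb <- femfit:::canal_axis_eval(p, femfit:::canal_station_at_z(p, 240))$points[1, ]
  dch <- (Pb - Pa) / sqrt(sum((Pb - Pa)^2))
  alpha <- -asin(dch[2]) * 180 / pi
  R <- rot_axis_test(c(1, 0, 0), alpha)
  tr_world <- rigid_transform(R, Pa - 10 * dch)
  fr_rigid <- rigid_transform(f$frame$axes, f$frame$origin)
  tr_frame <- rigid_compose(rigid_invert(fr_rigid), tr_world)
  pl <- structure(list(transform = tr_world, transform_frame = tr_frame,
                       entry_point = Pa, insertion_depth = 10,
                       rotation = 0, head_center_miss = 0,
                       converged = TRUE), class = "placement_result")
  g <- max_gap_middle(f, nm, pl)
  gaps <- g$gaps
  expect_gt(g$max_gap, gaps$gap[1] + 0.5)
  expect_gt(g$max_gap, gaps$gap[nrow(gaps)] + 0.5)
  # closed form: peak = (R - r) + chord sagitta
  sag <- 800 - sqrt(800^2 - 90^2)
  expect_equal(g$max_gap, 1 + sag, tolerance = 0.15)
})

test_that("the assembled report composes its parts consistently", {
  fem <- cylinder_femur(R = 6, L = 300)
  nl <- cylinder_nail(r = 5, L = 100)
  rep0 <- compute_fitness(fem, nl$mesh, nl$spec, manual_placement(50))
  expect_false(any(rep0$impinged))
  expect_equal(rep0$D_protrusion, 0)
  expect_equal(rep0$G_max_gap_middle, 1, tolerance = 0.05)
  expect_true(is.na(rep0$A_max_thickness_proximal))

  rep2 <- compute_fitness(fem, nl$mesh, nl$spec,
                          manual_placement(50, y_off = 2))
  field <- penetration_field(fem, nl$mesh, manual_placement(50, y_off = 2),
                             density = 4)
  keep <- field$points[, 3] >= 15
  pats <- extract_patches(stub_field(field$points[keep, , drop = FALSE],
                                     field$depth[keep],
                                     field$station[keep]))
  expect_equal(rep2$A_max_thickness_proximal,
               max(vapply(pats, function(p) p$max_thickness, 0)))
  expect_true(rep2$impinged[["proximal"]])
  expect_equal(unname(rep2$side["proximal"]), "anterior")
})

test_that("fitness reports round-trip through JSON", {
  fem <- cylinder_femur(R = 6, L = 300)
  nl <- cylinder_nail(r = 5, L = 100)
  rep <- compute_fitness(fem, nl$mesh, nl$spec,
                         manual_placement(50, y_off = 2))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_fitness_report(rep, tmp)
  back <- read_fitness_report(tmp)
  for (f in c("A_max_thickness_proximal", "B_length_proximal",
              "C_dist_proximal", "D_protrusion", "E_thickness_middle",
              "G_max_gap_middle", "H_length_distal"))
    expect_equal(back[[f]], rep[[f]], tolerance = 1e-12)
  expect_equal(unname(back$impinged), unname(rep$impinged))
})

test_that("signed depth agrees with analytic containment", {
  fem <- cylinder_femur(R = 6, L = 300, k = 96L)
  set.seed(17)
  pts <- cbind(runif(1000, -9, 9), runif(1000, -9, 9),
               runif(1000, 5, 295))
  d <- mesh_signed_distance(fem$mesh, pts)
  rad <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  clear <- abs(rad - 6) > 0.05  # skip the tessellation shell
  expect_true(all((d[clear] < 0) == (rad[clear] < 6)))
})
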