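test_that("design constructors carry the published design facts", {
  s <- make_pfna2_spec(240, 10)
  expect_equal(s$bend_angle, 5)
  expect_equal(s$proximal_diameter, 16.5)
  expect_equal(s$proximal_section, "flat_lateral")

  leg <- make_pfna_legacy_spec(240, 10)
  expect_equal(leg$bend_angle, 6)
  expect_equal(leg$proximal_diameter, 17)
  expect_equal(leg$proximal_section, "circular")
  expect_equal(leg$proximal_diameter - s$proximal_diameter, 0.5)

  it <- make_intertan_spec(200, 10)
  expect_equal(it$proximal_section, "trapezoidal")
  expect_true(it$twin_screws)
  it2 <- make_intertan_spec(200, 10, proximal_diameter = 15)
  expect_equal(it2$proximal_diameter, 15)
})

test_that("invalid dimensions are rejected", {
  expect_error(make_pfna2_spec(240, -1), class = "femfit_invalid_spec_error")
  expect_error(make_pfna_legacy_spec(0, 10),
               class = "femfit_invalid_spec_error")
  expect_error(nail_spec(total_length = 100, proximal_diameter = 8,
                         distal_diameter = 10, bend_angle = 0,
                         bend_station = 50, ccd_angle = 130),
               class = "femfit_invalid_spec_error")
  expect_error(nail_spec(total_length = 100, proximal_diameter = 10,
                         distal_diameter = 10, bend_angle = 20,
                         bend_station = 50, ccd_angle = 130),
               class = "femfit_invalid_spec_error")
  # section-specific fields must be zero unless the section matches
  expect_error(nail_spec(total_length = 100, proximal_diameter = 10,
                         distal_diameter = 10, bend_angle = 0,
                         bend_station = 50, ccd_angle = 130,
                         proximal_section = "circular", flat_depth = 1),
               class = "femfit_invalid_spec_error")
})

test_that("a degenerate flat section fails mesh construction", {
  s <- nail_spec(total_length = 100, proximal_diameter = 10,
                 distal_diameter = 8, bend_angle = 0, bend_station = 50,
                 ccd_angle = 130, proximal_section = "flat_lateral",
                 flat_depth = 6)
  expect_error(build_nail_mesh(s), class = "femfit_geometry_error")
})

test_that("a straight nail has a collinear axis", {
  s <- nail_spec(total_length = 150, proximal_diameter = 12,
                 distal_diameter = 10, bend_angle = 0, bend_station = 70,
                 ccd_angle = 130)
  nm <- build_nail_mesh(s)
  dev <- apply(nm$axis$points[, 1:2, drop = FALSE], 1,
               function(p) sqrt(sum(p^2)))
  expect_lt(max(dev), 1e-6)
  expect_equal(max(nm$axis$station), 150, tolerance = 0.1)
})

test_that("the built surface realizes the spec bend angle", {
  for (mk in list(make_pfna2_spec, make_pfna_legacy_spec)) {
    s <- mk(240, 10)
    nm <- build_nail_mesh(s)
    st <- nm$axis$station
    arc_half <- s$bend_radius * femfit:::deg2rad(s$bend_angle) / 2
    prox <- nm$axis$points[st < s$bend_station - arc_half - 1, ]
    dist <- nm$axis$points[st > s$bend_station + arc_half + 1, ]
    fitdir <- function(p) {
      sv <- svd(sweep(p, 2, colMeans(p)), nu = 0, nv = 1)
      as.numeric(sv$v[, 1])
    }
    ang <- acos(abs(sum(fitdir(prox) * fitdir(dist)))) * 180 / pi
    expect_equal(ang, s$bend_angle, tolerance = 0.1)
  }
})

test_that("cross-section girth converges to pi*d with sampling", {
  s <- nail_spec(total_length = 100, proximal_diameter = 10,
                 distal_diameter = 10, bend_angle = 0, bend_station = 50,
                 ccd_angle = 130)
  girth_at <- function(k) {
    nm <- build_nail_mesh(s, k, 2)
    ring <- nm$surface$vertices[abs(nm$station - 50) < 1e-9 &
                                  seq_along(nm$station) <=
                                  length(nm$station) - 2, , drop = FALSE]
    ring <- ring[order(atan2(ring[, 2], ring[, 1])), ]
    sum(sqrt(rowSums((ring - ring[c(2:nrow(ring), 1), ])^2)))
  }
  errs <- abs(vapply(c(16L, 32L, 64L), girth_at, 0) - pi * 10)
  expect_lt(errs[3] / (pi * 10), 0.01)       # 64 samples within 1 %
  expect_true(all(diff(errs) < 0))           # monotone improvement
})

test_that("straight circular nail volume matches pi r^2 L within 2%", {
  s <- nail_spec(total_length = 120, proximal_diameter = 9,
                 distal_diameter = 9, bend_angle = 0, bend_station = 60,
                 ccd_angle = 130)
  nm <- build_nail_mesh(s)
  expect_lt(abs(mesh_volume(nm$surface) / (pi * 4.5^2 * 120) - 1), 0.02)
})

test_that("mesh construction is deterministic", {
  s <- make_pfna2_spec(200, 10)
  a <- build_nail_mesh(s)
  b <- build_nail_mesh(s)
  expect_identical(a$surface$vertices, b$surface$vertices)
  expect_identical(a$surface$faces, b$surface$faces)
})

test_that("trapezoidal sections honour the configured AP depth", {
  it <- make_intertan_spec(200, 10)
  nm <- build_nail_mesh(it, 64L)
  ring <- nm$surface$vertices[nm$station < it$bend_station -
                                it$taper_length - 1, , drop = FALSE]
  expect_equal(diff(range(ring[, 2])), it$trapezoid_ap_depth,
               tolerance = 0.1)
  expect_equal(diff(range(ring[, 1])), it$proximal_diameter,
               tolerance = 0.1)
})

test_that("nail specs round-trip through YAML config entries", {
  s <- make_intertan_spec(200, 10)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_nail_spec(s, tmp)
  back <- read_nail_spec(tmp)
  expect_equal(unclass(back), unclass(s))
})
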