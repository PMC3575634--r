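# Shared fixtures: analytic cylinder constructions with closed-form
# penetration behaviour, and small helpers for hand-built placements
# and reports.

# straight circular tube of radius r built through the nail sweep
cylinder_mesh <- function(r, L, k = 64L, step = 2) {
  spec <- nail_spec(total_length = L, proximal_diameter = 2 * r,
                    distal_diameter = 2 * r, bend_angle = 0,
                    bend_station = L / 2, ccd_angle = 130,
                    head_station = L / 4)
  build_nail_mesh(spec, k, step)$surface
}

# canal-cylinder femur: radius R, length L along +z, GT apex at origin
cylinder_femur <- function(R = 6, L = 300, k = 64L) {
  mesh <- cylinder_mesh(R, L, k)
  lm <- landmarks(gt_apex = c(0, 0, 0), head_center = c(-40, 0, 30),
                  shaft_axis_points = cbind(0, 0, seq(100, 250, by = 25)),
                  anterior_dir = c(0, 1, 0))
  femur_model(mesh, lm, id = "cylinder")
}

# plain cylindrical "nail" of radius r, length L
cylinder_nail <- function(r = 5, L = 100, k = 64L) {
  spec <- nail_spec(total_length = L, proximal_diameter = 2 * r,
                    distal_diameter = 2 * r, bend_angle = 0,
                    bend_station = L / 2, ccd_angle = 130)
  list(spec = spec, mesh = build_nail_mesh(spec, k, 2))
}

# hand-built placement: nail axis parallel to +z, tip at (x, y, depth)
manual_placement <- function(depth, x_off = 0, y_off = 0, rot = 0) {
  tr <- rigid_transform(rot_z(rot), c(x_off, y_off, depth))
  structure(list(transform = tr, transform_frame = tr,
                 entry_point = c(x_off, y_off, 0),
                 insertion_depth = depth, rotation = rot,
                 head_center_miss = 0, converged = TRUE),
            class = "placement_result")
}

# minimal hand-built fitness report for cohort-level tests
stub_report <- function(femur_id, nail_id, impinged, values = list()) {
  defaults <- list(A_max_thickness_proximal = NA_real_,
                   B_length_proximal = NA_real_, C_dist_proximal = NA_real_,
                   D_protrusion = 0, E_thickness_middle = NA_real_,
                   E_length_middle = NA_real_, F_dist_middle = NA_real_,
                   G_max_gap_middle = 1, G_gap_station = 100,
                   G_max_clearance = 1, H_length_distal = NA_real_,
                   H_thickness_distal = NA_real_)
  fields <- utils::modifyList(defaults, values)
  structure(c(list(femur_id = femur_id, nail_id = nail_id), fields,
              list(impinged = impinged,
                   side = c(proximal = NA_character_,
                            middle = NA_character_,
                            distal = NA_character_),
                   n_patches = c(proximal = 0L, middle = 0L, distal = 0L),
                   insertion_depth = 2, head_center_miss = 0.1,
                   converged = TRUE,
                   opts = list(density = 4, threshold = 0.1,
                               linkage_radius = 2, exclude_entry_mm = 15,
                               gap_step = 2))),
            class = "fitness_report")
}

# hand-built penetration field (for patch-linking tests)
stub_field <- function(points, depth, station) {
  structure(list(points = points, depth = depth, station = station,
                 theta = rep(0, length(depth)), density = 4),
            class = "penetration_field")
}

impinged_vec <- function(prox = FALSE, mid = FALSE, dist = FALSE) {
  c(proximal = prox, middle = mid, distal = dist)
}

unitize_test <- function(v) v / sqrt(sum(v^2))

# Rodrigues rotation about a unit axis, degrees
rot_axis_test <- function(axis, angle_deg) {
  u <- unitize_test(axis)
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), nrow = 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}
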